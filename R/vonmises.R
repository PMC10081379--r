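#' Von Mises log-density
#'
#' @param theta Angles, radians.
#' @param mu Mean direction, radians.
#' @param kappa Concentration (> 0).
#' @param log Return the log-density (default) or the density.
#' @return (Log-)density values.
#' @export
dvonmises <- function(theta, mu, kappa, log = TRUE) {
  ld <- kappa * cos(theta - mu) -
    log(2 * pi) - (log(besselI(kappa, 0, expon.scaled = TRUE)) + kappa)
  if (log) ld else exp(ld)
}

#' Sample from a von Mises distribution (Best-Fisher rejection)
#'
#' @param n Number of draws.
#' @param mu Mean direction, radians (recycled).
#' @param kappa Concentration (>= 0; 0 gives the uniform circle).
#' @return Angles in radians, wrapped to `(-pi, pi]`.
#' @export
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-8) {
    return(stats::runif(n, -pi, pi))
  }
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1
  while (i <= n) {
    u1 <- stats::runif(1); u2 <- stats::runif(1); u3 <- stats::runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u2 > 0 || log(cc / u2) + 1 - cc >= 0) {
      out[i] <- sign(u3 - 0.5) * acos(f)
      i <- i + 1
    }
  }
  wrap_pi(out + rep_len(mu, n))
}

wrap_pi <- function(x) atan2(sin(x), cos(x))

# negative log posterior of the circular regression; p = (b1, b2, logk, logg)
vm_nlp <- function(p, y, x) {
  if (any(!is.finite(p)) || p[3] > 20 || p[4] > 20) return(1e10)
  b1 <- p[1]; b2 <- p[2]; kappa <- exp(p[3]); gamma <- exp(p[4])
  mu <- gamma * x + atan2(b2, b1)
  ll <- sum(dvonmises(y, mu, kappa, log = TRUE))
  if (!is.finite(ll)) return(1e10)
  lp <- stats::dnorm(b1, 0, 0.5, log = TRUE) +
    stats::dnorm(b2, 0, 0.5, log = TRUE) +
    stats::dnorm(p[3], 0, 1, log = TRUE) +
    stats::dnorm(p[4], 0, 0.5, log = TRUE)
  -(ll + lp)
}

#' Bayesian circular regression of gene angle on origin distance
#'
#' Fits the wrapped linear relationship between the gene angle `theta_g`
#' and origin distance `D`, whose periodicity with respect to `D` is
#' unknown (overlapping replication rounds make genes at multiple origin
#' distances share a gene angle). With both variables standardized to
#' `[-pi, pi]`, the model is
#' `theta_g ~ vonMises(A, kappa)` with
#' `cos(A) = b1 cos(gamma D) - b2 sin(gamma D)` and
#' `sin(A) = b2 cos(gamma D) + b1 sin(gamma D)`
#' (equivalently `A = gamma D + atan2(b2, b1)`), under priors
#' `b1, b2 ~ N(0, 0.5)`, `log kappa ~ N(0, 1)`, `log gamma ~ N(0, 0.5)`;
#' the lognormal prior keeps the gradient `gamma` positive (angle
#' orientation is fixed upstream in [gene_angle()]).
#'
#' Inference is MAP with multiple starts over `log gamma` (the posterior is
#' multimodal in the wrapping frequency) followed by a Laplace
#' approximation; posterior draws are sampled from the resulting Gaussian.
#' Fitted gene angles `theta_g_pred` are circular means of the per-draw
#' predictions, `atan2(mean(sin), mean(cos))`.
#'
#' @param theta_g Gene angles, degrees in `[0, 360)`.
#' @param D Origin distances, bp (standardized internally by the linear map
#'   `[0, max(D)] -> [-pi, pi]`).
#' @param n_draws Posterior draws from the Laplace approximation.
#' @param n_starts Multi-start grid size over `log gamma`.
#' @param seed Seed for the posterior draws.
#' @return A `replication_fit` object: posterior `draws` tibble
#'   (`beta1`, `beta2`, `kappa`, `gamma`), MAP estimates, posterior means
#'   `gamma_mean` / `kappa_mean`, per-gene `theta_g_pred` (degrees),
#'   `D_max` (bp), and the inference `method` label.
#' @export
fit_gene_angle_regression <- function(theta_g, D, n_draws = 2000,
                                      n_starts = 7, seed = 1) {
  ok <- is.finite(theta_g) & is.finite(D)
  theta_g <- theta_g[ok]; D <- D[ok]
  n <- length(theta_g)
  if (n < 50) stop("need at least 50 genes with angles and distances",
                   call. = FALSE)
  if (diff(range(D)) < 0.5 * max(D)) {
    stop("origin distances must span at least half their range",
         call. = FALSE)
  }
  D_max <- max(D)
  x <- D / D_max * 2 * pi - pi
  y <- deg2rad(theta_g) - pi          # [0, 360) deg -> [-pi, pi)
  starts <- lapply(seq(log(0.4), log(4), length.out = n_starts),
                   function(lg) c(0.5, 0, log(5), lg))
  fits <- lapply(starts, function(p0) {
    tryCatch(stats::optim(p0, vm_nlp, y = y, x = x, method = "BFGS",
                          control = list(maxit = 500)),
             error = function(e) NULL)
  })
  fits <- Filter(function(f) !is.null(f) && is.finite(f$value), fits)
  if (!length(fits)) stop("circular regression failed to converge",
                          call. = FALSE)
  best <- fits[[which.min(vapply(fits, `[[`, 0, "value"))]]
  hess <- stats::optimHess(best$par, vm_nlp, y = y, x = x)
  cov <- tryCatch(solve(hess), error = function(e) NULL)
  if (is.null(cov) || any(!is.finite(cov)) || any(diag(cov) <= 0)) {
    # near-singular curvature: fall back to a tiny jitter around the MAP
    cov <- diag(1e-8, 4)
  }
  set.seed(seed)
  ch <- chol((cov + t(cov)) / 2)
  draws <- matrix(stats::rnorm(n_draws * 4), n_draws, 4) %*% ch
  draws <- sweep(draws, 2, best$par, "+")
  draws_tbl <- tibble::tibble(beta1 = draws[, 1], beta2 = draws[, 2],
                              kappa = exp(draws[, 3]),
                              gamma = exp(draws[, 4]))
  # per-gene circular mean of posterior predicted angles
  phi0 <- atan2(draws[, 2], draws[, 1])
  pred_sin <- pred_cos <- numeric(n)
  for (s in seq_len(n_draws)) {
    a <- draws_tbl$gamma[s] * x + phi0[s]
    pred_sin <- pred_sin + sin(a)
    pred_cos <- pred_cos + cos(a)
  }
  pred_std <- atan2(pred_sin / n_draws, pred_cos / n_draws)
  structure(list(
    draws = draws_tbl,
    map = stats::setNames(c(best$par[1], best$par[2], exp(best$par[3]),
                            exp(best$par[4])),
                          c("beta1", "beta2", "kappa", "gamma")),
    gamma_mean = mean(draws_tbl$gamma),
    kappa_mean = mean(draws_tbl$kappa),
    theta_g_pred = wrap_deg(rad2deg(pred_std + pi)),
    D = D, D_max = D_max, n_genes = n,
    logpost = -best$value, convergence = best$convergence,
    method = "map_laplace"
  ), class = "replication_fit")
}

#' Predicted gene angle at new origin distances
#'
#' Posterior-mean (circular) prediction of `theta_g` for arbitrary origin
#' distances under a fitted replication model.
#'
#' @param fit A `replication_fit`.
#' @param D Origin distances, bp.
#' @return Angles in degrees `[0, 360)`.
#' @export
predict_gene_angle <- function(fit, D) {
  x <- D / fit$D_max * 2 * pi - pi
  phi0 <- atan2(fit$draws$beta2, fit$draws$beta1)
  a <- outer(fit$draws$gamma, x) + phi0          # draws x newD
  wrap_deg(rad2deg(atan2(colMeans(sin(a)), colMeans(cos(a))) + pi))
}

#' @export
print.replication_fit <- function(x, ...) {
  cat(sprintf("Von Mises gene angle ~ origin distance fit (%s, %d genes)\n",
              x$method, x$n_genes))
  cat(sprintf("  gamma = %.3f (posterior mean), kappa = %.1f\n",
              x$gamma_mean, x$kappa_mean))
  cat(sprintf("  D_max = %.3g bp\n", x$D_max))
  invisible(x)
}

#' Replication pattern statistics from the fitted gradient
#'
#' Converts the standardized gradient `gamma` into interpretable
#' replication statistics: the gradient in degrees per Mb
#' (`gamma * 360 / D_max`), the overlap fraction `1 - 1/gamma` (the
#' fraction of a replication round already underway when the previous one
#' finishes), and the average DNA polymerase speed
#' `v_DNAP = 6e6 / (t_d * gamma_deg_per_Mb)` in bp/s.
#'
#' @param fit A `replication_fit`.
#' @param t_d Doubling time, minutes.
#' @param origin_ter_distance_mb Origin-terminus distance in Mb used for
#'   the unit conversion; defaults to the fitted `D_max`.
#' @return One-row tibble: `gamma`, `gamma_deg_per_mb`, `overlap_fraction`,
#'   `v_dnap_bp_s`, plus 95% posterior intervals for `gamma` and `v_dnap`.
#' @export
replication_stats <- function(fit, t_d,
                              origin_ter_distance_mb = fit$D_max / 1e6) {
  g <- fit$gamma_mean
  if (g <= 0) stop("gamma must be positive", call. = FALSE)
  g_deg_mb <- g * 360 / origin_ter_distance_mb
  g_draws <- fit$draws$gamma * 360 / origin_ter_distance_mb
  v_draws <- 6e6 / (t_d * g_draws)
  tibble::tibble(
    gamma = g,
    gamma_deg_per_mb = g_deg_mb,
    overlap_fraction = 1 - 1 / g,
    v_dnap_bp_s = 6e6 / (t_d * g_deg_mb),
    gamma_lo = stats::quantile(fit$draws$gamma, 0.025),
    gamma_hi = stats::quantile(fit$draws$gamma, 0.975),
    v_dnap_lo = stats::quantile(v_draws, 0.025),
    v_dnap_hi = stats::quantile(v_draws, 0.975)
  )
}
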