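#' Least-squares sinusoid fit y = A + B sin(x + C)
#'
#' Linear in `(A, B cos C, B sin C)` via OLS on `sin(x)` and `cos(x)`;
#' `B` is normalized positive and `C` wrapped to `[0, 2 pi)`.
#'
#' @param x Angles in radians.
#' @param y Response.
#' @return Tibble with `A`, `B`, `C` (radians) and `r_squared`.
#' @export
fit_sinusoid <- function(x, y) {
  fit <- stats::lm(y ~ sin(x) + cos(x))
  co <- stats::coef(fit)
  B <- sqrt(co[2]^2 + co[3]^2)
  C <- atan2(co[3], co[2]) %% (2 * pi)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - sum(stats::residuals(fit)^2) / tss else NA_real_
  tibble::tibble(A = unname(co[1]), B = unname(B), C = unname(C),
                 r_squared = r2)
}

# centered moving average over a ranked covariate: each bin holds
# `frac` of the cells, adjacent bins shift by one cell
rolling_bins <- function(x, y, frac = 0.1) {
  ord <- order(x)
  x <- x[ord]; y <- y[ord]
  w <- max(2L, round(frac * length(x)))
  n_out <- length(x) - w + 1L
  cx <- cumsum(c(0, x)); cy <- cumsum(c(0, y))
  i <- seq_len(n_out)
  tibble::tibble(x = (cx[i + w] - cx[i]) / w, y = (cy[i + w] - cy[i]) / w)
}

#' Align smFISH and scRNA-seq cell-cycle signals by sinusoid phase
#'
#' Maps cell length to a cycle parameter `beta = 2 pi (L / L0 - 1)`, fits
#' `concentration = A + B sin(beta + C)` to the (binned) smFISH data and
#' `fraction = a + b sin(theta_c + c)` to the scRNA-seq profile, and reads
#' off the phase difference `phi = C - c`. `phi` (in degrees) estimates the
#' cell angle at birth, and the cell length at which *oriC* replicates
#' (`theta_c = 0`) is `L(0) = L0 (2 - phi / (2 pi))`.
#'
#' @param smfish_table Data frame with `length_um` and a concentration
#'   column (`mrna_conc`, or mRNA count divided by volume upstream).
#' @param scrnaseq_profile Data frame with `theta_c` (degrees) and
#'   `mrna_fraction`.
#' @param L0 Birth length, micrometres.
#' @param bin_frac Moving-average window as a fraction of cells for the
#'   smFISH fit (bins shift by one cell); set `NULL` to fit raw cells.
#' @param min_amplitude Amplitudes `|B|`, `|b|` below this are treated as an
#'   undefined phase and raise an error.
#' @return A `phase_alignment` object: the two sinusoid fits, `phi_rad`,
#'   `phi_deg` (cell angle at birth), and `L_at_theta0` (micrometres).
#' @export
sinusoid_phase_alignment <- function(smfish_table, scrnaseq_profile, L0,
                                     bin_frac = 0.1, min_amplitude = 1e-8) {
  sm <- tibble::as_tibble(smfish_table)
  sc <- tibble::as_tibble(scrnaseq_profile)
  beta <- 2 * pi * (sm$length_um / L0 - 1)
  conc <- sm$mrna_conc
  if (!is.null(bin_frac)) {
    b <- rolling_bins(beta, conc, frac = bin_frac)
    beta <- b$x; conc <- b$y
  }
  fish <- fit_sinusoid(beta, conc)
  seq_fit <- fit_sinusoid(deg2rad(sc$theta_c), sc$mrna_fraction)
  if (fish$B < min_amplitude || seq_fit$B < min_amplitude) {
    stop("sinusoid amplitude below noise floor: phase undefined",
         call. = FALSE)
  }
  phi <- (fish$C - seq_fit$C) %% (2 * pi)
  structure(list(smfish = fish, scrnaseq = seq_fit, L0 = L0,
                 phi_rad = phi, phi_deg = rad2deg(phi),
                 L_at_theta0 = length_at_initiation(L0, rad2deg(phi))),
            class = "phase_alignment")
}

#' Cell length at replication initiation from the birth phase shift
#'
#' `L(theta_c = 0) = L0 * (2 - phi / 360)` with `phi` the smFISH/scRNA-seq
#' phase difference in degrees (the cell angle at birth).
#'
#' @param L0 Birth length, micrometres.
#' @param phi_deg Phase difference, degrees.
#' @return Length in micrometres.
#' @export
length_at_initiation <- function(L0, phi_deg) {
  L0 * (2 - phi_deg / 360)
}

#' @export
print.phase_alignment <- function(x, ...) {
  cat("smFISH / scRNA-seq sinusoid phase alignment\n")
  cat(sprintf("  phi = %.1f deg (cell angle at birth)\n", x$phi_deg))
  cat(sprintf("  L(theta_c = 0) = %.2f um (L0 = %.2f um)\n",
              x$L_at_theta0, x$L0))
  invisible(x)
}

#' Two-Hill gene-dosage model of mRNA number versus cell length
#'
#' Expected mRNA per cell when expression doubles at each of two successive
#' replications of the locus:
#' `mRNA(L) = c (1 + 1/(1 + (Lr/L)^k) + 2/(1 + (n2 Lr/L)^k))`,
#' with `c` the baseline, `Lr` the length at which the gene replicates, `k`
#' the step steepness, and `n2` the fold change in length between successive
#' replication rounds. Plateaus are `c` for `L << Lr` and `4c` for
#' `L >> n2 Lr`.
#'
#' @param L Cell length, micrometres.
#' @param c_base,Lr,k,n2 Model parameters (all positive).
#' @return Expected mRNA number.
#' @export
hill_dosage_mean <- function(L, c_base, Lr, k, n2) {
  c_base * (1 + 1 / (1 + (Lr / L)^k) + 2 / (1 + (n2 * Lr / L)^k))
}

#' Fit the two-Hill dosage model to single-cell mRNA counts
#'
#' Bins counts by cell length with a one-cell-shift moving average (each bin
#' holding `bin_frac` of cells), then fits [hill_dosage_mean()] by
#' Levenberg-Marquardt nonlinear least squares.
#'
#' @param lengths Cell lengths, micrometres.
#' @param mrna_counts Per-cell mRNA counts.
#' @param bin_frac Moving-bin width as fraction of cells (default 0.05);
#'   `NULL` fits raw cells.
#' @param start Optional named start values for `c_base`, `Lr`, `k`, `n2`.
#' @return A `hill_fit` object: tibble `coef` (estimates + SEs), `r_squared`
#'   and the underlying `nls` fit.
#' @export
fit_hill_dosage <- function(lengths, mrna_counts, bin_frac = 0.05,
                            start = NULL) {
  L <- lengths; y <- mrna_counts
  if (!is.null(bin_frac)) {
    b <- rolling_bins(L, y, frac = bin_frac)
    L <- b$x; y <- b$y
  }
  if (is.null(start)) {
    start <- list(c_base = max(min(y), 1e-3), Lr = stats::median(L), k = 8,
                  n2 = 2)
  }
  fit <- minpack.lm::nlsLM(
    y ~ hill_dosage_mean(L, c_base, Lr, k, n2),
    start = start,
    lower = c(1e-6, 1e-6, 0.5, 1.01),
    upper = c(Inf, Inf, 200, 20),
    control = minpack.lm::nls.lm.control(maxiter = 500)
  )
  est <- summary(fit)$coefficients
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
  structure(list(
    coef = tibble::tibble(term = rownames(est), estimate = est[, 1],
                          std_error = est[, 2]),
    r_squared = r2, fit = fit, n_bins = length(y)
  ), class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat("Two-Hill dosage fit\n")
  print(x$coef)
  cat(sprintf("  r^2 = %.3f over %d bins\n", x$r_squared, x$n_bins))
  invisible(x)
}

# the DNA content model is valid only in the overlapping-replication regime
check_dna_regime <- function(T, T_C, T_D) {
  if (!(T > T_D)) {
    stop("DNA content regime violated: need T > T_D (got T = ", T,
         ", T_D = ", T_D, ")", call. = FALSE)
  }
  if (!(T > T_C / 2)) {
    stop("DNA content regime violated: need T > T_C / 2 (got T = ", T,
         ", T_C / 2 = ", T_C / 2, ")", call. = FALSE)
  }
  if (!(T < (T_C + T_D) / 2)) {
    stop("DNA content regime violated: need T < (T_C + T_D) / 2 (got T = ",
         T, ", (T_C + T_D) / 2 = ", (T_C + T_D) / 2, ")", call. = FALSE)
  }
  invisible(TRUE)
}

#' Piecewise-linear DNA content across the cell cycle
#'
#' Genome equivalents `g(t)` for a cell of age `t` in the regime
#' `max(T_D, T_C / 2) < T < (T_C + T_D) / 2`, where one replication round
#' ends at age `T - T_D` and the next initiates at age `3T - T_C - T_D`:
#' three linear branches with slopes `3/T_C`, `2/T_C` and `6/T_C`
#' (DNA production rates in ratio 3:2:6, matching 3, 2 and 6 active
#' replication fork pairs). `g` is continuous and `g(T) = 2 g(0)`.
#'
#' @param t Cell age, minutes, in `[0, T)`.
#' @param T Doubling time, minutes.
#' @param T_C Replication (C) period, minutes.
#' @param T_D Termination-to-division (D) period, minutes.
#' @return Genome equivalents; attribute `"fork_pairs"` gives the number of
#'   active fork pairs per evaluated age.
#' @export
dna_content <- function(t, T, T_C, T_D) {
  check_dna_regime(T, T_C, T_D)
  if (any(t < 0 | t >= T)) stop("t must lie in [0, T)", call. = FALSE)
  b1 <- T - T_D
  b2 <- 3 * T - T_C - T_D
  g <- ifelse(t < b1, 4 - 5 * T / T_C + 3 * T_D / T_C + 3 * t / T_C,
       ifelse(t < b2, 4 - 4 * T / T_C + 2 * T_D / T_C + 2 * t / T_C,
                      8 - 16 * T / T_C + 6 * T_D / T_C + 6 * t / T_C))
  attr(g, "fork_pairs") <- ifelse(t < b1, 3L, ifelse(t < b2, 2L, 6L))
  g
}

#' Fit the DNA content model to single-cell DAPI signal versus length
#'
#' Maps cell length to age through exponential elongation,
#' `t / T = log2(L / L_birth)` within the two-fold length window
#' `[L_birth, 2 L_birth]`, and fits `scale * g(t)` (see [dna_content()]) by
#' least squares over the dimensionless parameters `rc = T_C / T` and
#' `rd = T_D / T` with box constraints enforcing the model regime
#' (`1 < rc < 2`, `0 < rd < 1`, `rc + rd > 2`); the scale (fluorescence per
#' genome equivalent) is profiled out analytically. Fits whose parameters
#' land on the constraint boundary, or with `r^2 < r2_min`, are discarded.
#'
#' @param lengths Cell lengths, micrometres.
#' @param dapi_signal Per-cell integrated DAPI fluorescence (a.u.).
#' @param L_birth Lower edge of the two-fold length window; when `NULL` the
#'   window `[Lb, 2 Lb]` containing the most cells is found by grid search.
#' @param T Doubling time in minutes, if known, to report `T_C`, `T_D` in
#'   minutes.
#' @param r2_min Minimum r-squared to accept the fit (default 0.4).
#' @return A `dna_fit` object: `rc`, `rd`, `scale`, `r_squared`,
#'   `L_birth`, `L_at_oric` (length when *oriC* replicates,
#'   `L_birth * 2^(3 - rc - rd)`), optional `T_C`/`T_D`, `discarded` flag
#'   with reason.
#' @export
fit_dapi_profile <- function(lengths, dapi_signal, L_birth = NULL, T = NULL,
                             r2_min = 0.4) {
  ok <- is.finite(lengths) & is.finite(dapi_signal)
  lengths <- lengths[ok]; dapi_signal <- dapi_signal[ok]
  if (is.null(L_birth)) {
    grid <- stats::quantile(lengths, seq(0.01, 0.5, by = 0.01))
    counts <- vapply(grid, function(lb)
      sum(lengths >= lb & lengths <= 2 * lb), 0L)
    L_birth <- unname(grid[which.max(counts)])
  }
  win <- lengths >= L_birth & lengths <= 2 * L_birth
  if (sum(win) < 20) stop("too few cells in the two-fold window", call. = FALSE)
  tau <- log2(lengths[win] / L_birth)       # age as a fraction of T
  y <- dapi_signal[win]
  g_tau <- function(rc, rd) {
    b1 <- 1 - rd; b2 <- 3 - rc - rd
    ifelse(tau < b1, 4 + (-5 + 3 * rd + 3 * tau) / rc,
    ifelse(tau < b2, 4 + (-4 + 2 * rd + 2 * tau) / rc,
                     8 + (-16 + 6 * rd + 6 * tau) / rc))
  }
  obj <- function(p) {
    rc <- p[1]; rd <- p[2]
    if (rc + rd <= 2 + 1e-9) return(1e12)
    g <- g_tau(rc, rd)
    sc <- sum(y * g) / sum(g * g)
    sum((y - sc * g)^2)
  }
  lower <- c(1.001, 0.001); upper <- c(1.999, 0.999)
  starts <- list(c(1.6, 0.75), c(1.3, 0.9), c(1.9, 0.4), c(1.45, 0.65))
  opts <- lapply(starts, function(s)
    stats::optim(s, obj, method = "L-BFGS-B", lower = lower, upper = upper))
  opt <- opts[[which.min(vapply(opts, `[[`, 0, "value"))]]
  rc <- opt$par[1]; rd <- opt$par[2]
  g <- g_tau(rc, rd)
  sc <- sum(y * g) / sum(g * g)
  r2 <- 1 - sum((y - sc * g)^2) / sum((y - mean(y))^2)
  tol <- 1e-3
  at_bound <- rc < lower[1] + tol || rc > upper[1] - tol ||
    rd < lower[2] + tol || rd > upper[2] - tol || (rc + rd) < 2 + tol
  reason <- if (at_bound) "parameters at constraint boundary"
            else if (r2 < r2_min) sprintf("r^2 = %.3f < %.2f", r2, r2_min)
            else NA_character_
  out <- structure(list(
    rc = rc, rd = rd, scale = sc, r_squared = r2, L_birth = L_birth,
    L_at_oric = L_birth * 2^(3 - rc - rd),
    T_C = if (!is.null(T)) rc * T else NA_real_,
    T_D = if (!is.null(T)) rd * T else NA_real_,
    n_cells = sum(win), discarded = at_bound || r2 < r2_min, reason = reason
  ), class = "dna_fit")
  if (out$discarded) {
    warning("DAPI fit discarded: ", reason)
  }
  out
}

#' @export
print.dna_fit <- function(x, ...) {
  cat("DNA content (DAPI) cell-cycle fit\n")
  cat(sprintf("  T_C/T = %.3f, T_D/T = %.3f, r^2 = %.3f (n = %d)\n",
              x$rc, x$rd, x$r_squared, x$n_cells))
  cat(sprintf("  L at oriC replication = %.2f um%s\n", x$L_at_oric,
              if (x$discarded) "  [DISCARDED]" else ""))
  invisible(x)
}
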