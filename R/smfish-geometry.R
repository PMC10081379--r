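#' Spherocylinder width and volume from segmented length and area
#'
#' Approximating a bacterial cell as a spherocylinder (a cylinder with
#' hemispherical caps), the projected area of a cell of length `L` and width
#' `d` is `A = (L - d) d + pi d^2 / 4`. Inverting for the width gives
#' `d = (L - sqrt(L^2 - A (4 - pi))) / (2 - pi/2)` and the volume
#' `V = pi L d^2 / 4 - pi d^3 / 12`. In the sphere limit `L = d` the volume
#' reduces to `pi d^3 / 6`.
#'
#' @param length Cell length, micrometres (vector).
#' @param area Projected cell area, square micrometres (vector).
#' @return Tibble with `length`, `area`, `width`, `volume`.
#' @export
spherocylinder_geometry <- function(length, area) {
  disc <- length^2 - area * (4 - pi)
  if (any(disc < 0)) {
    stop("inconsistent length/area: L^2 < A * (4 - pi)", call. = FALSE)
  }
  d <- (length - sqrt(disc)) / (2 - pi / 2)
  tibble::tibble(length = length, area = area, width = d,
                 volume = pi * length * d^2 / 4 - pi * d^3 / 12)
}

#' Forward projected area of a spherocylinder
#' @param length,width Cell length and width, micrometres.
#' @return Projected area, square micrometres.
#' @export
spherocylinder_area <- function(length, width) {
  (length - width) * width + pi * width^2 / 4
}

#' Cell-length density under the (smoothed) 2L0/L^2 law
#'
#' In an exponentially growing population whose cells elongate at a rate
#' proportional to their length, lengths are distributed as
#' `p(L) = 2 L0 / L^2` on `[L0, 2 L0]`, with `L0` the birth length. To
#' absorb cell-cycle stochasticity and measurement error the law is
#' convolved with a Gaussian of width `sigma`:
#' `p(L) = (2 L0 / (sigma sqrt(2 pi))) * integral_{L0}^{2 L0} x^-2
#'  exp(-(L - x)^2 / (2 sigma^2)) dx`.
#' `sigma = 0` returns the sharp law; `sigma > 0` evaluates the convolution
#' by Gauss-Legendre quadrature in standardized units (integrand truncated
#' at 8 sigma).
#'
#' @param L Lengths at which to evaluate, micrometres.
#' @param L0 Birth length, micrometres (> 0).
#' @param sigma Smoothing noise, micrometres (>= 0).
#' @param nodes Quadrature nodes (default 64).
#' @return Density values, same length as `L`.
#' @export
length_pdf <- function(L, L0, sigma, nodes = 64) {
  stopifnot(L0 > 0, sigma >= 0)
  if (sigma == 0) {
    return(ifelse(L >= L0 & L <= 2 * L0, 2 * L0 / L^2, 0))
  }
  gl <- pracma::gaussLegendre(nodes, -1, 1)
  zlo <- pmax(-8, (L0 - L) / sigma)
  zhi <- pmin(8, (2 * L0 - L) / sigma)
  out <- numeric(length(L))
  ok <- zhi > zlo
  if (any(ok)) {
    half <- (zhi[ok] - zlo[ok]) / 2
    mid <- (zhi[ok] + zlo[ok]) / 2
    # z-nodes per L: x = L + sigma z stays inside [L0, 2L0]
    zz <- outer(half, gl$x) + mid                  # n_ok x nodes
    xx <- L[ok] + sigma * zz
    vals <- (2 * L0 / xx^2) * stats::dnorm(zz)
    out[ok] <- (vals %*% gl$w) * half
  }
  out
}

#' Sample cell lengths from the smoothed 2L0/L^2 law
#'
#' Exact sampling: inverse-CDF draw from the sharp law
#' (`x = 2 L0 / (2 - u)`, `u ~ U(0,1)`) plus independent Gaussian noise.
#'
#' @inheritParams length_pdf
#' @param n Number of cells.
#' @param seed Optional integer seed.
#' @return Numeric vector of lengths (micrometres).
#' @export
sample_lengths <- function(n, L0, sigma, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- 2 * L0 / (2 - stats::runif(n))
  x + stats::rnorm(n, 0, sigma)
}

#' Maximum-likelihood fit of the smoothed cell-length distribution
#'
#' Fits `(L0, sigma)` of the Gaussian-smoothed `2 L0 / L^2` law to measured
#' cell lengths by maximizing the likelihood (quadrature density from
#' [length_pdf()]), with standard errors from the observed information.
#'
#' @param lengths Measured cell lengths, micrometres (>= 100 cells).
#' @return A `length_fit` object (list): `L0`, `sigma`, their standard
#'   errors, `logLik`, `n`, `at_bound` flag, and `convergence` code.
#' @export
fit_length_distribution <- function(lengths) {
  lengths <- lengths[is.finite(lengths)]
  if (length(lengths) < 100) stop("need >= 100 cells", call. = FALSE)
  nll <- function(p) {
    L0 <- p[1]; sigma <- exp(p[2])
    if (L0 <= 0) return(1e10)
    d <- length_pdf(lengths, L0, sigma)
    if (any(!is.finite(d)) || any(d <= 0)) return(1e10)
    -sum(log(d))
  }
  L0_start <- mean(lengths) / (2 * log(2))
  p0 <- c(L0_start, log(0.15 * L0_start))
  opt <- stats::optim(p0, nll, method = "Nelder-Mead",
                      control = list(maxit = 2000))
  opt <- stats::optim(opt$par, nll, method = "BFGS", hessian = TRUE)
  L0 <- opt$par[1]; sigma <- exp(opt$par[2])
  se <- tryCatch({
    v <- solve(opt$hessian)
    c(sqrt(v[1, 1]), sqrt(v[2, 2]) * sigma)   # delta method for sigma
  }, error = function(e) c(NA_real_, NA_real_))
  at_bound <- sigma < 1e-4 * L0
  structure(list(L0 = L0, sigma = sigma, se_L0 = se[1], se_sigma = se[2],
                 logLik = -opt$value, n = length(lengths),
                 at_bound = at_bound, convergence = opt$convergence),
            class = "length_fit")
}

#' @export
print.length_fit <- function(x, ...) {
  cat(sprintf("Smoothed 2L0/L^2 length fit (n = %d cells)\n", x$n))
  cat(sprintf("  L0    = %.3f um (SE %.3f)\n", x$L0, x$se_L0))
  cat(sprintf("  sigma = %.3f um (SE %.3f)\n", x$sigma, x$se_sigma))
  invisible(x)
}
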