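#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy posterior summaries of a replication fit
#'
#' @param x A `replication_fit`.
#' @param ... Unused.
#' @return Tibble with one row per parameter: `term`, `estimate`
#'   (posterior mean), `std_error`, `conf_low`, `conf_high`.
#' @export
tidy.replication_fit <- function(x, ...) {
  d <- x$draws
  purrr::map_dfr(names(d), function(nm) {
    v <- d[[nm]]
    tibble::tibble(term = nm, estimate = mean(v), std_error = stats::sd(v),
                   conf_low = stats::quantile(v, 0.025),
                   conf_high = stats::quantile(v, 0.975))
  })
}

#' @rdname tidy.replication_fit
#' @export
glance.replication_fit <- function(x, ...) {
  tibble::tibble(n_genes = x$n_genes, gamma = x$gamma_mean,
                 kappa = x$kappa_mean, overlap_fraction = 1 - 1 / x$gamma_mean,
                 log_posterior = x$logpost, method = x$method)
}

#' Tidy methods for the expression, length, Hill and DAPI fits
#'
#' @param x A fitted object.
#' @param ... Unused.
#' @return A tibble of coefficients (`tidy`) or fit summaries (`glance`).
#' @name tidiers
NULL

#' @rdname tidiers
#' @export
tidy.expression_model <- function(x, ...) {
  tibble::tibble(term = c("(Intercept)", names(x$coef)),
                 estimate = c(x$intercept, unname(x$coef)))
}

#' @rdname tidiers
#' @export
glance.expression_model <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, alpha = x$alpha,
                 n_features = length(x$coef))
}

#' @rdname tidiers
#' @export
tidy.length_fit <- function(x, ...) {
  tibble::tibble(term = c("L0", "sigma"),
                 estimate = c(x$L0, x$sigma),
                 std_error = c(x$se_L0, x$se_sigma))
}

#' @rdname tidiers
#' @export
glance.length_fit <- function(x, ...) {
  tibble::tibble(logLik = x$logLik, n = x$n, at_bound = x$at_bound,
                 convergence = x$convergence)
}

#' @rdname tidiers
#' @export
tidy.hill_fit <- function(x, ...) x$coef

#' @rdname tidiers
#' @export
glance.hill_fit <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, n_bins = x$n_bins)
}

#' @rdname tidiers
#' @export
tidy.dna_fit <- function(x, ...) {
  tibble::tibble(term = c("T_C/T", "T_D/T", "scale", "L_at_oric"),
                 estimate = c(x$rc, x$rd, x$scale, x$L_at_oric))
}

#' @rdname tidiers
#' @export
glance.dna_fit <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, n_cells = x$n_cells,
                 L_birth = x$L_birth, discarded = x$discarded)
}

#' @rdname tidiers
#' @export
tidy.phase_alignment <- function(x, ...) {
  tibble::tibble(
    term = c("A", "B", "C", "a", "b", "c", "phi_deg", "L_at_theta0"),
    estimate = c(x$smfish$A, x$smfish$B, x$smfish$C,
                 x$scrnaseq$A, x$scrnaseq$B, x$scrnaseq$C,
                 x$phi_deg, x$L_at_theta0))
}

#' @rdname tidiers
#' @export
glance.phase_alignment <- function(x, ...) {
  tibble::tibble(phi_deg = x$phi_deg, L0 = x$L0, L_at_theta0 = x$L_at_theta0,
                 r_squared_smfish = x$smfish$r_squared,
                 r_squared_scrnaseq = x$scrnaseq$r_squared)
}
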