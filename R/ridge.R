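# exponent table for all monomials of total degree 1..4 in the four
# trig variables (cos/sin of each angle); 69 monomials, fixed order
trig_exponents <- function() {
  g <- expand.grid(e1 = 0:4, e2 = 0:4, e3 = 0:4, e4 = 0:4)
  g <- g[rowSums(g) >= 1 & rowSums(g) <= 4, ]
  g[order(rowSums(g), g$e1, g$e2, g$e3, g$e4), ]
}

# feature matrix for the cell angle-gene angle model: trig monomials up to
# degree 4 plus the raw angles in radians
trig_features <- function(theta_c_deg, theta_g_deg) {
  tc <- deg2rad(wrap_deg(theta_c_deg))
  tg <- deg2rad(wrap_deg(theta_g_deg))
  base <- cbind(c1 = cos(tc), s1 = sin(tc), c2 = cos(tg), s2 = sin(tg))
  ex <- trig_exponents()
  X <- matrix(1, length(tc), nrow(ex))
  for (k in seq_len(nrow(ex))) {
    e <- as.numeric(ex[k, ])
    for (v in 1:4) if (e[v] > 0) X[, k] <- X[, k] * base[, v]^e[v]
  }
  colnames(X) <- apply(ex, 1, function(e)
    paste0(c("c1", "s1", "c2", "s2")[e > 0],
           ifelse(e[e > 0] > 1, paste0("^", e[e > 0]), ""), collapse = "*"))
  cbind(X, theta_c = tc, theta_g = tg)
}

#' Ridge model of expression as a function of cell and gene angle
#'
#' Fits binned expression z-scores on a trigonometric polynomial of the
#' two angles: all interactions and combinations of `cos(theta_c)`,
#' `sin(theta_c)`, `cos(theta_g)`, `sin(theta_g)` up to total degree 4,
#' plus the untransformed angles in radians, under ridge penalty
#' `alpha = 10` with an unpenalized intercept. Trig monomials live in
#' `[-1, 1]`, so no feature standardization is applied.
#'
#' @param response Bins x bins matrix: expression averaged first in
#'   `theta_c` bins (rows) then in `theta_g` bins (columns); see
#'   [bin_by_gene_angle()].
#' @param theta_c_grid,theta_g_grid Angles (degrees) of the row / column
#'   bins.
#' @param alpha Ridge penalty (default 10).
#' @return An `expression_model`: coefficients, intercept, `alpha` and
#'   in-sample `r_squared`.
#' @export
fit_cell_gene_model <- function(response, theta_c_grid, theta_g_grid,
                                alpha = 10) {
  stopifnot(nrow(response) == length(theta_c_grid),
            ncol(response) == length(theta_g_grid))
  if (anyNA(response)) stop("NaNs in response grid", call. = FALSE)
  grid <- expand.grid(tc = theta_c_grid, tg = theta_g_grid)
  y <- as.vector(response)
  X <- trig_features(grid$tc, grid$tg)
  xm <- colMeans(X)
  ym <- mean(y)
  Xc <- sweep(X, 2, xm)
  A <- crossprod(Xc) + diag(alpha, ncol(Xc))
  beta <- solve(A, crossprod(Xc, y - ym))
  fitted <- drop(Xc %*% beta) + ym
  structure(list(
    coef = drop(beta), feature_means = xm, intercept = ym,
    alpha = alpha,
    r_squared = 1 - sum((y - fitted)^2) / sum((y - ym)^2)
  ), class = "expression_model")
}

#' Predict expression from cell and gene angles
#'
#' @param model An `expression_model`.
#' @param theta_c,theta_g Paired angle vectors, degrees (recycled to a
#'   common length).
#' @return Predicted expression values.
#' @export
predict_expression <- function(model, theta_c, theta_g) {
  n <- max(length(theta_c), length(theta_g))
  X <- trig_features(rep_len(theta_c, n), rep_len(theta_g, n))
  drop(sweep(X, 2, model$feature_means) %*% model$coef) + model$intercept
}

#' @export
print.expression_model <- function(x, ...) {
  cat(sprintf(
    "Trig-polynomial ridge expression model (alpha = %g, %d features)\n",
    x$alpha, length(x$coef)))
  cat(sprintf("  in-sample r^2 = %.3f\n", x$r_squared))
  invisible(x)
}

#' Average a cell angle-binned matrix within gene-angle bins
#'
#' Second binning stage for the ridge model: collapses the
#' `theta_c`-binned bins x genes matrix into bins x bins by averaging
#' genes within `n_bins` equal-width bins of `theta_g`. Empty gene-angle
#' bins are interpolated on the circle.
#'
#' @param binned A `binned_expression` ([bin_by_cell_angle()]).
#' @param theta_g Per-gene angles, degrees (matching the matrix columns).
#' @param n_bins Gene-angle bins (default 100).
#' @return List: `values` (theta_c bins x theta_g bins), `theta_g`
#'   (per-column mean gene angle) and `interpolated` flags.
#' @export
bin_by_gene_angle <- function(binned, theta_g, n_bins = 100) {
  stopifnot(length(theta_g) == ncol(binned$values))
  bin <- pmin(floor(wrap_deg(theta_g) / 360 * n_bins) + 1L, n_bins)
  occ <- tabulate(bin, n_bins)
  filled <- occ > 0
  vals <- matrix(NA_real_, binned$n_bins, n_bins)
  sums <- t(rowsum(t(binned$values), group = bin))
  vals[, as.integer(colnames(sums))] <- sweep(sums, 2, occ[filled], "/")
  for (i in seq_len(nrow(vals))) {
    vals[i, ] <- interpolate_circular(vals[i, ], filled)
  }
  centers <- (seq_len(n_bins) - 0.5) * 360 / n_bins
  tg <- rep(NA_real_, n_bins)
  tg[filled] <- rowsum(wrap_deg(theta_g), group = bin)[, 1] / occ[filled]
  tg[!filled] <- centers[!filled]
  list(values = vals, theta_g = tg, interpolated = !filled)
}

#' Replication-only prediction of cell-cycle expression
#'
#' Combines the two fitted models: origin distance is mapped to a
#' predicted gene angle through the circular regression, and expression is
#' then predicted on the cell-angle grid through the ridge model using
#' `theta_g_pred` in place of the observed gene angle. The result is the
#' expression expected from replication-driven dosage alone.
#'
#' @param expression_model A fitted [fit_cell_gene_model()].
#' @param replication_fit A fitted [fit_gene_angle_regression()].
#' @param theta_c_grid Cell-angle grid, degrees (per-bin mean angles).
#' @param D Named (or plain) vector of origin distances per gene; genes
#'   with missing `D` are excluded and listed in attribute `"excluded"`.
#' @return Matrix `length(theta_c_grid)` x genes of predicted expression.
#' @export
predict_replication_expression <- function(expression_model, replication_fit,
                                           theta_c_grid, D) {
  excluded <- which(!is.finite(D))
  keep <- setdiff(seq_along(D), excluded)
  tg_pred <- predict_gene_angle(replication_fit, D[keep])
  out <- matrix(NA_real_, length(theta_c_grid), length(keep))
  for (j in seq_along(keep)) {
    out[, j] <- predict_expression(expression_model, theta_c_grid,
                                   rep(tg_pred[j], length(theta_c_grid)))
  }
  colnames(out) <- names(D)[keep]
  attr(out, "excluded") <- names(D)[excluded] %||% excluded
  attr(out, "theta_g_pred") <- tg_pred
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
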