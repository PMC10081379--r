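#' Embed cells in two dimensions from position-binned expression
#'
#' Projects cells into the plane in which the cell angle is measured. The
#' default backend is the deterministic rank-2 PCA of the cells x bins
#' matrix, which maps a cycling population onto a wheel (two orthogonal
#' harmonics of the replication wave); any function taking the cells x bins
#' matrix and returning an n x 2 coordinate matrix can be plugged in
#' instead (e.g. a nonlinear embedding run with a fixed seed). Coordinates
#' are mean-centered.
#'
#' @param binned Bins x cells z-score matrix ([bin_genes_by_position()]).
#' @param backend `"pca"` or a function `(matrix) -> n x 2 matrix`.
#' @param seed Seed forwarded to function backends via `set.seed()`.
#' @return An n_cells x 2 matrix with columns `x`, `y`, mean-centered.
#' @export
embed_cells <- function(binned, backend = "pca", seed = 0) {
  if (ncol(binned) < 10) stop("need at least 10 cells", call. = FALSE)
  cells <- t(binned)
  if (is.function(backend)) {
    set.seed(seed)
    coords <- backend(cells)
    stopifnot(is.matrix(coords), nrow(coords) == nrow(cells),
              ncol(coords) == 2)
  } else if (identical(backend, "pca")) {
    pc <- stats::prcomp(cells, center = TRUE, scale. = FALSE, rank. = 2)
    coords <- pc$x[, 1:2, drop = FALSE]
  } else {
    stop("unknown embedding backend", call. = FALSE)
  }
  coords <- scale(coords, center = TRUE, scale = FALSE)
  dimnames(coords) <- list(colnames(binned), c("x", "y"))
  coords
}

#' Cell angle from a 2-D embedding
#'
#' The cell-cycle ordering coordinate: the two-argument arctangent of
#' (x, y), i.e. the angle measured clockwise from the positive y axis,
#' in degrees `[0, 360)`. Cells at the exact origin get angle 0 and are
#' recorded in the `"origin_cells"` attribute.
#'
#' @param embedding n x 2 mean-centered coordinate matrix ([embed_cells()]).
#' @return Named numeric vector of angles in degrees.
#' @export
cell_angle <- function(embedding) {
  x <- embedding[, 1]; y <- embedding[, 2]
  at_origin <- x == 0 & y == 0
  theta <- angle_from_xy(x, y)
  theta[at_origin] <- 0
  names(theta) <- rownames(embedding)
  if (any(at_origin)) {
    attr(theta, "origin_cells") <- which(at_origin)
  }
  theta
}

# linear interpolation of missing bin values around the circle
interpolate_circular <- function(vals, filled) {
  n <- length(vals)
  if (all(filled)) return(vals)
  if (!any(filled)) stop("no occupied bins to interpolate from", call. = FALSE)
  idx <- which(filled)
  for (i in which(!filled)) {
    dist_fwd <- (idx - i) %% n
    dist_bwd <- (i - idx) %% n
    nxt <- idx[which.min(dist_fwd)]
    prv <- idx[which.min(dist_bwd)]
    if (nxt == prv) { vals[i] <- vals[nxt]; next }
    w_f <- (i - prv) %% n
    w_b <- (nxt - i) %% n
    vals[i] <- (w_b * vals[prv] + w_f * vals[nxt]) / (w_f + w_b)
  }
  vals
}

#' Average expression within equal-width cell-angle bins
#'
#' Produces the cell angle-binned expression matrix: per-gene means over
#' `n_bins` equally spaced bins of `theta_c` (default 100). The per-bin
#' mean cell angle is stored and reused downstream as the prediction grid.
#' Empty bins are filled by linear interpolation on the circle and flagged.
#'
#' @param z Genes x cells expression (z-score) matrix.
#' @param theta_c Per-cell angles, degrees.
#' @param n_bins Number of equal-width angle bins.
#' @return A `binned_expression` object: list with `values` (n_bins x genes
#'   matrix), `theta` (per-bin mean angle, degrees), `occupancy` (cells per
#'   bin, summing to `ncol(z)`) and `interpolated` (logical per bin).
#' @export
bin_by_cell_angle <- function(z, theta_c, n_bins = 100) {
  stopifnot(length(theta_c) == ncol(z))
  bin <- pmin(floor(wrap_deg(theta_c) / 360 * n_bins) + 1L, n_bins)
  occupancy <- tabulate(bin, n_bins)
  filled <- occupancy > 0
  vals <- matrix(NA_real_, n_bins, nrow(z),
                 dimnames = list(NULL, rownames(z)))
  sums <- rowsum(t(z), group = bin)
  vals[as.integer(rownames(sums)), ] <- sums / occupancy[filled]
  theta <- rep(NA_real_, n_bins)
  theta[filled] <- rowsum(wrap_deg(theta_c), group = bin)[, 1] /
    occupancy[filled]
  centers <- (seq_len(n_bins) - 0.5) * 360 / n_bins
  theta[!filled] <- centers[!filled]
  for (j in seq_len(ncol(vals))) {
    vals[, j] <- interpolate_circular(vals[, j], filled)
  }
  structure(list(values = vals, theta = theta, occupancy = occupancy,
                 interpolated = !filled, n_bins = n_bins),
            class = "binned_expression")
}

#' @export
print.binned_expression <- function(x, ...) {
  cat(sprintf("binned_expression: %d angle bins x %d genes (%d interpolated bins)\n",
              x$n_bins, ncol(x$values), sum(x$interpolated)))
  invisible(x)
}

#' Cell angle-binned z-score profiles of each gene
#'
#' Convenience composition used by the pipeline: averages a (denoised or
#' normalized) expression matrix within cell-angle bins with
#' [bin_by_cell_angle()], then log2-transforms and z-scores each gene's
#' profile across the bins. Standardizing after binning is robust at very
#' low per-cell depth, where per-cell z-scores of individual sparse genes
#' are dominated by detection noise.
#'
#' @param expr Genes x cells non-negative expression matrix.
#' @param theta_c Per-cell angles, degrees.
#' @param n_bins Number of equal-width angle bins.
#' @return A `binned_expression` whose `values` are per-gene z-score
#'   profiles (bins x genes).
#' @export
bin_profiles <- function(expr, theta_c, n_bins = 100) {
  b <- bin_by_cell_angle(expr, theta_c, n_bins)
  b$values <- t(zscore_log(t(b$values)))
  b
}

#' Gene angle from PCA of the cell angle-binned expression matrix
#'
#' Orders genes by their cell-cycle expression timing: PCA is performed on
#' the transpose of the binned matrix (genes x bins) and the gene angle
#' `theta_g` is the angle between PC1 and PC2 scores, in the same
#' clockwise-from-+y convention as [cell_angle()]. Because PC directions
#' are arbitrary, when a `genome_model` is supplied the orientation is
#' auto-reversed (`theta_g -> 360 - theta_g`) if the trend of `theta_g`
#' against origin distance is negative; the flip is recorded.
#'
#' @param binned A `binned_expression` from [bin_by_cell_angle()].
#' @param gm Optional `genome_model` for orientation.
#' @return Tibble with `gene_id`, `theta_g` (degrees), `pc1`, `pc2`;
#'   attribute `"reversed"` records whether the orientation was flipped.
#' @export
gene_angle <- function(binned, gm = NULL) {
  m <- t(binned$values)              # genes x bins
  pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  if (ncol(pc$x) < 2 || pc$sdev[2] < 1e-12) {
    stop("degenerate PCA: binned expression has rank < 2", call. = FALSE)
  }
  theta <- angle_from_xy(pc$x[, 1], pc$x[, 2])
  reversed <- FALSE
  if (!is.null(gm)) {
    D <- gm$origin_distance[match(rownames(m), gm$gene_id)]
    if (circular_trend(theta, D) < 0) {
      theta <- wrap_deg(360 - theta)
      reversed <- TRUE
    }
  }
  out <- tibble::tibble(gene_id = rownames(m), theta_g = theta,
                        pc1 = pc$x[, 1], pc2 = pc$x[, 2])
  attr(out, "reversed") <- reversed
  out
}

# sign statistic for the circular-linear trend of theta (deg) vs D:
# positive when increasing D rotates theta clockwise on average
circular_trend <- function(theta, D, max_pairs = 20000) {
  ok <- is.finite(D)
  theta <- theta[ok]; D <- D[ok]
  n <- length(theta)
  if (n < 2) return(0)
  set.seed(0)
  i <- sample.int(n, min(max_pairs, n * (n - 1) / 2), replace = TRUE)
  j <- sample.int(n, length(i), replace = TRUE)
  keep <- i != j
  i <- i[keep]; j <- j[keep]
  sum(sin(deg2rad(theta[i] - theta[j])) * sign(D[i] - D[j]))
}

#' Rotate the cell angle so zero marks replication initiation
#'
#' The raw cell angle fixes only relative ordering; its zero is an
#' arbitrary gauge. This predicts the expression profile of an imaginary
#' gene at origin distance 0 from the fitted replication models, finds the
#' angle of minimum predicted expression (`theta_0`, the most likely angle
#' of replication initiation, where the dosage doubling begins), and
#' rotates all angles by `(theta_c - theta_0) mod 360`.
#'
#' @param theta_c Per-cell angles, degrees.
#' @param expression_model Fitted [fit_cell_gene_model()] object.
#' @param replication_fit Fitted [fit_gene_angle_regression()] object.
#' @param theta_grid Angles (degrees) on which to evaluate the predicted
#'   profile; typically the per-bin mean angles from [bin_by_cell_angle()].
#' @return List with `theta_c` (rotated), `theta_0` (degrees) and the
#'   predicted `profile` at `theta_grid`.
#' @export
rotate_zero <- function(theta_c, expression_model, replication_fit,
                        theta_grid = (0:99 + 0.5) * 3.6) {
  tg0 <- predict_gene_angle(replication_fit, 0)
  prof <- predict_expression(expression_model, theta_c = theta_grid,
                             theta_g = rep(tg0, length(theta_grid)))
  if (diff(range(prof)) < 1e-9) {
    stop("flat predicted profile: replication model uninformative",
         call. = FALSE)
  }
  theta_0 <- theta_grid[which.min(prof)]
  list(theta_c = wrap_deg(theta_c - theta_0), theta_0 = theta_0,
       profile = prof)
}
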