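#' Filter a count matrix by per-cell and per-gene UMI totals
#'
#' Removes barcodes whose total UMI falls below `min_umi_per_cell`, then
#' (on the retained cells) genes with a grand total below `min_gene_total`.
#' Defaults match typical thresholds for bacterial split-pool data
#' (15 UMI per barcode, 50 UMI per gene; some datasets use 20/40 and 100).
#'
#' @param counts Sparse genes x cells count matrix.
#' @param min_umi_per_cell,min_gene_total Non-negative thresholds.
#' @return The filtered count matrix.
#' @export
filter_matrix <- function(counts, min_umi_per_cell = 15, min_gene_total = 50) {
  stopifnot(min_umi_per_cell >= 0, min_gene_total >= 0)
  keep_cells <- Matrix::colSums(counts) >= min_umi_per_cell
  if (!any(keep_cells)) stop("all cells removed by UMI filter", call. = FALSE)
  out <- counts[, keep_cells, drop = FALSE]
  keep_genes <- Matrix::rowSums(out) >= min_gene_total
  out[keep_genes, , drop = FALSE]
}

# tag a matrix layer so transform provenance can be audited downstream
set_layer <- function(m, layer) {
  attr(m, "layer") <- c(attr(m, "layer"), layer)
  m
}

#' Transform provenance of an expression matrix
#' @param m Matrix produced by the preprocessing steps.
#' @return Character vector of applied layers (e.g. `"normalized"`,
#'   `"zscore"`).
#' @export
expr_layers <- function(m) attr(m, "layer")

#' Library-size normalization to the median per-cell total
#'
#' Rescales every cell so its total equals the median pre-normalization
#' UMI total across cells.
#'
#' @param counts Genes x cells count matrix (no zero-total cells; filter
#'   first).
#' @return Dense numeric matrix, layer `"normalized"`.
#' @export
normalize_library <- function(counts) {
  totals <- Matrix::colSums(counts)
  if (!length(totals)) stop("empty matrix", call. = FALSE)
  if (any(totals == 0)) {
    stop("zero-total cell present: filter before normalizing", call. = FALSE)
  }
  med <- stats::median(totals)
  out <- sweep(as.matrix(counts), 2, med / totals, "*")
  dimnames(out) <- dimnames(counts)
  set_layer(out, "normalized")
}

#' Per-gene z-scores of log2 expression
#'
#' Log2-transforms and standardizes each gene across cells (or bins),
#' using the population standard deviation. A pseudocount of 1 is applied
#' automatically when the layer contains zeros (library-normalized
#' counts); strictly positive denoised layers get none. Zero-variance
#' genes are set to all-zero rows and recorded in the `"flat_genes"`
#' attribute. Applying the function to an already z-scored layer skips the
#' log transform and re-standardizes, so the operation is idempotent.
#'
#' @param m Genes x cells (or genes x bins) non-negative matrix.
#' @param pseudocount Override the automatic pseudocount choice.
#' @return Matrix of z-scores, layer `"zscore"`.
#' @export
zscore_log <- function(m, pseudocount = NULL) {
  layers <- attr(m, "layer")
  m <- as.matrix(m)
  if ("zscore" %in% layers) {
    lg <- m
  } else {
    if (is.null(pseudocount)) pseudocount <- if (any(m == 0)) 1 else 0
    lg <- log2(m + pseudocount)
  }
  mu <- rowMeans(lg)
  sdv <- sqrt(rowMeans((lg - mu)^2))
  flat <- sdv == 0 | !is.finite(sdv)
  sdv[flat] <- 1
  z <- (lg - mu) / sdv
  z[flat, ] <- 0
  attr(z, "layer") <- layers
  z <- set_layer(z, if ("zscore" %in% layers) "rescore" else "zscore")
  attr(z, "flat_genes") <- rownames(m)[flat]
  z
}

#' Average gene z-scores within chromosomal position bins
#'
#' Collapses the genes x cells z-score matrix into bins x cells by averaging
#' member genes within half-open position bins of `bin_size_bp` starting at
#' coordinate 0 (typical bin sizes 50-400 kb). Empty bins are dropped and
#' recorded in the `"empty_bins"` attribute.
#'
#' @param z Genes x cells z-score matrix (rownames = gene ids).
#' @param gm A `genome_model` providing gene midpoints.
#' @param bin_size_bp Bin width in bp (> 0).
#' @return Bins x cells matrix; attribute `"bin_start"` gives each bin's
#'   left edge in bp.
#' @export
bin_genes_by_position <- function(z, gm, bin_size_bp = 50000) {
  if (bin_size_bp <= 0) stop("bin_size_bp must be positive", call. = FALSE)
  mid <- gm$midpoint[match(rownames(z), gm$gene_id)]
  if (anyNA(mid)) stop("genes missing from genome model", call. = FALSE)
  L <- attr(gm, "genome_length")
  n_bins <- ceiling(L / bin_size_bp)
  bin <- floor(mid / bin_size_bp) + 1
  out <- rowsum(z, group = bin) / as.vector(table(bin))
  occupied <- sort(unique(bin))
  rownames(out) <- paste0("bin_", occupied)
  attr(out, "bin_start") <- (occupied - 1) * bin_size_bp
  attr(out, "empty_bins") <- setdiff(seq_len(n_bins), occupied)
  set_layer(out, "position_binned")
}

#' Sum raw counts within chromosomal position bins
#'
#' Count-level companion to [bin_genes_by_position()]: sums UMI counts of
#' the genes in each half-open position bin. Pooling counts before the
#' normalize/log/z-score chain is the statistically efficient route when no
#' model-based denoiser is in play (the per-bin totals are far less sparse
#' than per-gene counts), and is the default input to the cell embedding.
#'
#' @param counts Genes x cells count matrix.
#' @param gm A `genome_model`.
#' @param bin_size_bp Bin width in bp (> 0).
#' @return Bins x cells count matrix with attribute `"bin_start"`.
#' @export
bin_counts_by_position <- function(counts, gm, bin_size_bp = 200000) {
  if (bin_size_bp <= 0) stop("bin_size_bp must be positive", call. = FALSE)
  mid <- gm$midpoint[match(rownames(counts), gm$gene_id)]
  if (anyNA(mid)) stop("genes missing from genome model", call. = FALSE)
  bin <- floor(mid / bin_size_bp) + 1
  out <- rowsum(as.matrix(counts), group = bin)
  occupied <- sort(unique(bin))
  rownames(out) <- paste0("bin_", occupied)
  attr(out, "bin_start") <- (occupied - 1) * bin_size_bp
  out
}

#' Bin x bin Spearman correlation map
#'
#' The chromosome-position correlation fingerprint: Spearman correlations
#' between positional bins across cells. Replication-driven dosage produces
#' the "X" (arm-symmetric) and nested "multi-X" patterns here; their absence
#' (e.g. stationary phase) leaves near-zero off-diagonal structure.
#'
#' @param binned Bins x cells matrix from [bin_genes_by_position()].
#' @return Symmetric bins x bins matrix, unit diagonal; constant bins give 0
#'   with a warning.
#' @export
gene_correlation_map <- function(binned) {
  if (ncol(binned) < 3) stop("need at least 3 cells", call. = FALSE)
  cc <- suppressWarnings(stats::cor(t(binned), method = "spearman"))
  if (anyNA(cc)) {
    warning("constant bin(s): undefined correlations set to 0")
    cc[is.na(cc)] <- 0
  }
  diag(cc) <- 1
  cc
}

#' Highly variable genes by LOWESS mean-variance regression
#'
#' Flags genes whose cell-cycle expression variance exceeds expectation:
#' library-normalize, average counts over `n_bins` equal-width bins of the
#' cell angle, drop genes with any zero bin, log2-transform, LOWESS-fit
#' variance against mean, and flag genes with observed/predicted variance
#' ratio above `ratio_threshold` and log2 mean above `min_log2_mean`.
#'
#' @param counts Genes x cells count matrix.
#' @param theta_c Per-cell angle in degrees.
#' @param n_bins Cell-angle bins for sparsity reduction (default 20).
#' @param ratio_threshold Variance-ratio cutoff (default 1.3).
#' @param min_log2_mean Expression floor on the log2 scale (default -10).
#' @param lowess_f LOWESS smoother span (default 0.3).
#' @return Tibble with one row per input gene: `gene_id`, `log2_mean`,
#'   `variance`, `predicted_variance`, `ratio`, `highly_variable`
#'   (genes dropped at the zero-bin step carry `NA` statistics and `FALSE`).
#' @export
highly_variable_genes <- function(counts, theta_c, n_bins = 20,
                                  ratio_threshold = 1.3, min_log2_mean = -10,
                                  lowess_f = 0.3) {
  if (ncol(counts) < 20) stop("need at least 20 cells", call. = FALSE)
  stopifnot(length(theta_c) == ncol(counts))
  norm <- normalize_library(counts)
  bin <- pmin(floor(theta_c / 360 * n_bins) + 1, n_bins)
  binned <- t(rowsum(t(norm), group = bin) / as.vector(table(bin)))
  keep <- rowSums(binned == 0) == 0
  lg <- log2(binned[keep, , drop = FALSE])
  mu <- rowMeans(lg)
  v <- apply(lg, 1, stats::var)
  lo <- stats::lowess(mu, v, f = lowess_f)
  pred <- stats::approx(lo$x, lo$y, xout = mu, rule = 2)$y
  ratio <- v / pmax(pred, 1e-12)
  res <- tibble::tibble(
    gene_id = rownames(counts),
    log2_mean = NA_real_, variance = NA_real_,
    predicted_variance = NA_real_, ratio = NA_real_,
    highly_variable = FALSE
  )
  i <- match(rownames(lg), res$gene_id)
  res$log2_mean[i] <- mu
  res$variance[i] <- v
  res$predicted_variance[i] <- pred
  res$ratio[i] <- ratio
  res$highly_variable[i] <- ratio > ratio_threshold & mu > min_log2_mean
  res
}

#' Smooth expression along the inferred cell-cycle manifold
#'
#' Cheap model-free denoiser used once a cell angle exists: each gene's
#' normalized expression is averaged within `n_bins` cell-angle bins,
#' circularly smoothed with a moving-average window, and read back per
#' cell at its bin. The result is a dense genes x cells matrix in which
#' each cell carries its gene's expected cycle value -- the role a
#' model-based denoiser plays for per-cell z-scoring at very low depth.
#'
#' @param expr Genes x cells non-negative expression matrix (normalized).
#' @param theta_c Per-cell angles, degrees.
#' @param n_bins Angle bins (default 100).
#' @param window Circular moving-average window in bins (odd; default 9).
#' @return Dense genes x cells matrix, layer `"denoised"`.
#' @export
smooth_by_angle <- function(expr, theta_c, n_bins = 100, window = 9) {
  b <- bin_by_cell_angle(expr, theta_c, n_bins)
  prof <- apply(b$values, 2, circular_ma, window = window)
  bin <- pmin(floor(wrap_deg(theta_c) / 360 * n_bins) + 1L, n_bins)
  out <- t(prof[bin, , drop = FALSE])
  dimnames(out) <- dimnames(expr)
  set_layer(out, "denoised")
}

# circular moving average of a profile vector
circular_ma <- function(x, window = 9) {
  n <- length(x)
  h <- (window - 1) %/% 2
  idx <- outer(seq_len(n), -h:h, function(i, o) ((i + o - 1) %% n) + 1)
  rowMeans(matrix(x[idx], n))
}

#' Denoise a count matrix (pluggable contract)
#'
#' Stand-in for an external probabilistic denoiser: the pipeline only
#' requires a non-negative dense matrix of the same shape. Methods:
#' `"passthrough-normalize"` (library normalization only), `"knn-smooth"`
#' (average each cell with its `k - 1` nearest neighbours in normalized
#' log space; `k = 1` is the identity), or `"external-adapter"` (call a
#' user-supplied `adapter(counts)`).
#'
#' @param counts Genes x cells count matrix.
#' @param method One of the three contract methods.
#' @param k Neighbourhood size for `"knn-smooth"`.
#' @param adapter Function for `"external-adapter"`.
#' @return Dense non-negative matrix, layer `"denoised"`.
#' @export
denoise <- function(counts,
                    method = c("passthrough-normalize", "knn-smooth",
                               "external-adapter"),
                    k = 10, adapter = NULL) {
  method <- match.arg(method)
  if (method == "passthrough-normalize") {
    out <- normalize_library(counts)
  } else if (method == "knn-smooth") {
    norm <- normalize_library(counts)
    lg <- log2(norm + 1)
    d <- as.matrix(stats::dist(t(lg)))
    nn <- apply(d, 2, function(col) order(col)[seq_len(min(k, length(col)))])
    nn <- matrix(nn, ncol = ncol(norm))
    out <- vapply(seq_len(ncol(norm)), function(j)
      rowMeans(norm[, nn[, j], drop = FALSE]), numeric(nrow(norm)))
    dimnames(out) <- dimnames(norm)
  } else {
    if (is.null(adapter)) {
      stop("external-adapter requires an adapter function", call. = FALSE)
    }
    out <- adapter(counts)
    if (!all(dim(out) == dim(counts)) || any(out < 0)) {
      stop("adapter must return a non-negative matrix of the same shape",
           call. = FALSE)
    }
  }
  attr(out, "layer") <- NULL
  set_layer(as.matrix(out), "denoised")
}
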