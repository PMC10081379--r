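#' Score divergence of genes from the replication-only expectation
#'
#' Subtracts the replication-predicted expression from the observed binned
#' z-scores and summarizes each gene by the standard deviation of the
#' residual profile, `sigma_corrected`. Genes are called
#' replication-divergent when they are highly variable AND
#' `sigma_corrected` exceeds the species threshold (0.6 for *E. coli*,
#' 0.5 for *S. aureus*). Optionally computes the peak/trough amplitude
#' (fourth-highest over fourth-lowest bin value, robust to single-bin
#' outliers) from a normalized-expression profile matrix.
#'
#' @param observed Bins x genes matrix of observed binned z-scores.
#' @param predicted Bins x genes matrix of replication-only predictions
#'   (same shape and column order).
#' @param hvg_flags Logical per gene ([highly_variable_genes()]).
#' @param threshold `sigma_corrected` cutoff (default 0.6).
#' @param normalized Optional bins x genes matrix of normalized (not
#'   z-scored) expression for the peak/trough ratio.
#' @return Tibble per gene: `gene_id`, `sigma_corrected`, `highly_variable`,
#'   `divergent`, and `peak_trough` when `normalized` is given.
#' @export
divergence_score <- function(observed, predicted, hvg_flags,
                             threshold = 0.6, normalized = NULL) {
  stopifnot(all(dim(observed) == dim(predicted)),
            length(hvg_flags) == ncol(observed))
  resid <- observed - predicted
  sigma <- apply(resid, 2, stats::sd)
  out <- tibble::tibble(
    gene_id = colnames(observed) %||% paste0("gene_", seq_along(sigma)),
    sigma_corrected = sigma,
    highly_variable = hvg_flags,
    divergent = hvg_flags & sigma > threshold
  )
  if (!is.null(normalized)) {
    out$peak_trough <- apply(normalized, 2, peak_trough_ratio)
  }
  out
}

# ratio of the 4th-highest to the 4th-lowest profile value
peak_trough_ratio <- function(profile) {
  s <- sort(profile)
  n <- length(s)
  if (n < 8) return(NA_real_)
  lo <- s[4]; hi <- s[n - 3]
  if (lo <= 0) return(NA_real_)
  hi / lo
}
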