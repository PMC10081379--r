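make_counts <- function(m) count_matrix(m)

test_that("UMI filters drop cells first, then genes", {
  m <- matrix(0L, 4, 3, dimnames = list(paste0("g", 1:4), paste0("c", 1:3)))
  m[, 1] <- c(5L, 3L, 1L, 1L)   # total 10
  m[, 2] <- c(6L, 5L, 2L, 2L)   # total 15
  m[, 3] <- c(9L, 5L, 4L, 2L)   # total 20
  cm <- make_counts(m)
  expect_equal(as.matrix(filter_matrix(cm, 0, 0)), m * 1)
  f <- filter_matrix(cm, 15, 0)
  expect_equal(ncol(f), 2L)
  # gene with 49 UMI across retained cells at threshold 50 is dropped
  m2 <- matrix(50L, 2, 10, dimnames = list(c("keep", "drop"), NULL))
  m2["drop", ] <- c(5L, 5L, 5L, 5L, 5L, 5L, 5L, 5L, 5L, 4L)  # 49 total
  f2 <- filter_matrix(make_counts(m2), 0, 50)
  expect_equal(rownames(f2), "keep")
  expect_error(filter_matrix(cm, 1000, 0), "all cells")
})

test_that("library normalization equalizes totals at the median", {
  m <- matrix(1, 2, 3)
  m[, 1] <- c(60, 40); m[, 2] <- c(150, 50); m[, 3] <- c(100, 200)
  norm <- normalize_library(make_counts(m))
  expect_equal(unname(colSums(norm)), c(200, 200, 200))
  # equal depths: identity
  eq <- matrix(c(3, 7, 6, 4), 2)
  expect_equal(unname(normalize_library(make_counts(eq))[, 1]), c(3, 7))
  # single cell: median is its own total
  one <- normalize_library(make_counts(matrix(c(2, 3), 2, 1)))
  expect_equal(unname(one[, 1]), c(2, 3))
  expect_error(normalize_library(matrix(c(1, 0, 0, 0), 2)), "zero-total")
})

test_that("z-scoring is a location-scale standardization of log2 values", {
  m <- matrix(c(1, 4, 2, 2), 2, 2, byrow = TRUE,
              dimnames = list(c("var", "flat"), NULL))
  z <- zscore_log(m, pseudocount = 0)
  # two-cell gene (1, 4): log2 = (0, 2) -> z = (-1, +1)
  expect_equal(unname(z["var", ]), c(-1, 1))
  # constant gene: all-zero row, flagged
  expect_equal(unname(z["flat", ]), c(0, 0))
  expect_true("flat" %in% attr(z, "flat_genes"))
  # scaling a gene by 10x leaves its z-row unchanged
  z10 <- zscore_log(m * 10, pseudocount = 0)
  expect_equal(z10["var", ], z["var", ])
  # idempotent re-standardization
  expect_equal(unname(zscore_log(z)), unname(z), ignore_attr = TRUE)
})

test_that("positional binning averages member genes over half-open bins", {
  gm <- genome_model(
    data.frame(gene_id = c("a", "b", "c"),
               start = c(10e3, 20e3, 160e3), end = c(11e3, 21e3, 161e3)),
    genome_length = 2.9e6, ori_position = 0, ter_position = 1.45e6)
  z <- matrix(c(1, -1, 3, 1, 0, 2), 3, 2,
              dimnames = list(c("a", "b", "c"), NULL))
  b <- bin_genes_by_position(z, gm, 50e3)
  # genes a and b share bin 1: averaged; gene c alone in bin 4
  expect_equal(unname(b[1, ]), c((1 - 1) / 2, (1 + 0) / 2))
  expect_equal(unname(b[2, ]), c(3, 2))
  # a 2.9 Mb genome at 50 kb bins can hold at most 58 bins
  expect_lte(nrow(b) + length(attr(b, "empty_bins")), 58)
  expect_error(bin_genes_by_position(z, gm, 0), "positive")
})

test_that("correlation maps flag duplicate and constant bins", {
  set.seed(20)
  b <- matrix(rnorm(40), 4, 10)
  b[2, ] <- b[1, ]            # duplicate bin
  cc <- gene_correlation_map(b)
  expect_equal(cc[1, 2], 1)
  expect_true(isSymmetric(cc))
  b[3, ] <- 5                 # constant bin
  expect_warning(cc2 <- gene_correlation_map(b), "constant")
  expect_equal(cc2[3, 4], 0)
  expect_error(gene_correlation_map(b[, 1:2]), "3 cells")
})

test_that("dosage structure appears in position-binned count correlations", {
  gm <- make_test_genome(n = 300)
  syn <- generate_sc_counts(gm, n_cells = 1500, depth_mean = 1000,
                            promoter_strength = rep(1, 300), seed = 21)
  bc <- bin_counts_by_position(syn$counts, gm, 1e5)
  cc <- gene_correlation_map(zscore_log(normalize_library(bc)))
  starts <- attr(bc, "bin_start")
  gm_bins <- genome_model(
    data.frame(gene_id = rownames(bc), start = starts, end = starts + 1),
    genome_length = attr(gm, "genome_length"),
    ori_position = attr(gm, "ori_position"),
    ter_position = attr(gm, "ter_position"))
  D <- gm_bins$origin_distance
  # arm-mirrored bins (similar D, opposite arms) correlate positively and
  # clearly above the off-diagonal background
  right <- which(gm_bins$arm == "right"); left <- which(gm_bins$arm == "left")
  mirror <- vapply(right, function(i) {
    j <- left[which.min(abs(D[left] - D[i]))]
    cc[i, j]
  }, 0)
  expect_gt(mean(mirror), 0.15)
  expect_gt(mean(mirror), mean(cc[upper.tri(cc)]) + 0.15)
  # stationary phase (no replication structure): flat multinomial counts
  # leave only weak compositional/sampling residue off the diagonal
  set.seed(22)
  flat <- count_matrix(matrix(rpois(300 * 1000, 2), 300, 1000,
                              dimnames = list(gm$gene_id, NULL)))
  ccf <- gene_correlation_map(zscore_log(normalize_library(
    bin_counts_by_position(flat, gm, 1e5))))
  expect_lt(mean(abs(ccf[upper.tri(ccf)])), 0.1)
})

test_that("LOWESS variance ratio flags engineered high-amplitude genes", {
  gm <- make_test_genome(n = 100)
  # a strong post-replication pulse gives ~10x cycle amplitude while the
  # profile stays positive (a 10x mean-preserving scaling would clamp at
  # zero and be dropped by the zero-bin rule)
  ts <- data.frame(gene_id = "g050", class = "pulse", pulse_height = 9,
                   pulse_tau = 8)
  syn <- generate_sc_counts(gm, n_cells = 3000, depth_mean = 135,
                            promoter_strength = rep(1, 100), trip_spec = ts,
                            seed = 23)
  theta <- syn$truth$cells$phase * 360
  hvg <- highly_variable_genes(syn$counts, theta)
  expect_true(hvg$highly_variable[hvg$gene_id == "g050"])
  expect_gt(hvg$ratio[hvg$gene_id == "g050"],
            hvg$ratio[hvg$gene_id == "g051"])
  expect_error(highly_variable_genes(syn$counts[, 1:10], theta[1:10]),
               "20 cells")
})

test_that("flat genes at high mean are not called highly variable", {
  set.seed(24)
  m <- matrix(rpois(80 * 2000, 10), 80, 2000,
              dimnames = list(sprintf("f%02d", 1:80), NULL))
  hvg <- highly_variable_genes(count_matrix(m), runif(2000, 0, 360))
  expect_lt(mean(hvg$highly_variable), 0.35)
})

test_that("HVG fraction on canonical dosage data sits near a quarter", {
  gm <- make_test_genome(n = 150)
  syn <- generate_sc_counts(gm, n_cells = 4000, depth_mean = 135, seed = 25)
  theta <- syn$truth$cells$phase * 360
  hvg <- highly_variable_genes(syn$counts, theta)
  frac <- mean(hvg$highly_variable, na.rm = TRUE)
  expect_gte(frac, 0.10)
  expect_lte(frac, 0.40)
})

test_that("denoising contract: passthrough and knn-smooth behave as stated", {
  set.seed(26)
  m <- matrix(rpois(40 * 60, 5), 40, 60,
              dimnames = list(paste0("g", 1:40), paste0("c", 1:60)))
  cm <- count_matrix(m)
  norm <- normalize_library(cm)
  pass <- denoise(cm, "passthrough-normalize")
  expect_equal(unname(pass), unname(norm), ignore_attr = TRUE)
  k1 <- denoise(cm, "knn-smooth", k = 1)
  expect_equal(unname(k1), unname(norm), ignore_attr = TRUE)
  # smoothing shrinks Poisson variance of flat genes
  k10 <- denoise(cm, "knn-smooth", k = 10)
  expect_lt(mean(apply(k10, 1, var)), mean(apply(norm, 1, var)))
  expect_error(denoise(cm, "external-adapter"), "adapter")
  doubled <- denoise(cm, "external-adapter", adapter = function(x)
    as.matrix(x) * 2)
  expect_equal(unname(doubled), unname(as.matrix(m) * 2),
               ignore_attr = TRUE)
})
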