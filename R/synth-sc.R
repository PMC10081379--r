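#' Deterministic per-cell copy number of a locus across the cell cycle
#'
#' Closed-form steady-state dosage schedule: with initiation every `t_d`
#' minutes, a fork reaching a locus `D` bp from *oriC* after `D / v` minutes,
#' and division `t_D` minutes after termination, the copy number of the
#' locus in a cell of age `a` is
#' `2 ^ floor((t_c + t_D - D/v + a) / t_d)` relative to one copy per
#' terminus-adjacent chromosome at birth. This is the deterministic
#' counterpart of the stochastic simulator in [simulate_copy_numbers()]:
#' truth is exact per cell, which is what parameter-recovery tests need.
#'
#' @param origin_distance Distance from *oriC* in bp (vector over genes).
#' @param phase Cell-cycle phase in `[0, 1)` (vector over cells); age is
#'   `phase * t_d`.
#' @param t_d Doubling time, minutes.
#' @param t_c C-period, minutes (time for a fork to run *oriC* to *ter*).
#' @param t_post D-period, minutes (termination to division).
#' @param arm_length Arm length in bp used to convert `t_c` into a fork
#'   speed `v = arm_length / t_c`.
#' @return List: `copies` (genes x cells matrix), `since_rep` (minutes since
#'   the locus was last replicated, same shape), `rep_phase` (per-gene phase
#'   in `[0,1)` at which the locus is replicated), `init_phase` (phase of
#'   replication initiation, i.e. the `D = 0` locus).
#' @export
copy_number_profile <- function(origin_distance, phase, t_d, t_c = 42,
                                t_post = 20, arm_length = 2.3e6) {
  v <- arm_length / t_c                      # bp per minute
  age <- phase * t_d
  lead <- t_c + t_post - origin_distance / v # minutes from locus replication
  u <- outer(lead, age, "+") / t_d           # to the division defining age 0
  list(copies = 2^floor(u),
       since_rep = (u - floor(u)) * t_d,
       rep_phase = ((origin_distance / v - t_c - t_post) %% t_d) / t_d,
       init_phase = ((-t_c - t_post) %% t_d) / t_d)
}

#' Generate a synthetic UMI count matrix with known cell-cycle ground truth
#'
#' Emulates an unsynchronized exponential population profiled by sparse
#' single-cell RNA-seq: per-cell cycle phases drawn uniformly, per-gene copy
#' numbers from the deterministic replication schedule on real bp
#' coordinates, expected expression = copy number x promoter strength x a
#' TRIP-class modifier, and UMIs allocated multinomially at a lognormal
#' per-cell depth (mean 135 transcripts per cell by default).
#'
#' TRIP classes engineer known divergences from the dosage-only expectation:
#' \describe{
#'   \item{canonical}{pure dosage: expression follows copy number.}
#'   \item{pulse}{a repression-release style burst after replication,
#'     multiplying expression by `1 + pulse_height * exp(-dt / pulse_tau)`
#'     with `dt` minutes since the locus was replicated.}
#'   \item{delayed}{the dosage step shifted later by
#'     `tss_distance / v_rnap`, the time for RNA polymerase to travel from
#'     the transcription-unit start to the gene.}
#'   \item{amplified}{mean-preserving scaling of the cycle profile by
#'     `amp_factor` (heterometry).}
#' }
#'
#' @param gm A `genome_model` supplying gene coordinates and origin
#'   distances.
#' @param n_cells Number of cells.
#' @param depth_mean Mean transcripts per cell (lognormal, `depth_sdlog`).
#' @param trip_spec Optional tibble with `gene_id`, `class` and class
#'   parameters (`pulse_height`, `pulse_tau` minutes, `tss_distance` bp,
#'   `v_rnap` nt/s, `amp_factor`); genes not listed are canonical.
#' @param replication_params List with `t_d`, `t_c`, `t_post` (minutes); arm
#'   lengths come from `gm`.
#' @param promoter_strength Optional per-gene positive weights (recycled);
#'   default lognormal strengths drawn under `seed`.
#' @param depth_sdlog Lognormal sd of per-cell depth on the log scale.
#' @param seed Integer seed; with it fixed the output is bit-identical.
#' @return List with `counts` (sparse genes x cells UMI matrix) and `truth`
#'   (list of `cells` tibble: barcode, phase; `genes` tibble: gene_id,
#'   promoter_strength, class, rep_phase, origin_distance; and the generator
#'   parameters).
#' @export
generate_sc_counts <- function(gm, n_cells = 2000, depth_mean = 135,
                               trip_spec = NULL,
                               replication_params = list(t_d = 26, t_c = 42,
                                                         t_post = 20),
                               promoter_strength = NULL, depth_sdlog = 0.35,
                               seed = 1) {
  set.seed(seed)
  rp <- replication_params
  arms <- arm_lengths(gm)
  n_genes <- nrow(gm)
  if (!is.null(trip_spec)) {
    unknown <- setdiff(trip_spec$gene_id, gm$gene_id)
    if (length(unknown)) {
      stop("trip_spec references unknown gene(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  phase <- stats::runif(n_cells)
  if (is.null(promoter_strength)) {
    promoter_strength <- stats::rlnorm(n_genes, meanlog = 0, sdlog = 1)
  }
  promoter_strength <- rep_len(promoter_strength, n_genes)

  # per-arm fork travel uses that arm's own length so both arms finish at ter
  expected <- matrix(0, n_genes, n_cells)
  since_rep <- matrix(0, n_genes, n_cells)
  rep_phase <- numeric(n_genes)
  spec <- trip_class_table(gm, trip_spec)
  for (arm in c("right", "left")) {
    idx <- which(gm$arm == arm)
    if (!length(idx)) next
    d_eff <- gm$origin_distance[idx]
    # a delayed gene sees its dosage step tss_distance / v_rnap minutes late,
    # equivalent to sitting (tss_distance / v_rnap) * v_dnap bp further out
    delay_min <- spec$delay_min[idx]
    v_dnap <- arms[[arm]] / rp$t_c
    cp <- copy_number_profile(d_eff + delay_min * v_dnap, phase,
                              t_d = rp$t_d, t_c = rp$t_c, t_post = rp$t_post,
                              arm_length = arms[[arm]])
    expected[idx, ] <- cp$copies
    since_rep[idx, ] <- cp$since_rep
    rep_phase[idx] <- cp$rep_phase
  }
  pulse <- spec$class == "pulse"
  if (any(pulse)) {
    expected[pulse, ] <- expected[pulse, , drop = FALSE] *
      (1 + spec$pulse_height[pulse] *
         exp(-since_rep[pulse, , drop = FALSE] / spec$pulse_tau[pulse]))
  }
  amp <- spec$class == "amplified"
  if (any(amp)) {
    m <- rowMeans(expected[amp, , drop = FALSE])
    expected[amp, ] <- pmax(0, m + spec$amp_factor[amp] *
                              (expected[amp, , drop = FALSE] - m))
  }
  expected <- expected * promoter_strength

  depth <- pmax(0L, as.integer(round(stats::rlnorm(
    n_cells, meanlog = log(depth_mean) - depth_sdlog^2 / 2, sdlog = depth_sdlog))))
  counts <- vapply(seq_len(n_cells), function(j) {
    if (depth[j] == 0 || sum(expected[, j]) == 0) return(integer(n_genes))
    as.integer(stats::rmultinom(1, depth[j], expected[, j]))
  }, integer(n_genes))
  barcodes <- sprintf("cell_%05d", seq_len(n_cells))
  cm <- count_matrix(counts, gene_ids = gm$gene_id, barcodes = barcodes)
  list(
    counts = cm,
    truth = list(
      cells = tibble::tibble(barcode = barcodes, phase = phase,
                             depth = depth),
      genes = tibble::tibble(gene_id = gm$gene_id,
                             promoter_strength = promoter_strength,
                             class = spec$class, rep_phase = rep_phase,
                             origin_distance = gm$origin_distance),
      init_phase = ((-rp$t_c - rp$t_post) %% rp$t_d) / rp$t_d,
      params = list(replication = rp, depth_mean = depth_mean,
                    depth_sdlog = depth_sdlog, seed = seed)
    )
  )
}

# expand a user trip_spec against the gene table, filling canonical defaults
trip_class_table <- function(gm, trip_spec) {
  out <- tibble::tibble(gene_id = gm$gene_id, class = "canonical",
                        pulse_height = 0, pulse_tau = 5, delay_min = 0,
                        amp_factor = 1)
  if (is.null(trip_spec)) return(out)
  ts <- tibble::as_tibble(trip_spec)
  i <- match(ts$gene_id, out$gene_id)
  out$class[i] <- ts$class
  if (!is.null(ts[["pulse_height"]])) out$pulse_height[i] <- ts[["pulse_height"]]
  if (!is.null(ts[["pulse_tau"]])) out$pulse_tau[i] <- ts[["pulse_tau"]]
  if (!is.null(ts[["tss_distance"]])) {
    v_rnap <- if (is.null(ts[["v_rnap"]])) 32 else ts[["v_rnap"]]   # nt/s
    out$delay_min[i] <- ts[["tss_distance"]] / (v_rnap * 60)
  }
  if (!is.null(ts[["amp_factor"]])) out$amp_factor[i] <- ts[["amp_factor"]]
  out$pulse_height[out$class != "pulse"] <- 0
  out$delay_min[out$class != "delayed"] <- 0
  out$amp_factor[out$class != "amplified"] <- 1
  out
}

#' Generate a synthetic growth curve
#'
#' `A600 = a0 * 2^(t / t_d) * exp(eps)`, `eps ~ N(0, noise_sd^2)`.
#'
#' @param t_d Doubling time, minutes (> 0).
#' @param times Sampling times, minutes.
#' @param noise_sd Multiplicative lognormal noise sd (0 = noiseless).
#' @param seed Integer seed.
#' @param a0 Optical density at time 0.
#' @return Tibble with `time_min`, `a600`.
#' @export
generate_growth_curve <- function(t_d, times = seq(0, 120, by = 10),
                                  noise_sd = 0, seed = 1, a0 = 0.005) {
  stopifnot(t_d > 0)
  set.seed(seed)
  tibble::tibble(
    time_min = times,
    a600 = a0 * 2^(times / t_d) * exp(stats::rnorm(length(times), 0, noise_sd))
  )
}
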