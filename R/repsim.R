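#' Expected steps between replication initiations for a target doubling time
#'
#' The gene-dosage simulator works in discrete steps, one step being the time
#' for a replication fork to advance one gene. To simulate a culture with
#' doubling time `t_d` when a full origin-to-terminus round (the C-period)
#' takes `t_c` minutes, initiations must fire every `mu = n * t_d / t_c`
#' steps, `n` being the number of genes in the longest replication unit.
#'
#' @param n Genes in the longest replication unit (e.g. 100 for a two-arm
#'   200-gene genome).
#' @param t_d Doubling time, minutes.
#' @param t_c C-period (time for one origin-to-terminus round), minutes.
#' @return Expected steps between initiations (numeric scalar).
#' @export
mu_from_doubling <- function(n, t_d, t_c) {
  stopifnot(n > 0, t_d > 0, t_c > 0)
  n * t_d / t_c
}

#' Partition a gene circle into replication units
#'
#' Splits `n_genes` genes arranged on a circular chromosome into directed
#' replication units under the rules: all origins initiate simultaneously;
#' replication halts at the terminus; each gene is replicated by the nearest
#' origin whose fork can reach it without passing through *ter*. Each unit is
#' a contiguous run of gene indices ordered from its origin toward *ter*.
#'
#' @param origins Integer gene indices (1-based) of replication origins.
#' @param ter Integer gene index of the terminus.
#' @param n_genes Total genes on the circle.
#' @return List of integer vectors, one per (origin, direction) unit, each
#'   ordered by distance from the unit's origin; every gene appears exactly
#'   once. Units are named `"<origin>_cw"` / `"<origin>_ccw"`.
#' @export
partition_replication_units <- function(origins, ter, n_genes) {
  origins <- as.integer(origins)
  if (anyDuplicated(origins)) stop("origins must be distinct", call. = FALSE)
  if (ter %in% origins) stop("an origin coincides with ter", call. = FALSE)
  n <- n_genes
  genes <- seq_len(n)
  # candidate (origin, direction) with circular distance; a fork travelling
  # from origin o in direction dir reaches g only if ter is not strictly
  # between o and g along that direction
  best_unit <- character(n)
  best_dist <- integer(n)
  for (g in genes) {
    cand_unit <- character(0); cand_dist <- integer(0); cand_rank <- numeric(0)
    for (oi in seq_along(origins)) {
      o <- origins[oi]
      d_cw <- (g - o) %% n
      d_ccw <- (o - g) %% n
      t_cw <- (ter - o) %% n
      t_ccw <- (o - ter) %% n
      if (t_cw >= d_cw) {
        cand_unit <- c(cand_unit, paste0(o, "_cw"))
        cand_dist <- c(cand_dist, d_cw)
        # on an exact tie prefer clockwise for the origin gene itself and
        # counterclockwise at the far boundary, so the two arms split evenly
        cand_rank <- c(cand_rank, oi + if (d_cw == 0) 0 else 0.5)
      }
      if (t_ccw >= d_ccw) {
        cand_unit <- c(cand_unit, paste0(o, "_ccw"))
        cand_dist <- c(cand_dist, d_ccw)
        cand_rank <- c(cand_rank, oi + if (d_ccw == 0) 0.5 else 0.25)
      }
    }
    if (!length(cand_unit)) stop("gene ", g, " unreachable", call. = FALSE)
    pick <- order(cand_dist, cand_rank)[1]
    best_unit[g] <- cand_unit[pick]
    best_dist[g] <- cand_dist[pick]
  }
  units <- split(genes, best_unit)
  dists <- split(best_dist, best_unit)
  out <- lapply(seq_along(units), function(i) units[[i]][order(dists[[i]])])
  names(out) <- names(units)
  out
}

#' Simulation configuration for the gene-dosage replication simulator
#'
#' @param n_genes Number of genes (default 200).
#' @param units Replication units as produced by
#'   [partition_replication_units()]; default two arms of `n_genes/2`.
#' @param t_d,t_c Doubling time and C-period in minutes; together with the
#'   longest unit they set `mu` via [mu_from_doubling()].
#' @param mu Expected steps between initiations; overrides `t_d`/`t_c` when
#'   given.
#' @param division_offset Steps between the first initiation and the first
#'   division; default 1.5x the longest replication unit (150 steps for the
#'   canonical 100-gene arms, matching a 40 min C + 20 min D period at 100
#'   steps per round).
#' @param n_cells Cells in the ensemble (default 1000).
#' @param burn_in Steps of joint burn-in after staggered initiation
#'   (default 1000).
#' @param seed Integer seed for the Poisson waiting-time draws.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 200, units = NULL, t_d = 26, t_c = 42,
                       mu = NULL, division_offset = NULL, n_cells = 1000,
                       burn_in = 1000, seed = 1) {
  if (is.null(units)) {
    units <- partition_replication_units(1L, as.integer(n_genes / 2 + 1),
                                         n_genes)
  }
  if (is.null(division_offset)) division_offset <- 1.5 * max(lengths(units))
  if (length(unique(sort(unlist(units)))) != n_genes) {
    stop("replication units must partition all genes", call. = FALSE)
  }
  if (is.null(mu)) mu <- mu_from_doubling(max(lengths(units)), t_d, t_c)
  if (mu <= 0) stop("mu must be positive", call. = FALSE)
  structure(list(n_genes = n_genes, units = units, mu = mu,
                 division_offset = division_offset, n_cells = n_cells,
                 burn_in = burn_in, t_d = t_d, t_c = t_c, seed = seed),
            class = "sim_config")
}

# event times at Poisson-distributed intervals (expected value mu steps,
# floored at one step), first event after the same law, truncated at horizon
poisson_event_times <- function(mu, horizon, offset = 0) {
  t <- offset
  out <- numeric(0)
  while (TRUE) {
    t <- t + max(1, stats::rpois(1, mu))
    if (t > horizon) break
    out <- c(out, t)
  }
  out
}

#' Simulate per-cell gene copy numbers under replication and division
#'
#' Runs the discrete-time dosage simulator: in each cell, replication
#' initiation events fire at intervals drawn from a Poisson distribution
#' with expected value `mu` steps; each initiation launches a fork at the
#' origin of every replication unit which advances one gene per step,
#' doubling the copy number as it passes; division events halve all copy
#' numbers (rounding up, so copies stay >= 1), starting `division_offset`
#' steps after the first initiation and recurring at independent
#' Poisson-distributed intervals. Cells are initiated one at a time (cell i
#' runs i extra steps) and then share a joint burn-in, yielding an
#' unsynchronized ensemble. The low dispersion of Poisson intervals
#' (sd ~ sqrt(mu)) is what preserves the replication-period resonance that
#' nests the correlation pattern under overlapping rounds.
#'
#' The per-gene copy number at the final step is computed exactly from the
#' event history: doublings and ceil-halvings of powers of two form a
#' reflected walk on the exponent, whose endpoint is the maximum suffix sum
#' of the signed event sequence (a Lindley recursion).
#'
#' @param config A [sim_config()].
#' @return List with `copies` (genes x cells integer matrix), `forks` (list
#'   per cell of per-unit active fork positions, in genes from the unit
#'   origin) and the `config`.
#' @export
simulate_copy_numbers <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_genes
  copies <- matrix(1, n, config$n_cells)
  forks <- vector("list", config$n_cells)
  unit_offsets <- lapply(config$units, function(u) seq_along(u) - 1)
  for (cell in seq_len(config$n_cells)) {
    horizon <- config$burn_in + cell
    inits <- poisson_event_times(config$mu, horizon)
    divs <- if (length(inits)) {
      first_div <- inits[1] + config$division_offset
      c(first_div, poisson_event_times(config$mu, horizon, offset = first_div))
    } else numeric(0)
    divs <- divs[divs <= horizon]
    cell_forks <- vector("list", length(config$units))
    for (ui in seq_along(config$units)) {
      unit <- config$units[[ui]]
      offs <- unit_offsets[[ui]]
      len <- length(unit)
      cell_forks[[ui]] <- (horizon - inits)[horizon - inits < len]
      if (!length(inits) && !length(divs)) next
      for (j in seq_along(unit)) {
        dbl <- inits + offs[j]
        dbl <- dbl[dbl <= horizon]
        times <- c(dbl, divs)
        if (!length(times)) next
        sgn <- c(rep(1, length(dbl)), rep(-1, length(divs)))
        # at equal times the doubling acts before the halving
        ord <- order(times, -sgn)
        suffix <- rev(cumsum(rev(sgn[ord])))
        copies[unit[j], cell] <- 2^max(0, suffix)
      }
    }
    forks[[cell]] <- cell_forks
  }
  list(copies = copies, forks = forks, config = config)
}

#' Gene-gene Spearman correlation of simulated (or observed) copy numbers
#'
#' Normalizes each cell by its total and computes the gene-gene Spearman
#' correlation matrix across cells. This is the simulator's prediction of
#' the chromosome-position-dependent correlation pattern (the "X" of two
#' arms, nesting into a "multi-X" under overlapping replication rounds).
#'
#' @param state Output of [simulate_copy_numbers()], or a genes x cells
#'   matrix.
#' @return Symmetric genes x genes Spearman matrix with unit diagonal;
#'   constant genes yield 0 off-diagonal entries with a warning.
#' @export
simulated_correlation_matrix <- function(state) {
  m <- if (is.list(state)) state$copies else state
  if (ncol(m) < 2) stop("need at least 2 cells", call. = FALSE)
  norm <- sweep(m, 2, colSums(m), "/")
  cc <- suppressWarnings(stats::cor(t(norm), method = "spearman"))
  if (anyNA(cc)) {
    warning("constant gene(s): undefined correlations set to 0")
    cc[is.na(cc)] <- 0
  }
  diag(cc) <- 1
  cc
}
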