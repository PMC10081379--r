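#' Generate a synthetic smFISH per-cell table with known parameters
#'
#' Draws per-cell observables from the package's own forward models:
#' lengths from the Gaussian-smoothed `2 L0 / L^2` law
#' ([sample_lengths()]), mRNA counts Poisson-distributed around the
#' two-Hill dosage mean ([hill_dosage_mean()]), DAPI fluorescence
#' proportional to the piecewise-linear DNA content ([dna_content()]) with
#' Gaussian noise, and projected areas from the spherocylinder forward
#' model at a fixed cell width.
#'
#' @param params List of generator parameters with elements
#'   `L0`, `sigma` (length law, micrometres), `hill` (list `c_base`, `Lr`,
#'   `k`, `n2`), `dna` (list `T`, `T_C`, `T_D`, minutes; must satisfy the
#'   regime `max(T_D, T_C/2) < T < (T_C + T_D)/2`), `dapi_scale`,
#'   `dapi_noise_sd` (a.u.), and `width` (micrometres).
#' @param n_cells Number of cells (0 gives an empty table).
#' @param seed Integer seed; output is bit-identical for a fixed seed.
#' @return Tibble with `cell_id`, `length_um`, `area_um2`, `mrna_count`,
#'   `dapi_au`; the generator parameters are attached as attribute
#'   `"params"`.
#' @export
generate_smfish_cells <- function(params = smfish_params(), n_cells = 2000,
                                  seed = 1) {
  p <- utils::modifyList(smfish_params(), params)
  check_dna_regime(p$dna$T, p$dna$T_C, p$dna$T_D)
  if (n_cells == 0) {
    return(tibble::tibble(cell_id = character(), length_um = numeric(),
                          area_um2 = numeric(), mrna_count = integer(),
                          dapi_au = numeric()))
  }
  set.seed(seed)
  L <- sample_lengths(n_cells, p$L0, p$sigma)
  L <- pmax(L, p$width * 1.01)   # segmentation cannot yield L < width
  mu <- hill_dosage_mean(L, p$hill$c_base, p$hill$Lr, p$hill$k, p$hill$n2)
  mrna <- stats::rpois(n_cells, mu)
  # age from length through exponential elongation, clamped to one cycle
  age <- p$dna$T * log2(pmin(pmax(L / p$L0, 1), 2 - 1e-9))
  g <- dna_content(age, p$dna$T, p$dna$T_C, p$dna$T_D)
  dapi <- p$dapi_scale * as.numeric(g) +
    stats::rnorm(n_cells, 0, p$dapi_noise_sd)
  out <- tibble::tibble(
    cell_id = sprintf("cell_%05d", seq_len(n_cells)),
    length_um = L,
    area_um2 = spherocylinder_area(L, p$width),
    mrna_count = mrna,
    dapi_au = dapi
  )
  attr(out, "params") <- p
  out
}

#' Default smFISH generator parameters
#'
#' Length-law parameters follow the fitted values for exponentially growing
#' *E. coli* (`L0` 3.43 um, `sigma` 0.56 um); the DNA content periods use
#' the classic fast-growth configuration `T = 26`, `T_C = 42`, `T_D = 20`
#' minutes; the Hill dosage defaults describe a mid-replichore gene
#' (`c_base = 5`, `Lr = 4` um, `k = 10`, `n2 = 2`).
#'
#' @return Named list of parameters accepted by [generate_smfish_cells()].
#' @export
smfish_params <- function() {
  list(L0 = 3.43, sigma = 0.56,
       hill = list(c_base = 5, Lr = 4, k = 10, n2 = 2),
       dna = list(T = 26, T_C = 42, T_D = 20),
       dapi_scale = 100, dapi_noise_sd = 15, width = 1.0)
}
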