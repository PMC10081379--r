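#' Build a circular genome model from GFF3 gene annotation
#'
#' Constructs the per-gene coordinate table used everywhere downstream:
#' 0-based midpoints, replichore arm assignment, and the origin distance `D`
#' measured as the circular arc from *oriC* along the gene's own arm (never
#' crossing *ter*). The chromosome is treated as circular with arithmetic
#' modulo `genome_length`; GFF 1-based starts are converted on read.
#'
#' @param gff_path Path to a GFF3 file with `gene` features.
#' @param ori_position,ter_position Replication origin and terminus positions
#'   in 0-based bp. Both required.
#' @param genome_length Chromosome length in bp. If `NULL`, taken from a
#'   `##sequence-region` pragma in the GFF.
#' @return A `genome_model`: a tibble with columns `gene_id`, `start`, `end`
#'   (0-based, half-open), `strand`, `midpoint`, `arm` (`"right"` for the
#'   replichore running from *oriC* in the direction of increasing
#'   coordinates, `"left"` otherwise) and `origin_distance` (bp), with
#'   attributes `genome_length`, `ori_position`, `ter_position`.
#' @export
build_genome_model <- function(gff_path, ori_position, ter_position,
                               genome_length = NULL) {
  if (missing(ori_position) || missing(ter_position) ||
      is.null(ori_position) || is.null(ter_position)) {
    stop("ori_position and ter_position must be configured", call. = FALSE)
  }
  lines <- readLines(gff_path)
  if (is.null(genome_length)) {
    sr <- grep("^##sequence-region", lines, value = TRUE)
    if (!length(sr)) {
      stop("genome_length not given and no ##sequence-region pragma in GFF",
           call. = FALSE)
    }
    genome_length <- as.numeric(strsplit(sr[1], "\\s+")[[1]][4])
  }
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  fields <- strsplit(body, "\t", fixed = TRUE)
  fields <- fields[vapply(fields, length, 1L) >= 9]
  type <- vapply(fields, `[[`, "", 3L)
  fields <- fields[type == "gene"]
  if (!length(fields)) stop("no gene features in GFF", call. = FALSE)
  start1 <- as.numeric(vapply(fields, `[[`, "", 4L))
  end1 <- as.numeric(vapply(fields, `[[`, "", 5L))
  strand <- vapply(fields, `[[`, "", 7L)
  attrs <- vapply(fields, `[[`, "", 9L)
  gene_id <- sub(".*(?:^|;)ID=([^;]+).*", "\\1", attrs)
  genome_model(
    tibble::tibble(gene_id = gene_id, start = start1 - 1, end = end1,
                   strand = strand),
    genome_length = genome_length,
    ori_position = ori_position, ter_position = ter_position
  )
}

#' Assemble a genome model from a gene coordinate table
#'
#' Programmatic counterpart of [build_genome_model()] used by the synthetic
#' generators and tests.
#'
#' @param genes Data frame with `gene_id`, `start`, `end` (0-based half-open
#'   bp) and optionally `strand` (defaults to `"+"`).
#' @inheritParams build_genome_model
#' @return A `genome_model` tibble; see [build_genome_model()].
#' @export
genome_model <- function(genes, genome_length, ori_position, ter_position) {
  genes <- tibble::as_tibble(genes)
  if (is.null(genes[["strand"]])) genes$strand <- "+"
  if (any(genes$start < 0 | genes$end > genome_length)) {
    stop("gene coordinates outside [0, genome_length)", call. = FALSE)
  }
  L <- genome_length
  ori <- ori_position %% L
  ter <- ter_position %% L
  genes$midpoint <- floor((genes$start + genes$end) / 2) %% L
  arc_right <- (ter - ori) %% L
  d_right <- (genes$midpoint - ori) %% L
  on_right <- d_right <= arc_right
  genes$arm <- ifelse(on_right, "right", "left")
  genes$origin_distance <- ifelse(on_right, d_right,
                                  (ori - genes$midpoint) %% L)
  out <- genes[, c("gene_id", "start", "end", "strand", "midpoint", "arm",
                   "origin_distance")]
  attr(out, "genome_length") <- L
  attr(out, "ori_position") <- ori
  attr(out, "ter_position") <- ter
  class(out) <- c("genome_model", class(out))
  out
}

#' Arm arc lengths of a genome model
#' @param gm A `genome_model`.
#' @return Named numeric vector `c(right=, left=)` of *oriC*-to-*ter* arcs (bp).
#' @export
arm_lengths <- function(gm) {
  L <- attr(gm, "genome_length")
  right <- (attr(gm, "ter_position") - attr(gm, "ori_position")) %% L
  c(right = right, left = L - right)
}

#' Distance of each gene from its transcription-unit start site
#'
#' Measures, along the direction of transcription, the distance from the
#' annotated transcription-unit (TU) start site to each member gene. Genes
#' belonging to several TUs are assigned the longest distance from any start
#' site. Genes whose computed distance is negative (midpoint upstream of the
#' TSS under the gene's strand) are flagged and excluded from downstream
#' delay regressions, as are genes absent from any TU.
#'
#' @param operon_table Data frame with columns `tu_id`, `tss_pos` (0-based
#'   bp) and `gene_id`; one row per TU membership.
#' @param gm A `genome_model`.
#' @param anchor Gene anchor for the distance: `"midpoint"` (default) or
#'   `"start"` (first base of the gene), the latter matching annotations
#'   where operon starts are proxied by the first gene's start.
#' @return Tibble with one row per gene of `gm`: `gene_id`, `tss_distance`
#'   (bp; `NA` when flagged), `n_tus`, `polycistronic` (member of any TU with
#'   more than one gene), and `flagged`.
#' @export
tss_distance <- function(operon_table, gm, anchor = c("midpoint", "start")) {
  anchor <- match.arg(anchor)
  operon_table <- tibble::as_tibble(operon_table)
  L <- attr(gm, "genome_length")
  pos <- if (anchor == "midpoint") gm$midpoint else {
    ifelse(gm$strand == "-", gm$end - 1, gm$start)
  }
  lookup <- stats::setNames(seq_len(nrow(gm)), gm$gene_id)
  tu_sizes <- table(operon_table$tu_id)
  hits <- operon_table[operon_table$gene_id %in% gm$gene_id, ]
  i <- lookup[hits$gene_id]
  fwd <- gm$strand[i] != "-"
  d <- ifelse(fwd, (pos[i] - hits$tss_pos) %% L, (hits$tss_pos - pos[i]) %% L)
  # anything more than half the chromosome "downstream" is really upstream
  neg <- d > L / 2
  hits$dist <- ifelse(neg, NA_real_, d)
  hits$poly <- as.vector(tu_sizes[hits$tu_id]) > 1
  per_gene <- dplyr::summarise(
    dplyr::group_by(hits, .data$gene_id),
    tss_distance = if (all(is.na(.data$dist))) NA_real_
                   else max(.data$dist, na.rm = TRUE),
    n_tus = dplyr::n(),
    polycistronic = any(.data$poly),
    any_neg = any(is.na(.data$dist)),
    .groups = "drop"
  )
  out <- dplyr::left_join(tibble::tibble(gene_id = gm$gene_id), per_gene,
                          by = "gene_id")
  out$n_tus[is.na(out$n_tus)] <- 0L
  out$polycistronic[is.na(out$polycistronic)] <- FALSE
  out$flagged <- out$n_tus == 0L | (is.na(out$tss_distance))
  out$any_neg <- NULL
  out
}

#' Doubling time from an optical-density growth curve
#'
#' Fits the linear model `log2(A600) ~ m * time + c` by ordinary least
#' squares over the user-designated linear range and returns the doubling
#' time `t_d = 1/m` in minutes.
#'
#' @param growth_curve Data frame with columns `time_min` and `a600`.
#' @param time_range Optional length-2 numeric giving the linear portion of
#'   the curve (inclusive); defaults to all points.
#' @return A one-row tibble: `slope` (1/min), `intercept`, `t_d` (min),
#'   `n_points`, `r_squared`.
#' @export
doubling_time <- function(growth_curve, time_range = NULL) {
  gc <- tibble::as_tibble(growth_curve)
  if (!is.null(time_range)) {
    gc <- gc[gc$time_min >= time_range[1] & gc$time_min <= time_range[2], ]
  }
  if (nrow(gc) < 3) stop("need at least 3 time points in range", call. = FALSE)
  fit <- stats::lm(log2(a600) ~ time_min, data = gc)
  m <- unname(stats::coef(fit)[2])
  if (!is.finite(m) || m <= 1e-12) {
    stop("non-positive growth slope: culture not growing", call. = FALSE)
  }
  tss <- sum((log2(gc$a600) - mean(log2(gc$a600)))^2)
  tibble::tibble(slope = m, intercept = unname(stats::coef(fit)[1]),
                 t_d = 1 / m, n_points = nrow(gc),
                 r_squared = 1 - sum(stats::residuals(fit)^2) / tss)
}
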