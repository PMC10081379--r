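# shared synthetic fixtures, built in code at test time

# circular test genome: n genes of 900 bp at random starts, E. coli-like
# geometry (4.6 Mb, oriC at 3.92 Mb, ter at 1.59 Mb)
make_test_genome <- function(n = 400, genome_length = 4.6e6,
                             ori = 3.92e6, ter = 1.59e6, seed = 5) {
  set.seed(seed)
  start <- sort(sample(0:(genome_length - 1000), n))
  genome_model(
    data.frame(gene_id = sprintf("g%03d", seq_len(n)),
               start = start, end = start + 900),
    genome_length = genome_length, ori_position = ori, ter_position = ter
  )
}

# tiny GFF3 written to a temp file
write_test_gff <- function(genes, genome_length, seqid = "chr") {
  path <- tempfile(fileext = ".gff3")
  lines <- c("##gff-version 3",
             sprintf("##sequence-region %s 1 %d", seqid, genome_length),
             vapply(seq_len(nrow(genes)), function(i) {
               paste(seqid, "test", "gene", genes$start1[i], genes$end1[i],
                     ".", genes$strand[i], ".",
                     paste0("ID=", genes$gene_id[i]), sep = "\t")
             }, ""))
  writeLines(lines, path)
  path
}

# adjusted Rand index for cluster-recovery checks
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  expected <- sum_a * sum_b / n
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# mean circular offset in degrees between two angle vectors
mean_circular_offset <- function(a, b) {
  d <- (a - b) * pi / 180
  atan2(mean(sin(d)), mean(cos(d))) * 180 / pi
}
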