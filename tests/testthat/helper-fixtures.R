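# small hand-built containers used across tests

make_snp <- function(freq, n = NULL, chrom = "chr1", pos = NULL) {
  freq <- as.matrix(freq)
  if (is.null(colnames(freq))) colnames(freq) <- sprintf("P%02d", seq_len(ncol(freq)))
  if (is.null(n)) n <- matrix(100L, nrow(freq), ncol(freq))
  if (length(n) == 1) n <- matrix(as.integer(n), nrow(freq), ncol(freq))
  colnames(n) <- colnames(freq)
  if (is.null(pos)) pos <- seq_len(nrow(freq)) * 1000L
  info <- data.frame(snp_id = sprintf("snp%03d", seq_len(nrow(freq))),
                     chrom = chrom, pos = pos, stringsAsFactors = FALSE)
  snp_table(info, freq, n)
}

make_gt <- function(geno, pop = NULL, chrom = "chr1", pos = NULL) {
  geno <- as.matrix(geno)
  if (is.null(pop)) pop <- rep("P01", nrow(geno))
  if (is.null(pos)) pos <- seq_len(ncol(geno)) * 1000L
  info <- data.frame(snp_id = sprintf("snp%03d", seq_len(ncol(geno))),
                     chrom = chrom, pos = pos, stringsAsFactors = FALSE)
  genotype_table(geno, pop, info)
}

# labeled symmetric distance matrix from a numeric vector of 1-D coordinates
coord_dist <- function(x, labels = sprintf("S%02d", seq_along(x))) {
  m <- abs(outer(x, x, "-"))
  dimnames(m) <- list(labels, labels)
  m
}

# random Euclidean distance matrix over n random 2-D points
random_dist <- function(n, labels = sprintf("S%02d", seq_len(n))) {
  pts <- matrix(stats::rnorm(2 * n), n)
  m <- as.matrix(stats::dist(pts))
  dimnames(m) <- list(labels, labels)
  m
}

tiny_cfg <- function(...) {
  args <- list(...)
  defaults <- list(n_pops = 12, n_snps = 600, n_genes = 30,
                   n_adaptive_genes = 3, n_env_vars = 4, n_ind_per_pop = 8,
                   missing_rate = 0.1, seed = 42)
  do.call(sim_config, utils::modifyList(defaults, args))
}
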