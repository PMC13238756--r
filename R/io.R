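# Tabular conventions: TSV, UTF-8, header row. SNP positions are 1-based in
# TSV/VCF; interval files (BED) are 0-based half-open. Conversions are
# centralized here.

#' Write / read a SNP table as TSV
#'
#' Columns: `chrom`, `pos`, `snp_id`, optional `gene_id`, then one
#' `freq_<pop>` and one `n_<pop>` column per population.
#'
#' @param snp a [snp_table()].
#' @param path file path.
#' @return the path (write) or a [snp_table()] (read).
#' @export
write_snp_table <- function(snp, path) {
  stopifnot(inherits(snp, "snp_table"))
  df <- snp$info[, intersect(c("chrom", "pos", "snp_id", "gene_id"),
                             names(snp$info)), drop = FALSE]
  fr <- as.data.frame(snp$freq); names(fr) <- paste0("freq_", pop_names(snp))
  nn <- as.data.frame(snp$n); names(nn) <- paste0("n_", pop_names(snp))
  utils::write.table(cbind(df, fr, nn), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_snp_table
#' @export
read_snp_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  fcols <- grep("^freq_", names(df), value = TRUE)
  ncols <- grep("^n_", names(df), value = TRUE)
  pops <- sub("^freq_", "", fcols)
  stopifnot(identical(pops, sub("^n_", "", ncols)))
  freq <- as.matrix(df[, fcols, drop = FALSE]); colnames(freq) <- pops
  n <- as.matrix(df[, ncols, drop = FALSE]); colnames(n) <- pops
  info <- df[, intersect(c("snp_id", "chrom", "pos", "gene_id"), names(df)),
             drop = FALSE]
  snp_table(info, freq, n)
}

#' Write / read a labeled distance matrix as square TSV
#'
#' Header row and first column carry the labels.
#'
#' @param d a [dist_matrix()].
#' @param path file path.
#' @param kind distance kind used when reading back.
#' @return the path (write) or a [dist_matrix()] (read).
#' @export
write_dist_matrix <- function(d, path) {
  m <- as.matrix(d)
  utils::write.table(data.frame(label = rownames(m), m, check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dist_matrix
#' @export
read_dist_matrix <- function(path, kind = "marine") {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  dist_matrix(m[, rownames(m), drop = FALSE], kind)
}

#' Write / read BED intervals (0-based half-open)
#'
#' Three required columns plus an optional name/class fourth column.
#'
#' @param intervals data.frame with `chrom`, `start`, `end` and optionally a
#'   fourth id column (`gene_id`, `name` or `class`).
#' @param path file path.
#' @param name_col which column to write in BED column 4.
#' @return the path (write) or a data.frame (read).
#' @export
write_bed <- function(intervals, path, name_col = NULL) {
  cols <- intervals[, c("chrom", "start", "end"), drop = FALSE]
  if (!is.null(name_col)) cols$name <- intervals[[name_col]]
  utils::write.table(cols, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  df <- utils::read.delim(path, header = FALSE)
  names(df) <- c("chrom", "start", "end", "name")[seq_len(ncol(df))]
  df
}

#' Write genotypes as a minimal VCF v4.2 (GT field, `./.` for missing)
#'
#' Dosages 0/1/2 become `0/0`, `0/1`, `1/1`; REF/ALT are placeholder A/C.
#'
#' @param gt a [genotype_table()].
#' @param path file path.
#' @return the path, invisibly.
#' @export
write_vcf <- function(gt, path) {
  stopifnot(inherits(gt, "genotype_table"))
  ids <- rownames(gt$geno)
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", ids), collapse = "\t"))
  code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  G <- t(gt$geno)                       # SNPs x individuals
  GS <- matrix("./.", nrow(G), ncol(G))
  obs <- !is.na(G)
  GS[obs] <- code[as.character(G[obs])]
  body <- paste(gt$info$chrom, gt$info$pos, gt$info$snp_id, "A", "C", ".",
                "PASS", ".", "GT",
                apply(GS, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a VCF and derive per-population allele frequencies
#'
#' Per population, the minor-allele frequency is computed from non-missing GT
#' calls and the allele count n is 2 x the number of non-missing individuals.
#' The ALT allele is folded to the global minor allele. Multi-allelic records
#' are skipped (count in attribute `n_multiallelic_skipped`).
#'
#' @param vcf_path VCF v4.x file with a GT field.
#' @param popmap data.frame with columns `sample` and `pop`, or path to a
#'   headerless two-column TSV.
#' @return list with `snp` (a [snp_table()]) and `geno` (a
#'   [genotype_table()]).
#' @export
read_vcf_freqs <- function(vcf_path, popmap) {
  if (is.character(popmap)) {
    popmap <- utils::read.delim(popmap, header = FALSE)
    names(popmap) <- c("sample", "pop")
  }
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT)
  gtmat <- vcfR::extract.gt(v, element = "GT")
  gtmat <- gtmat[!multi, , drop = FALSE]
  fix <- fix[!multi, , drop = FALSE]
  samples <- colnames(gtmat)
  if (!all(samples %in% popmap$sample))
    stop("VCF sample(s) missing from popmap: ",
         paste(setdiff(samples, popmap$sample), collapse = ", "))
  pop <- popmap$pop[match(samples, popmap$sample)]
  # dosage of ALT allele from diploid GT strings
  dosage <- function(g) {
    a <- substr(g, 1, 1); b <- substr(g, 3, 3)
    out <- suppressWarnings(as.integer(a) + as.integer(b))
    out
  }
  D <- matrix(dosage(gtmat), nrow = nrow(gtmat),
              dimnames = dimnames(gtmat))         # SNPs x individuals
  if (all(is.na(D))) stop("no genotype calls found")
  pops <- sort(unique(pop))
  freq <- matrix(NA_real_, nrow(D), length(pops), dimnames = list(NULL, pops))
  n <- matrix(0L, nrow(D), length(pops), dimnames = list(NULL, pops))
  for (pp in pops) {
    sub <- D[, pop == pp, drop = FALSE]
    nn <- rowSums(!is.na(sub))
    n[, pp] <- 2L * nn
    freq[, pp] <- ifelse(nn > 0, rowSums(sub, na.rm = TRUE) / (2 * nn), NA_real_)
  }
  # fold ALT to the global minor allele
  tot <- rowSums(n)
  fn <- freq * n
  fn[n == 0] <- 0
  galt <- ifelse(tot > 0, rowSums(fn) / tot, 0)
  flip <- galt > 0.5
  freq[flip, ] <- 1 - freq[flip, ]
  info <- data.frame(snp_id = fix$ID, chrom = fix$CHROM,
                     pos = as.integer(fix$POS), stringsAsFactors = FALSE)
  snp <- snp_table(info, freq, n)
  attr(snp, "n_multiallelic_skipped") <- sum(multi)
  G <- t(D)
  G[!(G %in% 0:2)] <- NA_integer_
  rownames(G) <- samples
  list(snp = snp, geno = genotype_table(G, pop, info))
}

#' Dataset-level SNP filters: global MAF and coverage fraction
#'
#' SNPs are retained iff the global folded MAF strictly exceeds `maf_min`
#' and the fraction of individuals with data reaches `coverage_frac`
#' (inclusive), mirroring "above 1%" / "in at least 75%" semantics.
#'
#' @param snp a [snp_table()].
#' @param maf_min strict global MAF threshold.
#' @param coverage_frac minimum fraction of allele copies observed.
#' @param total_alleles denominator for the coverage fraction (default: the
#'   maximum observed per-SNP total).
#' @return the filtered [snp_table()] with attributes `n_before`, `n_after`.
#' @export
apply_filters <- function(snp, maf_min = 0.01, coverage_frac = 0.75,
                          total_alleles = NULL) {
  stopifnot(inherits(snp, "snp_table"))
  tot <- rowSums(snp$n)
  if (is.null(total_alleles)) total_alleles <- max(tot)
  keep <- !is.na(snp$global_maf) & snp$global_maf > maf_min &
    tot / total_alleles >= coverage_frac
  if (!any(keep)) stop("no SNPs pass the filters")
  out <- snp_table(snp$info[keep, , drop = FALSE],
                   snp$freq[keep, , drop = FALSE],
                   snp$n[keep, , drop = FALSE])
  attr(out, "n_before") <- n_snps(snp)
  attr(out, "n_after") <- n_snps(out)
  out
}
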