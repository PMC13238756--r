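#' Construct a SNP table
#'
#' The central container of the pipeline: per-SNP, per-population minor-allele
#' frequencies together with the number of allele copies that informed each
#' estimate (2 x individuals passing coverage at that SNP), plus genomic
#' positions and the global folded minor-allele frequency.
#'
#' @param info data.frame with columns `snp_id`, `chrom`, `pos` (1-based) and
#'   optionally `gene_id`.
#' @param freq numeric matrix, SNPs x populations, entries in \[0, 1\].
#' @param n integer matrix, SNPs x populations, allele-copy counts (>= 0).
#' @return An object of class `snp_table`.
#' @export
snp_table <- function(info, freq, n) {
  stopifnot(is.data.frame(info), all(c("snp_id", "chrom", "pos") %in% names(info)))
  freq <- as.matrix(freq)
  n <- as.matrix(n)
  if (nrow(freq) != nrow(info) || !identical(dim(freq), dim(n)))
    stop("freq/n dimensions must match info rows")
  if (any(freq < 0 | freq > 1, na.rm = TRUE)) stop("frequencies must lie in [0, 1]")
  if (any(is.na(freq) & n > 0)) stop("missing frequency only allowed where n = 0")
  if (any(n < 0) || any(n != round(n))) stop("allele counts must be non-negative integers")
  if (is.null(colnames(freq))) stop("freq must carry population names as colnames")
  colnames(n) <- colnames(freq)
  rownames(freq) <- rownames(n) <- info$snp_id
  structure(
    list(info = info, freq = freq, n = n, global_maf = global_maf(freq, n)),
    class = "snp_table"
  )
}

#' Global folded minor-allele frequency
#'
#' n-weighted mean of per-population frequencies, folded to <= 0.5.
#'
#' @param freq,n matrices as in [snp_table()].
#' @return numeric vector, one entry per SNP.
#' @export
global_maf <- function(freq, n) {
  tot <- rowSums(n)
  fn <- freq * n
  fn[n == 0] <- 0                      # NA frequencies only occur at n = 0
  g <- ifelse(tot > 0, rowSums(fn) / tot, NA_real_)
  pmin(g, 1 - g)
}

#' @export
print.snp_table <- function(x, ...) {
  cat(sprintf("snp_table: %d SNPs x %d populations (%d chrom)\n",
              nrow(x$freq), ncol(x$freq), length(unique(x$info$chrom))))
  invisible(x)
}

n_snps <- function(x) nrow(x$freq)
pop_names <- function(x) colnames(x$freq)

#' Construct a genotype table
#'
#' @param geno integer matrix of allele dosages (0/1/2, NA = missing),
#'   individuals x SNPs, with individual ids as rownames.
#' @param pop character vector of population labels, one per individual.
#' @param info SNP info data.frame (`snp_id`, `chrom`, `pos`), rows matching
#'   `geno` columns.
#' @return An object of class `genotype_table`.
#' @export
genotype_table <- function(geno, pop, info) {
  geno <- as.matrix(geno)
  stopifnot(length(pop) == nrow(geno), nrow(info) == ncol(geno))
  if (!all(geno %in% c(0L, 1L, 2L, NA))) stop("dosages must be 0, 1, 2 or NA")
  colnames(geno) <- info$snp_id
  if (is.null(rownames(geno))) rownames(geno) <- sprintf("ind%04d", seq_len(nrow(geno)))
  structure(list(geno = geno, pop = as.character(pop), info = info),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("genotype_table: %d individuals x %d SNPs, %d populations\n",
              nrow(x$geno), ncol(x$geno), length(unique(x$pop))))
  invisible(x)
}

#' Construct a labeled distance matrix
#'
#' @param values square numeric matrix with identical row/column labels.
#' @param kind one of `genetic_fst`, `genetic_afd`, `pdistance`, `marine`,
#'   `environmental`, `ancestry`, `residual`.
#' @return numeric matrix with a `kind` attribute, class `dist_matrix`.
#' @export
dist_matrix <- function(values,
                        kind = c("genetic_fst", "genetic_afd", "pdistance",
                                 "marine", "environmental", "ancestry", "residual")) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("distance matrix must be square")
  if (is.null(rownames(values))) stop("distance matrix must be labeled")
  if (!identical(rownames(values), colnames(values))) stop("row/column labels differ")
  if (any(!is.finite(values))) stop("distance matrix entries must be finite")
  if (max(abs(values - t(values))) > 1e-12) stop("distance matrix must be symmetric")
  if (kind != "residual" && any(abs(diag(values)) > 1e-12))
    stop("diagonal must be zero for kind ", kind)
  structure(values, kind = kind, class = c("dist_matrix", "matrix", "array"))
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat(sprintf("dist_matrix (%s): %d labels\n", attr(x, "kind"), nrow(x)))
  print(unclass(x)[seq_len(min(6, nrow(x))), seq_len(min(6, ncol(x))), drop = FALSE])
  invisible(x)
}

#' Construct a per-SNP scan-statistic table
#'
#' One row per SNP per (method, tag); `orientation` tells downstream
#' aggregation whether larger values are more extreme or whether the value is
#' already a p-value.
#'
#' @param snp_id character vector.
#' @param method method name (e.g. `"pcadapt"`, `"rda"`, `"bf_analog"`).
#' @param tag axis or variable tag, `NA` where not applicable.
#' @param value numeric statistic.
#' @param orientation `"higher_more_extreme"` or `"is_p_value"`.
#' @return data.frame of class `scan_stats`.
#' @export
scan_stats <- function(snp_id, method, tag, value, orientation) {
  orientation <- match.arg(orientation, c("higher_more_extreme", "is_p_value"))
  if (orientation == "is_p_value" &&
      any(value <= 0 | value > 1, na.rm = TRUE))
    stop("p-values must lie in (0, 1]")
  out <- data.frame(snp_id = snp_id, method = method,
                    tag = if (length(tag)) tag else NA_character_,
                    value = value, orientation = orientation,
                    stringsAsFactors = FALSE)
  class(out) <- c("scan_stats", "data.frame")
  out
}

#' Construct one admixture replicate run
#'
#' @param Q matrix of individual ancestry proportions (individuals x K); rows
#'   must sum to 1 within 1e-6.
#' @param log_likelihood model log-likelihood of the run.
#' @param run_id identifier.
#' @return object of class `admixture_run`.
#' @export
admixture_run <- function(Q, log_likelihood, run_id) {
  Q <- as.matrix(Q)
  if (ncol(Q) < 1) stop("K must be >= 1")
  if (any(Q < 0 | Q > 1)) stop("Q entries must lie in [0, 1]")
  if (max(abs(rowSums(Q) - 1)) > 1e-6) stop("Q rows must sum to 1")
  structure(list(K = ncol(Q), Q = Q, log_likelihood = log_likelihood,
                 run_id = run_id),
            class = "admixture_run")
}

# lower-triangle vectorization shared by the Mantel machinery
lower_tri <- function(m) m[lower.tri(m)]

check_same_labels <- function(...) {
  mats <- list(...)
  lab <- rownames(mats[[1]])
  for (m in mats[-1])
    if (!identical(rownames(m), lab)) stop("distance matrices must share labels and order")
  lab
}
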