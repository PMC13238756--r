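#' Hudson FST between two populations (ratio of averages)
#'
#' Per SNP, with allele frequencies p_a, p_b and allele-copy counts n_a, n_b:
#' N = (p_a - p_b)^2 - p_a(1 - p_a)/(n_a - 1) - p_b(1 - p_b)/(n_b - 1) and
#' D = p_a(1 - p_b) + p_b(1 - p_a); FST = sum(N)/sum(D) over SNPs whose global
#' folded MAF exceeds `maf_min` and with n >= 2 allele copies in both
#' populations. The finite-sample correction makes the estimator unbiased
#' from allele frequencies; the ratio-of-averages form is robust to
#' low-information SNPs.
#'
#' @param snp a [snp_table()].
#' @param pop_a,pop_b population names.
#' @param maf_min global folded MAF threshold (strict `>`), applied as a
#'   dataset-level mask.
#' @return FST (numeric scalar) with attributes `n_snps_used` and
#'   `n_excluded_low_n`.
#' @export
compute_fst <- function(snp, pop_a, pop_b, maf_min = 0.01) {
  stopifnot(inherits(snp, "snp_table"))
  if (!all(c(pop_a, pop_b) %in% pop_names(snp))) stop("unknown population name")
  pa <- snp$freq[, pop_a]; pb <- snp$freq[, pop_b]
  na <- snp$n[, pop_a]; nb <- snp$n[, pop_b]
  maf_ok <- !is.na(snp$global_maf) & snp$global_maf > maf_min
  n_ok <- na >= 2 & nb >= 2
  keep <- maf_ok & n_ok
  if (!any(keep)) stop("no SNPs qualify for FST (MAF/count filters)")
  N <- (pa - pb)^2 - pa * (1 - pa) / (na - 1) - pb * (1 - pb) / (nb - 1)
  D <- pa * (1 - pb) + pb * (1 - pa)
  out <- sum(N[keep]) / sum(D[keep])
  attr(out, "n_snps_used") <- sum(keep)
  attr(out, "n_excluded_low_n") <- sum(maf_ok & !n_ok)
  out
}

#' Mean absolute allele frequency difference (AFD) between two populations
#'
#' Mean over qualifying SNPs of |p_a - p_b|; lies in \[0, 1\].
#'
#' @inheritParams compute_fst
#' @return AFD (numeric scalar) with attribute `n_snps_used`.
#' @export
compute_afd <- function(snp, pop_a, pop_b, maf_min = 0.01) {
  stopifnot(inherits(snp, "snp_table"))
  if (!all(c(pop_a, pop_b) %in% pop_names(snp))) stop("unknown population name")
  keep <- !is.na(snp$global_maf) & snp$global_maf > maf_min &
    snp$n[, pop_a] >= 2 & snp$n[, pop_b] >= 2
  if (!any(keep)) stop("no SNPs qualify for AFD (MAF/count filters)")
  out <- mean(abs(snp$freq[keep, pop_a] - snp$freq[keep, pop_b]))
  attr(out, "n_snps_used") <- sum(keep)
  out
}

#' All pairwise FST or AFD values as a distance matrix
#'
#' @param snp a [snp_table()].
#' @param what `"fst"` or `"afd"`.
#' @param maf_min global folded MAF threshold.
#' @return a [dist_matrix()] of kind `genetic_fst` or `genetic_afd`.
#' @export
genetic_dist_matrix <- function(snp, what = c("fst", "afd"), maf_min = 0.01) {
  what <- match.arg(what)
  pops <- pop_names(snp)
  f <- if (what == "fst") compute_fst else compute_afd
  m <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  for (i in seq_along(pops)[-1]) for (j in seq_len(i - 1)) {
    v <- as.numeric(f(snp, pops[i], pops[j], maf_min))
    m[i, j] <- m[j, i] <- v
  }
  dist_matrix(m, if (what == "fst") "genetic_fst" else "genetic_afd")
}

#' Uncorrected p-distance between two individuals, with genome-wide scaling
#'
#' Raw distance is the mean over co-observed SNPs of |g_i - g_j| / 2 on
#' dosage coding 0/1/2 (SNPs missing in either individual are ignored); the
#' scaled distance multiplies by the ratio of the number of polymorphic sites
#' in the dataset to the total genome length, expressing the distance as a
#' proportion of genome-wide differences.
#'
#' @param gt a [genotype_table()].
#' @param ind_i,ind_j individual ids (rownames of the dosage matrix).
#' @param n_snps_total number of SNPs in the dataset the genotypes came from.
#' @param genome_length total number of sites in the reference genome.
#' @return list with `raw`, `scaled` and `n_co_observed`.
#' @export
compute_pdistance <- function(gt, ind_i, ind_j, n_snps_total, genome_length) {
  stopifnot(inherits(gt, "genotype_table"))
  gi <- gt$geno[ind_i, ]; gj <- gt$geno[ind_j, ]
  ok <- !is.na(gi) & !is.na(gj)
  if (!any(ok)) stop("no co-observed SNPs between ", ind_i, " and ", ind_j)
  raw <- mean(abs(gi[ok] - gj[ok]) / 2)
  list(raw = raw, scaled = raw * n_snps_total / genome_length,
       n_co_observed = sum(ok))
}

#' All pairwise scaled p-distances
#'
#' @inheritParams compute_pdistance
#' @param scaled return the genome-scaled distance (default) or the raw one.
#' @return a [dist_matrix()] of kind `pdistance` over individuals.
#' @export
pdistance_matrix <- function(gt, n_snps_total = ncol(gt$geno),
                             genome_length = n_snps_total, scaled = TRUE) {
  ids <- rownames(gt$geno)
  m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (i in seq_along(ids)[-1]) for (j in seq_len(i - 1)) {
    d <- compute_pdistance(gt, ids[i], ids[j], n_snps_total, genome_length)
    m[i, j] <- m[j, i] <- if (scaled) d$scaled else d$raw
  }
  dist_matrix(m, "pdistance")
}

#' Environmental distance: Euclidean distance on leading PCA axes
#'
#' Variables are standardized, a PCA is run, and the distance is Euclidean on
#' the retained axes: either an explicit `n_axes`, or the smallest number of
#' axes whose cumulative explained variance reaches `var_threshold`.
#'
#' @param env sites x variables numeric matrix (rownames = site labels).
#' @param var_threshold cumulative-variance target used when `n_axes` is NULL.
#' @param n_axes explicit number of axes to retain (overrides the threshold).
#' @return a [dist_matrix()] of kind `environmental`, with attributes
#'   `n_axes` and `cum_var`.
#' @export
env_distance <- function(env, var_threshold = 0.92, n_axes = NULL) {
  env <- as.matrix(env)
  if (nrow(env) < 2 || ncol(env) < 2) stop("need >= 2 sites and >= 2 variables")
  if (anyNA(env)) stop("environment table must not contain missing values")
  sds <- apply(env, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping constant variable(s): ",
            paste(colnames(env)[sds == 0], collapse = ", "))
    env <- env[, sds > 0, drop = FALSE]
    if (ncol(env) == 0) stop("all variables are constant")
  }
  pc <- stats::prcomp(env, center = TRUE, scale. = TRUE)
  cv <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  k <- if (!is.null(n_axes)) min(n_axes, ncol(pc$x)) else which(cv >= var_threshold)[1]
  d <- as.matrix(stats::dist(pc$x[, seq_len(k), drop = FALSE]))
  dimnames(d) <- list(rownames(env), rownames(env))
  out <- dist_matrix(d, "environmental")
  attr(out, "n_axes") <- k
  attr(out, "cum_var") <- cv[k]
  out
}

#' Ancestry distance: absolute difference in site-average ancestry proportion
#'
#' @param sites data.frame with columns `site` and `q` (ancestry proportion
#'   in \[0, 1\]).
#' @return a [dist_matrix()] of kind `ancestry`.
#' @export
ancestry_distance <- function(sites) {
  if (!all(c("site", "q") %in% names(sites))) stop("sites needs columns site, q")
  if (anyNA(sites$q)) stop("missing ancestry proportion q")
  if (any(sites$q < 0 | sites$q > 1)) stop("q must lie in [0, 1]")
  d <- abs(outer(sites$q, sites$q, "-"))
  dimnames(d) <- list(sites$site, sites$site)
  dist_matrix(d, "ancestry")
}

#' Unrooted BIONJ tree from a distance matrix
#'
#' Neighbor joining with variance-weighted distance reduction (Gascuel 1997),
#' computed in double precision so that additive input matrices are
#' reproduced exactly by the tree's path lengths. Agglomeration ties are
#' broken by the lexicographically smallest label pair, making the topology
#' invariant to input label order. Negative branch lengths, when they occur,
#' are reported as computed so that additivity checks remain exact.
#'
#' @param d a [dist_matrix()] or plain labeled symmetric matrix (>= 3 labels).
#' @return list with `tree` (an `ape` "phylo" object) and `newick` (string).
#' @export
bionj_tree <- function(d) {
  m <- unclass(as.matrix(d))
  if (nrow(m) < 3) stop("BIONJ needs at least 3 labels")
  if (any(!is.finite(m))) stop("distances must be finite")
  if (is.null(rownames(m))) rownames(m) <- colnames(m) <- paste0("t", seq_len(nrow(m)))
  nwk <- bionj_newick(m)
  tr <- ape::read.tree(text = nwk)
  list(tree = tr, newick = nwk)
}

# Gascuel's BIONJ agglomeration, emitting a Newick string. D is reduced with
# weights lambda chosen to minimize the variance of the new distances; the
# variance matrix starts equal to D.
bionj_newick <- function(D) {
  lab <- rownames(D)
  # partial Newick strings for the active clusters
  rep_ <- lab
  V <- D
  fmt <- function(x) sprintf("%.17g", x)
  while (nrow(D) > 3) {
    n <- nrow(D)
    rs <- rowSums(D)
    Q <- (n - 2) * D - outer(rs, rs, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key <- paste(pmin(rep_[cand[, 1]], rep_[cand[, 2]]),
                 pmax(rep_[cand[, 1]], rep_[cand[, 2]]), sep = "\r")
    pick <- cand[order(key)[1], ]
    i <- pick[1]; j <- pick[2]
    bi <- D[i, j] / 2 + (rs[i] - rs[j]) / (2 * (n - 2))
    bj <- D[i, j] - bi
    lam <- if (V[i, j] > 0)
      min(max(0.5 + sum(V[j, -c(i, j)] - V[i, -c(i, j)]) / (2 * (n - 2) * V[i, j]),
              0), 1) else 0.5
    k <- setdiff(seq_len(n), c(i, j))
    Du <- lam * (D[i, k] - bi) + (1 - lam) * (D[j, k] - bj)
    Vu <- lam * V[i, k] + (1 - lam) * V[j, k] - lam * (1 - lam) * V[i, j]
    new_rep <- paste0("(", rep_[i], ":", fmt(bi), ",", rep_[j], ":", fmt(bj), ")")
    D <- rbind(cbind(D[k, k, drop = FALSE], Du), c(Du, 0))
    V <- rbind(cbind(V[k, k, drop = FALSE], Vu), c(Vu, 0))
    rep_ <- c(rep_[k], new_rep)
    rownames(D) <- colnames(D) <- rownames(V) <- colnames(V) <- NULL
  }
  b1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  b2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  b3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  paste0("(", rep_[1], ":", fmt(b1), ",", rep_[2], ":", fmt(b2), ",",
         rep_[3], ":", fmt(b3), ");")
}
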