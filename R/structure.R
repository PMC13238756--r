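#' PCA on genotype dosages or population frequencies
#'
#' Genotype mode: missing dosages are mean-imputed per SNP, columns are
#' centered and scaled by sqrt(2 p (1 - p)) with p the mean allele frequency
#' (Patterson standardization). Frequency mode (population x SNP matrix or a
#' [snp_table()]): columns are centered only. Axis signs are fixed by making
#' the largest-magnitude loading positive.
#'
#' @param x a [genotype_table()], a [snp_table()], or a plain samples x SNPs
#'   numeric matrix (treated as frequency mode).
#' @param n_axes number of axes to return.
#' @return list with `scores` (samples x n_axes), `loadings` (SNPs x n_axes)
#'   and `var_frac` (fractions over all axes; sums to 1).
#' @export
pca_freq <- function(x, n_axes = 2) {
  if (inherits(x, "genotype_table")) {
    G <- x$geno
    mu <- colMeans(G, na.rm = TRUE)
    for (j in which(colSums(is.na(G)) > 0)) G[is.na(G[, j]), j] <- mu[j]
    p <- mu / 2
    sc <- sqrt(2 * p * (1 - p))
    keep <- sc > 0
    if (!any(keep)) stop("zero-variance input")
    M <- sweep(sweep(G[, keep, drop = FALSE], 2, mu[keep]), 2, sc[keep], "/")
    ids <- colnames(G)[keep]
  } else {
    M <- if (inherits(x, "snp_table")) t(x$freq) else as.matrix(x)
    if (anyNA(M)) stop("frequency matrix must not contain missing values")
    M <- scale(M, center = TRUE, scale = FALSE)
    keep <- apply(M, 2, function(v) any(v != 0))
    if (!any(keep)) stop("zero-variance input")
    M <- M[, keep, drop = FALSE]
    ids <- colnames(M)
  }
  if (nrow(M) < 2) stop("need at least 2 rows")
  k <- min(n_axes, nrow(M) - 1, ncol(M))
  sv <- svd(M)
  var_frac <- sv$d^2 / sum(sv$d^2)
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  loadings <- sv$v[, seq_len(k), drop = FALSE]
  for (a in seq_len(k)) {
    if (loadings[which.max(abs(loadings[, a])), a] < 0) {
      loadings[, a] <- -loadings[, a]
      scores[, a] <- -scores[, a]
    }
  }
  rownames(scores) <- rownames(M)
  rownames(loadings) <- ids
  colnames(scores) <- colnames(loadings) <- sprintf("PC%d", seq_len(k))
  list(scores = scores, loadings = loadings, var_frac = var_frac)
}

#' Composite linkage disequilibrium within a base-pair window
#'
#' For every same-chromosome SNP pair closer than `window_bp`, r^2 is the
#' squared Pearson correlation of dosages over co-observed individuals.
#' Pairs monomorphic in the co-observed subset are skipped (count in the
#' `n_skipped_monomorphic` attribute).
#'
#' @param gt a [genotype_table()].
#' @param window_bp maximum pair distance in bp.
#' @return data.frame (`snp_i`, `snp_j`, `chrom`, `bp_distance`, `r2`).
#' @export
compute_ld <- function(gt, window_bp = 500000) {
  stopifnot(inherits(gt, "genotype_table"))
  info <- gt$info[order(gt$info$chrom, gt$info$pos), , drop = FALSE]
  res <- vector("list", 0)
  skipped <- 0L
  for (ch in unique(info$chrom)) {
    sub <- info[info$chrom == ch, , drop = FALSE]
    G <- gt$geno[, sub$snp_id, drop = FALSE]
    npairs <- 0L
    ii <- jj <- integer(0); dd <- r2 <- numeric(0)
    for (i in seq_len(nrow(sub) - 1)) {
      j <- i + 1L
      while (j <= nrow(sub) && sub$pos[j] - sub$pos[i] <= window_bp) {
        gi <- G[, i]; gj <- G[, j]
        ok <- !is.na(gi) & !is.na(gj)
        if (sum(ok) >= 2 && stats::sd(gi[ok]) > 0 && stats::sd(gj[ok]) > 0) {
          npairs <- npairs + 1L
          ii <- c(ii, i); jj <- c(jj, j)
          dd <- c(dd, sub$pos[j] - sub$pos[i])
          r2 <- c(r2, stats::cor(gi[ok], gj[ok])^2)
        } else skipped <- skipped + 1L
        j <- j + 1L
      }
    }
    if (npairs > 0)
      res[[ch]] <- data.frame(snp_i = sub$snp_id[ii], snp_j = sub$snp_id[jj],
                              chrom = ch, bp_distance = dd, r2 = r2,
                              stringsAsFactors = FALSE)
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(snp_i = character(0), snp_j = character(0), chrom = character(0),
               bp_distance = numeric(0), r2 = numeric(0))
  rownames(out) <- NULL
  attr(out, "n_skipped_monomorphic") <- skipped
  out
}

#' Graph-based LD pruning
#'
#' Builds a graph whose edges join SNP pairs within `max_bp` with r^2 above
#' `r2_max`, then repeatedly deletes the node of highest degree until no edges
#' remain (ties broken by larger sum of incident r^2, then by larger genomic
#' position). The postcondition -- no surviving pair within `max_bp` has
#' r^2 > `r2_max` -- is asserted before returning.
#'
#' @param pairs data.frame as returned by [compute_ld()]; must cover all
#'   same-chromosome pairs within `max_bp`.
#' @param snps either a character vector of SNP ids or a data.frame with
#'   columns `snp_id` and `pos` (positions are used for tie-breaking).
#' @param max_bp,r2_max edge thresholds.
#' @return character vector of surviving SNP ids.
#' @export
ld_prune <- function(pairs, snps, max_bp = 200000, r2_max = 0.1) {
  if (is.data.frame(snps)) {
    ids <- snps$snp_id
    pos <- stats::setNames(snps$pos, ids)
  } else {
    ids <- snps
    pos <- stats::setNames(seq_along(ids), ids)  # fall back to input order
  }
  e <- pairs[pairs$bp_distance <= max_bp & pairs$r2 > r2_max, , drop = FALSE]
  alive <- stats::setNames(rep(TRUE, length(ids)), ids)
  if (nrow(e)) {
    eact <- rep(TRUE, nrow(e))
    repeat {
      act <- which(eact)
      if (!length(act)) break
      nodes <- c(e$snp_i[act], e$snp_j[act])
      w <- c(e$r2[act], e$r2[act])
      deg <- tapply(rep(1L, length(nodes)), nodes, sum)
      cand <- names(deg)[deg == max(deg)]
      if (length(cand) > 1) {
        rsum <- tapply(w, nodes, sum)[cand]
        cand <- cand[rsum == max(rsum)]
        if (length(cand) > 1) cand <- cand[which.max(pos[cand])]
      }
      alive[cand] <- FALSE
      eact[eact] <- e$snp_i[act] != cand & e$snp_j[act] != cand
    }
  }
  kept <- ids[alive[ids]]
  bad <- pairs$bp_distance <= max_bp & pairs$r2 > r2_max &
    pairs$snp_i %in% kept & pairs$snp_j %in% kept
  stopifnot(!any(bad))
  kept
}

# all permutations of 1..k (k small)
all_perms <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (p in all_perms(k - 1L)) for (i in seq_len(k))
    out[[length(out) + 1L]] <- append(p, k, after = i - 1L)
  out
}

# best column permutation of Q2 to match Q1; returns perm and total |diff|
align_q <- function(Q1, Q2) {
  k <- ncol(Q1)
  C <- matrix(0, k, k)
  for (a in seq_len(k)) for (b in seq_len(k))
    C[a, b] <- sum(abs(Q1[, a] - Q2[, b]))
  if (k <= 7) {
    best <- NULL; best_cost <- Inf
    for (p in all_perms(k)) {
      cost <- sum(C[cbind(seq_len(k), p)])
      if (cost < best_cost) { best_cost <- cost; best <- p }
    }
  } else {            # greedy assignment for large K
    best <- integer(k); used <- rep(FALSE, k); best_cost <- 0
    Cw <- C
    for (step in seq_len(k)) {
      idx <- which(Cw == min(Cw), arr.ind = TRUE)[1, ]
      best[idx[1]] <- idx[2]; best_cost <- best_cost + C[idx[1], idx[2]]
      Cw[idx[1], ] <- Inf; Cw[, idx[2]] <- Inf
      used[idx[2]] <- TRUE
    }
  }
  list(perm = best, cost = best_cost)
}

#' Similarity between two admixture solutions
#'
#' 1 - (1/(2N)) * sum |Q - Q' P| maximized over column permutations P of the
#' second matrix (label-switching invariant); equals 1 for identical
#' solutions.
#'
#' @param Q1,Q2 individual x K ancestry matrices with the same dimensions.
#' @return similarity in \[0, 1\].
#' @export
q_similarity <- function(Q1, Q2) {
  stopifnot(identical(dim(Q1), dim(Q2)))
  1 - align_q(Q1, Q2)$cost / (2 * nrow(Q1))
}

#' Cluster replicate admixture runs into modes and average the major mode
#'
#' Runs are linked when their label-switching-invariant similarity
#' ([q_similarity()]) reaches `sim_threshold`; modes are the connected
#' components. The major mode is the largest (ties: higher mean
#' log-likelihood). Its Q is the element-wise mean of member Q matrices after
#' aligning each to a deterministic reference (highest log-likelihood member),
#' with rows re-normalized.
#'
#' @param runs list of [admixture_run()] objects sharing K and individual
#'   order.
#' @param sim_threshold linking threshold.
#' @return list with `modes` (list of run-id vectors, largest first),
#'   `major_mode` (run ids), `Q_major` (averaged Q), `similarity` (matrix).
#' @export
cluster_runs <- function(runs, sim_threshold = 0.85) {
  stopifnot(length(runs) >= 1)
  Ks <- vapply(runs, function(r) r$K, 1)
  if (length(unique(Ks)) != 1) stop("all runs must share the same K")
  ids <- vapply(runs, function(r) as.character(r$run_id), "")
  R <- length(runs)
  sim <- diag(1, R); dimnames(sim) <- list(ids, ids)
  for (i in seq_len(R - 1)) for (j in (i + 1):R)
    sim[i, j] <- sim[j, i] <- q_similarity(runs[[i]]$Q, runs[[j]]$Q)
  g <- igraph::graph_from_adjacency_matrix(sim >= sim_threshold,
                                           mode = "undirected", diag = FALSE)
  comp <- igraph::components(g)$membership
  modes <- split(ids, comp)
  ll <- vapply(runs, function(r) r$log_likelihood, 1)
  names(ll) <- ids
  sizes <- lengths(modes)
  mean_ll <- vapply(modes, function(m) mean(ll[m]), 1)
  ord <- order(-sizes, -mean_ll, vapply(modes, function(m) min(m), ""))
  modes <- lapply(modes[ord], function(m) sort(m))
  major <- modes[[1]]
  members <- runs[match(major, ids)]
  ref <- members[[order(-vapply(members, function(r) r$log_likelihood, 1),
                        vapply(members, function(r) as.character(r$run_id), ""))[1]]]
  acc <- matrix(0, nrow(ref$Q), ncol(ref$Q))
  for (r in members) acc <- acc + r$Q[, align_q(ref$Q, r$Q)$perm, drop = FALSE]
  Qm <- acc / length(members)
  Qm <- Qm / rowSums(Qm)
  dimnames(Qm) <- dimnames(ref$Q)
  list(modes = modes, major_mode = major, Q_major = Qm, similarity = sim)
}

#' Evanno's delta-K across admixture models
#'
#' delta-K(K) = |mean L(K+1) - 2 mean L(K) + mean L(K-1)| / sd(L(K)),
#' undefined at the smallest and largest K (reported as NA). A zero standard
#' deviation yields +Inf with a warning.
#'
#' @param likelihoods data.frame with columns `K` and `logL`, one row per
#'   replicate run.
#' @return data.frame (`K`, `n_runs`, `mean_logL`, `sd_logL`, `delta_k`).
#' @export
evanno_delta_k <- function(likelihoods) {
  stopifnot(all(c("K", "logL") %in% names(likelihoods)))
  Ks <- sort(unique(likelihoods$K))
  if (length(Ks) < 3 || any(diff(Ks) != 1))
    stop("need >= 3 consecutive K values")
  agg <- data.frame(
    K = Ks,
    n_runs = vapply(Ks, function(k) sum(likelihoods$K == k), 1L),
    mean_logL = vapply(Ks, function(k) mean(likelihoods$logL[likelihoods$K == k]), 1),
    sd_logL = vapply(Ks, function(k) stats::sd(likelihoods$logL[likelihoods$K == k]), 1)
  )
  if (any(agg$n_runs < 2)) stop("need >= 2 runs per K for the sd")
  dk <- rep(NA_real_, length(Ks))
  for (i in seq_along(Ks)[-c(1, length(Ks))]) {
    num <- abs(agg$mean_logL[i + 1] - 2 * agg$mean_logL[i] + agg$mean_logL[i - 1])
    if (agg$sd_logL[i] == 0) {
      warning("sd of log-likelihoods is 0 at K = ", Ks[i], "; delta-K is +Inf")
      dk[i] <- Inf
    } else dk[i] <- num / agg$sd_logL[i]
  }
  agg$delta_k <- dk
  agg
}
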