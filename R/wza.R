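#' Assign SNPs to annotated genes and build the background gene set
#'
#' Gene intervals are BED-style 0-based half-open \[start, end); a SNP with
#' 1-based position P belongs to a gene iff start <= P - 1 < end. Overlapping
#' genes are allowed (a SNP may belong to several). Genes with fewer than
#' `min_snps` assigned SNPs are excluded from the background set and from
#' testing.
#'
#' @param snps data.frame with `snp_id`, `chrom`, `pos` (1-based).
#' @param genes data.frame with `gene_id`, `chrom`, `start`, `end`.
#' @param min_snps background inclusion threshold.
#' @return list with `mapping` (data.frame `snp_id`, `gene_id`), `n_snps`
#'   (named per-gene counts) and `background` (gene ids with
#'   n >= `min_snps`).
#' @export
assign_snps_to_genes <- function(snps, genes, min_snps = 5) {
  stopifnot(all(c("snp_id", "chrom", "pos") %in% names(snps)),
            all(c("gene_id", "chrom", "start", "end") %in% names(genes)))
  if (any(genes$start >= genes$end)) stop("gene intervals must satisfy start < end")
  shared <- intersect(unique(snps$chrom), unique(genes$chrom))
  if (!length(shared))
    stop("chromosome name mismatch: SNPs on {",
         paste(unique(snps$chrom), collapse = ","), "} vs genes on {",
         paste(unique(genes$chrom), collapse = ","), "}")
  maps <- lapply(shared, function(ch) {
    s <- snps[snps$chrom == ch, , drop = FALSE]
    g <- genes[genes$chrom == ch, , drop = FALSE]
    if (!nrow(s) || !nrow(g)) return(NULL)
    # 0-based SNP position against 0-based closed [start, end - 1]
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(start = s$pos - 1L, width = 1L),
      IRanges::IRanges(start = g$start, end = g$end - 1L))
    if (!length(hits)) return(NULL)
    data.frame(snp_id = s$snp_id[S4Vectors::queryHits(hits)],
               gene_id = g$gene_id[S4Vectors::subjectHits(hits)],
               stringsAsFactors = FALSE)
  })
  mapping <- do.call(rbind, maps)
  if (is.null(mapping))
    mapping <- data.frame(snp_id = character(0), gene_id = character(0))
  cnt <- table(mapping$gene_id)
  n_per_gene <- stats::setNames(as.integer(cnt), names(cnt))
  list(mapping = mapping, n_snps = n_per_gene,
       background = sort(names(n_per_gene)[n_per_gene >= min_snps]))
}

#' Gene-windowed Z aggregation (WZA) of per-SNP statistics
#'
#' Per-SNP statistics are converted to empirical p-values
#' p_i = rank_desc(value) / (n + 1) (average ranks on ties) when the
#' orientation is `higher_more_extreme`, or used directly when they already
#' are p-values; then z_i = qnorm(1 - p_i). For each background gene,
#' Z = sum(w_i z_i) / sqrt(sum(w_i^2)) with heterozygosity weights
#' w_i = p(1 - p) from the global MAF, which corrects for the number of SNPs
#' in the gene. The gene p-value is the upper normal tail of Z
#' (`normal_tail`) or a rank-based empirical p across genes (`empirical`).
#'
#' @param stats a [scan_stats()] block for a single (method, tag).
#' @param assignment output of [assign_snps_to_genes()].
#' @param weights named per-SNP weights (global heterozygosity); equal
#'   weights are used when NULL.
#' @param mode `"normal_tail"` or `"empirical"`.
#' @return data.frame (`gene_id`, `n_snps`, `Z`, `p`, `method`, `tag`)
#'   restricted to background genes.
#' @export
wza <- function(stats, assignment, weights = NULL,
                mode = c("normal_tail", "empirical")) {
  mode <- match.arg(mode)
  key <- unique(stats[, c("method", "tag")])
  if (nrow(key) != 1) stop("wza() expects a single (method, tag); see wza_all()")
  stats <- stats[!is.na(stats$value), , drop = FALSE]
  n <- nrow(stats)
  if (!n) stop("no usable SNP statistics")
  ori <- unique(stats$orientation)
  p_snp <- if (ori == "higher_more_extreme")
    rank(-stats$value, ties.method = "average") / (n + 1) else stats$value
  z <- stats::qnorm(1 - p_snp)
  names(z) <- stats$snp_id
  w <- if (is.null(weights)) stats::setNames(rep(1, n), stats$snp_id) else weights
  map <- assignment$mapping
  map <- map[map$gene_id %in% assignment$background &
               map$snp_id %in% names(z), , drop = FALSE]
  zs <- split(z[map$snp_id], map$gene_id)
  ws <- split(as.numeric(w[map$snp_id]), map$gene_id)
  Z <- mapply(function(zi, wi) {
    den <- sqrt(sum(wi^2))
    if (den == 0) return(NA_real_)
    sum(wi * zi) / den
  }, zs, ws)
  if (anyNA(Z)) {
    warning(sum(is.na(Z)), " gene(s) with zero weight sum skipped")
    Z <- Z[!is.na(Z)]
  }
  gene_p <- if (mode == "normal_tail") stats::pnorm(Z, lower.tail = FALSE) else
    rank(-Z, ties.method = "average") / (length(Z) + 1)
  gene_p <- pmax(gene_p, .Machine$double.xmin)
  out <- data.frame(gene_id = names(Z),
                    n_snps = as.integer(lengths(zs)[names(Z)]),
                    Z = as.numeric(Z), p = as.numeric(gene_p),
                    method = key$method, tag = key$tag,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$p, out$gene_id), ]
}

#' Run WZA for every (method, tag) block of a scan-statistic table
#'
#' @inheritParams wza
#' @param stats a [scan_stats()] table possibly holding several methods/tags.
#' @return row-bound WZA tables.
#' @export
wza_all <- function(stats, assignment, weights = NULL,
                    mode = c("normal_tail", "empirical")) {
  mode <- match.arg(mode)
  sp <- split(stats, paste(stats$method, stats$tag, sep = "\r"))
  out <- do.call(rbind, lapply(sp, wza, assignment = assignment,
                               weights = weights, mode = mode))
  rownames(out) <- NULL
  out
}

#' Top candidate genes per method (strict p < p_max)
#'
#' @param wza_table output of [wza()] or [wza_all()].
#' @param p_max threshold (strict inequality); genes at exactly `p_max` are
#'   excluded. Empty sets are allowed.
#' @return named list of gene-id vectors, one per (method, tag).
#' @export
top_candidates <- function(wza_table, p_max = 0.001) {
  sp <- split(wza_table, ifelse(is.na(wza_table$tag), wza_table$method,
                                paste(wza_table$method, wza_table$tag, sep = ":")))
  lapply(sp, function(d) sort(d$gene_id[d$p < p_max]))
}

#' Pairwise overlap and multi-method consensus of candidate gene sets
#'
#' Pairwise overlap percentage uses the union of the pair as denominator.
#' The consensus list holds genes present in at least two sets.
#'
#' @param sets named list of gene-id vectors (>= 2 sets).
#' @return list with `pairwise` (data.frame: set_a, set_b, n_a, n_b, overlap,
#'   union, pct), `consensus` (gene ids in >= 2 sets), `union_size`, and
#'   `pct_multi` (consensus size as a percentage of the overall union).
#' @export
overlap_consensus <- function(sets) {
  if (length(sets) < 2) stop("need >= 2 sets")
  nm <- names(sets)
  pw <- list()
  for (i in seq_along(sets)[-length(sets)]) for (j in (i + 1):length(sets)) {
    ov <- length(intersect(sets[[i]], sets[[j]]))
    un <- length(union(sets[[i]], sets[[j]]))
    pw[[length(pw) + 1]] <- data.frame(
      set_a = nm[i], set_b = nm[j], n_a = length(sets[[i]]),
      n_b = length(sets[[j]]), overlap = ov, union = un,
      pct = if (un > 0) 100 * ov / un else NA_real_,
      stringsAsFactors = FALSE)
  }
  all_genes <- unlist(sets, use.names = FALSE)
  tab <- table(all_genes)
  consensus <- sort(names(tab)[tab >= 2])
  union_size <- length(tab)
  list(pairwise = do.call(rbind, pw), consensus = consensus,
       union_size = union_size,
       pct_multi = if (union_size > 0) 100 * length(consensus) / union_size
       else NA_real_)
}

# half-open interval overlap of gene intervals with a class of regions
genes_in_regions <- function(genes, regions, region_class = NULL) {
  r <- if (is.null(region_class)) regions else
    regions[regions$class == region_class, , drop = FALSE]
  flag <- rep(FALSE, nrow(genes))
  for (ch in unique(genes$chrom)) {
    gi <- which(genes$chrom == ch)
    rc <- r[r$chrom == ch, , drop = FALSE]
    if (!nrow(rc)) next
    for (k in seq_len(nrow(rc)))
      flag[gi] <- flag[gi] |
        (genes$start[gi] < rc$end[k] & rc$start[k] < genes$end[gi])
  }
  stats::setNames(flag, genes$gene_id)
}

#' Chi-squared enrichment of candidate genes in a class of genomic regions
#'
#' A gene is "in region" iff its interval overlaps (half-open arithmetic) any
#' region of the class. A 2x2 Pearson chi-squared test without continuity
#' correction (df = 1) contrasts candidate vs non-candidate background genes
#' inside vs outside the regions. The fold is the candidate in-region rate
#' over the background in-region rate. Tests with a zero margin are reported
#' as NA.
#'
#' @param candidates,background gene-id vectors (candidates must be a subset
#'   of background).
#' @param genes data.frame with `gene_id`, `chrom`, `start`, `end`.
#' @param regions data.frame with `chrom`, `start`, `end`, `class`.
#' @param region_class which class to test (NULL = all regions).
#' @param correct apply Yates continuity correction (off by default; large
#'   backgrounds make it immaterial).
#' @return data.frame (`chisq`, `p`, `fold`, counts).
#' @export
region_enrichment <- function(candidates, background, genes, regions,
                              region_class = NULL, correct = FALSE) {
  if (!all(candidates %in% background)) stop("candidates must be a subset of background")
  g <- genes[genes$gene_id %in% background, , drop = FALSE]
  inreg <- genes_in_regions(g, regions, region_class)
  is_cand <- g$gene_id %in% candidates
  tab <- table(factor(is_cand, c(TRUE, FALSE)),
               factor(inreg[g$gene_id], c(TRUE, FALSE)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(data.frame(chisq = NA_real_, p = NA_real_, fold = NA_real_,
                      cand_in = NA_integer_, cand_out = NA_integer_,
                      bg_in = NA_integer_, bg_out = NA_integer_))
  ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  fold <- (tab[1, 1] / sum(tab[1, ])) / (sum(tab[, 1]) / sum(tab))
  data.frame(chisq = unname(ct$statistic), p = unname(ct$p.value), fold = fold,
             cand_in = tab[1, 1], cand_out = tab[1, 2],
             bg_in = sum(tab[, 1]), bg_out = sum(tab[, 2]))
}

#' Region enrichment across a family of candidate sets and region classes
#'
#' Runs [region_enrichment()] for every (set, class) combination and applies
#' Benjamini-Hochberg correction across the whole family.
#'
#' @param candidate_sets named list of gene-id vectors.
#' @inheritParams region_enrichment
#' @param classes region classes to test (default: all present).
#' @return data.frame with one row per (set, class) plus `p_adj`.
#' @export
region_enrichment_table <- function(candidate_sets, background, genes, regions,
                                    classes = unique(regions$class),
                                    correct = FALSE) {
  rows <- list()
  for (nm in names(candidate_sets)) for (cl in classes) {
    r <- region_enrichment(candidate_sets[[nm]], background, genes, regions,
                           region_class = cl, correct = correct)
    rows[[length(rows) + 1]] <- cbind(data.frame(set = nm, class = cl), r)
  }
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out
}

#' QTL intervals within a slop distance of candidate genes
#'
#' A (gene, QTL) pair is reported iff the QTL interval intersects the gene
#' interval expanded by `slop` bp on both sides, in half-open arithmetic;
#' `slop = 0` reduces to plain interval overlap.
#'
#' @param candidates candidate gene ids.
#' @param genes gene annotation data.frame (`gene_id`, `chrom`, `start`,
#'   `end`).
#' @param qtl data.frame (`chrom`, `start`, `end` and optionally `name`).
#' @param slop expansion in bp.
#' @return data.frame (`gene_id`, `qtl_name`, `chrom`, `qtl_start`,
#'   `qtl_end`, `distance`).
#' @export
qtl_proximity <- function(candidates, genes, qtl, slop = 100000) {
  g <- genes[genes$gene_id %in% candidates, , drop = FALSE]
  if (is.null(qtl$name)) qtl$name <- sprintf("qtl%03d", seq_len(nrow(qtl)))
  rows <- list()
  for (i in seq_len(nrow(g))) {
    s <- max(0, g$start[i] - slop); e <- g$end[i] + slop
    hit <- qtl$chrom == g$chrom[i] & qtl$start < e & s < qtl$end
    for (k in which(hit)) {
      dist <- max(0, max(qtl$start[k] - g$end[i], g$start[i] - qtl$end[k]))
      rows[[length(rows) + 1]] <- data.frame(
        gene_id = g$gene_id[i], qtl_name = qtl$name[k], chrom = g$chrom[i],
        qtl_start = qtl$start[k], qtl_end = qtl$end[k], distance = dist,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(gene_id = character(0), qtl_name = character(0),
                      chrom = character(0), qtl_start = integer(0),
                      qtl_end = integer(0), distance = numeric(0)))
  do.call(rbind, rows)
}

#' Term enrichment of candidate genes (one-sided hypergeometric)
#'
#' For each term, the p-value is the upper hypergeometric tail of drawing at
#' least the observed number of term genes among the candidates from the
#' background; Benjamini-Hochberg correction is applied across terms.
#'
#' @param candidates,background gene-id vectors (candidates within
#'   background).
#' @param gene2term data.frame with columns `gene_id` and `term`.
#' @return data.frame (`term`, `n_candidates`, `n_background`, `p`, `p_adj`),
#'   sorted by p.
#' @export
term_enrichment <- function(candidates, background, gene2term) {
  if (!nrow(gene2term)) stop("empty gene-to-term map")
  if (!all(candidates %in% background)) stop("candidates must be a subset of background")
  g2t <- gene2term[gene2term$gene_id %in% background, , drop = FALSE]
  if (!any(g2t$gene_id %in% candidates)) stop("the map covers no candidate gene")
  N <- length(unique(background))
  n <- length(unique(candidates))
  terms <- split(unique(g2t)[, "gene_id"], unique(g2t)[, "term"])
  rows <- lapply(names(terms), function(tm) {
    K <- length(terms[[tm]])
    k <- length(intersect(terms[[tm]], candidates))
    data.frame(term = tm, n_candidates = k, n_background = K,
               p = stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out[order(out$p, out$term), ]
}
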