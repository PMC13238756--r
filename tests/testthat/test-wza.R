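make_genes <- function(starts, ends, chrom = "chr1") {
  data.frame(gene_id = sprintf("g%02d", seq_along(starts)), chrom = chrom,
             start = starts, end = ends, stringsAsFactors = FALSE)
}

make_snps_df <- function(pos, chrom = "chr1") {
  data.frame(snp_id = sprintf("s%03d", seq_along(pos)), chrom = chrom,
             pos = pos, stringsAsFactors = FALSE)
}

test_that("SNP-to-gene assignment uses half-open 0-based boundaries", {
  genes <- make_genes(100, 200)
  asg <- assign_snps_to_genes(make_snps_df(c(100, 101, 200, 201)), genes,
                              min_snps = 1)
  # 1-based pos 101..200 are inside [100, 200)
  expect_setequal(asg$mapping$snp_id, c("s002", "s003"))

  # genes below min_snps are dropped from the background
  genes2 <- make_genes(c(0, 1000), c(500, 1500))
  snps2 <- make_snps_df(c(1:4 * 100, 1101:1105))
  asg2 <- assign_snps_to_genes(snps2, genes2, min_snps = 5)
  expect_equal(asg2$background, "g02")
  expect_equal(unname(asg2$n_snps["g01"]), 4L)

  expect_error(assign_snps_to_genes(make_snps_df(5, chrom = "chrX"), genes),
               "mismatch")
})

test_that("WZA matches the closed-form toy and is rank-invariant", {
  genes <- make_genes(0, 10000)
  snps <- make_snps_df(1:5 * 100)
  asg <- assign_snps_to_genes(snps, genes, min_snps = 5)
  st <- scan_stats(snps$snp_id, "toy", NA_character_, c(0.1, 0.2, 0.3, 0.4, 0.5),
                   "is_p_value")
  out <- wza(st, asg)
  expect_equal(out$Z, sum(qnorm(1 - c(0.1, 0.2, 0.3, 0.4, 0.5))) / sqrt(5),
               tolerance = 1e-12)
  expect_equal(out$p, pnorm(out$Z, lower.tail = FALSE), tolerance = 1e-15)

  # a strictly monotone transform of a higher_more_extreme statistic changes
  # nothing (ranks only)
  set.seed(50)
  genes3 <- make_genes(c(0, 5000), c(5000, 10000))
  snps3 <- make_snps_df(sort(sample(1:10000, 30)))
  asg3 <- assign_snps_to_genes(snps3, genes3, min_snps = 5)
  v <- runif(30)
  s1 <- scan_stats(snps3$snp_id, "m", NA_character_, v, "higher_more_extreme")
  s2 <- scan_stats(snps3$snp_id, "m", NA_character_, exp(3 * v), "higher_more_extreme")
  expect_equal(wza(s1, asg3), wza(s2, asg3))
})

test_that("gene Z is standard normal under the null", {
  set.seed(51)
  n_genes <- 500; per <- 5
  genes <- make_genes((0:(n_genes - 1)) * 1000, (0:(n_genes - 1)) * 1000 + 999)
  pos <- as.vector(outer(1:per * 100, (0:(n_genes - 1)) * 1000, "+"))
  snps <- make_snps_df(sort(pos))
  asg <- assign_snps_to_genes(snps, genes, min_snps = 5)
  st <- scan_stats(snps$snp_id, "null", NA_character_,
                   runif(nrow(snps)), "is_p_value")
  out <- wza(st, asg)
  expect_lt(abs(mean(out$Z)), 0.1)
  expect_lt(abs(var(out$Z) - 1), 0.2)
})

test_that("top candidates use a strict threshold and empty sets are allowed", {
  wz <- data.frame(gene_id = c("a", "b", "c"), n_snps = 5,
                   Z = c(4, 3, 1), p = c(0.0005, 0.001, 0.2),
                   method = "m", tag = NA_character_)
  out <- top_candidates(wz, p_max = 0.001)
  expect_equal(out$m, "a")                 # p = 0.001 exactly is excluded
  expect_equal(top_candidates(wz, p_max = 1e-6)$m, character(0))
})

test_that("pairwise overlap uses the pair union as denominator", {
  sets <- list(x = sprintf("g%03d", 1:151),
               y = sprintf("g%03d", c(1:81, 200:306)))
  stopifnot(length(sets$y) == 188, length(intersect(sets$x, sets$y)) == 81)
  oc <- overlap_consensus(sets)
  expect_equal(oc$pairwise$overlap, 81)
  expect_equal(oc$pairwise$union, 258)
  expect_equal(oc$pairwise$pct, 100 * 81 / 258, tolerance = 1e-12)
  expect_setequal(oc$consensus, sprintf("g%03d", 1:81))

  same <- overlap_consensus(list(a = c("x", "y"), b = c("x", "y")))
  expect_equal(same$pairwise$pct, 100)
  disj <- overlap_consensus(list(a = "x", b = "y"))
  expect_equal(disj$pairwise$pct, 0)
})

test_that("region enrichment matches the textbook Pearson chi-squared", {
  # build genes/regions that yield the 2x2 table (10, 90 / 10, 890)
  genes <- make_genes((0:999) * 10000, (0:999) * 10000 + 1000)
  cand <- genes$gene_id[1:100]                 # 10 in-region, 90 out
  inreg_ids <- c(genes$gene_id[1:10], genes$gene_id[101:110])
  regions <- data.frame(chrom = "chr1",
                        start = genes$start[match(inreg_ids, genes$gene_id)],
                        end = genes$end[match(inreg_ids, genes$gene_id)],
                        class = "ancestry_tract")
  out <- region_enrichment(cand, genes$gene_id, genes, regions, "ancestry_tract")
  expect_equal(unlist(out[c("cand_in", "cand_out")]),
               c(cand_in = 10, cand_out = 90))
  a <- 10; b <- 90; cc <- 10; d <- 890; N <- a + b + cc + d
  chi_formula <- N * (a * d - b * cc)^2 /
    ((a + b) * (cc + d) * (a + cc) * (b + d))
  expect_equal(out$chisq, chi_formula, tolerance = 1e-12)
  expect_equal(out$fold, (10 / 100) / (20 / 1000), tolerance = 1e-12)

  # all candidates inside, background 50% inside -> fold 2, small p
  cand2 <- genes$gene_id[1:100]
  reg2 <- data.frame(chrom = "chr1", start = 0,
                     end = genes$end[500], class = "qtl")
  out2 <- region_enrichment(cand2, genes$gene_id, genes, regions = reg2, "qtl")
  expect_equal(out2$fold, 2, tolerance = 1e-12)
  expect_lt(out2$p, 1e-6)
})

test_that("uniform candidate draws reject at roughly the nominal rate", {
  set.seed(52)
  genes <- make_genes((0:999) * 10000, (0:999) * 10000 + 1000)
  regions <- data.frame(chrom = "chr1", start = 0, end = genes$end[300],
                        class = "tract")  # 30% of genes in-region
  rej <- 0
  for (b in 1:500) {
    cand <- sample(genes$gene_id, 100)
    out <- region_enrichment(cand, genes$gene_id, genes, regions, "tract")
    if (!is.na(out$p) && out$p < 0.05) rej <- rej + 1
  }
  expect_gte(rej / 500, 0.025)
  expect_lte(rej / 500, 0.075)
})

test_that("QTL proximity respects half-open slop arithmetic", {
  genes <- data.frame(gene_id = "g01", chrom = "chr1", start = 1000, end = 2000)
  qtl_in <- data.frame(chrom = "chr1", start = 101999, end = 102000, name = "q1")
  qtl_out <- data.frame(chrom = "chr1", start = 102000, end = 102001, name = "q2")
  expect_equal(qtl_proximity("g01", genes, qtl_in, slop = 100000)$qtl_name, "q1")
  expect_equal(nrow(qtl_proximity("g01", genes, qtl_out, slop = 100000)), 0L)
  # slop = 0 reduces to plain overlap
  qtl3 <- data.frame(chrom = "chr1", start = c(1999, 2000), end = c(2000, 2001),
                     name = c("in", "out"))
  expect_equal(qtl_proximity("g01", genes, qtl3, slop = 0)$qtl_name, "in")
})

test_that("term enrichment matches an exhaustive hypergeometric enumeration", {
  background <- sprintf("g%02d", 1:20)
  cand <- background[1:5]
  term_genes <- c(background[1:4], background[6:9])   # 4/5 cand, 4/15 others
  g2t <- data.frame(gene_id = term_genes, term = "T1")
  out <- term_enrichment(cand, background, g2t)
  # enumeration: P(X >= 4) drawing 5 from 20 with 8 term genes
  p_enum <- sum(sapply(4:5, function(k)
    choose(8, k) * choose(12, 5 - k))) / choose(20, 5)
  expect_equal(out$p, p_enum, tolerance = 1e-12)

  g2t2 <- rbind(g2t, data.frame(gene_id = background, term = "ALL"),
                data.frame(gene_id = cand, term = "EXACT"))
  out2 <- term_enrichment(cand, background, g2t2)
  expect_equal(out2$p[out2$term == "ALL"], 1)
  expect_equal(out2$term[which.min(out2$p)], "EXACT")
  expect_error(term_enrichment(cand, background, g2t[0, ]), "empty")
})

test_that("BH adjustment matches a brute-force step-up implementation", {
  set.seed(53)
  p <- runif(40)^2
  bh_brute <- function(p) {
    n <- length(p); o <- order(p)
    adj <- p[o] * n / seq_len(n)
    adj <- rev(cummin(rev(adj)))
    pmin(adj, 1)[order(o)]
  }
  g2t <- data.frame(gene_id = rep(sprintf("g%02d", 1:20), 2),
                    term = rep(c("A", "B"), each = 20))
  expect_equal(p.adjust(p, "BH"), bh_brute(p))
  expect_true(all(p.adjust(p, "BH") >= p))
})
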