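test_that("Hudson FST matches an independently coded per-SNP summation", {
  snp <- make_snp(cbind(A = c(0.1, 0.5, 0.9), B = c(0.2, 0.5, 0.7)), n = 100)
  got <- compute_fst(snp, "A", "B")
  # brute-force oracle: explicit per-SNP loop
  pa <- c(0.1, 0.5, 0.9); pb <- c(0.2, 0.5, 0.7); na <- nb <- 100
  Ns <- Ds <- 0
  for (l in 1:3) {
    Ns <- Ns + (pa[l] - pb[l])^2 - pa[l] * (1 - pa[l]) / (na - 1) -
      pb[l] * (1 - pb[l]) / (nb - 1)
    Ds <- Ds + pa[l] * (1 - pb[l]) + pb[l] * (1 - pa[l])
  }
  expect_equal(as.numeric(got), Ns / Ds, tolerance = 1e-12)
  expect_equal(attr(got, "n_snps_used"), 3L)
  expect_equal(as.numeric(compute_fst(snp, "B", "A")), as.numeric(got))
})

test_that("FST limit cases: identity and fixed difference", {
  same <- make_snp(cbind(A = c(0.3, 0.6), B = c(0.3, 0.6)), n = 1e6)
  expect_lt(abs(as.numeric(compute_fst(same, "A", "B"))), 1e-4)
  fixed <- make_snp(cbind(A = 0, B = 1), n = 1e6)
  expect_equal(as.numeric(compute_fst(fixed, "A", "B")), 1, tolerance = 1e-5)
})

test_that("SNPs with too few allele copies are excluded with a logged count", {
  snp <- make_snp(cbind(A = c(0.1, 0.4), B = c(0.9, 0.5)),
                  n = matrix(c(1, 100, 100, 100), 2))
  got <- compute_fst(snp, "A", "B")
  expect_equal(attr(got, "n_snps_used"), 1L)
  expect_equal(attr(got, "n_excluded_low_n"), 1L)
})

test_that("AFD equals the mean absolute frequency difference", {
  snp <- make_snp(cbind(A = c(0.2, 0.4, 0.6), B = c(0.3, 0.1, 0.6)))
  expect_equal(as.numeric(compute_afd(snp, "A", "B")), mean(c(0.1, 0.3, 0)),
               tolerance = 1e-12)
  ident <- make_snp(cbind(A = c(0.2, 0.4), B = c(0.2, 0.4)))
  expect_equal(as.numeric(compute_afd(ident, "A", "B")), 0)
  opp <- make_snp(cbind(A = c(0, 1), B = c(1, 0)))
  expect_equal(as.numeric(compute_afd(opp, "A", "B")), 1)
})

test_that("p-distance ignores missing data and applies the genome-wide scaling", {
  g <- rbind(i = c(0L, 0L, NA, 0L), j = c(1L, 0L, 2L, NA))
  gt <- make_gt(g)
  d <- compute_pdistance(gt, "i", "j", n_snps_total = 4, genome_length = 100)
  expect_equal(d$n_co_observed, 2L)
  expect_equal(d$raw, mean(c(0.5, 0)))       # missing SNPs dropped
  expect_equal(d$scaled, d$raw * 4 / 100)

  same <- make_gt(rbind(i = c(0L, 2L), j = c(0L, 2L)))
  expect_equal(compute_pdistance(same, "i", "j", 2, 10)$raw, 0)
  full <- make_gt(rbind(i = c(0L, 0L), j = c(2L, 2L)))
  expect_equal(compute_pdistance(full, "i", "j", 2, 10)$raw, 1)

  # the genome-wide scaling factor for the published SNP and genome counts
  gt2 <- make_gt(rbind(i = c(0L, 1L, 0L, 0L), j = c(1L, 1L, 0L, 0L)))
  d2 <- compute_pdistance(gt2, "i", "j", 4044588, 1516033356)
  expect_equal(d2$raw, 0.25 / 2)
  expect_equal(d2$scaled, d2$raw * 4044588 / 1516033356, tolerance = 1e-15)

  none <- make_gt(rbind(i = c(NA, 0L), j = c(1L, NA)))
  expect_error(compute_pdistance(none, "i", "j", 2, 10), "i.*j")
})

test_that("environmental distance is Euclidean on retained PCA axes", {
  # PCA is a rotation: with all axes kept, distances equal plain Euclidean
  set.seed(3)
  env <- matrix(rnorm(6), 3, 2, dimnames = list(paste0("S", 1:3), c("a", "b")))
  d <- env_distance(env, n_axes = 2)
  expect_equal(unclass(d), as.matrix(dist(scale(env))), tolerance = 1e-12,
               ignore_attr = TRUE)

  dup <- env[c(1, 1, 2), ]; rownames(dup) <- paste0("S", 1:3)
  expect_equal(unname(env_distance(dup, n_axes = 2)[1, 2]), 0)

  # threshold semantics: smallest axis count reaching the cumulative variance
  set.seed(4)
  big <- matrix(rnorm(330), 30, 11, dimnames = list(sprintf("S%02d", 1:30), NULL))
  colnames(big) <- sprintf("v%02d", 1:11)
  d2 <- env_distance(big, var_threshold = 0.92)
  k <- attr(d2, "n_axes")
  pc <- prcomp(big, center = TRUE, scale. = TRUE)
  cv <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  expect_gte(cv[k], 0.92)
  expect_lt(cv[k - 1], 0.92)

  cst <- cbind(big[, 1:2], const = 1)
  expect_warning(env_distance(cst, n_axes = 2), "constant")
  expect_error(suppressWarnings(
    env_distance(matrix(1, 3, 2,
                        dimnames = list(paste0("S", 1:3), c("a", "b"))))),
    "constant")
})

test_that("ancestry distance is |q_i - q_j| and a line metric", {
  sites <- data.frame(site = c("A", "B"), q = c(0, 0.77))
  expect_equal(unname(ancestry_distance(sites)["A", "B"]), 0.77)
  set.seed(5)
  s3 <- data.frame(site = c("A", "B", "C"), q = runif(3))
  d <- ancestry_distance(s3)
  expect_lte(d["A", "C"], d["A", "B"] + d["B", "C"] + 1e-15)
  expect_error(ancestry_distance(data.frame(site = "A", q = NA)), "missing")
})

test_that("BIONJ reproduces the closed-form three-taxon solution", {
  m <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- bionj_tree(m)$tree
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[c("A", "B", "C")], c(A = 1, B = 1, C = 3), tolerance = 1e-12)
})

test_that("BIONJ recovers additive five-taxon metrics exactly", {
  true_tree <- ape::read.tree(text = "((A:1,B:2):1.5,(C:0.5,D:1):2,E:3);")
  dm <- ape::cophenetic.phylo(true_tree)
  got <- bionj_tree(dm)$tree
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(true_tree), got)), 0)
  expect_lt(max(abs(ape::cophenetic.phylo(got)[rownames(dm), colnames(dm)] - dm)),
            1e-9)
  # label-order invariance of the topology
  perm <- c("E", "C", "A", "D", "B")
  got2 <- bionj_tree(dm[perm, perm])$tree
  expect_equal(as.numeric(ape::dist.topo(got, got2)), 0)
  expect_error(bionj_tree(dm[1:2, 1:2]), "3")
})

test_that("BIONJ agrees with the ape reference implementation", {
  skip_if_not_installed("ape")  # ape is an Import; guard for completeness
  set.seed(6)
  for (s in 1:5) {
    pts <- matrix(rnorm(16), 8)
    dm <- as.matrix(dist(pts))
    dimnames(dm) <- list(letters[1:8], letters[1:8])
    ref <- ape::bionj(as.dist(dm))
    got <- bionj_tree(dm)$tree
    expect_equal(as.numeric(ape::dist.topo(ref, got)), 0)
    # ape's bionj runs in single precision; lengths agree to that tolerance
    ref_d <- ape::cophenetic.phylo(ref)[letters[1:8], letters[1:8]]
    got_d <- ape::cophenetic.phylo(got)[letters[1:8], letters[1:8]]
    expect_lt(max(abs(ref_d - got_d)), 1e-5)
  }
})

test_that("mean pairwise FST increases with drift", {
  ms <- sapply(c(0.02, 0.05, 0.1), function(fd) {
    dat <- simulate_dataset(tiny_cfg(f_drift = fd, n_snps = 1500, beta_env = 0,
                                     missing_rate = 0, seed = 77))
    fst <- genetic_dist_matrix(dat$snp, "fst")
    mean(fst[lower.tri(fst)])
  })
  expect_true(all(diff(ms) > 0))
})
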