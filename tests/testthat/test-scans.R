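test_that("the scan flags a planted outlier SNP on top of background structure", {
  for (s in 1:5) {
    set.seed(30 + s)
    n <- 100
    grp <- rep(0:1, each = n / 2)
    # two demes with mild genome-wide differentiation so the PCs capture the
    # deme axis, plus one SNP with an extreme frequency contrast
    p0 <- runif(200, 0.1, 0.9)
    d <- rnorm(200, 0, 0.3)
    G <- matrix(0L, n, 200)
    for (j in 1:200) {
      pA <- plogis(qlogis(p0[j]) - d[j]); pB <- plogis(qlogis(p0[j]) + d[j])
      G[, j] <- rbinom(n, 2, ifelse(grp == 1, pB, pA))
    }
    G[, 1] <- rbinom(n, 2, ifelse(grp == 1, 0.98, 0.02))
    gt <- make_gt(G, pos = seq_len(200) * 1000L)
    sc <- pcadapt_scan(gt, k = 2)
    expect_equal(sc$snp_id[which.min(sc$value)], "snp001")
    expect_gt(attr(sc, "lambda"), 0.5)
    expect_lt(attr(sc, "lambda"), 1.5)
  }
})

test_that("duplicating all individuals preserves the per-SNP ranking", {
  set.seed(36)
  G <- matrix(rbinom(50 * 100, 2, 0.4), 50, 100)
  gt1 <- make_gt(G)
  gt2 <- make_gt(rbind(G, G))
  r1 <- rank(pcadapt_scan(gt1, k = 2)$value)
  r2 <- rank(pcadapt_scan(gt2, k = 2)$value)
  expect_gt(cor(r1, r2, method = "spearman"), 0.99)
})

test_that("k >= n is rejected and p-values stay in (0, 1]", {
  set.seed(37)
  gt <- make_gt(matrix(rbinom(200, 2, 0.5), 10, 20))
  expect_error(pcadapt_scan(gt, k = 10), "smaller")
  sc <- pcadapt_scan(gt, k = 2, maf_min = 0)
  expect_true(all(sc$value > 0 & sc$value <= 1, na.rm = TRUE))
})

test_that("VIF pruning removes collinear variables only", {
  set.seed(38)
  # Helmert contrasts: mutually orthogonal AND zero-sum columns, so all true
  # VIFs are exactly 1
  M <- stats::contr.helmert(20)[, 1:5]
  colnames(M) <- paste0("v", 1:5)
  kept <- vif_prune(M)
  expect_setequal(kept, colnames(M))
  expect_true(all(abs(attr(kept, "vif") - 1) < 1e-8))

  dup <- cbind(M[, 1:3], v4 = M[, 1])
  kept2 <- vif_prune(dup)
  expect_length(kept2, 3)
  expect_true(xor("v1" %in% kept2, "v4" %in% kept2))

  X <- matrix(rnorm(60), 30, 2, dimnames = list(NULL, c("a", "b")))
  X <- cbind(X, c = X[, 1] + X[, 2] + rnorm(30, 0, 0.01))
  kept3 <- vif_prune(X)
  expect_length(kept3, 2)
  expect_true(all(attr(kept3, "vif") < 10))
})

test_that("RDA reproduces brute-force least squares and the vegan fit", {
  set.seed(39)
  Y <- matrix(rnorm(10 * 50), 10, 50,
              dimnames = list(paste0("s", 1:10), paste0("snp", 1:50)))
  X <- matrix(rnorm(30), 10, 3, dimnames = list(paste0("s", 1:10), c("a", "b", "c")))
  md <- rda_fit(Y, X, n_perm = 0)
  # brute force: per-column lm on the standardized predictors
  Xs <- scale(X); Yc <- scale(Y, center = TRUE, scale = FALSE)
  fit <- lm.fit(cbind(1, Xs), Yc)
  Yhat <- cbind(1, Xs) %*% fit$coefficients
  expect_lt(max(abs(md$site_scores %*% t(md$loadings) - Yhat)), 1e-9)
  expect_equal(md$R2, sum(Yhat^2) / sum(Yc^2), tolerance = 1e-12)

  skip_if_not_installed("vegan")
  vg <- vegan::rda(Y ~ a + b + c, data = as.data.frame(X), scale = FALSE)
  expect_equal(md$R2, vg$CCA$tot.chi / vg$tot.chi, tolerance = 1e-10)
  expect_equal(md$adj_R2, vegan::RsquareAdj(vg)$adj.r.squared, tolerance = 1e-10)
  expect_equal(md$eig / (nrow(Y) - 1), unname(vg$CCA$eig), tolerance = 1e-10)
})

test_that("an exactly linear response gives R2 = 1 and a constant covariate changes nothing", {
  set.seed(40)
  X <- matrix(rnorm(20 * 2), 20, 2, dimnames = list(NULL, c("a", "b")))
  B <- matrix(rnorm(2 * 30), 2, 30)
  Y <- scale(X) %*% B
  md <- rda_fit(Y, X, n_perm = 0)
  expect_equal(md$R2, 1, tolerance = 1e-12)
  expect_equal(md$adj_R2, 1, tolerance = 1e-12)

  Y2 <- Y + matrix(rnorm(length(Y)), nrow(Y))
  m0 <- rda_fit(Y2, X, n_perm = 0)
  m1 <- rda_fit(Y2, X, covariate = rep(1, 20), n_perm = 0)
  expect_equal(m1$eig, m0$eig, tolerance = 1e-9)
  expect_lt(max(abs(abs(m1$loadings) - abs(m0$loadings))), 1e-9)
})

test_that("the Ezekiel adjustment is unbiased near zero under the null", {
  set.seed(41)
  vals <- replicate(100, {
    Y <- matrix(rnorm(30 * 40), 30, 40)
    X <- matrix(rnorm(30 * 5), 30, 5, dimnames = list(NULL, paste0("v", 1:5)))
    rda_fit(Y, X, n_perm = 0)$adj_R2
  })
  expect_lt(abs(mean(vals)), 0.05)
})

test_that("backward selection keeps a truly associated predictor, deterministically", {
  set.seed(42)
  n <- 30
  X <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("v", 1:5)))
  Y <- outer(X[, 1], rnorm(60)) + matrix(rnorm(n * 60, 0, 0.8), n, 60)
  kept <- backward_select(Y, X, p_stay = 0.1, n_perm = 199, seed = 5)
  expect_true("v1" %in% kept)
  kept2 <- backward_select(Y, X, p_stay = 0.1, n_perm = 199, seed = 5)
  expect_identical(kept, kept2)
})

test_that("variance partitioning fractions sum exactly and detect confounding", {
  set.seed(43)
  n <- 25
  env <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, paste0("e", 1:3)))
  q <- runif(n)
  geo <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("lon", "lat")))
  Y <- outer(scale(env[, 1])[, 1], rnorm(40)) + matrix(rnorm(n * 40), n, 40)
  vp <- variance_partition(Y, env, q, geo)
  expect_equal(sum(vp$fractions[1:7]), vp$adj_R2[["all"]], tolerance = 1e-10)

  # fully confounded sets: env duplicated as the ancestry vector
  vp2 <- variance_partition(Y, env[, 1, drop = FALSE], env[, 1], geo)
  expect_lt(abs(vp2$fractions[["unique_env"]]), 0.05)
  expect_lt(abs(vp2$fractions[["unique_ancestry"]]), 0.05)
  expect_gt(vp2$fractions[["joint_env_ancestry"]] +
              vp2$fractions[["joint_all"]],
            vp2$adj_R2[["env"]] - 0.1)
})

test_that("univariate GEA is rank-based and invariant to joint site permutation", {
  set.seed(44)
  n <- 10
  env <- cbind(v1 = rnorm(n))
  rownames(env) <- sprintf("P%02d", 1:n)
  fr <- matrix(runif(n * 5), 5, n, dimnames = list(NULL, rownames(env)))
  fr[1, ] <- rank(env[, 1]) / (n + 1)    # frequencies equal to the ranks
  snp <- make_snp(fr)
  st <- univariate_gea(snp, env)
  expect_equal(st$value[st$snp_id == "snp001"], 1)

  o <- sample(n)
  snp2 <- make_snp(fr[, o]); env2 <- env[o, , drop = FALSE]
  st2 <- univariate_gea(snp2, env2)
  expect_equal(st2$value, st$value)
})

test_that("Baypass count conversion rounds half to even", {
  snp <- make_snp(cbind(A = c(0.5, 0.26, 0), B = c(0.5, 0.26, 0)),
                  n = matrix(c(10, 7, 12), 3, 2))
  f <- tempfile()
  write_baypass_counts(snp, f)
  lines <- readLines(f)
  expect_equal(lines[1], "5 5 5 5")
  expect_equal(lines[2], "2 5 2 5")      # round(1.82), round(5.18)
  expect_equal(lines[3], "0 12 0 12")
})
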