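# One-step orthogonalized Gnanadesikan-Kettenring (OGK) robust location and
# scatter (Maronna & Zamar 2002), with median/MAD as the univariate robust
# location/scale. Falls back to the classical estimate (with a warning) when
# a scale degenerates.
cov_ogk <- function(X) {
  X <- as.matrix(X)
  k <- ncol(X)
  s <- apply(X, 2, stats::mad)
  if (any(s <= 0) || any(!is.finite(s))) return(NULL)
  Y <- sweep(X, 2, s, "/")
  U <- diag(1, k)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    sp <- stats::mad(Y[, i] + Y[, j])
    sm <- stats::mad(Y[, i] - Y[, j])
    U[i, j] <- U[j, i] <- (sp^2 - sm^2) / 4
  }
  ei <- eigen(U, symmetric = TRUE)
  Z <- Y %*% ei$vectors
  gam <- apply(Z, 2, stats::mad)^2
  if (any(gam <= 0) || any(!is.finite(gam))) return(NULL)
  muz <- apply(Z, 2, stats::median)
  A <- diag(s, k) %*% ei$vectors
  list(center = as.numeric(A %*% muz),
       cov = A %*% diag(gam, k) %*% t(A))
}

#' pcadapt-style genome scan (robust Mahalanobis distance on PCA z-scores)
#'
#' SNPs are filtered to global MAF > `maf_min`, mean-imputed and standardized
#' by sqrt(2 p (1 - p)); a k-component PCA is run; each SNP's k-vector of
#' z-scores is the regression coefficients of the standardized SNP on the
#' (orthonormal) components divided by the residual standard deviation. The
#' z-score cloud's robust covariance (OGK) yields Mahalanobis distances D^2;
#' the genomic inflation factor lambda = median(D^2) / median(chi^2_df)
#' rescales them and p-values come from the upper chi^2_df tail.
#'
#' @param gt a [genotype_table()].
#' @param k number of principal components.
#' @param maf_min global MAF filter (strict `>`), from mean dosages.
#' @param df chi-squared degrees of freedom (defaults to `k`).
#' @return [scan_stats()] of p-values (method `"pcadapt"`), with attributes
#'   `lambda`, `k`, `df` and `n_snps_tested`.
#' @export
pcadapt_scan <- function(gt, k, maf_min = 0.05, df = k) {
  stopifnot(inherits(gt, "genotype_table"))
  G <- gt$geno
  n <- nrow(G)
  if (k >= n) stop("k must be smaller than the number of individuals")
  p <- colMeans(G, na.rm = TRUE) / 2
  fold <- pmin(p, 1 - p)
  keep <- !is.na(fold) & fold > maf_min
  if (!any(keep)) stop("no SNPs pass the MAF filter")
  G <- G[, keep, drop = FALSE]
  p <- p[keep]
  mu <- 2 * p
  for (j in which(colSums(is.na(G)) > 0)) G[is.na(G[, j]), j] <- mu[j]
  M <- sweep(sweep(G, 2, mu), 2, sqrt(2 * p * (1 - p)), "/")
  sv <- svd(M, nu = k, nv = 0)
  U <- sv$u                               # n x k, orthonormal columns
  B <- crossprod(U, M)                    # k x S regression coefficients
  rss <- pmax(colSums(M^2) - colSums(B^2), 0)
  sigma <- sqrt(rss / (n - k))
  sigma[sigma == 0] <- NA
  Z <- t(B) / sigma                       # S x k z-scores
  ok <- stats::complete.cases(Z)
  rob <- cov_ogk(Z[ok, , drop = FALSE])
  if (is.null(rob)) {
    warning("degenerate robust covariance; falling back to classical estimate")
    rob <- list(center = colMeans(Z[ok, , drop = FALSE]),
                cov = stats::cov(Z[ok, , drop = FALSE]))
  }
  d2 <- rep(NA_real_, nrow(Z))
  d2[ok] <- stats::mahalanobis(Z[ok, , drop = FALSE], rob$center, rob$cov)
  lambda <- stats::median(d2, na.rm = TRUE) / stats::qchisq(0.5, df)
  pval <- stats::pchisq(d2 / lambda, df, lower.tail = FALSE)
  pval <- pmax(pval, .Machine$double.xmin)  # keep p in (0, 1]
  out <- scan_stats(colnames(G), "pcadapt", NA_character_, pval, "is_p_value")
  attr(out, "lambda") <- lambda
  attr(out, "k") <- k
  attr(out, "df") <- df
  attr(out, "n_snps_tested") <- sum(keep)
  out
}

#' Iterative variance-inflation-factor pruning of predictors
#'
#' VIF_j = 1 / (1 - R^2_j) from regressing variable j on all others; the
#' variable with the highest VIF is removed (ties: the later column) until
#' all VIFs are below `vif_max`. Perfectly collinear pairs (infinite VIF)
#' are handled.
#'
#' @param env sites x variables numeric matrix.
#' @param vif_max retention threshold.
#' @return character vector of retained variable names, with the final VIFs
#'   in attribute `vif`.
#' @export
vif_prune <- function(env, vif_max = 10) {
  env <- as.matrix(env)
  if (ncol(env) < 2) stop("need >= 2 variables")
  vars <- colnames(env)
  vif_of <- function(v) {
    X <- env[, setdiff(vars, v), drop = FALSE]
    fit <- stats::lm.fit(cbind(1, X), env[, v])
    r2 <- 1 - sum(fit$residuals^2) / sum((env[, v] - mean(env[, v]))^2)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }
  repeat {
    if (length(vars) == 1) break
    vif <- vapply(vars, vif_of, 1)
    if (all(vif < vif_max)) break
    worst <- which(vif == max(vif))
    vars <- vars[-worst[length(worst)]]   # ties: drop the later column
  }
  out <- vars
  attr(out, "vif") <- if (length(vars) > 1) vapply(vars, vif_of, 1) else
    stats::setNames(1, vars)
  out
}

#' Redundancy analysis (RDA) and partial RDA on population frequencies
#'
#' The response is the site x SNP frequency matrix, column-centered;
#' predictors are standardized. For a partial RDA both the response and the
#' predictors are replaced by their residuals on the covariate (with
#' intercept). Fitted values come from least squares; canonical axes from the
#' SVD of the fitted matrix. R^2 = SS_fit / SS_total and the Ezekiel
#' adjustment gives adj R^2 = 1 - (1 - R^2)(n - 1)/(n - m - 1) with m the
#' predictor count. Axis significance uses a pseudo-F (axis eigenvalue over
#' residual mean square) with free row permutation of the (residualized)
#' response; axes are retained sequentially while p < `alpha_axis`.
#'
#' @param freq a [snp_table()] or a sites x SNP numeric matrix.
#' @param env sites x predictors matrix (rownames = sites).
#' @param covariate optional numeric vector (e.g. ancestry proportion q).
#' @param n_perm permutations for the axis tests (0 = skip tests; all axes
#'   up to the model rank are then retained).
#' @param alpha_axis sequential retention threshold.
#' @param seed optional seed for the permutations.
#' @return object of class `rda_model`: `R2`, `adj_R2`, `eig`, `axis_p`,
#'   `retained_axes`, `site_scores`, `loadings` (SNP x axis), `predictors`,
#'   `covariate_name`.
#' @export
rda_fit <- function(freq, env, covariate = NULL, n_perm = 999,
                    alpha_axis = 0.05, seed = NULL) {
  Y <- if (inherits(freq, "snp_table")) t(freq$freq) else as.matrix(freq)
  X <- as.matrix(env)
  if (nrow(Y) != nrow(X)) stop("sites must match between response and predictors")
  n <- nrow(Y)
  m <- ncol(X)
  if (m >= n - 1) stop("too many predictors (m >= n - 1)")
  X <- scale(X)
  Y <- scale(Y, center = TRUE, scale = FALSE)
  cov_name <- NULL
  if (!is.null(covariate)) {
    cov_name <- deparse(substitute(covariate))
    qc <- qr(cbind(1, as.numeric(covariate)))
    Y <- qr.resid(qc, Y)
    X <- qr.resid(qc, X)
    sds <- apply(X, 2, stats::sd)
    X <- X[, sds > 1e-12, drop = FALSE]
    m <- ncol(env)  # Ezekiel m stays the user-facing predictor count
  }
  qx <- qr(X)
  Yhat <- qr.fitted(qx, Y)
  ss_tot <- sum(Y^2)
  ss_fit <- sum(Yhat^2)
  if (ss_tot == 0) stop("response has no variance")
  R2 <- ss_fit / ss_tot
  adj_R2 <- 1 - (1 - R2) * (n - 1) / (n - m - 1)
  n_axes <- min(qx$rank, n - 1)
  sv <- svd(Yhat, nu = n_axes, nv = n_axes)
  eig <- sv$d[seq_len(n_axes)]^2
  resid_ms <- (ss_tot - ss_fit) / (n - m - 1)

  axis_p <- rep(NA_real_, n_axes)
  retained <- seq_len(n_axes)
  if (n_perm > 0) {
    if (!is.null(seed)) set.seed(seed)
    Fobs <- eig / resid_ms
    # permuting Y's rows only permutes C = Y Y', so each permutation costs
    # O(n^2 rank) instead of a full refit on the SNP matrix
    Qx <- qr.Q(qx)[, seq_len(qx$rank), drop = FALSE]
    C <- tcrossprod(Y)
    Fperm <- matrix(0, n_perm, n_axes)
    for (b in seq_len(n_perm)) {
      o <- sample.int(n)
      M <- crossprod(Qx, C[o, o]) %*% Qx
      ep <- sort(pmax(eigen(M, symmetric = TRUE, only.values = TRUE)$values, 0),
                 decreasing = TRUE)
      ep <- ep[seq_len(n_axes)]
      rp <- (ss_tot - sum(ep)) / (n - m - 1)
      Fperm[b, ] <- ep / rp
    }
    retained <- integer(0)
    for (a in seq_len(n_axes)) {
      axis_p[a] <- (1 + sum(Fperm[, a] >= Fobs[a])) / (n_perm + 1)
      if (axis_p[a] < alpha_axis) retained <- c(retained, a) else break
    }
    if (!length(retained))
      warning("no significant RDA axes retained")
  }
  site_scores <- sv$u %*% diag(sv$d[seq_len(n_axes)], n_axes)
  loadings <- sv$v
  rownames(site_scores) <- rownames(Y)
  rownames(loadings) <- colnames(Y)
  colnames(site_scores) <- colnames(loadings) <- sprintf("RDA%d", seq_len(n_axes))
  structure(list(R2 = R2, adj_R2 = adj_R2, eig = eig, axis_p = axis_p,
                 retained_axes = retained, site_scores = site_scores,
                 loadings = loadings, predictors = colnames(X),
                 covariate_name = cov_name, n = n, m = m),
            class = "rda_model")
}

#' @export
print.rda_model <- function(x, ...) {
  cat(sprintf("%s: R2 = %.3f, adj R2 = %.3f, %d retained axes (of %d)\n",
              if (is.null(x$covariate_name)) "RDA" else
                paste0("pRDA (covariate: ", x$covariate_name, ")"),
              x$R2, x$adj_R2, length(x$retained_axes), length(x$eig)))
  invisible(x)
}

#' Export per-SNP squared loadings on retained RDA axes as scan statistics
#'
#' @param model an [rda_fit()] result.
#' @param method method label (`"rda"` or `"prda"`).
#' @return [scan_stats()], one block per retained axis (tags `RDA1`, ...),
#'   orientation `higher_more_extreme`.
#' @export
rda_scan_stats <- function(model, method = if (is.null(model$covariate_name)) "rda" else "prda") {
  stopifnot(inherits(model, "rda_model"))
  if (!length(model$retained_axes)) {
    warning("no retained axes: empty scan statistics")
    return(scan_stats(character(0), method, character(0), numeric(0),
                      "higher_more_extreme"))
  }
  blocks <- lapply(model$retained_axes, function(a)
    scan_stats(rownames(model$loadings), method, colnames(model$loadings)[a],
               model$loadings[, a]^2, "higher_more_extreme"))
  out <- do.call(rbind, blocks)
  class(out) <- c("scan_stats", "data.frame")
  out
}

# marginal drop-one pseudo-F for predictor j, computed from the response
# cross-product C = Y Y' (permutation-friendly: C[o, o] re-uses the same
# projectors). trace(Q' C Q) is the fitted sum of squares.
marginal_F_C <- function(C, ss_tot, Qfull, Qred, n, m) {
  fit_full <- sum(crossprod(Qfull, C) * t(Qfull))
  fit_red <- if (is.null(Qred)) 0 else sum(crossprod(Qred, C) * t(Qred))
  (fit_full - fit_red) / ((ss_tot - fit_full) / (n - m - 1))
}

#' Backward selection of RDA predictors by permutation
#'
#' Iteratively computes, for each retained predictor, the drop-one marginal
#' pseudo-F and its free-row-permutation p-value; the worst predictor is
#' removed while its p >= `p_stay`, stopping when all remaining predictors
#' are significant or one predictor remains.
#'
#' @inheritParams rda_fit
#' @param p_stay retention threshold.
#' @param n_perm permutations per marginal test.
#' @return character vector of retained predictor names.
#' @export
backward_select <- function(freq, env, covariate = NULL, p_stay = 0.1,
                            n_perm = 199, seed = NULL) {
  Y <- if (inherits(freq, "snp_table")) t(freq$freq) else as.matrix(freq)
  X <- scale(as.matrix(env))
  n <- nrow(Y)
  Y <- scale(Y, center = TRUE, scale = FALSE)
  if (!is.null(covariate)) {
    qc <- qr(cbind(1, as.numeric(covariate)))
    Y <- qr.resid(qc, Y)
    X <- qr.resid(qc, X)
  }
  if (!is.null(seed)) set.seed(seed)
  vars <- colnames(X)
  C <- tcrossprod(Y)
  ss_tot <- sum(diag(C))
  qQ <- function(M) {
    if (is.null(M) || ncol(M) == 0) return(NULL)
    q <- qr(M)
    qr.Q(q)[, seq_len(q$rank), drop = FALSE]
  }
  repeat {
    if (length(vars) == 1) break
    Xc <- X[, vars, drop = FALSE]
    m <- length(vars)
    Qfull <- qQ(Xc)
    pvals <- vapply(seq_along(vars), function(j) {
      Qred <- qQ(Xc[, -j, drop = FALSE])
      Fobs <- marginal_F_C(C, ss_tot, Qfull, Qred, n, m)
      Fp <- vapply(seq_len(n_perm), function(b) {
        o <- sample.int(n)
        marginal_F_C(C[o, o], ss_tot, Qfull, Qred, n, m)
      }, 1)
      (1 + sum(Fp >= Fobs)) / (n_perm + 1)
    }, 1)
    if (max(pvals) < p_stay) break
    vars <- vars[-which.max(pvals)]
  }
  vars
}

#' Three-way variance partitioning of population frequencies
#'
#' Adjusted R^2 (Ezekiel) is computed for the seven non-empty unions of the
#' three predictor sets via [rda_fit()] (no permutations); inclusion-exclusion
#' yields the unique, pairwise-joint and three-way-joint fractions plus the
#' residual. The seven signed components sum to the full-model adjusted R^2
#' by construction; the identity is asserted to 1e-10.
#'
#' @param freq a [snp_table()] or sites x SNP matrix.
#' @param env_set sites x variables matrix (set A: environment).
#' @param ancestry numeric vector (set B: ancestry proportion q).
#' @param geography sites x 2 matrix of longitude/latitude (set C).
#' @return list with `fractions` (named: unique_env, unique_ancestry,
#'   unique_geo, joint_env_ancestry, joint_env_geo, joint_ancestry_geo,
#'   joint_all, residual), and `adj_R2` for the seven unions.
#' @export
variance_partition <- function(freq, env_set, ancestry, geography) {
  A <- as.matrix(env_set)
  B <- matrix(as.numeric(ancestry), ncol = 1, dimnames = list(NULL, "ancestry"))
  C <- as.matrix(geography)
  if (!ncol(A) || !ncol(B) || !ncol(C)) stop("all three predictor sets must be non-empty")
  r2 <- function(X) rda_fit(freq, X, n_perm = 0)$adj_R2
  RA <- r2(A); RB <- r2(B); RC <- r2(C)
  RAB <- r2(cbind(A, B)); RAC <- r2(cbind(A, C)); RBC <- r2(cbind(B, C))
  RABC <- r2(cbind(A, B, C))
  a <- RABC - RBC
  b <- RABC - RAC
  c_ <- RABC - RAB
  g <- RA + RB + RC - RAB - RAC - RBC + RABC
  d <- RA + RB - RAB - g    # env & ancestry, not geo
  e <- RB + RC - RBC - g    # ancestry & geo, not env
  f <- RA + RC - RAC - g    # env & geo, not ancestry
  fr <- c(unique_env = a, unique_ancestry = b, unique_geo = c_,
          joint_env_ancestry = d, joint_ancestry_geo = e, joint_env_geo = f,
          joint_all = g, residual = 1 - RABC)
  stopifnot(abs(sum(fr[1:7]) - RABC) < 1e-10)
  list(fractions = fr,
       adj_R2 = c(env = RA, ancestry = RB, geo = RC, env_ancestry = RAB,
                  env_geo = RAC, ancestry_geo = RBC, all = RABC))
}

#' Univariate gene-environment association (per-SNP |Spearman| correlation)
#'
#' For each SNP and environmental variable, the statistic is the absolute
#' Spearman rank correlation between population frequencies and the variable
#' across sites -- a simple univariate analog of Bayes-factor style GEA
#' statistics, labeled `bf_analog`.
#'
#' @param freq a [snp_table()].
#' @param env sites x variables matrix.
#' @return [scan_stats()] with method `"bf_analog"`, one block per variable
#'   (tag = variable name), orientation `higher_more_extreme`.
#' @export
univariate_gea <- function(freq, env) {
  stopifnot(inherits(freq, "snp_table"))
  env <- as.matrix(env)
  if (nrow(env) < 4) stop("need >= 4 sites")
  stopifnot(identical(rownames(env), pop_names(freq)))
  P <- t(freq$freq)                      # sites x SNPs
  blocks <- lapply(colnames(env), function(v) {
    if (stats::sd(env[, v]) == 0) {
      warning("variable ", v, " is constant; statistics set to NA")
      val <- rep(NA_real_, ncol(P))
    } else {
      # SNPs monomorphic across sites give NA (zero variance), dropped by WZA
      val <- abs(as.numeric(suppressWarnings(
        stats::cor(P, env[, v], method = "spearman"))))
    }
    scan_stats(colnames(P), "bf_analog", v, val, "higher_more_extreme")
  })
  out <- do.call(rbind, blocks)
  class(out) <- c("scan_stats", "data.frame")
  out
}

#' Write allele counts in Baypass genotype-count format
#'
#' Per SNP and population, the minor count is round(p * n) and the major
#' count round((1 - p) * n) with n the allele-copy count; R's round-half-even
#' convention applies, so minor + major may differ from n by at most 1.
#' One line per SNP; per population a space-delimited "minor major" pair.
#'
#' @param snp a [snp_table()].
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_baypass_counts <- function(snp, path) {
  stopifnot(inherits(snp, "snp_table"))
  minor <- round(snp$freq * snp$n)
  major <- round((1 - snp$freq) * snp$n)
  k <- ncol(minor)
  inter <- matrix(NA_real_, nrow(minor), 2 * k)
  inter[, seq(1, 2 * k, 2)] <- minor
  inter[, seq(2, 2 * k, 2)] <- major
  lines <- apply(inter, 1, paste, collapse = " ")
  writeLines(lines, path)
  invisible(path)
}
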