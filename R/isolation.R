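# Permuted lower-triangle matrix: column b holds the lower triangle of
# x[perm_b, perm_b]. Vectorizing permutations this way keeps the Mantel
# machinery fast enough for calibration experiments.
perm_tri_matrix <- function(x, n_perm) {
  n <- nrow(x)
  lt <- lower.tri(x)
  out <- matrix(0, sum(lt), n_perm)
  for (b in seq_len(n_perm)) {
    o <- sample.int(n)
    out[, b] <- x[o, o][lt]
  }
  out
}

#' Simple Mantel test
#'
#' r is the Pearson correlation of the vectorized lower triangles; the
#' one-sided (positive) p-value is estimated by jointly permuting the row and
#' column order of `x`, with the add-one convention
#' p = (1 + #\{r_perm >= r_obs\}) / (n_perm + 1) so that p is never 0.
#'
#' @param x,y square symmetric distance matrices with identical labels.
#' @param n_perm number of permutations.
#' @param seed optional integer seed for reproducible permutations.
#' @return list with `r`, `p`, `n_perm`.
#' @export
mantel_test <- function(x, y, n_perm = 999, seed = NULL) {
  x <- as.matrix(x); y <- as.matrix(y)
  check_same_labels(x, y)
  if (nrow(x) < 4) stop("Mantel test needs >= 4 labels")
  vx <- lower_tri(x); vy <- lower_tri(y)
  if (stats::sd(vx) == 0 || stats::sd(vy) == 0)
    stop("zero-variance lower triangle")
  r <- stats::cor(vx, vy)
  if (!is.null(seed)) set.seed(seed)
  rp <- as.numeric(stats::cor(perm_tri_matrix(x, n_perm), vy))
  list(r = r, p = (1 + sum(rp >= r)) / (n_perm + 1), n_perm = n_perm)
}

#' Partial Mantel test
#'
#' Correlation of the residuals of the `x` and `y` lower triangles after each
#' is regressed on the `z` triangle. Permutations re-order `x`'s rows and
#' columns jointly and the residual correlation is recomputed for each
#' permutation, preserving the covariate's structure; one-sided (positive)
#' add-one p-value.
#'
#' @inheritParams mantel_test
#' @param z covariate distance matrix.
#' @return list with `r`, `p`, `n_perm`.
#' @export
partial_mantel_test <- function(x, y, z, n_perm = 999, seed = NULL) {
  x <- as.matrix(x); y <- as.matrix(y); z <- as.matrix(z)
  check_same_labels(x, y, z)
  if (nrow(x) < 5) stop("partial Mantel test needs >= 5 labels")
  vx <- lower_tri(x); vy <- lower_tri(y); vz <- lower_tri(z)
  if (stats::sd(vx) == 0 || stats::sd(vy) == 0)
    stop("zero-variance lower triangle")
  qz <- qr(cbind(1, vz))
  rx <- qr.resid(qz, vx)
  ry <- qr.resid(qz, vy)
  if (stats::sd(rx) < 1e-12 * stats::sd(vx) ||
      stats::sd(ry) < 1e-12 * stats::sd(vy)) {
    # covariate fully explains one side: no remaining association
    return(list(r = 0, p = 1, n_perm = n_perm))
  }
  r <- stats::cor(rx, ry)
  if (!is.null(seed)) set.seed(seed)
  RX <- qr.resid(qz, perm_tri_matrix(x, n_perm))
  rp <- as.numeric(stats::cor(RX, ry))
  list(r = r, p = (1 + sum(rp >= r)) / (n_perm + 1), n_perm = n_perm)
}

#' Build per-pair records with north/south categories
#'
#' One record per unordered site pair, carrying the genetic, ancestry, marine
#' and environmental distances and the pair category (`north-north`,
#' `south-south` or `north-south`) derived from the two sites' region flags.
#'
#' @param sites data.frame with columns `site` and `region`
#'   (`"north"`/`"south"`).
#' @param genetic,ancestry,marine,environmental distance matrices sharing the
#'   site labels (environmental may be NULL).
#' @return data.frame of pair records.
#' @export
make_pair_records <- function(sites, genetic, ancestry, marine,
                              environmental = NULL) {
  lab <- sites$site
  stopifnot(identical(rownames(as.matrix(genetic)), lab))
  reg <- stats::setNames(sites$region, lab)
  idx <- which(lower.tri(as.matrix(genetic)), arr.ind = TRUE)
  a <- lab[idx[, "row"]]; b <- lab[idx[, "col"]]
  categ <- ifelse(reg[a] == reg[b], paste(reg[a], reg[b], sep = "-"), "north-south")
  out <- data.frame(site_a = a, site_b = b, category = categ,
                    genetic = lower_tri(as.matrix(genetic)),
                    ancestry = lower_tri(as.matrix(ancestry)),
                    marine = lower_tri(as.matrix(marine)),
                    stringsAsFactors = FALSE)
  if (!is.null(environmental))
    out$environmental <- lower_tri(as.matrix(environmental))
  attr(out, "labels") <- lab
  out
}

#' Residual-substitution: regress genetic distance on ancestry + pair category
#'
#' Ordinary least squares of genetic distance on ancestry distance with a
#' separate intercept per pair category and (by default) a common ancestry
#' slope; the residuals are refolded into a symmetric matrix and substitute
#' for genetic distance in downstream partial Mantel tests, isolating the
#' variation not explained by colonization history.
#'
#' @param pairs output of [make_pair_records()].
#' @param interaction also fit ancestry x category slopes.
#' @return a [dist_matrix()] of kind `residual` (diagonal set to 0 and ignored
#'   downstream), with the fitted `lm` in attribute `model`.
#' @export
residualize_genetic <- function(pairs, interaction = FALSE) {
  stopifnot(all(c("genetic", "ancestry", "category") %in% names(pairs)))
  df <- pairs
  df$category <- factor(df$category)
  form <- if (interaction && nlevels(df$category) > 1)
    genetic ~ ancestry * category else if (nlevels(df$category) > 1)
      genetic ~ ancestry + category else genetic ~ ancestry
  fit <- stats::lm(form, data = df)
  if (anyNA(stats::coef(fit)))
    stop("rank-deficient design: ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))], collapse = ", "))
  lab <- attr(pairs, "labels")
  if (is.null(lab)) lab <- sort(unique(c(pairs$site_a, pairs$site_b)))
  m <- matrix(0, length(lab), length(lab), dimnames = list(lab, lab))
  r <- stats::resid(fit)
  ia <- match(pairs$site_a, lab); ib <- match(pairs$site_b, lab)
  m[cbind(ia, ib)] <- r
  m[cbind(ib, ia)] <- r
  out <- dist_matrix(m, "residual")
  attr(out, "model") <- fit
  out
}

#' Per-variable isolation-by-environment tests
#'
#' For each environmental variable v, the environmental distance is
#' |v_i - v_j| and a partial Mantel test relates the residual genetic
#' distance (from [residualize_genetic()]) to it with marine distance as the
#' covariate, over all sites or only northern/southern ones.
#'
#' @param residual residual genetic [dist_matrix()].
#' @param marine marine [dist_matrix()].
#' @param env sites x variables matrix (rownames = site labels).
#' @param sites data.frame with `site` and `region`.
#' @param subset `"all"`, `"north"` or `"south"`.
#' @param n_perm,seed permutation settings (the seed is re-applied per
#'   variable, so duplicated variables give identical results).
#' @return data.frame (`variable`, `subset`, `r`, `p`, `n_perm`); variables
#'   that are constant within the subset get NA with a warning.
#' @export
ibe_by_variable <- function(residual, marine, env, sites,
                            subset = c("all", "north", "south"),
                            n_perm = 999, seed = NULL) {
  subset <- match.arg(subset)
  keep <- if (subset == "all") sites$site else sites$site[sites$region == subset]
  if (length(keep) < 4) stop("subset '", subset, "' has fewer than 4 sites")
  rm_ <- as.matrix(residual)[keep, keep]
  mm <- as.matrix(marine)[keep, keep]
  ev <- as.matrix(env)[keep, , drop = FALSE]
  res <- lapply(colnames(ev), function(v) {
    d <- abs(outer(ev[, v], ev[, v], "-"))
    dimnames(d) <- list(keep, keep)
    if (stats::sd(lower_tri(d)) == 0) {
      warning("variable ", v, " is constant within subset ", subset)
      return(data.frame(variable = v, subset = subset, r = NA_real_,
                        p = NA_real_, n_perm = n_perm))
    }
    t <- partial_mantel_test(rm_, d, mm, n_perm = n_perm, seed = seed)
    data.frame(variable = v, subset = subset, r = t$r, p = t$p, n_perm = n_perm)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
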