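#' Configuration for the synthetic two-lineage coastal landscape
#'
#' The generator emulates the statistical structure that the downstream
#' analyses assume: ~30 populations strung along a coastline, a cline of
#' admixture between two divergent glacial lineages, Balding-Nichols drift
#' around lineage frequencies, spatially autocorrelated environmental
#' variables partially confounded with ancestry, a minority of genes carrying
#' environment-coupled allele-frequency shifts, and low-coverage-sequencing
#' style per-SNP missingness.
#'
#' @param n_pops number of populations placed on the coastline.
#' @param n_snps total number of SNPs.
#' @param n_genes number of annotated genes (SNPs are placed inside genes).
#' @param n_adaptive_genes number of genes whose SNPs are coupled to the
#'   first environmental variable.
#' @param n_env_vars number of environmental variables.
#' @param f_div divergence F between the two lineages, in (0, 1).
#' @param f_drift per-population drift F, in \[0, 1) (0 = no drift).
#' @param cline_steepness slope of the logistic ancestry cline along the
#'   coastline (per coastline distance unit); `Inf` gives two pure blocks.
#' @param env_ancestry_corr target sample correlation between environmental
#'   variable 1 and the ancestry proportion q, in \[-1, 1\].
#' @param beta_env logit-scale allele-frequency shift per standard deviation
#'   of the driver environmental variable, applied to adaptive SNPs.
#' @param n_ind_per_pop individuals sampled per population.
#' @param missing_rate per-SNP, per-individual probability of missing data.
#' @param seed integer seed; fixed seed gives bit-identical output.
#' @param n_chrom number of chromosomes genes are spread over.
#' @param gene_length,gene_spacing gene interval length and spacing (bp).
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_pops = 30, n_snps = 20000, n_genes = 1000,
                       n_adaptive_genes = 20, n_env_vars = 11,
                       f_div = 0.3, f_drift = 0.05, cline_steepness = 0.3,
                       env_ancestry_corr = 0.3, beta_env = 1,
                       n_ind_per_pop = 30, missing_rate = 0.25, seed = 1L,
                       n_chrom = 4L, gene_length = 10000L, gene_spacing = 100000L) {
  cfg <- list(n_pops = n_pops, n_snps = n_snps, n_genes = n_genes,
              n_adaptive_genes = n_adaptive_genes, n_env_vars = n_env_vars,
              f_div = f_div, f_drift = f_drift, cline_steepness = cline_steepness,
              env_ancestry_corr = env_ancestry_corr, beta_env = beta_env,
              n_ind_per_pop = n_ind_per_pop, missing_rate = missing_rate,
              seed = as.integer(seed), n_chrom = as.integer(n_chrom),
              gene_length = as.integer(gene_length),
              gene_spacing = as.integer(gene_spacing))
  counts <- c("n_pops", "n_snps", "n_genes", "n_adaptive_genes", "n_env_vars",
              "n_ind_per_pop", "n_chrom")
  for (nm in counts)
    if (cfg[[nm]] < 1 || cfg[[nm]] != round(cfg[[nm]])) stop(nm, " must be a count >= 1")
  if (cfg$n_adaptive_genes > cfg$n_genes) stop("n_adaptive_genes must be <= n_genes")
  if (f_div <= 0 || f_div >= 1) stop("f_div must lie in (0, 1)")
  if (f_drift < 0 || f_drift >= 1) stop("f_drift must lie in [0, 1)")
  if (cline_steepness <= 0) stop("cline_steepness must be > 0")
  if (abs(env_ancestry_corr) > 1) stop("env_ancestry_corr must lie in [-1, 1]")
  if (missing_rate < 0 || missing_rate > 1) stop("missing_rate must lie in [0, 1]")
  if (abs(cfg$seed) >= 2^31 - 10) stop("seed out of integer range")
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate the coastal landscape: sites, marine distances, environment, genes
#'
#' Populations are placed at increasing positions along a gently meandering
#' 2-D coastline polyline; marine distance is the along-coast path distance
#' (an exact path metric). Ancestry proportion q follows a logistic cline in
#' along-coast position plus truncated Gaussian noise; sites with q < 0.5 are
#' flagged "north" (Arctic-lineage dominated), the rest "south". Environmental
#' variables are standardized spatial Gaussian processes on the coastline;
#' variable 1 is constructed to have sample correlation exactly
#' `env_ancestry_corr` with q.
#'
#' @param cfg a [sim_config()].
#' @return list with `sites` (data.frame: site, lon, lat, coast_pos, q,
#'   region), `marine` ([dist_matrix()]), `env` (sites x variables matrix),
#'   `genes` (data.frame: gene_id, chrom, start, end; BED-style 0-based
#'   half-open), and `truth` (adaptive gene ids, per-gene effect signs, q).
#' @export
simulate_landscape <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_pops < 3) stop("n_pops must be >= 3: pairwise distance analyses are undefined")
  set.seed(cfg$seed)
  n <- cfg$n_pops

  # meandering coastline: unit-ish steps with small heading changes
  steps <- stats::runif(n - 1, 0.5, 1.5)
  heading <- cumsum(c(0, stats::rnorm(n - 2, 0, 0.25)))
  lon <- cumsum(c(0, steps * cos(heading)))
  lat <- cumsum(c(0, steps * sin(heading)))
  coast_pos <- cumsum(c(0, steps))
  site <- sprintf("P%02d", seq_len(n))

  marine <- abs(outer(coast_pos, coast_pos, "-"))
  dimnames(marine) <- list(site, site)

  mid <- (coast_pos[1] + coast_pos[n]) / 2
  if (is.infinite(cfg$cline_steepness)) {
    q <- as.numeric(coast_pos > mid)
  } else {
    q <- stats::plogis(cfg$cline_steepness * (coast_pos - mid)) +
      stats::rnorm(n, 0, 0.03)
    q <- pmin(pmax(q, 0), 1)
  }
  region <- ifelse(q < 0.5, "north", "south")

  # spatially autocorrelated environment: exponential GP on coastline distance
  range_par <- max(coast_pos) / 5
  K <- exp(-marine / range_par)
  L <- chol(K + diag(1e-8, n))
  env <- crossprod(L, matrix(stats::rnorm(n * cfg$n_env_vars), n))
  env <- scale(env)
  # variable 1: exact sample correlation with q by orthogonal construction
  rho <- cfg$env_ancestry_corr
  if (stats::sd(q) > 0) {
    zq <- as.numeric(scale(q))
    e <- env[, 1]
    ep <- stats::lm.fit(cbind(1, zq), e)$residuals
    if (stats::sd(ep) > 0) {
      ep <- as.numeric(scale(ep))
      env[, 1] <- rho * zq + sqrt(1 - rho^2) * ep
    }
  }
  dimnames(env) <- list(site, sprintf("env%02d", seq_len(cfg$n_env_vars)))

  # gene annotation: n_genes intervals tiled over n_chrom chromosomes
  per_chrom <- ceiling(cfg$n_genes / cfg$n_chrom)
  gi <- seq_len(cfg$n_genes) - 1L
  genes <- data.frame(
    gene_id = sprintf("gene%04d", seq_len(cfg$n_genes)),
    chrom = sprintf("chr%d", gi %/% per_chrom + 1L),
    start = (gi %% per_chrom) * cfg$gene_spacing,
    end = (gi %% per_chrom) * cfg$gene_spacing + cfg$gene_length,
    stringsAsFactors = FALSE
  )

  adaptive <- sort(sample(genes$gene_id, cfg$n_adaptive_genes))
  effect_sign <- stats::setNames(sample(c(-1, 1), cfg$n_adaptive_genes, replace = TRUE),
                                 adaptive)

  sites <- data.frame(site = site, lon = lon, lat = lat,
                      coast_pos = coast_pos, q = q, region = region,
                      stringsAsFactors = FALSE)
  list(sites = sites,
       marine = dist_matrix(marine, "marine"),
       env = env,
       genes = genes,
       truth = list(adaptive_gene_ids = adaptive, effect_sign = effect_sign,
                    q = stats::setNames(q, site)))
}

#' Simulate population allele frequencies under two-lineage admixture + drift
#'
#' Ancestral frequencies are Uniform(0.05, 0.95); the two lineage frequencies
#' follow the Balding-Nichols Beta model with divergence `f_div`; each
#' population's base frequency mixes the lineages by its ancestry q; adaptive
#' SNPs receive a logit-scale shift `beta_env * sign * env1` before local
#' drift (Balding-Nichols with `f_drift`); final frequencies are clamped to
#' \[1e-6, 1 - 1e-6\]. Per-SNP, per-population allele counts are 2 x a
#' binomial thinning of `n_ind_per_pop` at rate `1 - missing_rate`.
#'
#' @param cfg a [sim_config()].
#' @param land output of [simulate_landscape()].
#' @return list with `snp` (a [snp_table()], `info$gene_id` filled) and
#'   `truth` (the landscape truth extended with per-SNP lineage frequencies
#'   `a`, `b`, ancestral `x` and per-SNP effect `beta`).
#' @export
simulate_frequencies <- function(cfg, land) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  S <- cfg$n_snps
  n <- cfg$n_pops
  genes <- land$genes

  # place SNPs: gene picked uniformly, position uniform inside the gene
  gidx <- sample.int(nrow(genes), S, replace = TRUE)
  pos <- genes$start[gidx] + sample.int(cfg$gene_length, S, replace = TRUE)
  info <- data.frame(snp_id = NA_character_, chrom = genes$chrom[gidx],
                     pos = pos, gene_id = genes$gene_id[gidx],
                     stringsAsFactors = FALSE)
  o <- order(info$chrom, info$pos)
  info <- info[o, , drop = FALSE]
  info$snp_id <- sprintf("snp%06d", seq_len(S))
  rownames(info) <- NULL

  x <- stats::runif(S, 0.05, 0.95)
  bn <- function(m, f) {
    if (f == 0) return(m)
    stats::rbeta(length(m), m * (1 - f) / f, (1 - m) * (1 - f) / f)
  }
  a <- bn(x, cfg$f_div)
  b <- bn(x, cfg$f_div)

  q <- land$sites$q
  m <- outer(a, q) + outer(b, 1 - q)            # S x n base frequencies

  beta <- rep(0, S)
  adapt <- info$gene_id %in% land$truth$adaptive_gene_ids
  if (any(adapt)) {
    beta[adapt] <- cfg$beta_env * land$truth$effect_sign[info$gene_id[adapt]]
    eps <- 1e-9
    lm0 <- stats::qlogis(pmin(pmax(m[adapt, , drop = FALSE], eps), 1 - eps))
    shift <- outer(beta[adapt], land$env[, 1])
    m[adapt, ] <- stats::plogis(lm0 + shift)
  }

  p <- matrix(bn(as.numeric(m), cfg$f_drift), S, n)
  p <- pmin(pmax(p, 1e-6), 1 - 1e-6)
  n_pass <- matrix(stats::rbinom(S * n, cfg$n_ind_per_pop, 1 - cfg$missing_rate), S, n)
  colnames(p) <- colnames(n_pass) <- land$sites$site

  truth <- land$truth
  truth$a <- stats::setNames(a, info$snp_id)
  truth$b <- stats::setNames(b, info$snp_id)
  truth$x <- stats::setNames(x, info$snp_id)
  truth$beta <- stats::setNames(beta, info$snp_id)

  list(snp = snp_table(info, p, 2L * n_pass), truth = truth)
}

#' Simulate individual genotype dosages from population frequencies
#'
#' Dosages are Binomial(2, p) per individual; entries are set missing
#' independently with probability `missing_rate`.
#'
#' @param snp a [snp_table()].
#' @param cfg the [sim_config()] used to build it.
#' @return a [genotype_table()].
#' @export
simulate_genotypes <- function(snp, cfg) {
  stopifnot(inherits(snp, "snp_table"), inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 2L)
  pops <- pop_names(snp)
  S <- n_snps(snp)
  m <- cfg$n_ind_per_pop
  geno <- matrix(NA_integer_, length(pops) * m, S)
  pop <- rep(pops, each = m)
  for (i in seq_along(pops)) {
    rows <- (i - 1L) * m + seq_len(m)
    geno[rows, ] <- matrix(
      stats::rbinom(m * S, 2L, rep(snp$freq[, i], each = m)), m, S)
  }
  if (cfg$missing_rate > 0) {
    miss <- matrix(stats::runif(length(geno)) < cfg$missing_rate,
                   nrow(geno), ncol(geno))
    geno[miss] <- NA_integer_
  }
  rownames(geno) <- sprintf("%s_i%02d", pop, rep(seq_len(m), length(pops)))
  genotype_table(geno, pop, snp$info)
}

#' Simulate a complete dataset (landscape, frequencies, genotypes, truth)
#'
#' @param cfg a [sim_config()].
#' @param genotypes also draw individual genotypes (slower at large sizes).
#' @return list with `sites`, `marine`, `env`, `genes`, `snp`, `truth` and
#'   (optionally) `geno`.
#' @export
simulate_dataset <- function(cfg = sim_config(), genotypes = FALSE) {
  land <- simulate_landscape(cfg)
  fr <- simulate_frequencies(cfg, land)
  out <- list(sites = land$sites, marine = land$marine, env = land$env,
              genes = land$genes, snp = fr$snp, truth = fr$truth)
  if (genotypes) out$geno <- simulate_genotypes(fr$snp, cfg)
  out
}
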