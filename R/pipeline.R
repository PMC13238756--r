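#' Pipeline configuration
#'
#' Bundles the data source (a [sim_config()] for synthetic data, or paths to
#' a frequency TSV plus site/environment tables), the filter thresholds, the
#' permutation settings and the stage toggles.
#'
#' @param sim a [sim_config()] (the default data source).
#' @param maf_min dataset-level MAF filter (strict `>`).
#' @param scan_maf_min MAF filter for selection scans.
#' @param coverage_frac minimum fraction of observed allele copies.
#' @param ld_window_bp LD estimation window.
#' @param prune_bp,prune_r2_max pruning thresholds.
#' @param k_scan number of PCs for the pcadapt-style scan.
#' @param n_perm permutation count for Mantel and RDA axis tests.
#' @param seed master seed for every stochastic stage.
#' @param stages character vector of stages to run, in pipeline order.
#' @param genotypes draw individual genotypes (needed by the scans stage).
#' @param out_dir optional output directory for TSV/JSON artifacts.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            maf_min = 0.01, scan_maf_min = 0.05,
                            coverage_frac = 0.75,
                            ld_window_bp = 500000, prune_bp = 200000,
                            prune_r2_max = 0.1, k_scan = 10,
                            n_perm = 999, seed = sim$seed,
                            stages = c("filters", "distances", "structure",
                                       "isolation", "scans", "wza", "consensus"),
                            genotypes = TRUE, out_dir = NULL) {
  stopifnot(maf_min >= 0, maf_min < 0.5, coverage_frac >= 0, coverage_frac <= 1,
            prune_r2_max >= 0, prune_r2_max <= 1, n_perm >= 1)
  structure(list(sim = sim, maf_min = maf_min, scan_maf_min = scan_maf_min,
                 coverage_frac = coverage_frac, ld_window_bp = ld_window_bp,
                 prune_bp = prune_bp, prune_r2_max = prune_r2_max,
                 k_scan = k_scan, n_perm = n_perm, seed = as.integer(seed),
                 stages = stages, genotypes = genotypes, out_dir = out_dir),
            class = "pipeline_config")
}

need_stage <- function(report, stage, needed_by) {
  if (is.null(report[[stage]]))
    stop("stage '", needed_by, "' requires stage '", stage, "' to have run")
}

#' Run the full conservation-unit delineation pipeline
#'
#' Executes the enabled stages in order (filters, distances, structure,
#' isolation, scans, wza, consensus) on a synthetic dataset generated from
#' `cfg$sim`. Every stochastic stage is seeded from `cfg$seed`, so the same
#' configuration reproduces identical results. If `cfg$out_dir` is set, the
#' main tables and a JSON report are written there.
#'
#' @param cfg a [pipeline_config()].
#' @return the report: a named list with one block per executed stage plus
#'   `config` and `seed`; the simulated data are attached in attribute
#'   `data`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dat <- simulate_dataset(cfg$sim, genotypes = cfg$genotypes)
  report <- list(seed = cfg$seed,
                 config = cfg[c("maf_min", "scan_maf_min", "coverage_frac",
                                "ld_window_bp", "prune_bp", "prune_r2_max",
                                "k_scan", "n_perm")])
  snp <- dat$snp
  stats_all <- NULL

  if ("filters" %in% cfg$stages) {
    snp <- apply_filters(snp, cfg$maf_min, cfg$coverage_frac,
                         total_alleles = 2 * cfg$sim$n_ind_per_pop)
    report$filters <- list(n_before = attr(snp, "n_before"),
                           n_after = attr(snp, "n_after"))
  }

  if ("distances" %in% cfg$stages) {
    fst <- genetic_dist_matrix(snp, "fst", cfg$maf_min)
    afd <- genetic_dist_matrix(snp, "afd", cfg$maf_min)
    envd <- env_distance(dat$env)
    ancd <- ancestry_distance(dat$sites)
    report$distances <- list(
      fst_range = range(lower_tri(fst)), afd_range = range(lower_tri(afd)),
      env_axes = attr(envd, "n_axes"), env_cum_var = attr(envd, "cum_var"),
      fst = fst, afd = afd, env = envd, ancestry = ancd)
  }

  if ("structure" %in% cfg$stages) {
    pca <- pca_freq(snp, n_axes = 2)
    block <- list(pc_var_frac = pca$var_frac[1:2], scores = pca$scores)
    if (cfg$genotypes) {
      ld <- compute_ld(dat$geno, cfg$ld_window_bp)
      kept <- ld_prune(ld, snp$info[, c("snp_id", "pos")],
                       cfg$prune_bp, cfg$prune_r2_max)
      block$n_pruned_kept <- length(kept)
      block$n_ld_pairs <- nrow(ld)
    }
    report$structure <- block
  }

  if ("isolation" %in% cfg$stages) {
    need_stage(report, "distances", "isolation")
    d <- report$distances
    pairs <- make_pair_records(dat$sites, d$afd, d$ancestry, dat$marine, d$env)
    res <- residualize_genetic(pairs)
    ibd <- partial_mantel_test(res, dat$marine, d$env,
                               n_perm = cfg$n_perm, seed = cfg$seed)
    ibe <- partial_mantel_test(res, d$env, dat$marine,
                               n_perm = cfg$n_perm, seed = cfg$seed + 1L)
    ibc <- mantel_test(d$afd, d$ancestry, n_perm = cfg$n_perm,
                       seed = cfg$seed + 2L)
    per_var <- ibe_by_variable(res, dat$marine, dat$env, dat$sites, "all",
                               n_perm = cfg$n_perm, seed = cfg$seed + 3L)
    report$isolation <- list(residual = res,
                             ibd = ibd, ibe = ibe, ibc = ibc,
                             per_variable = per_var)
  }

  if ("scans" %in% cfg$stages) {
    gea <- univariate_gea(snp, dat$env)
    retained <- vif_prune(dat$env)
    rda <- rda_fit(snp, dat$env[, retained, drop = FALSE],
                   n_perm = cfg$n_perm, seed = cfg$seed + 4L)
    prda <- rda_fit(snp, dat$env[, retained, drop = FALSE],
                    covariate = dat$sites$q,
                    n_perm = cfg$n_perm, seed = cfg$seed + 5L)
    vp <- variance_partition(snp, dat$env, dat$sites$q,
                             as.matrix(dat$sites[, c("lon", "lat")]))
    stats_all <- gea
    block <- list(vif_retained = retained,
                  rda = rda, prda = prda,
                  rda_adj_R2 = rda$adj_R2, prda_adj_R2 = prda$adj_R2,
                  variance_fractions = vp$fractions)
    if (length(rda$retained_axes))
      stats_all <- rbind(stats_all, rda_scan_stats(rda, "rda"))
    if (length(prda$retained_axes))
      stats_all <- rbind(stats_all, rda_scan_stats(prda, "prda"))
    if (cfg$genotypes) {
      scan <- pcadapt_scan(dat$geno, k = min(cfg$k_scan, nrow(dat$geno$geno) - 1),
                           maf_min = cfg$scan_maf_min)
      block$lambda <- attr(scan, "lambda")
      stats_all <- rbind(stats_all, scan)
    }
    class(stats_all) <- c("scan_stats", "data.frame")
    report$scans <- block
  }

  if ("wza" %in% cfg$stages) {
    need_stage(report, "scans", "wza")
    asg <- assign_snps_to_genes(snp$info, dat$genes, min_snps = 5)
    w <- stats::setNames(snp$global_maf * (1 - snp$global_maf), snp$info$snp_id)
    wz <- wza_all(stats_all, asg, weights = w)
    report$wza <- list(table = wz, n_background = length(asg$background),
                       assignment = asg)
  }

  if ("consensus" %in% cfg$stages) {
    need_stage(report, "wza", "consensus")
    cand <- top_candidates(report$wza$table, p_max = 0.001)
    cand <- cand[lengths(cand) > 0]
    block <- list(candidates = cand)
    if (length(cand) >= 2) {
      oc <- overlap_consensus(cand)
      block$pairwise <- oc$pairwise
      block$consensus <- oc$consensus
      block$pct_multi <- oc$pct_multi
    }
    report$consensus <- block
  }

  if (!is.null(cfg$out_dir)) write_pipeline_outputs(report, dat, snp, cfg)
  attr(report, "data") <- dat
  report
}

# serialize the report's tables; the JSON strips non-scalar internals
write_pipeline_outputs <- function(report, dat, snp, cfg) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(cfg$out_dir, f)
  write_snp_table(snp, p("freqs.tsv"))
  utils::write.table(dat$sites, p("sites.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(site = rownames(dat$env), dat$env),
                     p("env.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  write_dist_matrix(dat$marine, p("marine_dist.tsv"))
  write_bed(dat$genes, p("genes.bed"), name_col = "gene_id")
  if (!is.null(report$distances)) {
    write_dist_matrix(report$distances$fst, p("fst.tsv"))
    write_dist_matrix(report$distances$afd, p("afd.tsv"))
  }
  if (!is.null(report$wza))
    utils::write.table(report$wza$table, p("wza.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  jsonlite::write_json(report_summary(report), p("report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(cfg$out_dir)
}

#' Scalar summary of a pipeline report (JSON-friendly)
#'
#' @param report output of [run_pipeline()].
#' @return nested list of scalars/vectors only.
#' @export
report_summary <- function(report) {
  out <- list(seed = report$seed, config = report$config)
  if (!is.null(report$filters)) out$filters <- report$filters
  if (!is.null(report$distances))
    out$distances <- report$distances[c("fst_range", "afd_range", "env_axes",
                                        "env_cum_var")]
  if (!is.null(report$structure))
    out$structure <- report$structure[intersect(
      c("pc_var_frac", "n_pruned_kept", "n_ld_pairs"), names(report$structure))]
  if (!is.null(report$isolation))
    out$isolation <- list(ibd_r = report$isolation$ibd$r,
                          ibd_p = report$isolation$ibd$p,
                          ibe_r = report$isolation$ibe$r,
                          ibe_p = report$isolation$ibe$p,
                          ibc_r = report$isolation$ibc$r,
                          ibc_p = report$isolation$ibc$p)
  if (!is.null(report$scans))
    out$scans <- list(vif_retained = report$scans$vif_retained,
                      rda_adj_R2 = report$scans$rda_adj_R2,
                      prda_adj_R2 = report$scans$prda_adj_R2,
                      variance_fractions = as.list(report$scans$variance_fractions),
                      lambda = report$scans$lambda)
  if (!is.null(report$wza))
    out$wza <- list(n_background = report$wza$n_background,
                    n_genes_tested = nrow(report$wza$table))
  if (!is.null(report$consensus))
    out$consensus <- list(n_sets = length(report$consensus$candidates),
                          n_consensus = length(report$consensus$consensus),
                          pct_multi = report$consensus$pct_multi)
  out
}
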