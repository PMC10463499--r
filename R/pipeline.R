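#' Pipeline run configuration
#'
#' Collects every analysis threshold at its default (prevalence floors
#' 1.5% / 30% / 60%, network |r| > 0.6 and BH alpha 0.05, Zi/Pi 2.5/0.62,
#' GWAS tiers 1e-6 / 1e-8 with Bonferroni study-wide alpha 0.05, MWAS
#' Bonferroni 0.05, Kruskal-Wallis 0.01) together with the simulation
#' config or input paths, the seed, and the output directory.
#'
#' @param sim a [sim_config] for a synthetic run, or `NULL` when reading
#'   `paths`.
#' @param paths named list of input files (`geno_vcf` or `geno_tsv`,
#'   `abundance`, `phenotype`) for a real-data run.
#' @param out_dir output directory.
#' @param seed master seed.
#' @param ... threshold overrides (see defaults in the function body).
#' @return a `run_config` list.
#' @export
pipeline_config <- function(sim = NULL, paths = NULL, out_dir = tempfile("run"),
                            seed = 1L, ...) {
  defaults <- list(
    prev_exclude = 0.015, prev_binary_gwas = 0.30, prev_split = 0.60,
    r_threshold = 0.6, network_alpha = 0.05,
    zi_threshold = 2.5, pi_threshold = 0.62,
    suggestive = 1e-6, genomewide = 1e-8, studywide_alpha = 0.05,
    mwas_alpha = 0.05, kw_alpha = 0.01,
    n_pcs_h2 = 5L, n_pcs_gwas = 3L, k_pcoa = 5L,
    maf_min = 0.05, max_missing = 0.3,
    clr_pseudocount = 1e-6, min_summed_abund = 1e-4,
    mantel_n_perm = 999L
  )
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  defaults[names(over)] <- over
  structure(c(list(sim = sim, paths = paths, out_dir = out_dir,
                   seed = as.integer(seed)), defaults),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Stages, in order: cohort input (simulated or read from files),
#' microbial feature engineering, co-occurrence network and keystone
#' taxa, relationship matrices and Mantel test, heritability scan,
#' phenotype h2/m2 (single and joint models), GWAS + mbGWAS + MWAS, and
#' the recursive-scenario integration. Every stage writes its tables
#' under `config$out_dir` and the run ends with a JSON manifest (seed,
#' thresholds, per-stage row counts). Deterministic given the seed.
#'
#' @param config a `run_config` from [pipeline_config()].
#' @return invisibly, a list with all stage results and `out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_counts <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # --- stage 0: inputs ------------------------------------------------
  if (!is.null(config$sim)) {
    cohort <- stage("simulate", simulate_cohort(config$sim))
  } else {
    p <- config$paths
    for (f in unlist(p)) {
      if (!file.exists(f)) stop("input file missing: ", f, call. = FALSE)
    }
    geno <- if (!is.null(p$geno_vcf)) read_genotypes_vcf(p$geno_vcf) else {
      df <- utils::read.table(p$geno_tsv, sep = "\t", header = TRUE,
                              check.names = FALSE)
      v <- as.matrix(df[, -1, drop = FALSE])
      rownames(v) <- df[[1]]
      storage.mode(v) <- "integer"
      genotype_matrix(v, data.frame(snp_id = colnames(v),
                                    chr = 1L, pos = seq_len(ncol(v))))
    }
    cohort <- list(
      geno = geno,
      abundance = read_abundance_tsv(p$abundance, kind = "relative"),
      phenotype = utils::read.table(p$phenotype, sep = "\t", header = TRUE,
                                    stringsAsFactors = FALSE),
      truth = NULL
    )
  }
  y <- cohort$phenotype$weight
  covars <- cohort$phenotype[, c("birthplace", "season")]

  # --- stage 1: features ----------------------------------------------
  rel <- stage("features", filter_genera(cohort$abundance))
  log_counts$genera_input <- ncol(cohort$abundance$values)
  log_counts$genera_filtered <- ncol(rel$values)
  feats <- stage("features", build_feature_set(
    rel, k_pcoa = config$k_pcoa, low = config$prev_exclude,
    split = config$prev_split, pseudocount = config$clr_pseudocount))
  log_counts$quantitative <- length(feats$traits$quantitative_ids)
  log_counts$binary <- length(feats$traits$binary_ids)
  utils::write.table(feats$community, file.path(config$out_dir, "community_traits.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # --- stage 2: network -----------------------------------------------
  core <- core_taxa(rel)
  ks <- stage("network", keystone_analysis(
    rel, min_summed_abund = config$min_summed_abund,
    min_prev = config$prev_exclude, r_threshold = config$r_threshold,
    alpha = config$network_alpha, pseudocount = config$clr_pseudocount,
    zi_threshold = config$zi_threshold, pi_threshold = config$pi_threshold))
  log_counts$core <- length(core)
  log_counts$keystone <- length(ks$keystone)
  if (nrow(ks$topology)) {
    utils::write.table(ks$topology, file.path(config$out_dir, "node_topology.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # --- stage 3: kinship -----------------------------------------------
  geno_qc <- stage("kinship", qc_genotypes(cohort$geno, maf_min = config$maf_min,
                                           max_missing = config$max_missing))
  grm <- stage("kinship", compute_grm(geno_qc))
  mrm <- stage("kinship", compute_mrm(cohort$abundance))
  pcs <- genetic_pcs(grm, k = config$n_pcs_h2)
  mant <- stage("kinship", mantel_test(grm, mrm, n_perm = config$mantel_n_perm,
                                       seed = child_seed(config$seed, "mantel")))
  log_counts$snps_qc <- ncol(geno_qc$values)

  # --- stage 4: heritability scan -------------------------------------
  X_h2 <- build_design(covars, pcs = pcs[, seq_len(config$n_pcs_h2), drop = FALSE])
  h2_scan <- stage("varcomp", feature_h2_scan(feats, X_h2, grm))
  log_counts$heritable_features <- sum(h2_scan$heritable)
  utils::write.table(h2_scan, file.path(config$out_dir, "h2_scan.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # --- stage 5: phenotype h2 / m2 -------------------------------------
  fit_h2 <- stage("varcomp", estimate_h2(y, X_h2, grm))
  fit_m2 <- stage("varcomp", estimate_m2(y, X_h2, mrm))
  fit_joint <- stage("varcomp", estimate_joint(y, X_h2, grm, mrm))
  vc_tab <- data.frame(
    model = c("h2_only", "m2_only", "joint", "joint"),
    component = c("genetic", "microbial", "genetic", "microbial"),
    share = c(fit_h2$ratios[1], fit_m2$ratios[1],
              fit_joint$ratios[1], fit_joint$ratios[2]),
    se = c(fit_h2$ratio_se[1], fit_m2$ratio_se[1],
           fit_joint$ratio_se[1], fit_joint$ratio_se[2])
  )
  utils::write.table(vc_tab, file.path(config$out_dir, "variance_components.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # --- stage 6: associations ------------------------------------------
  X_gwas <- build_design(covars, pcs = pcs[, seq_len(config$n_pcs_gwas), drop = FALSE])
  gwas <- stage("assoc", mlm_gwas(y, X_gwas, grm, geno_qc,
                                  suggestive = config$suggestive,
                                  genomewide = config$genomewide,
                                  studywide_alpha = config$studywide_alpha))
  prev <- prevalence(rel)
  mb <- stage("assoc", mbgwas_scan(feats, h2_scan, prev, X_gwas, grm, geno_qc,
                                   min_prev_binary = config$prev_binary_gwas,
                                   suggestive = config$suggestive,
                                   genomewide = config$genomewide,
                                   studywide_alpha = config$studywide_alpha))
  y_adj <- adjust_phenotype(y, covars)
  mwas <- stage("assoc", mwas_two_part(y_adj, rel,
                                       pcs = pcs[, seq_len(config$n_pcs_gwas), drop = FALSE],
                                       split = config$prev_split,
                                       min_prev = config$prev_exclude,
                                       alpha = config$mwas_alpha))
  log_counts$marker_genera <- sum(mwas$significant)
  utils::write.table(gwas, file.path(config$out_dir, "gwas_weight.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(mwas, file.path(config$out_dir, "mwas.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # --- stage 7: recursive ---------------------------------------------
  rec <- stage("recursive", recursive_report(
    mwas, mb, gwas, y, geno_qc, kw_alpha = config$kw_alpha))
  utils::write.table(rec$table, file.path(config$out_dir, "scenarios.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("microbiability")),
    seed = config$seed,
    thresholds = config[setdiff(names(config), c("sim", "paths", "out_dir", "seed"))],
    counts = log_counts,
    mantel = list(r = mant$r, p = mant$p),
    recursive_summary = as.list(rec$summary)
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(
    cohort = cohort, features = feats, core = core, keystone = ks,
    grm = grm, mrm = mrm, pcs = pcs, mantel = mant,
    h2_scan = h2_scan, fit_h2 = fit_h2, fit_m2 = fit_m2,
    fit_joint = fit_joint, gwas = gwas, mbgwas = mb, mwas = mwas,
    recursive = rec, out_dir = config$out_dir
  ))
}
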