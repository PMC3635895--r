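#' Default pipeline configuration
#'
#' All thresholds the pipeline applies, the platform roles, transformation
#' switches, the random seed and the synthetic-world parameters, as one
#' nested list. [read_config()] merges a JSON file over these defaults and
#' every CLI flag overrides its config key, so a full run is reproducible
#' from a single artifact.
#'
#' @return Nested named list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    outdir = "invasig_out",
    thresholds = list(p_discovery = 0.05, p_confirmation = 0.025,
                      p_gene_drug = 0.05, sd_quantile = 0.9),
    transform = list(expression = TRUE, phenotype = TRUE, drug = TRUE),
    platform_roles = list(discovery = "A", confirmation = "B"),
    chip = "chipA",
    class_signs = list(targeted_therapy = 1, tubulin_binding = -1),
    signature_drugs = c("tubulin_binding_01", "tubulin_binding_02",
                        "targeted_therapy_01", "targeted_therapy_02",
                        "targeted_therapy_03"),
    standardize_cohort_score = TRUE,
    simulate = list(
      n_lines = 53, n_groups = 8, n_probes_a = 2000, n_probes_b = 2000,
      n_planted = 50, n_signature = 8, effect_r = 0.6,
      drug_loading = 0.63, sig_sd_scale = 2.5, mm_frac = 0,
      chip_a_frac = 0.85,
      drug = list(n_drugs = 106,
                  class_sizes = list(tubulin_binding = 9, targeted_therapy = 8,
                                     alkylating = 30, antimetabolite = 30,
                                     topoisomerase = 29),
                  n_inactive = 7, effect_r = 0.95),
      validation = list(n_sensitive = 15, n_resistant = 15, score_shift = 1.5),
      cohort = list(n = 200, log_hr = 0.6931472, censoring_rate = 0.3)
    )
  )
}

#' Validate a pipeline configuration
#'
#' @param config Nested list as returned by [default_config()].
#' @return `config`, invisibly; errors on invalid entries.
#' @export
validate_config <- function(config) {
  th <- config$thresholds
  for (nm in c("p_discovery", "p_confirmation", "p_gene_drug", "sd_quantile")) {
    v <- th[[nm]]
    if (is.null(v) || !is.numeric(v) || v <= 0 || v >= 1) {
      stop_ivs("config: thresholds$%s must be in (0,1), got %s", nm,
               if (is.null(v)) "NULL" else format(v))
    }
  }
  if (!is.numeric(config$seed)) stop_ivs("config: seed must be numeric")
  invisible(config)
}

#' Read a JSON configuration file
#'
#' Keys present in the file override the defaults; absent keys keep their
#' default values (recursive merge).
#'
#' @param path JSON file path, or `NULL` for pure defaults.
#' @return Validated config list.
#' @export
read_config <- function(path = NULL) {
  config <- default_config()
  if (!is.null(path)) {
    user <- jsonlite::read_json(path, simplifyVector = TRUE)
    config <- utils::modifyList(config, user)
  }
  validate_config(config)
  config
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop_ivs("pipeline stage '%s' failed: %s", name, conditionMessage(e))
  })
}

#' Run the full integration pipeline
#'
#' Simulates (or, via `inputs`, loads) the cell-line panel, runs the
#' two-stage invasion-associated screen, the gene-drug correlation stage,
#' the four-filter signature derivation, the cell-line validation t-test and
#' the survival stage, writing one CSV per major result to `config$outdir`.
#' Every threshold actually applied is logged; the run is a pure function of
#' the config (including its seed).
#'
#' @param config A validated config list ([read_config()]).
#' @param stages Which stage outputs to write (default: all).
#' @return Invisible list of in-memory stage results (`panel`, `ia`,
#'   `gene_drug`, `counts`, `signature`, `validation`, `survival`, `files`).
#' @export
run_pipeline <- function(config = default_config(),
                         stages = c("invasion", "gene_drug", "signature",
                                    "validate", "survival")) {
  validate_config(config)
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)
  th <- config$thresholds
  sim <- config$simulate
  files <- character()
  ivs_log("INFO", "run_pipeline: seed=%d outdir=%s", seed, outdir)
  ivs_log("INFO", "thresholds: p_discovery=%g p_confirmation=%g p_gene_drug=%g sd_quantile=%g",
          th$p_discovery, th$p_confirmation, th$p_gene_drug, th$sd_quantile)

  panel <- run_stage("simulate", {
    ivs_log("INFO", "simulate: cell-line panel seed=%d", derive_seed(seed, 1))
    simulate_cell_line_panel(
      n_lines = sim$n_lines, n_groups = sim$n_groups,
      n_probes_a = sim$n_probes_a, n_probes_b = sim$n_probes_b,
      n_planted = sim$n_planted, effect_r = sim$effect_r,
      seed = derive_seed(seed, 1), n_signature = sim$n_signature,
      drug_loading = sim$drug_loading, sig_sd_scale = sim$sig_sd_scale,
      mm_frac = sim$mm_frac, chip_a_frac = sim$chip_a_frac)
  })
  sig_probes_true <- panel$truth$planted$probe_a[panel$truth$planted$is_signature]
  drugs <- run_stage("simulate", {
    gl <- stats::setNames(rep(sim$drug_loading, length(sig_probes_true)),
                          sig_probes_true)
    cls <- lapply(config$class_signs, function(s)
      list(sign = s, effect_r = sim$drug$effect_r))
    simulate_drug_panel(
      n_drugs = sim$drug$n_drugs,
      class_sizes = unlist(sim$drug$class_sizes),
      n_inactive = sim$drug$n_inactive,
      assoc_spec = list(latent = panel$truth$latent_drug, classes = cls,
                        gene_loadings = gl),
      seed = derive_seed(seed, 2))
  })

  ## Invasion-associated screen ------------------------------------------
  ia <- run_stage("invasion-assoc", {
    roles <- config$platform_roles
    exprs <- list(A = panel$expr_a, B = panel$expr_b)
    disc <- exprs[[roles$discovery]]
    conf <- exprs[[roles$confirmation]]
    ivs_log("INFO", "invasion-assoc: discovery=%s confirmation=%s",
            roles$discovery, roles$confirmation)
    icc <- stats::setNames(panel$invasion$icc, panel$invasion$cell_line)
    rec_d <- correlate_profile(disc, icc, transform = config$transform$expression)
    rec_c <- correlate_profile(conf, icc, transform = config$transform$expression)
    pm <- panel$probe_map
    if (roles$discovery != "A") {
      pm <- data.frame(probe_a = pm$probe_b, probe_b = pm$probe_a,
                       gene_symbol = pm$gene_symbol, stringsAsFactors = FALSE)
    }
    pairs <- match_probes(disc, conf,
                          stats::setNames(pm, c("probe_a", "probe_b", "gene_symbol")))
    two_stage_ia_selection(rec_d, rec_c, pairs,
                           p_disc = th$p_discovery, p_conf = th$p_confirmation)
  })
  if ("invasion" %in% stages) {
    f <- file.path(outdir, "ia_gene_table.csv")
    utils::write.csv(ia$table, f, row.names = FALSE)
    files <- c(files, f)
  }

  ## Gene-drug stage -------------------------------------------------------
  active <- run_stage("gene-drug", filter_inactive_drugs(drugs$panel))
  gd <- run_stage("gene-drug", {
    ia_probes <- unique(ia$table$probe_discovery)
    if (!length(ia_probes)) stop("empty IA probe set")
    sub <- expression_matrix(panel$expr_a$values[ia_probes, , drop = FALSE], "A")
    gene_drug_correlations(sub, active, transform = config$transform$drug)
  })
  counts <- run_stage("gene-drug", count_significant(gd, alpha = th$p_gene_drug))
  if ("gene_drug" %in% stages) {
    f1 <- file.path(outdir, "gene_drug_r.csv")
    f2 <- file.path(outdir, "gene_drug_p.csv")
    f3 <- file.path(outdir, "drug_counts.csv")
    utils::write.csv(as.data.frame(gd$r), f1)
    utils::write.csv(as.data.frame(gd$p), f2)
    utils::write.csv(counts$per_drug, f3, row.names = FALSE)
    files <- c(files, f1, f2, f3)
  }

  ## Signature derivation --------------------------------------------------
  signature <- run_stage("signature", {
    sets <- significant_probe_sets(gd, alpha = th$p_gene_drug,
                                   drugs = config$signature_drugs)
    common <- intersect_drug_correlated(sets)
    on_chip <- filter_platform(common, panel$membership, config$chip)
    hi_sd <- filter_by_sd(panel$expr_a, on_chip, quantile = th$sd_quantile)
    consistent <- filter_direction_consistency(
      hi_sd, gd, expected = unlist(config$class_signs),
      drugs = config$signature_drugs)
    ann <- unique(data.frame(probe = panel$probe_map$probe_a,
                             gene_symbol = panel$probe_map$gene_symbol,
                             stringsAsFactors = FALSE))
    ivs_log("INFO", "signature: %d common -> %d on-chip -> %d high-SD -> %d consistent",
            length(common), length(on_chip), length(hi_sd), length(consistent))
    collapse_probes_to_genes(consistent, ann, panel$expr_a, gd)
  })
  if ("signature" %in% stages) {
    f <- file.path(outdir, "signature.csv")
    utils::write.csv(as.data.frame(signature), f, row.names = FALSE)
    files <- c(files, f)
  }
  sig_genes <- if (nrow(signature)) signature$gene else sprintf("SG%d", 1:8)

  ## Cell-line validation ---------------------------------------------------
  validation <- run_stage("validate-cells", {
    vp <- simulate_validation_panel(sim$validation$n_sensitive,
                                    sim$validation$n_resistant,
                                    sim$validation$score_shift,
                                    seed = derive_seed(seed, 3),
                                    genes = sig_genes)
    rs <- compute_risk_score(vp$expr, sig_genes)
    list(panel = vp, scores = rs, test = compare_groups(rs, vp$labels))
  })

  ## Survival stage ---------------------------------------------------------
  surv <- run_stage("survival", {
    ch <- simulate_survival_cohort(sim$cohort$n, sim$cohort$log_hr,
                                   censoring_rate = sim$cohort$censoring_rate,
                                   seed = derive_seed(seed, 4),
                                   genes = sig_genes)
    X <- t(as.matrix(as.data.frame(ch)[, sig_genes, drop = FALSE]))
    colnames(X) <- ch$patient_id
    rs <- compute_risk_score(X, sig_genes,
                             standardize = isTRUE(config$standardize_cohort_score))
    kl <- km_logrank(ch, rs$group)
    ch2 <- ch
    ch2$risk_group <- as.integer(rs$group == "high")
    cox <- cox_multivariate(ch2, c("risk_group", "age", "stage"))
    list(cohort = ch, scores = rs, km = kl, cox = cox)
  })
  if ("validate" %in% stages || "survival" %in% stages) {
    f <- file.path(outdir, "risk_scores.csv")
    utils::write.csv(surv$scores, f, row.names = FALSE)
    files <- c(files, f)
  }
  if ("survival" %in% stages) {
    f <- file.path(outdir, "survival_report.csv")
    rep <- rbind(
      data.frame(variable = "logrank_chi2", value = surv$km$logrank_chi2,
                 stringsAsFactors = FALSE),
      data.frame(variable = "logrank_p", value = surv$km$logrank_p),
      data.frame(variable = "validation_t_p", value = validation$test$p_two_sided),
      data.frame(variable = "ia_fdr", value = ia$fdr$fdr),
      data.frame(variable = paste0("cox_hr_", surv$cox$coefficients$variable),
                 value = surv$cox$coefficients$hr))
    utils::write.csv(rep, f, row.names = FALSE)
    files <- c(files, f)
  }
  ivs_log("INFO", "run_pipeline: wrote %d file(s)", length(files))
  invisible(list(panel = panel, drugs = drugs, ia = ia, gene_drug = gd,
                 counts = counts, signature = signature,
                 validation = validation, survival = surv, files = files))
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `invasion-assoc`, `gene-drug`, `signature`,
#' `validate-cells`, `survival`, `run-all`. Common flags: `--config <path>`,
#' `--seed <int>`, `--outdir <path>` (each flag overrides its config key).
#' `simulate` writes the synthetic input files plus the ground-truth CSV;
#' the stage subcommands run the pipeline and write that stage's outputs.
#'
#' @param args Character vector (default: the process's trailing arguments).
#' @return Invisibly, the pipeline result (or `NULL` for `simulate`).
#' @export
invasig_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  subs <- c("simulate", "invasion-assoc", "gene-drug", "signature",
            "validate-cells", "survival", "run-all")
  if (!length(args) || !args[1] %in% subs) {
    stop_ivs("usage: invasig <%s> [--config F] [--seed N] [--outdir D]",
             paste(subs, collapse = "|"))
  }
  cmd <- args[1]
  opt <- list(config = NULL, seed = NULL, outdir = NULL)
  i <- 2
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (!key %in% names(opt) || i == length(args)) {
      stop_ivs("invasig: bad argument '%s'", args[i])
    }
    opt[[key]] <- args[i + 1]
    i <- i + 2
  }
  config <- read_config(opt$config)
  if (!is.null(opt$seed)) config$seed <- as.integer(opt$seed)
  if (!is.null(opt$outdir)) config$outdir <- opt$outdir
  validate_config(config)

  if (cmd == "simulate") {
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    sim <- config$simulate
    panel <- simulate_cell_line_panel(
      n_lines = sim$n_lines, n_groups = sim$n_groups,
      n_probes_a = sim$n_probes_a, n_probes_b = sim$n_probes_b,
      n_planted = sim$n_planted, effect_r = sim$effect_r,
      seed = derive_seed(config$seed, 1), n_signature = sim$n_signature,
      drug_loading = sim$drug_loading, sig_sd_scale = sim$sig_sd_scale,
      mm_frac = sim$mm_frac, chip_a_frac = sim$chip_a_frac)
    gl <- with(panel$truth, stats::setNames(planted$drug_loading[planted$is_signature],
                                            planted$probe_a[planted$is_signature]))
    cls <- lapply(config$class_signs, function(s)
      list(sign = s, effect_r = sim$drug$effect_r))
    drugs <- simulate_drug_panel(
      n_drugs = sim$drug$n_drugs, class_sizes = unlist(sim$drug$class_sizes),
      n_inactive = sim$drug$n_inactive,
      assoc_spec = list(latent = panel$truth$latent_drug, classes = cls,
                        gene_loadings = gl),
      seed = derive_seed(config$seed, 2))
    write_expression_matrix(panel$expr_a, file.path(config$outdir, "expr_a.tsv"))
    write_expression_matrix(panel$expr_b, file.path(config$outdir, "expr_b.tsv"))
    utils::write.csv(panel$probe_map, file.path(config$outdir, "probe_map.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(panel$invasion),
                     file.path(config$outdir, "invasion.csv"), row.names = FALSE)
    write_drug_panel(drugs$panel, file.path(config$outdir, "drugs.csv"))
    write_simulation_truth(list(planted = panel$truth$planted,
                                drug_assoc = drugs$truth),
                           file.path(config$outdir, "truth.csv"))
    ivs_log("INFO", "simulate: inputs written to %s", config$outdir)
    return(invisible(NULL))
  }
  stages <- switch(cmd,
                   "run-all" = c("invasion", "gene_drug", "signature",
                                 "validate", "survival"),
                   "invasion-assoc" = "invasion",
                   "gene-drug" = "gene_drug",
                   "signature" = "signature",
                   "validate-cells" = "validate",
                   "survival" = "survival")
  invisible(run_pipeline(config, stages = stages))
}
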