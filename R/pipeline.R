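# End-to-end orchestration of the synthetic cross-species analysis:
# simulate -> differential expression -> signatures/templates -> orthology
# translation -> scoring/classification -> survival & correlation reports.
# Stages communicate only via files in the declared formats, so every
# intermediate artifact is auditable and re-runs with the same config are
# byte-identical.

#' Configuration for the end-to-end synthetic pipeline
#'
#' Selection parameters default to the values used throughout the
#' analysis: 75 up-regulated genes per subtype at logFC > 0.75 for the
#' subtype templates, top 100 up-regulated at logFC > 1 for the z-sum
#' panel signature, top 500 by significance (either direction) for the
#' survival-stratification signature, and correlation-score
#' classification at 0.1 / -0.1.
#'
#' @param out_dir Output directory for all artifacts.
#' @param seed Integer seed for every source of randomness.
#' @param n_samples,n_genes,genes_per_subtype_block,block_effect,noise_sd,n_batches,batch_effect_sd,hazard_beta,censor_time
#'   Cohort simulation settings, see [cohort_sim_config()].
#' @param subtype_labels Subtype vocabulary (default CMS1-CMS4 analogues).
#' @param n_per_subtype,lfc_subtype Template selection parameters.
#' @param n_panel,lfc_panel z-sum panel signature selection parameters.
#' @param n_survival_signature Survival signature size.
#' @param pos_threshold,neg_threshold,classify_mode Correlation-score
#'   classification settings, see [classify_by_correlation()].
#' @param models Named list of mouse-model settings; each element is a
#'   list with `target_subtype` and `overlap_fraction`.  Defaults to a
#'   planted KPN-like model on the last (CMS4-like) subtype and an
#'   APN-like model on the second (CMS2-like) subtype.
#' @param frac_one_to_many Fraction of one-to-many rows in the simulated
#'   orthology table.
#' @param overlap_fraction Overlap fraction for the default models.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            seed = 1L,
                            n_samples = 400,
                            n_genes = 1000,
                            subtype_labels = paste0("CMS", 1:4),
                            genes_per_subtype_block = 150,
                            block_effect = 1.5,
                            noise_sd = 1,
                            n_batches = 1,
                            batch_effect_sd = 0,
                            hazard_beta = 0.5,
                            censor_time = 1825,
                            n_per_subtype = 75,
                            lfc_subtype = 0.75,
                            n_panel = 100,
                            lfc_panel = 1,
                            n_survival_signature = 500,
                            pos_threshold = 0.1,
                            neg_threshold = -0.1,
                            classify_mode = c("two_group", "three_group"),
                            models = NULL,
                            frac_one_to_many = 0.1,
                            overlap_fraction = 0.7) {
  stopifnot(is.character(out_dir), length(out_dir) == 1L)
  classify_mode <- match.arg(classify_mode)
  seed <- assert_count(seed, "seed")
  last <- subtype_labels[[length(subtype_labels)]]
  second <- subtype_labels[[min(2L, length(subtype_labels))]]
  models <- models %||% list(
    KPN_like = list(target_subtype = last,
                    overlap_fraction = overlap_fraction),
    APN_like = list(target_subtype = second,
                    overlap_fraction = overlap_fraction))
  structure(list(out_dir = out_dir, seed = seed,
                 n_samples = n_samples, n_genes = n_genes,
                 subtype_labels = subtype_labels,
                 genes_per_subtype_block = genes_per_subtype_block,
                 block_effect = block_effect, noise_sd = noise_sd,
                 n_batches = n_batches, batch_effect_sd = batch_effect_sd,
                 hazard_beta = hazard_beta, censor_time = censor_time,
                 n_per_subtype = n_per_subtype, lfc_subtype = lfc_subtype,
                 n_panel = n_panel, lfc_panel = lfc_panel,
                 n_survival_signature = n_survival_signature,
                 pos_threshold = pos_threshold,
                 neg_threshold = neg_threshold,
                 classify_mode = classify_mode,
                 models = models,
                 frac_one_to_many = frac_one_to_many),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' The YAML document holds any subset of the arguments of
#' [pipeline_config()]; `overrides` (e.g. CLI flags) take precedence over
#' file values.
#'
#' @param path YAML file path.
#' @param overrides Named list of overriding values.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, overrides = list()) {
  if (!file.exists(path)) stop2("config file not found: %s", path)
  vals <- yaml::read_yaml(path) %||% list()
  vals[names(overrides)] <- overrides
  unknown <- setdiff(names(vals), names(formals(pipeline_config)))
  if (length(unknown))
    stop2("unknown config field(s): %s", paste(unknown, collapse = ", "))
  do.call(pipeline_config, vals)
}

#' Run the end-to-end synthetic cross-species pipeline
#'
#' Executes six stages in dependency order (simulate, de, signatures,
#' orthology, scoring, survival), writing every intermediate artifact
#' under `config$out_dir` plus a JSON run report (`run_report.json`) with
#' the seed, parameters, per-stage artifacts and accumulated warnings.
#' Any stage error aborts with the stage name and output directory.
#' Re-running with an identical config reproduces identical artifacts.
#'
#' @param config A [pipeline_config()].
#' @return The run report, invisibly (a list).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$out_dir, ...)
  report <- list(package = "xsubtype",
                 version = as.character(utils::packageVersion("xsubtype")),
                 seed = config$seed,
                 parameters = unclass(config),
                 stages = list())
  state <- new.env(parent = emptyenv())

  run_stage <- function(name, fun) {
    warnings <- character()
    artifacts <- withCallingHandlers(
      tryCatch(fun(), error = function(e) {
        stop2("pipeline stage '%s' failed (%s): %s",
              name, config$out_dir, conditionMessage(e))
      }),
      warning = function(w) {
        warnings <<- c(warnings, conditionMessage(w))
        invokeRestart("muffleWarning")
      },
      message = function(m) {
        warnings <<- c(warnings, sub("\n$", "", conditionMessage(m)))
        invokeRestart("muffleMessage")
      })
    report$stages[[name]] <<- list(artifacts = unname(artifacts),
                                   warnings = warnings)
  }

  run_stage("simulate", function() {
    cc <- cohort_sim_config(
      n_samples = config$n_samples, n_genes = config$n_genes,
      subtype_labels = config$subtype_labels,
      genes_per_subtype_block = config$genes_per_subtype_block,
      block_effect = config$block_effect, noise_sd = config$noise_sd,
      n_batches = config$n_batches,
      batch_effect_sd = config$batch_effect_sd,
      hazard_beta = config$hazard_beta, censor_time = config$censor_time,
      seed = config$seed)
    state$cohort <- simulate_cohort(cc)
    write_expression_tsv(state$cohort$expression, out("expression.tsv"))
    write_clinical_csv(state$cohort$clinical, out("clinical.csv"))
    write_gmt(state$cohort$blocks, out("subtype_blocks.gmt"))
    state$orth <- simulate_orthology(
      frac_one_to_many = config$frac_one_to_many, seed = config$seed + 1L,
      human_genes = rownames(state$cohort$expression))
    write_orthology_tsv(state$orth, out("orthology.tsv"))
    state$mouse_de <- lapply(seq_along(config$models), function(i) {
      m <- config$models[[i]]
      simulate_mouse_profiles(
        mouse_sim_config(m$target_subtype, m$overlap_fraction,
                         seed = config$seed + 1L + i),
        state$cohort$blocks, state$orth)
    })
    names(state$mouse_de) <- names(config$models)
    for (m in names(state$mouse_de))
      write_de_tsv(state$mouse_de[[m]],
                   out(sprintf("mouse_de_%s.tsv", m)))
    c("expression.tsv", "clinical.csv", "subtype_blocks.gmt",
      "orthology.tsv", sprintf("mouse_de_%s.tsv", names(state$mouse_de)))
  })

  run_stage("de", function() {
    expr <- state$cohort$expression
    clin <- state$cohort$clinical
    state$de <- lapply(config$subtype_labels, function(st) {
      welch_de(expr, clin$sample[clin$subtype == st],
               clin$sample[clin$subtype != st])
    })
    names(state$de) <- config$subtype_labels
    for (st in config$subtype_labels)
      write_de_tsv(state$de[[st]], out(sprintf("de_%s.tsv", st)))
    sprintf("de_%s.tsv", config$subtype_labels)
  })

  run_stage("signatures", function() {
    state$template <- build_subtype_templates(
      state$de, n_per_subtype = config$n_per_subtype,
      lfc_threshold = config$lfc_subtype)
    tdf <- data.frame(gene = rownames(state$template$weights),
                      state$template$weights, check.names = FALSE)
    utils::write.table(tdf, out("templates.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    target <- config$models[[1L]]$target_subtype
    state$risk_sig <- select_top_signature(
      state$de[[target]], n = config$n_survival_signature,
      lfc_threshold = 0, direction = "both", name = "risk_signature")
    write_signature_tsv(state$risk_sig, out("risk_signature.tsv"))
    state$panel_sig <- select_top_signature(
      state$de[[target]], n = config$n_panel,
      lfc_threshold = config$lfc_panel, direction = "up",
      name = "panel_signature")
    write_signature_tsv(state$panel_sig, out("panel_signature.tsv"))
    c("templates.tsv", "risk_signature.tsv", "panel_signature.tsv")
  })

  run_stage("orthology", function() {
    index <- orthology_index(state$orth)
    state$mouse_human <- lapply(state$mouse_de, translate_de_table,
                                index = index, direction = "mouse2human")
    summaries <- lapply(state$mouse_human, attr, "translation")
    for (m in names(state$mouse_human))
      write_de_tsv(state$mouse_human[[m]],
                   out(sprintf("mouse_de_%s_human.tsv", m)))
    jsonlite::write_json(summaries, out("orthology_summary.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    c(sprintf("mouse_de_%s_human.tsv", names(state$mouse_human)),
      "orthology_summary.json")
  })

  run_stage("scoring", function() {
    state$corr <- model_subtype_correlation(state$mouse_human,
                                            state$template)
    cdf <- data.frame(model = rownames(state$corr$r), state$corr$r,
                      check.names = FALSE)
    utils::write.csv(cdf, out("model_subtype_correlation.csv"),
                     row.names = FALSE, quote = FALSE)
    scores <- correlation_score_samples(state$cohort$expression,
                                        state$risk_sig)
    scores$group <- classify_by_correlation(
      scores, pos_threshold = config$pos_threshold,
      neg_threshold = config$neg_threshold, mode = config$classify_mode)
    state$scores <- scores
    utils::write.csv(scores, out("sample_scores.csv"), row.names = FALSE,
                     quote = FALSE)
    c("model_subtype_correlation.csv", "sample_scores.csv")
  })

  run_stage("survival", function() {
    clin <- state$cohort$clinical
    groups <- state$scores$group[match(clin$sample, state$scores$sample)]
    lr <- logrank_test(clin$time, clin$event, groups)
    km <- lapply(split(seq_len(nrow(clin)), groups), function(idx) {
      curve <- km_estimate(clin$time[idx], clin$event[idx])
      list(n = length(idx), time = curve$time, surv = curve$surv)
    })
    argmax <- apply(state$corr$r, 1L, function(r) colnames(state$corr$r)[which.max(r)])
    res <- list(logrank = list(statistic = lr$statistic,
                               p.value = lr$p.value, df = lr$df),
                groups = km,
                model_best_subtype = as.list(argmax))
    jsonlite::write_json(res, out("survival.json"), auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    report$summary <<- list(logrank_p = lr$p.value,
                            model_best_subtype = as.list(argmax))
    "survival.json"
  })

  jsonlite::write_json(report, out("run_report.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(report)
}
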