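# Synthetic-data generators: human-like expression cohorts with subtype
# gene blocks, batch effects and score-linked censored survival; mouse-model
# DE profiles planted on a chosen subtype; orthology tables with one-to-many
# mappings; and a packaged GEMM metastasis-incidence table.
#
# Expression is simulated directly on the log scale as Gaussian blocks (the
# downstream maths operates on log expression); survival uses exponential
# hazards with administrative censoring; subtype blocks are disjoint by
# construction so template sizes and classifications are analytically
# checkable.  All generators are deterministic under the single integer
# seed in their config and leave the global RNG state untouched.

#' Configuration for a synthetic human-like cohort
#'
#' @param n_samples,n_genes Cohort dimensions (positive integers).
#' @param subtype_labels Subtype vocabulary; default four labels emulating
#'   CMS1-CMS4.
#' @param genes_per_subtype_block Genes in each subtype's up-regulated
#'   block (default 150); blocks are pairwise disjoint and require
#'   `genes_per_subtype_block * length(subtype_labels) <= n_genes`.
#' @param block_effect Log-units added to a subtype's block genes in that
#'   subtype's samples (default 1.5).
#' @param noise_sd Residual per-gene Gaussian noise SD in log units
#'   (default 1, must be > 0).
#' @param n_batches Number of batches (default 1 = no batch structure).
#' @param batch_effect_sd SD of additive gene-by-batch offsets (default 0).
#' @param hazard_beta Log-hazard increase per unit of the standardized
#'   hazard-subtype block score (default 0.5).
#' @param hazard_subtype Subtype whose block score drives the hazard
#'   (default: last label, the CMS4-like mesenchymal analogue).
#' @param censor_time Administrative censoring horizon in days (default
#'   1825, i.e. five years of recurrence-free follow-up).
#' @param baseline_mean,baseline_sd Distribution of per-gene baseline log
#'   expression (defaults 7 and 1).
#' @param seed Integer seed threaded to all randomness.
#' @return Object of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(n_samples, n_genes,
                              subtype_labels = paste0("CMS", 1:4),
                              genes_per_subtype_block = 150,
                              block_effect = 1.5,
                              noise_sd = 1,
                              n_batches = 1,
                              batch_effect_sd = 0,
                              hazard_beta = 0.5,
                              hazard_subtype = NULL,
                              censor_time = 1825,
                              baseline_mean = 7,
                              baseline_sd = 1,
                              seed = 1L) {
  n_samples <- assert_count(n_samples, "n_samples", lower = 2L)
  n_genes <- assert_count(n_genes, "n_genes", lower = 1L)
  if (!length(subtype_labels) || anyDuplicated(subtype_labels))
    stop2("cohort_sim_config: subtype_labels must be unique and non-empty")
  genes_per_subtype_block <- assert_count(genes_per_subtype_block,
                                          "genes_per_subtype_block", lower = 1L)
  if (genes_per_subtype_block * length(subtype_labels) > n_genes)
    stop2(paste0("cohort_sim_config: genes_per_subtype_block x number of ",
                 "subtypes (%d x %d) exceeds n_genes (%d)"),
          genes_per_subtype_block, length(subtype_labels), n_genes)
  assert_scalar_number(block_effect, "block_effect")
  assert_scalar_number(noise_sd, "noise_sd")
  if (noise_sd <= 0) stop2("cohort_sim_config: noise_sd must be > 0")
  n_batches <- assert_count(n_batches, "n_batches", lower = 0L)
  assert_scalar_number(batch_effect_sd, "batch_effect_sd", lower = 0)
  assert_scalar_number(hazard_beta, "hazard_beta")
  hazard_subtype <- hazard_subtype %||%
    subtype_labels[[length(subtype_labels)]]
  if (!hazard_subtype %in% subtype_labels)
    stop2("cohort_sim_config: hazard_subtype '%s' not in subtype_labels",
          hazard_subtype)
  assert_scalar_number(censor_time, "censor_time")
  if (censor_time <= 0) stop2("cohort_sim_config: censor_time must be > 0")
  assert_scalar_number(baseline_mean, "baseline_mean")
  assert_scalar_number(baseline_sd, "baseline_sd", lower = 0)
  seed <- assert_count(seed, "seed")
  structure(list(n_samples = n_samples, n_genes = n_genes,
                 subtype_labels = as.character(subtype_labels),
                 genes_per_subtype_block = genes_per_subtype_block,
                 block_effect = block_effect, noise_sd = noise_sd,
                 n_batches = n_batches, batch_effect_sd = batch_effect_sd,
                 hazard_beta = hazard_beta, hazard_subtype = hazard_subtype,
                 censor_time = censor_time, baseline_mean = baseline_mean,
                 baseline_sd = baseline_sd, seed = seed),
            class = "cohort_sim_config")
}

#' Simulate a human-like expression cohort with clinical annotation
#'
#' Generates a log-scale genes x samples matrix in which each subtype's
#' block genes have their mean elevated by `block_effect` in that
#' subtype's samples, optional additive gene-by-batch offsets, and a
#' clinical table with censored recurrence-free survival whose log-hazard
#' is `hazard_beta` times the standardized mean expression of the
#' hazard-subtype block ("block score").  Event times are exponential
#' with baseline rate `log(2) / (censor_time / 2)` (median event at half
#' the censoring horizon) and are administratively censored at
#' `censor_time`.
#'
#' @param config A [cohort_sim_config()].
#' @return List of class `sim_cohort` with elements `expression` (matrix),
#'   `clinical` (data.frame: sample, time, event, cms, cris, batch),
#'   `blocks` (named list of subtype block gene sets) and `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_sim_config"))
  withr::with_seed(config$seed, {
    k <- length(config$subtype_labels)
    genes <- sprintf("G%05d", seq_len(config$n_genes))
    samples <- sprintf("S%04d", seq_len(config$n_samples))
    blocks <- split(genes[seq_len(k * config$genes_per_subtype_block)],
                    rep(config$subtype_labels,
                        each = config$genes_per_subtype_block))
    blocks <- blocks[config$subtype_labels]
    # balanced subtype assignment, shuffled
    subtype <- sample(rep_len(config$subtype_labels, config$n_samples))
    baseline <- stats::rnorm(config$n_genes, config$baseline_mean,
                             config$baseline_sd)
    mat <- matrix(stats::rnorm(config$n_genes * config$n_samples,
                               sd = config$noise_sd),
                  nrow = config$n_genes,
                  dimnames = list(genes, samples)) + baseline
    for (st in config$subtype_labels) {
      idx <- subtype == st
      mat[blocks[[st]], idx] <- mat[blocks[[st]], idx] + config$block_effect
    }
    batch <- rep("batch1", config$n_samples)
    if (config$n_batches > 1L) {
      batch <- sample(rep_len(paste0("batch", seq_len(config$n_batches)),
                              config$n_samples))
      offsets <- matrix(stats::rnorm(config$n_genes * config$n_batches,
                                     sd = config$batch_effect_sd),
                        nrow = config$n_genes)
      for (b in seq_len(config$n_batches)) {
        idx <- batch == paste0("batch", b)
        mat[, idx] <- mat[, idx] + offsets[, b]
      }
    }
    block_score <- colMeans(mat[blocks[[config$hazard_subtype]], ,
                                drop = FALSE])
    score <- as.numeric(scale(block_score))
    base_rate <- log(2) / (config$censor_time / 2)
    latent <- stats::rexp(config$n_samples,
                          rate = base_rate * exp(config$hazard_beta * score))
    clinical <- data.frame(
      sample = samples,
      time = pmin(latent, config$censor_time),
      event = latent < config$censor_time,
      cms = if (identical(config$subtype_labels, paste0("CMS", 1:4)))
        subtype else NA_character_,
      subtype = subtype,
      cris = NA_character_,
      batch = batch,
      stringsAsFactors = FALSE)
    structure(list(expression = mat, clinical = clinical, blocks = blocks,
                   config = config),
              class = "sim_cohort")
  })
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("sim_cohort: %d genes x %d samples, %d subtypes, seed %d\n",
              nrow(x$expression), ncol(x$expression),
              length(x$blocks), x$config$seed))
  invisible(x)
}

#' Configuration for a synthetic mouse-model DE profile
#'
#' @param target_subtype Subtype whose block the mouse profile should
#'   resemble.
#' @param overlap_fraction Fraction of the target subtype's block genes
#'   up-regulated in the mouse profile, in \[0, 1\] (default 0.7).
#' @param lfc_scale Positive multiplier on the planted log fold changes
#'   (default 1).
#' @param background_sd SD of the background logFC noise relative to
#'   `lfc_scale` (default 0.3).
#' @param seed Integer seed.
#' @return Object of class `mouse_sim_config`.
#' @export
mouse_sim_config <- function(target_subtype, overlap_fraction = 0.7,
                             lfc_scale = 1, background_sd = 0.3, seed = 1L) {
  assert_scalar_number(overlap_fraction, "overlap_fraction",
                       lower = 0, upper = 1)
  assert_scalar_number(lfc_scale, "lfc_scale")
  if (lfc_scale <= 0) stop2("mouse_sim_config: lfc_scale must be > 0")
  assert_scalar_number(background_sd, "background_sd", lower = 0)
  seed <- assert_count(seed, "seed")
  structure(list(target_subtype = as.character(target_subtype),
                 overlap_fraction = overlap_fraction,
                 lfc_scale = lfc_scale, background_sd = background_sd,
                 seed = seed),
            class = "mouse_sim_config")
}

#' Simulate a mouse-model DE profile planted on a target subtype
#'
#' Returns a mouse-gene DE table covering every human cohort gene with a
#' mouse orthologue (highest-homology mapping).  A fraction
#' `overlap_fraction` of the target subtype's block genes (those with
#' orthologues) receive strong positive log fold changes
#' (`lfc_scale * (1.5 + |N(0, 0.25)|)`) and tiny p-values; all other genes
#' carry background noise (`N(0, background_sd * lfc_scale)`, uniform p).
#'
#' @param config A [mouse_sim_config()].
#' @param cohort_blocks Named list of per-subtype human block gene sets
#'   (the `blocks` element of [simulate_cohort()]).
#' @param orthology Orthology table (data.frame, see
#'   [read_orthology_tsv()]) covering the cohort genes.
#' @return A mouse-gene DE table (data.frame: gene, logFC, pvalue, padj)
#'   with a `planted_genes` attribute naming the up-regulated mouse genes.
#' @export
simulate_mouse_profiles <- function(config, cohort_blocks, orthology) {
  stopifnot(inherits(config, "mouse_sim_config"), is.list(cohort_blocks))
  if (!config$target_subtype %in% names(cohort_blocks))
    stop2("simulate_mouse_profiles: unknown subtype '%s' (available: %s)",
          config$target_subtype, paste(names(cohort_blocks), collapse = ", "))
  index <- orthology_index(orthology)
  human_genes <- sort(unique(orthology$human_gene))
  res <- resolve_orthologues(human_genes, index, "human2mouse")
  withr::with_seed(config$seed, {
    block <- cohort_blocks[[config$target_subtype]]
    block_mapped <- intersect(block, names(res$mapping))
    n_plant <- round(config$overlap_fraction * length(block))
    if (n_plant > length(block_mapped)) {
      warn2("simulate_mouse_profiles: only %d of %d block genes have orthologues",
            length(block_mapped), n_plant)
      n_plant <- length(block_mapped)
    }
    planted_human <- sort(sample(block_mapped, n_plant))
    mouse_genes <- unname(res$mapping)
    de <- data.frame(
      gene = mouse_genes,
      logFC = stats::rnorm(length(mouse_genes),
                           sd = config$background_sd * config$lfc_scale),
      pvalue = stats::runif(length(mouse_genes)),
      stringsAsFactors = FALSE)
    plant_idx <- match(unname(res$mapping[planted_human]), de$gene)
    de$logFC[plant_idx] <- config$lfc_scale *
      (1.5 + abs(stats::rnorm(n_plant, sd = 0.25)))
    de$pvalue[plant_idx] <- 10^-stats::runif(n_plant, 8, 30)
    de$padj <- bh_adjust(de$pvalue)
    attr(de, "planted_genes") <- de$gene[plant_idx]
    de
  })
}

#' Simulate a human-mouse orthology table
#'
#' Generates `(human gene, mouse gene, homology percent)` rows.  A
#' fraction `frac_one_to_many` of the human genes (exactly
#' `round(frac_one_to_many * n_pairs)`) receive a second mouse partner
#' with a strictly lower homology percentage, emulating one-to-many
#' Biomart mappings; with `frac_one_to_many = 0` the mapping is a
#' bijection.
#'
#' @param n_pairs Number of human genes (ignored when `human_genes` is
#'   given).
#' @param frac_one_to_many Fraction of human genes with >= 2 partners, in
#'   \[0, 1).
#' @param seed Integer seed.
#' @param human_genes Optional explicit human gene ids (e.g. the row names
#'   of a simulated cohort matrix); mouse ids are derived as `"m<human>"`.
#' @return Orthology table data.frame (human_gene, mouse_gene,
#'   homology_pct).
#' @export
simulate_orthology <- function(n_pairs, frac_one_to_many = 0, seed = 1L,
                               human_genes = NULL) {
  assert_scalar_number(frac_one_to_many, "frac_one_to_many", lower = 0)
  if (frac_one_to_many >= 1)
    stop2("simulate_orthology: frac_one_to_many must be < 1")
  seed <- assert_count(seed, "seed")
  if (is.null(human_genes)) {
    n_pairs <- assert_count(n_pairs, "n_pairs", lower = 1L)
    human_genes <- sprintf("H%05d", seq_len(n_pairs))
  } else {
    human_genes <- as.character(human_genes)
    n_pairs <- length(human_genes)
  }
  withr::with_seed(seed, {
    primary <- data.frame(
      human_gene = human_genes,
      mouse_gene = paste0("m", human_genes),
      homology_pct = round(stats::runif(n_pairs, 80, 100), 1),
      stringsAsFactors = FALSE)
    n_multi <- round(frac_one_to_many * n_pairs)
    if (n_multi > 0) {
      multi <- sort(sample(human_genes, n_multi))
      secondary <- data.frame(
        human_gene = multi,
        mouse_gene = paste0("m", multi, ".2"),
        homology_pct = pmax(
          0,
          primary$homology_pct[match(multi, primary$human_gene)] -
            round(stats::runif(n_multi, 5, 15), 1)),
        stringsAsFactors = FALSE)
      out <- rbind(primary, secondary)
    } else {
      out <- primary
    }
    out <- out[order(out$human_gene, -out$homology_pct), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Packaged KPN metastasis-incidence cohort
#'
#' A deterministic 29-animal KPN cohort in which 24 animals carry liver
#' metastases (83%) and every animal carries at least one metastatic site
#' (100% metastasis).  The liver/no-liver split encodes the KPN model's
#' characteristic incidence; all non-liver site assignments and the survival days are
#' synthetic placeholders (flagged by the `synthetic_sites` attribute) and
#' carry no biological information.
#'
#' @return data.frame of class `gemm_cohort` with columns animal,
#'   genotype, time_days, event, sites (";"-separated labels from
#'   [MET_SITES]).
#' @export
kpn_incidence_fixture <- function() {
  n <- 29L
  sites <- character(n)
  sites[1:24] <- "liver"
  sites[1:6] <- paste(sites[1:6], "lung", sep = ";")
  sites[7:14] <- paste(sites[7:14], "lymph-node", sep = ";")
  sites[15:17] <- paste(sites[15:17], "diaphragm", sep = ";")
  sites[25:27] <- "lymph-node"
  sites[28] <- "lung"
  sites[29] <- "peritoneum"
  structure(data.frame(animal = sprintf("KPN-%02d", seq_len(n)),
                       genotype = "KPN",
                       time_days = 150 + 7 * (seq_len(n) - 1L),
                       event = TRUE,
                       sites = sites,
                       stringsAsFactors = FALSE),
            synthetic_sites = "all non-liver sites and survival days are synthetic placeholders",
            class = c("gemm_cohort", "data.frame"))
}
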