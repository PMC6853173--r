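# Synthetic-data generators: configuration contracts, determinism, and the
# statistical structure the downstream analysis assumes.

test_that("cohort config rejects violated constraints by name", {
  expect_error(cohort_sim_config(n_samples = 10, n_genes = 100,
                                 genes_per_subtype_block = 50),
               "genes_per_subtype_block")
  expect_error(cohort_sim_config(n_samples = 10, n_genes = 1000,
                                 noise_sd = 0),
               "noise_sd")
  expect_error(cohort_sim_config(n_samples = 10, n_genes = 1000,
                                 subtype_labels = c("A", "A")),
               "subtype_labels")
  expect_error(cohort_sim_config(n_samples = 10, n_genes = 1000,
                                 hazard_subtype = "CMS9"),
               "CMS9")
})

test_that("identical config and seed give identical cohorts", {
  cc <- cohort_sim_config(n_samples = 40, n_genes = 620, seed = 42)
  a <- simulate_cohort(cc)
  b <- simulate_cohort(cc)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  # subtype blocks are pairwise disjoint and sized as configured
  expect_true(all(lengths(a$blocks) == 150))
  expect_identical(anyDuplicated(unlist(a$blocks)), 0L)
})

test_that("null configuration carries no subtype or survival signal", {
  cc <- cohort_sim_config(n_samples = 2000, n_genes = 80,
                          genes_per_subtype_block = 20,
                          block_effect = 0, hazard_beta = 0, seed = 5)
  sim <- simulate_cohort(cc)
  score <- colMeans(sim$expression[sim$blocks[[cc$hazard_subtype]], ])
  expect_lt(abs(cor(score, sim$clinical$time)), 0.06)
  # per-gene group means differ only by sampling noise
  g <- sim$expression[1L, ]
  grp <- sim$clinical$subtype
  spread <- diff(range(tapply(g, grp, mean)))
  expect_lt(spread, 5 * cc$noise_sd / sqrt(500))
})

test_that("additive batch effects are removed by per-batch centering", {
  cc <- cohort_sim_config(n_samples = 60, n_genes = 100,
                          genes_per_subtype_block = 20,
                          n_batches = 2, batch_effect_sd = 2, seed = 8)
  sim <- simulate_cohort(cc)
  batch <- sim$clinical$batch
  diffs <- abs(rowMeans(sim$expression[, batch == "batch1"]) -
                 rowMeans(sim$expression[, batch == "batch2"]))
  expect_gt(mean(diffs), 0.5)  # batches really differ before centering
  centred <- center_by_batch(sim$expression, batch)
  diffs2 <- abs(rowMeans(centred[, batch == "batch1"]) -
                  rowMeans(centred[, batch == "batch2"]))
  expect_lt(max(diffs2), 1e-10)
})

test_that("Welch DE recovers planted subtype blocks at calibrated settings", {
  cc <- cohort_sim_config(n_samples = 500, n_genes = 620,
                          block_effect = 1.5, noise_sd = 1, seed = 11)
  sim <- simulate_cohort(cc)
  clin <- sim$clinical
  target <- "CMS3"
  de <- welch_de(sim$expression, clin$sample[clin$subtype == target],
                 clin$sample[clin$subtype != target])
  top <- de$gene[order(de$padj, de$pvalue)][seq_len(150)]
  recovery <- length(intersect(top, sim$blocks[[target]])) / 150
  expect_gte(recovery, 0.9)
})

test_that("simulated orthology tables have the requested structure", {
  bij <- simulate_orthology(100, frac_one_to_many = 0, seed = 3)
  expect_identical(nrow(bij), 100L)
  expect_identical(anyDuplicated(bij$human_gene), 0L)
  expect_identical(anyDuplicated(bij$mouse_gene), 0L)

  multi <- simulate_orthology(1000, frac_one_to_many = 0.2, seed = 3)
  n_multi <- sum(table(multi$human_gene) >= 2L)
  expect_identical(n_multi, 200L)
  # partners of one human gene have distinct homology percentages
  per_h <- split(multi$homology_pct, multi$human_gene)
  expect_true(all(vapply(per_h, function(h) !anyDuplicated(h), logical(1L))))

  # byte-identical reproduction under the same seed
  f1 <- tempfile(); f2 <- tempfile()
  write_orthology_tsv(simulate_orthology(500, 0.3, seed = 9), f1)
  write_orthology_tsv(simulate_orthology(500, 0.3, seed = 9), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_error(simulate_orthology(10, frac_one_to_many = 1), "< 1")
})

test_that("packaged KPN cohort has the documented counts", {
  fx <- kpn_incidence_fixture()
  expect_identical(nrow(fx), 29L)
  sites <- strsplit(fx$sites, ";", fixed = TRUE)
  expect_identical(sum(vapply(sites, function(s) "liver" %in% s, logical(1L))),
                   24L)
  expect_identical(sum(lengths(sites) == 0L), 0L)
  expect_true(all(unlist(sites) %in% MET_SITES))
  expect_true(all(fx$time_days > 0))
  expect_match(attr(fx, "synthetic_sites"), "synthetic")
})

test_that("mouse profiles plant signal on the target subtype", {
  cc <- cohort_sim_config(n_samples = 60, n_genes = 620, seed = 21)
  sim <- simulate_cohort(cc)
  orth <- simulate_orthology(human_genes = rownames(sim$expression),
                             frac_one_to_many = 0.1, seed = 22)
  index <- orthology_index(orth)
  de_list <- lapply(names(sim$blocks), function(st) {
    clin <- sim$clinical
    welch_de(sim$expression, clin$sample[clin$subtype == st],
             clin$sample[clin$subtype != st])
  })
  names(de_list) <- names(sim$blocks)
  tpl <- build_subtype_templates(de_list, 50, 0.75)

  argmax_for <- function(overlap, seed) {
    de <- simulate_mouse_profiles(
      mouse_sim_config("CMS4", overlap, seed = seed), sim$blocks, orth)
    human <- suppressMessages(translate_de_table(de, index, "mouse2human"))
    cm <- model_subtype_correlation(list(m = human), tpl)
    colnames(cm$r)[which.max(cm$r[1L, ])]
  }
  # full overlap forces maximal correlation with the target subtype
  expect_identical(argmax_for(1, seed = 1), "CMS4")
  # no planted signal: the target is not systematically the argmax
  null_hits <- sum(vapply(1:20, function(s) argmax_for(0, s) == "CMS4",
                          logical(1L)))
  expect_lt(null_hits, 14L)
  expect_error(
    simulate_mouse_profiles(mouse_sim_config("CMS9"), sim$blocks, orth),
    "unknown subtype")
  expect_error(mouse_sim_config("CMS4", overlap_fraction = 1.2),
               "overlap_fraction")
})

test_that("mouse profile generation is deterministic under its seed", {
  blocks <- list(A = sprintf("H%05d", 1:20), B = sprintf("H%05d", 21:40))
  orth <- simulate_orthology(human_genes = sprintf("H%05d", 1:40), seed = 2)
  cfg <- mouse_sim_config("A", 0.5, seed = 77)
  expect_identical(simulate_mouse_profiles(cfg, blocks, orth),
                   simulate_mouse_profiles(cfg, blocks, orth))
})
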