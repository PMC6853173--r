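# Sample and model scoring: z-standardization, z-sum panels, median and
# threshold stratification, correlation scores, model-subtype correlation,
# infiltration scores, batch centering.

row_sds_test <- function(x) apply(x, 1, sd)

test_that("gene-wise z-scoring standardizes with the sample sd", {
  expect_equal(unname(zscore_by_gene(rbind(g = c(1, 2, 3)))[1, ]),
               c(-1, 0, 1))
  m <- rand_expr(40, 12, seed = 1)
  z <- zscore_by_gene(m)
  expect_lt(max(abs(rowMeans(z))), 1e-12)
  expect_lt(max(abs(row_sds_test(z) - 1)), 1e-12)
  expect_warning(z0 <- zscore_by_gene(rbind(a = c(1, 1, 1), b = 1:3)),
                 "zero-variance")
  expect_true(all(z0["a", ] == 0))
  expect_error(zscore_by_gene(matrix(1:3, ncol = 1)), ">= 2 samples")
})

test_that("panel z-sum scores match a direct-computation oracle", {
  m <- rand_expr(3, 4, seed = 2)
  panel <- score_panel("toy", rownames(m))
  sc <- panel_sum_score(m, panel)
  z <- t(apply(m, 1, function(r) (r - mean(r)) / sd(r)))
  expect_equal(sc$score, unname(colSums(z)))
  # cohort mean ~ 0 whenever all panel genes are present
  expect_lt(abs(sum(sc$score)), 1e-10)
})

test_that("panel scoring drops absent genes with a warning, never imputes", {
  m <- rand_expr(20, 6, seed = 3)
  rownames(m)[1:13] <- notch_panel()$genes[1:13]  # HES2 absent
  expect_warning(sc <- panel_sum_score(m, notch_panel()),
                 "1 panel gene\\(s\\) absent")
  z <- zscore_by_gene(m[notch_panel()$genes[1:13], ])
  expect_equal(sc$score, unname(colSums(z)))
  expect_error(panel_sum_score(rand_expr(5, 4, seed = 1), wnt_panel()),
               "WNT")
})

test_that("packaged NOTCH and WNT panels carry the documented gene sets", {
  expect_length(notch_panel()$genes, 14L)
  expect_true(all(c("NOTCH1", "HES1", "DTX1", "JAG1") %in%
                    notch_panel()$genes))
  expect_length(wnt_panel()$genes, 15L)
  expect_true(all(c("LGR5", "AXIN2", "MYC", "ZNRF3") %in% wnt_panel()$genes))
})

test_that("median stratification is strict-above, within strata", {
  expect_identical(unname(median_stratify(c(1, 2, 3, 4))),
                   c("low", "low", "high", "high"))
  expect_identical(unname(median_stratify(c(2, 2, 2))),
                   c("low", "low", "low"))
  withr::with_seed(4, {
    x <- rnorm(40)
    strata <- rep(c("KRASmut", "KRASwt"), each = 20)
    got <- median_stratify(x, strata)
    want <- character(40)
    for (s in unique(strata)) {
      idx <- strata == s
      want[idx] <- ifelse(x[idx] > median(x[idx]), "high", "low")
    }
    expect_identical(unname(got), want)
  })
})

test_that("signature-correlation scores are Pearson r against the weights", {
  de <- rand_de(200, seed = 5)
  sig <- select_top_signature(de, 200, 0, "both")
  m <- rand_expr(250, 10, seed = 6)
  rownames(m)[1:200] <- sig$genes
  sc <- correlation_score_samples(m, sig)
  centred <- m[sig$genes, ] - rowMeans(m[sig$genes, ])
  for (j in c(1L, 5L, 10L))
    expect_equal(sc$score[j], oracle_pearson(centred[, j], unname(sig$weights)),
                 tolerance = 1e-12)
  # centred sample vector proportional to the weights: r = 1; negated: -1
  u <- withr::with_seed(7, rnorm(200))
  m2 <- cbind(a = sig$weights, b = -sig$weights, c = u, d = -u) + 5
  rownames(m2) <- sig$genes
  sc2 <- correlation_score_samples(m2, sig)
  expect_equal(sc2$score[1:2], c(1, -1), tolerance = 1e-12)
  few <- rand_expr(5, 4, seed = 1)
  rownames(few) <- c(sig$genes[1:2], "x1", "x2", "x3")  # only 2 overlap
  expect_error(correlation_score_samples(few, sig), ">= 3")
})

test_that("correlation scores are invariant to positive affine weight rescaling", {
  de <- rand_de(50, seed = 7)
  sig <- select_top_signature(de, 50, 0, "both")
  m <- rand_expr(50, 8, seed = 8)
  rownames(m) <- sig$genes
  sc <- correlation_score_samples(m, sig)
  rescaled <- sig
  rescaled$weights <- 2.5 * sig$weights + 7
  sc2 <- correlation_score_samples(m, rescaled)
  expect_equal(sc$score, sc2$score, tolerance = 1e-12)
})

test_that("threshold classification implements both modes", {
  x <- c(a = 0.15, b = 0.05, c = -0.2, d = 0.1)
  expect_identical(unname(classify_by_correlation(x)),
                   c("high", "low", "low", "low"))
  expect_identical(unname(classify_by_correlation(x, mode = "three_group")),
                   c("positive", "unassigned", "negative", "unassigned"))
  expect_error(classify_by_correlation(x, pos_threshold = -0.2,
                                       neg_threshold = 0.2),
               "neg_threshold")
})

test_that("model-subtype correlations match brute-force Pearson per cell", {
  de4 <- synthetic_subtype_de(4, n_strong = 60, seed = 9)
  tpl <- build_subtype_templates(de4, 40, 0.75)
  withr::with_seed(10, {
    genes <- rownames(tpl$weights)
    model <- data.frame(gene = sample(genes, 120), logFC = rnorm(120),
                        pvalue = runif(120), stringsAsFactors = FALSE)
    model$padj <- p.adjust(model$pvalue, "BH")
  })
  cm <- model_subtype_correlation(list(mod = model), tpl)
  common <- intersect(rownames(tpl$weights), model$gene)
  for (st in colnames(tpl$weights)) {
    want <- oracle_pearson(model$logFC[match(common, model$gene)],
                           tpl$weights[common, st])
    expect_equal(cm$r["mod", st], want, tolerance = 1e-12)
    expect_identical(cm$n["mod", st], length(common) + 0)
  }
  # a model whose logFC equals a template column correlates at exactly 1
  perfect <- data.frame(gene = rownames(tpl$weights),
                        logFC = tpl$weights[, 2], pvalue = 0.5, padj = 0.5,
                        stringsAsFactors = FALSE)
  cm2 <- model_subtype_correlation(list(p = perfect), tpl)
  expect_equal(unname(cm2$r["p", 2]), 1, tolerance = 1e-12)
  expect_identical(colnames(cm2$r)[which.max(cm2$r["p", ])],
                   colnames(tpl$weights)[2])
  tiny <- data.frame(gene = rownames(tpl$weights)[1:2], logFC = c(1, 2),
                     pvalue = 0.5, padj = 0.5, stringsAsFactors = FALSE)
  expect_error(model_subtype_correlation(list(t = tiny), tpl), "'t'")
})

test_that("infiltration scores equal the mean-then-standardize oracle", {
  m <- rand_expr(30, 10, seed = 11)
  sets <- list(neutrophils = rownames(m)[1:5],
               fibroblasts = rownames(m)[6:12],
               t_cells = rownames(m)[13]) # single-marker set
  sc <- infiltration_scores(m, sets)
  raw <- rbind(colMeans(m[sets$neutrophils, ]),
               colMeans(m[sets$fibroblasts, ]),
               m[sets$t_cells, ])
  z <- t(apply(raw, 1, function(r) (r - mean(r)) / sd(r)))
  expect_equal(unname(sc), unname(z), tolerance = 1e-12)
  # single-marker set reduces to that gene's z-row
  expect_equal(sc["t_cells", ],
               zscore_by_gene(m)[sets$t_cells, ], tolerance = 1e-12)
  expect_error(infiltration_scores(m, list(bad = c("NOPE"))), "'bad'")
})

test_that("batch centering preserves gene means and removes offsets", {
  m <- rand_expr(25, 10, seed = 12)
  expect_equal(center_by_batch(m, rep("b1", 10)), m)
  batches <- rep(c("b1", "b2"), each = 5)
  shifted <- m
  shifted[, 6:10] <- shifted[, 6:10] + 3
  centred <- center_by_batch(shifted, batches)
  expect_lt(max(abs(rowMeans(centred[, 1:5]) - rowMeans(centred[, 6:10]))),
            1e-12)
  expect_equal(rowMeans(centred), rowMeans(shifted), tolerance = 1e-12)
  expect_error(center_by_batch(m, c(rep("b1", 9), "b2")), "singleton")
})
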