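# Welch DE engine, top-N signature selection, subtype templates, and the
# serrated (WNT-target-restricted) signature.

test_that("welch_de matches the closed-form Welch computation", {
  expr <- rbind(g1 = c(1, 1, 2, 0, 0, 1))
  colnames(expr) <- sprintf("s%d", 1:6)
  de <- welch_de(expr, c("s1", "s2", "s3"), c("s4", "s5", "s6"))
  ht <- t.test(c(1, 1, 2), c(0, 0, 1))  # independent oracle
  expect_equal(de$logFC, unname(diff(rev(ht$estimate))))
  expect_equal(de$pvalue, ht$p.value)

  # random multi-gene case against per-gene t.test
  expr <- rand_expr(30, 14, seed = 9)
  a <- colnames(expr)[1:7]; b <- colnames(expr)[8:14]
  de <- welch_de(expr, a, b)
  for (i in c(1L, 13L, 30L)) {
    ht <- t.test(expr[i, a], expr[i, b])
    expect_equal(de$pvalue[i], ht$p.value)
    expect_equal(de$logFC[i], unname(ht$estimate[1] - ht$estimate[2]))
  }
})

test_that("welch_de handles degenerate and invalid groupings", {
  expr <- rand_expr(5, 8, seed = 2)
  # duplicated samples under new ids: logFC exactly 0
  dup <- cbind(expr[, 1:4], expr[, 1:4])
  colnames(dup) <- sprintf("s%d", 1:8)
  de <- welch_de(dup, sprintf("s%d", 1:4), sprintf("s%d", 5:8))
  expect_true(all(de$logFC == 0))
  # zero variance in both groups -> p = 1, logFC still reported
  flat <- matrix(c(rep(2, 4), rep(1, 4)), nrow = 1,
                 dimnames = list("g", sprintf("s%d", 1:8)))
  de <- welch_de(flat, sprintf("s%d", 1:4), sprintf("s%d", 5:8))
  expect_equal(de$pvalue, 1)
  expect_equal(de$logFC, 1)
  expect_error(welch_de(expr, colnames(expr)[1:3], colnames(expr)[3:5]),
               "overlap")
  expect_error(welch_de(expr, colnames(expr)[1], colnames(expr)[2:4]),
               ">= 2 samples")
})

test_that("welch_de p-values are uniform under the null", {
  expr <- rand_expr(5000, 40, seed = 31)
  de <- welch_de(expr, colnames(expr)[1:20], colnames(expr)[21:40])
  ks <- suppressWarnings(ks.test(de$pvalue, "punif"))
  expect_lt(unname(ks$statistic), 0.02)
})

test_that("top-N selection applies strict thresholds, ranking and shortfall", {
  de <- rand_de(400, seed = 5)
  # surplus candidates: exactly n returned
  sig <- select_top_signature(de, 100, 0.5, "up")
  expect_length(sig, 100L)
  expect_true(all(sig$weights > 0.5))
  # shortfall: all qualifying genes plus a warning
  de40 <- de[order(-de$logFC), ][1:60, ]
  de40$logFC <- c(runif(40, 1.1, 2), runif(20, -1, 0.9))
  expect_warning(sig <- select_top_signature(de40, 75, 1, "up"),
                 "only 40")
  expect_length(sig, 40L)
  expect_error(select_top_signature(de, 0, 0, "up"), "'n'")
})

test_that("top-N selection equals the sort-and-slice oracle and ignores row order", {
  for (seed in 1:3) {
    de <- rand_de(300, seed = seed)
    # force padj ties so the documented tie-break is exercised
    de$padj <- round(de$padj, 1)
    for (dir in c("up", "down", "both")) {
      sig <- select_top_signature(de, 50, 0.3, dir)
      expect_identical(sig$genes, oracle_top_n(de, 50, 0.3, dir))
      shuf <- de[withr::with_seed(seed, sample(nrow(de))), ]
      sig2 <- select_top_signature(shuf, 50, 0.3, dir)
      expect_identical(sig2$genes, sig$genes)
    }
  }
})

test_that("subtype templates report the per-subtype selection arithmetic", {
  de4 <- synthetic_subtype_de(4, n_strong = 90, seed = 1)
  tpl4 <- build_subtype_templates(de4, 75, 0.75)
  expect_identical(tpl4$n_total, 300L)
  de5 <- synthetic_subtype_de(5, n_strong = 90, seed = 2)
  tpl5 <- build_subtype_templates(de5, 75, 0.75)
  expect_identical(tpl5$n_total, 375L)
  # disjoint blocks: union equals the sum
  expect_identical(tpl4$n_union, 300L)
})

test_that("template union arithmetic matches set algebra with shared genes", {
  de2 <- synthetic_subtype_de(2, n_strong = 40, seed = 3)
  shared <- data.frame(gene = sprintf("SHARED%02d", 1:10),
                       logFC = runif(10, 2, 3), pvalue = 1e-30,
                       padj = 1e-28, stringsAsFactors = FALSE)
  de2 <- lapply(de2, function(de) {
    out <- rbind(de[, colnames(shared)], shared)
    out$padj <- p.adjust(out$pvalue, "BH")
    out
  })
  tpl <- build_subtype_templates(de2, 30, 0.75)
  union_oracle <- length(unique(c(oracle_top_n(de2[[1]], 30, 0.75, "up"),
                                  oracle_top_n(de2[[2]], 30, 0.75, "up"))))
  expect_identical(tpl$n_total, 60L)
  expect_identical(tpl$n_union, union_oracle)
  expect_lt(tpl$n_union, 60L)  # sharing really occurred
})

test_that("template columns equal the per-subtype signature weights", {
  de4 <- synthetic_subtype_de(4, n_strong = 85, seed = 6)
  tpl <- build_subtype_templates(de4, 60, 0.75)
  for (st in names(de4)) {
    sig <- select_top_signature(de4[[st]], 60, 0.75, "up")
    expect_equal(tpl$weights[sig$genes, st], sig$weights)
    off <- setdiff(rownames(tpl$weights), sig$genes)
    expect_true(all(tpl$weights[off, st] == 0))
  }
  bad <- de4
  bad$SUB1$logFC <- -abs(bad$SUB1$logFC)
  expect_error(suppressWarnings(build_subtype_templates(bad, 60, 0.75)),
               "SUB1")
})

test_that("serrated signature restricts the DE table to WNT targets", {
  de <- rand_de(100, seed = 8)
  targets <- de$gene[1:12]
  sig <- serrated_signature(de, targets)
  expect_length(sig, 12L)
  expect_equal(unname(sig$weights),
               de$logFC[match(sig$genes, de$gene)])
  expect_warning(sig2 <- serrated_signature(de, c(targets, "ABS1", "ABS2",
                                                  "ABS3")),
                 "3 WNT target")
  expect_length(sig2, 12L)
  expect_error(serrated_signature(de, c("NOPE1", "NOPE2")), "no WNT target")
  de$logFC <- 0
  expect_true(all(serrated_signature(de, targets)$weights == 0))
})
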