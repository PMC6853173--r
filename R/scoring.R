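# Per-sample and per-model scoring: z-sum panel scores (NOTCH, WNT,
# KPN/KP-style), signature-correlation scores with threshold
# classification, model-vs-subtype correlation matrices, marker-mean
# infiltration scores, and batch mean-centering.

#' Construct a gene score panel
#'
#' @param name Panel name.
#' @param genes Unique gene ids.
#' @param signs Optional per-gene sign (+1/-1), default +1 for all genes.
#' @return Object of class `score_panel`.
#' @export
score_panel <- function(name, genes, signs = NULL) {
  genes <- as.character(genes)
  if (anyDuplicated(genes)) stop2("score_panel: duplicated genes in '%s'", name)
  signs <- signs %||% rep(1, length(genes))
  stopifnot(length(signs) == length(genes), all(signs %in% c(-1, 1)))
  structure(list(name = name, genes = genes,
                 signs = stats::setNames(as.numeric(signs), genes)),
            class = "score_panel")
}

#' @export
print.score_panel <- function(x, ...) {
  cat(sprintf("score_panel '%s': %d genes\n", x$name, length(x$genes)))
  invisible(x)
}

#' Packaged NOTCH-score gene panel
#'
#' Receptors, ligands and canonical targets of NOTCH signalling whose
#' summed standardized expression defines the NOTCH-score.
#' @return A `score_panel` of 14 genes.
#' @export
notch_panel <- function() {
  score_panel("NOTCH", c("JAG1", "JAG2", "DLL1", "DLL3", "DLL4",
                         "NOTCH1", "NOTCH2", "NOTCH3", "NOTCH4",
                         "HES1", "HES2", "HEY1", "HEY2", "DTX1"))
}

#' Packaged WNT-score gene panel
#'
#' WNT pathway target genes whose summed standardized expression defines
#' the WNT-score.
#' @return A `score_panel` of 15 genes.
#' @export
wnt_panel <- function() {
  score_panel("WNT", c("ASCL2", "AXIN2", "BMP4", "MRTO4", "HILPDA",
                       "NOP16", "KITLG", "LGR5", "MYC", "NOP2",
                       "PPIF", "SOX4", "PAAF1", "ZIC2", "ZNRF3"))
}

#' Standardize an expression matrix gene-wise
#'
#' Each gene row is centred to mean 0 and scaled to sample standard
#' deviation 1 (n - 1 denominator) across samples.  Zero-variance rows
#' become all-zero with a warning.
#'
#' @param expr Expression matrix (genes x samples), >= 2 samples.
#' @return Matrix of the same shape.
#' @export
zscore_by_gene <- function(expr) {
  stopifnot(is.matrix(expr))
  if (ncol(expr) < 2L)
    stop2("zscore_by_gene: >= 2 samples required")
  m <- rowMeans(expr)
  s <- row_sds(expr)
  zero <- s == 0
  if (any(zero))
    warn2("zscore_by_gene: %d zero-variance gene(s) set to 0", sum(zero))
  s[zero] <- 1
  z <- (expr - m) / s
  z[zero, ] <- 0
  z
}

#' z-sum panel score per sample
#'
#' `score(sample) = sum over present panel genes of sign x z-scored
#' expression`.  Panel genes absent from the matrix are dropped with a
#' warning (never imputed).  When all panel genes are present the scores
#' sum to ~0 across the cohort by construction.
#'
#' @param expr Expression matrix (genes x samples, log scale).
#' @param panel A [score_panel()], e.g. [notch_panel()] or [wnt_panel()],
#'   or a signature-derived panel (e.g. KPN/KP top-100 genes).
#' @return data.frame with columns sample, score; panel name in the
#'   `score_name` attribute.
#' @export
panel_sum_score <- function(expr, panel) {
  stopifnot(is.matrix(expr), inherits(panel, "score_panel"))
  present <- intersect(panel$genes, rownames(expr))
  if (!length(present))
    stop2("panel_sum_score: no gene of panel '%s' present in the matrix (%s)",
          panel$name, paste(panel$genes, collapse = ", "))
  n_absent <- length(panel$genes) - length(present)
  if (n_absent > 0)
    warn2("panel_sum_score: %d panel gene(s) absent", n_absent)
  z <- zscore_by_gene(expr[present, , drop = FALSE])
  score <- colSums(z * panel$signs[present])
  structure(data.frame(sample = colnames(expr), score = unname(score),
                       stringsAsFactors = FALSE),
            score_name = panel$name)
}

#' Median stratification of sample scores
#'
#' Samples with score strictly above the median are labelled `"high"`,
#' the rest `"low"`.  When a stratification factor is supplied (e.g. KRAS
#' status or CMS label) the median is computed within each stratum
#' ("within-group median").
#'
#' @param scores data.frame with columns sample, score (as returned by the
#'   scoring functions), or a numeric vector.
#' @param strata Optional per-sample stratum labels.
#' @return Character vector of labels ("high"/"low"), named by sample where
#'   sample ids are available.
#' @export
median_stratify <- function(scores, strata = NULL) {
  x <- if (is.data.frame(scores)) scores$score else scores
  nm <- if (is.data.frame(scores)) scores$sample else names(scores)
  if (length(x) < 2L) stop2("median_stratify: >= 2 samples required")
  if (is.null(strata)) strata <- rep("all", length(x))
  stopifnot(length(strata) == length(x))
  out <- character(length(x))
  for (s in unique(strata)) {
    idx <- which(strata == s)
    med <- stats::median(x[idx])
    out[idx] <- ifelse(x[idx] > med, "high", "low")
  }
  if (!is.null(nm)) names(out) <- nm
  out
}

#' Signature-correlation score per sample
#'
#' The matrix is restricted to the signature genes present (>= 3 required)
#' and mean-centred gene-wise; each sample is scored by the Pearson
#' correlation of its centred expression vector with the signature weight
#' vector.  With `binary_weights = TRUE` the weights are replaced by
#' sign(weight), an up/down indicator variant.
#'
#' @param expr Expression matrix (genes x samples, log scale).
#' @param signature A `gene_signature`.
#' @param binary_weights Use sign(weight) instead of the weights.
#' @return data.frame with columns sample, score (Pearson r).
#' @export
correlation_score_samples <- function(expr, signature,
                                      binary_weights = FALSE) {
  stopifnot(is.matrix(expr), inherits(signature, "gene_signature"))
  present <- intersect(signature$genes, rownames(expr))
  if (length(present) < 3L)
    stop2("correlation_score_samples: only %d signature gene(s) in matrix (>= 3 required)",
          length(present))
  n_absent <- length(signature$genes) - length(present)
  if (n_absent > 0)
    warn2("correlation_score_samples: %d signature gene(s) absent", n_absent)
  sub <- expr[present, , drop = FALSE]
  centred <- sub - rowMeans(sub)
  w <- signature$weights[present]
  if (binary_weights) w <- sign(w)
  r <- as.numeric(stats::cor(centred, w))
  structure(data.frame(sample = colnames(expr), score = r,
                       stringsAsFactors = FALSE),
            score_name = signature$name)
}

#' Classify samples by correlation score thresholds
#'
#' Default is the two-group split used for survival curves: `"high"` for
#' score > `pos_threshold`, `"low"` otherwise.  `mode = "three_group"`
#' gives the positive / negative / unassigned variant (score >
#' `pos_threshold` positive, score < `neg_threshold` negative).
#'
#' @param scores data.frame with columns sample, score, or numeric vector.
#' @param pos_threshold Positive threshold (default 0.1).
#' @param neg_threshold Negative threshold (default -0.1); must be <=
#'   `pos_threshold`.
#' @param mode `"two_group"` or `"three_group"`.
#' @return Character vector of group labels, named by sample when ids are
#'   available.
#' @export
classify_by_correlation <- function(scores, pos_threshold = 0.1,
                                    neg_threshold = -0.1,
                                    mode = c("two_group", "three_group")) {
  mode <- match.arg(mode)
  assert_scalar_number(pos_threshold, "pos_threshold")
  assert_scalar_number(neg_threshold, "neg_threshold")
  if (neg_threshold > pos_threshold)
    stop2("classify_by_correlation: neg_threshold > pos_threshold")
  x <- if (is.data.frame(scores)) scores$score else scores
  nm <- if (is.data.frame(scores)) scores$sample else names(scores)
  out <- if (mode == "two_group") {
    ifelse(x > pos_threshold, "high", "low")
  } else {
    ifelse(x > pos_threshold, "positive",
           ifelse(x < neg_threshold, "negative", "unassigned"))
  }
  if (!is.null(nm)) names(out) <- nm
  out
}

#' Correlate mouse-model signatures with subtype templates
#'
#' Each cell (model, subtype) is the Pearson correlation between the
#' model's logFC vector and the subtype's template weight column over the
#' template genes present in that model's DE table (absent genes are
#' dropped for that model; the gene count used is recorded per cell).
#' Model DE tables must already be in the template's (human) gene
#' namespace — see [translate_de_table()].
#'
#' @param model_signatures Named list of DE tables, one per mouse model.
#' @param template A [build_subtype_templates()] result.
#' @return Object of class `correlation_matrix`: list with `r` (models x
#'   subtypes Pearson matrix) and `n` (genes used per cell).
#' @export
model_subtype_correlation <- function(model_signatures, template) {
  stopifnot(is.list(model_signatures), !is.null(names(model_signatures)),
            inherits(template, "subtype_template"))
  tgenes <- rownames(template$weights)
  subtypes <- colnames(template$weights)
  models <- names(model_signatures)
  r <- n <- matrix(NA_real_, length(models), length(subtypes),
                   dimnames = list(models, subtypes))
  for (m in models) {
    de <- model_signatures[[m]]
    validate_de(de)
    genes <- intersect(tgenes, de$gene)
    if (length(genes) < 3L)
      stop2("model_subtype_correlation: model '%s' overlaps the template in %d gene(s) (>= 3 required)",
            m, length(genes))
    lfc <- de$logFC[match(genes, de$gene)]
    for (st in subtypes) {
      r[m, st] <- stats::cor(lfc, template$weights[genes, st])
      n[m, st] <- length(genes)
    }
  }
  structure(list(r = r, n = n), class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat("model-subtype Pearson correlation matrix:\n")
  print(round(x$r, 3))
  invisible(x)
}

#' Marker-based infiltration scores
#'
#' For each cell type the raw score is the mean log expression of that
#' type's marker genes present in the matrix, per sample; raw scores are
#' then z-standardized per cell type across samples.  This is a
#' transparent marker-mean scorer in the spirit of MCP-counter-style
#' abundance estimation; marker gene sets are supplied by the user (GMT).
#'
#' @param expr Expression matrix (genes x samples, log scale).
#' @param marker_sets Named list of marker gene vectors (see [read_gmt()]).
#' @return Matrix of standardized scores, cell types x samples.
#' @export
infiltration_scores <- function(expr, marker_sets) {
  stopifnot(is.matrix(expr), is.list(marker_sets),
            !is.null(names(marker_sets)))
  raw <- matrix(NA_real_, length(marker_sets), ncol(expr),
                dimnames = list(names(marker_sets), colnames(expr)))
  for (ct in names(marker_sets)) {
    present <- intersect(marker_sets[[ct]], rownames(expr))
    if (!length(present))
      stop2("infiltration_scores: no marker gene of set '%s' in matrix", ct)
    raw[ct, ] <- colMeans(expr[present, , drop = FALSE])
  }
  zscore_by_gene(raw)
}

#' Remove additive batch effects by per-batch gene centering
#'
#' For every gene, each batch's mean is subtracted and the overall gene
#' mean re-added, so per-gene overall means are preserved while additive
#' batch offsets cancel.  A documented lightweight alternative to full
#' empirical-Bayes batch correction for the synthetic cohorts.
#'
#' @param expr Expression matrix (genes x samples).
#' @param batches Per-sample batch labels (length = ncol(expr)); each batch
#'   needs >= 2 samples.
#' @return Centred matrix of the same shape.
#' @export
center_by_batch <- function(expr, batches) {
  stopifnot(is.matrix(expr))
  if (length(batches) != ncol(expr) || anyNA(batches))
    stop2("center_by_batch: every sample needs a batch label")
  tab <- table(batches)
  if (any(tab < 2L))
    stop2("center_by_batch: singleton batch '%s'",
          names(tab)[which(tab < 2L)[1L]])
  global <- rowMeans(expr)
  out <- expr
  for (b in names(tab)) {
    idx <- which(batches == b)
    out[, idx] <- expr[, idx] - rowMeans(expr[, idx, drop = FALSE]) + global
  }
  out
}
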