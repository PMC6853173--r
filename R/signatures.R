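# Signature construction from differential-expression results: top-N
# selections, per-subtype weight templates, and a simple internal Welch-t
# DE engine so synthetic tests need no external DE tool.

new_gene_signature <- function(name, genes, weights, metadata = list()) {
  stopifnot(length(genes) == length(weights), !anyDuplicated(genes),
            all(is.finite(weights)))
  structure(list(name = name, genes = as.character(genes),
                 weights = stats::setNames(as.numeric(weights),
                                           as.character(genes)),
                 metadata = metadata),
            class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("gene_signature '%s': %d genes\n", x$name, length(x$genes)))
  if (length(x$metadata))
    cat("  ", paste(names(x$metadata),
                    vapply(x$metadata, function(v) paste(format(v), collapse = ","),
                           character(1L)),
                    sep = "=", collapse = "; "), "\n", sep = "")
  invisible(x)
}

#' @export
length.gene_signature <- function(x) length(x$genes)

#' Per-gene Welch two-sample differential expression on log expression
#'
#' A deliberately simple, pluggable DE engine: log fold change is the
#' difference of group means on the log scale, significance is the Welch
#' (unequal-variance) t test, and adjusted p-values use Benjamini-Hochberg.
#' External DE tables (DESeq2, limma, ...) are accepted everywhere a DE
#' table is consumed; this engine exists so that synthetic cohorts can be
#' analysed end to end.
#'
#' Genes with zero variance in both groups get `pvalue = 1` (logFC still
#' reported as the mean difference).
#'
#' @param expr Expression matrix (genes x samples, log scale).
#' @param group_a,group_b Disjoint character vectors of sample ids, each of
#'   size >= 2.  logFC is mean(A) - mean(B).
#' @return DE table: data.frame with columns gene, logFC, pvalue, padj,
#'   baseMean.
#' @export
welch_de <- function(expr, group_a, group_b) {
  stopifnot(is.matrix(expr))
  if (length(intersect(group_a, group_b)))
    stop2("welch_de: groups overlap (%s)",
          paste(utils::head(intersect(group_a, group_b), 3L), collapse = ", "))
  miss <- setdiff(c(group_a, group_b), colnames(expr))
  if (length(miss))
    stop2("welch_de: sample(s) not in matrix: %s",
          paste(utils::head(miss, 3L), collapse = ", "))
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop2("welch_de: each group needs >= 2 samples")
  a <- expr[, group_a, drop = FALSE]
  b <- expr[, group_b, drop = FALSE]
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1)
  vb <- rowSums((b - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  tstat <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  degenerate <- va == 0 & vb == 0
  p[degenerate] <- 1
  out <- data.frame(gene = rownames(expr), logFC = ma - mb, pvalue = p,
                    padj = bh_adjust(p),
                    baseMean = rowMeans(cbind(a, b)),
                    stringsAsFactors = FALSE, row.names = NULL)
  out
}

#' Select the top-N signature genes from a DE table
#'
#' Candidates are filtered by direction and a strict log-fold-change
#' threshold (`logFC > lfc_threshold` for `"up"`, `logFC < -lfc_threshold`
#' for `"down"`, `|logFC| > lfc_threshold` for `"both"`), then ranked by
#' ascending adjusted p ("most significantly regulated"), ties broken by
#' descending `|logFC|`, then ascending gene id.  The first
#' `min(n, candidates)` genes are returned, with a warning when fewer than
#' `n` qualify.
#'
#' @param de DE table (columns gene, logFC, pvalue, padj).
#' @param n Number of genes requested (>= 1).
#' @param lfc_threshold Non-negative log fold-change threshold, strict.
#' @param direction `"up"`, `"down"` or `"both"`.
#' @param name Signature name.
#' @return A `gene_signature` whose weights are the signed logFC values.
#' @export
select_top_signature <- function(de, n, lfc_threshold = 0,
                                 direction = c("up", "down", "both"),
                                 name = NULL) {
  validate_de(de)
  direction <- match.arg(direction)
  n <- assert_count(n, "n", lower = 1L)
  assert_scalar_number(lfc_threshold, "lfc_threshold", lower = 0)
  keep <- switch(direction,
                 up   = de$logFC > lfc_threshold,
                 down = de$logFC < -lfc_threshold,
                 both = abs(de$logFC) > lfc_threshold)
  cand <- de[keep, , drop = FALSE]
  ord <- order(cand$padj, -abs(cand$logFC), cand$gene)
  cand <- cand[ord, , drop = FALSE]
  if (nrow(cand) < n)
    warn2("select_top_signature: only %d of %d requested genes qualify",
          nrow(cand), n)
  top <- utils::head(cand, n)
  new_gene_signature(
    name %||% sprintf("top%d_%s_lfc%s", n, direction, format(lfc_threshold)),
    top$gene, top$logFC,
    metadata = list(n_requested = n, lfc_threshold = lfc_threshold,
                    direction = direction, n_candidates = nrow(cand)))
}

#' Build subtype weight templates from per-subtype DE tables
#'
#' For each subtype the top `n_per_subtype` up-regulated genes passing the
#' strict logFC threshold are selected ([select_top_signature()] with
#' `direction = "up"`); the template gene list is the union of all
#' selections and the weight matrix holds each subtype's logFC on its own
#' selected genes, 0 elsewhere.  The per-subtype selected-gene total (e.g.
#' 4 x 75 = 300 for CMS, 5 x 75 = 375 for CRIS) is reported separately from
#' the union size, which is what correlations use.
#'
#' @param de_list Named list of DE tables, one per subtype (>= 2).
#' @param n_per_subtype Genes selected per subtype (default 75).
#' @param lfc_threshold Strict logFC threshold (default 0.75).
#' @return Object of class `subtype_template`: list with `weights`
#'   (genes x subtypes matrix), `selected` (per-subtype gene lists),
#'   `n_total` (summed selection sizes) and `n_union`.
#' @export
build_subtype_templates <- function(de_list, n_per_subtype = 75,
                                    lfc_threshold = 0.75) {
  stopifnot(is.list(de_list), !is.null(names(de_list)))
  if (length(de_list) < 2L)
    stop2("build_subtype_templates: >= 2 subtypes required")
  sigs <- lapply(names(de_list), function(st) {
    sig <- select_top_signature(de_list[[st]], n = n_per_subtype,
                                lfc_threshold = lfc_threshold,
                                direction = "up", name = st)
    if (!length(sig$genes))
      stop2("build_subtype_templates: subtype '%s' yields 0 qualifying genes",
            st)
    sig
  })
  names(sigs) <- names(de_list)
  union_genes <- unique(unlist(lapply(sigs, `[[`, "genes"), use.names = FALSE))
  w <- matrix(0, nrow = length(union_genes), ncol = length(sigs),
              dimnames = list(union_genes, names(sigs)))
  for (st in names(sigs)) w[sigs[[st]]$genes, st] <- sigs[[st]]$weights
  structure(list(weights = w,
                 selected = lapply(sigs, `[[`, "genes"),
                 n_total = sum(lengths(lapply(sigs, `[[`, "genes"))),
                 n_union = length(union_genes),
                 n_per_subtype = n_per_subtype,
                 lfc_threshold = lfc_threshold),
            class = "subtype_template")
}

#' @export
print.subtype_template <- function(x, ...) {
  cat(sprintf(
    "subtype_template: %d subtypes, %d genes selected in total (union %d)\n",
    ncol(x$weights), x$n_total, x$n_union))
  invisible(x)
}

#' Restrict a DE contrast to WNT target genes (serrated signature)
#'
#' The serrated-versus-tubular adenoma signature is the DE table restricted
#' to a supplied WNT target gene list; all overlapping genes are kept with
#' their signed logFC as weights (no top-N selection), supporting
#' serrated-vs-tubular heatmap comparisons.
#'
#' @param de DE table of the serrated-vs-tubular contrast.
#' @param wnt_target_genes Non-empty character vector of WNT target genes.
#' @param name Signature name.
#' @return A `gene_signature`.
#' @export
serrated_signature <- function(de, wnt_target_genes,
                               name = "serrated_vs_tubular") {
  validate_de(de)
  if (!length(wnt_target_genes))
    stop2("serrated_signature: WNT target list is empty")
  present <- intersect(wnt_target_genes, de$gene)
  if (!length(present))
    stop2("serrated_signature: no WNT target gene found in the DE table")
  n_absent <- length(setdiff(wnt_target_genes, de$gene))
  if (n_absent > 0)
    warn2("serrated_signature: %d WNT target gene(s) absent from the DE table",
          n_absent)
  rows <- de[match(present, de$gene), , drop = FALSE]
  new_gene_signature(name, rows$gene, rows$logFC,
                     metadata = list(n_targets = length(wnt_target_genes),
                                     n_absent = n_absent))
}
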