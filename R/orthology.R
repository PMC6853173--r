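# Cross-species gene mapping.  One-to-many orthologue mappings (as returned
# by Biomart-style homology tables) are resolved by keeping, for each source
# gene, the partner with the highest homology percentage.

#' Build a bidirectional orthology lookup index
#'
#' Partner lists are sorted by descending homology percentage, ties broken
#' by ascending partner gene id, so that "take the first partner"
#' implements the highest-homology rule deterministically.
#'
#' @param orth Orthology table: data.frame with columns `human_gene`,
#'   `mouse_gene`, `homology_pct` (see [read_orthology_tsv()]).
#' @return An object of class `orthology_index`.
#' @export
orthology_index <- function(orth) {
  validate_orthology(orth)
  build <- function(from, to) {
    ord <- order(orth[[from]], -orth$homology_pct, orth[[to]])
    split(
      data.frame(partner = orth[[to]][ord], homology = orth$homology_pct[ord],
                 stringsAsFactors = FALSE),
      factor(orth[[from]][ord], levels = unique(orth[[from]][ord]))
    )
  }
  structure(list(h2m = build("human_gene", "mouse_gene"),
                 m2h = build("mouse_gene", "human_gene")),
            class = "orthology_index")
}

#' @export
print.orthology_index <- function(x, ...) {
  cat(sprintf("orthology_index: %d human genes, %d mouse genes\n",
              length(x$h2m), length(x$m2h)))
  invisible(x)
}

lookup_for_direction <- function(index, direction) {
  direction <- match.arg(direction, c("human2mouse", "mouse2human"))
  if (direction == "human2mouse") index$h2m else index$m2h
}

#' Resolve genes to single orthologue partners
#'
#' Each input gene maps to at most one partner: for one-to-many mappings the
#' partner with the highest homology percentage is selected (ties broken by
#' ascending partner gene id).  Genes without any partner are returned in
#' `unmapped`, never silently dropped.
#'
#' @param genes Character vector of gene ids.
#' @param index An [orthology_index()].
#' @param direction `"human2mouse"` or `"mouse2human"`.
#' @return List with `mapping` (named character vector, source -> partner)
#'   and `unmapped` (character vector).
#' @export
resolve_orthologues <- function(genes, index,
                                direction = c("human2mouse", "mouse2human")) {
  stopifnot(inherits(index, "orthology_index"))
  direction <- match.arg(direction)
  lut <- lookup_for_direction(index, direction)
  genes <- as.character(genes)
  hit <- genes %in% names(lut)
  mapping <- vapply(lut[genes[hit]], function(d) d$partner[[1L]], character(1L))
  names(mapping) <- genes[hit]
  list(mapping = mapping, unmapped = genes[!hit])
}

#' Translate a differential-expression table across species
#'
#' Gene ids are replaced by their highest-homology orthologue partners.
#' Unmapped genes are dropped (count reported via message and in the
#' `translation` attribute).  When two source genes map to the same target
#' gene, the row with the smaller adjusted p is kept (ties: smaller raw p,
#' then ascending source gene id).
#'
#' @param de DE table (columns gene, logFC, pvalue, padj).
#' @param index An [orthology_index()].
#' @param direction `"human2mouse"` or `"mouse2human"`.
#' @return Translated DE table with a `translation` attribute
#'   (list: mapped, unmapped, collisions).
#' @export
translate_de_table <- function(de, index,
                               direction = c("human2mouse", "mouse2human")) {
  validate_de(de)
  direction <- match.arg(direction)
  res <- resolve_orthologues(de$gene, index, direction)
  keep <- de$gene %in% names(res$mapping)
  out <- de[keep, , drop = FALSE]
  source_gene <- out$gene
  out$gene <- unname(res$mapping[source_gene])
  # collision rule: smallest padj wins, then smallest p, then source gene id
  ord <- order(out$gene, out$padj, out$pvalue, source_gene)
  out <- out[ord, , drop = FALSE]
  dup <- duplicated(out$gene)
  n_collisions <- sum(dup)
  out <- out[!dup, , drop = FALSE]
  rownames(out) <- NULL
  message(sprintf(
    "translate_de_table: %d mapped, %d unmapped dropped, %d collisions resolved",
    nrow(out), length(res$unmapped), n_collisions))
  attr(out, "translation") <- list(mapped = nrow(out),
                                   unmapped = length(res$unmapped),
                                   collisions = n_collisions)
  out
}
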