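# Readers and writers for the plain-text formats the pipeline exchanges.
# Every reader validates strictly and rejects rather than coerces; error
# messages name the file, the offending row/line and the violated rule.

#' Read a log-scale expression matrix from TSV
#'
#' The file must have a header row of unique sample identifiers and a first
#' column (`gene`) of unique gene identifiers; all remaining cells must be
#' finite numbers (log-scale expression).  Missing values are rejected: the
#' downstream scoring maths assumes fully observed matrices.
#'
#' @param path Path to a tab-separated file.
#' @return Numeric matrix, genes in rows (rownames), samples in columns
#'   (colnames).
#' @seealso [write_expression_tsv()]
#' @export
read_expression_tsv <- function(path) {
  if (!file.exists(path)) stop2("expression file not found: %s", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3L)
    stop2("%s: expression matrix needs a gene column plus >= 2 samples", path)
  genes <- as.character(df[[1L]])
  dup <- genes[duplicated(genes)]
  if (length(dup))
    stop2("%s: duplicated gene id '%s'", path, dup[[1L]])
  samples <- colnames(df)[-1L]
  dup <- samples[duplicated(samples)]
  if (length(dup))
    stop2("%s: duplicated sample id '%s'", path, dup[[1L]])
  for (j in seq_along(samples)) {
    col <- df[[j + 1L]]
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(col))))[1L]
      stop2("%s: non-numeric value at row %d, column '%s'",
            path, bad %||% 1L, samples[[j]])
    }
    if (anyNA(col) || any(!is.finite(col))) {
      bad <- which(!is.finite(col))[1L]
      stop2("%s: missing/non-finite value at row %d, column '%s'",
            path, bad, samples[[j]])
    }
  }
  mat <- as.matrix(df[, -1L, drop = FALSE])
  rownames(mat) <- genes
  mat
}

#' Write an expression matrix to TSV
#'
#' @param mat Numeric matrix with gene rownames and sample colnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(mat, path) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-set collection from a GMT file
#'
#' Standard GMT semantics: one set per line, tab-separated fields
#' `name`, `description`, then gene ids.  Gene order is preserved;
#' duplicate genes within a line are collapsed with a warning; duplicate
#' set names are an error.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors of gene ids, with a
#'   `descriptions` attribute (named character vector).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop2("GMT file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  descs <- character()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L)
      stop2("%s: line %d has %d tab-separated fields (>= 3 required)",
            path, i, length(fields))
    name <- fields[[1L]]
    if (name %in% names(sets))
      stop2("%s: duplicated set name '%s' at line %d", path, name, i)
    genes <- fields[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warn2("%s: set '%s' contains duplicated genes; collapsed", path, name)
      genes <- unique(genes)
    }
    if (!length(genes))
      stop2("%s: set '%s' at line %d is empty", path, name, i)
    sets[[name]] <- genes
    descs[[name]] <- fields[[2L]]
  }
  attr(sets, "descriptions") <- descs
  sets
}

#' Write a gene-set collection to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional named character vector of set descriptions;
#'   defaults to the set name.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  descriptions <- descriptions %||% attr(sets, "descriptions") %||%
    stats::setNames(names(sets), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, descriptions[[nm]] %||% nm, sets[[nm]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read a clinical annotation table from CSV
#'
#' Required columns: `sample` (unique ids), `time` (non-negative, days),
#' `event` (0/1 or TRUE/FALSE).  Optional columns: `cms` (CMS1-CMS4 or NA),
#' `cris` (CRIS-A..CRIS-E or NA), `batch`.  Unknown subtype labels are
#' rejected.
#'
#' @param path Path to a CSV file.
#' @return data.frame with columns sample, time, event (logical) and any
#'   optional columns present.
#' @export
read_clinical_csv <- function(path) {
  if (!file.exists(path)) stop2("clinical file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("sample", "time", "event")
  miss <- setdiff(req, colnames(df))
  if (length(miss))
    stop2("%s: missing required column(s): %s", path,
          paste(miss, collapse = ", "))
  df$sample <- as.character(df$sample)
  dup <- df$sample[duplicated(df$sample)]
  if (length(dup)) stop2("%s: duplicated sample id '%s'", path, dup[[1L]])
  if (!is.numeric(df$time) || anyNA(df$time))
    stop2("%s: 'time' must be numeric with no missing values", path)
  bad <- which(df$time < 0)[1L]
  if (!is.na(bad))
    stop2("%s: row %d has negative time %s", path, bad, format(df$time[bad]))
  if (!all(df$event %in% c(0, 1, TRUE, FALSE)))
    stop2("%s: 'event' must be 0/1 or TRUE/FALSE", path)
  df$event <- as.logical(df$event)
  if ("cms" %in% colnames(df)) {
    bad <- setdiff(stats::na.omit(unique(df$cms)), CMS_LEVELS)
    if (length(bad)) stop2("%s: unknown CMS label '%s'", path, bad[[1L]])
  }
  if ("cris" %in% colnames(df)) {
    bad <- setdiff(stats::na.omit(unique(df$cris)), CRIS_LEVELS)
    if (length(bad)) stop2("%s: unknown CRIS label '%s'", path, bad[[1L]])
  }
  df
}

#' Write a clinical table to CSV
#' @param clinical data.frame as returned by [read_clinical_csv()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clinical_csv <- function(clinical, path) {
  utils::write.csv(clinical, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Read a human-mouse orthology table from TSV
#'
#' Required columns: `human_gene`, `mouse_gene`, `homology_pct` (in
#' \[0, 100\]).  (human, mouse) pairs must be unique; one-to-many mappings
#' are expected and resolved later by [resolve_orthologues()].
#'
#' @param path Path to a TSV file.
#' @return data.frame with the three columns above.
#' @export
read_orthology_tsv <- function(path) {
  if (!file.exists(path)) stop2("orthology file not found: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("human_gene", "mouse_gene", "homology_pct")
  miss <- setdiff(req, colnames(df))
  if (length(miss))
    stop2("%s: missing required column(s): %s", path,
          paste(miss, collapse = ", "))
  validate_orthology(df, path)
  df
}

validate_orthology <- function(df, where = "orthology table") {
  if (!is.numeric(df$homology_pct) || anyNA(df$homology_pct))
    stop2("%s: 'homology_pct' must be numeric with no missing values", where)
  bad <- which(df$homology_pct < 0 | df$homology_pct > 100)[1L]
  if (!is.na(bad))
    stop2("%s: row %d has homology_pct %s outside [0, 100]",
          where, bad, format(df$homology_pct[bad]))
  key <- paste(df$human_gene, df$mouse_gene, sep = "\r")
  dup <- which(duplicated(key))[1L]
  if (!is.na(dup))
    stop2("%s: duplicated (human, mouse) pair at row %d: %s / %s",
          where, dup, df$human_gene[dup], df$mouse_gene[dup])
  invisible(df)
}

#' Write an orthology table to TSV
#' @param orth data.frame with columns human_gene, mouse_gene, homology_pct.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_orthology_tsv <- function(orth, path) {
  utils::write.table(orth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a differential-expression table from TSV
#'
#' Required columns: `gene` (unique), `logFC` (log2 units), `pvalue` and
#' `padj` (both in \[0, 1\]).  An optional `baseMean` column is carried
#' through.  External DE tables (e.g. from DESeq2 or limma exports) are
#' first-class inputs as long as they use these column names.
#'
#' @param path Path to a TSV file.
#' @return data.frame (a DE table).
#' @export
read_de_tsv <- function(path) {
  if (!file.exists(path)) stop2("DE file not found: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("gene", "logFC", "pvalue", "padj")
  miss <- setdiff(req, colnames(df))
  if (length(miss))
    stop2("%s: missing required column(s): %s", path,
          paste(miss, collapse = ", "))
  validate_de(df, path)
  df
}

validate_de <- function(df, where = "DE table") {
  df$gene <- as.character(df$gene)
  dup <- df$gene[duplicated(df$gene)]
  if (length(dup)) stop2("%s: duplicated gene '%s'", where, dup[[1L]])
  if (!is.numeric(df$logFC) || any(!is.finite(df$logFC)))
    stop2("%s: 'logFC' must be finite numeric", where)
  for (col in c("pvalue", "padj")) {
    v <- df[[col]]
    if (!is.numeric(v) || anyNA(v) || any(v < 0 | v > 1))
      stop2("%s: '%s' must be numeric in [0, 1]", where, col)
  }
  invisible(df)
}

#' Write a differential-expression table to TSV
#' @param de DE table data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_de_tsv <- function(de, path) {
  utils::write.table(de, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write a gene signature as TSV (columns gene, weight, rank)
#'
#' @param path Path to a TSV file.
#' @param name Signature name (reader only; defaults to the file name).
#' @return [read_signature_tsv()] returns a `gene_signature`;
#'   [write_signature_tsv()] returns `path` invisibly.
#' @export
read_signature_tsv <- function(path, name = basename(path)) {
  if (!file.exists(path)) stop2("signature file not found: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("gene", "weight"), colnames(df))
  if (length(miss))
    stop2("%s: missing required column(s): %s", path,
          paste(miss, collapse = ", "))
  if ("rank" %in% colnames(df)) df <- df[order(df$rank), , drop = FALSE]
  new_gene_signature(name, df$gene, df$weight, metadata = list(source = path))
}

#' @rdname read_signature_tsv
#' @param signature A `gene_signature` object.
#' @export
write_signature_tsv <- function(signature, path) {
  stopifnot(inherits(signature, "gene_signature"))
  df <- data.frame(gene = signature$genes, weight = signature$weights,
                   rank = seq_along(signature$genes))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
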