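# Promoter motif scanning: IUPAC consensus matching on both strands, for
# locating putative transcription-factor binding sites (e.g. the RBPJ core
# site upstream of NOTCH target genes such as Tgfb2).

IUPAC_CODES <- c(A = "A", C = "C", G = "G", T = "T",
                 R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
                 B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT")

#' Default RBPJ core consensus motif
#'
#' The canonical RBPJ (CSL) DNA-binding core site.  The motif is a
#' parameter of every scanning function; this constant is only the packaged
#' default.
#' @format Character scalar `"TGGGAA"`.
#' @export
RBPJ_CORE_MOTIF <- "TGGGAA"

#' Scan a DNA sequence for an IUPAC consensus motif
#'
#' Reports every position whose subsequence matches the IUPAC pattern.
#' Minus-strand hits are matches of the reverse complement of the motif
#' against the forward sequence and are reported with forward-strand start
#' coordinates (1-based, first base of the matched window).  Overlapping
#' hits are all reported.  `N` in the sequence never matches.  Matching is
#' case-insensitive.
#'
#' @param sequence DNA string over A, C, G, T, N (case-insensitive).
#' @param motif IUPAC consensus string (default [RBPJ_CORE_MOTIF]).
#' @param strands `"both"` or `"forward"`.
#' @param motif_name Label recorded per hit (defaults to the motif string).
#' @return data.frame with columns start, strand (`"+"`/`"-"`), match (the
#'   forward-strand subsequence) and motif, ordered by start then strand.
#' @export
scan_iupac <- function(sequence, motif = RBPJ_CORE_MOTIF,
                       strands = c("both", "forward"),
                       motif_name = motif) {
  strands <- match.arg(strands)
  sequence <- toupper(as.character(sequence))
  motif <- toupper(as.character(motif))
  seq_chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  bad <- which(!seq_chars %in% c("A", "C", "G", "T", "N"))[1L]
  if (!is.na(bad))
    stop2("scan_iupac: invalid sequence character '%s' at position %d",
          seq_chars[bad], bad)
  motif_chars <- strsplit(motif, "", fixed = TRUE)[[1L]]
  bad <- which(!motif_chars %in% names(IUPAC_CODES))[1L]
  if (!is.na(bad))
    stop2("scan_iupac: invalid IUPAC code '%s' at motif position %d",
          motif_chars[bad], bad)
  if (nchar(motif) > nchar(sequence))
    return(data.frame(start = integer(), strand = character(),
                      match = character(), motif = character(),
                      stringsAsFactors = FALSE))
  subj <- Biostrings::DNAString(sequence)
  find_hits <- function(pat, strand) {
    m <- Biostrings::matchPattern(Biostrings::DNAString(pat), subj,
                                  fixed = c(pattern = FALSE, subject = TRUE))
    starts <- Biostrings::start(m)
    matches <- as.character(m)
    keep <- !grepl("N", matches, fixed = TRUE)  # N in sequence never matches
    if (!any(keep))
      return(NULL)
    data.frame(start = starts[keep], strand = strand, match = matches[keep],
               motif = motif_name, stringsAsFactors = FALSE)
  }
  hits <- list(find_hits(motif, "+"))
  if (strands == "both") {
    rc <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(motif)))
    hits <- c(hits, list(find_hits(rc, "-")))
  }
  out <- do.call(rbind, hits)
  if (is.null(out))
    return(data.frame(start = integer(), strand = character(),
                      match = character(), motif = character(),
                      stringsAsFactors = FALSE))
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan FASTA sequences for an IUPAC motif
#'
#' Runs [scan_iupac()] on every sequence of a FASTA file.  With a TSS
#' offset (position of the transcription start site within each sequence,
#' 1-based) hits are additionally reported relative to the TSS
#' (`tss_relative_start = start - tss_offset`, so negative values lie
#' upstream of the TSS).
#'
#' @param path Path to a FASTA file.
#' @param motif IUPAC consensus string.
#' @param strands `"both"` or `"forward"`.
#' @param tss_offset Optional 1-based TSS position within the sequences.
#' @return data.frame with columns seq_id, start, strand, match, motif and
#'   (when `tss_offset` is given) tss_relative_start.
#' @export
scan_fasta <- function(path, motif = RBPJ_CORE_MOTIF,
                       strands = c("both", "forward"), tss_offset = NULL) {
  strands <- match.arg(strands)
  if (!file.exists(path)) stop2("FASTA file not found: %s", path)
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))  # id = header up to whitespace
  out <- do.call(rbind, lapply(seq_along(seqs), function(i) {
    hits <- scan_iupac(as.character(seqs[[i]]), motif, strands)
    if (!nrow(hits)) return(NULL)
    data.frame(seq_id = names(seqs)[i], hits, stringsAsFactors = FALSE)
  }))
  if (is.null(out))
    out <- data.frame(seq_id = character(), start = integer(),
                      strand = character(), match = character(),
                      motif = character(), stringsAsFactors = FALSE)
  if (!is.null(tss_offset)) {
    assert_scalar_number(tss_offset, "tss_offset")
    out$tss_relative_start <- out$start - tss_offset
  }
  out
}
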