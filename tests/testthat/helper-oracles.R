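# Independent brute-force oracles and small fixture builders.  Each oracle
# deliberately recomputes the quantity from first principles, without
# touching the implementation path it checks.

# product-limit estimate evaluated at the sorted unique observed times
oracle_km <- function(time, event) {
  event <- as.logical(event)
  times <- sort(unique(time))
  s <- 1
  out <- data.frame(time = times, surv = NA_real_)
  for (i in seq_along(times)) {
    t <- times[i]
    n_risk <- sum(time >= t)           # deaths processed before censorings
    d <- sum(time == t & event)
    if (d > 0) s <- s * (1 - d / n_risk)
    out$surv[i] <- s
  }
  out
}

oracle_pearson <- function(x, y) {
  xm <- x - mean(x); ym <- y - mean(y)
  sum(xm * ym) / sqrt(sum(xm^2) * sum(ym^2))
}

oracle_bh <- function(p) {
  n <- length(p)
  ord <- order(p, decreasing = TRUE)
  adj <- numeric(n)
  running_min <- 1
  for (i in seq_along(ord)) {
    rank <- n - i + 1
    running_min <- min(running_min, p[ord[i]] * n / rank)
    adj[ord[i]] <- running_min
  }
  pmin(adj, 1)
}

oracle_fisher_rz <- function(r1, n1, r2, n2) {
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z = z, p = 2 * pnorm(-abs(z)))
}

# argmax-homology orthologue resolution by explicit grouping
oracle_resolve <- function(orth, genes, direction = "human2mouse") {
  from <- if (direction == "human2mouse") "human_gene" else "mouse_gene"
  to <- if (direction == "human2mouse") "mouse_gene" else "human_gene"
  mapping <- character(); unmapped <- character()
  for (g in genes) {
    rows <- orth[orth[[from]] == g, , drop = FALSE]
    if (!nrow(rows)) { unmapped <- c(unmapped, g); next }
    best <- rows[rows$homology_pct == max(rows$homology_pct), , drop = FALSE]
    mapping[[g]] <- sort(best[[to]])[1L]
  }
  list(mapping = mapping, unmapped = unmapped)
}

# top-N selection by explicit filter + sort + slice
oracle_top_n <- function(de, n, lfc, direction) {
  keep <- switch(direction,
                 up = de$logFC > lfc,
                 down = de$logFC < -lfc,
                 both = abs(de$logFC) > lfc)
  cand <- de[keep, , drop = FALSE]
  cand <- cand[order(cand$padj, -abs(cand$logFC), cand$gene), , drop = FALSE]
  head(cand$gene, n)
}

IUPAC_SETS <- list(A = "A", C = "C", G = "G", T = "T",
                   R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                   W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                   B = c("C", "G", "T"), D = c("A", "G", "T"),
                   H = c("A", "C", "T"), V = c("A", "C", "G"),
                   N = c("A", "C", "G", "T"))

oracle_revcomp <- function(s) {
  comp <- chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", s)
  paste(rev(strsplit(comp, "")[[1L]]), collapse = "")
}

# sliding-window IUPAC match; sequence N never matches any pattern code
oracle_motif_scan <- function(sequence, motif) {
  sequence <- toupper(sequence)
  match_at <- function(pat, pos) {
    pc <- strsplit(pat, "")[[1L]]
    sc <- strsplit(substr(sequence, pos, pos + nchar(pat) - 1L), "")[[1L]]
    all(mapply(function(p, s) s %in% IUPAC_SETS[[p]], pc, sc))
  }
  hits <- list()
  for (pat in c(motif, oracle_revcomp(motif))) {
    strand <- if (pat == motif) "+" else "-"
    for (pos in seq_len(nchar(sequence) - nchar(pat) + 1L)) {
      if (match_at(pat, pos))
        hits[[length(hits) + 1L]] <- data.frame(
          start = pos, strand = strand,
          match = substr(sequence, pos, pos + nchar(pat) - 1L),
          stringsAsFactors = FALSE)
    }
  }
  # a palindromic-equivalent pattern can hit both strands at one position
  out <- do.call(rbind, hits)
  if (is.null(out)) return(data.frame(start = integer(), strand = character(),
                                      match = character()))
  out <- unique(out)
  out[order(out$start, out$strand), , drop = FALSE]
}

# --- fixture builders -------------------------------------------------------

rand_de <- function(n, seed = 1L, lfc_sd = 1.5) {
  withr::with_seed(seed, {
    p <- runif(n)^2
    data.frame(gene = sprintf("g%04d", sample(n)),
               logFC = rnorm(n, sd = lfc_sd),
               pvalue = p, padj = p.adjust(p, "BH"),
               stringsAsFactors = FALSE)
  })
}

rand_expr <- function(n_genes, n_samples, seed = 1L) {
  withr::with_seed(seed, {
    matrix(rnorm(n_genes * n_samples, mean = 6),
           nrow = n_genes,
           dimnames = list(sprintf("g%04d", seq_len(n_genes)),
                           sprintf("s%03d", seq_len(n_samples))))
  })
}

rand_orthology <- function(n, seed = 1L, frac_multi = 0.3,
                           with_ties = TRUE) {
  withr::with_seed(seed, {
    human <- sprintf("H%04d", seq_len(n))
    rows <- lapply(human, function(h) {
      k <- if (runif(1) < frac_multi) sample(2:4, 1L) else 1L
      hom <- round(runif(k, 0, 100), if (with_ties) 0 else 1)
      data.frame(human_gene = h,
                 mouse_gene = paste0("m", h, "_", seq_len(k)),
                 homology_pct = hom, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

# small synthetic per-subtype DE tables with a guaranteed number of
# strongly up-regulated, significant genes per subtype (disjoint blocks)
synthetic_subtype_de <- function(n_subtypes, n_strong = 90, n_noise = 200,
                                 seed = 1L) {
  withr::with_seed(seed, {
    out <- list()
    for (i in seq_len(n_subtypes)) {
      strong <- data.frame(
        gene = sprintf("ST%d_up%03d", i, seq_len(n_strong)),
        logFC = runif(n_strong, 1.0, 3.0),
        pvalue = 10^-runif(n_strong, 8, 20),
        stringsAsFactors = FALSE)
      noise <- data.frame(
        gene = sprintf("noise%04d", seq_len(n_noise)),
        logFC = rnorm(n_noise, sd = 0.3),
        pvalue = runif(n_noise),
        stringsAsFactors = FALSE)
      de <- rbind(strong, noise)
      de$padj <- p.adjust(de$pvalue, "BH")
      out[[paste0("SUB", i)]] <- de
    }
    out
  })
}
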