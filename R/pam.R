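#' Summarise upstream PAMs of protospacer hits
#'
#' Filters to uniquely placed hits with read support of at least
#' `min_reads`, tallies the k-mer immediately 5' of each protospacer,
#' and computes a position frequency matrix (PFM), per-position consensus
#' (argmax, lexicographic tie-break), the modal whole-k-mer fraction, and
#' per-position information content `info_bits[j] = 2 - H_j` where `H_j`
#' is the Shannon entropy (log2) of PFM column `j` — no small-sample
#' correction.
#'
#' Two weightings are available: `per_spacer` (each unique spacer counts
#' once; the default, since read support conflates amplification with
#' acquisition frequency) and `per_read` (weighted by read support).
#'
#' @param hits data.frame of hits with `pam`, `unique`, `reads`.
#' @param min_reads minimum read support (default 10).
#' @param weighting `"per_spacer"` or `"per_read"`.
#' @param k PAM length in nt (default 3).
#' @return an object of class `PamSummary`; with zero contributing hits,
#'   an empty-summary sentinel with `n = 0`.
#' @export
summarize_pams <- function(hits, min_reads = 10L,
                           weighting = c("per_spacer", "per_read"),
                           k = 3L) {
  weighting <- match.arg(weighting)
  keep <- rep(TRUE, nrow(hits))
  if ("unique" %in% names(hits)) keep <- keep & hits$unique
  if ("reads" %in% names(hits)) keep <- keep & hits$reads >= min_reads
  keep <- keep & !is.na(hits$pam) & nchar(hits$pam) == k &
    !grepl("[^ACGT]", hits$pam)
  h <- hits[keep, , drop = FALSE]
  if (!nrow(h)) {
    return(structure(list(k = k, n = 0L, counts = numeric(0),
                          pfm = matrix(NA_real_, 4, k,
                                       dimnames = list(DNA_BASES, NULL)),
                          consensus = NA_character_,
                          modal_kmer = NA_character_,
                          modal_fraction = NA_real_, modal_tie = FALSE,
                          info_bits = rep(NA_real_, k),
                          weighting = weighting, min_reads = min_reads),
                     class = "PamSummary"))
  }
  w <- if (weighting == "per_read") as.numeric(h$reads)
       else rep(1, nrow(h))
  counts <- tapply(w, h$pam, sum)
  counts <- counts[order(-counts, names(counts))]
  total <- sum(counts)

  pfm <- matrix(0, 4, k, dimnames = list(DNA_BASES, NULL))
  chars <- do.call(rbind, strsplit(h$pam, "", fixed = TRUE))
  for (j in seq_len(k))
    pfm[, j] <- vapply(DNA_BASES,
                       function(b) sum(w[chars[, j] == b]), numeric(1))
  pfm <- sweep(pfm, 2, colSums(pfm), "/")
  consensus <- paste(DNA_BASES[apply(pfm, 2, which.max)], collapse = "")
  info_bits <- apply(pfm, 2, function(p) {
    p <- p[p > 0]
    2 + sum(p * log2(p))
  })
  modal <- names(counts)[1]
  tie <- sum(counts == counts[[1]]) > 1
  structure(list(k = k, n = as.integer(sum(h$pam != "")),
                 counts = counts, pfm = pfm, consensus = consensus,
                 modal_kmer = modal,
                 modal_fraction = as.numeric(counts[[1]] / total),
                 modal_tie = tie, info_bits = as.numeric(info_bits),
                 weighting = weighting, min_reads = min_reads),
            class = "PamSummary")
}

#' @export
print.PamSummary <- function(x, ...) {
  if (x$n == 0) {
    cat("PamSummary: no contributing hits\n")
    return(invisible(x))
  }
  cat("PamSummary (", x$weighting, ", min_reads=", x$min_reads, "): ",
      x$n, " hits\n", sep = "")
  cat("  consensus ", x$consensus, "; modal ", x$modal_kmer, " at ",
      sprintf("%.1f%%", 100 * x$modal_fraction),
      if (x$modal_tie) " (tied)" else "", "\n", sep = "")
  cat("  info (bits):", sprintf("%.2f", x$info_bits), "\n")
  invisible(x)
}

#' Write a PAM summary (counts and PFM) as TSV
#'
#' The PFM file has rows A, C, G, T — directly usable as a logo matrix.
#'
#' @param pam a `PamSummary`.
#' @param counts_path path for the k-mer counts TSV.
#' @param pfm_path optional path for the 4 x k PFM TSV.
#' @return `counts_path`, invisibly.
#' @export
write_pam_summary <- function(pam, counts_path, pfm_path = NULL) {
  df <- data.frame(pam = names(pam$counts), count = as.numeric(pam$counts),
                   stringsAsFactors = FALSE)
  write.table(df, counts_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(pfm_path)) {
    m <- as.data.frame(pam$pfm)
    names(m) <- paste0("pos", seq_len(ncol(m)))
    write.table(cbind(base = rownames(pam$pfm), m), pfm_path, sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(counts_path)
}
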