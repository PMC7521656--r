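DNA_BASES <- c("A", "C", "G", "T")

#' Random DNA sequence with a given GC content
#'
#' Bases are drawn i.i.d. with P(G) = P(C) = gc/2 and P(A) = P(T) =
#' (1 - gc)/2, the simplest model of a GC-rich replicon.
#'
#' @param n sequence length in nt.
#' @param gc target GC fraction in `[0, 1]`.
#' @return a single character string of length `n`.
#' @export
random_dna <- function(n, gc = 0.5) {
  stopifnot(n >= 0, gc >= 0, gc <= 1)
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

#' Realised GC fraction of a DNA string
#' @param x a single DNA string.
#' @return numeric GC fraction.
#' @export
gc_fraction <- function(x) {
  b <- strsplit(x, "", fixed = TRUE)[[1]]
  mean(b %in% c("G", "C"))
}

# Extract [start, end) (0-based half-open) from a replicon sequence,
# wrapping past the end when `circular`. `strand` "-" returns the reverse
# complement, i.e. the sequence as read off the minus strand.
extract_interval <- function(seq, start, end, strand = "+", circular = FALSE) {
  L <- nchar(seq, type = "bytes")  # sequences are ASCII; O(1)
  stopifnot(end > start, end - start <= L)
  if (end <= L && start >= 0) {
    s <- substr(seq, start + 1, end)
  } else if (circular) {
    idx <- (seq.int(start, end - 1L) %% L) + 1
    s <- paste(strsplit(seq, "", fixed = TRUE)[[1]][idx], collapse = "")
  } else {
    stop("interval [", start, ",", end, ") outside linear replicon of length ", L)
  }
  if (strand == "-") s <- revcomp(s)
  s
}

# 3-nt motif immediately 5' of a protospacer on its own strand:
# for "+" hits the genomic triplet just before `start`, for "-" hits the
# reverse complement of the triplet just after `end`.
upstream_pam <- function(seq, start, end, strand, circular = FALSE, k = 3L) {
  L <- nchar(seq, type = "bytes")
  if (strand == "+") {
    if (start - k >= 0) {
      extract_interval(seq, start - k, start, "+", circular)
    } else if (circular) {
      extract_interval(seq, start - k + L, start + L, "+", circular)
    } else {
      NA_character_
    }
  } else {
    if (end + k <= L || circular) {
      revcomp(extract_interval(seq, end, end + k, "+", circular))
    } else {
      NA_character_
    }
  }
}
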