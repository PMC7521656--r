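#' Simulate amplicon reads of an expanded CRISPR locus
#'
#' Each read is `adapter + k random bases + leader anchor + (repeat +
#' novel spacer) x m + repeat + endogenous-spacer anchor`, with `k`
#' uniform in `config$random_prefix_range` and `m = 2` with probability
#' `config$double_insertion_fraction` (the second, array-distal unit
#' carries another planted spacer drawn uniformly from the truth table).
#' Substitution errors are applied i.i.d. at `config$error_rate`; a
#' configurable fraction of reads is emitted reverse-complemented.
#' The number of reads per planted spacer is `truth$reads`. Randomness is
#' seeded with `config$seed + 2`.
#'
#' @param locus a `CrisprLocus`.
#' @param truth a `TruthTable` from [sample_prespacers()].
#' @param design an [amplicon_design()].
#' @param config a [simulation_config()].
#' @return a list with `reads` (data.frame `read_id`, `seq`) and `labels`
#'   (per-read truth: planted spacer id(s), unit count, orientation,
#'   random-prefix length, and the error-free construct `clean_seq`).
#' @export
simulate_amplicon_reads <- function(locus, truth, design, config) {
  stopifnot(inherits(locus, "CrisprLocus"), inherits(design, "AmpliconDesign"),
            nrow(truth) >= 1)
  validate_simulation_config(config)
  set.seed(config$seed + 2L)

  idx <- rep(seq_len(nrow(truth)), truth$reads)
  N <- length(idx)
  if (N == 0)
    stop("truth table has zero planted reads; set config$n_reads > 0")
  idx <- sample(idx)  # interleave spacers across the file

  m <- 1L + rbinom(N, 1L, config$double_insertion_fraction)
  partner <- sample.int(nrow(truth), N, replace = TRUE)
  k <- sample(seq(config$random_prefix_range[1],
                  config$random_prefix_range[2]),
              N, replace = TRUE)
  prefix <- vapply(k, function(n) if (n == 0) "" else random_dna(n, 0.5),
                   character(1))

  rep_seq <- locus$repeat_seq
  units <- ifelse(m == 1L,
                  paste0(rep_seq, truth$seq[idx]),
                  paste0(rep_seq, truth$seq[idx], rep_seq,
                         truth$seq[partner]))
  construct <- paste0(design$adapter, prefix, design$forward_anchor,
                      units, rep_seq, design$reverse_anchor)

  if (!is.null(config$read_length)) {
    too_long <- nchar(construct) > config$read_length
    if (any(too_long))
      stop("read_length (", config$read_length, ") shorter than ",
           sum(too_long), " amplicon construct(s); longest is ",
           max(nchar(construct)), " nt")
  }

  rc <- runif(N) < config$revcomp_fraction
  oriented <- construct
  if (any(rc)) oriented[rc] <- revcomp(construct[rc])
  seqs <- apply_substitutions(oriented, config$error_rate)

  read_id <- sprintf("read%07d", seq_len(N))
  list(reads = data.frame(read_id = read_id, seq = seqs,
                          stringsAsFactors = FALSE),
       labels = data.frame(read_id = read_id,
                           spacer_id = truth$spacer_id[idx],
                           spacer_id2 = ifelse(m == 2L,
                                               truth$spacer_id[partner],
                                               NA_character_),
                           n_units = m,
                           orient = ifelse(rc, "-", "+"),
                           prefix_len = k,
                           clean_seq = construct,
                           stringsAsFactors = FALSE))
}

# i.i.d. substitution errors at per-base rate `rate`; substituted bases are
# drawn uniformly from the three alternatives.
apply_substitutions <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  n_err <- rbinom(length(seqs), nchar(seqs), rate)
  for (i in which(n_err > 0)) {
    b <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    pos <- sample.int(length(b), n_err[i])
    for (p in pos) b[p] <- sample(setdiff(DNA_BASES, b[p]), 1)
    seqs[i] <- paste(b, collapse = "")
  }
  seqs
}

#' Write reads to FASTQ (constant quality "I")
#' @param reads data.frame with `read_id` and `seq`.
#' @param path output path (".gz" suffix compresses).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  dna <- Biostrings::DNAStringSet(setNames(reads$seq, reads$read_id))
  qual <- Biostrings::PhredQuality(
    Biostrings::BStringSet(strrep("I", nchar(reads$seq))))
  qdna <- Biostrings::QualityScaledDNAStringSet(dna, qual)
  Biostrings::writeQualityScaledXStringSet(
    qdna, path, compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Read a FASTQ file into a reads data.frame
#' @param path FASTQ path (gzip allowed).
#' @return data.frame with `read_id` and `seq`.
#' @export
read_fastq <- function(path) {
  dna <- Biostrings::readDNAStringSet(path, format = "fastq")
  data.frame(read_id = sub("\\s.*$", "", names(dna)),
             seq = as.character(dna), stringsAsFactors = FALSE)
}
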