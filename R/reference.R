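#' Construct a multi-replicon reference genome object
#'
#' Container for replicon sequences plus annotated feature intervals.
#' Coordinates are 0-based half-open throughout; a feature's `strand`
#' records, for `target_site`, the coding strand of the targeted gene.
#'
#' @param replicons named character vector of replicon sequences (ACGT).
#' @param circular logical vector (recycled) marking circular replicons.
#' @param features data.frame with columns `replicon`, `start`, `end`,
#'   `strand`, `kind`, `label`; `kind` is one of `transposase`, `rRNA`,
#'   `provirus`, `target_site`, `hen_site`, `plasmid_marker`.
#' @return an object of class `ReferenceGenome`.
#' @export
reference_genome <- function(replicons, circular = FALSE,
                             features = empty_features()) {
  stopifnot(is.character(replicons), !is.null(names(replicons)),
            all(nzchar(names(replicons))))
  circular <- rep_len(as.logical(circular), length(replicons))
  names(circular) <- names(replicons)
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  ref <- structure(list(replicons = replicons, circular = circular,
                        features = features),
                   class = "ReferenceGenome")
  validate_reference(ref)
  ref
}

empty_features <- function() {
  data.frame(replicon = character(), start = integer(), end = integer(),
             strand = character(), kind = character(), label = character(),
             stringsAsFactors = FALSE)
}

FEATURE_KINDS <- c("transposase", "rRNA", "provirus", "target_site",
                   "hen_site", "plasmid_marker")
HOTSPOT_KINDS <- c("transposase", "rRNA", "provirus")

validate_reference <- function(ref) {
  ok_alpha <- vapply(ref$replicons,
                     function(s) !grepl("[^ACGT]", s), logical(1))
  if (!all(ok_alpha)) stop("replicon sequences must be over {A,C,G,T}")
  f <- ref$features
  if (nrow(f)) {
    if (!all(f$kind %in% FEATURE_KINDS))
      stop("unknown feature kind(s): ",
           paste(setdiff(f$kind, FEATURE_KINDS), collapse = ", "))
    if (!all(f$replicon %in% names(ref$replicons)))
      stop("feature on unknown replicon")
    L <- replicon_lengths(ref)[f$replicon]
    if (any(f$start < 0 | f$end > L | f$start >= f$end))
      stop("feature intervals must lie within [0, replicon length)")
    if (sum(f$kind == "target_site") > 1)
      stop("at most one target_site feature is supported")
  }
  invisible(ref)
}

#' Replicon lengths of a reference genome
#' @param ref a `ReferenceGenome`.
#' @return named integer vector of lengths in nt.
#' @export
replicon_lengths <- function(ref) {
  vapply(ref$replicons, nchar, integer(1), type = "bytes")
}

#' @export
print.ReferenceGenome <- function(x, ...) {
  L <- replicon_lengths(x)
  cat("ReferenceGenome:", length(L), "replicon(s),",
      format(sum(L), big.mark = ","), "nt total\n")
  for (nm in names(L))
    cat(sprintf("  %-12s %8d nt  %s\n", nm, L[[nm]],
                if (x$circular[[nm]]) "circular" else "linear"))
  if (nrow(x$features))
    cat("  features:", paste(sprintf("%s (%d)", names(table(x$features$kind)),
                                     table(x$features$kind)),
                             collapse = ", "), "\n")
  invisible(x)
}

# Coordinate of the target cut site: the 5' boundary of the target_site
# feature on the declared coding strand.
target_cut_site <- function(ref) {
  f <- ref$features[ref$features$kind == "target_site", , drop = FALSE]
  if (nrow(f) != 1) return(NULL)
  list(replicon = f$replicon[1],
       coord = if (f$strand[1] == "+") f$start[1] else f$end[1],
       coding_strand = f$strand[1])
}

#' Generate a synthetic multi-replicon reference genome
#'
#' Emulates a GC-rich archaeal host: one main chromosome plus one or more
#' smaller plasmids, with non-overlapping hotspot features (transposases,
#' rRNA operon, an integrated provirus) and, when configured, a
#' self-targeting protospacer site on the chromosome and a
#' homing-endonuclease (HEN) cut site on the first plasmid. Deterministic
#' under `config$seed`.
#'
#' @param config a [simulation_config()].
#' @return a `ReferenceGenome`.
#' @export
make_reference <- function(config) {
  validate_simulation_config(config)
  set.seed(config$seed)
  lens <- c(chromosome = config$chromosome_length)
  if (length(config$plasmid_lengths))
    lens <- c(lens, setNames(config$plasmid_lengths,
                             paste0("plasmid", seq_along(config$plasmid_lengths))))
  seqs <- vapply(lens, random_dna, character(1), gc = config$gc)

  want <- data.frame(replicon = character(), len = integer(),
                     kind = character(), label = character(),
                     strand = character(), stringsAsFactors = FALSE)
  add <- function(want, replicon, len, kind, label, strand = "+") {
    rbind(want, data.frame(replicon = replicon, len = as.integer(len),
                           kind = kind, label = label, strand = strand,
                           stringsAsFactors = FALSE))
  }
  fl <- config$feature_lengths
  if (config$n_transposase > 0)
    for (i in seq_len(config$n_transposase))
      want <- add(want, "chromosome", fl[["transposase"]], "transposase",
                  paste0("ISH-", i), sample(c("+", "-"), 1))
  if (config$n_rrna > 0)
    for (i in seq_len(config$n_rrna))
      want <- add(want, "chromosome", fl[["rRNA"]], "rRNA",
                  paste0("rrn-", i))
  if (config$n_provirus > 0)
    for (i in seq_len(config$n_provirus))
      want <- add(want, "chromosome", fl[["provirus"]], "provirus",
                  paste0("orc-provirus-", i))
  if (config$target_site)
    want <- add(want, "chromosome", config$target_length, "target_site",
                "crtI-target", config$target_strand)
  if (config$hen_site) {
    if (!length(config$plasmid_lengths))
      stop("hen_site requires at least one plasmid replicon")
    want <- add(want, "plasmid1", config$hen_length, "hen_site", "HEN-site")
  }

  features <- empty_features()
  margin <- 100L  # keep features away from linear ends and each other
  for (i in seq_len(nrow(want))) {
    w <- want[i, ]
    L <- lens[[w$replicon]]
    if (L < w$len + 2 * margin)
      stop("replicon ", w$replicon, " (", L,
           " nt) too small to hold feature ", w$label, " (", w$len, " nt)")
    placed <- FALSE
    existing <- features[features$replicon == w$replicon, , drop = FALSE]
    for (try in 1:1000) {
      s <- sample.int(L - w$len - 2L * margin, 1L) + margin
      if (!nrow(existing) ||
          all(s + w$len + margin <= existing$start |
              s >= existing$end + margin)) {
        features <- rbind(features,
                          data.frame(replicon = w$replicon, start = s,
                                     end = s + w$len, strand = w$strand,
                                     kind = w$kind, label = w$label,
                                     stringsAsFactors = FALSE))
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("could not place feature ", w$label, " without overlap; ",
           "replicon too crowded")
  }
  features <- features[order(features$replicon, features$start), ]
  rownames(features) <- NULL
  reference_genome(seqs, circular = config$circular, features = features)
}

#' Write a reference genome to FASTA (and features to BED6)
#'
#' @param ref a `ReferenceGenome`.
#' @param fasta path for the FASTA file.
#' @param bed optional path for a BED6 file of the features
#'   (`name` = `kind:label`, `score` = 0).
#' @return `fasta`, invisibly.
#' @export
write_reference <- function(ref, fasta, bed = NULL) {
  dna <- Biostrings::DNAStringSet(ref$replicons)
  Biostrings::writeXStringSet(dna, fasta)
  if (!is.null(bed)) write_features_bed(ref$features, bed)
  invisible(fasta)
}

write_features_bed <- function(features, path) {
  if (!nrow(features)) {
    file.create(path)
    return(invisible(path))
  }
  bed <- data.frame(chrom = features$replicon, start = features$start,
                    end = features$end,
                    name = paste0(features$kind, ":", features$label),
                    score = 0L, strand = features$strand)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a reference genome from FASTA (+ optional BED6 features)
#'
#' @param fasta FASTA path.
#' @param bed optional BED6 path as written by [write_reference()].
#' @param circular logical, recycled over replicons.
#' @return a `ReferenceGenome`.
#' @export
read_reference <- function(fasta, bed = NULL, circular = FALSE) {
  dna <- Biostrings::readDNAStringSet(fasta)
  seqs <- setNames(as.character(dna), sub("\\s.*$", "", names(dna)))
  features <- empty_features()
  if (!is.null(bed) && file.exists(bed) && file.size(bed) > 0) {
    b <- read.table(bed, sep = "\t", stringsAsFactors = FALSE)
    kind_label <- strsplit(b$V4, ":", fixed = TRUE)
    features <- data.frame(replicon = b$V1, start = b$V2, end = b$V3,
                           strand = b$V6,
                           kind = vapply(kind_label, `[`, "", 1),
                           label = vapply(kind_label, function(x)
                             paste(x[-1], collapse = ":"), ""),
                           stringsAsFactors = FALSE)
  }
  reference_genome(seqs, circular = circular, features = features)
}
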