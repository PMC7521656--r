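#' Describe a CRISPR locus
#'
#' A locus is a leader followed by alternating repeats and spacers; new
#' spacers are inserted at the leader-proximal end. Handle lengths are
#' informational constants of crRNA maturation in this subtype (8-nt 5'
#' handle, 22-nt 3' handle) and are not used by the parser.
#'
#' @param locus_id short identifier (e.g. "P1", "P2", "C").
#' @param leader leader sequence (5' of the first repeat).
#' @param repeat_seq the direct-repeat sequence.
#' @param spacers character vector of endogenous spacers, leader-proximal
#'   first.
#' @param five_prime_handle_len,three_prime_handle_len crRNA handle
#'   lengths in nt.
#' @return an object of class `CrisprLocus`.
#' @export
crispr_locus <- function(locus_id, leader, repeat_seq, spacers,
                         five_prime_handle_len = 8L,
                         three_prime_handle_len = 22L) {
  stopifnot(nzchar(locus_id), nchar(leader) > 0, nchar(repeat_seq) > 0,
            length(spacers) >= 1, all(nchar(spacers) > 0))
  if (nchar(repeat_seq) < five_prime_handle_len)
    stop("repeat shorter than the 5' handle length")
  structure(list(locus_id = locus_id, leader = leader,
                 repeat_seq = repeat_seq, spacers = as.character(spacers),
                 five_prime_handle_len = as.integer(five_prime_handle_len),
                 three_prime_handle_len = as.integer(three_prime_handle_len)),
            class = "CrisprLocus")
}

#' @export
print.CrisprLocus <- function(x, ...) {
  cat("CrisprLocus ", x$locus_id, ": leader ", nchar(x$leader),
      " nt, repeat ", nchar(x$repeat_seq), " nt, ",
      length(x$spacers), " endogenous spacer(s)\n", sep = "")
  invisible(x)
}

#' Generate a random CRISPR locus
#'
#' Sequences of the real leader, repeat and spacers are locus-specific;
#' the generator synthesises a random 30-nt repeat, 120-nt leader and
#' endogenous spacers per seed. All downstream code is sequence-agnostic.
#'
#' @param seed integer seed.
#' @param locus_id identifier (default "P1").
#' @param n_spacers number of endogenous spacers.
#' @param repeat_len,leader_len lengths in nt.
#' @param spacer_length_range inclusive spacer length bounds.
#' @param gc GC fraction for the synthesised sequences.
#' @return a `CrisprLocus`.
#' @export
make_locus <- function(seed = 1L, locus_id = "P1", n_spacers = 4L,
                       repeat_len = 30L, leader_len = 120L,
                       spacer_length_range = c(34L, 39L), gc = 0.5) {
  set.seed(seed + 10L)
  leader <- random_dna(leader_len, gc)
  repeat_seq <- random_dna(repeat_len, gc)
  lens <- sample(seq(spacer_length_range[1], spacer_length_range[2]),
                 n_spacers, replace = TRUE)
  spacers <- vapply(lens, random_dna, character(1), gc = gc)
  crispr_locus(locus_id, leader, repeat_seq, spacers)
}

#' Describe the amplicon/primer scheme of an acquisition assay
#'
#' The sequenced amplicon is: adapter, 0-3 random bases, a forward primer
#' anchored at the 3' end of the leader, the (possibly expanded) array,
#' ending inside an endogenous spacer where the reverse primer binds.
#'
#' @param locus a `CrisprLocus`.
#' @param adapter adapter sequence preceding the random bases.
#' @param anchor_len length of the leader / endogenous-spacer anchors.
#' @param anchor_spacer index of the endogenous spacer the reverse primer
#'   binds (default 1, the leader-proximal spacer).
#' @param anchor_max_mismatches,repeat_max_mismatches Hamming budgets for
#'   anchor and repeat matching.
#' @return an object of class `AmpliconDesign`.
#' @export
amplicon_design <- function(locus, adapter = "TCGTCGGCAGCGTC",
                            anchor_len = 20L, anchor_spacer = 1L,
                            anchor_max_mismatches = 2L,
                            repeat_max_mismatches = 3L) {
  stopifnot(inherits(locus, "CrisprLocus"),
            anchor_len <= nchar(locus$leader),
            anchor_spacer <= length(locus$spacers),
            anchor_len <= nchar(locus$spacers[anchor_spacer]),
            anchor_max_mismatches >= 0, repeat_max_mismatches >= 0)
  ll <- nchar(locus$leader)
  structure(list(locus_id = locus$locus_id,
                 adapter = adapter,
                 forward_anchor = substr(locus$leader, ll - anchor_len + 1L, ll),
                 reverse_anchor = substr(locus$spacers[anchor_spacer], 1L,
                                         anchor_len),
                 anchor_spacer = as.integer(anchor_spacer),
                 anchor_max_mismatches = as.integer(anchor_max_mismatches),
                 repeat_max_mismatches = as.integer(repeat_max_mismatches)),
            class = "AmpliconDesign")
}

#' Write / read a locus description as YAML
#'
#' @param locus a `CrisprLocus`.
#' @param path file path.
#' @return `path` (write) or a `CrisprLocus` (read).
#' @export
write_locus <- function(locus, path) {
  yaml::write_yaml(unclass(locus), path)
  invisible(path)
}

#' @rdname write_locus
#' @export
read_locus <- function(path) {
  x <- yaml::read_yaml(path)
  crispr_locus(x$locus_id, x$leader, x$repeat_seq, unlist(x$spacers),
               x$five_prime_handle_len %||% 8L,
               x$three_prime_handle_len %||% 22L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
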