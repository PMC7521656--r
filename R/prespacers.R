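#' Plant prespacer acquisition events on a reference genome
#'
#' Draws `config$n_prespacers` protospacer origins from a three-component
#' mixture emulating targeting-induced acquisition:
#'
#' * **target** (weight `w_target`): offset from the target cut site by a
#'   geometric decay (`target_decay_scale`), with the strand assigned by
#'   the configured rule (default: upstream of the cut from the coding
#'   strand, downstream from the template strand);
#' * **hotspot** (`w_hotspot`): uniform within a randomly chosen hotspot
#'   feature (transposase, rRNA or provirus), either strand;
#' * **background** (`w_background`): uniform genome-wide, either strand.
#'
#' With probability `pam_modal_fraction` a draw is constrained (by
#' rejection sampling over positions indexed by upstream trinucleotide) so
#' that the 3 nt 5' of the protospacer, on the protospacer strand, equal
#' `pam_modal_motif`; otherwise the upstream trinucleotide is left
#' unconstrained. The reference sequence itself is never rewritten.
#'
#' Planted read counts allocate `config$n_reads` over the events by a
#' uniform multinomial. Randomness is seeded with `config$seed + 1`.
#'
#' @param ref a `ReferenceGenome`.
#' @param config a [simulation_config()].
#' @return a `TruthTable` data.frame with columns `spacer_id`, `seq`,
#'   `replicon`, `start`, `end`, `strand`, `component`, `pam`, `reads`.
#' @export
sample_prespacers <- function(ref, config) {
  validate_simulation_config(config)
  set.seed(config$seed + 1L)
  n <- config$n_prespacers
  stopifnot(n >= 1)
  L <- replicon_lengths(ref)
  cut <- target_cut_site(ref)
  if (config$w_target > 0 && is.null(cut))
    stop("w_target > 0 but the reference has no target_site feature")
  hot <- ref$features[ref$features$kind %in% HOTSPOT_KINDS, , drop = FALSE]
  if (config$w_hotspot > 0 && !nrow(hot))
    stop("w_hotspot > 0 but the reference has no hotspot features")

  motif <- config$pam_modal_motif
  # candidate protospacer anchors whose upstream trinucleotide equals the
  # modal motif: "+" candidates are starts, "-" candidates are ends
  cand <- do.call(rbind, lapply(names(ref$replicons), function(nm) {
    s <- ref$replicons[[nm]]
    plus <- find_matches_cpp(s, motif, 0L)$pos + 3L
    minus <- find_matches_cpp(s, revcomp(motif), 0L)$pos
    rbind(data.frame(replicon = nm, anchor = plus, strand = "+"),
          data.frame(replicon = nm, anchor = minus, strand = "-"))
  }))

  comp <- sample(c("target", "hotspot", "background"), n, replace = TRUE,
                 prob = c(config$w_target, config$w_hotspot,
                          config$w_background))
  lens <- sample(seq(config$spacer_length_range[1],
                     config$spacer_length_range[2]),
                 n, replace = TRUE)
  want_modal <- runif(n) < config$pam_modal_fraction
  flip <- function(s) if (s == "+") "-" else "+"
  strand_for <- function(rule, coding) if (rule == "coding") coding else flip(coding)

  draw_target <- function(len) {
    Lr <- L[[cut$replicon]]
    p <- min(1, 1 / config$target_decay_scale)
    for (try in 1:10000) {
      offset <- rgeom(1, p)
      if (runif(1) < 0.5) {  # upstream of the cut on the coding strand
        if (cut$coding_strand == "+") {
          e <- cut$coord - offset; s <- e - len
        } else {
          s <- cut$coord + offset; e <- s + len
        }
        strand <- strand_for(config$upstream_strand, cut$coding_strand)
      } else {               # downstream
        if (cut$coding_strand == "+") {
          s <- cut$coord + offset; e <- s + len
        } else {
          e <- cut$coord - offset; s <- e - len
        }
        strand <- strand_for(config$downstream_strand, cut$coding_strand)
      }
      if (s >= 0 && e <= Lr)
        return(list(replicon = cut$replicon, start = s, end = e,
                    strand = strand))
    }
    stop("could not place a target-proximal prespacer inside the replicon")
  }

  draw_hotspot <- function(len, modal) {
    f <- hot[sample.int(nrow(hot), 1L), ]
    if (modal) {
      ok <- cand[cand$replicon == f$replicon &
                 ((cand$strand == "+" & cand$anchor >= f$start &
                   cand$anchor + len <= f$end) |
                  (cand$strand == "-" & cand$anchor <= f$end &
                   cand$anchor - len >= f$start)), , drop = FALSE]
      if (!nrow(ok))
        stop("no position with upstream ", motif, " available in hotspot ",
             f$label, " for a ", len, "-nt prespacer")
      row <- ok[sample.int(nrow(ok), 1L), ]
      if (row$strand == "+")
        list(replicon = row$replicon, start = row$anchor,
             end = row$anchor + len, strand = "+")
      else
        list(replicon = row$replicon, start = row$anchor - len,
             end = row$anchor, strand = "-")
    } else {
      s <- f$start + sample.int(f$end - f$start - len + 1L, 1L) - 1L
      list(replicon = f$replicon, start = s, end = s + len,
           strand = sample(c("+", "-"), 1L))
    }
  }

  draw_background <- function(len, modal) {
    if (modal) {
      ok <- cand[(cand$strand == "+" &
                  cand$anchor + len <= L[cand$replicon]) |
                 (cand$strand == "-" & cand$anchor - len >= 0), ,
                 drop = FALSE]
      if (!nrow(ok))
        stop("no genome position with upstream ", motif,
             " available for a ", len, "-nt prespacer")
      row <- ok[sample.int(nrow(ok), 1L), ]
      if (row$strand == "+")
        list(replicon = row$replicon, start = row$anchor,
             end = row$anchor + len, strand = "+")
      else
        list(replicon = row$replicon, start = row$anchor - len,
             end = row$anchor, strand = "-")
    } else {
      nm <- sample(names(L), 1L, prob = L)
      s <- sample.int(L[[nm]] - len + 1L, 1L) - 1L
      list(replicon = nm, start = s, end = s + len,
           strand = sample(c("+", "-"), 1L))
    }
  }

  out_replicon <- character(n); out_start <- integer(n)
  out_end <- integer(n); out_strand <- character(n)
  out_seq <- character(n); out_pam <- character(n)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(n)) {
    len <- lens[i]
    for (outer_try in 1:10000) {
      pos <- switch(comp[i],
                    target = {
                      # rejection on the PAM constraint re-draws the offset
                      p <- NULL
                      for (try in 1:10000) {
                        cand_pos <- draw_target(len)
                        pam <- upstream_pam(ref$replicons[[cand_pos$replicon]],
                                            cand_pos$start, cand_pos$end,
                                            cand_pos$strand,
                                            ref$circular[[cand_pos$replicon]])
                        if (!want_modal[i] ||
                            (!is.na(pam) && pam == motif)) { p <- cand_pos; break }
                      }
                      if (is.null(p))
                        stop("no target-proximal position with upstream ",
                             motif, " found after 10000 draws")
                      p
                    },
                    hotspot = draw_hotspot(len, want_modal[i]),
                    background = draw_background(len, want_modal[i]))
      seq_i <- extract_interval(ref$replicons[[pos$replicon]], pos$start,
                                pos$end, pos$strand,
                                ref$circular[[pos$replicon]])
      if (!config$distinct_spacers || is.null(seen[[seq_i]])) {
        if (config$distinct_spacers) seen[[seq_i]] <- TRUE
        break
      }
      if (outer_try == 10000)
        stop("could not draw ", n, " pairwise-distinct spacer sequences")
    }
    out_replicon[i] <- pos$replicon
    out_start[i] <- pos$start
    out_end[i] <- pos$end
    out_strand[i] <- pos$strand
    out_seq[i] <- seq_i
    out_pam[i] <- upstream_pam(ref$replicons[[pos$replicon]], pos$start,
                               pos$end, pos$strand,
                               ref$circular[[pos$replicon]])
  }
  truth <- data.frame(replicon = out_replicon, start = out_start,
                      end = out_end, strand = out_strand,
                      component = comp, seq = out_seq, pam = out_pam,
                      stringsAsFactors = FALSE)
  truth$spacer_id <- sprintf("sp%05d", seq_len(n))
  truth$reads <- if (config$n_reads > 0)
    as.integer(rmultinom(1, config$n_reads, rep(1, n))) else 0L
  truth <- truth[, c("spacer_id", "seq", "replicon", "start", "end",
                     "strand", "component", "pam", "reads")]
  class(truth) <- c("TruthTable", "data.frame")
  truth
}

#' Convert a truth table into protospacer-hit form
#'
#' Builds the hit records the mapping stage would produce for the planted
#' events (zero mismatches, unique placement), so downstream PAM and
#' hotspot stages can be exercised directly against the simulator truth.
#'
#' @param truth a `TruthTable`.
#' @return a data.frame of protospacer hits.
#' @export
truth_to_hits <- function(truth) {
  data.frame(spacer_id = truth$spacer_id, seq = truth$seq,
             replicon = truth$replicon, start = truth$start,
             end = truth$end, strand = truth$strand,
             mismatches = 0L, unique = TRUE, pam = truth$pam,
             reads = truth$reads, stringsAsFactors = FALSE)
}

#' Write / read a truth table as TSV
#' @param truth a `TruthTable`.
#' @param path file path.
#' @return `path` (write) or a `TruthTable` (read).
#' @export
write_truth <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  truth <- read.table(path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE)
  class(truth) <- c("TruthTable", "data.frame")
  truth
}
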