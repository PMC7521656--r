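#' Orient and trim amplicon reads to the start of the array
#'
#' Locates the adapter and then the leader (forward) anchor, allowing up
#' to `design$anchor_max_mismatches` substitutions for each, in the read
#' and in its reverse complement, with 0-3 random bases (configurable)
#' between adapter and anchor. On success the adapter, random prefix and
#' anchor are stripped and the array-proximal remainder is returned in
#' leader-to-array orientation. Rejections are data, not errors: they are
#' returned with a reason code (`no_adapter`, `no_anchor`,
#' `empty_remainder`).
#'
#' @param reads data.frame with `read_id` and `seq`, or a character vector.
#' @param design an [amplicon_design()].
#' @param random_prefix_range integer pair: random-base counts to try
#'   between adapter and anchor.
#' @return data.frame with `read_id`, `trimmed` (NA when rejected),
#'   `orient` ("+" as-is, "-" reverse-complemented), `reason` ("" when
#'   accepted).
#' @export
orient_and_trim <- function(reads, design, random_prefix_range = c(0L, 3L)) {
  if (is.character(reads))
    reads <- data.frame(read_id = paste0("read", seq_along(reads)),
                        seq = reads, stringsAsFactors = FALSE)
  res <- trim_reads_cpp(reads$seq, design$adapter, design$forward_anchor,
                        design$anchor_max_mismatches,
                        as.integer(random_prefix_range[1]),
                        as.integer(random_prefix_range[2]))
  data.frame(read_id = reads$read_id, trimmed = res$trimmed,
             orient = res$orient, reason = res$reason,
             stringsAsFactors = FALSE)
}

#' Detect newly inserted repeat-spacer units in trimmed reads
#'
#' Greedy scan of each trimmed read (which must begin at the first
#' repeat): the repeat is matched with up to
#' `design$repeat_max_mismatches` substitutions, each inter-repeat
#' segment is a candidate spacer, and scanning stops when the endogenous
#' next-spacer anchor (within `design$anchor_max_mismatches`) or the read
#' end is reached. Segments matching an endogenous spacer of the locus
#' are discarded; what remains are novel spacers in leader-proximal
#' order. Reads whose array contains no novel segment are classed
#' `unexpanded`; structural failures are rejected with a reason code
#' (`no_repeat_start`, `short_segment`, `no_terminal_anchor`).
#'
#' @param trimmed character vector of trimmed reads (NA allowed,
#'   propagated), e.g. the `trimmed` column of [orient_and_trim()].
#' @param locus the `CrisprLocus` the amplicon derives from.
#' @param design the [amplicon_design()].
#' @param min_spacer_len,max_spacer_len plausible spacer length bounds
#'   used to delimit segments.
#' @return a list with `status` (per read: `expanded`, `unexpanded` or a
#'   reject reason; NA in = NA out) and `spacers` (per read, character
#'   vector of novel spacers, leader-proximal first).
#' @export
detect_expansion <- function(trimmed, locus, design,
                             min_spacer_len = 20L, max_spacer_len = 60L) {
  res <- scan_array_cpp(trimmed, locus$repeat_seq,
                        design$repeat_max_mismatches,
                        design$reverse_anchor,
                        design$anchor_max_mismatches,
                        as.integer(min_spacer_len),
                        as.integer(max_spacer_len))
  status <- res$status
  spacers <- res$spacers
  # drop segments that are in fact endogenous spacers (deep amplicons)
  endo <- locus$spacers
  for (i in seq_along(spacers)) {
    segs <- spacers[[i]]
    if (!length(segs)) next
    is_endo <- vapply(segs, function(s) {
      any(nchar(endo) == nchar(s) &
            vapply(endo, function(e)
              nchar(e) == nchar(s) &&
                hamming(e, s) <= design$anchor_max_mismatches, logical(1)))
    }, logical(1))
    if (any(is_endo)) {
      spacers[[i]] <- segs[!is_endo]
      if (!length(spacers[[i]]) && identical(status[i], "expanded"))
        status[i] <- "unexpanded"
    }
  }
  list(status = status, spacers = spacers)
}

#' Parse an amplicon library end-to-end
#'
#' Convenience wrapper: [orient_and_trim()] then [detect_expansion()].
#'
#' @inheritParams orient_and_trim
#' @inheritParams detect_expansion
#' @return an object of class `ParsedReads`: a list with
#'   `status` (data.frame `read_id`, `status`, `orient`),
#'   `spacers` (data.frame `read_id`, `seq`, `index` with `index` 1 =
#'   leader-proximal), and `rejects` (named count vector by reason,
#'   including parser-stage reasons).
#' @export
parse_reads <- function(reads, locus, design,
                        random_prefix_range = c(0L, 3L),
                        min_spacer_len = 20L, max_spacer_len = 60L) {
  tr <- orient_and_trim(reads, design, random_prefix_range)
  det <- detect_expansion(tr$trimmed, locus, design, min_spacer_len,
                          max_spacer_len)
  status <- ifelse(is.na(tr$trimmed), tr$reason, det$status)
  n_spacers <- lengths(det$spacers)
  sp <- data.frame(
    read_id = rep(tr$read_id, n_spacers),
    seq = unlist(det$spacers, use.names = FALSE),
    index = unlist(lapply(n_spacers[n_spacers > 0], seq_len),
                   use.names = FALSE),
    stringsAsFactors = FALSE)
  if (!nrow(sp))
    sp <- data.frame(read_id = character(), seq = character(),
                     index = integer(), stringsAsFactors = FALSE)
  reject <- !status %in% c("expanded", "unexpanded")
  rejects <- if (any(reject)) table(status[reject]) else
    table(character(0))
  structure(list(status = data.frame(read_id = tr$read_id, status = status,
                                     orient = tr$orient,
                                     stringsAsFactors = FALSE),
                 spacers = sp,
                 rejects = setNames(as.integer(rejects), names(rejects))),
            class = "ParsedReads")
}

#' @export
print.ParsedReads <- function(x, ...) {
  tab <- table(x$status$status)
  cat("ParsedReads:", nrow(x$status), "reads\n")
  for (nm in names(tab)) cat(sprintf("  %-18s %d\n", nm, tab[[nm]]))
  invisible(x)
}

#' Aggregate per-read novel spacers into supported calls
#'
#' Groups identical spacer sequences (exact match; reads were already
#' orientation-normalised), sums read support, and records the insertion
#' index as the modal observed index. Output is sorted by support
#' descending, ties broken lexicographically by sequence. Calls below
#' `min_reads` are dropped.
#'
#' @param parsed a `ParsedReads` object (or its `spacers` data.frame).
#' @param locus_id locus identifier attached to the calls.
#' @param min_reads minimum read support to keep a call (default 1:
#'   aggregation keeps everything; the >= 10 filter belongs to the PAM
#'   stage).
#' @return data.frame of `SpacerCall` records: `locus_id`, `spacer_id`,
#'   `seq`, `reads`, `index`.
#' @export
aggregate_calls <- function(parsed, locus_id = "P1", min_reads = 1L) {
  sp <- if (inherits(parsed, "ParsedReads")) parsed$spacers else parsed
  if (!nrow(sp))
    return(data.frame(locus_id = character(), spacer_id = character(),
                      seq = character(), reads = integer(),
                      index = integer(), stringsAsFactors = FALSE))
  reads <- tapply(sp$read_id, sp$seq, function(x) length(unique(x)))
  modal_index <- tapply(sp$index, sp$seq, function(ix) {
    t <- table(ix)
    as.integer(names(t)[which.max(t)])
  })
  out <- data.frame(seq = names(reads), reads = as.integer(reads),
                    index = as.integer(modal_index[names(reads)]),
                    stringsAsFactors = FALSE)
  out <- out[out$reads >= min_reads, , drop = FALSE]
  out <- out[order(-out$reads, out$seq), , drop = FALSE]
  rownames(out) <- NULL
  data.frame(locus_id = locus_id,
             spacer_id = sprintf("ns%05d", seq_len(nrow(out))),
             seq = out$seq, reads = out$reads, index = out$index,
             stringsAsFactors = FALSE)
}

#' Write spacer calls as TSV
#' @param calls data.frame from [aggregate_calls()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_calls <- function(calls, path) {
  write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
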