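#' Map a spacer to a reference genome by mismatch-tolerant search
#'
#' Exhaustive Hamming-distance scan (compiled) of both strands of every
#' replicon, returning ALL positions with at most `max_mm` substitutions.
#' Circular replicons are searched on a virtual extension of length
#' `L + spacer length - 1`, so hits may wrap the origin: `start` is always
#' in `[0, L)` and `end = start + length` may exceed `L`, to be
#' interpreted modulo `L`. Each hit carries its upstream PAM: the 3 nt
#' immediately 5' of the protospacer on the protospacer strand (genomic
#' reverse complement for "-" hits). The hit with `unique = TRUE` is the
#' single best hit when exactly one hit attains the minimal mismatch
#' count; with ties, no hit is flagged unique.
#'
#' @param spacer a single DNA string (ACGT).
#' @param ref a `ReferenceGenome`.
#' @param max_mm maximum Hamming distance (default 2).
#' @param spacer_id identifier copied into the hits.
#' @return data.frame of `ProtospacerHit` records sorted by
#'   `(mismatches, replicon, start)`: `spacer_id`, `replicon`, `start`,
#'   `end`, `strand`, `mismatches`, `unique`, `pam`.
#' @export
map_spacer <- function(spacer, ref, max_mm = 2L, spacer_id = NA_character_) {
  if (grepl("[^ACGT]", spacer))
    stop("spacer contains non-ACGT symbols: ", spacer)
  m <- nchar(spacer)
  if (m < 12L) stop("spacer shorter than the minimum query length (12 nt)")
  rc <- revcomp(spacer)
  hits <- list()
  for (nm in names(ref$replicons)) {
    s <- ref$replicons[[nm]]
    L <- nchar(s, type = "bytes")
    text <- if (ref$circular[[nm]] && m > 1L)
      paste0(s, substr(s, 1L, m - 1L)) else s
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") spacer else rc
      found <- find_matches_cpp(text, pat, as.integer(max_mm))
      keep <- found$pos < L  # starts beyond L-1 would duplicate wrapped hits
      if (!any(keep)) next
      pos <- found$pos[keep]
      hits[[length(hits) + 1L]] <-
        data.frame(spacer_id = spacer_id, replicon = nm, start = pos,
                   end = pos + m, strand = strand,
                   mismatches = found$mm[keep], stringsAsFactors = FALSE)
    }
  }
  if (!length(hits))
    return(data.frame(spacer_id = character(), replicon = character(),
                      start = integer(), end = integer(),
                      strand = character(), mismatches = integer(),
                      unique = logical(), pam = character(),
                      stringsAsFactors = FALSE))
  h <- do.call(rbind, hits)
  h <- h[order(h$mismatches, h$replicon, h$start, h$strand), , drop = FALSE]
  rownames(h) <- NULL
  h$unique <- h$mismatches == min(h$mismatches) &
    sum(h$mismatches == min(h$mismatches)) == 1L
  h$pam <- vapply(seq_len(nrow(h)), function(i)
    upstream_pam(ref$replicons[[h$replicon[i]]], h$start[i], h$end[i],
                 h$strand[i], ref$circular[[h$replicon[i]]]),
    character(1))
  h
}

#' Map a table of spacer calls to the reference
#'
#' Applies [map_spacer()] to each call and binds the hits, carrying the
#' call's read support.
#'
#' @param calls data.frame from [aggregate_calls()] (needs `spacer_id`,
#'   `seq`, `reads`), or any data.frame with those columns.
#' @param ref a `ReferenceGenome`.
#' @param max_mm maximum Hamming distance per spacer.
#' @return data.frame of hits with a `reads` column appended.
#' @export
map_spacers <- function(calls, ref, max_mm = 2L) {
  out <- lapply(seq_len(nrow(calls)), function(i) {
    h <- map_spacer(calls$seq[i], ref, max_mm, calls$spacer_id[i])
    if (nrow(h)) h$reads <- calls$reads[i]
    h
  })
  out <- out[vapply(out, nrow, integer(1)) > 0]
  if (!length(out))
    return(data.frame(spacer_id = character(), replicon = character(),
                      start = integer(), end = integer(),
                      strand = character(), mismatches = integer(),
                      unique = logical(), pam = character(),
                      reads = integer(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Annotate hits with distances to the target and HEN sites
#'
#' `distance_to_target` is the signed offset from the target cut-site
#' coordinate to the hit's nearest edge, negative when the hit lies
#' upstream on the declared coding strand of the targeted gene, 0 when
#' the hit covers the cut site. `distance_to_hen` is the minimal
#' unsigned gap between the hit interval and the HEN-site interval (0
#' when overlapping). Hits on other replicons get NA.
#'
#' @param hits data.frame of protospacer hits.
#' @param ref a `ReferenceGenome` (whose features may include
#'   `target_site` and `hen_site`).
#' @return `hits` with `distance_to_target` and `distance_to_hen` columns.
#' @export
annotate_distances <- function(hits, ref) {
  cut <- target_cut_site(ref)
  hits$distance_to_target <- rep(NA_integer_, nrow(hits))
  if (!is.null(cut) && nrow(hits)) {
    on_rep <- hits$replicon == cut$replicon
    d <- ifelse(hits$start <= cut$coord & cut$coord < hits$end, 0L,
                ifelse(hits$end <= cut$coord,
                       hits$end - cut$coord,      # left of the cut
                       hits$start - cut$coord))   # right of the cut
    if (cut$coding_strand == "-") d <- -d
    hits$distance_to_target[on_rep] <- as.integer(d[on_rep])
  }
  hen <- ref$features[ref$features$kind == "hen_site", , drop = FALSE]
  hits$distance_to_hen <- rep(NA_integer_, nrow(hits))
  if (nrow(hen) >= 1 && nrow(hits)) {
    hen <- hen[1, ]
    on_rep <- hits$replicon == hen$replicon
    gap <- pmax(0L, pmax(hits$start, hen$start) - pmin(hits$end, hen$end))
    hits$distance_to_hen[on_rep] <- as.integer(gap[on_rep])
  }
  hits
}

#' Tabulate spacer sources per replicon and per feature kind
#'
#' Counts spacer calls per replicon and per overlapped feature kind, both
#' unweighted (unique spacers) and weighted by read support. Only hits
#' flagged `unique` contribute by default, so multimapping spacers are
#' not double counted.
#'
#' @param hits data.frame of hits (with `reads`; `unique` used when
#'   `unique_only`).
#' @param ref a `ReferenceGenome`.
#' @param unique_only count only uniquely placed spacers (default TRUE).
#' @return list with `replicons` (replicon, spacers, reads, fraction,
#'   read_fraction) and `features` (kind, spacers, reads).
#' @export
classify_source <- function(hits, ref, unique_only = TRUE) {
  h <- if (unique_only && nrow(hits)) hits[hits$unique, , drop = FALSE]
       else hits
  reps <- names(ref$replicons)
  if (!"reads" %in% names(h)) h$reads <- 1L
  n_sp <- vapply(reps, function(r) sum(h$replicon == r), integer(1))
  n_rd <- vapply(reps, function(r) sum(h$reads[h$replicon == r]), numeric(1))
  repl <- data.frame(replicon = reps, spacers = n_sp, reads = n_rd,
                     fraction = if (sum(n_sp)) n_sp / sum(n_sp) else 0 * n_sp,
                     read_fraction = if (sum(n_rd)) n_rd / sum(n_rd)
                                     else 0 * n_rd,
                     stringsAsFactors = FALSE)
  rownames(repl) <- NULL
  f <- ref$features
  kinds <- unique(f$kind)
  feat <- do.call(rbind, lapply(kinds, function(kd) {
    fk <- f[f$kind == kd, , drop = FALSE]
    ov <- rep(FALSE, nrow(h))
    for (j in seq_len(nrow(fk)))
      ov <- ov | (h$replicon == fk$replicon[j] &
                    h$start < fk$end[j] & h$end > fk$start[j])
    data.frame(kind = kd, spacers = sum(ov), reads = sum(h$reads[ov]),
               stringsAsFactors = FALSE)
  }))
  if (is.null(feat))
    feat <- data.frame(kind = character(), spacers = integer(),
                       reads = numeric(), stringsAsFactors = FALSE)
  list(replicons = repl, features = feat)
}

#' Write protospacer hits as TSV and BED6
#'
#' BED6 uses `name` = spacer id and `score` = read support.
#'
#' @param hits data.frame of hits.
#' @param tsv path for the TSV (all columns).
#' @param bed optional BED6 path.
#' @return `tsv`, invisibly.
#' @export
write_hits <- function(hits, tsv, bed = NULL) {
  write.table(hits, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(bed)) {
    bed_df <- data.frame(chrom = hits$replicon, start = hits$start,
                         end = hits$end, name = hits$spacer_id,
                         score = if ("reads" %in% names(hits)) hits$reads
                                 else 0L,
                         strand = hits$strand)
    write.table(bed_df, bed, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(tsv)
}
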