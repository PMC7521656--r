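#' Call acquisition hotspots against a Poisson background
#'
#' Tiles each replicon with non-overlapping windows, counts uniquely
#' placed spacers per window (a hit is assigned to the window containing
#' its start), computes upper-tail Poisson p-values against the uniform
#' expectation `total hits x window width / genome length`, adjusts with
#' Benjamini-Hochberg across all windows, and merges maximal runs of
#' adjacent significant windows into hotspot calls annotated with the
#' features they overlap.
#'
#' @param hits data.frame of mapped hits (with `unique`, `strand`;
#'   `reads` used for the read-weighted count when present).
#' @param ref a `ReferenceGenome`.
#' @param window window width in nt (default 1000).
#' @param alpha BH significance threshold on q-values (default 0.05).
#' @param unique_only use only uniquely placed hits (default TRUE).
#' @return list with `windows` (one row per window: `replicon`, `start`,
#'   `end`, `observed`, `observed_reads`, `plus`, `minus`, `expected`,
#'   `p`, `q`, `significant`) and `hotspots` (merged significant runs
#'   with overlapping feature labels).
#' @export
call_hotspots <- function(hits, ref, window = 1000L, alpha = 0.05,
                          unique_only = TRUE) {
  L <- replicon_lengths(ref)
  if (window > min(L))
    stop("window (", window, " nt) larger than the smallest replicon (",
         min(L), " nt)")
  h <- if (unique_only && nrow(hits)) hits[hits$unique, , drop = FALSE]
       else hits
  if (!"reads" %in% names(h)) h$reads <- 1L
  win <- do.call(rbind, lapply(names(L), function(nm) {
    starts <- seq(0L, L[[nm]] - 1L, by = window)
    data.frame(replicon = nm, start = starts,
               end = pmin(starts + window, L[[nm]]),
               stringsAsFactors = FALSE)
  }))
  win$observed <- 0L; win$observed_reads <- 0
  win$plus <- 0L; win$minus <- 0L
  if (nrow(h)) {
    pos <- h$start %% L[h$replicon]  # wrapped starts stay in [0, L)
    wi <- match(paste(h$replicon, (pos %/% window) * window),
                paste(win$replicon, win$start))
    agg <- function(v) {
      out <- rep(0, nrow(win))
      t <- tapply(v, wi, sum)
      out[as.integer(names(t))] <- as.numeric(t)
      out
    }
    win$observed <- as.integer(agg(rep(1L, nrow(h))))
    win$observed_reads <- agg(h$reads)
    win$plus <- as.integer(agg(as.integer(h$strand == "+")))
    win$minus <- as.integer(agg(as.integer(h$strand == "-")))
  }
  total <- sum(win$observed)
  win$expected <- total * (win$end - win$start) / sum(L)
  win$p <- ppois(win$observed - 1L, win$expected, lower.tail = FALSE)
  win$q <- p.adjust(win$p, method = "BH")
  win$significant <- win$q <= alpha & win$observed > 0L

  hotspots <- merge_significant_windows(win, ref)
  list(windows = win, hotspots = hotspots)
}

merge_significant_windows <- function(win, ref) {
  empty <- data.frame(replicon = character(), start = integer(),
                      end = integer(), observed = integer(),
                      observed_reads = numeric(), plus = integer(),
                      minus = integer(), expected = numeric(),
                      p = numeric(), q = numeric(), features = character(),
                      stringsAsFactors = FALSE)
  sig <- win[win$significant, , drop = FALSE]
  if (!nrow(sig)) return(empty)
  out <- list()
  for (nm in unique(sig$replicon)) {
    s <- sig[sig$replicon == nm, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    run <- cumsum(c(TRUE, s$start[-1] != s$end[-nrow(s)]))
    for (r in unique(run)) {
      blk <- s[run == r, , drop = FALSE]
      f <- ref$features
      ov <- f$replicon == nm & f$start < max(blk$end) & f$end > min(blk$start)
      out[[length(out) + 1L]] <-
        data.frame(replicon = nm, start = min(blk$start),
                   end = max(blk$end), observed = sum(blk$observed),
                   observed_reads = sum(blk$observed_reads),
                   plus = sum(blk$plus), minus = sum(blk$minus),
                   expected = sum(blk$expected), p = min(blk$p),
                   q = min(blk$q),
                   features = paste(f$label[ov], collapse = ","),
                   stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res[order(res$replicon, res$start), , drop = FALSE]
}

#' Profile acquisition around the target site
#'
#' Bins uniquely placed hits by signed distance to the target cut site
#' (negative = upstream on the declared coding strand) and strand, fits a
#' per-side geometric decay scale by maximum likelihood on the distances,
#' and reports the upstream coding-strand and downstream template-strand
#' fractions — the strand-bias signature of interference-driven
#' acquisition.
#'
#' @param hits data.frame of hits; `distance_to_target` is computed via
#'   [annotate_distances()] if absent.
#' @param ref a `ReferenceGenome` with a `target_site` feature.
#' @param radius profiling radius in nt (default 5000).
#' @param bin bin width in nt (default 100).
#' @param unique_only use only uniquely placed hits (default TRUE).
#' @return an object of class `TargetProfile`: list with `bins`
#'   (`bin_start`, `strand`, `count`), `decay_scale_upstream`,
#'   `decay_scale_downstream` (nt; NA with fewer than 2 side hits),
#'   `upstream_coding_fraction`, `downstream_template_fraction`, `n`
#'   (hits within the radius). With no hits in the radius, a sentinel
#'   with `n = 0`.
#' @export
profile_target <- function(hits, ref, radius = 5000L, bin = 100L,
                           unique_only = TRUE) {
  cut <- target_cut_site(ref)
  if (is.null(cut)) stop("reference has no target_site feature")
  if (!"distance_to_target" %in% names(hits))
    hits <- annotate_distances(hits, ref)
  h <- if (unique_only && nrow(hits)) hits[hits$unique, , drop = FALSE]
       else hits
  h <- h[!is.na(h$distance_to_target) &
           abs(h$distance_to_target) <= radius, , drop = FALSE]
  if (!nrow(h)) {
    return(structure(list(bins = data.frame(bin_start = integer(),
                                            strand = character(),
                                            count = integer()),
                          decay_scale_upstream = NA_real_,
                          decay_scale_downstream = NA_real_,
                          upstream_coding_fraction = NA_real_,
                          downstream_template_fraction = NA_real_,
                          n = 0L, radius = radius, bin = bin),
                     class = "TargetProfile"))
  }
  d <- h$distance_to_target
  breaks <- seq(-radius - bin, radius + bin, by = bin)
  bin_start <- breaks[findInterval(d, breaks)]
  bins <- as.data.frame(table(bin_start = bin_start, strand = h$strand),
                        stringsAsFactors = FALSE)
  bins$bin_start <- as.integer(bins$bin_start)
  bins <- bins[bins$Freq > 0, , drop = FALSE]
  names(bins)[3] <- "count"
  bins <- bins[order(bins$bin_start, bins$strand), , drop = FALSE]
  rownames(bins) <- NULL

  coding <- cut$coding_strand
  template <- if (coding == "+") "-" else "+"
  up <- -d[d < 0]; down <- d[d > 0]
  # geometric decay: offsets ~ Geom(1/s); MLE gives s = 1 + mean(offset)
  fit_scale <- function(x) if (length(x) >= 2) 1 + mean(x) else NA_real_
  structure(list(bins = bins,
                 decay_scale_upstream = fit_scale(up),
                 decay_scale_downstream = fit_scale(down),
                 upstream_coding_fraction =
                   if (length(up)) mean(h$strand[d < 0] == coding)
                   else NA_real_,
                 downstream_template_fraction =
                   if (length(down)) mean(h$strand[d > 0] == template)
                   else NA_real_,
                 n = nrow(h), radius = radius, bin = bin),
            class = "TargetProfile")
}

#' @export
print.TargetProfile <- function(x, ...) {
  if (x$n == 0) {
    cat("TargetProfile: no hits within radius\n")
    return(invisible(x))
  }
  cat("TargetProfile:", x$n, "hits within", x$radius, "nt of the cut\n")
  cat(sprintf("  decay scale (nt): upstream %.0f, downstream %.0f\n",
              x$decay_scale_upstream, x$decay_scale_downstream))
  cat(sprintf("  upstream coding-strand fraction %.3f | downstream template-strand fraction %.3f\n",
              x$upstream_coding_fraction, x$downstream_template_fraction))
  invisible(x)
}

#' Write hotspot calls / target profile as TSV (hotspots also as BED)
#'
#' @param hs result of [call_hotspots()].
#' @param tsv TSV path for merged hotspot calls.
#' @param bed optional BED path (`score` = observed count).
#' @return `tsv`, invisibly.
#' @export
write_hotspots <- function(hs, tsv, bed = NULL) {
  write.table(hs$hotspots, tsv, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(bed)) {
    b <- hs$hotspots
    bed_df <- data.frame(chrom = b$replicon, start = b$start, end = b$end,
                         name = paste0("hotspot_", seq_len(nrow(b))),
                         score = b$observed, strand = ".")
    write.table(bed_df, bed, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  invisible(tsv)
}

#' @rdname write_hotspots
#' @param profile a `TargetProfile`.
#' @param path TSV path for the binned profile.
#' @export
write_profile <- function(profile, path) {
  write.table(profile$bins, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
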