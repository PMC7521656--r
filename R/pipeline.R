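#' Configuration for a full pipeline run
#'
#' Either a simulation block (`sim`, a [simulation_config()]) or paths to
#' existing inputs (`reads_fastq` plus `locus_yaml`; `reference_fasta` and
#' `features_bed` optional). When the reference is absent the mapping,
#' PAM, hotspot and profile stages are skipped with a logged notice.
#'
#' @param out_dir output directory (created if needed).
#' @param sim optional [simulation_config()] driving the simulate stage.
#' @param reads_fastq,locus_yaml,reference_fasta,features_bed input paths
#'   used when `sim` is NULL.
#' @param circular logical for replicons read from FASTA.
#' @param min_reads PAM-stage read-support filter (default 10).
#' @param max_mm mapping mismatch budget (default 2).
#' @param window,alpha hotspot window (nt) and BH threshold.
#' @param radius,bin target-profile radius and bin width (nt).
#' @param force overwrite existing outputs (default TRUE).
#' @return an object of class `RunConfig`.
#' @export
run_config <- function(out_dir, sim = NULL, reads_fastq = NULL,
                       locus_yaml = NULL, reference_fasta = NULL,
                       features_bed = NULL, circular = TRUE,
                       min_reads = 10L, max_mm = 2L, window = 1000L,
                       alpha = 0.05, radius = 5000L, bin = 100L,
                       force = TRUE) {
  if (is.null(sim) && (is.null(reads_fastq) || is.null(locus_yaml)))
    stop("run_config needs either a simulation block or reads + locus paths")
  if (!is.null(sim)) validate_simulation_config(sim)
  structure(list(out_dir = out_dir, sim = sim, reads_fastq = reads_fastq,
                 locus_yaml = locus_yaml, reference_fasta = reference_fasta,
                 features_bed = features_bed, circular = circular,
                 min_reads = as.integer(min_reads),
                 max_mm = as.integer(max_mm), window = as.integer(window),
                 alpha = alpha, radius = as.integer(radius),
                 bin = as.integer(bin), force = isTRUE(force)),
            class = "RunConfig")
}

#' Run the acquisition-analysis pipeline
#'
#' Executes the requested stages — simulate (optional), parse, map, PAM,
#' hotspots, target profile — writing per-stage TSV/FASTA/FASTQ/BED
#' outputs plus a machine-readable JSON summary into `config$out_dir`.
#' Re-running the same configuration reproduces identical outputs.
#'
#' @param config a [run_config()].
#' @param quiet suppress progress messages.
#' @return the run summary (a named list), invisibly; also written as
#'   `summary.json`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "RunConfig"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  if (!config$force && file.exists(file.path(out, "summary.json")))
    stop("outputs already present in ", out, " (use force = TRUE)")
  say <- function(...) if (!quiet) message("[haloadapt] ", ...)

  ref <- NULL
  if (!is.null(config$sim)) {
    say("simulate: reference, locus, prespacers, reads (seed ",
        config$sim$seed, ")")
    ref <- make_reference(config$sim)
    locus <- make_locus(config$sim$seed,
                        spacer_length_range = config$sim$spacer_length_range)
    design <- amplicon_design(locus)
    truth <- sample_prespacers(ref, config$sim)
    sim <- simulate_amplicon_reads(locus, truth, design, config$sim)
    reads <- sim$reads
    write_reference(ref, file.path(out, "reference.fasta"),
                    file.path(out, "features.bed"))
    write_locus(locus, file.path(out, "locus.yaml"))
    write_truth(truth, file.path(out, "truth.tsv"))
    write_fastq(reads, file.path(out, "reads.fastq"))
  } else {
    say("load: reads from ", config$reads_fastq)
    reads <- read_fastq(config$reads_fastq)
    locus <- read_locus(config$locus_yaml)
    design <- amplicon_design(locus)
    if (!is.null(config$reference_fasta))
      ref <- read_reference(config$reference_fasta, config$features_bed,
                            circular = config$circular)
  }

  say("parse: ", nrow(reads), " reads")
  parsed <- parse_reads(reads, locus, design)
  calls <- aggregate_calls(parsed, locus$locus_id)
  write_calls(calls, file.path(out, "calls.tsv"))
  st <- table(factor(parsed$status$status,
                     levels = union(c("expanded", "unexpanded"),
                                    unique(parsed$status$status))))
  n_expanded <- as.integer(st[["expanded"]])
  n_unexpanded <- as.integer(st[["unexpanded"]])
  n_rejected <- nrow(reads) - n_expanded - n_unexpanded
  stopifnot(n_expanded + n_unexpanded + n_rejected == nrow(reads))

  summary <- list(
    n_reads = nrow(reads),
    expanded_reads = n_expanded,
    unexpanded_reads = n_unexpanded,
    rejected_reads = n_rejected,
    rejects_by_reason = as.list(parsed$rejects),
    unique_spacers = nrow(calls),
    parameters = list(min_reads = config$min_reads, max_mm = config$max_mm,
                      window = config$window, alpha = config$alpha,
                      radius = config$radius, bin = config$bin,
                      seed = if (!is.null(config$sim)) config$sim$seed
                             else NULL))

  if (is.null(ref)) {
    say("no reference: skipping map, PAM, hotspot and profile stages")
    summary$skipped_stages <- c("map", "pam", "hotspots", "profile")
  } else {
    say("map: ", nrow(calls), " spacers, max_mm=", config$max_mm)
    hits <- map_spacers(calls, ref, config$max_mm)
    hits <- annotate_distances(hits, ref)
    write_hits(hits, file.path(out, "hits.tsv"), file.path(out, "hits.bed"))
    src <- classify_source(hits, ref)
    summary$replicon_fractions <- setNames(as.list(src$replicons$fraction),
                                           src$replicons$replicon)

    pam_sp <- summarize_pams(hits, config$min_reads, "per_spacer")
    pam_rd <- summarize_pams(hits, config$min_reads, "per_read")
    write_pam_summary(pam_sp, file.path(out, "pam_counts.tsv"),
                      file.path(out, "pam_pfm.tsv"))
    summary$pam <- list(
      per_spacer = list(modal = pam_sp$modal_kmer,
                        fraction = pam_sp$modal_fraction, n = pam_sp$n),
      per_read = list(modal = pam_rd$modal_kmer,
                      fraction = pam_rd$modal_fraction, n = pam_rd$n))

    say("hotspots: window ", config$window, " nt")
    hs <- call_hotspots(hits, ref, config$window, config$alpha)
    write_hotspots(hs, file.path(out, "hotspots.tsv"),
                   file.path(out, "hotspots.bed"))
    summary$n_hotspots <- nrow(hs$hotspots)

    if (!is.null(target_cut_site(ref))) {
      prof <- profile_target(hits, ref, config$radius, config$bin)
      write_profile(prof, file.path(out, "target_profile.tsv"))
      summary$target_profile <- list(
        n = prof$n,
        decay_scale_upstream = prof$decay_scale_upstream,
        decay_scale_downstream = prof$decay_scale_downstream,
        upstream_coding_fraction = prof$upstream_coding_fraction,
        downstream_template_fraction = prof$downstream_template_fraction)
    } else {
      say("no target_site feature: skipping profile stage")
      summary$skipped_stages <- "profile"
    }
  }

  jsonlite::write_json(summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  say("done: ", out)
  invisible(summary)
}
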