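#' Simulation configuration for the acquisition-assay generator
#'
#' Bundles every tunable of the synthetic-data module: the reference genome
#' (replicon lengths, GC content, feature layout), the prespacer origin
#' mixture, PAM bias, and the amplicon read model. One seed fixes all
#' downstream randomness; the generator stages use fixed offsets from it
#' (reference: `seed`, prespacers: `seed + 1`, reads: `seed + 2`) so the
#' stages can be re-run independently yet reproducibly.
#'
#' @param seed integer seed controlling all randomness.
#' @param chromosome_length,plasmid_lengths replicon lengths in nt; one
#'   "chromosome" plus one plasmid per element of `plasmid_lengths`.
#' @param gc GC fraction of the simulated replicons (the modelled host is
#'   GC-rich, default 0.65).
#' @param n_transposase,n_rrna,n_provirus number of hotspot features of
#'   each kind placed on the chromosome.
#' @param feature_lengths named lengths (nt) for the hotspot feature kinds.
#' @param target_site logical; place a self-targeting protospacer site on
#'   the chromosome.
#' @param target_length length of the target site in nt.
#' @param target_strand coding strand of the targeted gene ("+" or "-").
#' @param hen_site logical; place a homing-endonuclease (HEN) cut site on
#'   the first plasmid.
#' @param hen_length length of the HEN site in nt.
#' @param circular logical, recycled over replicons.
#' @param n_prespacers number of acquisition events to plant.
#' @param w_target,w_hotspot,w_background origin mixture weights (must sum
#'   to 1): target-proximal with distance decay and a strand rule;
#'   uniform within a random hotspot feature; uniform genome-wide.
#' @param target_decay_scale geometric decay scale (nt) of the
#'   cut-site-to-prespacer distance for the target component.
#' @param upstream_strand,downstream_strand strand rule for the target
#'   component: `"coding"` or `"template"` relative to the declared coding
#'   strand of the targeted gene. Defaults encode the observed asymmetry:
#'   prespacers upstream of the cut come from the coding strand, downstream
#'   from the template strand.
#' @param pam_modal_motif modal 3-nt upstream PAM planted by rejection
#'   sampling.
#' @param pam_modal_fraction fraction of prespacers constrained to carry
#'   the modal PAM (default 0.76, the adaptation consensus fraction the
#'   assay is calibrated to).
#' @param spacer_length_range inclusive spacer length bounds in nt.
#' @param distinct_spacers logical; redraw origins until all planted spacer
#'   sequences are pairwise distinct.
#' @param n_reads total amplicon reads, allocated to planted spacers by a
#'   uniform multinomial.
#' @param error_rate per-base substitution rate applied i.i.d. to reads.
#' @param double_insertion_fraction probability a read carries two new
#'   repeat-spacer units instead of one.
#' @param random_prefix_range integer pair: bounds of the 0-3 random bases
#'   inserted between adapter and locus-specific primer.
#' @param revcomp_fraction fraction of reads emitted reverse-complemented.
#' @param read_length fixed read length, or `NULL` for full-amplicon reads;
#'   an error is raised if any construct exceeds it.
#' @return an object of class `SimulationConfig` (a validated list).
#' @export
simulation_config <- function(seed = 1L,
                              chromosome_length = 200000L,
                              plasmid_lengths = 20000L,
                              gc = 0.65,
                              n_transposase = 5L,
                              n_rrna = 1L,
                              n_provirus = 1L,
                              feature_lengths = c(transposase = 1200L,
                                                  rRNA = 5000L,
                                                  provirus = 8000L),
                              target_site = TRUE,
                              target_length = 34L,
                              target_strand = "+",
                              hen_site = FALSE,
                              hen_length = 30L,
                              circular = TRUE,
                              n_prespacers = 1000L,
                              w_target = 0.4,
                              w_hotspot = 0.3,
                              w_background = 0.3,
                              target_decay_scale = 500,
                              upstream_strand = "coding",
                              downstream_strand = "template",
                              pam_modal_motif = "TAC",
                              pam_modal_fraction = 0.76,
                              spacer_length_range = c(34L, 39L),
                              distinct_spacers = FALSE,
                              n_reads = 50000L,
                              error_rate = 0,
                              double_insertion_fraction = 0,
                              random_prefix_range = c(0L, 3L),
                              revcomp_fraction = 0.5,
                              read_length = NULL) {
  cfg <- list(seed = as.integer(seed),
              chromosome_length = as.integer(chromosome_length),
              plasmid_lengths = as.integer(plasmid_lengths),
              gc = gc,
              n_transposase = as.integer(n_transposase),
              n_rrna = as.integer(n_rrna),
              n_provirus = as.integer(n_provirus),
              feature_lengths = feature_lengths,
              target_site = isTRUE(target_site),
              target_length = as.integer(target_length),
              target_strand = target_strand,
              hen_site = isTRUE(hen_site),
              hen_length = as.integer(hen_length),
              circular = circular,
              n_prespacers = as.integer(n_prespacers),
              w_target = w_target,
              w_hotspot = w_hotspot,
              w_background = w_background,
              target_decay_scale = target_decay_scale,
              upstream_strand = upstream_strand,
              downstream_strand = downstream_strand,
              pam_modal_motif = toupper(pam_modal_motif),
              pam_modal_fraction = pam_modal_fraction,
              spacer_length_range = as.integer(spacer_length_range),
              distinct_spacers = isTRUE(distinct_spacers),
              n_reads = as.integer(n_reads),
              error_rate = error_rate,
              double_insertion_fraction = double_insertion_fraction,
              random_prefix_range = as.integer(random_prefix_range),
              revcomp_fraction = revcomp_fraction,
              read_length = if (is.null(read_length)) NULL
                            else as.integer(read_length))
  validate_simulation_config(cfg)
  structure(cfg, class = "SimulationConfig")
}

validate_simulation_config <- function(cfg) {
  probs <- c(w_target = cfg$w_target, w_hotspot = cfg$w_hotspot,
             w_background = cfg$w_background,
             pam_modal_fraction = cfg$pam_modal_fraction,
             error_rate = cfg$error_rate,
             double_insertion_fraction = cfg$double_insertion_fraction,
             revcomp_fraction = cfg$revcomp_fraction,
             gc = cfg$gc)
  bad <- probs < 0 | probs > 1
  if (any(bad))
    stop("probabilities out of [0,1]: ",
         paste(names(probs)[bad], collapse = ", "))
  w <- cfg$w_target + cfg$w_hotspot + cfg$w_background
  if (abs(w - 1) > 1e-9)
    stop("mixture weights must sum to 1 (got ", format(w, digits = 12), ")")
  if (cfg$target_decay_scale <= 0)
    stop("target_decay_scale must be > 0")
  if (length(cfg$spacer_length_range) != 2 ||
      cfg$spacer_length_range[1] > cfg$spacer_length_range[2] ||
      cfg$spacer_length_range[1] < 1)
    stop("spacer_length_range must be an increasing positive pair")
  if (nchar(cfg$pam_modal_motif) != 3 ||
      !all(strsplit(cfg$pam_modal_motif, "")[[1]] %in% DNA_BASES))
    stop("pam_modal_motif must be a 3-mer over ACGT")
  if (!cfg$target_strand %in% c("+", "-"))
    stop("target_strand must be '+' or '-'")
  if (cfg$random_prefix_range[1] < 0 ||
      cfg$random_prefix_range[1] > cfg$random_prefix_range[2])
    stop("random_prefix_range must be a non-negative increasing pair")
  invisible(cfg)
}

#' @export
print.SimulationConfig <- function(x, ...) {
  cat("SimulationConfig (seed ", x$seed, ")\n", sep = "")
  cat("  genome: chromosome ", x$chromosome_length, " nt + ",
      length(x$plasmid_lengths), " plasmid(s), GC ", x$gc, "\n", sep = "")
  cat("  prespacers: n=", x$n_prespacers, ", mixture (target/hotspot/bg) ",
      x$w_target, "/", x$w_hotspot, "/", x$w_background, "\n", sep = "")
  cat("  PAM: ", x$pam_modal_motif, " at fraction ", x$pam_modal_fraction,
      "\n", sep = "")
  cat("  reads: n=", x$n_reads, ", error rate ", x$error_rate,
      ", double-insertion ", x$double_insertion_fraction, "\n", sep = "")
  invisible(x)
}
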