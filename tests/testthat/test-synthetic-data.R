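test_that("reference generation is deterministic and respects configuration", {
  cfg <- small_config(seed = 11)
  ref1 <- make_reference(cfg)
  ref2 <- make_reference(cfg)
  expect_identical(ref1$replicons, ref2$replicons)
  expect_identical(ref1$features, ref2$features)
  expect_setequal(names(ref1$replicons), c("chromosome", "plasmid1"))

  # features are non-overlapping and inside their replicons
  f <- ref1$features
  expect_true(all(f$start >= 0 & f$end <= replicon_lengths(ref1)[f$replicon]))
  chr <- f[f$replicon == "chromosome", ]
  chr <- chr[order(chr$start), ]
  expect_true(all(chr$start[-1] >= chr$end[-nrow(chr)]))
  expect_identical(sum(f$kind == "target_site"), 1L)

  # no features requested -> empty feature table
  bare <- make_reference(small_config(seed = 2, n_transposase = 0,
                                      n_rrna = 0, n_provirus = 0,
                                      target_site = FALSE))
  expect_identical(nrow(bare$features), 0L)

  # a replicon too small for its features errors out
  expect_error(make_reference(small_config(seed = 3,
                                           chromosome_length = 900L)),
               "too small|crowded")
})

test_that("realised GC content concentrates at the configured fraction", {
  cfg <- simulation_config(seed = 4, chromosome_length = 200000L,
                           plasmid_lengths = integer(0), gc = 0.65,
                           n_transposase = 0, n_rrna = 0, n_provirus = 0,
                           target_site = FALSE)
  ref <- make_reference(cfg)
  expect_lt(abs(gc_fraction(ref$replicons[["chromosome"]]) - 0.65), 0.01)
})

test_that("truth table round-trips against the reference", {
  cfg <- small_config(seed = 21, n_prespacers = 300, n_reads = 0)
  ref <- make_reference(cfg)
  truth <- sample_prespacers(ref, cfg)
  expect_identical(nrow(truth), 300L)
  ok <- vapply(seq_len(nrow(truth)), function(i) {
    s <- haloadapt:::extract_interval(ref$replicons[[truth$replicon[i]]],
                                      truth$start[i], truth$end[i],
                                      truth$strand[i],
                                      ref$circular[[truth$replicon[i]]])
    s == truth$seq[i]
  }, logical(1))
  expect_true(all(ok))
  # stored PAM is the trinucleotide 5' of the protospacer on its strand
  pam_ok <- vapply(seq_len(nrow(truth)), function(i) {
    p <- haloadapt:::upstream_pam(ref$replicons[[truth$replicon[i]]],
                                  truth$start[i], truth$end[i],
                                  truth$strand[i],
                                  ref$circular[[truth$replicon[i]]])
    identical(p, truth$pam[i])
  }, logical(1))
  expect_true(all(pam_ok))
  # seed reproducibility
  expect_identical(truth, sample_prespacers(ref, cfg))
})

test_that("PAM planting hits the configured modal fraction", {
  cfg <- small_config(seed = 22, n_prespacers = 2000, n_reads = 0,
                      pam_modal_fraction = 0.76)
  ref <- make_reference(cfg)
  truth <- sample_prespacers(ref, cfg)
  p <- 0.76
  tol <- 4 * sqrt(p * (1 - p) / nrow(truth))
  expect_lt(abs(mean(truth$pam == "TAC") - p), tol + 0.01)

  all_modal <- sample_prespacers(ref, small_config(seed = 23,
                                                   n_prespacers = 200,
                                                   n_reads = 0,
                                                   pam_modal_fraction = 1))
  expect_true(all(all_modal$pam == "TAC"))
})

test_that("target component obeys the strand rule and distance decay limit", {
  cfg <- small_config(seed = 24, n_prespacers = 500, n_reads = 0,
                      w_target = 1, w_hotspot = 0, w_background = 0,
                      pam_modal_fraction = 0)
  ref <- make_reference(cfg)
  cut <- haloadapt:::target_cut_site(ref)
  truth <- sample_prespacers(ref, cfg)
  up <- truth$end <= cut$coord     # upstream of the cut (coding strand +)
  down <- truth$start >= cut$coord
  expect_true(all(truth$strand[up] == cut$coding_strand))
  expect_true(all(truth$strand[down] != cut$coding_strand))

  # decay scale -> minimal: all origins hug the cut site
  tight <- sample_prespacers(ref, small_config(seed = 25, n_prespacers = 100,
                                               n_reads = 0, w_target = 1,
                                               w_hotspot = 0,
                                               w_background = 0,
                                               pam_modal_fraction = 0,
                                               target_decay_scale = 1))
  d <- pmax(tight$start - cut$coord, cut$coord - tight$end)
  expect_true(all(d <= 5))
})

test_that("background component is length-proportional across replicons", {
  cfg <- small_config(seed = 26, n_prespacers = 10000, n_reads = 0,
                      w_target = 0, w_hotspot = 0, w_background = 1,
                      pam_modal_fraction = 0)
  ref <- make_reference(cfg)
  truth <- sample_prespacers(ref, cfg)
  L <- replicon_lengths(ref)
  p_chr <- L[["chromosome"]] / sum(L)
  frac <- mean(truth$replicon == "chromosome")
  expect_lt(abs(frac - p_chr), 4 * sqrt(p_chr * (1 - p_chr) / nrow(truth)))
  expect_lt(abs(mean(truth$strand == "+") - 0.5),
            4 * sqrt(0.25 / nrow(truth)))
})

test_that("simulated reads embed their planted spacers and reproduce byte-identically", {
  cfg <- small_config(seed = 31, n_prespacers = 50, n_reads = 500)
  ref <- make_reference(cfg)
  locus <- make_locus(31)
  design <- amplicon_design(locus)
  truth <- sample_prespacers(ref, cfg)
  sim <- simulate_amplicon_reads(locus, truth, design, cfg)
  expect_identical(nrow(sim$reads), 500L)

  # error-free reads contain the planted spacer as an exact substring
  planted <- truth$seq[match(sim$labels$spacer_id, truth$spacer_id)]
  fwd <- ifelse(sim$labels$orient == "-", revcomp(sim$reads$seq),
                sim$reads$seq)
  expect_true(all(mapply(grepl, planted, fwd, fixed = TRUE)))

  # byte-identical FASTQ under a fixed seed
  f1 <- tempfile(fileext = ".fastq"); f2 <- tempfile(fileext = ".fastq")
  write_fastq(simulate_amplicon_reads(locus, truth, design, cfg)$reads, f1)
  write_fastq(simulate_amplicon_reads(locus, truth, design, cfg)$reads, f2)
  expect_identical(readLines(f1), readLines(f2))

  # double insertions carry exactly two units
  cfg2 <- small_config(seed = 32, n_prespacers = 20, n_reads = 100,
                       double_insertion_fraction = 1)
  truth2 <- sample_prespacers(ref, cfg2)
  sim2 <- simulate_amplicon_reads(locus, truth2, design, cfg2)
  expect_true(all(sim2$labels$n_units == 2L))

  # a read length shorter than the construct is a configuration error
  cfg3 <- small_config(seed = 33, n_prespacers = 20, n_reads = 100,
                       read_length = 100L)
  expect_error(simulate_amplicon_reads(locus, truth, design, cfg3),
               "read_length")
})
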