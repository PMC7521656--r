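make_parser_fixture <- function(seed = 41) {
  locus <- make_locus(seed)
  design <- amplicon_design(locus)
  list(locus = locus, design = design)
}

test_that("orient_and_trim strips adapter, random bases and anchor in both orientations", {
  fx <- make_parser_fixture()
  d <- fx$design
  set.seed(1)
  x <- random_dna(80, 0.5)

  r1 <- paste0(d$adapter, "GT", d$forward_anchor, x)
  tr <- orient_and_trim(c(r1, revcomp(r1)), d)
  expect_identical(tr$trimmed, c(x, x))
  expect_identical(tr$orient, c("+", "-"))
  expect_identical(tr$reason, c("", ""))

  # zero random bases also accepted
  r0 <- paste0(d$adapter, d$forward_anchor, x)
  expect_identical(orient_and_trim(r0, d)$trimmed, x)

  # anchor exceeding the mismatch budget rejects with a reason code
  bad_anchor <- mutate_bases(d$forward_anchor, d$anchor_max_mismatches + 1L)
  expect_gt(hamming(bad_anchor, d$forward_anchor), d$anchor_max_mismatches)
  rbad <- paste0(d$adapter, "A", bad_anchor, x)
  trbad <- orient_and_trim(rbad, d)
  expect_true(is.na(trbad$trimmed))
  expect_identical(trbad$reason, "no_anchor")

  # an anchor at exactly the budget is still accepted
  edge_anchor <- mutate_bases(d$forward_anchor, d$anchor_max_mismatches)
  expect_identical(orient_and_trim(paste0(d$adapter, edge_anchor, x), d)$trimmed,
                   x)

  # garbage without the adapter
  expect_identical(orient_and_trim(random_dna(100, 0.5), d)$reason,
                   "no_adapter")
})

test_that("detect_expansion classifies unexpanded, single and double insertions", {
  fx <- make_parser_fixture()
  locus <- fx$locus; d <- fx$design
  rep_seq <- locus$repeat_seq
  set.seed(2)
  s1 <- random_dna(36, 0.5)
  s2 <- random_dna(38, 0.5)

  unexp <- paste0(rep_seq, d$reverse_anchor)
  one <- paste0(rep_seq, s1, rep_seq, d$reverse_anchor)
  two <- paste0(rep_seq, s1, rep_seq, s2, rep_seq, d$reverse_anchor)
  det <- detect_expansion(c(unexp, one, two), locus, d)
  expect_identical(det$status, c("unexpanded", "expanded", "expanded"))
  expect_identical(det$spacers[[2]], s1)
  expect_identical(det$spacers[[3]], c(s1, s2))  # leader-proximal first

  # repeat carrying its full mismatch budget still delimits the spacer
  noisy_rep <- mutate_bases(rep_seq, d$repeat_max_mismatches)
  noisy <- paste0(rep_seq, s1, noisy_rep, d$reverse_anchor)
  det2 <- detect_expansion(noisy, locus, d)
  expect_identical(det2$status, "expanded")
  expect_identical(det2$spacers[[1]], s1)

  # a read that does not begin with the repeat is rejected
  det3 <- detect_expansion(paste0("ACGT", one), locus, d)
  expect_identical(det3$status, "no_repeat_start")

  # a segment matching an endogenous spacer is not a novel call
  endo <- paste0(rep_seq, locus$spacers[2], rep_seq, d$reverse_anchor)
  det4 <- detect_expansion(endo, locus, d)
  expect_identical(det4$status, "unexpanded")
})

test_that("parsing conserves reads and support on an error-free library", {
  cfg <- small_config(seed = 42, n_prespacers = 60, n_reads = 2000)
  ref <- make_reference(cfg)
  fx <- make_parser_fixture(42)
  truth <- sample_prespacers(ref, cfg)
  sim <- simulate_amplicon_reads(fx$locus, truth, fx$design, cfg)
  parsed <- parse_reads(sim$reads, fx$locus, fx$design)

  st <- table(parsed$status$status)
  expect_identical(as.integer(st[["expanded"]]), 2000L)
  # conservation: expanded + unexpanded + rejected = input
  expect_identical(sum(st), 2000L)

  calls <- aggregate_calls(parsed, "P1")
  expect_identical(sum(calls$reads), 2000L)
  # every planted sequence with >= 1 read is recovered with exact support
  # (independently drawn events can share a sequence; support adds up)
  planted <- tapply(truth$reads, truth$seq, sum)
  planted <- planted[planted > 0]
  expect_setequal(calls$seq, names(planted))
  m <- match(names(planted), calls$seq)
  expect_identical(calls$reads[m], as.integer(planted))
})

test_that("parsing is orientation-invariant and reports no chimeric spacers", {
  cfg <- small_config(seed = 43, n_prespacers = 30, n_reads = 400)
  ref <- make_reference(cfg)
  fx <- make_parser_fixture(43)
  truth <- sample_prespacers(ref, cfg)
  sim <- simulate_amplicon_reads(fx$locus, truth, fx$design, cfg)

  flipped <- sim$reads
  flipped$seq <- revcomp(flipped$seq)
  c1 <- aggregate_calls(parse_reads(sim$reads, fx$locus, fx$design), "P1")
  c2 <- aggregate_calls(parse_reads(flipped, fx$locus, fx$design), "P1")
  expect_identical(c1, c2)

  # no chimeras: every call is a contiguous substring of some input read
  haystack <- c(sim$reads$seq, revcomp(sim$reads$seq))
  found <- vapply(c1$seq, function(s)
    any(grepl(s, haystack, fixed = TRUE)), logical(1))
  expect_true(all(found))
})

test_that("recovery under substitution errors is bounded below by the per-read oracle", {
  cfg <- small_config(seed = 44, n_prespacers = 40, n_reads = 800,
                      error_rate = 0.01)
  ref <- make_reference(cfg)
  fx <- make_parser_fixture(44)
  locus <- fx$locus; d <- fx$design
  truth <- sample_prespacers(ref, cfg)
  sim <- simulate_amplicon_reads(locus, truth, d, cfg)
  parsed <- parse_reads(sim$reads, locus, d)

  # oracle: a read must parse if no anchored segment exceeds its budget;
  # segment positions are reconstructed from the known construct layout
  lab <- sim$labels
  fwd <- ifelse(lab$orient == "-", revcomp(sim$reads$seq), sim$reads$seq)
  al <- nchar(d$adapter); fl <- nchar(d$forward_anchor)
  rl <- nchar(locus$repeat_seq); vl <- nchar(d$reverse_anchor)
  seg_mm <- function(obs, clean, from, len)
    hamming(substr(obs, from, from + len - 1),
            substr(clean, from, from + len - 1))
  must_parse <- vapply(seq_len(nrow(lab)), function(i) {
    obs <- fwd[i]; clean <- lab$clean_seq[i]
    sp1 <- nchar(truth$seq[match(lab$spacer_id[i], truth$spacer_id)])
    pos <- 1L
    ok <- seg_mm(obs, clean, pos, al) <= d$anchor_max_mismatches
    pos <- pos + al + lab$prefix_len[i]
    ok <- ok && seg_mm(obs, clean, pos, fl) <= d$anchor_max_mismatches
    pos <- pos + fl
    ok <- ok && seg_mm(obs, clean, pos, rl) <= d$repeat_max_mismatches
    pos <- pos + rl + sp1
    if (lab$n_units[i] == 2L) {
      sp2 <- nchar(truth$seq[match(lab$spacer_id2[i], truth$spacer_id)])
      ok <- ok && seg_mm(obs, clean, pos, rl) <= d$repeat_max_mismatches
      pos <- pos + rl + sp2
    }
    ok <- ok && seg_mm(obs, clean, pos, rl) <= d$repeat_max_mismatches
    pos <- pos + rl
    ok && seg_mm(obs, clean, pos, vl) <= d$anchor_max_mismatches
  }, logical(1))

  recovered <- parsed$status$status == "expanded"
  expect_true(all(recovered[must_parse]))
  expect_gte(mean(recovered), mean(must_parse))
})

test_that("aggregation orders by support with lexicographic ties and handles empty input", {
  sp <- data.frame(read_id = c("r1", "r2", "r3", "r4"),
                   seq = c("TTTT", "TTTT", "AAAA", "CCCC"),
                   index = c(1L, 1L, 1L, 2L), stringsAsFactors = FALSE)
  calls <- aggregate_calls(sp, "P1")
  expect_identical(calls$seq, c("TTTT", "AAAA", "CCCC"))  # 2, then tie A < C
  expect_identical(calls$reads, c(2L, 1L, 1L))
  expect_identical(calls$index, c(1L, 1L, 2L))

  empty <- aggregate_calls(sp[0, ], "P1")
  expect_identical(nrow(empty), 0L)

  # min_reads filter
  expect_identical(aggregate_calls(sp, "P1", min_reads = 2L)$seq, "TTTT")
})
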