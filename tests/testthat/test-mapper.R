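test_that("map_spacer equals a brute-force Hamming scan on random spacers", {
  set.seed(51)
  ref <- reference_genome(c(chrA = random_dna(5000, 0.65),
                            chrB = random_dna(2000, 0.65)),
                          circular = c(TRUE, FALSE))
  for (mm in 0:2) {
    for (i in 1:15) {
      # half random queries, half mutated genuine substrings (guaranteed hits)
      sp <- if (i %% 2 == 0) random_dna(36, 0.65) else {
        s0 <- substr(ref$replicons[[1]], 1000 + 40 * i, 1035 + 40 * i)
        mutate_bases(s0, mm)
      }
      got <- map_spacer(sp, ref, mm)
      want <- brute_force_map(sp, ref, mm)
      expect_identical(got[, c("replicon", "start", "end", "strand",
                               "mismatches")],
                       want, label = paste("mm", mm, "query", i))
    }
  }
})

test_that("mapping is strand-symmetric and resolves circular wrap", {
  set.seed(52)
  ref <- reference_genome(c(chr = random_dna(5000, 0.5)), circular = TRUE)
  sp <- substr(ref$replicons[[1]], 1001, 1036)

  h <- map_spacer(sp, ref, 0)
  expect_identical(nrow(h), 1L)
  expect_identical(h$start, 1000L)
  expect_identical(h$end, 1036L)
  expect_identical(h$strand, "+")
  expect_identical(h$mismatches, 0L)
  expect_true(h$unique)

  # reverse complement: same interval, opposite strand
  hrc <- map_spacer(revcomp(sp), ref, 0)
  expect_identical(hrc[, c("replicon", "start", "end")],
                   h[, c("replicon", "start", "end")])
  expect_identical(hrc$strand, "-")

  # spacer spanning the circular origin maps as one wrapped hit
  L <- nchar(ref$replicons[[1]])
  wrap <- paste0(substr(ref$replicons[[1]], L - 9, L),
                 substr(ref$replicons[[1]], 1, 26))
  hw <- map_spacer(wrap, ref, 0)
  expect_identical(nrow(hw), 1L)
  expect_identical(hw$start, L - 10L)
  expect_identical(hw$end, L - 10L + 36L)   # end > L: interpret modulo L
  # ...and the same query finds nothing on a linearised copy
  lin <- reference_genome(ref$replicons, circular = FALSE)
  expect_identical(nrow(map_spacer(wrap, lin, 0)), 0L)

  # PAM is the trinucleotide 5' of the protospacer on the hit strand
  expect_identical(h$pam, substr(ref$replicons[[1]], 998, 1000))
  expect_identical(hrc$pam,
                   revcomp(substr(ref$replicons[[1]], 1037, 1039)))

  expect_error(map_spacer("ACGTNACGTACGTACGT", ref), "non-ACGT")
})

test_that("multimapping spacers are reported fully and never flagged unique", {
  set.seed(53)
  core <- random_dna(36, 0.5)
  filler1 <- random_dna(300, 0.5); filler2 <- random_dna(300, 0.5)
  ref <- reference_genome(
    c(chr = paste0(filler1, core, filler2, core, random_dna(100, 0.5))),
    circular = FALSE)
  h <- map_spacer(core, ref, 0)
  expect_identical(nrow(h), 2L)
  expect_false(any(h$unique))
  expect_identical(h$start, c(300L, 636L))
})

test_that("distance annotation follows the sign and gap conventions", {
  set.seed(54)
  seqs <- c(chr = random_dna(10000, 0.5), plas = random_dna(4000, 0.5))
  feats <- data.frame(replicon = c("chr", "plas"),
                      start = c(6000L, 2000L), end = c(6034L, 2030L),
                      strand = c("+", "+"),
                      kind = c("target_site", "hen_site"),
                      label = c("target", "hen"), stringsAsFactors = FALSE)
  ref <- reference_genome(seqs, circular = FALSE, features = feats)

  hits <- data.frame(
    spacer_id = sprintf("s%d", 1:6),
    replicon = c("chr", "chr", "chr", "plas", "plas", "plas"),
    start = c(5950L, 5990L, 6100L, 2010L, 1843L, 2500L),
    end = c(5986L, 6026L, 6136L, 2046L, 1879L, 2536L),
    strand = "+", mismatches = 0L, unique = TRUE, pam = "TAC",
    stringsAsFactors = FALSE)
  ann <- annotate_distances(hits, ref)

  # cut site at 6000 (coding strand +): upstream negative, overlap zero
  expect_identical(ann$distance_to_target[1], -14L)
  expect_identical(ann$distance_to_target[2], 0L)
  expect_identical(ann$distance_to_target[3], 100L)
  expect_true(all(is.na(ann$distance_to_target[4:6])))

  # HEN site [2000, 2030): overlap 0; gap ends 121 nt before the site; far
  expect_identical(ann$distance_to_hen[4], 0L)
  expect_identical(ann$distance_to_hen[5], 121L)
  expect_identical(ann$distance_to_hen[6], 470L)
  expect_true(all(is.na(ann$distance_to_hen[1:3])))
})

test_that("source classification tabulates replicons and features", {
  cfg <- small_config(seed = 55, n_prespacers = 400, n_reads = 400,
                      w_target = 0, w_hotspot = 0.5, w_background = 0.5,
                      pam_modal_fraction = 0)
  ref <- make_reference(cfg)
  truth <- sample_prespacers(ref, cfg)
  hits <- truth_to_hits(truth)
  src <- classify_source(hits, ref)

  expect_identical(sum(src$replicons$spacers), nrow(truth))
  expect_equal(sum(src$replicons$fraction), 1)
  n_chr <- sum(truth$replicon == "chromosome")
  expect_identical(src$replicons$spacers[src$replicons$replicon == "chromosome"],
                   n_chr)
  # hotspot-component spacers overlap hotspot features
  hot_kinds <- src$features[src$features$kind %in%
                              c("transposase", "rRNA", "provirus"), ]
  expect_gte(sum(hot_kinds$spacers), sum(truth$component == "hotspot"))

  # all hits on one replicon -> other fraction zero
  chr_only <- hits[hits$replicon == "chromosome", ]
  src2 <- classify_source(chr_only, ref)
  expect_identical(src2$replicons$fraction[src2$replicons$replicon == "plasmid1"],
                   0)
})
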