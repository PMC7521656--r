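# Desk-scale simulation fixtures: a 20 kb chromosome + 8 kb plasmid with
# compact hotspot features, so whole-pipeline tests stay fast.
small_config <- function(seed = 1L, ...) {
  defaults <- list(chromosome_length = 20000L,
                   plasmid_lengths = 8000L,
                   n_transposase = 2L, n_rrna = 1L, n_provirus = 1L,
                   feature_lengths = c(transposase = 600L, rRNA = 800L,
                                       provirus = 1000L),
                   n_prespacers = 100L, n_reads = 1000L)
  args <- utils::modifyList(defaults, list(...))
  do.call(simulation_config, c(list(seed = seed), args))
}

# Hits drawn uniformly over the genome: the hotspot null model.
uniform_hits <- function(ref, n, seed) {
  set.seed(seed)
  L <- replicon_lengths(ref)
  nm <- sample(names(L), n, replace = TRUE, prob = L)
  start <- vapply(nm, function(r) sample.int(L[[r]] - 36L, 1L) - 1L,
                  integer(1))
  data.frame(spacer_id = sprintf("u%05d", seq_len(n)), replicon = nm,
             start = start, end = start + 36L,
             strand = sample(c("+", "-"), n, replace = TRUE),
             mismatches = 0L, unique = TRUE, pam = "TAC", reads = 1L,
             stringsAsFactors = FALSE)
}

# Reference with the target site centred, so the geometric tail of the
# distance decay is not clipped by a replicon edge.
centered_target_ref <- function(seed, L = 30000L, cut = 15000L) {
  set.seed(seed)
  reference_genome(
    c(chromosome = random_dna(L, 0.65)), circular = FALSE,
    features = data.frame(replicon = "chromosome", start = cut,
                          end = cut + 34L, strand = "+",
                          kind = "target_site", label = "target",
                          stringsAsFactors = FALSE))
}

# Independent brute-force Hamming mapper: scans every position of every
# replicon on both strands using integer vectors, honouring circularity by
# sequence extension. Used as the oracle for map_spacer().
brute_force_map <- function(spacer, ref, max_mm) {
  m <- nchar(spacer)
  out <- list()
  for (nm in names(ref$replicons)) {
    s <- ref$replicons[[nm]]
    L <- nchar(s)
    text <- if (ref$circular[[nm]]) paste0(s, substr(s, 1, m - 1)) else s
    ti <- utf8ToInt(text)
    n <- length(ti)
    if (n < m) next
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") spacer else haloadapt::revcomp(spacer)
      pi <- utf8ToInt(pat)
      mm <- integer(n - m + 1)
      for (j in seq_len(m))
        mm <- mm + (ti[j:(n - m + j)] != pi[j])
      hit <- which(mm <= max_mm)
      hit <- hit[hit <= L]            # starts must lie in [0, L)
      if (length(hit))
        out[[length(out) + 1L]] <-
          data.frame(replicon = nm, start = hit - 1L, end = hit - 1L + m,
                     strand = strand, mismatches = mm[hit],
                     stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(replicon = character(), start = integer(),
                      end = integer(), strand = character(),
                      mismatches = integer(), stringsAsFactors = FALSE))
  h <- do.call(rbind, out)
  h <- h[order(h$mismatches, h$replicon, h$start, h$strand), ]
  rownames(h) <- NULL
  h
}

# Independent Benjamini-Hochberg implementation (step-up from the largest
# p-value), used as the oracle for the hotspot q-values.
brute_force_bh <- function(p) {
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(n / (n:1) * p[o]))[ro]
  q
}

# Substitute `k` random positions of a string with a different base.
mutate_bases <- function(s, k) {
  b <- strsplit(s, "")[[1]]
  pos <- sample(length(b), k)
  for (p in pos) b[p] <- sample(setdiff(c("A", "C", "G", "T"), b[p]), 1)
  paste(b, collapse = "")
}
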