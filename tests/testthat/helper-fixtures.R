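# Small fixtures built in code, shared across test files.

toy_aln <- function() {
  mt_alignment(c(s1 = "ACGTACGT", s2 = "ACGAACGT", s3 = "ACTTACGA",
                 s4 = "ACGTACGA"))
}

# random gapless alignment over A/C/G/T
random_aln <- function(n, L, seed, gap_frac = 0, n_frac = 0) {
  set.seed(seed)
  m <- matrix(sample(c("A", "C", "G", "T"), n * L, replace = TRUE), n, L)
  if (gap_frac > 0) m[sample(length(m), gap_frac * length(m))] <- "-"
  if (n_frac > 0) m[sample(length(m), n_frac * length(m))] <- "N"
  mt_alignment(setNames(apply(m, 1, paste, collapse = ""),
                        paste0("t", seq_len(n))))
}

# brute-force p-distance oracle on two character vectors
oracle_pdist <- function(x, y) {
  cx <- strsplit(x, "")[[1]]; cy <- strsplit(y, "")[[1]]
  ok <- cx %in% c("A", "C", "G", "T") & cy %in% c("A", "C", "G", "T")
  sum(cx[ok] != cy[ok]) / sum(ok)
}

# a small simulated mosaic dataset used by several files (one 400-bp event)
small_mosaic <- function(seed = 11) {
  simulate_mosaic(sim_config(
    genome_length = 4000, n_species = 2,
    n_individuals_per_species = c(3, 1),
    interspecific_divergence = 0.08, intraspecific_divergence = 0.004,
    planted_events = data.frame(recipient = "A1", donor = "B",
                                start = 1500, length = 400, mutations = 2),
    seed = seed))
}
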