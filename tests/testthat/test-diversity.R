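test_that("p-distance counts differing comparable sites", {
  aln <- mt_alignment(c(a = "ACGT", b = "ACGA"))
  d <- p_distance(aln, "a", "b", se = "none")
  expect_equal(d$value, 0.25)
  expect_equal(d$n_sites, 4L)
  same <- mt_alignment(c(a = "ACGT", b = "ACGT"))
  d0 <- p_distance(same, "a", "b")
  expect_equal(d0$value, 0)
  expect_equal(d0$se, 0)
  gappy <- mt_alignment(c(a = "A-GTN", b = "ACGAC"))
  expect_equal(p_distance(gappy, "a", "b", se = "none")$n_sites, 3L)
  allgap <- mt_alignment(c(a = "---", b = "AAA"))
  expect_error(p_distance(allgap, "a", "b"), "comparable")
})

test_that("p-distance is symmetric, bounded, and matches a site oracle", {
  aln <- random_aln(5, 300, seed = 21, gap_frac = 0.05, n_frac = 0.03)
  for (i in 1:4) {
    d1 <- p_distance(aln, aln$ids[i], aln$ids[i + 1], se = "none")
    d2 <- p_distance(aln, aln$ids[i + 1], aln$ids[i], se = "none")
    expect_equal(d1$value, d2$value)
    expect_gte(d1$value, 0); expect_lte(d1$value, 1)
    expect_equal(d1$value, oracle_pdist(aln$seqs[i], aln$seqs[i + 1]))
  }
})

test_that("nucleotide diversity equals the hand-enumerated pair mean", {
  aln <- mt_alignment(c(a = "AAAA", b = "AAAT", c = "AATT"))
  expect_equal(nucleotide_diversity(aln, se = "none")$pi,
               (0.25 + 0.5 + 0.25) / 3)
  expect_equal(nucleotide_diversity(
    mt_alignment(c(a = "ACGT", b = "ACGT")), se = "none")$pi, 0)
})

test_that("diversity equals the mean of distance-matrix off-diagonals", {
  for (seed in c(31, 32, 33)) {
    aln <- random_aln(6, 250, seed, gap_frac = 0.04)
    pi_hat <- nucleotide_diversity(aln, se = "none")$pi
    dm <- distance_matrix(aln)$value
    expect_equal(pi_hat, mean(dm[upper.tri(dm)]), tolerance = 1e-12)
  }
})

test_that("bootstrap SEs are reproducible under a fixed seed", {
  aln <- random_aln(4, 400, seed = 41)
  d1 <- p_distance(aln, "t1", "t2", n_boot = 200, seed = 99)
  d2 <- p_distance(aln, "t1", "t2", n_boot = 200, seed = 99)
  expect_identical(d1$se, d2$se)
  expect_gt(d1$se, 0)
  pi1 <- nucleotide_diversity(aln, n_boot = 100, seed = 99)
  pi2 <- nucleotide_diversity(aln, n_boot = 100, seed = 99)
  expect_identical(pi1$se, pi2$se)
})

test_that("distance matrix matches an independent double loop", {
  aln <- random_aln(5, 180, seed = 51, gap_frac = 0.05)
  dm <- distance_matrix(aln)
  expect_equal(diag(dm$value), rep(0, 5), ignore_attr = TRUE)
  for (i in 1:4) for (j in (i + 1):5) {
    expect_equal(dm$value[i, j], oracle_pdist(aln$seqs[i], aln$seqs[j]))
    expect_equal(dm$value[j, i], dm$value[i, j])
  }
})

test_that("sliding windows follow the start/midpoint conventions", {
  aln <- random_aln(4, 260, seed = 61)
  pr <- sliding_profile(aln, "pi", window = 100, step = 25)
  expect_equal(pr$midpoint, seq(1, 161, by = 25) + 49)
  # direct recomputation per window
  for (w in seq_len(nrow(pr))) {
    s <- pr$midpoint[w] - 49
    expect_equal(pr$value[w],
                 nucleotide_diversity(extract_region(aln, region_spec(s, s + 99)),
                                      se = "none")$pi)
  }
  const <- mt_alignment(c(a = strrep("A", 120), b = strrep("A", 120)))
  expect_true(all(sliding_profile(const, "pi", 50, 10)$value == 0))
  expect_error(sliding_profile(aln, "pi", window = 500), "window")
})

test_that("windowed dxy, site-weighted over a tiling, recovers the global distance", {
  aln <- random_aln(2, 400, seed = 71)
  pr <- sliding_profile(aln, "dxy", window = 50, step = 50)
  d <- p_distance(aln, "t1", "t2", se = "none")$value
  expect_equal(sum(pr$value * pr$n_sites) / sum(pr$n_sites), d,
               tolerance = 1e-9)
})

test_that("all-gap windows are flagged and valued zero", {
  aln <- mt_alignment(c(a = paste0(strrep("-", 60), strrep("A", 60)),
                        b = paste0(strrep("-", 60), strrep("A", 60))))
  pr <- sliding_profile(aln, "pi", window = 30, step = 30)
  expect_true(all(pr$no_data[1:2]))
  expect_true(all(pr$value[pr$no_data] == 0))
})

test_that("HD detection recovers planted divergent blocks, none elsewhere", {
  # pairwise recombinant-vs-clean profiles: every planted 300-bp block at
  # 4.5% donor divergence yields a covering HD region and nothing is called
  # for the clean pair (20 seeded replicates)
  for (seed in 1:20) {
    sim <- simulate_mosaic(sim_config(
      genome_length = 6000, n_species = 2,
      n_individuals_per_species = c(3, 1),
      interspecific_divergence = 0.045, intraspecific_divergence = 0.003,
      planted_events = data.frame(recipient = "A1", donor = "B",
                                  start = 2501, length = 300, mutations = 0),
      seed = 200 + seed))
    hd <- detect_hd_regions_pairwise(sim$alignment, c("A1", "A2"))
    overlaps <- hd$start <= 2800 & hd$end >= 2501
    expect_gte(sum(overlaps), 1L)
    expect_equal(sum(!overlaps), 0L)  # no false regions
    peak <- hd$peak_midpoint[which(overlaps)[1]]
    expect_gte(peak, 2451); expect_lte(peak, 2850)
    clean <- detect_hd_regions_pairwise(sim$alignment, c("A2", "A3"))
    expect_equal(nrow(clean), 0L)
  }
})

test_that("HD run-length and merge rules behave as specified", {
  mk_profile <- function(values) {
    structure(data.frame(midpoint = seq_along(values) * 25 + 24,
                         value = values,
                         n_sites = 100, no_data = FALSE),
              window = 50, step = 25,
              class = c("sliding_profile", "data.frame"))
  }
  flat <- mk_profile(rep(0.001, 40))
  expect_equal(nrow(detect_hd_regions(flat)), 0L)
  zero <- mk_profile(rep(0, 40))
  expect_equal(nrow(detect_hd_regions(zero)), 0L)
  lone <- mk_profile(c(rep(0.001, 20), 0.3, rep(0.001, 19)))
  expect_equal(nrow(detect_hd_regions(lone, min_windows = 2)), 0L)
  # a 1-window gap inside a run is bridged
  gap <- mk_profile(c(rep(0.001, 10), 0.3, 0.3, 0.001, 0.3, rep(0.001, 26)))
  expect_equal(nrow(detect_hd_regions(gap, min_windows = 3)), 1L)
})

test_that("neighbor joining recovers random additive trees", {
  for (seed in c(5, 6, 7)) {
    set.seed(seed)
    tr <- ape::rtree(7)
    nw <- nj_tree(stats::cophenetic(tr))
    expect_equal(ape::dist.topo(ape::unroot(tr),
                                ape::unroot(attr(nw, "phylo"))), 0,
                 ignore_attr = TRUE)
    expect_true(is.character(nw) && grepl(";$", nw))
  }
  expect_error(nj_tree(matrix(0, 2, 2, dimnames = list(c("a", "b"),
                                                       c("a", "b")))),
               "3 taxa")
})

test_that("HD-region trees show the recombinant grouping with the donor", {
  sim <- small_mosaic(seed = 12)
  frag <- extract_region(sim$alignment, region_spec(1500, 1899))
  nw <- nj_tree(distance_matrix(frag))
  tr <- attr(nw, "phylo")
  # A1 carries the B fragment: its closest leaf in the fragment tree is B1
  d <- ape::cophenetic.phylo(tr)
  expect_equal(names(which.min(d["A1", colnames(d) != "A1"])), "B1")
  # whole-genome tree keeps A1 with its conspecifics
  nw2 <- nj_tree(distance_matrix(delete_regions(sim$alignment,
                                                region_spec(1500, 1899))))
  d2 <- ape::cophenetic.phylo(attr(nw2, "phylo"))
  expect_true(names(which.min(d2["A1", colnames(d2) != "A1"])) %in%
                c("A2", "A3"))
})
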