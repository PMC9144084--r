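# brute-force four-gamete check used as the oracle in several tests
oracle_incompatible <- function(p1, p2) {
  ok <- !is.na(p1) & !is.na(p2)
  combos <- unique(paste(p1[ok], p2[ok]))
  length(combos) == 4L
}

test_that("informative sites match a per-column counting oracle", {
  aln <- mt_alignment(c(a = "AAAA", b = "AAAA", c = "AACA", d = "AACA"))
  expect_equal(informative_sites(aln)$columns, 3L)
  same <- mt_alignment(c(a = "ACGT", b = "ACGT", c = "ACGT", d = "ACGT"))
  expect_length(informative_sites(same)$columns, 0L)
  aln2 <- random_aln(6, 200, seed = 81, gap_frac = 0.05, n_frac = 0.05)
  m <- as.matrix(aln2)
  oracle <- which(vapply(seq_len(200), function(j) {
    b <- m[, j]; b <- b[b %in% c("A", "C", "G", "T")]
    sum(table(b) >= 2) >= 2
  }, TRUE))
  expect_equal(informative_sites(aln2)$columns, oracle)
})

test_that("PHI is null on a perfect phylogeny and flags uninformative input", {
  # clonal, homoplasy-free: every mutation on one internal edge
  base <- strrep("A", 60)
  put <- function(s, cols, ch) {
    v <- strsplit(s, "")[[1]]; v[cols] <- ch; paste(v, collapse = "")
  }
  seqs <- rep(base, 8)
  seqs[1:4] <- vapply(seqs[1:4], put, "", cols = c(5, 15, 25), ch = "C")
  seqs[1:2] <- vapply(seqs[1:2], put, "", cols = c(8, 18), ch = "G")
  seqs[5:6] <- vapply(seqs[5:6], put, "", cols = c(11, 21), ch = "T")
  aln <- mt_alignment(setNames(seqs, paste0("s", 1:8)))
  ph <- phi_test(aln, w = 60, n_permutations = 500, seed = 1)
  expect_true(ph$computable)
  expect_equal(ph$statistic, 0)
  expect_equal(ph$p_value, 1)
  # star tree with strictly private mutations has no informative sites
  star <- mt_alignment(setNames(vapply(1:5, function(i) {
    put(base, i * 7, "G")
  }, ""), paste0("t", 1:5)))
  expect_false(phi_test(star, n_permutations = 10)$computable)
})

test_that("PHI statistic is invariant to row order and state relabeling", {
  sim <- small_mosaic(seed = 13)
  aln <- sim$alignment
  ph <- phi_test(aln, n_permutations = 200, seed = 5)
  shuffled <- subset_alignment(aln, rev(aln$ids))
  ph2 <- phi_test(shuffled, n_permutations = 200, seed = 5)
  expect_equal(ph2$statistic, ph$statistic)
  relab <- mt_alignment(setNames(chartr("ACGT", "GTAC", aln$seqs), aln$ids))
  ph3 <- phi_test(relab, n_permutations = 200, seed = 5)
  expect_equal(ph3$statistic, ph$statistic)
})

test_that("PHI matches exhaustive enumeration on a six-site toy", {
  # 4 sequences, 6 informative columns at positions spread so that the
  # window matters; patterns chosen to mix compatible and incompatible pairs
  pats <- list(c("A", "A", "C", "C"), c("A", "C", "A", "C"),
               c("A", "A", "C", "C"), c("A", "C", "C", "A"),
               c("C", "C", "A", "A"), c("A", "C", "A", "C"))
  pos <- c(2, 6, 10, 14, 18, 22)
  L <- 24
  m <- matrix("G", 4, L)
  for (j in seq_along(pos)) m[, pos[j]] <- pats[[j]]
  aln <- mt_alignment(setNames(apply(m, 1, paste, collapse = ""),
                               paste0("s", 1:4)))
  w <- 8
  ph <- phi_test(aln, w = w, n_permutations = 2000, seed = 3)
  # oracle: mean incompatibility over nearby pairs, direct enumeration
  near <- which(outer(pos, pos, function(a, b) b - a) <= w &
                  upper.tri(diag(6)), arr.ind = TRUE)
  obs <- mean(apply(near, 1, function(ij) {
    oracle_incompatible(pats[[ij[1]]], pats[[ij[2]]])
  }))
  expect_equal(ph$statistic, obs)
  # exhaustive permutation distribution over all 6! site orders
  perms <- as.matrix(expand.grid(rep(list(1:6), 6)))
  perms <- perms[apply(perms, 1, function(x) length(unique(x)) == 6L), ]
  stats <- apply(perms, 1, function(sigma) {
    mean(apply(near, 1, function(ij) {
      oracle_incompatible(pats[[sigma[ij[1]]]], pats[[sigma[ij[2]]]])
    }))
  })
  p_exact <- mean(stats <= obs + 1e-12)
  se <- sqrt(p_exact * (1 - p_exact) / 2000)
  expect_lt(abs(ph$p_value - p_exact), 3 * se + 1 / 2000)
})

test_that("MaxChi is exact on the hand-built step pattern", {
  a <- strrep("A", 60)
  b <- paste0(strrep("A", 30), strrep("C", 30))
  aln <- mt_alignment(c(x = a, y = b))
  mc <- maxchi_scan(aln, "x", "y", k = 15, n_permutations = 200, seed = 2)
  expect_equal(mc$max_chi, 30)
  expect_equal(mc$best_breakpoint, 30L)
  expect_lt(mc$p_value, 0.05)
})

test_that("MaxChi permutation p agrees with exhaustive enumeration on a tiny toy", {
  # 8 comparable sites, 3 mismatches: enumerate all C(8,3) arrangements
  y_obs <- c(0L, 0L, 0L, 0L, 0L, 1L, 1L, 1L)
  a <- strrep("A", 8)
  b <- paste(ifelse(y_obs == 1L, "C", "A"), collapse = "")
  aln <- mt_alignment(c(x = a, y = b))
  k <- 2
  max_chi_of <- function(y) {
    n <- length(y); s <- cumsum(y)
    t <- k:(n - k)
    L1 <- s[t] - c(0L, s)[t - k + 1L]; R1 <- s[t + k] - s[t]
    aa <- k - L1; bb <- L1; cc <- k - R1; dd <- R1
    num <- 2 * k * (aa * dd - bb * cc)^2
    den <- as.numeric(k) * k * (aa + cc) * (bb + dd)
    max(ifelse(den > 0, num / den, 0))
  }
  obs <- max_chi_of(y_obs)
  combos <- utils::combn(8, 3)
  exact <- mean(apply(combos, 2, function(ix) {
    y <- integer(8); y[ix] <- 1L
    max_chi_of(y) >= obs - 1e-12
  }))
  mc <- maxchi_scan(aln, "x", "y", k = k, n_permutations = 2000, seed = 4)
  expect_equal(mc$max_chi, obs)
  se <- sqrt(exact * (1 - exact) / 2000)
  expect_lt(abs(mc$p_value - exact), 3 * se + 1 / 2000)
})

test_that("MaxChi flags homogeneous and undersized inputs", {
  set.seed(17)
  a <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  v <- strsplit(a, "")[[1]]
  flip <- sample(400, 20)  # uniform noise, no breakpoint
  v[flip] <- chartr("ACGT", "CAGT", v[flip])
  aln <- mt_alignment(c(x = a, y = paste(v, collapse = "")))
  mc <- maxchi_scan(aln, "x", "y", k = 30, n_permutations = 300, seed = 6)
  expect_gt(mc$p_value, 0.05)
  tiny <- mt_alignment(c(x = "ACGTACGT", y = "ACGTACGA"))
  expect_false(maxchi_scan(tiny, "x", "y", k = 30)$computable)
})

test_that("triplet scan calls sides correctly and finds planted runs", {
  sim <- small_mosaic(seed = 14)
  aln <- sim$alignment
  ts <- triplet_scan(aln, "A1", "A2", "B1")
  expect_equal(nrow(ts$segments), 1L)
  expect_lt(ts$segments$begin[1], 1900)  # overlaps planted 1500-1899
  expect_gt(ts$segments$end[1], 1500)
  # candidate identical to parent A -> never strictly closer to B
  ident <- mt_alignment(c(cand = aln$seqs[1], pa = aln$seqs[1],
                          pb = aln$seqs[4]))
  ts2 <- triplet_scan(ident, "cand", "pa", "pb")
  expect_true(all(ts2$windows$call %in% c("A", "tie")))
  expect_equal(nrow(ts2$segments), 0L)
  expect_error(triplet_scan(aln, "A1", "A1", "B1"), "distinct")
})

test_that("Bonferroni correction clamps at one", {
  expect_equal(bonferroni(0.01, 1), 0.01)
  expect_equal(bonferroni(0.01, 200), 1)
  expect_equal(bonferroni(2.2e-16, 6), 1.32e-15)
  expect_error(bonferroni(0, 3))
})

test_that("call_events recovers a planted fragment with nearby breakpoints", {
  sim <- small_mosaic(seed = 15)
  ev <- call_events(sim$alignment, c("A1", "A2", "A3"), sim$groups,
                    maxchi_permutations = 300, phi_permutations = 300,
                    seed = 15)
  expect_equal(unique(ev$recombinant), "A1")
  expect_equal(unique(ev$minor_parent), "B1")
  tr <- sim$truth$events
  expect_lte(abs(ev$breakpoint_begin[1] - tr$begin[1]), 50)
  expect_lte(abs(ev$breakpoint_end[1] - tr$end[1]), 50)
  expect_equal(ev$mismatches[1], 2L)
  # definitional: candidate is closer to minor than major inside segment
  m <- as.matrix(sim$alignment)
  seg <- ev$begin[1]:ev$end[1]
  d_minor <- mean(m["A1", seg] != m[ev$minor_parent[1], seg])
  d_major <- mean(m["A1", seg] != m[ev$major_parent[1], seg])
  expect_lt(d_minor, d_major)
})

test_that("call_events is quiet on recombination-free data", {
  n_called <- 0L
  for (seed in 1:10) {
    sim <- simulate_mosaic(sim_config(
      genome_length = 5000, n_species = 2,
      n_individuals_per_species = c(3, 1),
      interspecific_divergence = 0.08, intraspecific_divergence = 0.004,
      seed = 700 + seed))
    ev <- call_events(sim$alignment, c("A1", "A2", "A3"), sim$groups,
                      maxchi_permutations = 200, phi_permutations = 200,
                      seed = seed)
    n_called <- n_called + nrow(ev)
  }
  expect_lte(n_called, 1L)  # at most one false call across ten null sets
})

test_that("call_events validates its reference configuration", {
  sim <- small_mosaic(seed = 16)
  only_a <- sim$groups[startsWith(names(sim$groups), "A")]
  expect_error(call_events(sim$alignment, "A1", only_a, seed = 1),
               "other than")
  expect_error(call_events(sim$alignment, c("Z9"), sim$groups, seed = 1),
               "Z9")
})
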