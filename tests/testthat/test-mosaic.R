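fake_event <- function(recombinant, begin, end, p, minor = "B1",
                       major = "A2", mm = 0L) {
  data.frame(recombinant = recombinant, major_parent = major,
             minor_parent = minor, begin = begin, end = end,
             breakpoint_begin = begin, breakpoint_end = end,
             span = end - begin + 1L, ungapped_length = end - begin + 1L,
             p_maxchi_begin = p, p_maxchi_end = p, p_phi = p,
             p_value = p, p_corrected = p, mismatches = mm)
}

test_that("mosaic annotation orders events and resolves overlaps", {
  ev <- rbind(fake_event("g1", 500, 900, 0.01),
              fake_event("g1", 100, 200, 0.02),
              fake_event("g1", 850, 1200, 0.001))
  ann <- annotate_mosaic(ev, "g1")
  expect_equal(nrow(ann$events), 2L)          # 500-900 lost to 850-1200
  expect_equal(ann$events$begin, c(100, 850)) # sorted by begin
  expect_length(ann$notes, 1L)
  expect_match(ann$notes, "500-900")
  empty <- annotate_mosaic(fake_event("g1", 1, 2, 1)[0, ], "g1")
  expect_equal(nrow(empty$events), 0L)
  expect_error(annotate_mosaic(fake_event("g2", 1, 5, 0.01), "g1"),
               "g2")
})

test_that("fragment mismatch counts, positions and recency calls agree with truth", {
  sim <- simulate_mosaic(sim_config(
    genome_length = 4000, n_species = 2,
    n_individuals_per_species = c(3, 1),
    interspecific_divergence = 0.08, intraspecific_divergence = 0.004,
    planted_events = data.frame(
      recipient = c("A1", "A2"), donor = "B",
      start = c(1000, 2500), length = c(400, 500), mutations = c(3, 0)),
    seed = 31))
  tr <- sim$truth$events
  rc1 <- count_fragment_mismatches(sim$alignment, list(
    recombinant = "A1", minor_parent = "B1",
    begin = tr$begin[1], end = tr$end[1]))
  expect_equal(rc1$mismatches, 3L)
  expect_equal(rc1$call, "diverged")
  expect_equal(rc1$positions, sim$truth$mutation_positions[[1]])
  rc2 <- count_fragment_mismatches(sim$alignment, list(
    recombinant = "A2", minor_parent = "B1",
    begin = tr$begin[2], end = tr$end[2]))
  expect_equal(rc2$mismatches, 0L)
  expect_equal(rc2$call, "identical")
})

test_that("markers flag exact-copy fragments as diagnostic", {
  sim <- simulate_mosaic(sim_config(
    genome_length = 4000, n_species = 2,
    n_individuals_per_species = c(3, 1),
    interspecific_divergence = 0.08, intraspecific_divergence = 0.004,
    planted_events = data.frame(
      recipient = c("A1", "A1"), donor = "B",
      start = c(800, 2600), length = c(400, 400), mutations = c(0, 4)),
    seed = 32))
  tr <- sim$truth$events
  ev <- rbind(fake_event("A1", tr$begin[1], tr$end[1], 0.001),
              fake_event("A1", tr$begin[2], tr$end[2], 0.001))
  ann <- annotate_mosaic(ev, "A1")
  mk <- extract_markers(list(ann), sim$alignment)
  expect_equal(nrow(mk), 2L)
  expect_true(mk$diagnostic_identical[1])
  expect_equal(mk$identity_fraction[1], 1)
  expect_false(mk$diagnostic_identical[2])
  expect_lt(mk$identity_fraction[2], 1)
  expect_equal(nrow(extract_markers(list(annotate_mosaic(ev[0, ], "A1")),
                                    sim$alignment)), 0L)
})

test_that("markers are consistent with mismatch counting", {
  sim <- small_mosaic(seed = 33)
  scan <- recombination_scan(sim$alignment, c("A1", "A2", "A3"), sim$groups,
                             phi_permutations = 300,
                             event_phi_permutations = 300,
                             maxchi_permutations = 300, seed = 33)
  expect_equal(nrow(scan$markers), 1L)
  # the planted fragment carries 2 post-transfer mutations: diverged,
  # and the identity fraction must agree with the mismatch count
  expect_false(scan$markers$diagnostic_identical[1])
  rc <- count_fragment_mismatches(sim$alignment, list(
    recombinant = scan$markers$recombinant_id[1],
    minor_parent = scan$markers$minor_parent_id[1],
    begin = scan$markers$start[1], end = scan$markers$end[1]))
  expect_gt(rc$mismatches, 0L)
  span <- scan$markers$end[1] - scan$markers$start[1] + 1  # gapless fixture
  expect_equal(scan$markers$identity_fraction[1],
               1 - rc$mismatches / span)
  expect_equal(length(scan$recency), 1L)
  expect_equal(scan$recency[[1]]$call, "diverged")
})

test_that("the pipeline writes a complete, deterministic report bundle", {
  sim <- small_mosaic(seed = 34)
  d1 <- tempfile(); d2 <- tempfile()
  cfgargs <- list(phi_permutations = 300, event_phi_permutations = 300,
                  maxchi_permutations = 300, seed = 34, bed = TRUE)
  s1 <- do.call(run_pipeline, c(list(sim$alignment, c("A1", "A2", "A3"),
                                     sim$groups, d1), cfgargs))
  s2 <- do.call(run_pipeline, c(list(sim$alignment, c("A1", "A2", "A3"),
                                     sim$groups, d2), cfgargs))
  files <- c("profile.tsv", "hd_regions.tsv", "distances.tsv", "tree.nwk",
             "events.tsv", "markers.tsv", "report.json", "run.log")
  for (f in files) expect_true(file.exists(file.path(d1, f)), label = f)
  # byte-identical reports under a fixed seed
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  # report JSON round-trips through a parse
  rep1 <- jsonlite::fromJSON(file.path(d1, "report.json"))
  expect_equal(rep1$alignment_length, 4000)
  expect_equal(sort(names(rep1$groups)), sort(names(sim$groups)))
  # the planted event shows up once in the annotation of A1
  expect_equal(rep1$annotations$A1$n_events, 1L)
  expect_equal(nrow(s1$events), nrow(s2$events))
})

test_that("pipeline accepts file inputs and rejects missing groups", {
  sim <- small_mosaic(seed = 35)
  fa <- tempfile(fileext = ".fa"); write_fasta(sim$alignment, fa)
  gf <- tempfile()
  write.table(data.frame(names(sim$groups), unname(sim$groups)), gf,
              sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  d <- tempfile()
  s <- run_pipeline(fa, c("A1", "A2", "A3"), gf, d,
                    phi_permutations = 200, event_phi_permutations = 200,
                    maxchi_permutations = 200, seed = 35)
  expect_s3_class(s, "mtscan")
  expect_error(recombination_scan(sim$alignment, "nope", sim$groups),
               "nope")
})

test_that("scan object prints and plots without error", {
  sim <- small_mosaic(seed = 36)
  scan <- recombination_scan(sim$alignment, c("A1", "A2", "A3"), sim$groups,
                             phi_permutations = 200,
                             event_phi_permutations = 200,
                             maxchi_permutations = 200, seed = 36)
  expect_output(print(scan), "recombination events")
  expect_output(summary(scan), "High-divergence")
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(scan))
})
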