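#' Scan an alignment for interspecific mitochondrial recombination
#'
#' The package's main entry point: runs the whole analysis on an aligned set
#' of candidate genomes and reference genomes from related species, and
#' returns one classed object holding every stage's result.
#'
#' Stages, in order: (1) sliding-window nucleotide diversity over the
#' candidate genomes (kept for plotting and summaries); (2) detection of
#' high-divergence (HD) regions from the pairwise candidate profiles
#' (\code{\link{detect_hd_regions_pairwise}}, which sees each fragment at
#' its undiluted pair divergence); (3) a global PHI permutation test over
#' all sequences;
#' (4) recombination-event calling (triplet closer-parent scan, refinement to
#' donor-matching variable sites, MaxChi flank tests, per-segment PHI,
#' Bonferroni correction); (5) per-genome mosaic annotation; (6) recency
#' classification of each fragment by recombinant-vs-donor mismatch count;
#' (7) diagnostic-marker extraction.
#'
#' @param aln an \code{mt_alignment} containing candidates and references.
#' @param candidates ids of the genomes tested for recombination.
#' @param groups named character vector mapping every id to a group (species)
#'   label; same-group sequences act as potential major parents, other-group
#'   sequences as potential minor parents.
#' @param window,step sliding-window geometry in columns (defaults 100 / 25).
#' @param fold_threshold,absolute_floor,min_windows HD-region detection
#'   parameters, see \code{\link{detect_hd_regions_pairwise}}.
#' @param phi_w PHI nearby-pair window (default 100).
#' @param phi_permutations permutations for the global PHI test (default
#'   10000; raise to 100000 to resolve p below 1e-5).
#' @param event_phi_permutations,maxchi_permutations permutation counts for
#'   the per-event tests (defaults 1000).
#' @param k MaxChi half-window in sites (default 30).
#' @param flank half-width in columns of the MaxChi flank regions (default 500).
#' @param alpha significance level on corrected p-values (default 0.05).
#' @param seed RNG seed governing every permutation test.
#' @return An object of class \code{mtscan}: list with \code{profile},
#'   \code{hd_regions}, \code{phi}, \code{events}, \code{annotations} (one
#'   \code{mosaic_annotation} per candidate), \code{recency} (list of
#'   \code{recency_call}s), \code{markers}, \code{candidates}, \code{groups},
#'   \code{config} and \code{call}.
#' @seealso \code{\link{run_pipeline}} for the file-writing wrapper,
#'   \code{\link{simulate_mosaic}} for generating test data.
#' @examples
#' sim <- simulate_mosaic(sim_config(
#'   genome_length = 2000, n_individuals = c(3, 1),
#'   interspecific_divergence = 0.08,
#'   planted_events = data.frame(recipient = "A1", donor = "B",
#'                               start = 500, length = 400, mutations = 1),
#'   seed = 7))
#' scan <- recombination_scan(sim$alignment, candidates = c("A1", "A2", "A3"),
#'                            groups = sim$groups, phi_permutations = 200,
#'                            event_phi_permutations = 200,
#'                            maxchi_permutations = 200, seed = 7)
#' scan$events[, c("recombinant", "minor_parent", "begin", "end")]
#' @export
recombination_scan <- function(aln, candidates, groups,
                               window = 100L, step = 25L,
                               fold_threshold = 5, absolute_floor = 0.03,
                               min_windows = 4L, phi_w = 100L,
                               phi_permutations = 10000L,
                               event_phi_permutations = 1000L,
                               maxchi_permutations = 1000L,
                               k = 30L, flank = 500L,
                               alpha = 0.05, seed = 1L) {
  stopifnot(inherits(aln, "mt_alignment"))
  missing_ids <- setdiff(c(candidates, names(groups)), aln$ids)
  if (length(missing_ids)) {
    stop("ids not in alignment: ", paste(missing_ids, collapse = ", "))
  }
  config <- list(window = window, step = step,
                 fold_threshold = fold_threshold,
                 absolute_floor = absolute_floor, min_windows = min_windows,
                 phi_w = phi_w, phi_permutations = phi_permutations,
                 event_phi_permutations = event_phi_permutations,
                 maxchi_permutations = maxchi_permutations, k = k,
                 flank = flank, alpha = alpha, seed = seed)
  profile <- sliding_profile(aln, "pi", window = window, step = step,
                             ids = candidates)
  hd <- detect_hd_regions_pairwise(aln, ids = candidates, window = window,
                                   step = step,
                                   fold_threshold = fold_threshold,
                                   absolute_floor = absolute_floor,
                                   min_windows = min_windows)
  phi <- phi_test(subset_alignment(aln, names(groups)), w = phi_w,
                  n_permutations = phi_permutations, seed = seed)
  events <- call_events(aln, candidates, groups, window = window,
                        step = step, k = k, flank = flank,
                        maxchi_permutations = maxchi_permutations,
                        phi_permutations = event_phi_permutations,
                        phi_w = phi_w, alpha = alpha, seed = seed)
  annotations <- lapply(candidates, function(cand) {
    ev <- events[events$recombinant == cand, , drop = FALSE]
    annotate_mosaic(ev, cand)
  })
  names(annotations) <- candidates
  merged <- do.call(rbind, lapply(annotations, function(a) a$events))
  recency <- if (!is.null(merged) && nrow(merged)) {
    lapply(seq_len(nrow(merged)),
           function(i) count_fragment_mismatches(aln, merged[i, ]))
  } else list()
  markers <- extract_markers(annotations, aln)
  structure(list(profile = profile, hd_regions = hd, phi = phi,
                 events = events, annotations = annotations,
                 recency = recency, markers = markers,
                 candidates = candidates, groups = groups,
                 config = config, alignment = aln,
                 call = match.call()),
            class = "mtscan")
}

#' @export
print.mtscan <- function(x, ...) {
  cat("Mitochondrial recombination scan\n")
  cat(sprintf("  %d sequences x %d columns; %d candidate genome(s)\n",
              length(x$alignment$ids), x$alignment$length,
              length(x$candidates)))
  cat(sprintf("  HD regions: %d\n", nrow(x$hd_regions)))
  if (x$phi$computable) {
    cat(sprintf("  global PHI: statistic %.4f, p = %.3g\n",
                x$phi$statistic, x$phi$p_value))
  } else {
    cat("  global PHI: not computable\n")
  }
  n_merged <- sum(vapply(x$annotations, function(a) nrow(a$events), 0L))
  cat(sprintf("  recombination events: %d (%d significant tests of %d, alpha = %g)\n",
              n_merged, nrow(x$events), attr(x$events, "n_tests"),
              x$config$alpha))
  if (length(x$recency)) {
    ident <- sum(vapply(x$recency, function(r) r$call == "identical", TRUE))
    cat(sprintf("  fragment recency: %d identical, %d diverged\n",
                ident, length(x$recency) - ident))
  }
  invisible(x)
}

#' @export
summary.mtscan <- function(object, ...) {
  x <- object
  print(x)
  if (nrow(x$hd_regions)) {
    cat("\nHigh-divergence regions:\n")
    print(as.data.frame(x$hd_regions))
  }
  if (nrow(x$events)) {
    cat("\nEvents:\n")
    print(as.data.frame(x$events)[, c("recombinant", "major_parent",
                                      "minor_parent", "begin", "end",
                                      "p_corrected", "mismatches")])
  }
  if (nrow(x$markers)) {
    cat("\nDiagnostic markers:\n")
    print(as.data.frame(x$markers)[, c("label", "minor_parent_id",
                                       "identity_fraction",
                                       "diagnostic_identical")])
  }
  invisible(x)
}

#' Plot a recombination scan
#'
#' Base-graphics view of the sliding diversity profile with HD regions
#' shaded and called event intervals marked under the axis.
#'
#' @param x an \code{mtscan} object.
#' @param ... passed to \code{plot.default}.
#' @export
plot.mtscan <- function(x, ...) {
  pr <- x$profile
  graphics::plot(pr$midpoint, pr$value, type = "l",
                 xlab = "alignment position (midpoint)",
                 ylab = attr(pr, "stat"), ...)
  if (nrow(x$hd_regions)) {
    for (i in seq_len(nrow(x$hd_regions))) {
      graphics::rect(x$hd_regions$start[i], 0, x$hd_regions$end[i],
                     max(pr$value), col = grDevices::adjustcolor("red", 0.15),
                     border = NA)
    }
  }
  if (nrow(x$events)) {
    graphics::segments(x$events$begin, 0, x$events$end, 0,
                       lwd = 4, col = "black")
  }
  invisible(x)
}

scan_report <- function(scan) {
  list(
    config = scan$config,
    n_sequences = length(scan$alignment$ids),
    alignment_length = scan$alignment$length,
    candidates = scan$candidates,
    groups = as.list(scan$groups),
    pi = nucleotide_diversity(subset_alignment(scan$alignment,
                                               scan$candidates),
                              se = "none")$pi,
    hd_regions = as.data.frame(scan$hd_regions),
    phi = scan$phi[c("statistic", "p_value", "n_informative",
                     "n_permutations", "seed", "computable")],
    n_tests = attr(scan$events, "n_tests"),
    events = as.data.frame(scan$events),
    annotations = lapply(scan$annotations, function(a) {
      list(genome_id = a$genome_id, backbone_id = a$backbone_id,
           n_events = nrow(a$events), events = as.data.frame(a$events),
           notes = a$notes)
    }),
    recency = lapply(scan$recency, function(r) {
      list(recombinant = r$event$recombinant,
           minor_parent = r$event$minor_parent,
           begin = r$event$begin, end = r$event$end,
           mismatches = r$mismatches, positions = r$positions,
           call = r$call)
    }),
    markers = as.data.frame(scan$markers)
  )
}

#' Run the full pipeline and write its outputs
#'
#' Thin orchestration over \code{\link{recombination_scan}}: reads the
#' alignment (if given as a path), runs the scan, and writes the profile, HD
#' regions, distance matrix, neighbor-joining tree, event table, markers, a
#' machine-readable JSON report and a run log to \code{out_dir}. Given fixed
#' inputs, configuration and seed, two runs produce byte-identical reports.
#'
#' @param aln an \code{mt_alignment} or a path to an aligned FASTA file.
#' @param candidates candidate genome ids.
#' @param groups named character vector id -> group, or a path to a
#'   two-column tab-separated file (id, group).
#' @param out_dir output directory (created if needed).
#' @param ... configuration passed to \code{\link{recombination_scan}}.
#' @param bed also write the HD regions as a BED-like 0-based half-open file.
#' @return The \code{mtscan} object, invisibly.
#' @export
run_pipeline <- function(aln, candidates, groups, out_dir, ..., bed = FALSE) {
  if (is.character(aln)) aln <- read_fasta(aln)
  if (is.character(groups) && length(groups) == 1L && file.exists(groups)) {
    gdf <- read.table(groups, sep = "\t", header = FALSE,
                      col.names = c("id", "group"),
                      stringsAsFactors = FALSE)
    groups <- setNames(gdf$group, gdf$id)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  scan <- recombination_scan(aln, candidates, groups, ...)
  write_profile(scan$profile, file.path(out_dir, "profile.tsv"))
  write.table(as.data.frame(scan$hd_regions),
              file.path(out_dir, "hd_regions.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (bed) {
    regs <- lapply(seq_len(nrow(scan$hd_regions)), function(i)
      region_spec(scan$hd_regions$start[i], scan$hd_regions$end[i],
                  sprintf("HD%d", i)))
    write_regions(regs, file.path(out_dir, "hd_regions.bed"), bed = TRUE)
  }
  dm <- distance_matrix(aln, se = "none")
  write_distance_matrix(dm, file.path(out_dir, "distances.tsv"))
  if (length(aln$ids) >= 3L) {
    writeLines(nj_tree(dm), file.path(out_dir, "tree.nwk"))
  }
  write_events(scan$events, file.path(out_dir, "events.tsv"))
  write.table(as.data.frame(scan$markers),
              file.path(out_dir, "markers.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  report <- scan_report(scan)
  writeLines(jsonlite::toJSON(report, auto_unbox = TRUE, digits = 10,
                              pretty = TRUE, null = "null"),
             file.path(out_dir, "report.json"))
  log <- c(
    sprintf("mtmosaic run: %d sequences x %d columns",
            length(aln$ids), aln$length),
    sprintf("candidates: %s", paste(candidates, collapse = ", ")),
    sprintf("config: %s", paste(sprintf("%s=%s", names(scan$config),
                                        unlist(scan$config)),
                                collapse = " ")),
    sprintf("hd_regions: %d", nrow(scan$hd_regions)),
    sprintf("events: %d (of %d tests)", nrow(scan$events),
            attr(scan$events, "n_tests")),
    sprintf("markers: %d (%d diagnostic-identical)", nrow(scan$markers),
            sum(scan$markers$diagnostic_identical)))
  writeLines(log, file.path(out_dir, "run.log"))
  invisible(scan)
}
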