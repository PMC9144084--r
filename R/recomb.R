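#' Parsimony-informative sites of an alignment
#'
#' A column is parsimony-informative when, after excluding gaps and N, it
#' carries at least two states each present in at least two sequences.
#' These columns are the substrate of the PHI test.
#'
#' @param aln an \code{mt_alignment}.
#' @return A list of class \code{informative_sites}: \code{columns} (1-based
#'   alignment columns, increasing), \code{states} (character matrix,
#'   sequences x informative columns, gaps/N as NA), \code{ids}.
#' @export
informative_sites <- function(aln) {
  m <- as.matrix(aln)
  m[!(m %in% BASES)] <- NA_character_
  keep <- vapply(seq_len(ncol(m)), function(j) {
    tab <- table(m[, j])
    sum(tab >= 2L) >= 2L
  }, TRUE)
  cols <- which(keep)
  structure(list(columns = cols,
                 states = m[, cols, drop = FALSE],
                 ids = aln$ids),
            class = "informative_sites")
}

# Binarize informative columns to their two most frequent states (ties broken
# alphabetically for determinism); rows carrying other states or missing data
# become NA for that column.
binarize_sites <- function(info) {
  st <- info$states
  out <- matrix(NA_integer_, nrow = ncol(st), ncol = nrow(st))  # sites x seqs
  for (j in seq_len(ncol(st))) {
    tab <- sort(table(st[, j]), decreasing = TRUE)
    nm <- names(tab)
    # stable order: count desc, then alphabet
    nm <- nm[order(-as.integer(tab), nm)]
    major <- nm[1L]; minor <- nm[2L]
    x <- rep(NA_integer_, nrow(st))
    x[st[, j] == major] <- 0L
    x[st[, j] == minor] <- 1L
    out[j, ] <- x
  }
  out
}

# Pairwise four-gamete incompatibility among binarized sites: entry (i, j) is
# 1 when all four haplotype combinations occur among sequences observed at
# both sites.
incompatibility_matrix <- function(x) {
  A0 <- x == 0L; A0[is.na(A0)] <- FALSE; storage.mode(A0) <- "double"
  A1 <- x == 1L; A1[is.na(A1)] <- FALSE; storage.mode(A1) <- "double"
  M00 <- tcrossprod(A0) > 0
  M01 <- A0 %*% t(A1) > 0
  M11 <- tcrossprod(A1) > 0
  inc <- M00 & M01 & t(M01) & M11
  storage.mode(inc) <- "integer"
  inc
}

#' Pairwise homoplasy index (PHI) permutation test for recombination
#'
#' Informative columns are binarized to their two most frequent states; for
#' every pair of informative columns at alignment distance at most \code{w},
#' incompatibility is 1 when the pair violates the four-gamete condition.
#' The statistic is the mean incompatibility over those nearby pairs. Under
#' clonal evolution homoplasy is position-independent, so the null is built
#' by permuting the site patterns across the informative-site positions and
#' recomputing; recombination makes nearby sites \emph{more} compatible than
#' permuted ones, so significance is the lower tail:
#' \code{p = (1 + #\{perm <= observed\}) / (n_permutations + 1)}.
#'
#' @param aln an \code{mt_alignment} (4+ sequences for a meaningful test).
#' @param w nearby-pair window in alignment columns (default 100).
#' @param n_permutations permutation count (default 100000, enough to
#'   resolve p below 1e-5).
#' @param seed RNG seed.
#' @return A list of class \code{phi_test} with \code{statistic},
#'   \code{p_value}, \code{n_informative}, \code{n_pairs}, \code{window_w},
#'   \code{n_permutations}, \code{seed}, \code{mean_perm} and
#'   \code{computable}. When fewer than two informative sites fall within
#'   \code{w} of each other the result is flagged \code{computable = FALSE}
#'   with NA statistic and p.
#' @export
phi_test <- function(aln, w = 100L, n_permutations = 100000L, seed = 1L) {
  info <- informative_sites(aln)
  not_comp <- structure(
    list(statistic = NA_real_, p_value = NA_real_,
         n_informative = length(info$columns), n_pairs = 0L,
         window_w = as.integer(w), n_permutations = as.integer(n_permutations),
         seed = as.integer(seed), mean_perm = NA_real_, computable = FALSE,
         degenerate = NA),
    class = "phi_test")
  n <- length(info$columns)
  if (n < 2L) return(not_comp)
  pos <- info$columns
  # nearby pairs (i < j, pos[j] - pos[i] <= w) by two-pointer sweep
  ai <- integer(0); bi <- integer(0)
  j0 <- 1L
  for (j in 2L:n) {
    while (pos[j] - pos[j0] > w) j0 <- j0 + 1L
    if (j0 < j) {
      ai <- c(ai, j0:(j - 1L)); bi <- c(bi, rep(j, j - j0))
    }
  }
  if (!length(ai)) return(not_comp)
  x <- binarize_sites(info)
  inc <- incompatibility_matrix(x)
  observed <- mean(inc[cbind(ai, bi)])
  res <- with_seed(seed, phi_permute(inc, ai - 1L, bi - 1L,
                                     as.integer(n_permutations), observed))
  structure(
    list(statistic = observed,
         p_value = (1 + res$count_le) / (n_permutations + 1),
         n_informative = n, n_pairs = length(ai),
         window_w = as.integer(w),
         n_permutations = as.integer(n_permutations),
         seed = as.integer(seed), mean_perm = res$mean_perm,
         computable = TRUE,
         # no incompatible pair exists among any two informative sites: the
         # permutation null is a point mass at the observed value and the
         # test carries no information in either direction
         degenerate = sum(inc) == 0L),
    class = "phi_test")
}

#' @export
print.phi_test <- function(x, ...) {
  if (!x$computable) {
    cat("PHI test: not computable (", x$n_informative,
        " informative sites)\n", sep = "")
    return(invisible(x))
  }
  cat(sprintf(
    "PHI test: statistic = %.4f (perm mean %.4f), p = %.3g\n", x$statistic,
    x$mean_perm, x$p_value))
  cat(sprintf("  %d informative sites, %d nearby pairs (w = %d), %d permutations\n",
              x$n_informative, x$n_pairs, x$window_w, x$n_permutations))
  invisible(x)
}

#' MaxChi-style breakpoint scan for a sequence pair
#'
#' Sites comparable between the two sequences are ordered along the
#' alignment and labelled match/mismatch. At each cut between consecutive
#' sites (with \code{k} sites on each side fully available), the 2x2 table of
#' (match, mismatch) x (left half-window, right half-window) is formed and
#' its chi-square statistic computed (no continuity correction). The best
#' breakpoint is the alignment column of the last left-half site at the
#' maximizing cut (ties toward the smallest column). Significance comes from
#' permuting the match/mismatch labels over sites and recomputing the
#' maximum.
#'
#' With \code{sites = "all"} every pair-comparable column enters the site
#' list; with \code{sites = "polymorphic"} (the classical MaxChi convention)
#' the list is restricted to columns that are polymorphic across \emph{all}
#' sequences of \code{aln}, which concentrates the signal when overall
#' divergence is low relative to the half-window size.
#'
#' @param aln an \code{mt_alignment}; for \code{sites = "polymorphic"} it
#'   should contain the full sequence context, not just the pair.
#' @param id_a,id_b the sequence pair (candidate recombinant and a parent).
#' @param k sites per half-window (default 30).
#' @param n_permutations permutations for the max statistic (default 1000).
#' @param seed RNG seed.
#' @param sites site-list convention, \code{"all"} or \code{"polymorphic"}.
#' @return A list of class \code{maxchi} with \code{pair},
#'   \code{best_breakpoint} (alignment column), \code{max_chi},
#'   \code{p_value}, \code{chi_profile} (data frame: column, chi), \code{k},
#'   \code{n_sites}, \code{seed}, \code{computable}.
#' @export
maxchi_scan <- function(aln, id_a, id_b, k = 30L, n_permutations = 1000L,
                        seed = 1L, sites = c("all", "polymorphic")) {
  sites <- match.arg(sites)
  k <- as.integer(k)
  m <- as.matrix(aln)
  ps <- pair_sites(m, seq_index(aln, id_a), seq_index(aln, id_b))
  keep <- ps$comp
  if (sites == "polymorphic") {
    poly <- vapply(seq_len(ncol(m)), function(j) {
      b <- m[, j]; b <- b[b %in% BASES]
      length(unique(b)) >= 2L
    }, TRUE)
    keep <- keep & poly
  }
  cols <- which(keep)
  y <- as.integer(ps$diff[cols])
  n <- length(y)
  if (n < 2L * k) {
    return(structure(list(pair = c(id_a, id_b), best_breakpoint = NA_integer_,
                          max_chi = NA_real_, p_value = NA_real_,
                          chi_profile = NULL, k = k, n_sites = n,
                          seed = as.integer(seed), computable = FALSE),
                     class = "maxchi"))
  }
  chi_at_cuts <- function(y) {
    s <- cumsum(y)
    t <- k:(n - k)                     # cut after site t
    L1 <- s[t] - c(0L, s)[t - k + 1L]  # mismatches in left k sites
    R1 <- s[t + k] - s[t]
    a <- k - L1; b <- L1; cc <- k - R1; d <- R1
    num <- 2 * k * (a * d - b * cc)^2
    den <- as.numeric(k) * k * (a + cc) * (b + d)
    chi <- ifelse(den > 0, num / den, 0)
    list(t = t, chi = chi)
  }
  obs <- chi_at_cuts(y)
  best_i <- which.max(obs$chi)
  best_t <- obs$t[best_i]
  max_chi <- obs$chi[best_i]
  count_ge <- with_seed(seed, {
    sum(vapply(seq_len(n_permutations), function(b) {
      max(chi_at_cuts(y[sample.int(n)])$chi)
    }, 0) >= max_chi - 1e-12)
  })
  structure(
    list(pair = c(id_a, id_b),
         best_breakpoint = cols[best_t],
         max_chi = max_chi,
         p_value = (1 + count_ge) / (n_permutations + 1),
         chi_profile = data.frame(column = cols[obs$t], chi = obs$chi),
         k = k, n_sites = n, seed = as.integer(seed), computable = TRUE),
    class = "maxchi")
}

#' @export
print.maxchi <- function(x, ...) {
  if (!x$computable) {
    cat("MaxChi: not computable (", x$n_sites, " comparable sites)\n", sep = "")
    return(invisible(x))
  }
  cat(sprintf("MaxChi %s vs %s: max chi-square = %.2f at column %d, p = %.3g\n",
              x$pair[1L], x$pair[2L], x$max_chi, x$best_breakpoint, x$p_value))
  invisible(x)
}

#' Triplet closer-parent scan
#'
#' For a candidate recombinant and two putative parents, each sliding window
#' is called \code{"A"} or \code{"B"} according to which parent the candidate
#' is strictly closer to (windowed p-distance, pairwise deletion), or
#' \code{"tie"}; windows with no comparable sites for either pair are ties.
#' Maximal runs of \code{"B"} calls are the candidate recombinant segments.
#'
#' @param aln an \code{mt_alignment}.
#' @param candidate_id,parent_a,parent_b three distinct sequence ids;
#'   \code{parent_a} plays the backbone (major) role, \code{parent_b} the
#'   putative donor (minor) role.
#' @param window,step window geometry in columns (defaults 100 / 25).
#' @return A list of class \code{triplet_scan}: \code{windows} (data frame
#'   with start, end, midpoint, d_a, d_b, call) and \code{segments} (data
#'   frame of maximal "B" runs: begin, end in alignment columns).
#' @export
triplet_scan <- function(aln, candidate_id, parent_a, parent_b,
                         window = 100L, step = 25L) {
  ids <- c(candidate_id, parent_a, parent_b)
  if (anyDuplicated(ids)) stop("candidate and parents must be distinct")
  window <- as.integer(window); step <- as.integer(step)
  m <- as.matrix(aln)
  ic <- seq_index(aln, candidate_id)
  ia <- seq_index(aln, parent_a)
  ib <- seq_index(aln, parent_b)
  pa <- pair_sites(m, ic, ia)
  pb <- pair_sites(m, ic, ib)
  cDa <- c(0, cumsum(pa$diff)); cCa <- c(0, cumsum(pa$comp))
  cDb <- c(0, cumsum(pb$diff)); cCb <- c(0, cumsum(pb$comp))
  starts <- seq.int(1L, aln$length - window + 1L, by = step)
  da <- db <- numeric(length(starts))
  call <- character(length(starts))
  for (w in seq_along(starts)) {
    s <- starts[w]; e <- s + window
    na <- cCa[e] - cCa[s]; nb <- cCb[e] - cCb[s]
    if (na == 0L || nb == 0L) {
      da[w] <- NA_real_; db[w] <- NA_real_; call[w] <- "tie"
      next
    }
    da[w] <- (cDa[e] - cDa[s]) / na
    db[w] <- (cDb[e] - cDb[s]) / nb
    call[w] <- if (db[w] < da[w]) "B" else if (da[w] < db[w]) "A" else "tie"
  }
  wins <- data.frame(start = starts, end = starts + window - 1L,
                     midpoint = starts + (window - 1L) %/% 2L,
                     d_a = da, d_b = db, call = call)
  isb <- call == "B"
  segments <- data.frame(begin = integer(0), end = integer(0))
  if (any(isb)) {
    idx <- which(isb)
    grp <- cumsum(c(1L, diff(idx) > 1L))
    segments <- do.call(rbind, lapply(split(idx, grp), function(run) {
      data.frame(begin = wins$start[run[1L]],
                 end = wins$end[run[length(run)]])
    }))
    rownames(segments) <- NULL
  }
  structure(list(windows = wins, segments = segments,
                 candidate = candidate_id, parent_a = parent_a,
                 parent_b = parent_b, window = window, step = step),
            class = "triplet_scan")
}

#' Bonferroni correction
#'
#' @param p raw p-value in (0, 1].
#' @param m number of tests (>= 1).
#' @return \code{min(1, m * p)}.
#' @export
bonferroni <- function(p, m) {
  stopifnot(all(p > 0), all(p <= 1), m >= 1)
  pmin(1, m * p)
}

# Variable sites between two rows (both unambiguous, differing), as columns.
variable_columns <- function(m, i, j) {
  ps <- pair_sites(m, i, j)
  which(ps$diff)
}

#' Call recombination events
#'
#' The full event-calling procedure. For each candidate and each ordered
#' (major from the candidate's own group, minor from another group) reference
#' pair, a triplet scan proposes segments; each segment is refined to the
#' interval from the first to the last candidate-vs-major variable site
#' inside the run at which the candidate matches the minor parent. Each
#' distinct (candidate, minor, refined interval) becomes one test, scored by
#' the most conservative of: MaxChi p at the beginning flank, MaxChi p at the
#' ending flank (candidate vs the selected backbone major), and the PHI p on
#' the alignment restricted to the segment plus one window on each side.
#' P-values are Bonferroni-corrected by the total number of tests and events
#' with corrected p below \code{alpha} are retained. For retained events the
#' major parent is the same-group sequence minimizing the whole-genome
#' distance outside the candidate's segments, and the minor parent is the
#' other-group sequence minimizing the within-segment distance; mismatches
#' between candidate and minor inside the segment are counted.
#'
#' @param aln an \code{mt_alignment}.
#' @param candidates ids to test for recombination.
#' @param groups named character vector mapping sequence ids to group labels
#'   (e.g. species); must cover all candidates and references. Sequences of
#'   the candidate's own group (including other candidates) are potential
#'   major parents; sequences of other groups are potential minor parents.
#' @param window,step triplet-scan window geometry (defaults 100 / 25).
#' @param k MaxChi half-window size in sites (default 30).
#' @param flank half-width, in columns, of the region around each breakpoint
#'   on which the flanking MaxChi statistics are computed (default 500).
#' @param maxchi_permutations,phi_permutations permutation counts for the
#'   per-event tests (defaults 1000 each).
#' @param phi_w PHI nearby-pair window (default 100).
#' @param alpha significance level on Bonferroni-corrected p (default 0.05).
#' @param seed RNG seed; per-test seeds are derived from it.
#' @return An object of class \code{recomb_events}: a data frame with one row
#'   per retained event. \code{begin}/\code{end} delimit the fragment core
#'   (first..last donor-supporting informative site; the interval used for
#'   mismatch and identity accounting), while
#'   \code{breakpoint_begin}/\code{breakpoint_end} estimate the breakpoints
#'   as midpoints between the core and the nearest flanking
#'   backbone-supporting sites. Remaining columns: span, ungapped_length,
#'   p_maxchi_begin, p_maxchi_end, p_phi (NA when the segment is too short
#'   for a directional PHI), p_value (conservative max), p_corrected,
#'   mismatches. Attributes \code{n_tests} (the Bonferroni m) and
#'   \code{alpha}.
#' @export
call_events <- function(aln, candidates, groups, window = 100L, step = 25L,
                        k = 30L, flank = 500L,
                        maxchi_permutations = 1000L, phi_permutations = 1000L,
                        phi_w = 100L, alpha = 0.05, seed = 1L) {
  groups <- groups[names(groups) %in% aln$ids]
  miss <- setdiff(candidates, names(groups))
  if (length(miss)) stop("candidate(s) without group label: ",
                         paste(miss, collapse = ", "))
  # iterate in ingest order for reproducibility
  ord <- function(ids) ids[order(match(ids, aln$ids))]
  candidates <- ord(candidates)
  m <- as.matrix(aln)
  L <- aln$length
  merge_runs <- function(runs) {
    runs <- runs[order(runs$begin), , drop = FALSE]
    out <- runs[1, , drop = FALSE]
    out$majors <- list(out$major[[1L]])
    for (i in seq_len(nrow(runs))[-1L]) {
      j <- nrow(out)
      if (runs$begin[i] <= out$end[j]) {
        out$end[j] <- max(out$end[j], runs$end[i])
        out$majors[[j]] <- union(out$majors[[j]], runs$major[i])
      } else {
        nr <- runs[i, , drop = FALSE]
        nr$majors <- list(nr$major[[1L]])
        out <- rbind(out, nr)
      }
    }
    out
  }
  # stage 1: triplet scans propose raw runs, pooled per (candidate, minor)
  # across all same-group majors (overlapping runs are unioned: different
  # majors see the same planted segment with small boundary jitter). A run
  # must be proposed by a majority of majors: a run seen only against one
  # major says more about that major (e.g. its own recombinant fragment)
  # than about the candidate.
  raw <- list()
  for (cand in candidates) {
    g <- groups[[cand]]
    majors <- ord(setdiff(names(groups)[groups == g], cand))
    minors <- ord(names(groups)[groups != g])
    if (!length(minors)) {
      stop(sprintf(
        "no reference from a group other than '%s' for candidate '%s'", g, cand))
    }
    if (!length(majors)) {
      stop(sprintf("no same-group reference for candidate '%s' (group '%s')",
                   cand, g))
    }
    support_min <- length(majors) %/% 2L + 1L
    for (b in minors) {
      runs <- list()
      for (a in majors) {
        ts <- triplet_scan(aln, cand, a, b, window = window, step = step)
        if (nrow(ts$segments)) {
          runs[[length(runs) + 1L]] <- cbind(ts$segments, major = a)
        }
      }
      if (!length(runs)) next
      mr <- merge_runs(do.call(rbind, runs))
      mr <- mr[vapply(mr$majors, length, 0L) >= support_min, , drop = FALSE]
      if (!nrow(mr)) next
      raw[[length(raw) + 1L]] <- cbind(candidate = cand, minor = b,
                                       mr[, c("begin", "end")])
    }
  }
  # backbone (reported) major per candidate: min distance outside the
  # candidate's pooled runs
  backbone <- list()
  for (cand in candidates) {
    drop <- logical(L)
    for (r in raw) {
      if (!nrow(r) || r$candidate[1L] != cand) next
      for (i in seq_len(nrow(r))) drop[r$begin[i]:r$end[i]] <- TRUE
    }
    g <- groups[[cand]]
    majors <- ord(setdiff(names(groups)[groups == g], cand))
    d <- vapply(majors, function(a) {
      ps <- pair_sites(m, seq_index(aln, cand), seq_index(aln, a))
      comp <- ps$comp & !drop
      if (!sum(comp)) return(Inf)
      sum(ps$diff & !drop) / sum(comp)
    }, 0)
    backbone[[cand]] <- majors[which.min(d)]
  }
  run_dist <- function(i1, i2, span) {
    ps <- pair_sites(m, i1, i2)
    comp <- sum(ps$comp[span])
    if (!comp) return(NA_real_)
    sum(ps$diff[span]) / comp
  }
  has_own_run <- function(id, lo, hi) {
    for (r in raw) {
      if (!nrow(r) || r$candidate[1L] != id) next
      if (any(r$begin <= hi & r$end >= lo)) return(TRUE)
    }
    FALSE
  }
  # per-run detection reference and proposal filter. The detection reference
  # is the same-group sequence most divergent from the candidate inside the
  # run (a fellow recombinant sharing the fragment carries no breakpoint
  # contrast there). A run is only promoted to a test when the candidate is
  # strictly closer to the minor inside the run than to its closest
  # conspecific without a run of its own at this locus -- the "high
  # similarity to another species" signature of a transferred fragment.
  #
  # Refinement works on trio-informative sites (all three of candidate,
  # reference, minor unambiguous; reference != minor; candidate equal to one
  # of them): "donor support" where the candidate sides with the minor,
  # "backbone support" where it sides with the reference. The fragment core
  # is the maximal-scoring contiguous block (donor +1, backbone -2), which
  # stops chance donor-matches in the backbone from stretching the fragment.
  # Reported begin/end delimit the core; breakpoint_begin/_end estimate the
  # true breakpoints as midpoints between the core and the nearest flanking
  # backbone-support sites.
  tests <- list()
  for (r in raw) {
    cand <- r$candidate[1L]; b <- r$minor[1L]
    g <- groups[[cand]]
    majors <- ord(setdiff(names(groups)[groups == g], cand))
    ib <- seq_index(aln, b); icand <- seq_index(aln, cand)
    for (s in seq_len(nrow(r))) {
      span <- r$begin[s]:r$end[s]
      d_in <- vapply(majors, function(a) {
        d <- run_dist(icand, seq_index(aln, a), span)
        if (is.na(d)) -Inf else d
      }, 0)
      a_det <- majors[which.max(d_in)]
      ia <- seq_index(aln, a_det)
      trio_ok <- m[icand, ] %in% BASES & m[ia, ] %in% BASES &
        m[ib, ] %in% BASES & m[ia, ] != m[ib, ]
      donor <- trio_ok & m[icand, ] == m[ib, ]
      bbone <- trio_ok & m[icand, ] == m[ia, ]
      sites <- which(donor | bbone)
      sites_in <- sites[sites >= r$begin[s] & sites <= r$end[s]]
      if (!length(sites_in)) next
      score <- ifelse(donor[sites_in], 1, -1)
      # Kadane: maximal-sum contiguous block of trio-informative sites;
      # resets only on a strictly negative running sum so that a single
      # backbone-support site (e.g. a post-transfer mutation that happens to
      # match the reference) near a fragment edge cannot truncate the block
      best <- 0; best_i <- 0L; best_j <- -1L
      cur <- 0; cur_i <- 1L
      for (jj in seq_along(score)) {
        if (cur < 0) { cur <- 0; cur_i <- jj }
        cur <- cur + score[jj]
        if (cur > best) { best <- cur; best_i <- cur_i; best_j <- jj }
      }
      if (best_j < best_i) next
      core <- sites_in[best_i:best_j]
      core_donor <- core[donor[core]]
      # minimal evidence: at least 3 donor-support sites; the core must be
      # anomalously similar to the donor (under half the genome-wide
      # candidate-minor divergence), mirroring the near-identity expected of
      # a transferred fragment; and the candidate must be strictly closer to
      # the minor inside the core than to its closest conspecific without a
      # run of its own at this locus
      if (length(core_donor) < 3L) next
      cb <- min(core_donor); ce <- max(core_donor)
      d_seg <- run_dist(icand, ib, cb:ce)
      d_gw <- run_dist(icand, ib, seq_len(L))
      if (is.na(d_seg) || d_seg >= 0.5 * d_gw) next
      clean <- majors[!vapply(majors, has_own_run, TRUE, lo = cb, hi = ce)]
      if (length(clean)) {
        d_clean <- vapply(clean, function(a) {
          d <- run_dist(icand, seq_index(aln, a), cb:ce)
          if (is.na(d)) Inf else d
        }, 0)
        if (d_seg >= min(d_clean)) next
      }
      bb_before <- sites[bbone[sites] & sites < cb]
      bb_after <- sites[bbone[sites] & sites > ce]
      bp_begin <- if (length(bb_before)) (max(bb_before) + cb) %/% 2L else cb
      bp_end <- if (length(bb_after)) (min(bb_after) + ce + 1L) %/% 2L else ce
      tests[[length(tests) + 1L]] <- list(
        candidate = cand, minor = b, detection_ref = a_det,
        begin = cb, end = ce,
        breakpoint_begin = bp_begin, breakpoint_end = bp_end,
        trio_cols = sites, n_donor_sites = length(core_donor))
    }
  }
  empty <- structure(
    data.frame(recombinant = character(0), major_parent = character(0),
               minor_parent = character(0), begin = integer(0),
               end = integer(0), breakpoint_begin = integer(0),
               breakpoint_end = integer(0), span = integer(0),
               ungapped_length = integer(0), p_maxchi_begin = numeric(0),
               p_maxchi_end = numeric(0), p_phi = numeric(0),
               p_value = numeric(0), p_corrected = numeric(0),
               mismatches = integer(0)),
    n_tests = 0L, alpha = alpha, class = c("recomb_events", "data.frame"))
  if (!length(tests)) return(empty)
  # one hypothesis per candidate locus: tests whose cores overlap (whatever
  # minor proposed them) describe the same fragment, so keep the widest
  # core -- the most complete description -- and let the later minor-parent
  # reassignment pick the donor
  keep <- logical(length(tests))
  for (cand in unique(vapply(tests, `[[`, "", "candidate"))) {
    idx <- which(vapply(tests, `[[`, "", "candidate") == cand)
    spans <- vapply(tests[idx], function(t) t$end - t$begin + 1L, 0L)
    begins <- vapply(tests[idx], `[[`, 0L, "begin")
    for (i in idx[order(-spans, begins)]) {
      t <- tests[[i]]
      taken <- idx[keep[idx]]
      clash <- any(vapply(tests[taken], function(u) {
        t$begin <= u$end && t$end >= u$begin
      }, TRUE))
      if (!clash) keep[i] <- TRUE
    }
  }
  tests <- tests[keep]
  n_tests <- length(tests)

  rows <- list()
  for (i in seq_along(tests)) {
    t <- tests[[i]]
    cand <- t$candidate
    a <- backbone[[cand]]
    a_det <- t$detection_ref
    trio <- c(cand, a_det, t$minor)
    sub_seed <- as.integer(seed) + i
    # flank MaxChi on the triplet's polymorphic sites (the RDP convention):
    # sites varying only in unrelated lineages would dilute the half-window
    # contrast. The half-window size is capped at the core's donor-support
    # count -- sites beyond the fragment's informative content can only
    # dilute the table -- and the flank is widened to the nearest 2k + 10
    # trio-informative sites when the fixed flank holds too few.
    k_t <- max(5L, min(as.integer(k), t$n_donor_sites))
    flank_scan <- function(center) {
      lo <- max(1L, center - as.integer(flank))
      hi <- min(L, center + as.integer(flank) - 1L)
      need <- 2L * k_t + 10L
      inside <- t$trio_cols[t$trio_cols >= lo & t$trio_cols <= hi]
      if (length(inside) < need && length(t$trio_cols) >= need) {
        nearest <- t$trio_cols[order(abs(t$trio_cols - center))][seq_len(need)]
        lo <- min(lo, min(nearest))
        hi <- max(hi, max(nearest))
      }
      sub <- extract_region(subset_alignment(aln, trio),
                            region_spec(lo, hi))
      maxchi_scan(sub, cand, a_det, k = k_t,
                  n_permutations = maxchi_permutations, seed = sub_seed,
                  sites = "polymorphic")
    }
    mc_b <- flank_scan(t$breakpoint_begin)
    mc_e <- flank_scan(t$breakpoint_end)
    # PHI context: segment plus flanking backbone on both sides. Nearby
    # site pairs straddling a breakpoint carry the opposite signal to the
    # within-genealogy pairs PHI relies on; their share is roughly
    # w / span, so the component is only directionally stable for long
    # segments and is skipped below 10x the pair window.
    ph <- NULL
    if (t$end - t$begin + 1L >= 10L * phi_w) {
      lo <- max(1L, t$begin - as.integer(flank))
      hi <- min(L, t$end + as.integer(flank))
      ph <- phi_test(extract_region(aln, region_spec(lo, hi)), w = phi_w,
                     n_permutations = phi_permutations, seed = sub_seed)
      # a degenerate PHI (no incompatibility possible anywhere in the
      # restricted region) has no power and cannot veto the event
      if (!ph$computable || isTRUE(ph$degenerate)) ph <- NULL
    }
    ps <- c(if (mc_b$computable) mc_b$p_value,
            if (mc_e$computable) mc_e$p_value,
            if (!is.null(ph)) ph$p_value)
    if (!length(ps)) next
    p_raw <- max(ps)
    rows[[length(rows) + 1L]] <- data.frame(
      recombinant = cand, major_parent = a, minor_parent = t$minor,
      begin = t$begin, end = t$end,
      breakpoint_begin = t$breakpoint_begin,
      breakpoint_end = t$breakpoint_end,
      span = t$end - t$begin + 1L,
      ungapped_length = ungapped_length(aln, cand,
                                        region_spec(t$begin, t$end)),
      p_maxchi_begin = if (mc_b$computable) mc_b$p_value else NA_real_,
      p_maxchi_end = if (mc_e$computable) mc_e$p_value else NA_real_,
      p_phi = if (!is.null(ph)) ph$p_value else NA_real_,
      p_value = p_raw,
      p_corrected = bonferroni(p_raw, n_tests),
      mismatches = NA_integer_)
  }
  if (!length(rows)) return(empty)
  ev <- do.call(rbind, rows)
  ev <- ev[ev$p_corrected < alpha, , drop = FALSE]
  if (!nrow(ev)) {
    attr(empty, "n_tests") <- n_tests
    return(empty)
  }
  # reassign minor parent by within-segment distance; count mismatches
  for (i in seq_len(nrow(ev))) {
    cand <- ev$recombinant[i]
    g <- groups[[cand]]
    minors <- ord(names(groups)[groups != g])
    reg <- region_spec(ev$begin[i], ev$end[i])
    d <- vapply(minors, function(b) {
      ps <- pair_sites(m, seq_index(aln, cand), seq_index(aln, b))
      comp <- ps$comp[reg$start:reg$end]
      if (!sum(comp)) return(Inf)
      sum(ps$diff[reg$start:reg$end]) / sum(comp)
    }, 0)
    best <- minors[which.min(d)]
    ev$minor_parent[i] <- best
    ps <- pair_sites(m, seq_index(aln, cand), seq_index(aln, best))
    ev$mismatches[i] <- sum(ps$diff[reg$start:reg$end])
  }
  ev <- ev[order(match(ev$recombinant, aln$ids), ev$begin), , drop = FALSE]
  rownames(ev) <- NULL
  structure(ev, n_tests = n_tests, alpha = alpha,
            class = c("recomb_events", "data.frame"))
}

#' Write called events as a tab-separated table
#'
#' @param events a \code{recomb_events} data frame.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_events <- function(events, path) {
  write.table(as.data.frame(events), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
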