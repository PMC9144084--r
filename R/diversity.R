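# Per-pair site indicators: for rows i, j of the character matrix, which
# columns are comparable (both unambiguous bases) and which of those differ.
pair_sites <- function(m, i, j) {
  a <- m[i, ]; b <- m[j, ]
  comp <- a %in% BASES & b %in% BASES
  list(comp = comp, diff = comp & a != b)
}

boot_se_mean <- function(x, n_boot, seed) {
  n <- length(x)
  if (n < 2L) return(0)
  with_seed(seed, {
    reps <- vapply(seq_len(n_boot),
                   function(i) mean(x[sample.int(n, n, replace = TRUE)]), 0)
    sd(reps)
  })
}

#' Pairwise p-distance between two aligned sequences
#'
#' The proportion of differing sites among comparable sites, where a site is
#' comparable when both sequences carry an unambiguous base (gaps and N are
#' excluded pairwise). No multiple-hit correction is applied. The standard
#' error is a site bootstrap: comparable sites are resampled with replacement
#' and the distance recomputed.
#'
#' @param aln an \code{mt_alignment}.
#' @param id_a,id_b sequence ids.
#' @param se one of \code{"bootstrap"} or \code{"none"}.
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @return A list of class \code{distance_estimate} with \code{value},
#'   \code{se} and \code{n_sites}.
#' @examples
#' aln <- mt_alignment(c(a = "ACGT", b = "ACGA"))
#' p_distance(aln, "a", "b", se = "none")$value  # 0.25
#' @export
p_distance <- function(aln, id_a, id_b, se = c("bootstrap", "none"),
                       n_boot = 1000L, seed = 1729L) {
  se <- match.arg(se)
  m <- as.matrix(aln)
  ps <- pair_sites(m, seq_index(aln, id_a), seq_index(aln, id_b))
  n <- sum(ps$comp)
  if (n == 0L) {
    stop(sprintf("no comparable sites between '%s' and '%s'", id_a, id_b))
  }
  d <- as.numeric(ps$diff[ps$comp])
  value <- mean(d)
  se_val <- if (se == "bootstrap") boot_se_mean(d, n_boot, seed) else NA_real_
  structure(list(value = value, se = se_val, n_sites = n),
            class = "distance_estimate")
}

# Matrices of per-pair difference / comparability indicators over columns,
# one row per unordered pair (the workhorse behind pi, profiles, bootstrap).
pair_indicator_matrices <- function(m) {
  ns <- nrow(m)
  pairs <- utils::combn(ns, 2L)
  is_base <- matrix(m %in% BASES, nrow = ns)
  D <- matrix(0, ncol(pairs), ncol(m))
  C <- matrix(0, ncol(pairs), ncol(m))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    comp <- is_base[i, ] & is_base[j, ]
    C[k, ] <- comp
    D[k, ] <- comp & m[i, ] != m[j, ]
  }
  list(pairs = pairs, D = D, C = C)
}

#' Nucleotide diversity of an alignment
#'
#' \eqn{\pi}: the mean pairwise p-distance over all unordered sequence pairs,
#' with pairwise deletion of non-comparable sites. The standard error is a
#' site bootstrap: alignment columns are resampled with replacement and
#' \eqn{\pi} recomputed on each replicate.
#'
#' @param aln an \code{mt_alignment} (at least 2 sequences).
#' @param se one of \code{"bootstrap"} or \code{"none"}.
#' @param n_boot bootstrap replicates.
#' @param seed RNG seed for the bootstrap.
#' @return A list of class \code{diversity_estimate} with \code{pi},
#'   \code{se} and \code{n_sequences}.
#' @export
nucleotide_diversity <- function(aln, se = c("bootstrap", "none"),
                                 n_boot = 1000L, seed = 1729L) {
  se <- match.arg(se)
  m <- as.matrix(aln)
  pim <- pair_indicator_matrices(m)
  csum <- rowSums(pim$C)
  if (any(csum == 0)) {
    k <- which(csum == 0)[1L]
    stop(sprintf("no comparable sites between '%s' and '%s'",
                 aln$ids[pim$pairs[1L, k]], aln$ids[pim$pairs[2L, k]]))
  }
  pi_hat <- mean(rowSums(pim$D) / csum)
  se_val <- NA_real_
  if (se == "bootstrap") {
    L <- ncol(m)
    se_val <- with_seed(seed, {
      reps <- vapply(seq_len(n_boot), function(b) {
        w <- tabulate(sample.int(L, L, replace = TRUE), L)
        dc <- pim$D %*% w
        cc <- pim$C %*% w
        ok <- cc > 0
        mean(dc[ok] / cc[ok])
      }, 0)
      sd(reps)
    })
  }
  structure(list(pi = pi_hat, se = se_val, n_sequences = n_seq(aln)),
            class = "diversity_estimate")
}

#' @export
print.diversity_estimate <- function(x, ...) {
  cat(sprintf("pi = %.4f +- %s  (n = %d sequences)\n", x$pi,
              if (is.na(x$se)) "NA" else sprintf("%.4f", x$se),
              x$n_sequences))
  invisible(x)
}

#' Pairwise distance matrix
#'
#' All unordered pairwise p-distances (pairwise deletion), zero diagonal.
#'
#' @param aln an \code{mt_alignment}.
#' @param se passed to \code{\link{p_distance}} per pair.
#' @param n_boot,seed bootstrap controls.
#' @return A list of class \code{distance_matrix} with symmetric numeric
#'   matrices \code{value}, \code{se}, \code{n_sites}, dimnames = ids.
#' @export
distance_matrix <- function(aln, se = c("none", "bootstrap"),
                            n_boot = 1000L, seed = 1729L) {
  se <- match.arg(se)
  ids <- aln$ids
  ns <- length(ids)
  V <- matrix(0, ns, ns, dimnames = list(ids, ids))
  S <- matrix(0, ns, ns, dimnames = list(ids, ids))
  N <- matrix(NA_integer_, ns, ns, dimnames = list(ids, ids))
  for (i in seq_len(ns - 1L)) {
    for (j in (i + 1L):ns) {
      d <- p_distance(aln, ids[i], ids[j], se = se,
                      n_boot = n_boot, seed = seed)
      V[i, j] <- V[j, i] <- d$value
      S[i, j] <- S[j, i] <- if (is.na(d$se)) 0 else d$se
      N[i, j] <- N[j, i] <- d$n_sites
    }
  }
  structure(list(value = V, se = S, n_sites = N, ids = ids),
            class = "distance_matrix")
}

#' Sliding-window diversity or divergence profile
#'
#' A window of \code{window} alignment columns moves along the alignment in
#' increments of \code{step}; the statistic is computed on each full window
#' (trailing partial windows are dropped) and assigned to the window's
#' midpoint column \code{start + floor((window - 1) / 2)}. Gaps count toward
#' the window span but are excluded from the statistic. For \code{stat =
#' "dxy"} the alignment must contain exactly two sequences (or pass
#' \code{ids}); \code{"pi"} averages over all pairs.
#'
#' @param aln an \code{mt_alignment}.
#' @param stat \code{"pi"} or \code{"dxy"}.
#' @param window window size in columns (default 100).
#' @param step step size in columns (default 25).
#' @param ids optional subset of sequence ids to profile.
#' @return An object of class \code{sliding_profile}: a data frame with
#'   columns \code{midpoint}, \code{value}, \code{n_sites} (total comparable
#'   sites in the window) and \code{no_data} (window had zero comparable
#'   sites; its value is 0), with attributes \code{window}, \code{step},
#'   \code{stat}.
#' @export
sliding_profile <- function(aln, stat = c("pi", "dxy"), window = 100L,
                            step = 25L, ids = NULL) {
  stat <- match.arg(stat)
  if (!is.null(ids)) aln <- subset_alignment(aln, ids)
  window <- as.integer(window); step <- as.integer(step)
  if (window > aln$length) stop("window larger than alignment length")
  if (step < 1L) stop("step must be >= 1")
  if (stat == "dxy" && n_seq(aln) != 2L) {
    stop("stat = 'dxy' needs exactly 2 sequences (use ids= to select a pair)")
  }
  m <- as.matrix(aln)
  pim <- pair_indicator_matrices(m)
  # windowed sums via cumulative sums along columns
  cD <- cbind(0, t(apply(pim$D, 1L, cumsum)))
  cC <- cbind(0, t(apply(pim$C, 1L, cumsum)))
  starts <- seq.int(1L, aln$length - window + 1L, by = step)
  mids <- starts + (window - 1L) %/% 2L
  np <- nrow(pim$D)
  value <- numeric(length(starts))
  nsite <- integer(length(starts))
  nodata <- logical(length(starts))
  for (w in seq_along(starts)) {
    s <- starts[w]
    dw <- cD[, s + window] - cD[, s]
    cw <- cC[, s + window] - cC[, s]
    ok <- cw > 0
    nsite[w] <- sum(cw)
    if (!any(ok)) {
      value[w] <- 0; nodata[w] <- TRUE
    } else {
      value[w] <- mean(dw[ok] / cw[ok])
    }
  }
  structure(
    data.frame(midpoint = mids, value = value, n_sites = nsite,
               no_data = nodata),
    window = window, step = step, stat = stat,
    class = c("sliding_profile", "data.frame")
  )
}

#' Write a sliding profile as tab-separated text
#'
#' Columns: midpoint, value, n_comparable_sites.
#' @param profile a \code{sliding_profile}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_profile <- function(profile, path) {
  df <- data.frame(midpoint = profile$midpoint,
                   value = profile$value,
                   n_comparable_sites = profile$n_sites)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a distance matrix as tab-separated text
#'
#' Square matrix with a header row and a leading id column.
#' @param dm a \code{distance_matrix}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_distance_matrix <- function(dm, path) {
  df <- data.frame(id = dm$ids, dm$value, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Detect high-divergence (HD) regions in a sliding profile
#'
#' Codifies the visual peak-picking of sliding-window plots: the background
#' is the median window value; a window is a candidate when its value exceeds
#' \code{max(fold_threshold * background, absolute_floor)}; maximal runs of
#' candidate windows separated by at most one non-candidate window are
#' merged; runs with fewer than \code{min_windows} candidate windows are
#' discarded. Each surviving run becomes one HD region spanning the first
#' candidate window's start to the last candidate window's end, with its peak
#' at the maximal window (ties toward the smaller midpoint).
#'
#' @param profile a \code{sliding_profile}.
#' @param fold_threshold multiple of the background median (default 5).
#' @param absolute_floor minimum absolute window value (default 0.02),
#'   guarding against a near-zero background.
#' @param min_windows minimum candidate windows per region (default 2).
#' @param merge_gap maximum number of consecutive non-candidate windows
#'   bridged inside a region (default 1). With overlapping windows a real
#'   block can dip below threshold for a few windows; raising this to about
#'   \code{window / step} makes regions robust to such dips.
#' @return An object of class \code{hd_regions}: a data frame with columns
#'   \code{start}, \code{end}, \code{peak_midpoint}, \code{peak_value},
#'   \code{background}.
#' @seealso \code{\link{detect_hd_regions_pairwise}} for the more sensitive
#'   pairwise-profile detector used by \code{\link{recombination_scan}}.
#' @export
detect_hd_regions <- function(profile, fold_threshold = 5, absolute_floor = 0.02,
                              min_windows = 2L, merge_gap = 1L) {
  if (nrow(profile) == 0L) stop("empty profile")
  window <- attr(profile, "window")
  bg <- median(profile$value)
  thr <- max(fold_threshold * bg, absolute_floor)
  cand <- profile$value > thr
  empty <- structure(
    data.frame(start = integer(0), end = integer(0),
               peak_midpoint = integer(0), peak_value = numeric(0),
               background = numeric(0)),
    class = c("hd_regions", "data.frame")
  )
  if (!any(cand)) return(empty)
  # merge candidate runs separated by <= merge_gap non-candidate windows
  idx <- which(cand)
  grp <- cumsum(c(1L, diff(idx) > merge_gap + 1L))
  out <- lapply(split(idx, grp), function(run) {
    if (length(run) < min_windows) return(NULL)
    first <- run[1L]; last <- run[length(run)]
    win_start <- profile$midpoint - (window - 1L) %/% 2L
    vals <- profile$value[run]
    peak <- run[which.max(vals)]  # which.max: first max = smaller midpoint
    data.frame(start = win_start[first],
               end = win_start[last] + window - 1L,
               peak_midpoint = profile$midpoint[peak],
               peak_value = profile$value[peak],
               background = bg)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(empty)
  rownames(out) <- NULL
  structure(out, class = c("hd_regions", "data.frame"))
}

#' Detect high-divergence regions from pairwise profiles
#'
#' Runs a sliding divergence profile for every unordered pair of the given
#' sequences, detects HD regions on each, and merges overlapping regions
#' across pairs. This mirrors how mosaic structure is read off pairwise
#' comparison plots: a fragment carried by one genome shows its full
#' interspecific divergence against every non-carrier, whereas a multi-genome
#' diversity profile dilutes it by the fraction of affected pairs, which can
#' push a single-carrier region below any threshold separating it from
#' background mutation clusters.
#'
#' The default thresholds are stricter than \code{\link{detect_hd_regions}}
#' (floor 0.03, four candidate windows, dips up to \code{window / step}
#' windows bridged) because a pair profile carries the undiluted signal: a
#' transferred fragment sits at the full interspecific divergence while
#' point clusters of intraspecific mutations never span more than one
#' window.
#'
#' @param aln an \code{mt_alignment}.
#' @param ids sequences whose pairwise profiles are scanned (default: all).
#' @param window,step profile geometry (defaults 100 / 25).
#' @param fold_threshold,absolute_floor,min_windows,merge_gap passed to
#'   \code{\link{detect_hd_regions}} per pair.
#' @return An \code{hd_regions} data frame (merged across pairs); the peak
#'   fields refer to the pair window with the highest value inside each
#'   merged region, and \code{background} to that pair's profile.
#' @export
detect_hd_regions_pairwise <- function(aln, ids = NULL, window = 100L,
                                       step = 25L, fold_threshold = 5,
                                       absolute_floor = 0.03,
                                       min_windows = 4L,
                                       merge_gap = window %/% step) {
  if (is.null(ids)) ids <- aln$ids
  regs <- list()
  for (i in seq_len(length(ids) - 1L)) {
    for (j in (i + 1L):length(ids)) {
      pr <- sliding_profile(aln, "dxy", window = window, step = step,
                            ids = c(ids[i], ids[j]))
      r <- detect_hd_regions(pr, fold_threshold = fold_threshold,
                             absolute_floor = absolute_floor,
                             min_windows = min_windows,
                             merge_gap = merge_gap)
      if (nrow(r)) regs[[length(regs) + 1L]] <- r
    }
  }
  empty <- structure(
    data.frame(start = integer(0), end = integer(0),
               peak_midpoint = integer(0), peak_value = numeric(0),
               background = numeric(0)),
    class = c("hd_regions", "data.frame")
  )
  if (!length(regs)) return(empty)
  allr <- do.call(rbind, regs)
  allr <- allr[order(allr$start), , drop = FALSE]
  out <- allr[1L, , drop = FALSE]
  for (i in seq_len(nrow(allr))[-1L]) {
    k <- nrow(out)
    if (allr$start[i] <= out$end[k]) {
      out$end[k] <- max(out$end[k], allr$end[i])
      if (allr$peak_value[i] > out$peak_value[k]) {
        out$peak_value[k] <- allr$peak_value[i]
        out$peak_midpoint[k] <- allr$peak_midpoint[i]
        out$background[k] <- allr$background[i]
      }
    } else {
      out <- rbind(out, allr[i, , drop = FALSE])
    }
  }
  rownames(out) <- NULL
  structure(out, class = c("hd_regions", "data.frame"))
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor joining (via \pkg{ape}), with negative branch lengths
#' clamped to zero. Used for per-region phylogenetic-discordance checks in
#' place of full likelihood tree inference.
#'
#' @param dm a \code{distance_matrix}, or a plain symmetric numeric matrix
#'   with dimnames.
#' @return A newick string; the \code{ape::phylo} object is attached as
#'   attribute \code{"phylo"}.
#' @export
nj_tree <- function(dm) {
  V <- if (inherits(dm, "distance_matrix")) dm$value else as.matrix(dm)
  if (nrow(V) < 3L) stop("neighbor joining needs at least 3 taxa")
  if (any(!is.finite(V))) stop("non-finite distances")
  tr <- ape::nj(as.dist(V))
  tr$edge.length[tr$edge.length < 0] <- 0
  structure(ape::write.tree(tr), phylo = tr)
}
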