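#' Assemble the mosaic annotation of one genome
#'
#' Orders a genome's recombination events along the alignment and resolves
#' overlaps: when two events overlap, the one with the smaller corrected p
#' survives (ties toward the smaller begin) and the discarded one is recorded
#' in a note. The result describes the genome as a backbone (major parent)
#' carrying an ordered, non-overlapping set of donated fragments.
#'
#' @param events a \code{recomb_events} data frame (or compatible), all rows
#'   referring to \code{genome_id}.
#' @param genome_id the annotated genome.
#' @param backbone_id the backbone (major parent); defaults to the most
#'   frequent major parent among the events, or NA when there are none.
#' @return An object of class \code{mosaic_annotation}: list with
#'   \code{genome_id}, \code{backbone_id}, \code{events} (sorted,
#'   non-overlapping data frame) and \code{notes} (character).
#' @export
annotate_mosaic <- function(events, genome_id, backbone_id = NULL) {
  events <- as.data.frame(events)
  if (nrow(events) && any(events$recombinant != genome_id)) {
    stop(sprintf("event for '%s' passed to annotation of '%s'",
                 events$recombinant[events$recombinant != genome_id][1L],
                 genome_id))
  }
  if (is.null(backbone_id)) {
    backbone_id <- if (nrow(events)) {
      names(sort(table(events$major_parent), decreasing = TRUE))[1L]
    } else NA_character_
  }
  notes <- character(0)
  if (nrow(events)) {
    events <- events[order(events$p_corrected, events$begin), , drop = FALSE]
    kept <- events[0, , drop = FALSE]
    for (i in seq_len(nrow(events))) {
      e <- events[i, , drop = FALSE]
      clash <- nrow(kept) && any(e$begin <= kept$end & e$end >= kept$begin)
      if (clash) {
        notes <- c(notes, sprintf(
          "discarded overlapping event %d-%d (minor %s, corrected p %.3g)",
          e$begin, e$end, e$minor_parent, e$p_corrected))
      } else {
        kept <- rbind(kept, e)
      }
    }
    events <- kept[order(kept$begin), , drop = FALSE]
    rownames(events) <- NULL
  }
  structure(list(genome_id = genome_id, backbone_id = backbone_id,
                 events = events, notes = notes),
            class = "mosaic_annotation")
}

#' @export
print.mosaic_annotation <- function(x, ...) {
  cat(sprintf("mosaic annotation for %s (backbone %s): %d event(s)\n",
              x$genome_id, x$backbone_id, nrow(x$events)))
  if (nrow(x$events)) {
    for (i in seq_len(nrow(x$events))) {
      e <- x$events[i, ]
      cat(sprintf("  %d-%d from %s (corrected p %.3g, %d mismatch(es))\n",
                  e$begin, e$end, e$minor_parent, e$p_corrected, e$mismatches))
    }
  }
  for (n in x$notes) cat("  note:", n, "\n")
  invisible(x)
}

#' Count recombinant-vs-donor mismatches inside a fragment
#'
#' Counts the columns within \code{[begin, end]} at which the recombinant and
#' the minor (donor) parent both carry unambiguous bases and differ. A
#' fragment with zero mismatches is an exact copy of the donor
#' (\code{call = "identical"}), the signature of a very recent transfer (or a
#' PCR-jumping artifact); accumulated mismatches (\code{call = "diverged"})
#' mark post-transfer substitutions and argue for a genuine, older event.
#'
#' @param aln an \code{mt_alignment}.
#' @param event one row of a \code{recomb_events} data frame (or any list
#'   with \code{recombinant}, \code{minor_parent}, \code{begin}, \code{end}).
#' @return A list of class \code{recency_call}: \code{event} (the input),
#'   \code{mismatches}, \code{positions} (alignment columns), \code{call}
#'   (\code{"identical"} or \code{"diverged"}), \code{note}.
#' @export
count_fragment_mismatches <- function(aln, event) {
  event <- as.list(event)
  m <- as.matrix(aln)
  reg <- region_spec(event$begin, event$end)
  check_region(aln, reg)
  ps <- pair_sites(m, seq_index(aln, event$recombinant),
                   seq_index(aln, event$minor_parent))
  idx <- reg$start:reg$end
  pos <- idx[ps$diff[idx]]
  k <- length(pos)
  structure(
    list(event = event, mismatches = k, positions = pos,
         call = if (k == 0L) "identical" else "diverged",
         note = if (k == 0L) {
           "fragment is an exact copy of the donor (recent transfer or PCR artifact)"
         } else {
           sprintf("%d post-transfer mismatch(es) at %s: consistent with a historical event, not PCR jumping",
                   k, paste(pos, collapse = ", "))
         }),
    class = "recency_call")
}

#' @export
print.recency_call <- function(x, ...) {
  cat(sprintf("%s fragment %d-%d vs %s: %d mismatch(es) -> %s\n",
              x$event$recombinant, x$event$begin, x$event$end,
              x$event$minor_parent, x$mismatches, x$call))
  invisible(x)
}

#' Extract diagnostic markers from mosaic annotations
#'
#' One marker per annotated event: the fragment region, the recombinant and
#' its donor, and the fraction of comparable within-region sites at which the
#' two are identical. Markers with identity fraction exactly 1 are flagged
#' \code{diagnostic_identical}; such regions distinguish hybrids unambiguously
#' and can be used to monitor ongoing hybridization.
#'
#' @param annotations a list of \code{mosaic_annotation}s (or a single one).
#' @param aln the \code{mt_alignment} the annotations refer to.
#' @return A data frame of class \code{diagnostic_markers}: columns
#'   \code{recombinant_id}, \code{minor_parent_id}, \code{start}, \code{end},
#'   \code{label}, \code{identity_fraction}, \code{diagnostic_identical}.
#' @export
extract_markers <- function(annotations, aln) {
  if (inherits(annotations, "mosaic_annotation")) annotations <- list(annotations)
  m <- as.matrix(aln)
  rows <- list()
  for (ann in annotations) {
    ev <- ann$events
    if (!nrow(ev)) next
    for (i in seq_len(nrow(ev))) {
      e <- ev[i, ]
      ps <- pair_sites(m, seq_index(aln, e$recombinant),
                       seq_index(aln, e$minor_parent))
      idx <- e$begin:e$end
      ncomp <- sum(ps$comp[idx])
      idf <- if (ncomp) 1 - sum(ps$diff[idx]) / ncomp else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        recombinant_id = e$recombinant, minor_parent_id = e$minor_parent,
        start = e$begin, end = e$end,
        label = sprintf("%s:%d-%d", e$recombinant, e$begin, e$end),
        identity_fraction = idf,
        diagnostic_identical = !is.na(idf) && idf == 1)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(recombinant_id = character(0), minor_parent_id = character(0),
               start = integer(0), end = integer(0), label = character(0),
               identity_fraction = numeric(0),
               diagnostic_identical = logical(0))
  rownames(out) <- NULL
  structure(out, class = c("diagnostic_markers", "data.frame"))
}
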