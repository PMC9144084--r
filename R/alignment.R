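#' @useDynLib mtmosaic, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median sd setNames optim runif as.dist
#' @importFrom utils write.table read.table head tail
NULL

ALPHABET <- c("A", "C", "G", "T", "N", "-")
BASES <- c("A", "C", "G", "T")

# IUPAC ambiguity codes other than N are mapped to N on ingest: the distance
# and recombination statistics treat anything but A/C/G/T as missing, and a
# partial-information code cannot change a site's comparability.
normalize_residues <- function(x) {
  x <- toupper(x)
  chartr("RYSWKMBDHV.", "NNNNNNNNNN-", x)
}

#' Construct a multiple alignment
#'
#' The container used by every stage of the pipeline: an ordered set of
#' equal-length gapped sequences over the alphabet \code{A,C,G,T,N,-}.
#' Residues are uppercased and IUPAC ambiguity codes other than \code{N} are
#' mapped to \code{N} on ingest. Coordinates throughout the package are
#' 1-based, inclusive, in alignment-column space.
#'
#' @param seqs character vector of aligned sequences (equal length).
#' @param ids unique sequence identifiers; defaults to \code{names(seqs)}.
#' @param descriptions optional free-text descriptions, one per sequence.
#' @return An object of class \code{mt_alignment} with fields \code{ids},
#'   \code{descriptions}, \code{seqs} and \code{length} (alignment columns).
#' @examples
#' aln <- mt_alignment(c(a = "ACGT", b = "ACGA"))
#' aln$length
#' @export
mt_alignment <- function(seqs, ids = names(seqs), descriptions = NULL) {
  if (is.null(ids)) stop("sequence ids are required")
  ids <- as.character(ids)
  seqs <- normalize_residues(as.character(seqs))
  if (length(seqs) < 2L) stop("an alignment needs at least 2 sequences")
  if (any(!nzchar(ids))) stop("sequence ids must be non-empty")
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id: ", ids[duplicated(ids)][1L])
  }
  len <- nchar(seqs[1L])
  bad <- which(nchar(seqs) != len)
  if (length(bad)) {
    stop(sprintf("record '%s' has length %d, expected %d",
                 ids[bad[1L]], nchar(seqs[bad[1L]]), len))
  }
  for (i in seq_along(seqs)) {
    m <- regexpr(sprintf("[^%s]", paste(ALPHABET, collapse = "")), seqs[i])
    if (m > 0L) {
      stop(sprintf("record '%s' has illegal character '%s' at position %d",
                   ids[i], substr(seqs[i], m, m), m))
    }
  }
  if (is.null(descriptions)) descriptions <- rep("", length(seqs))
  structure(
    list(ids = unname(ids), descriptions = unname(as.character(descriptions)),
         seqs = unname(seqs), length = len),
    class = "mt_alignment"
  )
}

#' @export
print.mt_alignment <- function(x, ...) {
  cat(sprintf("mt_alignment: %d sequences x %d columns\n",
              length(x$ids), x$length))
  cat("  ids:", paste(head(x$ids, 8L), collapse = ", "),
      if (length(x$ids) > 8L) "..." else "", "\n")
  invisible(x)
}

#' @export
as.matrix.mt_alignment <- function(x, ...) {
  m <- do.call(rbind, strsplit(x$seqs, "", fixed = TRUE))
  rownames(m) <- x$ids
  m
}

n_seq <- function(aln) length(aln$ids)

seq_index <- function(aln, id) {
  i <- match(id, aln$ids)
  if (is.na(i)) stop("sequence id not in alignment: ", id)
  i
}

#' Subset an alignment to a set of sequences
#'
#' @param aln an \code{mt_alignment}.
#' @param ids sequence ids to keep; output preserves the requested order.
#' @return An \code{mt_alignment} with the selected records.
#' @export
subset_alignment <- function(aln, ids) {
  idx <- vapply(ids, seq_index, 0L, aln = aln)
  mt_alignment(aln$seqs[idx], ids = aln$ids[idx],
               descriptions = aln$descriptions[idx])
}

#' Define an alignment region
#'
#' Regions are 1-based inclusive column intervals, matching how breakpoints
#' are reported throughout the package.
#'
#' @param start,end first and last alignment column (inclusive).
#' @param label optional region label (e.g. a gene name).
#' @return A \code{region_spec} list with fields \code{start}, \code{end},
#'   \code{label}.
#' @export
region_spec <- function(start, end, label = "") {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 1L || end < start) {
    stop("invalid region: need 1 <= start <= end")
  }
  structure(list(start = start, end = end, label = as.character(label)),
            class = "region_spec")
}

check_region <- function(aln, region) {
  if (!inherits(region, "region_spec")) {
    region <- region_spec(region[[1L]], region[[2L]],
                          if (length(region) >= 3L) region[[3L]] else "")
  }
  if (region$end > aln$length) {
    stop(sprintf("region %d-%d out of range for alignment of length %d",
                 region$start, region$end, aln$length))
  }
  region
}

#' Extract a column interval from an alignment
#'
#' @param aln an \code{mt_alignment}.
#' @param region a \code{region_spec} (or a \code{c(start, end)} pair).
#' @return The sub-alignment of columns \code{start..end}, inclusive.
#' @examples
#' aln <- mt_alignment(c(a = "ACGT", b = "ACGA"))
#' extract_region(aln, region_spec(3, 3))$seqs
#' @export
extract_region <- function(aln, region) {
  region <- check_region(aln, region)
  mt_alignment(substr(aln$seqs, region$start, region$end),
               ids = aln$ids, descriptions = aln$descriptions)
}

#' Delete column intervals from an alignment
#'
#' Removes the union of the given regions' columns; overlapping regions are
#' permitted and the remaining columns keep their original order. This is the
#' operation behind "alignment with the high-divergence regions excluded".
#'
#' @param aln an \code{mt_alignment}.
#' @param regions a list of \code{region_spec}s.
#' @return An \code{mt_alignment} of length \code{aln$length} minus the size
#'   of the column union.
#' @export
delete_regions <- function(aln, regions) {
  if (inherits(regions, "region_spec")) regions <- list(regions)
  drop <- logical(aln$length)
  for (r in regions) {
    r <- check_region(aln, r)
    drop[r$start:r$end] <- TRUE
  }
  keep <- which(!drop)
  if (length(keep) == 0L) stop("all columns would be deleted")
  m <- as.matrix(aln)[, keep, drop = FALSE]
  mt_alignment(apply(m, 1L, paste, collapse = ""),
               ids = aln$ids, descriptions = aln$descriptions)
}

#' Count non-gap residues of one record inside a region
#'
#' Fragment lengths are conventionally reported "excluding alignment gaps";
#' this gives that number for a single sequence.
#'
#' @param aln an \code{mt_alignment}.
#' @param id sequence id.
#' @param region a \code{region_spec}.
#' @return Integer count of residues that are not \code{-}.
#' @export
ungapped_length <- function(aln, id, region) {
  region <- check_region(aln, region)
  s <- substr(aln$seqs[seq_index(aln, id)], region$start, region$end)
  nchar(gsub("-", "", s, fixed = TRUE))
}

#' Map an alignment column to an ungapped sequence position
#'
#' Read-only conversion from alignment-column space to the 1-based position
#' within a single ungapped sequence. Columns at which the sequence has a gap
#' map to the position of the last preceding residue (0 if none).
#'
#' @param aln an \code{mt_alignment}.
#' @param id sequence id.
#' @param columns integer vector of alignment columns.
#' @return Integer vector of ungapped positions.
#' @export
ungapped_position <- function(aln, id, columns) {
  ch <- strsplit(aln$seqs[seq_index(aln, id)], "", fixed = TRUE)[[1L]]
  cum <- cumsum(ch != "-")
  columns <- as.integer(columns)
  if (any(columns < 1L | columns > aln$length)) stop("column out of range")
  cum[columns]
}

#' Read an aligned FASTA file
#'
#' Parses with \pkg{Biostrings} and normalizes residues (uppercase; ambiguity
#' codes other than N mapped to N). Input order is preserved; all downstream
#' outputs list sequences in ingest order.
#'
#' @param path path to a FASTA file of equal-length sequences.
#' @return An \code{mt_alignment}.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- Biostrings::readBStringSet(path)
  hdr <- names(ss)
  ids <- sub("\\s.*$", "", hdr)
  desc <- ifelse(grepl("\\s", hdr), sub("^\\S+\\s+", "", hdr), "")
  mt_alignment(as.character(ss), ids = ids, descriptions = desc)
}

#' Write an alignment to FASTA
#'
#' @param aln an \code{mt_alignment}.
#' @param path output path.
#' @param width line width for wrapping.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(aln, path, width = 70L) {
  hdr <- ifelse(nzchar(aln$descriptions),
                paste(aln$ids, aln$descriptions), aln$ids)
  ss <- Biostrings::BStringSet(setNames(aln$seqs, hdr))
  Biostrings::writeXStringSet(ss, filepath = path, width = width)
  invisible(path)
}

#' Read sequences from a GenBank flat file
#'
#' Minimal read-only convenience: extracts the accession (VERSION, falling
#' back to LOCUS) and the ORIGIN sequence of each record. Features and
#' annotations are ignored. Multiple records per file are supported; the
#' result is unaligned, so records are returned as a named character vector
#' rather than an \code{mt_alignment}.
#'
#' @param path path to a GenBank flat file.
#' @return Named character vector of normalized sequences.
#' @export
read_genbank <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  recs <- split(lines, cumsum(grepl("^LOCUS", lines)))
  recs <- recs[names(recs) != "0"]
  if (!length(recs)) stop("no GenBank records found in ", path)
  out <- character(0)
  for (rec in recs) {
    ver <- grep("^VERSION", rec, value = TRUE)
    id <- if (length(ver)) strsplit(trimws(ver[1L]), "\\s+")[[1L]][2L] else
      strsplit(trimws(rec[1L]), "\\s+")[[1L]][2L]
    o <- grep("^ORIGIN", rec)
    if (!length(o)) stop("record ", id, " has no ORIGIN section")
    body <- rec[(o[1L] + 1L):length(rec)]
    body <- body[!grepl("^//", body)]
    seq <- gsub("[^A-Za-z]", "", paste(body, collapse = ""))
    out[id] <- normalize_residues(seq)
  }
  out
}

#' Read a region file
#'
#' Three-column tab-separated text: label, start, end (1-based inclusive).
#'
#' @param path path to the region file.
#' @return List of \code{region_spec}s.
#' @export
read_regions <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("label", "start", "end"),
                   stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)),
         function(i) region_spec(df$start[i], df$end[i], df$label[i]))
}

#' Write regions to a tab-separated file
#'
#' @param regions list of \code{region_spec}s.
#' @param path output path.
#' @param bed if \code{TRUE}, write BED-like 0-based half-open coordinates
#'   (label, start-1, end) instead of the native 1-based inclusive format.
#' @return \code{path}, invisibly.
#' @export
write_regions <- function(regions, path, bed = FALSE) {
  if (inherits(regions, "region_spec")) regions <- list(regions)
  df <- data.frame(
    label = vapply(regions, function(r) r$label, ""),
    start = vapply(regions, function(r) r$start, 0L),
    end = vapply(regions, function(r) r$end, 0L)
  )
  if (bed) df$start <- df$start - 1L
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Run expr with a fixed RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
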