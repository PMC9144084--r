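# Expected p-distance between two tips of a star phylogeny whose branches
# substitute each site independently with probabilities qa, qb (replacement
# uniform among the 3 alternative bases). Coincident substitutions to the
# same base are counted as identity, hence the -4/3 term.
pair_divergence <- function(qa, qb) qa + qb - (4 / 3) * qa * qb

# Per-branch substitution probabilities reproducing a matrix of pairwise
# divergence targets on a star phylogeny. Exact closed form for two
# lineages; least-squares fit for three or more.
solve_branch_probs <- function(targets) {
  n <- nrow(targets)
  if (n == 1L) return(0)
  if (n == 2L) {
    d <- targets[1L, 2L]
    q <- (2 - sqrt(4 - 16 * d / 3)) / (8 / 3)
    return(rep(q, 2L))
  }
  pairs <- utils::combn(n, 2L)
  d <- targets[t(pairs)]
  obj <- function(lq) {
    q <- exp(lq)
    sum((pair_divergence(q[pairs[1L, ]], q[pairs[2L, ]]) - d)^2)
  }
  fit <- optim(log(pmax(rowMeans(targets) * n / (n - 1L) / 2, 1e-4)), obj,
               method = "BFGS", control = list(maxit = 500, reltol = 1e-14))
  q <- exp(fit$par)
  resid <- max(abs(pair_divergence(q[pairs[1L, ]], q[pairs[2L, ]]) - d))
  if (resid > 1e-6 || any(q <= 0) || any(q >= 0.75)) {
    stop("unsatisfiable interspecific divergence targets")
  }
  q
}

#' Configure a mosaic-genome simulation
#'
#' Describes the data regime the detection pipeline assumes: a few species
#' lineages at interspecific divergence, several conspecific individuals at
#' low intraspecific divergence, and recombinant fragments planted from donor
#' species into recipient genomes with a known number of post-transfer
#' mutations. Sites evolve independently with uniform replacement among the
#' three alternative bases (Jukes-Cantor-like), no rate heterogeneity and no
#' indels, so the alignment is gapless and planted breakpoints are exact.
#'
#' @param genome_length alignment columns (default 16500, a typical fish
#'   mitochondrial genome).
#' @param n_species number of species lineages (default 3).
#' @param n_individuals_per_species integer vector (recycled) of individuals
#'   per species (default \code{c(5, 1, 1)}: a focal species panel plus one
#'   reference genome per donor species).
#' @param interspecific_divergence pairwise expected p-distance targets
#'   between species references: a single value, a vector over species pairs
#'   in \code{combn} order (1-2, 1-3, 2-3, ...), or a full symmetric matrix.
#'   Default \code{c(0.085, 0.045, 0.085)}: the focal species sits 8.5% from
#'   the first donor and 4.5% from the second.
#' @param intraspecific_divergence expected p-distance between conspecific
#'   individuals (default 0.003); individuals are derived from their species
#'   reference at per-site rate \code{intraspecific_divergence / 2}.
#' @param planted_events data frame with columns \code{recipient} (individual
#'   id), \code{donor} (species name or individual id), \code{start},
#'   \code{length} (alignment columns) and \code{mutations} (post-transfer
#'   substitutions applied inside the fragment); NULL for none.
#' @param species_names species labels (default LETTERS); individual ids are
#'   \code{paste0(species, index)}, e.g. \code{"A1"}.
#' @param seed RNG seed; identical seeds give byte-identical output.
#' @return A validated list of class \code{sim_config}.
#' @seealso \code{\link{reference_mosaic_config}} for the bundled icefish-like
#'   regime, \code{\link{simulate_mosaic}}.
#' @export
sim_config <- function(genome_length = 16500L, n_species = 3L,
                       n_individuals_per_species = c(5L, 1L, 1L),
                       interspecific_divergence = c(0.085, 0.045, 0.085),
                       intraspecific_divergence = 0.003,
                       planted_events = NULL,
                       species_names = LETTERS[seq_len(n_species)],
                       seed = 1L) {
  n_species <- as.integer(n_species)
  genome_length <- as.integer(genome_length)
  stopifnot(n_species >= 1L, genome_length >= 1L)
  n_ind <- rep_len(as.integer(n_individuals_per_species), n_species)
  npair <- n_species * (n_species - 1L) / 2L
  D <- matrix(0, n_species, n_species)
  if (is.matrix(interspecific_divergence)) {
    D <- interspecific_divergence
  } else if (npair > 0L) {
    v <- rep_len(interspecific_divergence, npair)
    D[t(utils::combn(n_species, 2L))] <- v
    D <- D + t(D)
  }
  offdiag <- D[upper.tri(D)]
  if (n_species > 1L && (any(offdiag <= 0) || any(offdiag >= 0.75))) {
    stop("interspecific divergences must lie in (0, 0.75)")
  }
  if (intraspecific_divergence <= 0 || intraspecific_divergence >= 0.75) {
    stop("intraspecific divergence must lie in (0, 0.75)")
  }
  ids <- unlist(lapply(seq_len(n_species), function(s) {
    paste0(species_names[s], seq_len(n_ind[s]))
  }))
  groups <- setNames(rep(species_names, n_ind), ids)
  if (!is.null(planted_events)) {
    planted_events <- as.data.frame(planted_events)
    need <- c("recipient", "donor", "start", "length", "mutations")
    if (!all(need %in% names(planted_events))) {
      stop("planted_events needs columns: ", paste(need, collapse = ", "))
    }
    planted_events$end <- planted_events$start + planted_events$length - 1L
    if (any(planted_events$start < 1L) ||
        any(planted_events$end > genome_length)) {
      stop("planted event out of genome bounds")
    }
    if (any(!planted_events$recipient %in% ids)) stop("unknown recipient id")
    for (r in unique(planted_events$recipient)) {
      e <- planted_events[planted_events$recipient == r, , drop = FALSE]
      e <- e[order(e$start), , drop = FALSE]
      if (nrow(e) > 1L && any(e$start[-1L] <= e$end[-nrow(e)])) {
        stop("overlapping planted events for recipient ", r)
      }
    }
    if (any(planted_events$mutations > planted_events$length)) {
      stop("more post-transfer mutations than fragment sites")
    }
  }
  structure(list(genome_length = genome_length, n_species = n_species,
                 n_individuals_per_species = n_ind,
                 interspecific_divergence = D,
                 intraspecific_divergence = intraspecific_divergence,
                 planted_events = planted_events,
                 species_names = species_names[seq_len(n_species)],
                 ids = ids, groups = groups, seed = as.integer(seed)),
            class = "sim_config")
}

#' The bundled reference simulation regime
#'
#' A ready-made \code{\link{sim_config}} emulating the icefish study
#' conditions the package is validated against: three species lineages
#' (a focal species "A" with five individuals and two donor species "B" and
#' "C" with one reference genome each) at 8.5% / 4.5% interspecific and 0.3%
#' intraspecific divergence over 16,500 columns, with four planted fragments
#' at the canonical coordinates: 140 bp at 5566 (donor B, 0 post-transfer
#' mutations), 1710 bp at 10167 into two recipients (donor B, 2 mutations
#' each), 425 bp at 12946 (donor C, 4 mutations) and 359 bp at 15606
#' (donor B, 0 mutations). Recipients A1 (three fragments), A2 (one) and A3
#' (one); A4 and A5 stay clean.
#'
#' @param seed RNG seed.
#' @return A \code{sim_config}.
#' @export
reference_mosaic_config <- function(seed = 1L) {
  sim_config(
    genome_length = 16500L, n_species = 3L,
    n_individuals_per_species = c(5L, 1L, 1L),
    interspecific_divergence = c(0.085, 0.045, 0.085),
    intraspecific_divergence = 0.003,
    planted_events = data.frame(
      recipient = c("A1", "A1", "A1", "A2", "A3"),
      donor = c("B", "B", "B", "B", "C"),
      start = c(5566L, 10167L, 15606L, 10167L, 12946L),
      length = c(140L, 1710L, 359L, 1710L, 425L),
      mutations = c(0L, 2L, 0L, 2L, 4L)),
    seed = seed)
}

mutate_chars <- function(chars, idx) {
  if (!length(idx)) return(chars)
  off <- sample.int(3L, length(idx), replace = TRUE)
  base_idx <- match(chars[idx], BASES)
  chars[idx] <- BASES[(base_idx - 1L + off) %% 4L + 1L]
  chars
}

#' Simulate an aligned mosaic-genome dataset
#'
#' Draws a uniform-random ancestral sequence; derives one reference per
#' species by independent per-site substitution with branch probabilities
#' calibrated (exactly, accounting for coincident substitutions) to the
#' configured pairwise divergence targets; derives individuals from their
#' species reference at rate \code{intraspecific_divergence / 2}; then
#' creates recombinants by splicing donor fragments over recipient columns
#' and applying exactly the configured number of post-transfer substitutions
#' inside each fragment, at recorded positions. The alignment is gapless.
#'
#' @param config a \code{\link{sim_config}}.
#' @return A list with \code{alignment} (an \code{mt_alignment}),
#'   \code{truth} (class \code{sim_truth}: planted events with exact
#'   \code{begin}/\code{end} columns, donor ids and mutation positions, the
#'   realized species-reference divergences, and the seed) and \code{groups}
#'   (named id -> species vector, ready for \code{\link{recombination_scan}}).
#' @export
simulate_mosaic <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  L <- config$genome_length
  ns <- config$n_species
  with_seed(config$seed, {
    q <- solve_branch_probs(config$interspecific_divergence)
    anc <- BASES[sample.int(4L, L, replace = TRUE)]
    refs <- lapply(seq_len(ns), function(s) {
      mutate_chars(anc, which(runif(L) < q[s]))
    })
    names(refs) <- config$species_names
    r_intra <- config$intraspecific_divergence / 2
    seqs <- list()
    for (s in seq_len(ns)) {
      for (i in seq_len(config$n_individuals_per_species[s])) {
        id <- paste0(config$species_names[s], i)
        seqs[[id]] <- mutate_chars(refs[[s]], which(runif(L) < r_intra))
      }
    }
    ev <- config$planted_events
    truth_events <- data.frame(recipient = character(0), donor = character(0),
                               begin = integer(0), end = integer(0),
                               n_mutations = integer(0))
    mut_positions <- list()
    if (!is.null(ev) && nrow(ev)) {
      for (i in seq_len(nrow(ev))) {
        donor <- ev$donor[i]
        if (donor %in% config$species_names) donor <- paste0(donor, "1")
        if (!donor %in% names(seqs)) stop("unknown donor: ", ev$donor[i])
        rng <- ev$start[i]:ev$end[i]
        frag <- seqs[[donor]][rng]
        nm <- ev$mutations[i]
        pos <- sort(sample(rng, nm))
        frag[match(pos, rng)] <- mutate_chars(frag[match(pos, rng)],
                                              seq_len(nm))
        seqs[[ev$recipient[i]]][rng] <- frag
        truth_events <- rbind(truth_events, data.frame(
          recipient = ev$recipient[i], donor = donor,
          begin = as.integer(ev$start[i]), end = as.integer(ev$end[i]),
          n_mutations = as.integer(nm)))
        mut_positions[[i]] <- as.integer(pos)
      }
    }
    realized <- matrix(0, ns, ns, dimnames = list(config$species_names,
                                                  config$species_names))
    if (ns > 1L) {
      for (s in seq_len(ns - 1L)) for (t in (s + 1L):ns) {
        realized[s, t] <- realized[t, s] <- mean(refs[[s]] != refs[[t]])
      }
    }
    aln <- mt_alignment(vapply(seqs, paste, "", collapse = ""),
                        ids = names(seqs))
    truth <- structure(
      list(events = truth_events, mutation_positions = mut_positions,
           realized_divergence = realized, seed = config$seed),
      class = "sim_truth")
    list(alignment = aln, truth = truth, groups = config$groups)
  })
}

#' Write a simulation truth file
#'
#' JSON with fixed key ordering; write then read round-trips.
#'
#' @param truth a \code{sim_truth}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_truth <- function(truth, path) {
  obj <- list(
    seed = truth$seed,
    events = lapply(seq_len(nrow(truth$events)), function(i) {
      list(recipient = truth$events$recipient[i],
           donor = truth$events$donor[i],
           begin = truth$events$begin[i],
           end = truth$events$end[i],
           n_mutations = truth$events$n_mutations[i],
           mutation_positions = I(truth$mutation_positions[[i]]))
    }),
    realized_divergence = truth$realized_divergence
  )
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = 10,
                              pretty = TRUE),
             path)
  invisible(path)
}

#' Read a simulation truth file
#'
#' @param path path written by \code{\link{write_truth}}.
#' @return A \code{sim_truth}.
#' @export
read_truth <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  for (f in c("seed", "events", "realized_divergence")) {
    if (is.null(obj[[f]])) stop("truth file missing field: ", f)
  }
  need <- c("recipient", "donor", "begin", "end", "n_mutations",
            "mutation_positions")
  events <- data.frame(recipient = character(0), donor = character(0),
                       begin = integer(0), end = integer(0),
                       n_mutations = integer(0))
  mut_positions <- list()
  for (i in seq_along(obj$events)) {
    e <- obj$events[[i]]
    for (f in need) {
      if (is.null(e[[f]])) stop("truth event missing field: ", f)
    }
    events <- rbind(events, data.frame(
      recipient = e$recipient, donor = e$donor,
      begin = as.integer(e$begin), end = as.integer(e$end),
      n_mutations = as.integer(e$n_mutations)))
    mut_positions[[i]] <- as.integer(unlist(e$mutation_positions))
  }
  rd <- obj$realized_divergence
  if (is.list(rd)) rd <- do.call(rbind, lapply(rd, unlist))
  structure(list(events = events, mutation_positions = mut_positions,
                 realized_divergence = rd,
                 seed = as.integer(obj$seed)),
            class = "sim_truth")
}
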