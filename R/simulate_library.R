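#' Simulate a codon-mutant clone library
#'
#' Draws, for every clone, a Poisson(lambda_mut) number of mutated
#' codons (truncated at L), positions uniformly without replacement
#' over 1..L, and for each mutated position a codon drawn uniformly
#' from the 63 non-wild-type triplets (NNN model: all alternatives,
#' including stops and synonymous codons).
#'
#' @param preset a [library_preset()].
#' @param seed integer seed or NULL.
#' @return An object of class `clone_library`: list with the preset and
#'   a data.table `mutations` (clone_id, position, codon).  Clones
#'   absent from `mutations` are unmutated.
#' @export
simulate_clone_library <- function(preset, seed = NULL) {
  stopifnot(inherits(preset, "library_preset"))
  if (preset$lambda_mut > preset$L)
    stop("degenerate preset: lambda_mut exceeds gene length")
  L <- preset$L
  n <- preset$n_clones
  with_seed(seed, {
    k <- rpois(n, preset$lambda_mut)
    while (any(bad <- k > L)) k[bad] <- rpois(sum(bad), preset$lambda_mut)
    idx <- which(k > 0L)
    pos_list <- lapply(idx, function(i)
      if (k[i] == 1L) sample.int(L, 1L) else sample.int(L, k[i]))
    clone_id <- rep.int(idx, k[idx])
    position <- unlist(pos_list, use.names = FALSE)
    if (is.null(position)) position <- integer(0)
    # uniform over the 63 non-wt codons: draw an index 1..63 and skip
    # past the wt codon's slot
    wt_idx <- match(preset$wt_codons, codon_alphabet())
    alt <- sample.int(63L, length(position), replace = TRUE)
    alt <- alt + (alt >= wt_idx[position])
    mutations <- data.table::data.table(
      clone_id = clone_id, position = position,
      codon = codon_alphabet()[alt])
    data.table::setkey(mutations, clone_id, position)
    structure(list(preset = preset, mutations = mutations,
                   n_clones = n),
              class = "clone_library")
  })
}

#' @export
print.clone_library <- function(x, ...) {
  cat(sprintf("<clone_library> %s: %d clones, %d mutations (mean %.3f/clone)\n",
              x$preset$gene_id, x$n_clones, nrow(x$mutations),
              nrow(x$mutations) / x$n_clones))
  invisible(x)
}

#' Planted per-substitution effect multipliers
#'
#' Ground-truth fitness table for recovery testing: each
#' (position, mutant amino acid) pair maps to a non-negative
#' multiplier applied to the base selection rate.  Unlisted
#' substitutions (and all synonymous changes) have multiplier 1.
#'
#' @param position integer residue positions (1-based).
#' @param aa one-letter mutant amino acids.
#' @param multiplier non-negative multipliers.
#' @return data.table of class `effect_table`.
#' @export
effect_table <- function(position = integer(0), aa = character(0),
                         multiplier = numeric(0)) {
  stopifnot(length(position) == length(aa),
            length(aa) == length(multiplier),
            all(multiplier >= 0))
  x <- data.table::data.table(position = as.integer(position),
                              aa = aa, multiplier = as.numeric(multiplier))
  data.table::setkey(x, position, aa)
  data.table::setattr(x, "class", c("effect_table", class(x)))
  x
}

#' Selection probability of a single clone
#'
#' `min(1, base_rate * prod(multipliers))` over the clone's amino-acid
#' changes; synonymous codon changes contribute multiplier 1, so a
#' wild-type (or all-synonymous) clone is selected at `base_rate`.
#'
#' @param clone data.frame with columns `position`, `codon` (the
#'   clone's mutated codons); zero rows for a wild-type clone.
#' @param wt_codons wild-type codons of the gene.
#' @param effects an [effect_table()].
#' @param base_rate per-cell selection probability of a wild-type
#'   clone.
#' @return Probability in `[0, 1]`.
#' @export
clone_selection_probability <- function(clone, wt_codons, effects,
                                        base_rate) {
  stopifnot(base_rate >= 0, base_rate <= 1)
  if (NROW(clone) == 0L) return(base_rate)
  mut_aa <- translate_codons(clone$codon)
  wt_aa <- translate_codons(wt_codons[clone$position])
  keep <- mut_aa != wt_aa
  if (!any(keep)) return(base_rate)
  m <- lookup_multiplier(effects, clone$position[keep], mut_aa[keep])
  min(1, base_rate * prod(m))
}

lookup_multiplier <- function(effects, position, aa) {
  if (is.null(effects) || nrow(effects) == 0L)
    return(rep(1, length(position)))
  q <- data.table::data.table(position = as.integer(position), aa = aa)
  hit <- effects[q, on = c("position", "aa")]$multiplier
  hit[is.na(hit)] <- 1
  hit
}

# vectorised per-clone selection probabilities for a whole library
selection_probabilities <- function(library, effects, base_rate) {
  n <- library$n_clones
  p <- rep(base_rate, n)
  mut <- library$mutations
  if (nrow(mut) == 0L) return(p)
  mut_aa <- translate_codons(mut$codon)
  wt_aa <- translate_codons(library$preset$wt_codons[mut$position])
  ns <- mut_aa != wt_aa
  if (!any(ns)) return(p)
  d <- data.table::data.table(clone_id = mut$clone_id[ns],
                              m = lookup_multiplier(effects,
                                                    mut$position[ns],
                                                    mut_aa[ns]))
  agg <- d[, list(mult = prod(m)), by = "clone_id"]
  p[agg$clone_id] <- pmin(1, base_rate * agg$mult)
  p
}

#' Simulate a selection screen over a clone library
#'
#' Cells are allocated to clones by multinomial sampling (`n_cells`
#' cells, clones equiprobable, emulating outgrowth of a pooled
#' library); the unselected control table is that allocation.  The
#' selected table draws, per clone, a binomial number of surviving
#' cells with the clone's selection probability.
#'
#' @param library a [simulate_clone_library()] result.
#' @param effects an [effect_table()] of planted multipliers.
#' @param config a [screen_config()]; `config$seed` is honoured.
#' @return list of class `screen_counts` with integer vectors
#'   `selected` and `unselected` (one entry per clone) and the
#'   per-clone probabilities used.
#' @export
simulate_selection <- function(library, effects = effect_table(),
                               config = screen_config()) {
  stopifnot(inherits(library, "clone_library"))
  p <- selection_probabilities(library, effects, config$base_rate)
  with_seed(config$seed, {
    n <- library$n_clones
    cells <- as.integer(rmultinom(1L, config$n_cells, rep(1, n))[, 1L])
    selected <- rbinom(n, cells, p)
    if (sum(selected) < 100L)
      warning("underpowered screen: fewer than 100 selected cells")
    structure(list(selected = selected, unselected = cells,
                   probabilities = p),
              class = "screen_counts")
  })
}

#' Exact codon-count table implied by clone counts
#'
#' The "perfect sequencing" route: converts per-clone counts directly
#' into a per-position codon-count matrix, bypassing read simulation
#' and consensus calling.  Serves as the zero-error oracle for the
#' sequencing-based route.
#'
#' @param library a `clone_library`.
#' @param clone_counts integer vector of per-clone weights (one entry
#'   per clone).
#' @param sample_id label stored on the table.
#' @return A `codon_count_table` (positions x 64 matrix).
#' @export
codon_counts_from_clones <- function(library, clone_counts,
                                     sample_id = "sample") {
  stopifnot(length(clone_counts) == library$n_clones)
  L <- library$preset$L
  counts <- matrix(0, nrow = L, ncol = 64L,
                   dimnames = list(seq_len(L), codon_alphabet()))
  total <- sum(clone_counts)
  wt_idx <- match(library$preset$wt_codons, codon_alphabet())
  counts[cbind(seq_len(L), wt_idx)] <- total
  mut <- library$mutations
  if (nrow(mut) > 0L) {
    w <- clone_counts[mut$clone_id]
    keep <- w > 0
    if (any(keep)) {
      d <- data.table::data.table(position = mut$position[keep],
                                  codon = mut$codon[keep], w = w[keep])
      agg <- d[, list(n = sum(w)), by = c("position", "codon")]
      ci <- match(agg$codon, codon_alphabet())
      counts[cbind(agg$position, ci)] <-
        counts[cbind(agg$position, ci)] + agg$n
      # subtract from wt what was reassigned to mutants
      per_pos <- d[, list(n = sum(w)), by = "position"]
      counts[cbind(per_pos$position, wt_idx[per_pos$position])] <-
        counts[cbind(per_pos$position, wt_idx[per_pos$position])] - per_pos$n
    }
  }
  codon_count_table(counts, wt_codons = library$preset$wt_codons,
                    sample_id = sample_id)
}
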