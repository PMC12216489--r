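#' Shannon entropy of preference distributions (bits)
#'
#' `SE = -sum(pi * log2(pi))` with `0 * log 0 := 0`.  Rows must sum to
#' 1 within 1e-6.  High entropy marks mutationally tolerant sites; a
#' point mass gives 0, a uniform distribution over 20 residues gives
#' `log2(20) ~ 4.3219`.
#'
#' @param p a preference row (numeric vector summing to 1) or a
#'   preference matrix (one row per site).
#' @return Entropy in bits (vector for a matrix input).
#' @export
shannon_entropy <- function(p) {
  if (is.matrix(p)) {
    bad <- abs(rowSums(p) - 1) > 1e-6
    if (any(bad)) stop("preference rows not normalized: site(s) ",
                       paste(utils::head(which(bad), 5L), collapse = ", "))
    x <- unclass(p)
    x[x == 0] <- 1  # 1 * log2(1) = 0
    return(-rowSums(x * log2(x)))
  }
  if (abs(sum(p) - 1) > 1e-6) stop("preference row not normalized")
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Per-site differential-selection summaries
#'
#' `pos_sum_diffsel` is the sum of positive diffsel entries;
#' `max_diffsel` is the largest diffsel over non-wild-type residues
#' (the wild-type entry, identically 0, would floor the maximum).
#'
#' @param diffsel a `diffsel_matrix`, or a numeric vector for one site
#'   (with `wt_aa` naming the wild-type residue to exclude).
#' @param wt_aa wild-type residue(s); defaults to the matrix
#'   attribute.
#' @return data.frame with `site`, `pos_sum_diffsel`, `max_diffsel`.
#' @export
site_diffsel_summaries <- function(diffsel, wt_aa = NULL) {
  if (!is.matrix(diffsel)) diffsel <- matrix(diffsel, nrow = 1,
                                             dimnames = list(1, names(diffsel)))
  wt_aa <- wt_aa %||% attr(diffsel, "wt_aa")
  if (is.null(wt_aa)) stop("wild-type amino acids unknown")
  x <- unclass(diffsel)
  pos_sum <- rowSums(pmax(x, 0))
  wt_col <- match(wt_aa, colnames(x))
  x[cbind(seq_len(nrow(x)), wt_col)] <- -Inf
  data.frame(site = seq_len(nrow(x)),
             pos_sum_diffsel = pos_sum,
             max_diffsel = apply(x, 1L, max))
}

#' Min-max scale a metric over the sites of one protein
#'
#' `(v - min) / (max - min)`, mapping the smallest value to 0 and the
#' largest to 1.  A constant vector maps to all zeros ("all minimal");
#' callers should flag this degenerate case.
#'
#' @param v numeric vector (one value per site).
#' @return Scaled vector in `[0, 1]`.
#' @export
minmax_scale <- function(v) {
  stopifnot(length(v) >= 1L)
  rng <- range(v)
  if (rng[1L] == rng[2L]) return(rep(0, length(v)))
  (v - rng[1L]) / (rng[2L] - rng[1L])
}

#' Composite gain-of-function site score
#'
#' `score = pos_sum_diffsel_scaled + max_diffsel_scaled - SE_scaled`,
#' each component min-max scaled per protein, so scores lie in
#' `[-1, 2]`: high positive selection at a low-entropy (otherwise
#' intolerant) site scores highest.
#'
#' @param pos_sum_scaled,max_scaled,se_scaled scaled metrics in
#'   `[0, 1]`.
#' @return Numeric score vector.
#' @export
composite_score <- function(pos_sum_scaled, max_scaled, se_scaled) {
  stopifnot(all(pos_sum_scaled >= 0 & pos_sum_scaled <= 1),
            all(max_scaled >= 0 & max_scaled <= 1),
            all(se_scaled >= 0 & se_scaled <= 1))
  pos_sum_scaled + max_scaled - se_scaled
}

#' Score every site of a protein
#'
#' Combines Shannon entropy (from replicate-aggregated preferences)
#' and the differential-selection summaries (from replicate-aggregated
#' diffsel) into the composite score, sorted descending by score with
#' ties broken by site index.
#'
#' @param preferences a `preference_matrix`.
#' @param diffsel a `diffsel_matrix` of the same sites.
#' @return data.frame of class `site_score_table`: site, wt_aa, SE,
#'   pos_sum_diffsel, max_diffsel, the three scaled metrics, score.
#' @export
score_sites <- function(preferences, diffsel) {
  stopifnot(nrow(preferences) == nrow(diffsel))
  se <- shannon_entropy(preferences)
  sums <- site_diffsel_summaries(diffsel)
  out <- data.frame(
    site = sums$site,
    wt_aa = attr(diffsel, "wt_aa") %||% NA_character_,
    SE = se,
    pos_sum_diffsel = sums$pos_sum_diffsel,
    max_diffsel = sums$max_diffsel,
    SE_scaled = minmax_scale(se),
    pos_sum_diffsel_scaled = minmax_scale(sums$pos_sum_diffsel),
    max_diffsel_scaled = minmax_scale(sums$max_diffsel),
    stringsAsFactors = FALSE)
  out$score <- composite_score(out$pos_sum_diffsel_scaled,
                               out$max_diffsel_scaled, out$SE_scaled)
  out <- out[order(-out$score, out$site), ]
  rownames(out) <- NULL
  class(out) <- c("site_score_table", class(out))
  out
}

#' Nominate the top-k candidate substitutions
#'
#' Takes the k highest-scoring sites and, at each, the non-wild-type
#' amino acid with the largest differential selection (ties broken by
#' alphabetical order; site ties by lower index).
#'
#' @param scores a [score_sites()] table.
#' @param diffsel the `diffsel_matrix` the scores derive from.
#' @param k number of substitutions (default 8, the number of
#'   candidates advanced to validation per protein).
#' @return data.frame: rank, site, wt_aa, substitution (e.g. "M77H"),
#'   aa, diffsel, score.
#' @export
select_top_substitutions <- function(scores, diffsel, k = 8L) {
  stopifnot(k >= 0L)
  if (k > nrow(scores)) {
    warning("k exceeds the number of sites; truncating")
    k <- nrow(scores)
  }
  top <- utils::head(scores, k)
  if (k == 0L)
    return(data.frame(rank = integer(0), site = integer(0),
                      wt_aa = character(0), aa = character(0),
                      substitution = character(0), diffsel = numeric(0),
                      score = numeric(0), stringsAsFactors = FALSE))
  x <- unclass(diffsel)
  wt_aa <- attr(diffsel, "wt_aa")
  pick <- vapply(seq_len(k), function(i) {
    row <- x[top$site[i], ]
    row[colnames(x) == wt_aa[top$site[i]]] <- -Inf
    # which.max returns the first (alphabetical) maximum
    which.max(row)
  }, integer(1))
  aa <- colnames(x)[pick]
  data.frame(rank = seq_len(k), site = top$site, wt_aa = top$wt_aa,
             aa = aa,
             substitution = paste0(top$wt_aa, top$site, aa),
             diffsel = x[cbind(top$site, pick)],
             score = top$score, stringsAsFactors = FALSE)
}

#' Write the complete per-site scoring table as TSV
#'
#' One row per site with entropy, diffsel summaries, scaled metrics,
#' composite score and the nominated substitution, mirroring the
#' supplementary scoring-table layout.
#'
#' @param scores a [score_sites()] table.
#' @param diffsel the matching `diffsel_matrix`.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_site_scores <- function(scores, diffsel, path) {
  subs <- select_top_substitutions(scores, diffsel, k = nrow(scores))
  merged <- merge(as.data.frame(scores),
                  subs[, c("site", "aa", "diffsel")],
                  by = "site", sort = FALSE)
  data.table::setnames(merged, c("aa", "diffsel"),
                       c("top_substitution", "top_substitution_diffsel"))
  merged <- merged[order(-merged$score, merged$site), ]
  write_tsv_(merged, path)
}
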