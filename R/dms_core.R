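#' Normalize a count table to reads per million (RPM)
#'
#' @param table numeric matrix of counts (codon- or amino-acid-level);
#'   attributes are preserved.
#' @return Matrix of the same shape whose grand total is 1e6.
#' @export
to_rpm <- function(table) {
  total <- sum(table)
  if (total <= 0) stop("empty sample: total count is zero")
  out <- table * (1e6 / total)
  attributes(out) <- attributes(table)
  out
}

aa_levels <- function() c(aa_alphabet(), "*")

#' Aggregate a codon-level table to amino-acid level
#'
#' Sums synonymous codons per site.  Stop codons are aggregated into a
#' `*` column, retained for QC; downstream preference and differential
#' selection operations exclude it.
#'
#' @param table a `codon_count_table` (or matrix with 64 codon
#'   columns); counts or RPM.
#' @return Matrix sites x 21 (20 amino acids + `*`), with attributes
#'   `wt_aa` and `sample_id`.
#' @export
aggregate_to_aa <- function(table) {
  stopifnot(ncol(table) == 64L)
  aa_of <- translate_codons(colnames(table))
  ind <- outer(aa_of, aa_levels(), "==") * 1
  out <- unclass(table) %*% ind
  colnames(out) <- aa_levels()
  rownames(out) <- rownames(table)
  wt_codons <- attr(table, "wt_codons")
  structure(out,
            wt_aa = if (!is.null(wt_codons)) translate_codons(wt_codons),
            sample_id = attr(table, "sample_id"))
}

check_same_shape <- function(a, b) {
  if (!identical(dim(a), dim(b)) ||
      !identical(colnames(a), colnames(b)))
    stop("tables do not share the same shape")
}

#' Per-entry enrichment of selected over unselected RPM
#'
#' `(sel + p) / (unsel + p)` with a symmetric pseudocount `p`
#' (default 0.5 RPM), guaranteeing finite positive ratios.
#'
#' @param sel,unsel amino-acid-level RPM matrices of identical shape.
#' @param pseudocount positive pseudocount in RPM units.
#' @return Matrix of enrichment ratios.
#' @export
enrichment <- function(sel, unsel, pseudocount = 0.5) {
  stopifnot(pseudocount > 0)
  check_same_shape(sel, unsel)
  out <- (unclass(sel) + pseudocount) / (unclass(unsel) + pseudocount)
  attributes(out) <- attributes(unclass(sel))
  attr(out, "wt_aa") <- attr(sel, "wt_aa")
  out
}

#' Amino-acid preferences from enrichment ratios
#'
#' Per site, the preference of an amino acid is its enrichment divided
#' by the site's summed enrichment over the 20 standard amino acids
#' (stop excluded); each row sums to 1.
#'
#' @param enr enrichment matrix (from [enrichment()]).
#' @return Matrix sites x 20 of class `preference_matrix`.
#' @export
preferences <- function(enr) {
  keep <- intersect(colnames(enr), aa_alphabet())
  x <- unclass(enr)[, keep, drop = FALSE]
  out <- x / rowSums(x)
  structure(out, wt_aa = attr(enr, "wt_aa"),
            class = c("preference_matrix", "matrix", "array"))
}

#' Wild-type-relative differential selection (log2)
#'
#' For site s and amino acid a:
#' `log2( ((sel[s,a]+p)/(sel[s,wt]+p)) / ((unsel[s,a]+p)/(unsel[s,wt]+p)) )`.
#' The wild-type entry is 0 by construction; positive values mark
#' residues favored over wild type under selection.  Stop codons are
#' excluded (kept in the QC aggregate only).
#'
#' @param sel,unsel amino-acid-level RPM matrices.
#' @param wt_aa wild-type amino acid per site (default: the `wt_aa`
#'   attribute of `sel`).
#' @param pseudocount positive pseudocount in RPM units (default 0.5).
#' @return Matrix sites x 20 of class `diffsel_matrix`, attribute
#'   `wt_aa`.
#' @export
differential_selection <- function(sel, unsel, wt_aa = NULL,
                                   pseudocount = 0.5) {
  stopifnot(pseudocount > 0)
  check_same_shape(sel, unsel)
  wt_aa <- wt_aa %||% attr(sel, "wt_aa")
  if (is.null(wt_aa)) stop("wild-type amino acids unknown")
  keep <- intersect(colnames(sel), aa_alphabet())
  s <- unclass(sel)[, keep, drop = FALSE]
  u <- unclass(unsel)[, keep, drop = FALSE]
  wt_col <- match(wt_aa, keep)
  if (anyNA(wt_col)) stop("wt_aa contains non-standard residues")
  sw <- s[cbind(seq_len(nrow(s)), wt_col)]
  uw <- u[cbind(seq_len(nrow(u)), wt_col)]
  out <- log2(((s + pseudocount) / (sw + pseudocount)) /
                ((u + pseudocount) / (uw + pseudocount)))
  out[cbind(seq_len(nrow(out)), wt_col)] <- 0
  structure(out, wt_aa = wt_aa,
            class = c("diffsel_matrix", "matrix", "array"))
}

#' Aggregate replicate preference and differential-selection tables
#'
#' Preferences are averaged entrywise and rows renormalized to sum to
#' 1; differential selection is the entrywise median, the robust
#' summary used for reporting.
#'
#' @param preference_list list of preference matrices (identical
#'   shapes).
#' @param diffsel_list list of diffsel matrices (identical shapes).
#' @return list with `preferences` (mean, renormalized) and `diffsel`
#'   (median); either element NULL when its input list is empty/NULL.
#' @export
aggregate_replicates <- function(preference_list = NULL,
                                 diffsel_list = NULL) {
  agg <- function(lst, fun) {
    stopifnot(length(lst) >= 1L)
    for (x in lst[-1L]) check_same_shape(lst[[1L]], x)
    arr <- array(unlist(lapply(lst, unclass)),
                 dim = c(dim(lst[[1L]]), length(lst)))
    out <- apply(arr, c(1, 2), fun)
    dimnames(out) <- dimnames(lst[[1L]])
    attributes(out) <- attributes(unclass(lst[[1L]]))
    out
  }
  prefs <- NULL
  if (length(preference_list) > 0L) {
    prefs <- agg(preference_list, mean)
    prefs <- prefs / rowSums(prefs)
    attr(prefs, "wt_aa") <- attr(preference_list[[1L]], "wt_aa")
    class(prefs) <- c("preference_matrix", "matrix", "array")
  }
  dsel <- NULL
  if (length(diffsel_list) > 0L) {
    dsel <- agg(diffsel_list, median)
    attr(dsel, "wt_aa") <- attr(diffsel_list[[1L]], "wt_aa")
    class(dsel) <- c("diffsel_matrix", "matrix", "array")
  }
  list(preferences = prefs, diffsel = dsel)
}

#' Pearson correlation between two replicate matrices
#'
#' Computed over all flattened (site, amino acid) entries.  A constant
#' matrix has no defined correlation; `NA` is returned with a warning.
#'
#' @param a,b matrices of identical shape.
#' @return Pearson r, or NA for degenerate input.
#' @export
replicate_correlation <- function(a, b) {
  check_same_shape(a, b)
  x <- as.vector(unclass(a)); y <- as.vector(unclass(b))
  if (sd(x) == 0 || sd(y) == 0) {
    warning("correlation undefined for a constant matrix")
    return(NA_real_)
  }
  cor(x, y)
}

#' Write a sites-x-amino-acids matrix as tidy and/or wide TSV
#'
#' @param mat preference or diffsel matrix.
#' @param path output TSV.
#' @param layout "tidy" (site, aa, value) or "wide" (heatmap export).
#' @param value name of the value column in tidy layout.
#' @return `path`, invisibly.
#' @export
write_site_matrix <- function(mat, path, layout = c("tidy", "wide"),
                              value = "value") {
  layout <- match.arg(layout)
  if (layout == "wide") {
    dt <- data.table::data.table(site = seq_len(nrow(mat)))
    wt <- attr(mat, "wt_aa")
    if (!is.null(wt)) dt$wt_aa <- wt
    dt <- cbind(dt, data.table::as.data.table(unclass(mat)))
    return(write_tsv_(dt, path))
  }
  dt <- data.table::as.data.table(as.table(unclass(mat)))
  data.table::setnames(dt, c("site", "aa", value))
  dt$site <- as.integer(dt$site)
  data.table::setorderv(dt, c("site", "aa"))
  write_tsv_(dt, path)
}
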