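parse_read_ids <- function(id) {
  parts <- data.table::tstrsplit(id, ":", fixed = TRUE)
  ok <- length(parts) >= 2L
  if (!ok) {
    return(data.table::data.table(segment_id = rep(NA_character_,
                                                   length(id)),
                                  barcode = NA_character_,
                                  clone_id = NA_integer_))
  }
  data.table::data.table(
    segment_id = parts[[1L]],
    barcode = parts[[2L]],
    clone_id = if (length(parts) >= 3L)
      suppressWarnings(as.integer(parts[[3L]])) else NA_integer_)
}

#' Group reads by molecular barcode
#'
#' Partitions reads by (segment, barcode); groups smaller than
#' `min_reads_per_barcode` are discarded and tallied, as are reads
#' whose id lacks a parseable `segment:barcode` prefix.
#'
#' @param reads a `read_set` or data.frame with columns `id`, `seq`.
#' @param min_reads_per_barcode minimum group size retained
#'   (default 2).
#' @return data.table of class `barcode_groups` with one read per row
#'   (`segment_id`, `barcode`, `clone_id`, `seq`), sorted by group;
#'   attributes `n_reads_in`, `n_rejected_malformed`,
#'   `n_discarded_small_group`, `group_sizes`.
#' @export
group_by_barcode <- function(reads, min_reads_per_barcode = 2L) {
  n_in <- nrow(reads)
  meta <- parse_read_ids(reads$id)
  meta$seq <- reads$seq
  bad <- is.na(meta$segment_id) | is.na(meta$barcode) |
    meta$segment_id == "" | meta$barcode == ""
  n_malformed <- sum(bad)
  meta <- meta[!bad]
  data.table::setkey(meta, segment_id, barcode)
  meta[, `:=`(grp_n = .N), by = c("segment_id", "barcode")]
  small <- meta$grp_n < min_reads_per_barcode
  n_small <- sum(small)
  meta <- meta[!small]
  sizes <- meta[, list(n = .N), by = c("segment_id", "barcode")]$n
  meta[, grp_n := NULL]
  data.table::setattr(meta, "n_reads_in", n_in)
  data.table::setattr(meta, "n_rejected_malformed", n_malformed)
  data.table::setattr(meta, "n_discarded_small_group", n_small)
  data.table::setattr(meta, "group_sizes", sizes)
  data.table::setattr(meta, "class", c("barcode_groups", class(meta)))
  meta
}

#' Call per-molecule consensus sequences
#'
#' Per codon position the strict-majority codon among the group's
#' reads is called; codons with a tie or no strict majority are masked
#' (`NNN`) and contribute no count downstream.  Reads whose length
#' differs from the group's first read (indels) are ignored.
#'
#' Given a plain character vector of reads, returns the single
#' consensus string; given a `barcode_groups` table, returns one row
#' per molecule.
#'
#' @param groups a `barcode_groups` table or a character vector of
#'   reads from one molecule.
#' @return Consensus string(s): character scalar, or data.table with
#'   columns `segment_id`, `barcode`, `clone_id`, `consensus`.
#' @export
call_consensus <- function(groups) {
  if (is.character(groups)) {
    stopifnot(length(groups) >= 1L)
    return(cpp_consensus_groups(groups, length(groups)))
  }
  stopifnot(inherits(groups, "barcode_groups"))
  if (nrow(groups) == 0L)
    return(data.table::data.table(segment_id = character(0),
                                  barcode = character(0),
                                  clone_id = integer(0),
                                  consensus = character(0)))
  # rows are sorted by (segment, barcode): consensus over run lengths
  heads <- groups[, list(clone_id = clone_id[1L], n = .N),
                  by = c("segment_id", "barcode")]
  cons <- cpp_consensus_groups(groups$seq, heads$n)
  data.table::data.table(segment_id = heads$segment_id,
                         barcode = heads$barcode,
                         clone_id = heads$clone_id,
                         consensus = cons)
}

#' Construct a codon-count table
#'
#' @param counts numeric matrix, rows = codon positions 1..L, columns
#'   = the 64 codons in [codon_alphabet()] order.
#' @param wt_codons wild-type codons (length L).
#' @param sample_id sample label.
#' @param n_skipped_masked number of masked/ambiguous codon calls that
#'   were dropped (QC tally).
#' @return Matrix of class `codon_count_table`.
#' @export
codon_count_table <- function(counts, wt_codons, sample_id = "sample",
                              n_skipped_masked = 0L) {
  stopifnot(is.matrix(counts), ncol(counts) == 64L,
            nrow(counts) == length(wt_codons), all(counts >= 0))
  dimnames(counts) <- list(seq_len(nrow(counts)), codon_alphabet())
  structure(counts, class = c("codon_count_table", "matrix", "array"),
            wt_codons = wt_codons, sample_id = sample_id,
            n_skipped_masked = n_skipped_masked)
}

#' Count codon observations from consensus molecules
#'
#' Each unmasked codon of each consensus molecule contributes one
#' count at its gene position; masked (`NNN`/ambiguous) codons are
#' skipped and tallied.  Row sums therefore never exceed the number of
#' molecules covering the position.
#'
#' @param consensus data.table from [call_consensus()].
#' @param wt_codons reference codons (length L).
#' @param segments segment map locating each `segment_id` on the gene.
#' @param sample_id sample label.
#' @return A [codon_count_table()].
#' @export
count_codons <- function(consensus, wt_codons, segments,
                         sample_id = "sample") {
  L <- length(wt_codons)
  segments <- check_segments(segments, L)
  counts <- matrix(0, nrow = L, ncol = 64L,
                   dimnames = list(seq_len(L), codon_alphabet()))
  wt_idx <- match(wt_codons, codon_alphabet())
  n_masked_total <- 0L
  for (s in seq_len(nrow(segments))) {
    rows <- consensus$segment_id == segments$segment_id[s]
    if (!any(rows)) next
    seqs <- consensus$consensus[rows]
    p0 <- segments$start_codon[s]
    p1 <- segments$end_codon[s]
    ref <- paste(wt_codons[p0:p1], collapse = "")
    mm <- cpp_codon_mismatches(seqs, ref)
    span <- p0:p1
    cov <- length(seqs)
    # start from full wt coverage, then move mutant/masked calls out
    counts[cbind(span, wt_idx[span])] <-
      counts[cbind(span, wt_idx[span])] + cov
    if (length(mm$seq) > 0L) {
      pos <- p0 + mm$codon_idx - 1L
      agg <- data.table::data.table(pos = pos, codon = mm$codon)[
        , list(n = .N), by = c("pos", "codon")]
      ci <- match(agg$codon, codon_alphabet())
      counts[cbind(agg$pos, ci)] <- counts[cbind(agg$pos, ci)] + agg$n
      per_pos <- data.table::data.table(pos = pos)[, list(n = .N), by = "pos"]
      counts[cbind(per_pos$pos, wt_idx[per_pos$pos])] <-
        counts[cbind(per_pos$pos, wt_idx[per_pos$pos])] - per_pos$n
    }
    if (length(mm$masked_seq) > 0L) {
      mpos <- p0 + mm$masked_codon_idx - 1L
      mt <- data.table::data.table(pos = mpos)[, list(n = .N), by = "pos"]
      counts[cbind(mt$pos, wt_idx[mt$pos])] <-
        counts[cbind(mt$pos, wt_idx[mt$pos])] - mt$n
      n_masked_total <- n_masked_total + length(mm$masked_seq)
    }
  }
  codon_count_table(counts, wt_codons, sample_id,
                    n_skipped_masked = n_masked_total)
}

#' Reconstruct clone genotypes from consensus molecules
#'
#' Synthetic-mode helper: uses the clone id carried in the read ids to
#' assemble, per clone, one consensus molecule per segment (the first
#' encountered) and lists the codon positions that differ from wild
#' type.  The zero-sequencing-error round trip through this function
#' recovers the simulated library exactly.
#'
#' @param consensus data.table from [call_consensus()] (with
#'   `clone_id`).
#' @param wt_codons reference codons.
#' @param segments segment map.
#' @return data.table of class `clone_genotypes` (clone_id, position,
#'   codon); attribute `clone_ids` lists every clone observed (also
#'   the unmutated ones).
#' @export
clone_genotypes <- function(consensus, wt_codons, segments) {
  L <- length(wt_codons)
  segments <- check_segments(segments, L)
  if (anyNA(consensus$clone_id))
    stop("consensus table lacks clone ids (not a synthetic run?)")
  one <- unique(consensus, by = c("clone_id", "segment_id"))
  out <- vector("list", nrow(segments))
  for (s in seq_len(nrow(segments))) {
    rows <- one$segment_id == segments$segment_id[s]
    if (!any(rows)) next
    seqs <- one$consensus[rows]
    ids <- one$clone_id[rows]
    p0 <- segments$start_codon[s]
    ref <- paste(wt_codons[p0:segments$end_codon[s]], collapse = "")
    mm <- cpp_codon_mismatches(seqs, ref)
    if (length(mm$seq) > 0L)
      out[[s]] <- data.table::data.table(
        clone_id = ids[mm$seq],
        position = p0 + mm$codon_idx - 1L,
        codon = mm$codon)
  }
  geno <- data.table::rbindlist(out)
  if (nrow(geno) == 0L)
    geno <- data.table::data.table(clone_id = integer(0),
                                   position = integer(0),
                                   codon = character(0))
  data.table::setkey(geno, clone_id, position)
  data.table::setattr(geno, "clone_ids", sort(unique(consensus$clone_id)))
  data.table::setattr(geno, "class", c("clone_genotypes", class(geno)))
  geno
}

#' Library quality control against the Poisson mutation-load model
#'
#' Reports the mean mutated-codon count per clone, the mutation-count
#' histogram, a chi-square goodness-of-fit p value against a Poisson
#' with the estimated mean (tail bins pooled to expected counts >= 5,
#' one df spent on the estimated mean), and the coefficient of
#' variation of per-position mutation counts (positional uniformity).
#'
#' @param genotypes a `clone_genotypes` table, or a `clone_library`
#'   (truth-table QC).
#' @param L gene length in codons (taken from the library when one is
#'   given).
#' @return list of class `library_qc_report`: `n_clones`,
#'   `mean_mut_per_clone`, `mut_count_histogram`, `poisson_gof_p`,
#'   `positional_cv`, `low_confidence`.
#' @export
library_qc <- function(genotypes, L = NULL) {
  if (inherits(genotypes, "clone_library")) {
    L <- genotypes$preset$L
    clone_ids <- seq_len(genotypes$n_clones)
    mut <- genotypes$mutations
  } else {
    stopifnot(!is.null(L))
    clone_ids <- attr(genotypes, "clone_ids") %||%
      sort(unique(genotypes$clone_id))
    mut <- genotypes
  }
  n <- length(clone_ids)
  per_clone <- integer(n)
  if (nrow(mut) > 0L) {
    tab <- mut[, list(k = .N), by = "clone_id"]
    per_clone[match(tab$clone_id, clone_ids)] <- tab$k
  }
  mean_k <- mean(per_clone)
  hist <- table(factor(per_clone, levels = 0:max(per_clone)))
  gof <- poisson_gof(as.integer(hist), mean_k)
  pos_counts <- tabulate(mut$position, nbins = L)
  cv <- if (mean(pos_counts) > 0) sd(pos_counts) / mean(pos_counts) else NA_real_
  structure(list(n_clones = n, mean_mut_per_clone = mean_k,
                 mut_count_histogram = hist, poisson_gof_p = gof,
                 positional_cv = cv, low_confidence = n < 100L),
            class = "library_qc_report")
}

poisson_gof <- function(obs, lambda) {
  if (lambda <= 0 || sum(obs) == 0L) return(NA_real_)
  n <- sum(obs)
  kmax <- length(obs) - 1L
  p <- dpois(0:kmax, lambda)
  p[kmax + 1L] <- p[kmax + 1L] + (1 - sum(p))  # fold the tail in
  exp_n <- n * p
  # pool from the right until expected counts are >= 5
  while (length(exp_n) > 2L && exp_n[length(exp_n)] < 5) {
    k <- length(exp_n)
    exp_n[k - 1L] <- exp_n[k - 1L] + exp_n[k]
    obs[k - 1L] <- obs[k - 1L] + obs[k]
    exp_n <- exp_n[-k]; obs <- obs[-k]
  }
  df <- length(obs) - 2L  # one df for the estimated mean
  if (df < 1L) return(NA_real_)
  stat <- sum((obs - exp_n)^2 / exp_n)
  pchisq(stat, df, lower.tail = FALSE)
}

#' @export
print.library_qc_report <- function(x, ...) {
  cat(sprintf(paste0("<library_qc_report> %d clones, mean %.3f mutated ",
                     "codons/clone\n  Poisson GOF p = %s, positional CV = %.3f%s\n"),
              x$n_clones, x$mean_mut_per_clone,
              format(x$poisson_gof_p, digits = 3), x$positional_cv,
              if (x$low_confidence) "  [LOW CONFIDENCE: < 100 clones]" else ""))
  invisible(x)
}

#' Write / read a codon-count table as tidy TSV (position, codon, count)
#' @param table a `codon_count_table`.
#' @param path TSV path.
#' @return `path` (write) or a `codon_count_table` (read).
#' @export
write_codon_counts <- function(table, path) {
  dt <- data.table::as.data.table(as.table(unclass(table)))
  data.table::setnames(dt, c("position", "codon", "count"))
  dt <- dt[dt$count != 0 | dt$codon == attr(table, "wt_codons")[as.integer(dt$position)]]
  dt$position <- as.integer(dt$position)
  data.table::setorderv(dt, c("position", "codon"))
  write_tsv_(dt, path)
}

#' @rdname write_codon_counts
#' @param wt_codons reference codons for the table being read.
#' @param sample_id sample label.
#' @export
read_codon_counts <- function(path, wt_codons, sample_id = "sample") {
  dt <- read_tsv_(path)
  L <- length(wt_codons)
  counts <- matrix(0, nrow = L, ncol = 64L,
                   dimnames = list(seq_len(L), codon_alphabet()))
  counts[cbind(dt$position, match(dt$codon, codon_alphabet()))] <- dt$count
  codon_count_table(counts, wt_codons, sample_id)
}
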