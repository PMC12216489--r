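#' Construct a codon-mutant library preset
#'
#' A preset fixes the wild-type coding sequence, the Poisson mutation
#' rate of the mutagenesis (mean mutated codons per clone) and the
#' number of clones to simulate.
#'
#' @param gene_id text label for the gene.
#' @param L gene length in codons (ignored when `wt_codons` is given).
#' @param wt_codons character vector of L wild-type codons, or NULL to
#'   generate a synthetic stand-in coding sequence (ATG start, no
#'   internal stops, deterministic per `gene_id`).
#' @param lambda_mut mean mutated codons per clone (Poisson rate).
#' @param n_clones number of clones in the library.
#' @return An object of class `library_preset`.
#' @examples
#' p <- library_preset("toy", L = 10, lambda_mut = 1.5, n_clones = 100)
#' @export
library_preset <- function(gene_id, L = NULL, wt_codons = NULL,
                           lambda_mut = 1.5, n_clones = 1000L) {
  if (is.null(wt_codons)) {
    if (is.null(L)) stop("give either 'L' or 'wt_codons'")
    wt_codons <- synthetic_wt_codons(gene_id, L)
  }
  L <- length(wt_codons)
  stopifnot(L >= 1L, lambda_mut >= 0, n_clones >= 1L)
  if (!all(nchar(wt_codons) == 3L) ||
      any(grepl("[^ACGT]", wt_codons)))
    stop("wt_codons must be uppercase DNA triplets")
  structure(list(gene_id = gene_id, L = L, wt_codons = wt_codons,
                 lambda_mut = lambda_mut, n_clones = as.integer(n_clones)),
            class = "library_preset")
}

#' @export
print.library_preset <- function(x, ...) {
  cat(sprintf("<library_preset> %s: L=%d codons, lambda=%.2f, n_clones=%d\n",
              x$gene_id, x$L, x$lambda_mut, x$n_clones))
  invisible(x)
}

# Deterministic synthetic coding sequence: ATG then uniform non-stop
# codons.  Stand-in for a real reference gene; seeded by the gene id so
# each preset always yields the same sequence.
synthetic_wt_codons <- function(gene_id, L) {
  stopifnot(L >= 1L)
  sense <- setdiff(codon_alphabet(),
                   names(which(Biostrings::GENETIC_CODE == "*")))
  with_seed(child_seed(20260101L, paste0("wt:", gene_id)), {
    c("ATG", sample(sense, L - 1L, replace = TRUE))[seq_len(L)]
  })
}

#' Built-in library presets emulating the screened adaptation genes
#'
#' Three presets mirror the published codon-mutant libraries: a
#' cas1-like gene (289 codons, 1.8 mutated codons per clone), a
#' cas2-like gene (113 codons, 1.3) and a csn2-like gene (220 codons,
#' 1.5).  Wild-type sequences are synthetic stand-ins (see
#' [library_preset()]); lengths and rates are the screen parameters.
#'
#' @param name one of "cas1", "cas2", "csn2".
#' @param n_clones library size (default 10000).
#' @return A `library_preset`.
#' @export
dms_preset <- function(name = c("cas1", "cas2", "csn2"), n_clones = 10000L) {
  name <- match.arg(name)
  par <- switch(name,
    cas1 = list(L = 289L, lambda = 1.8),
    cas2 = list(L = 113L, lambda = 1.3),
    csn2 = list(L = 220L, lambda = 1.5))
  library_preset(name, L = par$L, lambda_mut = par$lambda, n_clones = n_clones)
}

#' Variant presets with planted true fold changes
#'
#' Named after the validated variant/assay combinations; `true_fold` is
#' the planted effect size each simulation should recover: oligo spacer
#' acquisition folds 3.9 (YT) and 5.0 (MYT), phage-immunity folds 3, 5
#' and 7 (T, YT, MYT), and E. coli host folds 1.7 and 1.6.
#'
#' @param name optional preset name; if omitted the full table is
#'   returned.
#' @return A data.frame with columns `name`, `true_fold`, or a single
#'   row when `name` is given.
#' @export
variant_preset <- function(name = NULL) {
  tab <- data.frame(
    name = c("YT-oligo", "MYT-oligo", "T-phage", "YT-phage", "MYT-phage",
             "YT-ecoli", "MYT-ecoli"),
    true_fold = c(3.9, 5.0, 3, 5, 7, 1.7, 1.6),
    stringsAsFactors = FALSE)
  if (is.null(name)) return(tab)
  row <- tab[tab$name == name, , drop = FALSE]
  if (nrow(row) == 0L) stop("unknown variant preset: ", name)
  row
}

#' Screen configuration for selection and sequencing simulations
#'
#' @param base_rate per-cell selection probability of a wild-type clone
#'   (default 1e-5).
#' @param n_cells number of cells subjected to selection.
#' @param reads_per_clone_mean mean sequenced molecules per clone and
#'   segment when depth is not given explicitly.
#' @param reads_per_barcode reads emitted per barcoded molecule.
#' @param seq_error_rate per-base substitution error probability
#'   (default 1e-3).
#' @param seed integer seed or NULL.
#' @return An object of class `screen_config`.
#' @export
screen_config <- function(base_rate = 1e-5, n_cells = 1e8,
                          reads_per_clone_mean = 3,
                          reads_per_barcode = 3L,
                          seq_error_rate = 1e-3, seed = NULL) {
  stopifnot(base_rate >= 0, base_rate <= 1, n_cells >= 0,
            reads_per_clone_mean >= 0, reads_per_barcode >= 0,
            seq_error_rate >= 0, seq_error_rate < 1)
  structure(list(base_rate = base_rate, n_cells = n_cells,
                 reads_per_clone_mean = reads_per_clone_mean,
                 reads_per_barcode = as.integer(reads_per_barcode),
                 seq_error_rate = seq_error_rate, seed = seed),
            class = "screen_config")
}

#' Default subamplicon segmentation of a gene
#'
#' Tiles codons 1..L into contiguous segments of at most `max_codons`
#' codons (about 180 nt, the scale of one sequencing read), mirroring
#' the five/two/three subamplicon design used for the real genes.
#'
#' @param L gene length in codons.
#' @param n_segments number of segments; default chosen from
#'   `max_codons`.
#' @param max_codons maximum codons per segment (default 60).
#' @return data.frame with columns `segment_id`, `start_codon`,
#'   `end_codon`.
#' @export
default_segments <- function(L, n_segments = NULL, max_codons = 60L) {
  if (is.null(n_segments)) n_segments <- ceiling(L / max_codons)
  stopifnot(n_segments >= 1L, n_segments <= L)
  bounds <- as.integer(floor(seq(0L, L, length.out = n_segments + 1L)))
  data.frame(segment_id = paste0("S", seq_len(n_segments)),
             start_codon = bounds[-length(bounds)] + 1L,
             end_codon = bounds[-1L],
             stringsAsFactors = FALSE)
}

check_segments <- function(segments, L) {
  s <- segments[order(segments$start_codon), , drop = FALSE]
  if (s$start_codon[1L] != 1L || s$end_codon[nrow(s)] != L ||
      (nrow(s) > 1L && any(s$start_codon[-1L] != s$end_codon[-nrow(s)] + 1L)))
    stop("segments must tile codons 1..", L, " without gaps or overlaps")
  invisible(s)
}
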