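# Full-gene nucleotide string for each requested clone.
clone_sequences <- function(library, clone_ids) {
  wt <- paste(library$preset$wt_codons, collapse = "")
  uniq <- sort(unique(clone_ids))
  seqs <- rep(wt, length(uniq))
  names(seqs) <- as.character(uniq)
  mut <- library$mutations[library$mutations$clone_id %in% uniq, ]
  if (nrow(mut) > 0L) {
    j <- match(mut$clone_id, uniq)
    for (r in seq_len(nrow(mut))) {
      p <- mut$position[r]
      substr(seqs[j[r]], 3L * p - 2L, 3L * p) <- mut$codon[r]
    }
  }
  seqs[as.character(clone_ids)]
}

random_barcodes <- function(n, width = 12L) {
  draw <- function(k) {
    m <- matrix(sample(c("A", "C", "G", "T"), k * width, replace = TRUE),
                nrow = k)
    do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
  }
  bc <- draw(n)
  while (anyDuplicated(bc)) {
    dup <- which(duplicated(bc))
    bc[dup] <- draw(length(dup))
  }
  bc
}

#' Simulate barcoded-subamplicon sequencing reads
#'
#' Each sequenced molecule is one subamplicon segment of one clone's
#' plasmid, tagged with a unique random barcode;
#' `config$reads_per_barcode` reads are emitted per molecule, covering
#' the full segment at a fixed offset, with independent per-base
#' substitution errors at `config$seq_error_rate`.  Read ids encode
#' segment, barcode and source clone (`seg:barcode:clone:read`) for
#' round-trip testing.
#'
#' Molecule depth is controlled by exactly one of:
#' * `molecules_per_clone`: every clone with a positive count
#'   contributes exactly that many molecules per segment (library QC
#'   mode);
#' * `n_molecules`: per segment, this many molecules are sampled
#'   multinomially with weights `clone_counts` (screen mode);
#' * neither: `n_molecules` defaults to
#'   `round(reads_per_clone_mean * number of clones with count > 0)`.
#'
#' @param clone_counts integer vector of per-clone counts (e.g. a
#'   component of [simulate_selection()]).
#' @param library the `clone_library` the counts refer to.
#' @param config a [screen_config()]; `config$seed` is honoured.
#' @param segments segment map (see [default_segments()]); defaults to
#'   the gene's default tiling.
#' @param molecules_per_clone,n_molecules depth controls, see above.
#' @return data.table of class `read_set` with columns `id`, `seq`;
#'   attributes `segments` and `read_counts`.
#' @export
simulate_reads <- function(clone_counts, library, config = screen_config(),
                           segments = NULL, molecules_per_clone = NULL,
                           n_molecules = NULL) {
  stopifnot(inherits(library, "clone_library"))
  L <- library$preset$L
  if (is.null(segments)) segments <- default_segments(L)
  segments <- check_segments(segments, L)
  with_seed(config$seed, {
    present <- which(clone_counts > 0)
    if (length(present) == 0L)
      return(empty_read_set(segments))
    if (!is.null(molecules_per_clone)) {
      mol_clones <- rep(present, each = molecules_per_clone)
    } else {
      if (is.null(n_molecules))
        n_molecules <- round(config$reads_per_clone_mean * length(present))
      draw <- rmultinom(1L, n_molecules,
                        clone_counts[present] / sum(clone_counts[present]))[, 1L]
      mol_clones <- rep(present, draw)
    }
    if (length(mol_clones) == 0L) return(empty_read_set(segments))
    gene_seq <- clone_sequences(library, mol_clones)
    out <- vector("list", nrow(segments))
    mol0 <- 0L
    for (s in seq_len(nrow(segments))) {
      from <- 3L * segments$start_codon[s] - 2L
      to <- 3L * segments$end_codon[s]
      tmpl <- substring(gene_seq, from, to)
      nm <- length(tmpl)
      bc <- random_barcodes(nm)
      rpb <- config$reads_per_barcode
      seqs <- rep(tmpl, each = rpb)
      if (config$seq_error_rate > 0)
        seqs <- cpp_add_read_errors(seqs, config$seq_error_rate)
      ids <- sprintf("%s:%s:%d:%d",
                     segments$segment_id[s],
                     rep(bc, each = rpb),
                     rep(mol_clones, each = rpb),
                     rep(seq_len(rpb), times = nm))
      out[[s]] <- data.table::data.table(id = ids, seq = seqs)
      mol0 <- mol0 + nm
    }
    reads <- data.table::rbindlist(out)
    data.table::setattr(reads, "segments", segments)
    data.table::setattr(reads, "n_molecules", mol0)
    data.table::setattr(reads, "class",
                        c("read_set", class(reads)))
    reads
  })
}

empty_read_set <- function(segments) {
  reads <- data.table::data.table(id = character(0), seq = character(0))
  data.table::setattr(reads, "segments", segments)
  data.table::setattr(reads, "n_molecules", 0L)
  data.table::setattr(reads, "class", c("read_set", class(reads)))
  reads
}

#' Write simulated reads as FASTQ (Phred+33, constant quality)
#'
#' @param reads a `read_set` (or data.frame with `id`, `seq`).
#' @param path output file; `.gz` suffix enables gzip compression.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  qual <- strrep("I", nchar(reads$seq))
  rec <- paste0("@", reads$id, "\n", reads$seq, "\n+\n", qual)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeLines(rec, con)
  invisible(path)
}

#' Read FASTQ into a read table (gzip-aware)
#'
#' Qualities are discarded: consensus calling, not base quality, is the
#' error-correction mechanism in this pipeline.
#'
#' @param path FASTQ file.
#' @return data.table with columns `id`, `seq`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  data.table::data.table(id = names(x), seq = as.character(x))
}

#' Write the reference gene as FASTA
#' @param preset a `library_preset`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(preset, path) {
  x <- Biostrings::DNAStringSet(paste(preset$wt_codons, collapse = ""))
  names(x) <- preset$gene_id
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a reference coding sequence from FASTA
#' @param path FASTA file with one coding sequence.
#' @return list with `gene_id` and `wt_codons`.
#' @export
read_reference_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  if (length(x) < 1L) stop("no sequence in ", path)
  s <- as.character(x[[1L]])
  if (nchar(s) %% 3L != 0L)
    stop("reference length is not a multiple of 3")
  list(gene_id = names(x)[1L],
       wt_codons = substring(s, seq(1L, nchar(s), 3L),
                             seq(3L, nchar(s), 3L)))
}

#' Write the clone-library ground truth as TSV
#'
#' Columns: clone_id, position, wt_codon, mut_codon, multiplier (the
#' planted effect of the amino-acid change, 1 when unlisted or
#' synonymous).
#'
#' @param library a `clone_library`.
#' @param effects an [effect_table()].
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_truth_table <- function(library, effects = effect_table(), path) {
  mut <- library$mutations
  wt_codon <- library$preset$wt_codons[mut$position]
  mut_aa <- translate_codons(mut$codon)
  wt_aa <- translate_codons(wt_codon)
  mult <- ifelse(mut_aa == wt_aa, 1,
                 lookup_multiplier(effects, mut$position, mut_aa))
  write_tsv_(data.table::data.table(
    clone_id = mut$clone_id, position = mut$position,
    wt_codon = wt_codon, mut_codon = mut$codon, multiplier = mult), path)
}
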