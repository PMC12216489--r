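#' @keywords internal
`%||%` <- function(x, y) if (is.null(x)) y else x

#' The 64 DNA codons, in the order used by all codon-count tables
#'
#' Order follows [Biostrings::GENETIC_CODE].
#' @return Character vector of 64 codons.
#' @export
codon_alphabet <- function() names(Biostrings::GENETIC_CODE)

#' The 20 standard amino acids (one-letter, alphabetical)
#' @return Character vector of length 20.
#' @export
aa_alphabet <- function() {
  aa <- sort(unique(unname(Biostrings::GENETIC_CODE)))
  setdiff(aa, "*")
}

#' Translate codons to one-letter amino acids
#'
#' @param codons character vector of DNA triplets (uppercase).
#' @return Character vector of amino acids ("*" for stop).
#' @export
translate_codons <- function(codons) {
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  if (anyNA(aa)) stop("invalid codon(s): ",
                      paste(unique(codons[is.na(aa)]), collapse = ", "))
  aa
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so seeded simulations do
#' not perturb the global random stream.  With `seed = NULL` the
#' expression runs against the current stream.
#'
#' @param seed integer seed or NULL.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a stage-specific child seed from a master seed
#'
#' Deterministic hash of (master seed, stage name), kept below 2^31 so
#' it is a valid R integer seed.  Used by [run_pipeline()] so that each
#' stochastic stage can be rerun in isolation.
#'
#' @param master integer master seed.
#' @param stage character stage label.
#' @return Integer seed in `[0, 2^31 - 2]`.
#' @export
child_seed <- function(master, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  m <- 2147483647  # 2^31 - 1, prime
  h <- as.double(master) %% m
  for (k in utf8ToInt(stage)) h <- (h * 131 + k) %% m
  as.integer(h)
}

# fwrite wrapper keeping TSV output byte-stable across runs
write_tsv_ <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t", quote = FALSE, eol = "\n")
  invisible(path)
}

read_tsv_ <- function(path) data.table::fread(path, sep = "\t")
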