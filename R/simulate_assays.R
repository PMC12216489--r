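#' Default tenfold serial-dilution plating scheme
#'
#' Plated fraction of the culture on a plate is `dilution * volume`.
#' Defaults put the expected selective counts near the countable range
#' for acquisition rates around 1e-5 with 1e8 cells.
#'
#' @return data.frame with columns `plate`, `dilution`, `volume`.
#' @export
default_dilution_scheme <- function() {
  data.frame(
    plate = c("selective", "selective", "selective", "total", "total"),
    dilution = c(1, 1e-1, 1e-2, 1e-5, 1e-6),
    volume = 0.1,
    stringsAsFactors = FALSE)
}

#' Simulate a serial-dilution plating experiment
#'
#' Colony counts are Poisson: selective plates with mean
#' `true_rate * n_cells * dilution * volume`, total plates with mean
#' `n_cells * dilution * volume`.
#'
#' @param true_rate true per-cell acquisition rate.
#' @param n_cells cells in the recovered culture.
#' @param dilution_scheme data.frame with `plate`
#'   ("selective"/"total"), `dilution`, `volume`; defaults to
#'   [default_dilution_scheme()].
#' @param seed integer seed or NULL.
#' @param strain_id label.
#' @return data.frame of class `plating_experiment` with columns
#'   `strain_id`, `plate`, `dilution`, `volume`, `colonies`.
#' @export
simulate_plating <- function(true_rate, n_cells,
                             dilution_scheme = default_dilution_scheme(),
                             seed = NULL, strain_id = "strain") {
  stopifnot(true_rate >= 0, n_cells >= 0,
            all(dilution_scheme$dilution > 0),
            all(dilution_scheme$volume > 0))
  with_seed(seed, {
    frac <- dilution_scheme$dilution * dilution_scheme$volume
    mu <- ifelse(dilution_scheme$plate == "selective",
                 true_rate * n_cells * frac, n_cells * frac)
    out <- data.frame(strain_id = strain_id,
                      plate = dilution_scheme$plate,
                      dilution = dilution_scheme$dilution,
                      volume = dilution_scheme$volume,
                      colonies = rpois(length(mu), mu),
                      stringsAsFactors = FALSE)
    class(out) <- c("plating_experiment", class(out))
    out
  })
}

#' Simulate a phage-survival (BIM) assay for one variant versus wt
#'
#' Surviving colonies after lytic infection split into two classes:
#' CRISPR survivors (new spacer acquired), Poisson with mean
#' `mu_crispr_wt` (wild type) or `true_fold * mu_crispr_wt` (variant),
#' and non-CRISPR escapers, Poisson with mean `nu_noncrispr` shared by
#' both strains.  `n_colonies_assayed` colonies are drawn without
#' replacement and scored by PCR for an expanded array
#' (hypergeometric).  With `mu_crispr_wt = 70` and `nu_noncrispr = 50`
#' the expected wild-type PCR-positive fraction is 7/12.
#'
#' @param mu_crispr_wt mean CRISPR-survivor colonies for wild type.
#' @param nu_noncrispr mean non-CRISPR escaper colonies (both strains).
#' @param variant a [variant_preset()] name or one-row data.frame.
#' @param n_colonies_assayed colonies PCR-checked per strain.
#' @param seed integer seed or NULL.
#' @return data.frame of class `phage_survival` with one row per
#'   strain ("wt" and the variant): `strain_id`, `total_survivors`,
#'   `n_assayed`, `n_pcr_positive`.
#' @export
simulate_phage_survival <- function(mu_crispr_wt = 70, nu_noncrispr = 50,
                                    variant = "MYT-phage",
                                    n_colonies_assayed = 12L, seed = NULL) {
  if (is.character(variant)) variant <- variant_preset(variant)
  stopifnot(variant$true_fold > 0, mu_crispr_wt >= 0, nu_noncrispr >= 0)
  with_seed(seed, {
    one <- function(strain, mu) {
      nc <- rpois(1L, mu)
      nn <- rpois(1L, nu_noncrispr)
      m <- min(n_colonies_assayed, nc + nn)
      pos <- if (m == 0L) 0L else rhyper(1L, nc, nn, m)
      data.frame(strain_id = strain, total_survivors = nc + nn,
                 n_assayed = m, n_pcr_positive = pos,
                 stringsAsFactors = FALSE)
    }
    out <- rbind(one("wt", mu_crispr_wt),
                 one(variant$name, variant$true_fold * mu_crispr_wt))
    class(out) <- c("phage_survival", class(out))
    out
  })
}

#' Simulate a pairwise growth-competition experiment
#'
#' Two strains start at fraction 0.5 each.  Every day the mixed
#' culture passes a binomial bottleneck of `bottleneck_size` cells
#' (1:100 dilution of an overnight culture) and then grows
#' deterministically with the variant's per-day `fitness_ratio`
#' relative to wild type.  `bottleneck_size = Inf` gives the
#' deterministic limit.
#'
#' @param fitness_ratio relative per-day growth weight of the variant.
#' @param days number of daily passages (default 6).
#' @param bottleneck_size cells surviving each dilution (default 1e6).
#' @param seed integer seed or NULL.
#' @return Numeric vector of variant fractions, days 0..`days`.
#' @export
simulate_competition <- function(fitness_ratio, days = 6L,
                                 bottleneck_size = 1e6, seed = NULL) {
  stopifnot(fitness_ratio >= 0, days >= 0)
  with_seed(seed, {
    f <- numeric(days + 1L)
    f[1L] <- 0.5
    for (d in seq_len(days)) {
      cur <- f[d]
      if (is.finite(bottleneck_size)) {
        nv <- rbinom(1L, as.integer(bottleneck_size), cur)
        cur <- nv / bottleneck_size
      }
      den <- cur * fitness_ratio + (1 - cur)
      f[d + 1L] <- if (den == 0) cur else cur * fitness_ratio / den
    }
    names(f) <- paste0("day", 0:days)
    f
  })
}
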