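cfu_per_ml <- function(plates) {
  # most-countable-plate rule: prefer 30-300 colonies; among those take
  # the largest count (most precise); otherwise the highest count seen
  countable <- plates$colonies >= 30 & plates$colonies <= 300
  use <- if (any(countable)) {
    idx <- which(countable)
    idx[which.max(plates$colonies[idx])]
  } else which.max(plates$colonies)
  plates$colonies[use] / (plates$dilution[use] * plates$volume[use])
}

#' Spacer-acquisition rate from a plating experiment
#'
#' CFU/mL per medium is `colonies / (dilution * volume)` from the most
#' countable plate (30-300 colonies preferred); the rate is the
#' selective/total ratio of CFU/mL (the selective-marker over
#' total-CFU colony ratio).
#'
#' @param exp a [simulate_plating()] result, or any data.frame with
#'   columns `plate` ("selective"/"total"), `dilution`, `volume`,
#'   `colonies`.
#' @return list of class `acquisition_rate`: `strain_id`, `rate`,
#'   `cfu_selective`, `cfu_total`, `below_detection` (TRUE when no
#'   selective colony was observed on any plate).
#' @export
acquisition_rate <- function(exp) {
  sel <- exp[exp$plate == "selective", , drop = FALSE]
  tot <- exp[exp$plate == "total", , drop = FALSE]
  if (nrow(sel) == 0L || nrow(tot) == 0L)
    stop("need at least one selective and one total plate")
  cfu_tot <- cfu_per_ml(tot)
  if (cfu_tot <= 0) stop("zero total CFU: cannot form a rate")
  below <- all(sel$colonies == 0)
  cfu_sel <- if (below) 0 else cfu_per_ml(sel)
  structure(list(strain_id = exp$strain_id[1L] %||% NA_character_,
                 rate = cfu_sel / cfu_tot,
                 cfu_selective = cfu_sel, cfu_total = cfu_tot,
                 below_detection = below),
            class = "acquisition_rate")
}

#' Two-tailed unpaired Welch t-test
#'
#' `t = (mean_a - mean_b) / sqrt(s2_a/n_a + s2_b/n_b)` with
#' Welch-Satterthwaite degrees of freedom and a two-tailed p value.
#' When both groups have zero variance and equal means, p = 1.
#'
#' @param a,b numeric vectors (each of length >= 2).
#' @return list: `t`, `df`, `p`, `mean_a`, `mean_b`.
#' @export
welch_t_test <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    stop("Welch t-test needs at least 2 observations per group")
  na <- length(a); nb <- length(b)
  va <- var(a); vb <- var(b)
  se2 <- va / na + vb / nb
  ma <- mean(a); mb <- mean(b)
  if (se2 == 0) {
    t <- if (ma == mb) 0 else sign(ma - mb) * Inf
    return(list(t = t, df = na + nb - 2,
                p = if (ma == mb) 1 else 0, mean_a = ma, mean_b = mb))
  }
  t <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df), mean_a = ma, mean_b = mb)
}

#' Fold change of variant over wild-type acquisition rates
#'
#' Fold is the ratio of group means (matching normalization of
#' aggregate quantities by the wild-type value); the p value comes
#' from a two-tailed Welch t-test on the raw replicate rates (set
#' `log = TRUE` to test log10 rates instead).
#'
#' @param variant,wt numeric vectors of replicate rates (at least 1
#'   each; at least 2 per group for the test).
#' @param log test log10-transformed rates.
#' @return list of class `fold_change`: `fold`, `t`, `df`, `p`
#'   (`t`/`df`/`p` NA for singleton groups).
#' @export
fold_change <- function(variant, wt, log = FALSE) {
  stopifnot(length(variant) >= 1L, length(wt) >= 1L, mean(wt) > 0)
  fold <- mean(variant) / mean(wt)
  tt <- if (length(variant) >= 2L && length(wt) >= 2L) {
    if (log) welch_t_test(log10(variant), log10(wt))
    else welch_t_test(variant, wt)
  } else list(t = NA_real_, df = NA_real_, p = NA_real_)
  structure(list(fold = fold, t = tt$t, df = tt$df, p = tt$p),
            class = "fold_change")
}

#' Phage-immunity fold relative to wild type
#'
#' `fold = (total_variant * pcr_fraction_variant) / (total_wt *
#' pcr_fraction_wt)`: surviving colonies weighted by the PCR-confirmed fraction carrying
#' a new spacer, normalized to the wild-type value.
#'
#' @param records data.frame with columns `strain_id`,
#'   `total_survivors`, `n_assayed`, `n_pcr_positive` (e.g. from
#'   [simulate_phage_survival()]); must include the wild type.
#' @param wt_strain strain id of the wild type (default "wt").
#' @return Named numeric vector of folds, one per non-wt strain; NA
#'   with a warning when the wild-type PCR fraction is zero.
#' @export
phage_immunity_fold <- function(records, wt_strain = "wt") {
  stopifnot(all(records$n_pcr_positive <= records$n_assayed))
  wt <- records[records$strain_id == wt_strain, , drop = FALSE]
  if (nrow(wt) != 1L) stop("need exactly one wild-type record")
  others <- records[records$strain_id != wt_strain, , drop = FALSE]
  wt_val <- wt$total_survivors * wt$n_pcr_positive / wt$n_assayed
  folds <- with(others,
                total_survivors * n_pcr_positive / n_assayed) / wt_val
  if (wt_val == 0) {
    warning("wild-type PCR-positive fraction is zero: fold undefined")
    folds <- rep(NA_real_, nrow(others))
  }
  setNames(folds, others$strain_id)
}

one_sample_t <- function(x, mu) {
  n <- length(x)
  m <- mean(x); s <- sd(x)
  se <- s / sqrt(n)
  if (se == 0) {
    t <- if (m == mu) 0 else sign(m - mu) * Inf
    return(list(mean = m, sd = s, t = t,
                p = if (m == mu) 1 else 0,
                ci_lo = m, ci_hi = m))
  }
  t <- (m - mu) / se
  hw <- qt(0.975, n - 1L) * se
  list(mean = m, sd = s, t = t, p = 2 * pt(-abs(t), n - 1L),
       ci_lo = m - hw, ci_hi = m + hw)
}

#' Growth-competition deviation analysis
#'
#' Per passage day, a one-sample two-tailed t-test of the replicate
#' variant fractions against the neutral expectation 0.5.  A variant
#' without fitness cost shows no significant deviation on any day.
#'
#' @param fractions matrix of variant fractions, one row per
#'   replicate, columns day0..dayD (e.g. `rbind()` of
#'   [simulate_competition()] runs); day 0 (the 0.5 inoculum) is
#'   reported but not tested.
#' @return data.frame of class `competition_analysis`: day, mean, sd,
#'   ci_lo, ci_hi, t, p (NA when fewer than 2 replicates).
#' @export
competition_analysis <- function(fractions) {
  if (is.vector(fractions)) fractions <- matrix(fractions, nrow = 1L)
  days <- seq_len(ncol(fractions)) - 1L
  out <- lapply(seq_along(days), function(j) {
    x <- fractions[, j]
    if (length(x) < 2L || days[j] == 0L)
      return(data.frame(day = days[j], mean = mean(x), sd = sd(x),
                        ci_lo = NA_real_, ci_hi = NA_real_,
                        t = NA_real_, p = NA_real_))
    tt <- one_sample_t(x, 0.5)
    data.frame(day = days[j], mean = tt$mean, sd = tt$sd,
               ci_lo = tt$ci_lo, ci_hi = tt$ci_hi, t = tt$t, p = tt$p)
  })
  out <- do.call(rbind, out)
  class(out) <- c("competition_analysis", class(out))
  out
}
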