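# Independent brute-force oracles, kept deliberately naive (scalar
# loops, textbook formulas) so they share no code path with the
# package implementation.

oracle_enrichment <- function(sel, unsel, p) {
  out <- sel
  for (i in seq_len(nrow(sel)))
    for (j in seq_len(ncol(sel)))
      out[i, j] <- (sel[i, j] + p) / (unsel[i, j] + p)
  out
}

oracle_preferences <- function(enr) {
  out <- enr
  for (i in seq_len(nrow(enr))) {
    s <- 0
    for (j in seq_len(ncol(enr))) s <- s + enr[i, j]
    for (j in seq_len(ncol(enr))) out[i, j] <- enr[i, j] / s
  }
  out
}

oracle_diffsel <- function(sel, unsel, wt_aa, p) {
  out <- sel
  for (i in seq_len(nrow(sel))) {
    w <- which(colnames(sel) == wt_aa[i])
    for (j in seq_len(ncol(sel))) {
      num <- (sel[i, j] + p) / (sel[i, w] + p)
      den <- (unsel[i, j] + p) / (unsel[i, w] + p)
      out[i, j] <- log(num / den, base = 2)
    }
    out[i, w] <- 0
  }
  out
}

oracle_pearson <- function(x, y) {
  x <- as.vector(x); y <- as.vector(y)
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

oracle_welch <- function(a, b) {
  # textbook Welch-Satterthwaite, written out longhand
  na <- length(a); nb <- length(b)
  va <- sum((a - mean(a))^2) / (na - 1)
  vb <- sum((b - mean(b))^2) / (nb - 1)
  t <- (mean(a) - mean(b)) / sqrt(va / na + vb / nb)
  df <- (va / na + vb / nb)^2 /
    ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

# small aa-level matrix with attributes set, for core-stat tests
toy_aa_matrix <- function(values, wt_aa) {
  m <- matrix(values, nrow = length(wt_aa),
              dimnames = list(seq_along(wt_aa),
                              aa_alphabet()[seq_len(length(values) /
                                                      length(wt_aa))]))
  attr(m, "wt_aa") <- wt_aa
  m
}
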