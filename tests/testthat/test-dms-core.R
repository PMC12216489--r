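test_that("RPM normalization scales to one million total", {
  m <- matrix(c(3, 1, 0, 0), nrow = 1,
              dimnames = list(1, c("AAA", "AAC", "AAG", "AAT")))
  # pad to a 64-column codon table
  full <- matrix(0, 1, 64, dimnames = list(1, codon_alphabet()))
  full[, colnames(m)] <- m
  r <- to_rpm(full)
  expect_equal(unname(r[1, "AAA"]), 750000)
  expect_equal(unname(r[1, "AAC"]), 250000)
  expect_equal(sum(r), 1e6)
  # uniform counts over k cells
  u <- matrix(1, 1, 64, dimnames = list(1, codon_alphabet()))
  expect_true(all(to_rpm(u) == 1e6 / 64))
  expect_error(to_rpm(full * 0), "zero")
})

test_that("amino-acid aggregation sums synonymous codons and conserves totals", {
  tab <- matrix(0, 2, 64, dimnames = list(1:2, codon_alphabet()))
  tab[1, "CTG"] <- 2; tab[1, "CTA"] <- 1; tab[1, "AAA"] <- 4
  tab[2, "TAA"] <- 3; tab[2, "ATG"] <- 5
  tab <- codon_count_table(tab, wt_codons = c("CTG", "ATG"))
  aa <- aggregate_to_aa(tab)
  expect_equal(unname(aa[1, "L"]), 3)
  expect_equal(unname(aa[1, "K"]), 4)
  expect_equal(unname(aa[2, "*"]), 3)  # stop kept as QC column
  expect_equal(rowSums(aa), rowSums(unclass(tab)),
               ignore_attr = TRUE)
  expect_equal(attr(aa, "wt_aa"), c("L", "M"))
})

test_that("enrichment, preferences and diffsel match brute-force oracles", {
  set.seed(99)
  wt_aa <- c("M", "K", "L")
  sel <- toy_aa_matrix(round(runif(60, 0, 2000), 1), wt_aa)
  unsel <- toy_aa_matrix(round(runif(60, 0, 2000), 1), wt_aa)
  p <- 0.5

  enr <- enrichment(sel, unsel, p)
  expect_lt(max(abs(enr - oracle_enrichment(sel, unsel, p))), 1e-12)
  expect_true(all(enr > 0) && all(is.finite(enr)))

  prefs <- preferences(enr)
  expect_lt(max(abs(unclass(prefs) - oracle_preferences(unclass(enr)))),
            1e-12)
  expect_true(all(abs(rowSums(prefs) - 1) < 1e-9))

  dsel <- differential_selection(sel, unsel, wt_aa, p)
  expect_lt(max(abs(unclass(dsel) -
                      oracle_diffsel(sel, unsel, wt_aa, p))), 1e-12)
  expect_equal(unname(unclass(dsel)[cbind(1:3, match(wt_aa,
                                                     colnames(dsel)))]),
               c(0, 0, 0))

  # worked examples
  expect_true(all(abs(enrichment(sel, sel, p) - 1) < 1e-12))
  z <- toy_aa_matrix(c(0), "A"); o <- toy_aa_matrix(c(999.5), "A")
  expect_equal(unname(enrichment(z, o, 0.5)[1, 1]), 5e-4)
  e3 <- matrix(c(2, 1, 1), 1, dimnames = list(1, c("A", "C", "D")))
  expect_equal(unname(preferences(e3)[1, ]), c(0.5, 0.25, 0.25),
               ignore_attr = TRUE)
  # direct evaluation of the stated diffsel example
  sel1 <- matrix(c(100, 900), 1, dimnames = list(1, c("A", "C")))
  uns1 <- matrix(c(500, 500), 1, dimnames = list(1, c("A", "C")))
  d1 <- differential_selection(sel1, uns1, "C", 0.5)
  expect_equal(unname(d1[1, "A"]),
               log2((100.5 / 900.5) / (500.5 / 500.5)),
               tolerance = 1e-12)
  expect_equal(round(unname(d1[1, "A"]), 3), -3.164)
})

test_that("diffsel is antisymmetric, scale invariant and monotone", {
  set.seed(7)
  wt_aa <- c("A", "G")
  sel <- toy_aa_matrix(round(runif(40, 0, 1000)), wt_aa)
  unsel <- toy_aa_matrix(round(runif(40, 0, 1000)), wt_aa)

  d <- differential_selection(sel, unsel, wt_aa)
  d_swap <- differential_selection(unsel, sel, wt_aa)
  expect_equal(unclass(d), -unclass(d_swap), tolerance = 1e-12,
               ignore_attr = TRUE)

  # scale invariance through RPM: multiply raw counts of one sample
  selc <- matrix(0, 2, 64, dimnames = list(1:2, codon_alphabet()))
  unselc <- selc
  set.seed(8)
  selc[, ] <- rpois(128, 50); unselc[, ] <- rpois(128, 50)
  selc <- codon_count_table(selc, c("AAA", "GGG"))
  unselc <- codon_count_table(unselc, c("AAA", "GGG"))
  pipe <- function(s, u) {
    sa <- aggregate_to_aa(to_rpm(s)); ua <- aggregate_to_aa(to_rpm(u))
    list(d = differential_selection(sa, ua),
         p = preferences(enrichment(sa, ua)))
  }
  a <- pipe(selc, unselc)
  b <- pipe(codon_count_table(unclass(selc) * 17, c("AAA", "GGG")), unselc)
  expect_equal(unclass(a$d), unclass(b$d), tolerance = 1e-12)
  expect_equal(unclass(a$p), unclass(b$p), tolerance = 1e-12)

  # monotonicity: raising one amino acid's selected RPM raises its
  # diffsel and its preference
  sel2 <- sel; sel2[1, "C"] <- sel2[1, "C"] + 100
  d2 <- differential_selection(sel2, unsel, wt_aa)
  expect_gt(d2[1, "C"], d[1, "C"])
  p1 <- preferences(enrichment(sel, unsel))
  p2 <- preferences(enrichment(sel2, unsel))
  expect_gt(p2[1, "C"], p1[1, "C"])
})

test_that("replicate aggregation averages preferences and medians diffsel", {
  wt_aa <- c("A", "C")
  set.seed(11)
  mk_pref <- function() {
    m <- matrix(runif(40), 2, 20, dimnames = list(1:2, aa_alphabet()))
    m <- m / rowSums(m)
    structure(m, wt_aa = wt_aa,
              class = c("preference_matrix", "matrix", "array"))
  }
  p1 <- mk_pref(); p2 <- mk_pref()
  agg <- aggregate_replicates(preference_list = list(p1, p2))
  expect_true(all(abs(rowSums(agg$preferences) - 1) < 1e-9))
  same <- aggregate_replicates(preference_list = list(p1, p1))
  expect_equal(unclass(same$preferences), unclass(p1), tolerance = 1e-12)

  d <- matrix(0, 1, 3, dimnames = list(1, c("A", "C", "D")))
  mk_d <- function(v) structure(d + v, wt_aa = "A",
                                class = c("diffsel_matrix", "matrix",
                                          "array"))
  agg_d <- aggregate_replicates(diffsel_list = list(mk_d(1), mk_d(2),
                                                    mk_d(10)))
  expect_true(all(agg_d$diffsel == 2))
})

test_that("replicate correlation is Pearson over flattened entries", {
  a <- matrix(c(0.1, 0.9, 0.5, 0.5), 2, 2, byrow = TRUE,
              dimnames = list(1:2, c("A", "C")))
  b <- matrix(c(0.2, 0.8, 0.4, 0.6), 2, 2, byrow = TRUE,
              dimnames = list(1:2, c("A", "C")))
  expect_equal(replicate_correlation(a, a), 1.0)
  expect_equal(replicate_correlation(a, 3 * a + 2), 1.0)
  expect_lt(abs(replicate_correlation(a, b) - oracle_pearson(a, b)),
            1e-12)
  const <- matrix(1, 2, 2, dimnames = dimnames(a))
  expect_warning(r <- replicate_correlation(a, const), "constant")
  expect_true(is.na(r))
})

test_that("median diffsel ranks planted multipliers (recovery property)", {
  # plant multipliers {0, 0.1, 1, 5, 10} at five sites and check the
  # rank correlation with median diffsel over three replicate screens;
  # the exact-count route keeps this fast
  preset <- library_preset("rec", L = 60, lambda_mut = 1.5,
                           n_clones = 8000L)
  mult <- c(0, 0.1, 1, 5, 10)
  sites <- c(10L, 20L, 30L, 40L, 50L)
  wt_aa <- translate_codons(preset$wt_codons)
  target_aa <- vapply(sites, function(s)
    setdiff(c("L", "S", "R"), wt_aa[s])[1L], character(1))
  eff <- effect_table(sites, target_aa, mult)
  reps <- lapply(1:3, function(r) {
    lib <- simulate_clone_library(preset, seed = 60 + r)
    cfg <- screen_config(base_rate = 1e-4, n_cells = 1.6e8,
                         seed = 70 + r)
    scr <- simulate_selection(lib, eff, cfg)
    sel_aa <- aggregate_to_aa(to_rpm(
      codon_counts_from_clones(lib, scr$selected)))
    unsel_aa <- aggregate_to_aa(to_rpm(
      codon_counts_from_clones(lib, scr$unselected)))
    differential_selection(sel_aa, unsel_aa)
  })
  med <- aggregate_replicates(diffsel_list = reps)$diffsel
  got <- med[cbind(sites, match(target_aa, colnames(med)))]
  expect_gte(cor(mult, got, method = "spearman"), 0.9)
  # planted enhancer positive, planted null negative
  expect_gt(got[5], 0)
  expect_lt(got[1], 0)
})
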