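test_that("clone libraries follow the truncated-Poisson mutation model", {
  # lambda = 0: every clone wild type
  p0 <- library_preset("null", L = 20, lambda_mut = 0, n_clones = 50)
  expect_equal(nrow(simulate_clone_library(p0, seed = 1)$mutations), 0L)

  preset <- dms_preset("cas1", n_clones = 10000L)
  lib <- simulate_clone_library(preset, seed = 42)
  k <- tabulate(factor(lib$mutations$clone_id,
                       levels = seq_len(lib$n_clones)),
                nbins = lib$n_clones)
  lam <- preset$lambda_mut
  n <- lib$n_clones
  # mean and variance of the load within 3 SE of Poisson expectations
  expect_lt(abs(mean(k) - lam), 3 * sqrt(lam / n))
  expect_lt(abs(var(k) - lam), 3 * sqrt((lam + 2 * lam^2) / n))
  # no duplicate positions within a clone; mutants differ from wt
  expect_false(any(duplicated(lib$mutations[, c("clone_id", "position")])))
  expect_true(all(lib$mutations$codon !=
                    preset$wt_codons[lib$mutations$position]))
  # positions uniform across the gene (chi-square not rejected)
  pos_tab <- tabulate(lib$mutations$position, nbins = preset$L)
  gof <- stats::chisq.test(pos_tab)
  expect_gt(gof$p.value, 0.001)
  # determinism: identical seed, identical library
  expect_identical(lib$mutations,
                   simulate_clone_library(preset, seed = 42)$mutations)
  # degenerate preset rejected
  bad <- library_preset("bad", L = 2, lambda_mut = 5, n_clones = 10)
  expect_error(simulate_clone_library(bad), "degenerate")
})

test_that("clone selection probability multiplies planted effects", {
  wt <- c("ATG", "AAA", "CTG")  # M K L
  eff <- effect_table(c(2L, 3L), c("R", "P"), c(5, 0))
  no_mut <- data.frame(position = integer(0), codon = character(0))
  expect_equal(clone_selection_probability(no_mut, wt, eff, 1e-5), 1e-5)
  one <- data.frame(position = 2L, codon = "AGA")  # K2R, multiplier 5
  expect_equal(clone_selection_probability(one, wt, eff, 1e-5), 5e-5)
  both <- data.frame(position = c(2L, 3L), codon = c("AGA", "CCC"))
  expect_equal(clone_selection_probability(both, wt, eff, 1e-5), 0)
  # synonymous change is neutral even if an effect is listed at the site
  syn <- data.frame(position = 3L, codon = "CTA")  # Leu -> Leu
  expect_equal(clone_selection_probability(syn, wt, eff, 1e-5), 1e-5)
  # cap at probability 1
  big <- effect_table(2L, "R", 1e7)
  expect_equal(clone_selection_probability(one, wt, big, 1e-5), 1)
})

test_that("selection sampling matches binomial thinning", {
  # homogeneous effects: selected fraction close to base_rate
  preset <- library_preset("flat", L = 10, lambda_mut = 0.5,
                           n_clones = 200L)
  lib <- simulate_clone_library(preset, seed = 7)
  cfg <- screen_config(base_rate = 1e-3, n_cells = 1e7, seed = 8)
  scr <- simulate_selection(lib, effect_table(), cfg)
  frac <- sum(scr$selected) / sum(scr$unselected)
  se <- sqrt(1e-3 / 1e7)
  expect_lt(abs(frac - 1e-3), 3 * se)

  # one planted enhancer (x10) at 1% library frequency: its
  # selected:unselected frequency ratio is ~10x the wt clones' ratio
  wt2 <- translate_codons(library_preset("toy", L = 3,
                                         lambda_mut = 1,
                                         n_clones = 1L)$wt_codons[2])
  mut_codon <- if (wt2 == "P") "AAA" else "CCC"  # guarantee nonsynonymous
  lib2 <- manual_library(3L, 100L,
                         data.frame(clone_id = 1L, position = 2L,
                                    codon = mut_codon))
  eff <- effect_table(2L, translate_codons(mut_codon), 10)
  cfg2 <- screen_config(base_rate = 1e-3, n_cells = 1e7, seed = 9)
  scr2 <- simulate_selection(lib2, eff, cfg2)
  ratio_enh <- (scr2$selected[1] / sum(scr2$selected)) /
    (scr2$unselected[1] / sum(scr2$unselected))
  ratio_wt <- (sum(scr2$selected[-1]) / sum(scr2$selected)) /
    (sum(scr2$unselected[-1]) / sum(scr2$unselected))
  expect_lt(abs(ratio_enh / ratio_wt - 10) / 10, 0.2)

  # all effects zero with base_rate zero: empty selected table
  eff0 <- effect_table(seq_len(3L), rep("P", 3), rep(0, 3))
  cfg3 <- screen_config(base_rate = 0, n_cells = 1e6, seed = 10)
  expect_warning(scr3 <- simulate_selection(lib2, eff0, cfg3),
                 "underpowered")
  expect_equal(sum(scr3$selected), 0L)
})

test_that("simulated reads obey counting, error-rate and round-trip rules", {
  preset <- library_preset("seg", L = 50, lambda_mut = 1, n_clones = 100L)
  lib <- simulate_clone_library(preset, seed = 5)
  segs <- default_segments(preset$L, n_segments = 1L)

  cfg0 <- screen_config(seq_error_rate = 0, reads_per_barcode = 3L,
                        seed = 6)
  reads <- simulate_reads(rep(1L, 100L), lib, cfg0, segs,
                          molecules_per_clone = 1L)
  expect_equal(nrow(reads), 300L)
  ids <- data.table::tstrsplit(reads$id, ":", fixed = TRUE)
  expect_equal(length(unique(ids[[2]])), 100L)  # distinct barcodes
  # zero error: every read equals its clone's segment sequence
  clone_of <- as.integer(ids[[3]])
  templates <- dmscreen:::clone_sequences(lib, clone_of)
  expect_true(all(reads$seq == templates))

  # error rate: mean mismatches per read ~ len * rate
  cfg1 <- screen_config(seq_error_rate = 1e-3, reads_per_barcode = 1L,
                        seed = 16)
  reads1 <- simulate_reads(rep(1L, 100L), lib, cfg1, segs,
                           n_molecules = 10000L)
  ids1 <- data.table::tstrsplit(reads1$id, ":", fixed = TRUE)
  tmpl1 <- dmscreen:::clone_sequences(lib, as.integer(ids1[[3]]))
  mismatches <- mapply(function(a, b)
    sum(charToRaw(a) != charToRaw(b)), reads1$seq, tmpl1,
    USE.NAMES = FALSE)
  expected <- 150 * 1e-3
  expect_lt(abs(mean(mismatches) - expected) / expected, 0.10)

  # invalid tiling rejected
  bad <- data.frame(segment_id = "S1", start_codon = 1L, end_codon = 49L)
  expect_error(simulate_reads(rep(1L, 100L), lib, cfg0, bad), "tile")

  # determinism: byte-identical reads under the same seed
  again <- simulate_reads(rep(1L, 100L), lib, cfg0, segs,
                          molecules_per_clone = 1L)
  expect_identical(reads$seq, again$seq)
  expect_identical(reads$id, again$id)
})

test_that("plating simulation is Poisson in the plated fractions", {
  expect_true(all(simulate_plating(0, 1e8, seed = 1)$colonies[
    simulate_plating(0, 1e8, seed = 1)$plate == "selective"] == 0))

  scheme <- data.frame(plate = c("selective", "total"),
                       dilution = c(1e-2, 1e-7), volume = 1)
  counts <- t(vapply(1:200, function(s)
    simulate_plating(1e-5, 1e8, scheme, seed = s)$colonies,
    numeric(2)))
  # expected counts 10 and 10 on both plates
  expect_lt(abs(mean(counts[, 1]) - 10), 3 * sqrt(10 / 200))
  expect_lt(abs(mean(counts[, 2]) - 10), 3 * sqrt(10 / 200))

  # Monte-Carlo unbiasedness of the rate estimator over 50 seeds
  rates <- vapply(1:50, function(s)
    acquisition_rate(simulate_plating(1e-5, 1e8, seed = 100 + s))$rate,
    numeric(1))
  expect_gt(mean(rates) / 1e-5, 0.9)
  expect_lt(mean(rates) / 1e-5, 1.1)
})

test_that("phage-survival simulation matches its generative model", {
  # nu = 0: every assayed colony is PCR-positive
  rec <- simulate_phage_survival(70, 0, "T-phage", 12L, seed = 3)
  expect_true(all(rec$n_pcr_positive == rec$n_assayed))
  # true_fold = 1 behaves like wt in expectation
  one <- data.frame(name = "null-variant", true_fold = 1)
  tots <- t(vapply(1:100, function(s) {
    r <- simulate_phage_survival(70, 50, one, 12L, seed = s)
    r$total_survivors
  }, numeric(2)))
  expect_lt(abs(mean(tots[, 1]) - mean(tots[, 2])),
            3 * sqrt(2 * 120 / 100))
  # fold-7 estimator close to 7 in expectation (exact value 490/70)
  folds <- vapply(1:60, function(s)
    phage_immunity_fold(simulate_phage_survival(
      70, 50, "MYT-phage", 12L, seed = 200 + s))[["MYT-phage"]],
    numeric(1))
  expect_lt(abs(mean(folds) - 7) / 7, 0.2)
})

test_that("competition series follow the bottleneck-growth model", {
  # neutral, deterministic limit: every fraction exactly 0.5
  f <- simulate_competition(1, days = 6L, bottleneck_size = Inf)
  expect_equal(unname(f), rep(0.5, 7))
  # zero fitness: extinct by day 1
  f0 <- simulate_competition(0, days = 3L, bottleneck_size = 1e4, seed = 2)
  expect_equal(unname(f0[-1]), rep(0, 3))
  # closed-form deterministic limit for fitness 1.1 over 6 days
  f1 <- simulate_competition(1.1, days = 6L, bottleneck_size = Inf)
  expect_equal(unname(f1[7]), 0.5 * 1.1^6 / (0.5 * 1.1^6 + 0.5),
               tolerance = 1e-12)
  # neutral with a large finite bottleneck stays near 0.5
  f2 <- simulate_competition(1, days = 6L, bottleneck_size = 1e6, seed = 4)
  expect_true(all(abs(f2 - 0.5) < 0.01))
  # determinism
  expect_identical(f2, simulate_competition(1, days = 6L,
                                            bottleneck_size = 1e6,
                                            seed = 4))
})
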