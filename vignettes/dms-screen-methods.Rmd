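---
title: "Methods: simulating and scoring spacer-acquisition DMS screens"
author: "dmscreen maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and scoring spacer-acquisition DMS screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmscreen)
```

## The experiment this package models

Deep mutational scanning (DMS) of the type II-A CRISPR adaptation
proteins couples a codon-mutant library of a *cas* gene to a
selectable spacer-acquisition phenotype: cells that integrate a
reporter-activating spacer become erythromycin resistant, so plating
the library on selective versus non-selective media separates
functional variants from the bulk. Comparative sequencing of the two
populations quantifies, for every amino-acid substitution, how
selection changed its frequency. `dmscreen` implements that analysis
chain — and, because the deposited sequencing data are not needed for
desk-scale validation, a generative simulator whose ground truth every
downstream stage must recover.

## Statistics layers

Counts are normalized to reads per million (RPM) per sample, then
aggregated from codons to amino acids (stop codons kept in a `*` QC
column and excluded from all residue-level statistics). With a
symmetric pseudocount $p$ (default 0.5 RPM):

* **Enrichment**: $e(s,a) = \frac{\mathrm{sel}(s,a)+p}{\mathrm{unsel}(s,a)+p}$.
* **Preference**: $\pi(s,a) = e(s,a) / \sum_{a'} e(s,a')$, a per-site
  probability distribution over the 20 residues.
* **Differential selection** (diffsel): $\log_2$ of the mutant:wild-type
  enrichment ratio,
  $d(s,a) = \log_2\!\frac{(\mathrm{sel}(s,a)+p)/(\mathrm{sel}(s,wt)+p)}
  {(\mathrm{unsel}(s,a)+p)/(\mathrm{unsel}(s,wt)+p)}$, zero at the
  wild-type residue by construction.
* **Shannon entropy**: $SE(s) = -\sum_a \pi(s,a)\log_2 \pi(s,a)$,
  in bits (base 2, matching the log2 convention of diffsel; the source
  protocol does not fix a base). High entropy marks mutational
  tolerance.

Replicates are combined as the entrywise *mean* of preferences (rows
renormalized) and the entrywise *median* of diffsel; replicate
agreement is summarized by Pearson correlation over all flattened
(site, residue) entries.

The composite gain-of-function score is
$\mathrm{score} = \mathrm{possum}_{sc} + \mathrm{max}_{sc} - SE_{sc}$,
where $\mathrm{possum} = \sum_a \max(0, d(s,a))$,
$\mathrm{max} = \max_{a \ne wt} d(s,a)$, and each metric is min-max
scaled to $[0,1]$ per protein, so scores lie in $[-1,2]$: strong,
concentrated positive selection at an otherwise intolerant site scores
highest. The top `k = 8` sites (the number of candidates advanced to
wet-lab validation per protein) are nominated with their
highest-diffsel substitution, ties broken by lower site index then
alphabetical residue.

### Why the pseudocount is symmetric, and the other numerical choices

The upstream protocol delegates scoring to external software without
printing parameters, so this package fixes them explicitly:

* $p = 0.5$ RPM added to all four terms: keeps every ratio finite and
  preserves the antisymmetry property (swapping selected and
  unselected negates diffsel exactly), which the test suite asserts.
* Diffsel is computed at amino-acid level after codon aggregation,
  matching the per-residue heatmaps that are the reported layer.
* `max_diffsel` excludes the wild-type residue (identically zero, it
  would floor the metric).
* Constant metric vectors min-max scale to all zeros rather than
  dividing by zero; the degenerate case is flagged by the QC output.
* Preference rows are renormalized after replicate averaging so the
  row-sum invariant survives floating-point accumulation.
* Entropy validation rejects rows whose sum deviates from 1 by more
  than 1e-6.

Whether the original preferences derive from ratio normalization or
from a Bayesian inference mode is not documented; the ratio definition
above is adopted and stated as such. Similarly, replicate Pearson
correlations are computed entrywise (per-site summaries would be the
alternative reading).

## The synthetic world

The generator plants known truth at every stage so that recovery, not
plausibility, is the test standard.

* **Library**: per clone, a Poisson($\lambda$) number of mutated
  codons (truncated at the gene length), positions uniform without
  replacement, mutant codons uniform over all 63 alternatives (NNN
  model — the tiling mutagenesis samples all codons, and no
  restriction is documented). Presets mirror the three screened
  genes: cas1-like (289 codons, $\lambda = 1.8$), cas2-like (113,
  1.3), csn2-like (220, 1.5). Wild-type sequences are deterministic
  synthetic stand-ins (ATG start, no internal stops) — lengths and
  rates, not sequences, are what downstream statistics exercise.
* **Selection**: cells are allocated to clones multinomially
  (`n_cells` total); each cell survives selection with probability
  `min(1, base_rate × ∏ multipliers)` over the clone's amino-acid
  changes. Effects are multiplicative (the simplest composable model;
  per-substitution selection is all the assay reports), synonymous
  changes are neutral by construction, and the planted `effect_table`
  is the recovery oracle. Defaults `base_rate = 1e-5` and
  `seq_error_rate = 1e-3` are package choices; the protocol prints
  neither.
* **Sequencing**: each molecule is one subamplicon segment of one
  clone, tagged with a unique random barcode (collisions are a
  declared non-goal and are not simulated), read `reads_per_barcode`
  times with independent per-base substitution errors. Reads span
  their whole segment at a fixed offset — the codon-tiling design
  yields substitution-only variants, so no indel alignment is needed
  and length-discordant reads are simply ignored.
* **Validation assays**: plating uses Poisson colony counts at the
  plated fractions of tenfold serial dilutions; phage survival splits
  colonies into CRISPR survivors (Poisson, scaled by the planted fold)
  and non-CRISPR escapers (Poisson, shared rate), with the
  PCR-positive count hypergeometric among assayed colonies — with
  $\mu_{wt} = 70$, $\nu = 50$ the expected wild-type PCR fraction is
  7/12; competition passages a 0.5/0.5 mixture through daily binomial
  bottlenecks (1:100 dilutions) followed by deterministic
  fitness-weighted growth.

What a green test does **not** establish: the simulator has no PCR
amplification bias, chimeras, barcode collisions, indels, batch
effects between replicates, or phage population dynamics, and its
per-substitution effects are epistasis-free. Recovery under this model
validates the estimator algebra and the processing chain, not
robustness to those artefacts.

## Consensus calling

Reads sharing a (segment, barcode) pair are collapsed per codon by
strict majority; ties and non-majorities are masked and contribute no
count, and groups below `min_reads_per_barcode = 2` are dropped (and
tallied — the suite checks read conservation). With a 1e-3 per-base
error rate and 3 reads per molecule, the residual per-codon consensus
error is below 1e-5, so consensus rather than base quality is the
error-correction mechanism; quality scores are read but ignored.

## Screen regimes, depth and what ranking needs

Two regime parameters dominate whether planted gain-of-function sites
are recoverable at desk scale:

* **Selected colonies per clone.** The published screen recovered
  roughly 2–3 selected colonies per library clone (3.8×10⁵ colonies
  from 1.4×10⁵ clones). The end-to-end acceptance world reproduces
  that regime (~2 colonies/clone). At an order of magnitude fewer
  colonies the selected counts per substitution become 0–2 and
  ranking is dominated by count discreteness — a property of the
  experiment, not of the estimator.
* **Unselected coverage.** With fewer than ~2 molecules per clone and
  segment, substitutions present in the library drop out of the
  unselected sample, and the pseudocount then manufactures extreme
  positive diffsel for any such slot that gains a couple of selected
  reads. Three molecules per clone per segment (the default screen
  coverage here; the real screens sequenced far deeper) keeps the
  dropout probability negligible for multi-codon amino acids.

The demo configuration shipped with the tests runs a deliberately
small screen (2,000 clones): planted effects show clearly positive
diffsel there, but top-k membership is only asserted in the
full-scale acceptance world.

## Assay statistics

Acquisition rates divide selective by total CFU/mL, each taken from
the most countable plate (30–300 colonies preferred, else the highest
count — the tenfold-dilution protocol does not state a rule, so this
package fixes one). Fold changes are ratios of group means (matching
"divided by the wild-type value" applied to aggregate quantities, not
means of per-replicate ratios), with two-tailed Welch t-tests on the
raw replicate rates (a log10 option exists but is off, matching the
graphing-software default workflow the protocol cites). No
multiple-testing correction is applied across variants, as in the
source analysis. The phage-immunity fold multiplies surviving colonies
by the PCR-confirmed new-spacer fraction and normalizes to wild type.

Two estimator properties worth knowing:

* The per-seed phage-immunity fold is a ratio with a noisy wild-type
  denominator (PCR fraction from 12 colonies, CV ≈ 24%), so its mean
  over seeds is biased upward by ≈ 9% (exact expectation 7.61 for a
  planted 7-fold); the package reports the estimator as defined
  rather than a bias-corrected variant.
* Testing six passage days at α = 0.05 each gives a family-wise
  type-I rate near 18% even under a perfect null (days are only
  partially correlated through the shared random walk), so "no
  significant day" is expected to fail in roughly one run in five —
  a Holm option is available for users who want family-wise control,
  but it is off by default to match the per-comparison reporting of
  the source analysis.

## Reproducibility

Every stochastic function takes an explicit seed and restores the
caller's RNG state; the pipeline derives stage seeds from the master
seed by a stable string hash (`child_seed`), so any stage can be rerun
in isolation and a configuration reruns byte-identically. The run
configuration is JSON (no YAML parser is available in the supported
dependency set); unknown keys are rejected rather than ignored.

One denominator is deliberately left unresolved: published library
"coverage" figures imply a variant-space size of roughly L×20, but
L×19 (excluding wild type) is equally defensible; nothing in this
package depends on either convention, and both are merely noted here.

## Limitations

Clone-resolved deconvolution of multi-mutant clones is out of scope —
counts are marginal per substitution, as in the source analysis — so
diffsel attributes a multi-mutation clone's fate to each of its
substitutions. Structure-aware filtering, conservation priors, adapter
trimming, demultiplexing and paired-end merging are likewise out of
scope.
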