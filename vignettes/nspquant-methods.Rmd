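---
title: "Methods: quantification, moderation and classification in nspquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantification, moderation and classification in nspquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical models and the design choices
behind `nspquant` — the conventions a reader needs to interpret its
output, and the reasoning at the points where more than one defensible
convention exists.

## The data model

The unit of input is a *channel-resolved precursor record*: one
(modified peptide sequence, charge) species observed in one SILAC
channel (light L, intermediate M, heavy H) of one run, carrying an
MS1-level and an MS2-level quantity plus three confidence scores
(precursor q-value, channel q-value, translated q-value). In a pulsed
labeling experiment the M and H channels carry newly synthesized
protein; ratios between channels within one run are therefore the
quantity of biological interest, and they are unaffected by run-to-run
normalization questions.

Filtering applies strict thresholds: a record is kept only when all
three q-values are strictly below their thresholds (default 0.01 each).
"Strictly" mirrors the conventional `< 0.01` phrasing; a record at
exactly 0.01 is removed. Absent q-value columns (inputs from search
engines that do not emit channel-level confidence) pass with a prominent
warning rather than an error, because the filter cannot be meaningfully
applied. Contaminant removal treats a multi-accession protein group as
contaminated when *any* member matches the contaminant list or prefix —
conservative, since a shared peptide signal cannot be attributed away
from the contaminant. The q-value filter is applied per record as read;
whether precursor FDR should instead be controlled globally across runs
is left to the search engine that produced the q-values.

## MaxLFQ channel quantification

For one protein group, let `x_j` be the unknown log2 abundance of column
`j` (a run-channel pair). Every pair of columns sharing at least
`min_shared` precursors (default 1) contributes an equation
`x_b − x_a = r_ab`, where `r_ab` is the *median* over shared precursors
of the log2 intensity differences (an even count uses the mean of the
central values). The estimate minimizes `Σ (x_b − x_a − r_ab)²`, solved
per connected component via the graph Laplacian with a sum-to-zero
constraint. The solution is defined up to a constant per component; we
anchor each component so that its summed linear-scale abundance equals
the component's total observed precursor intensity (the MaxLFQ
convention). Columns in singleton components fall back to their summed
intensity. Zero intensities are treated as absent: a zero carries no
ratio information and its logarithm is undefined.

Two consequences of the anchoring are worth knowing. First, strict
column-scale equivariance (scale one column's intensities by `c`, its
abundance scales by `c`) holds exactly on ratio-consistent data and only
approximately otherwise, because the anchor is the total intensity, not
per-column sums. Second, abundances are comparable *within* a component;
ratio formation therefore runs MaxLFQ jointly over all run-channel
columns of a protein by default, which keeps per-channel values mutually
comparable. `mode = "per_channel"` solves each channel separately for
users who want the alternative reading; on the benchmark designs both
modes recover the same channel shares and median ratios.

The precursor count attached to each protein counts distinct (modified
sequence, charge) species — channels and runs do not multiply it. It is
the coverage covariate for the variance prior below.

## Moderated differential expression

The design is one-sample on within-replicate ratios: each replicate run
yields one log2 (treatment channel / control channel) value per protein,
so run-level nuisance factors cancel inside the ratio. Per protein,
`log2_fc` is the replicate mean, `s²` the sample variance, `df = n − 1`;
proteins with fewer than two ratios are reported with their fold change
but not tested.

The empirical-Bayes prior makes the prior variance a function of
precursor count. On the log scale, `e = log s² − digamma(df/2) +
log(df/2)` is an unbiased estimate of `log σ₀²` under the scaled
chi-square sampling model; a loess of `e` on `log(count)` (span 0.75,
degree 1, configurable) gives the count trend. The prior degrees of
freedom follow by method of moments: the excess of the residual variance
of `e` over `mean(trigamma(df/2))` equals `trigamma(d0/2)`, inverted by
Newton iteration. When the excess is non-positive there is no evidence
of variance heterogeneity beyond sampling noise and `d0 = ∞`; in that
limit the prior is the arithmetic mean of the variances when counts are
constant (so the degenerate all-equal case returns the observed value)
and the exponentiated corrected trend otherwise. These conventions match
the moments estimator in `limma::fitFDist`, which the test suite uses as
an independent cross-check in the constant-covariate case. Variances are
floored at 1e-12 before logging so exact-zero variances (possible with
duplicated values) cannot dominate the fit.

Testing uses the squeeze `s²_post = (d0·s²_prior + df·s²)/(d0 + df)`,
`t = log2_fc / sqrt(s²_post/n)`, and a two-sided p from the t
distribution with `df + d0` degrees of freedom, capped at 1e6 when `d0`
is infinite. BH adjustment is applied within each condition/time point —
each volcano panel is its own multiple-testing family, matching how
per-time-point results are reported and interpreted. Significance calls
(default |log2 FC| > 0.585, adjusted p < 0.05) are restricted to unique
protein groups; a multi-accession group's fold change is ambiguous at
the protein level. Ratios are not re-centered before testing (no
normalization is imposed on ratio formation); a median-centering step
can be added upstream by the user if their design warrants it.

## Temporal response classes

A protein is *selected* when some time point shows |log2 FC| > 1 with
adjusted p < 0.05 *and* its ratios are precise across the time course
(CV < 20%). Its *class* is the earliest time point at the laxer
0.585/0.05 thresholds, mapped first → early, last → late, interior →
intermediate. Because 1 > 0.585, every selected protein necessarily
receives a class; the code still guards the contrary case with a
warning, which can only trigger under user-supplied inconsistent
thresholds.

The CV phrase "across all time points" admits three formalizations, and
the choice matters:

* **pooled** — one CV over all replicates of all time points. This
  conflates genuine regulation with noise: a protein stepping 2.8-fold
  at a late time point has a pooled CV far above 20% *because it is
  regulated*, so the filter would delete exactly the late and
  intermediate classes the analysis exists to find.
* **max** — the worst per-time-point replicate CV. A pure precision
  filter, but a CV estimated from 3 replicates has 2 degrees of freedom,
  and the maximum of five such estimates exceeds 20% by chance for an
  appreciable fraction of genuinely precise, low-coverage proteins.
* **mean** (default) — the average per-time-point replicate CV. The same
  precision filter with the estimation noise averaged out.

The default is `mean`; both alternatives remain available via
`cv_mode`. Untested time points count as non-significant rather than as
errors, provided at least one time point was tested; time-point order
comes from configuration, never from file order.

## Over-representation analysis

The one-sided hypergeometric tail `P(X ≥ k)` is evaluated through the
stable distribution function in `stats`. Gene sets are intersected with
the background (the quantified proteins of the same condition) before
counting, so genes never observable in the experiment cannot inflate
set sizes; query genes outside the background are dropped with a
warning. Matching uses the first gene symbol of a group, upper-cased.
Sets with fewer than 3 background members are skipped by default — an
artifact convention of common ORA practice, not a statement about the
underlying test. BH correction runs across the tested sets.

## The synthetic-data generator

The generator emulates the statistical structure of triple-SILAC
channel-resolved reports, not mass spectra. Per protein it draws a
baseline intensity (log2-normal, mean 20, sd 2 — placeholder scale
constants, not fitted to any dataset), a truncated negative-binomial
peptide count (mean 5, dispersion 2, minimum 1, reproducing
overdispersed coverage), and per peptide a log2-normal ionization factor
(sd 1). Channel abundances are baseline × mixing proportion; the
benchmark mixtures are 70/15/15 and 20/40/40 L/M/H, so the expected
log2 H/M is 0 in both and the channel intensity shares are known
exactly. Time-course designs multiply the regulated channel by
`2^effect` from the class onset onward — a step profile; real responses
rise gradually, but a step suffices to define ground-truth classes, and
classification only thresholds significance per time point. Both the
MS1- and MS2-style quantity of a row receive independent multiplicative
log-normal noise (sd in log2 units; 0.25 for benchmarks, 0.15 for the
time-course default). Rows are dropped independently at the missingness
rate (benchmark default 5%); a decoy fraction (default 2%) receives
q-values failing the 0.01 thresholds on all three scores, the rest
q-values strictly below 0.01 — q-values are two-point because the
pipeline only thresholds them. "Sticky" background contamination, when
enabled, adds light-channel intensity drawn independently of the
protein's own abundance, reflecting the observation that unlabeled
carry-over is abundance-independent. One seed drives every draw; the
report generator uses a deterministic offset of the design seed so truth
and report are independently reproducible.

What the generator does *not* model bounds what passing tests show about
real data: no retention-time or spectral interference structure, no
intensity-dependent missingness, no correlation between peptides of a
protein beyond the shared abundance, no label-incorporation kinetics
during the pulse, and no search-engine scoring behavior. Recovery of
mixing proportions here validates the estimator chain, not any
instrument.

## Problem sizes and numerical conventions

The standard study conditions used by the test suite and the acceptance
script are 5000 proteins × 3 runs per benchmark mixture at noise sd
0.25, 300 proteins × 5 time points × 3 replicates at noise sd 0.15 with
effect 1.5 for the classifier, 2000 proteins for prior-recovery
simulations, and 500 random small matrices (≤ 6 columns, ≤ 8 precursors)
for MaxLFQ oracle equivalence at 1e-9 relative tolerance. Duplicate
(precursor, column) observations aggregate by maximum; pairwise ratio
medians use R's `median` (mean of central values on even counts);
least-squares systems are solved exactly per component, with a
brute-force pseudo-inverse solver kept in the test suite as the
independent oracle. The pipeline records a config hash, seed and
per-stage row counts in `manifest.json`, and identical configs reproduce
byte-identical artifacts.

## Known limitations

* Protein groups are taken as given; no protein inference or razor
  peptide logic.
* No iBAQ or absolute quantification; LFQ values are comparable within,
  not across, connected components.
* The moderated test covers the one-sample ratio design only — no
  multi-factor linear models or covariates.
* ORA treats gene sets as flat symbol lists; no ontology-graph
  redundancy handling.
* The generator's intensity scale constants are conventions, not
  estimates; absolute intensity values in simulations are meaningful
  only relative to each other.
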