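---
title: "rdnsv: model, assumptions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{rdnsv: model, assumptions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

rdnsv measures how densely nonsynonymous SNVs (nsSNVs) populate a set of
genes relative to the neutral expectation inferred from synonymous SNVs
(sSNVs). It rests on three ingredients.

**1. Sites as mutational opportunities.** Each coding basepair allows three
single-basepair changes, each weighted 1/3 and classified by its effect
under the standard genetic code (synonymous / missense / nonsense; stop
gains are pooled with missense as nonsynonymous, mirroring how nsSNVs are
counted). A fourfold-degenerate third position therefore contributes a full
synonymous site, a nondegenerate position a full nonsynonymous site, and
partially degenerate positions fractional thirds. The same enumeration
splits sites into transition opportunities (one per basepair) and
transversion opportunities (two per basepair). Counts accumulate in exact
integer thirds and are divided by 3 only when ratios are formed, so the
conservation identities (sSite + nsSite = L, transition sites = L/3) hold
exactly and are asserted on every computed object.

**2. The code-bias correction.** With per-site densities Rn = nsSNV/nsSite
and Rs = sSNV/sSite, the raw ratio Rn/Rs is biased because transitions are
both faster (per-opportunity rate ratio `w`, default 4 — equivalently a
per-basepair transition/transversion rate ratio κ = w/2 = 2) and enriched
among synonymous opportunities. Writing q_s = sSite_ts/sSite:

    f_s = (w q_s + (1 - q_s)) / (w/3 + 2/3)

and analogously f_ns from q_n = nsSite_ts/nsSite. In human coding sequence
q_s ≈ 0.5 gives f_s = 1.25 and q_n ≈ 4/14 gives f_ns ≈ 0.93, so the
corrected statistic is rdnsv = f · Rn/Rs with f = f_s/f_ns ≈ 1.35. The
prose formulation "the code reduces the nonsynonymous relative to the
synonymous mutation rate by f_ns/f_s ≈ 0.74" is the same correction:
dividing by 0.74 equals multiplying by 1.35. We adopt the multiplicative
form because it matches the printed endpoint f′ = (sSite/nsSite)·f ≈
0.3 × 1.35 ≈ 0.4, the rule-of-thumb multiplier for the raw nsSNV/sSNV
count ratio. By default factors are computed from the analyzed gene set's
own site composition; `fixed_correction_factors()` supplies the
genome-wide constants (1.25, 0.925) for exact replication of published
numbers.

**3. The frequency-spectrum regression.** rdnsv computed on all SNVs mixes
two selection signals: the fraction of nonsynonymous sites that tolerate no
segregating variant at all, and the frequency shift of tolerated but
deleterious variants. Binning SNVs by derived allele frequency (disjoint
half-open bins with default edges 2, 5, 10, 20, 40, 80, 95%) and fitting
ordinary least squares of per-bin rdnsv on x = ln(p_rep/p0) yields:
intercept a = rdnsv_0 (predicted density at p0 = 0.01, "close to 0"),
interpreted as the tolerated-site fraction, and rdnsv_1 = a + b ln(1/p0) at
frequency 1, the fraction of sites where fixation is not prevented. The
slope b (per natural-log unit) measures purifying selection on segregating
variants; positive selection would raise rdnsv_1 without raising rdnsv_0.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `w` | 4 | per-opportunity rate ratio | human transition bias κ ≈ 2 per basepair; each basepair has 1 ts and 2 tv opportunities |
| bin edges | .02, .05, .10, .20, .40, .80, .95 | derived allele frequency | standard published stratification; variants ≥ 0.95 are excluded (ancestral misassignment risk near fixation) |
| `p0` | 0.01 | frequency | anchor of the log transform; chosen so that the published rdnsv_1 values equal intercept + slope·ln(100) — this reconstruction is exact for four of the five published gene-set models (the fifth differs only by slope rounding) and is treated as normative |
| p_rep | geometric mean of bin bounds | frequency | a representative frequency on the log scale; the first bin's zero bound is replaced by 1/n_chromosomes, the smallest observable frequency |
| `n_perm` | 10000 | permutations | label permutations for gene-category comparisons |
| `set_size`, `n_draws` | 1500, 10000 | genes, draws | background envelope of random gene sets (2.5/97.5% quantiles) |
| `z_threshold` | 1.0 | Z-score | expression specificity cut for tissue-based candidate sets |

## Polarization and annotation conventions

Derived alleles come from an outgroup (ancestral) base when it matches one
of the two observed alleles — VCF `AA` INFO or a sidecar TSV, lowercase
(low-confidence) calls accepted; otherwise the minor allele is taken as the
most likely derived allele and flagged (`minor-allele-fallback`), with ties
resolved toward the ALT allele. Monomorphic records are excluded with a
warning. Multi-allelic records are split; only strict single-base SNVs are
kept. Coordinates are 0-based half-open internally, converted at the VCF
boundary. One canonical transcript per gene is required; SNVs hitting two
genes' transcripts are annotated against both and logged. SNVs in codons
containing ambiguity codes, or in a terminal stop codon, are skipped — the
same codons that site counting skips, so numerators and denominators stay
matched.

## What the simulator emulates — and what it does not

`simulate_cds()`/`simulate_snvs()` generate the world the estimator
assumes: in-frame stop-free coding sequences on both strands (1–3 exons per
gene), SNVs placed independently on mutational opportunities with
probability proportional to the rate weight (w for transitions), a fraction
π of nonsynonymous opportunities that never emit ("intolerant", assigned
per site, not per gene), and derived counts drawn from a discretized
spectrum on {1/N, …, (N−1)/N}: mass ∝ 1/k (the standard neutral
expectation) for neutral variants, ∝ (1/k)·exp(−γk/N) for deleterious
tolerated nonsynonymous variants. Synonymous variants are always neutral.
Defaults (200 genes × 250–350 codons, N = 400 chromosomes, sSNV density
0.02 per sSite — the order observed when a few hundred human exomes are
pooled; π = 0.45, γ = 2, 25% of tolerated nonsynonymous sites strictly
neutral) sketch a realistic candidate-gene scenario and were fixed before
any calibration results were inspected.

Because frequencies are drawn from *normalized* spectra, emission is
independent of γ and the expected pooled rdnsv equals 1 − π exactly; γ only
moves nonsynonymous mass toward rare bins (so with γ > 0 the fitted
intercept sits somewhat above 1 − π, and the slope turns negative). An
alternative "thinned" model, in which deleterious sites also lose total
polymorphism by the factor Σ(e^{−γk/N}/k)/Σ(1/k), would couple emission to
γ; we chose the normalized form because the estimator's intercept then has
an exact known truth for γ = 0 recovery tests. `expected_truth()` computes
the per-bin expectations by integrating bin occupancy under both spectra.

The simulator deliberately omits demography, linkage and background
selection, CpG hypermutability, recurrent mutation (at most one SNV per
opportunity), and selection on synonymous sites. A green calibration test
therefore establishes that the estimator recovers its own generative truth
— not that real exomes satisfy these assumptions. In particular, real-data
deviations concentrated in the lowest frequency bin (sequencing false
positives, non-linearity of the spectrum) are not modeled; the fit reports
the lowest-bin residual separately so users can inspect it.

## Numerical choices, tie-breaks, degenerate inputs

- Site counts: exact integer thirds; conversion to floating point only at
  ratio time. Internal stop codons are an error naming the codon index;
  terminal stops are stripped; N-containing codons are skipped and logged.
- `rdnsv_estimate()` with sSNV = 0 returns NA with a warning — an
  undefined estimate, deliberately neither 0 nor infinity.
- Bins with zero synonymous SNVs are dropped from the regression (with a
  warning), never imputed; the fit requires ≥ 3 usable bins.
- The regression is unweighted OLS. Weighting by bin precision was
  considered and rejected: the published models are unweighted, and
  weights would couple the fit to the SNV counts the statistic already
  normalizes away.
- Slope-vs-0 and intercept-vs-1 t-tests share the residual variance of the
  same fit; reported rounding for summary tables is two decimals, half-up.
- Permutation p-values are two-sided (absolute difference) with the
  add-one correction p = (1 + n_exceed)/(n_perm + 1), so p is never 0 and
  never below 1/(n_perm + 1). Exhaustive enumeration (small unions)
  reports the exact proportion including the observed partition.
  Permutation statistics are recomputed from pooled counts of each
  permuted set — matching how Rn, Rs and rdnsv are defined on sets — not
  averaged over per-gene values.
- Expression specificity: log2, per-gene Z-scores across included tissues;
  zero-variance genes are specific nowhere (logged). Ranking ties break by
  total specificity count, then gene id, making selection deterministic.
- All randomness sits behind explicit integer seeds recorded in outputs;
  a seeded simulation reproduces its FASTA/VCF outputs byte for byte.

## Known limitations

Cumulative (rather than disjoint) frequency bins are available behind a
flag but disjoint bins are normative. The method is not a substitute for
divergence-based Ka/Ks machinery: it ignores multiple mutational pathways
between codons and recurrent mutation, which is appropriate for
within-species SNV data but not for species comparisons. Estimates for
small gene sets inherit ratio-estimator noise — bins with few synonymous
SNVs are individually unstable even though the fit remains unbiased, and
the [0.80, 0.95) bin typically holds ~1% of SNVs at default simulation
scale. Non-linear spectrum models and explicit false-positive modeling of
the lowest bin are out of scope.
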