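---
title: "Post-imputation QC of association spikes with the Midrange Filter"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Post-imputation QC of association spikes with the Midrange Filter}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(midrangeqc)
library(dplyr)
```

## The problem

Genotype imputation infers untyped SNPs from a sequenced reference panel and
reports, for every individual and SNP, a posterior probability triplet over
the genotypes 0/1/2. Downstream association tests collapse the triplet into
either the **dosage** (the expected alternative-allele count
$e = p_1 + 2p_2$, which preserves uncertainty) or the **best guess** (the
argmax genotype, which discards it). Imputation error biases the resulting
P-values in both directions, so post-imputation quality control filters SNPs
by an imputation-quality score — most commonly the IMPUTE info score with one
of two established thresholds, 0.3 (permissive) or 0.8 (stringent).

Neither threshold is satisfactory. Association signals are not isolated
SNPs: linkage disequilibrium (LD) spreads a real signal over a **spike** of
low P-values at neighbouring SNPs, and per-SNP thresholding deletes spikes
fully, partially or not at all. In the *midrange* of quality (info between
0.3 and 0.8), true and false associations are thoroughly mixed, and any
single threshold either sacrifices true signals (0.8) or retains false ones
(0.3).

## The Midrange Filter

The filter classifies whole spikes, not SNPs, using three observations:

1. A spike that contains a significant **typed** SNP is anchored by a
   directly observed genotype and is kept outright.
2. Imputation-induced false signals are dominated by SNPs whose imputation
   was driven by allele frequency rather than individual-specific
   information; these score very low. Any spike whose **minimum** member
   quality fails the lower threshold is discarded.
3. Dosage has more power than best guess, because it retains the
   uncertainty. A signal visible **only** in best guess is therefore
   suspicious unless its imputation is high-confidence: a best-guess-specific
   spike whose **maximum** member quality fails the upper threshold is
   discarded.

Everything else is kept. Spikes are built by single-linkage chaining of
*suggestive* SNPs (P \< 5e-7, a deliberately looser net than the 5e-8
genome-wide significance used for discovery) with a strict \< 2 Mb
neighbour gap; both thresholds and the gap follow established GWAS
conventions. Only spikes that contain at least one genome-wide significant
SNP constitute discovered signals and receive a verdict.

Two boundary conventions matter and are fixed throughout: "does not meet a
threshold" is strict (`q < t` fails; a value exactly at the threshold
passes), and the midrange stratum is accordingly `lower <= q < upper`, so
the three per-SNP strata partition the SNPs kept by the lower threshold.

Quality is computed **per cohort group** (cases and controls separately) and
combined per SNP with the minimum by default: a confident joint score can
mask a badly imputed group, and a low score in even one group undermines the
association. `group_combine = "mean"`/`"max"` are available for settings
(e.g. continuous phenotypes) where per-group scores are unavailable or
approximate.

## Quality measures

`quality_table()` computes, per SNP and group: the IMPUTE info score (the
estimated ratio of observed to expected statistical information for the
allele-frequency estimate; monomorphic SNPs score 1 by convention, negative
raw values are clipped to 0 and logged), a MaCH-style dosage-variance ratio
(may exceed 1), a Beagle-style dosage R² (squared correlation between
dosage and best guess; 0 when either is constant), and surrogate Iam/hiQ
accuracy scores. The Iam surrogates are normalized total-variation distances
of the triplets from the uniform triplet (`iam_chance`; low means imputation
close to random) and from the Hardy–Weinberg triplet at the estimated
frequency (`iam_hwe`; low means frequency-driven imputation), with the
ordering `iam_hwe <= iam_chance` enforced and
`iam_combined = iam_hwe - iam_chance + 1`. The hiQ surrogate is the
normalized heterozygosity of the mean triplet. These surrogates reproduce
the documented qualitative behaviour of the original scores but are **not**
numerically comparable to published Iam/hiQ thresholds; they are excluded
from any threshold-based decision by default.

## The synthetic cohort generator

`simulate_cohort()` provides a fully seeded, desk-scale emulation of a
case-control imputation study, so the filter can be exercised end-to-end
with known truth labels:

* **Haplotype pool.** Per-SNP allele frequencies are drawn from a truncated
  Beta(0.8, 0.8); positions have lognormal spacing (sdlog 1.5 around a mean
  of 30 kb by default), giving SNP clusters and deserts as on a real
  chromosome; LD comes from a first-order copying process whose switch
  probability scales with the physical gap (a gap of one mean spacing
  switches with probability `ld_decay`, default 0.1). Distance-scaled
  switching is deliberate: with a constant per-pair probability the
  imputation quality of all SNPs would be nearly identical, whereas real
  studies span low, mid and high quality.
* **Even halves.** The pool is split into a test half (study individuals)
  and a reference base of equal size. Each group's reference panel of
  `panel_size` individuals is resampled with replacement from the shared
  base, emulating separately simulated per-group panels: deep panels
  converge to the same base distribution, shallow panels retain independent
  sampling noise — the regime in which imputation-induced false
  associations arise. `mismatch = TRUE` diverges the test population from
  the reference base by a Balding–Nichols model (Fst 0.05).
* **Disease model.** Case/control status follows a logistic model with
  log-odds-ratio effects at the configured loci (additive, dominant or
  recessive coding; odds ratios 1.5/3 are the intended menu), intercept
  solved for a population prevalence of 0.1, and rejection sampling to the
  group quotas. Disease loci are restricted to minor allele frequencies in
  [0.05, 0.4] so effects are discoverable.
* **Deletion.** Scaffold mode emulates a genotyping array: in each block of
  `1/fraction` SNPs the most common SNP is kept (common-variant-biased,
  quasi-regular). Uniform mode deletes each SNP independently (the 80%
  uniform deletion setting is available). Disease loci get no protection.
* **Surrogate imputation.** For each individual and untyped SNP, reference
  individuals are weighted by `alpha^d` (`alpha` 0.1) where `d` is the
  genotype distance over the `k_window = 5` nearest typed SNPs; the triplet
  is the weight-normalized reference genotype distribution, shrunk towards
  the panel's Hardy–Weinberg distribution by a quarter pseudo-reference of
  weight. The shrinkage makes small-evidence posteriors honestly uncertain:
  with a shallow or mismatched panel the triplet collapses towards
  frequency-driven imputation, which scores low on info — the same coupling
  between failure mode and score that real imputation exhibits. Typed SNPs
  are never altered.
* **Truth.** The complete (pre-deletion) data are association-tested once;
  a SNP is a true signal iff its complete-data P passes 5e-8, and a spike
  is true iff it contains at least one true significant member.

What the generator does **not** emulate: realistic recombination maps,
phasing, haplotype-model imputation (a window-match surrogate stands in for
it), chromosome-specific structure, or rare-variant error modes beyond
frequency-driven collapse. Passing tests on this generator show that the
filter's logic behaves as designed under the intended statistical structure;
they do not certify performance on any particular real dataset.

## Worked example: the packaged cohort application

The packaged table `load_psycourse_top_snps()` contains the 80 top SNPs (P \< 5e-6 in
either format) of a published psychiatric case-control GWAS (1,121 cases,
404 controls, jointly imputed), with the imputation quality as delivered
("initial") and the minimum of the quality recalculated separately per
diagnosis group ("min"). The study has no genome-wide significant SNP, so
the exploratory 5e-6 level serves as the presence and anchor threshold.

```{r psycourse}
res <- filter_psycourse()
res$decisions |>
  select(spike_id, n_members, format_specific, has_typed_significant,
         q_min, q_max, verdict, reason) |>
  arrange(verdict)
```

The filter discards exactly two signals: a singleton on chromosome 6 whose
recalculated per-group minimum quality (0.238) fails the lower threshold,
and a best-guess-specific singleton on chromosome 1 whose quality (0.603)
fails the upper threshold required of best-guess-only signals. The
chromosome 20 spike — two SNPs at recalculated quality 0.518/0.514, which a
plain 0.8 threshold would delete entirely — is preserved because it is
dosage-detectable and meets the lower threshold.

## The shipped benchmark

`benchmark_configs()` defines 20 seeded replicates at desk scale: 800 SNPs
on a ~60 Mb chromosome, 200 cases and 200 controls, two additive loci with
odds ratio 3, a 20% array scaffold, alternating a deep well-matched
per-group panel (2,000 individuals) with a shallow mismatched one (75).
The sizes were chosen by a scaling argument: a spurious association needs a
group dosage shift of about $5.45 \cdot \mathrm{sd}(e) \cdot 2/\sqrt{n}$ to
cross 5e-8, and the benchmark keeps that bar above the between-panel noise
at midrange quality, so imputation-induced significance concentrates at
low-information SNPs, as in full-scale studies. The acceptance suite runs
the benchmark with unrestricted scans (`restrict_initial = FALSE`), the
design used when evaluating filters against a gold standard — under the
practical restricted workflow a purely low-quality false signal would never
be tested in the first place.

One benchmark property is known not to hold fully at this scale: the
between-panel window-conditional sampling noise has a heavy, LD-correlated
tail that occasionally lifts a midrange-quality spike to significance in the
shallow-panel arm. Such spikes are dosage-detectable with acceptable minimum
quality, so the Midrange Filter keeps them by design while the stringent
0.8 per-SNP threshold deletes them; the filter's false-discard count
therefore trails the 0.8 threshold's in the shallow arm. This channel
shrinks with panel depth roughly as $1/\sqrt{P}$ and is negligible at
real panel sizes; at desk scale it can be suppressed only by panels so deep
that false spikes disappear altogether.

## Numerical conventions

* Best-guess ties break towards the lowest genotype; near-ties are snapped
  at 12 decimals first so floating noise cannot flip a argmax.
* Dosage-only VCFs are reconstructed by assigning the dosage mass to the
  two nearest integer genotypes (lossy; the dosage itself round-trips
  exactly). VCF output rounds GP/DS to 4 decimals; `read_vcf()`
  renormalizes triplet sums.
* Spike chaining treats a gap of exactly 2,000,000 bp as a split; spikes
  never span chromosomes; aggregation uses positions only, never P-values.
* Quality extremes of a spike are taken over its suggestive imputed
  members; typed members (which have no meaningful imputation quality)
  contribute the anchor rule instead. The member set follows the suggestive
  threshold because membership itself does.
* Association fits are IRLS (at most 100 iterations, deviance tolerance 1e-12) with
  Wald tests on the SNP coefficient; complete separation (|beta| > 15) and
  non-convergence are flagged and excluded rather than reported as numbers.
  The Wald choice (over likelihood-ratio or score tests) is the common GWAS
  default and is bounded against an independent likelihood-maximization
  oracle in the test suite.
* `false_percent()` rounds half-up to 2 decimals, matching the printed
  style of published confusion tables.
* ROC curves sweep the discard rule `quality < t` over the sorted unique
  scores with infinite endpoints; the trapezoid AUC equals the exhaustive
  pair statistic P(false scores below true) with ties counted half.

## Known limitations

* The simulator's imputation surrogate shares no code with haplotype-model
  imputation software; its quality scores are realistic in distribution and
  failure mode, not in per-SNP value.
* The Iam/hiQ surrogates support relative, not absolute, interpretation.
* Spikes present in both formats are treated as dosage-detectable; whether
  a both-format spike whose best-guess support vanishes after filtering
  should be reclassified is left open, as the underlying method leaves it
  open.
* Only biallelic autosomal-style variants are handled; multi-allelic VCF
  records are skipped, and no special handling exists for the MHC or the
  sex chromosomes, where any automatic filter decision deserves manual
  review.
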