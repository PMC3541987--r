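---
title: "Detecting and comparing acquired uniparental disomy across tumor cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and comparing acquired uniparental disomy across tumor cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aupdscan)
```

## The problem

Acquired uniparental disomy (aUPD, also called copy-neutral loss of
heterozygosity) is a somatic state in which both homologues of a chromosomal
region derive from one parent. It silently homozygoses whatever was already
on the retained haplotype — point mutations, methylation, imprinting — while
leaving total copy number unchanged, so it is invisible to pure copy-number
analysis. On SNP arrays it appears as a stretch of markers with no
heterozygous genotype calls (B-allele frequencies collapsing away from 0.5)
at a log2 intensity ratio near zero.

`aupdscan` implements the full analysis chain for tumor SNP-array cohorts:

1. segmentation of per-chromosome genotype-call sequences into retained vs
   UPD states with a distance-aware two-state hidden Markov model,
2. a copy-neutrality filter on segment mean logR,
3. a breakpoint-based taxonomy of segments (whole-chromosome / telomeric /
   centromeric),
4. cytoband and chromosome-arm recurrence maps per tumor subtype, and
5. rank-based comparisons of per-sample aUPD burden between groups,

together with a seeded synthetic cohort generator that plants
mechanism-labelled events, so the whole chain is testable end to end against
a known truth without any external download.

## The detection model

Each chromosome of a sample is a sequence of genotype calls
$c_1, \dots, c_n$ (categories Het, Hom, NoCall) at positions
$x_1 < \dots < x_n$. The hidden state is binary: RET (heterozygosity
retained) or UPD. Emissions, with $h$ the heterozygous-call rate in RET,
$\varepsilon$ the residual het-call rate inside aUPD (genotyping error), and
$\nu$ the no-call rate:

$$P(\mathrm{Het}\mid \mathrm{RET}) = h(1-\nu),\quad
  P(\mathrm{Het}\mid \mathrm{UPD}) = \varepsilon(1-\nu),\quad
  P(\mathrm{NoCall}\mid \cdot) = \nu,$$

with the Hom probabilities absorbing the remainder. Transitions relax toward
the stationary distribution $\pi = (1-\pi_U, \pi_U)$ with genomic distance
$d$:

$$P(s \to s') = (1-\rho)\,[s = s'] + \rho\,\pi_{s'},\qquad
  \rho = 1 - e^{-d/L}.$$

This gives the identity matrix at $d = 0$ and the prior at large gaps, a
principled behaviour for irregularly spaced array markers. Decoding is exact
Viterbi in log space, with ties broken toward RET: a false aUPD call
pollutes downstream recurrence maps, so calling is deliberately
conservative. The test-suite checks the decoder against exhaustive
enumeration of all $2^n$ paths on sequences of up to 12 markers.

aUPD is *copy-neutral* LOH, so LOH alone is not enough: each candidate
segment's mean logR must fall inside a neutral band. Strongly negative
segments are re-labelled deletion-LOH (hemizygous loss also removes
heterozygosity) and excluded from all aUPD statistics; everything else
outside the band is rejected.

Two calling modes exist because cohorts differ in what they provide. With a
matched normal (`mode = "paired"`), markers are pre-filtered to those
heterozygous in the normal, and the RET het rate becomes
$h_\mathrm{paired} = 1 - \varepsilon_\mathrm{het} \approx 0.98$. Without
one (`mode = "unpaired"`), all markers are decoded at the population
heterozygosity $h \approx 0.30$; long runs of homozygosity by chance are
then the known failure mode, bounded by the marker floor (below) and by the
transition cost, which at default parameters requires roughly 50
consecutive homozygous markers before a UPD call can win.

### Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `het_rate` | 0.30 | prob. | population het-call rate at informative markers |
| `het_rate_paired` | 0.98 | prob. | het rate at normal-het markers (paired) |
| `upd_het_leak` | 0.02 | prob. | residual het calls inside aUPD |
| `no_call_rate` | 0.02 | prob. | NC rate, state-independent |
| `prior_upd` | 0.01 | prob. | stationary UPD probability |
| `decay_length` | 10 | Mb | transition persistence scale |
| `min_markers` | 25 | count | segment marker floor |
| `min_length` | 1 | Mb | segment length floor |
| `neutral_band` | 0.30 | logR | copy-neutral acceptance band |
| `deletion_threshold` | -0.8 | logR | deletion-LOH boundary |

The upstream software used in the original cohort study does not publish
its HMM parameters, so these defaults are this package's own choices; they
were set from the emission/transition model's arithmetic (e.g. the
~50-marker break-even above makes the unpaired false-positive rate per
window below $(1-h)^{50} \approx 10^{-8}$) and are deliberately
conservative. Exact reproduction of the original region catalogue is not a
goal and would not be possible from the publication alone.

## Segment taxonomy

Mechanism, not position, defines the classes: one mitotic recombination
leaves a telomere-bounded segment, two or more leave an interstitial
segment, and chromosome loss plus reduplication makes the entire chromosome
uniparental. The classifier reads these off the called breakpoints:

* reaches both chromosome ends and covers at least `whole_coverage` (0.90)
  of the chromosome → **whole**;
* reaches exactly one end → **telomeric**;
* reaches neither → **centromeric** (interstitial).

"Centromeric" therefore does *not* require overlap with the centromere —
the class is defined by the number of inferred recombination events. A
configuration switch is unnecessary for the counting identities (total =
segmental + whole, segmental = telomeric + centromeric) because they hold
for any assignment, but users auditing the centromere-contact reading can
intersect the segment table with `genome$centromeres` directly.

Array probes never reach the physical telomere, so "reaches an end" means
within `telomere_proximity` (1 Mb) of position 0 or the chromosome length,
or touching the outermost probed marker. On chromosomes shorter than
$2\delta/(1-\theta)$ a segment can reach both ends yet miss the coverage
floor; that degenerate case falls back to telomeric. Acrocentric p-arms
carry no special handling: with the marker-extent fallback, an arm without
markers simply cannot veto end-reach.

## Recurrence maps

A sample hits a cytoband if any of its aUPD segments overlaps the band by
at least 1 bp; each sample counts once per band, and the denominator is the
subtype's *full* sample count, aUPD-negative samples included — this is the
convention behind published percentages of the form "15.2% of the subtype
at band X". Arm-level maps aggregate the same hit indicator over the arm's
bands. Recurrent regions are maximal runs of coordinate-adjacent bands that
each clear a frequency floor and a minimum hit count (default 3, so a
single sample never constitutes "recurrence"); the run's peak band is its
most frequent band, ties resolving toward the telomere. How the original
study delimited its minimal recurrent regions is not stated; the
run-of-qualifying-bands rule is one defensible reading and is implemented
uniformly.

## Group statistics

Per-sample burden is the count of aUPD regions ("frequency of aUPD"); a
group's positive percentage is the fraction of samples with at least one
region. Group location differences use the Kruskal-Wallis rank test with
mid-ranks and tie correction,

$$H = \frac{12}{N(N+1)} \sum_i n_i\left(\bar R_i - \frac{N+1}{2}\right)^2
      \Big/ \left(1 - \frac{\sum_t (t^3 - t)}{N^3 - N}\right),$$

with the chi-square approximation on $k-1$ degrees of freedom even at small
group sizes, matching standard statistical software. When every pooled
value is identical the statistic is defined as 0 with $p = 1$. P-values are
reported raw — the original analysis used an unadjusted two-sided 0.05
threshold — with an opt-in Benjamini-Hochberg flag for users who prefer
multiplicity control. The implementation is checked against
`stats::kruskal.test` to $10^{-10}$ on random instances; the package's own
implementation exists because the statistic is part of the validated
surface, and the base-R routine serves as the independent oracle.

## The synthetic cohort generator

The generator emulates the statistical structure of the SNP-array cohorts
this analysis targets, not any particular array platform:

* uniformly spaced markers (optional jitter), population heterozygosity
  0.30, genotype-call error 0.01, no-call rate 0.02;
* copy-neutral logR $\sim N(0, 0.15)$, BAF at the genotype mean (0, 0.5, 1)
  with sd 0.04, attenuated toward 0.5 at LOH markers when purity < 1;
* events planted by mechanism — whole (full chromosome), telomeric (one
  uniform breakpoint, random end), interstitial (two ordered uniform
  breakpoints, span at least 3 Mb) — at mix (0.13, 0.26, 0.61), the
  whole : telomeric : centromeric proportion of the published 724-region
  catalogue (94 : 189 : 441);
* nine default subtype specifications with the published sample sizes
  (295 classified samples) and published aUPD prevalences (0.73
  myxofibrosarcoma ... 0 synovial sarcoma);
* per-positive-sample event counts from a zero-truncated Poisson. The
  publication gives only the overall burden (724 regions over 315 samples,
  mean 2.3, median 0, range 0–37); the median of 0 motivates modelling
  zero-inflation through the prevalence parameter and the positive tail
  through the truncated Poisson. Per-subtype means are not published;
  defaults place mean 5.5 on the karyotypically complex
  (non-translocation) subtypes and 3.0 on the fusion-driven ones, which
  reproduces the overall total (expected ≈ 678 regions for the 295
  classified samples) and the reported direction of the group difference.

Two generator conventions keep planted mechanism labels *identifiable*, so
that recovery tests are well-posed: breakpoints stay `breakpoint_margin`
(2 Mb) clear of chromosome ends (a nominally interstitial event abutting
the telomere would be indistinguishable from — and biologically equivalent
to — a telomeric one), and events on one chromosome keep at least that
margin of separation (closer pairs would decode as a single segment). On
the 4-chromosome toy genome a very large event draw may not fit; the
generator re-draws the placement and, as a last resort, trims the count —
at human scale (22 autosomes) this is immaterial.

What the generator does **not** model: platform probe effects and GC waves,
subclonality, chromothripsis, genotype-call reversion under impurity
(contamination enters only through BAF attenuation, because genotype
callers behave idiosyncratically on mixed samples). Passing recovery tests
therefore demonstrates correctness of the segmentation and accounting
machinery under a clean noise model, not performance on degraded clinical
arrays.

## Numerical and design choices

* Coordinates are 0-based half-open internally; marker files are 1-based
  and convert at the I/O boundary. Segment output is BED-compatible.
* Decoding is per-chromosome and contiguous across the centromere; segments
  are not split at the centromere gap (centromere-spanning aUPD is a real
  observation that the taxonomy handles through the centromeric class).
* Viterbi ties prefer RET; the final state on a tie is RET as well.
* Floating-point values are written at 9-decimal precision, which makes
  write → read → write byte-stable; rerunning a stage reproduces its
  artifacts exactly, and staged and combined pipeline runs are
  byte-identical.
* Sex chromosomes are excluded by default: without sex-matched references,
  hemizygous X would masquerade as LOH.
* Percentages are stored full-precision and rounded only for presentation.

## Problem sizes used by the tests and the acceptance script

The recovery benchmark uses the 4-chromosome toy genome (290 Mb), 40
samples in two subtype groups, 5 000 markers per chromosome and default
noise; the noise-free replicate must reach 100% recovery, 100% precision
and 100% mechanism-to-class agreement. The cohort-scale statistical
replication runs 100 burden-level replicates of the 295-sample design on
the 22-autosome synthetic genome. The acceptance script renders and calls
the full 295-sample cohort at 2 500 markers per chromosome (≈ 55 000
markers per sample), a density at which the smallest plantable event
(3 Mb) still spans ≥ 25 markers on the largest chromosome.

Paired-mode breakpoint accuracy is within five informative-marker spacings
for ≥ 90% of recovered events. Unpaired mode cannot meet that bound in
principle: the called boundary extends through the run of by-chance
homozygous germline markers beyond the true breakpoint, a geometric
overshoot with success probability $h$ per marker, so
$P(\text{overshoot} \le 5) \approx 1 - (1-h)^6 \approx 0.88$ per boundary
at $h = 0.30$. This is an information limit of genotype-call data, not an
implementation artifact; BAF-aware emissions would be the way past it and
are future work.

## Known limitations

* Viterbi only — no forward-backward posteriors or confidence tracts.
* No subclonal fraction estimation; low-purity samples lose sensitivity
  before the genotype calls reflect it.
* Recurrence significance is raw frequency, not permutation-calibrated.
* The liposarcoma pairwise contrasts reported in the source cohort study
  cannot be verified numerically (per-sample counts were not published);
  only their machinery (two-group rank tests on subgroup pairs) is tested.
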