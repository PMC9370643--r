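---
title: "Methods: count-based DET calling for BNF-contrasting genotypes"
author: "canedet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: count-based DET calling for BNF-contrasting genotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canedet)
```

## Scope and design

`canedet` implements the count-based differential-expression recipe used to
contrast two sugarcane genotypes of high and low biological-nitrogen-fixation
(BNF) efficiency across a 16-library design: 2 genotypes × 2 tissues (root,
shoot) × 2 growth conditions (germinated stalks naturally colonized by
diazotrophic bacteria; bacteria-free hydroponics) × 2 biological replicates.
The package consumes transcript-level read counts (alignment and assembly are
upstream, out of scope) and produces, per tissue/condition cell, a DET table
for the genotype contrast, genotype-exclusivity calls, set-algebra summaries
across cells, term-enrichment tables, and the two accompanying validation
quantifications (ΔCt qPCR ratios, MPN bacterial loads).

## The DET model and its assumptions

For a transcript with pooled counts $c_a, c_b$ and pooled library totals
$T_a, T_b$, the test conditions on all margins of the table
$[c_a, T_a - c_a; c_b, T_b - c_b]$, under which $c_a$ is hypergeometric. The
two-sided p-value sums the probabilities of all tables at most as probable as
the observed one; the comparison uses a relative tolerance of $10^{-7}$ so
that mathematically tied tables are not split by floating-point noise. This
is exact *if reads are acquired by independent counting* (binomial/Poisson
sampling of a fixed transcript proportion). It does **not** model biological
variability between replicates: pooling replicates and testing counts treats
two plants as one doubly-deep library.

The consequence is quantified by the package's own null simulations (run by
`scripts/acceptance.R` and the acceptance tests): with Poisson noise the
Bonferroni-corrected procedure keeps the family-wise error rate at or below
the nominal 5%, while with negative-binomial noise at dispersion
$\varphi = 0.1$ and study-scale depth ($10^6$ reads/library) essentially
every null run produces at least one false DET. We report this honestly
rather than patching the statistic: the procedure *is* the pooled exact
test, and its anti-conservativeness under overdispersion is a known property
of this class of methods. Two mitigations are built in:

* `min_abs_log2fc` — require a minimal effect size in addition to
  significance (default 0, i.e. off, matching the original recipe);
* `replicate_mode = "PER_PAIR_CONSENSUS"` — test every replicate pair across
  the groups separately and call only transcripts significant with one
  direction in all pairs, an emulation of "testing every library
  combination" that is robust to a single discordant replicate.

Direction (`UP_A` = up in the high-BNF genotype) always follows the larger
RPKM. Fold changes are reported as $\log_2(\mathrm{RPKM}_a /
\mathrm{RPKM}_b)$ with a pseudocount (default 0.25 RPKM, roughly the
smallest nonzero RPKM at the canonical depth) applied only for reporting;
calls never depend on the pseudocount, and transcripts absent from one
genotype are routed to the exclusivity rule instead.

RPKM itself is $c \cdot 10^9 / (T \cdot L)$ with $L$ the transcript length in
bp. Library totals default to column sums of the count matrix — the only
self-contained choice, since whether denominators should be sequenced or
mapped reads is ambiguous in this kind of pipeline description — and can be
overridden by a side file.

### Multiple testing

The Bonferroni denominator $m$ is the number of transcripts actually tested
*within one comparison* (nonzero pooled count in at least one group), not
across comparisons; `adjust_bonferroni(p, m)` accepts a larger global $m$
when a family-wide correction across the four cells is wanted. Bonferroni
was kept (rather than BH) because the method controls the family-wise error
rate by construction; BH is offered only in the enrichment module.

### Exclusivity

A transcript is exclusive to a genotype when it has $\ge 1$ read in at least
`min_positive_libraries` (default 5) of that genotype's 8 libraries and zero
reads in all libraries of the other genotype, symmetrically. Exclusive
transcripts are reported independently of the DET calls and flagged in DET
records, because whether exclusives form a subset of the DET list is not
defined by the recipe; the package does not conflate the two.

## Set algebra

Venn partitioning assigns each transcript of the union to the unique region
matching its membership signature; by default membership is by transcript id
(a transcript called in opposite directions in two cells still counts once),
with `ignore_direction = FALSE` splitting by (id, direction). Partitions are
capped at 6 sets (64 regions). The stalk ∩ hydroponics "common pattern"
intersection keeps transcripts present in both cells *with the same
direction*; its report total is always the disjoint root + shoot sum.
Percentages (e.g. loci mapped per species) use half-up rounding; note that
published tables occasionally truncate instead, which is why one species row
of the worked-example table cannot be matched by any rounding rule and is
excluded from exact checks.

## Enrichment

For each term with $K \ge 1$ annotated background transcripts,
$p = P(X \ge k)$, $X \sim \mathrm{Hyper}(N, K, n)$. The background defaults
to all annotated transcripts of the count matrix — the most conservative
self-contained choice when the original tool's background is unspecified.
The Rich Factor is $k/K$ (per-category denominators): the figure-legend
definition "foreground transcripts in the category divided by background
transcripts" reads most naturally per category, and $k/K$ is the convention
of the enrichment-dot-plot tools this emulates. Raw $p < 0.05$ is the
default significance rule, matching the emulated analysis; BH is available.

## qPCR quantification

Relative expression is $E^{-\Delta C_t}$ with
$\Delta C_t = C_t^{target} - \tfrac12(C_t^{28S} + C_t^{GAPDH})$ and $E = 2$
by default. Averaging the two reference $C_t$ values arithmetically equals
normalizing by the geometric mean of the two reference quantities, the
standard dual-reference convention. Sample ratios propagate replicate
standard deviations by the delta method and are reported with their
$\log_2$, so they compare directly with DET fold changes via
`concordance()` (sign agreement; exact zeros match nothing). Amplification
efficiencies are parameters, not estimated: standard curves are out of
scope.

## MPN estimation

Tube outcomes follow the single-hit model: a tube receiving $v_i$ mL of
undiluted homogenate is positive with probability $1 - e^{-c v_i}$. The
likelihood is maximized by bisection on the score function (strictly
decreasing in $c$), bracketing $[10^{-6}, 10^{15}]$ organisms/mL; 100
halvings on the $\log_{10}$ scale leave the relative error far below the
$10^{-9}$ target, verified against the single-dilution closed form
$c = -\ln(1 - p/n)/v$ and a $10^5$-point likelihood-grid scan. All-negative
series return 0 (`ALL_NEGATIVE`); all-positive series return the upper
bracket as a lower bound (`ALL_POSITIVE`). The Wald interval uses the
observed information on the $\ln c$ scale, evaluated in log space so that
saturated dilutions underflow to zero influence instead of overflowing.

Assay geometry defaults: ten-fold dilutions, 100 µL inocula
(`inoculum_volume = 0.1` mL), homogenate factor 10 mL/g (1 g tissue in 9 mL
saline, volumes treated as additive), and 3 tubes per dilution. The
emulated protocol inoculated a single semi-solid tube per dilution — 1 is
accepted — but 3 is the smallest standard MPN design and gives simulations
a finite-variance estimator, so it is the default. MPN look-up tables are
deliberately not emulated; the ML estimator subsumes them.

## The simulator: what it emulates, what it does not

`simulate_experiment()` draws counts
$X_{tl} \sim \mathrm{NB}(\mu_{tl}, \varphi)$ with variance
$\mu + \varphi\mu^2$ ($\varphi = 0.1$ by default, the usual bulk RNA-seq
magnitude; $\varphi = 0$ gives Poisson). Per-transcript baseline abundances
are log-normal ($\log_2$ sd 2, several orders of magnitude of dynamic
range), normalized so expected column sums equal the configured depth
(default $10^6$ reads/library, a scaled-down stand-in for the study's 2–14
million). Differential transcripts (default 10%, split evenly between
directions) have the up-genotype mean multiplied by $2^{|log2FC|}$ (default
$|log2FC| = 2$) in all 8 libraries of that genotype; exclusive transcripts
(default 2%) have structural zeros in one genotype and are guaranteed
$\ge 1$ read in at least 5 libraries of the other, so the planted truth
satisfies the exclusivity rule by construction. One master seed derives
fixed substreams per component (lengths, baselines, truth assignment,
counts), making every generator a pure function of (config, seed).

What the simulator does *not* emulate: read-level artifacts (mapping bias,
multi-mapping across the polyploid genome's homeologs), isoform structure,
library-preparation batch effects, tissue-specific (rather than
genotype-global) effects, and correlated annotation structure. Passing
recovery tests therefore demonstrates correctness of the implementation
under the stated noise model, not robustness of the Fisher recipe to
everything real sugarcane data contains.

## Numerical choices

* Fisher p-values: excluded tables form a contiguous interval around the
  hypergeometric mode (unimodality), located by vectorized binary search on
  the log-pmf — $O(\log \mathrm{support})$ per table — then summed with
  `phyper`. Agreement with full enumeration is $< 10^{-12}$ for all tables
  with totals $\le 25$ and with `stats::fisher.test` (the independent
  reference) to $10^{-9}$ on random tables.
* Tie tolerance $10^{-7}$ (relative) on the "at most as probable"
  comparison, the same guard used by standard implementations.
* Half-up rounding for percentages implements a one-ulp nudge before
  `floor(x + 0.5)` to keep exactly-representable halves stable.
* N50: descending sort, first length where the cumulative sum reaches half
  the total (the dominant community convention); permutation-invariant.
* BLAST best-hit rule: smallest e-value, then larger bit score, then input
  order; output ordered by query so the filter is idempotent. Whether
  "mapped proteins" summaries should count best hits only or any hit is not
  decidable from the emulated description, so both modes are exposed
  (`best_hit_only`).

## Problem sizes in the shipped checks

The test suite and `scripts/acceptance.R` use 500-transcript matrices at
$10^6$ reads/library for recovery and null calibration (400–1000 null runs),
the full $\le 25$-totals table grid ($\approx 1.2 \times 10^5$ tables) for
Fisher exactness, all hypergeometric configurations with $N \le 40$ for
enrichment exactness, 200 seeded replicates for planted-term ranking, and
500 seeded dilution series per tube design for MPN consistency. These sizes
were chosen so the whole suite runs in minutes on one CPU while leaving the
binomial error bands of the calibration checks tight enough to be
informative.

## Known limitations

* The pooled Fisher + Bonferroni procedure is anti-conservative under
  biological overdispersion (see above); DET counts on real replicated data
  should be read as descriptive, and the consensus mode or a
  dispersion-modelling method should back any inferential claim.
* Bonferroni within-comparison leaves the across-comparison family
  uncorrected by default.
* Enrichment treats terms independently: no GO-DAG propagation, term
  ancestry, or pathway topology.
* The MPN confidence interval is a Wald approximation on $\log_{10} c$; for
  extreme patterns (single positive tube) it is wide and asymmetric in
  coverage.
* ΔCt assumes the configured amplification efficiency; the two-sample
  ratio design does not cover calibrator-based ΔΔCt layouts.
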