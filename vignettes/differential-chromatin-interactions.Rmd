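---
title: "Differential chromatin interaction profiles and regulator inference: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential chromatin interaction profiles and regulator inference: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hicdci)
```

This vignette documents the statistical model behind `hicdci`, the choices
made where the design was genuinely open, and what the bundled synthetic
data can and cannot tell you about behavior on real Hi-C.

## The model

### Distance-decay normalization

Intra-chromosomal Hi-C contact frequency falls roughly as a power law of
genomic distance, and the decay curve differs between libraries. Before any
comparison, each chromosome's raw counts are normalized *within sample*:

$$ n_{ij} = \frac{c_{ij}}{\bar c_{|i-j|}}, \qquad
   \bar c_d = \frac{1}{N-d}\sum_{|k-l|=d} c_{kl}, $$

where $N$ is the number of bins on the chromosome. Two points matter.
First, zero pixels are observations: they stay in the denominator count
$N-d$, so sparse regions are not inflated. Second, the transform is
scale-free per chromosome — multiplying a library's counts by any constant
leaves $n_{ij}$ unchanged — so replicates of different sequencing depth
need no pre-scaling. This normalization removes only the distance effect;
it is not a substitute for bias correction (GC, mappability, enzyme
cleavage), which should be handled upstream if desired, on copies of the
data — the method itself consumes *raw* counts.

### Contact score arrays and the per-bin test

For bin $i$, the contact score array is the vector of $n_{i,i+\delta}$ for
signed distances $\delta \in \{-D_b,\dots,-1,+1,\dots,+D_b\}$, truncated at
chromosome ends, with $D_b = D/b$ for distance bound $D$ (default
200 kb) and bin size $b$ (typically 5 kb, giving 80 flanking values).
The self-interaction $\delta = 0$ is excluded by default: the diagonal is
dominated by self-ligation and coverage rather than interaction with
flanking regions (`include_diagonal = TRUE` restores it).

Given $m$ control and $n$ treatment replicates, each of the $m \times n$
(control, treatment) array pairs is compared by a paired t-test on the
per-position differences (treatment minus control, $L - 1$ df, two-sided).
The $mn$ p-values are combined by Fisher's method,
$\chi^2 = -2\sum \ln p_k$ on $2mn$ df, and the score is
$S_i = \mathrm{sign}\!\left(\sum_k t_k\right)\cdot(-\log_{10} p)$.
The sign rule agrees with the majority of the individual t statistics
whenever a majority exists and breaks ties by magnitude; an exactly zero
sum gives sign 0 and $S = 0$.

The cross-pair scheme deliberately tests all $m \times n$ pairs even though
pairs share replicates, so for $m, n > 1$ the combined p-values are
anticonservative — they are scores for ranking, not calibrated error rates.
The null-calibration test therefore checks uniformity at $m = n = 1$, where
the tests are independent.

### Assumptions

The paired t-test treats the per-position differences of normalized values
as exchangeable draws with a common mean. They are neither Gaussian nor
homoscedastic (variance grows with distance as counts shrink), but at
$L \approx 80$ positions the statistic is close to its nominal null
distribution — the suite verifies a Kolmogorov–Smirnov distance below 0.1
from uniformity over 2 020 null bins, and observes about 0.03. The method
assumes differential signal acts *in cis* within $\pm D$; interchromosomal
pixels are dropped on read, and genome rearrangements (which move signal
without any regulator acting) are out of scope.

### CRE projection and TR ranking

Each catalog element takes the score of the bin containing its midpoint.
Elements are small (~0.1–1 kb) relative to bins (≥ 5 kb), so midpoint
assignment is unambiguous; the rare boundary-spanning element follows its
midpoint. Elements in no-data bins are *excluded*, not zero-filled — zero
means "no change", absence of data must not imitate it.

Each compendium dataset gets the Mann–Whitney AUROC of its bound elements
against the score-ranked element list (midranks for ties; ranking
tie-break by element ordinal for determinism). Per TR, three statistics
are computed: a one-sided Wilcoxon of the TR's AUCs versus all other
datasets' AUCs, a z-score $(\bar A_{TR} - \bar A)/s_A$, and the maximum
AUC. Each is turned into a rank quantile $r = \mathrm{rank}/N_{TR}$ (ties
share the mean rank), and $s = r_w + r_z + r_m$ is referred to the lower
tail of the Irwin–Hall distribution with $k = 3$ via the closed form

$$ P(s) = \frac{1}{k!} \sum_{j=0}^{\lfloor s \rfloor} (-1)^j
          \binom{k}{j} (s-j)^k . $$

The choice of exactly these three statistics and $k = 3$ is inherited
design from the established regulator-ranking scheme this stage follows;
it is isolated behind `rank_trs()` so the statistic set can be changed in
one place. The decrease-direction list is computed by negating the CRE
profile and re-ranking — the two directions are exact mirror images, which
the suite checks byte-for-byte.

## Tunable parameters

| parameter | default | units | notes |
|---|---|---|---|
| `bin_size` | from data | bp | must match the contact maps; not resampled |
| `D` (`genomic_distance`) | 200 000 | bp | flanking window; must be a multiple of `bin_size`; larger D trades locality for power |
| `include_diagonal` | `FALSE` | — | self-interaction in the score array |
| `coverage_adjust` | `FALSE` | — | residualize S on the log2 coverage ratio |

There are deliberately few knobs. The coverage covariate is
$x_i = \log_2\frac{\overline{cov}^{T}_i + 1}{\overline{cov}^{C}_i + 1}$
(within-band row sums, mean over replicates, +1 pseudocount), fitted by
ordinary least squares over scored bins; a constant covariate returns the
profile unchanged with a warning. No formula for this covariate is fixed
by the method's description beyond "account for coverage changes", so the
simplest stable choice is used and kept behind one function. Note that when
a genuine gain of interactions raises within-band coverage, the adjustment
absorbs part of that signal too — it is an option, not a default.

## Numerical choices

* **p-floor**: p-values are clamped at $10^{-300}$ before any logarithm,
  keeping every score finite.
* **Zero-variance differences**: identical arrays give $(t, p) = (0, 1)$; a
  nonzero constant shift gives $t = \pm\infty$ with the p-floor. For the
  sign sum, infinite t values enter as $\pm 10^6$ surrogates.
* **Canonical summation**: per-bin Fisher and sign sums are accumulated in
  a sorted order, so swapping the two conditions negates every score and
  reproduces every p bit-for-bit (the suite asserts `identical()`).
* **Degenerate strata**: distances with zero mean count normalize to 0;
  all-zero matrices normalize without division errors; bins whose arrays
  are all-zero in every replicate of both conditions are flagged `no_data`
  with $S = 0$ and excluded from regression, rank-sum tests and CRE
  scoring.
* **Wilcoxon p-values**: the TR-vs-rest test uses the exact rank-sum
  distribution for small tie-free samples and the tie/continuity-corrected
  normal approximation otherwise (the standard `wilcox.test` switch). The
  suite verifies exact agreement with complete enumeration at group sizes
  ≤ 4 and closeness under ties.
* **Determinism**: all ranking tie-breaks are fixed (element ordinal in the
  CRE list, TR name in the final table), so identical inputs give
  byte-identical output tables.

## The synthetic generator

`sim_config()` describes a genome of `n_chroms` × `bins_per_chrom` bins in
which counts are drawn as
$c_{ij} \sim \mathrm{Poisson}\!\left(\lambda_0 (d+1)^{-\alpha} f_{ij}\right)$
with $f_{ij}$ equal to a block's fold change when both partners lie inside
the block (treatment only) and 1 otherwise. A toy CRE catalog (200 bp
elements, uniform placement) and a toy compendium are drawn from the same
configuration: the causal TR binds in-block elements at
`bound_fraction * enrichment` (capped at 1) and all decoys uniformly at
`bound_fraction`.

Defaults are the conditions under which the end-to-end recovery property is
stated and tested: 2 chromosomes × 400 bins at 5 kb, $\alpha = 1$ (a
typical Hi-C decay slope), $\lambda_0 = 100$ expected counts on the
diagonal (a realistic local depth for 5-kb maps), 2 replicates per
condition, one 30-bin (150 kb) block per chromosome at fold change 3 —
within the ±200 kb tested band — 50 TRs × 2 datasets, 5% background
binding and 10× causal enrichment. A `dispersion` knob switches the noise
to negative binomial for overdispersion robustness checks.

What the generator does *not* emulate: TADs and compartments (block gains
are flat, not nested), loop anchors, GC/mappability bias, ligation
artifacts, or copy-number structure. Passing tests therefore demonstrate
the statistical machinery — normalization identities, test calibration,
ranking behavior, ground-truth recovery under the stated noise model — not
robustness to every bias of real Hi-C libraries.

Problem sizes in the test-suite and acceptance script were chosen to keep a
full run in the low minutes on one core: 800 scored bins per end-to-end
replicate experiment, 2 020 bins for null calibration, 20 seeds for the
recovery and background-control properties, $10^6$ draws for the
Irwin–Hall Monte-Carlo cross-check.

## Replicate-noise background

Comparing two replicates of the *same* condition yields a profile of pure
technical variation. TRs that rank highly against such a profile are false
positives of the pipeline, and the same logic applies to real data: a
regulator inferred from a within-condition comparison should be discounted
if it also appears in the cross-condition list. The suite checks that the
causal TR of the simulation is *not* recovered from replicate noise (outside
the top decile in at least 18 of 20 seeds).

## Known limitations

* The dependence among cross-pair t-tests makes multi-replicate p-values
  anticonservative; treat scores as a ranking, not as error-controlled
  significance calls.
* The method aggregates a bin's interactions over its whole ±D window; it
  will not detect a regulator acting through one or a handful of individual
  loops.
* Distance normalization removes only distance decay; systematic biases
  shared across distance strata pass through.
* The Juicer `.hic` reader supports format versions 7–8 (BP resolutions,
  raw observed counts). Files were validated by round-trip against the
  package's own writer; normalization vectors and fragment resolutions in
  third-party files are ignored.
* When a contact gain is also a coverage gain (as in the bundled
  simulation), the optional coverage regression removes part of the real
  signal along with the confounder.
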