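---
title: "Methods: de novo CNV detection in case-parent trios via the minimum distance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: de novo CNV detection in case-parent trios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdcnv)
```

## The problem

In a case-parent trio genotyped on a SNP array, a *de novo* copy number
variant (CNV) is a copy number in the offspring that cannot be reached by
Mendelian transmission from the parental copy numbers — for example a
hemizygous deletion in the child of two diploid parents. Marker-level
summaries of relative copy number (log R ratios, LRR) and allelic balance
(B allele frequencies, BAF) carry substantial technical structure: probe
effects, batch differences in noise, and *genomic waves* — slowly varying,
GC-correlated drifts of the LRR. Waves are particularly damaging in trio
analyses because a trough that spans a run of homozygous genotypes mimics a
deletion, and whether it is called de novo or inherited depends only on
which family members happen to be homozygous there.

## The minimum distance

For marker $i$, let $r_{i,F}, r_{i,M}, r_{i,O}$ be the father, mother and
offspring LRR. With paternal and maternal distances
$\delta_{F,i} = r_{i,O} - r_{i,F}$ and $\delta_{M,i} = r_{i,O} - r_{i,M}$,
the minimum distance is

$$d_i = \arg\min_{\delta \in \{\delta_{F,i}, \delta_{M,i}\}} |\delta|,$$

the signed parental difference of smaller magnitude (`minimum_distance()`).
Any additive artifact shared by the offspring and at least one parent —
waves, batch shifts, probe effects — cancels in $d$, while a copy number
present in the offspring and absent from both parents shifts $d$ away from
zero. The statistic is relative: transmitted CNVs (shared by a parent) leave
$d$ near zero, and regions where *both* parents are deleted but the
offspring is diploid produce positive $d$; absolute copy-number
classification is therefore deferred to the posterior step below. Ties
$|\delta_F| = |\delta_M|$ are resolved toward the paternal distance; any
fixed rule gives the same $|d|$.

## Segmentation

The univariate $d$ is segmented per chromosome arm by circular binary
segmentation (CBS), implemented natively in compiled code. For an interval
of $n$ values the circular two-sample statistic of the arc (window) of
length $L$ starting after position $a$ is

$$T = \frac{\bar d_{\text{arc}} - \bar d_{\text{rest}}}
{\hat\sigma\sqrt{1/L + 1/(n-L)}},$$

with $\hat\sigma$ the sample standard deviation of the whole interval. Using
the interval-level $\hat\sigma$ (rather than a pooled within-arc estimate)
makes the statistic permutation-invariant in scale, so the permutation null
depends on the data only through the multiset of values. The maximizing arc
over all positions and lengths is accepted as a changepoint pair when its
permutation p-value falls below `alpha` (default 0.01, `n_perm` default
10,000), and the procedure recurses on the resulting sub-intervals.

Two implementation points matter for reproducibility and speed:

* **Exactness of the permutation decision.** The test curtails sampling once
  the exceedance count reaches `ceiling(alpha * n_perm)` (the final p-value
  estimate could then no longer fall below `alpha`), and skips window
  lengths whose upper bounds — the sum of the $L$ largest centered absolute
  values (permutation-invariant) and the range of the permuted centered
  cumulative sum (per permutation) — cannot reach the observed maximum.
  Both devices change the cost, never the accept/reject decision of the
  full `n_perm` test.
* **Seeding.** Each tested interval derives its permutation seed
  deterministically from `seg_params(seed)` and the interval's position and
  length, so results are identical across runs and independent of the order
  in which arms or trios are processed.

Large gaps in array coverage (centromeres, assay deserts) are handled before
segmentation: a new region opens at any inter-marker gap above 75,000 bp,
except that a region holding fewer than 1,000 markers is not closed — the
gap is ignored (`split_by_gaps()`). Without a centromere table, whole
chromosomes are treated as single arms; supplying one splits them into p/q.

After segmentation, breakpoints are pruned (`prune_segments()`): adjacent
segments are merged while the standardized mean difference
$z = |\bar d_i - \bar d_j| / (\hat\sigma_d\sqrt{1/n_i + 1/n_j})$ of the
closest pair falls below `prune_z` (default 3), with $\hat\sigma_d$ the MAD
of the arm's minimum distance, which is robust to the CNV segments
themselves. Segments with fewer than `min_seg_markers` markers are then
absorbed into the neighbor with the nearer mean. The published description
of this post-processing names its ingredients (coverage and the
standardized difference in segment means) without an exact formula; the
$z$-merge rule is this package's concrete instantiation and the threshold is
configurable.

## Trio states and Mendelian transmission

Copy numbers 0–4 are coded by the PennCNV-style symbols 1, 2, 3, 5, 6. Of
the $5^3 = 125$ father–mother–offspring triplets, the 4 in which both
parents are homozygous null while the offspring carries one or more copies
are biologically impossible and excluded, leaving the 121-state space $S$
(`enumerate_states()`).

Mendelian transmission is modeled at the copy-number level: a parent with
copy number $c$ carries $\lceil c/2\rceil$ and $\lfloor c/2\rfloor$ copies
on its two homologs and transmits either with probability 1/2; the offspring
copy number is the sum of the transmitted copies, capped at 4 (gains beyond
two copies pool into the top state). This homolog-enumeration model
(`mendelian_prob()`) reproduces the conventional published transmission
table; because the original tabled values are part of a supplement rather
than the main text, the table is exposed (`mendelian_table()`) and
replaceable throughout. The offspring conditional integrates a latent
Mendelian indicator:

$$P(s_O \mid s_F, s_M) = p_m\,P_{\text{Mendel}}(s_O \mid s_F, s_M)
  + (1 - p_m)\,\tfrac15,$$

with $p_m = 1 - 1.5\times10^{-6}$ by default and a uniform non-Mendelian
marginal. A state is flagged de novo exactly when its Mendelian probability
is zero (`is_de_novo()`).

## Emission models and Baum–Welch estimation

Sample $k$'s LRR in copy-number state $s$ follows a robust mixture
(`lrr_density()`):

$$r \sim (1-\varepsilon_{r,k})\,N(\mu_{r,k,s}, \sigma_{r,k,s})
  + \varepsilon_{r,k}\,U(l_r, u_r),$$

the uniform component absorbing outliers independent of copy number.
Default means for copy numbers 0–4 are $(-2, -0.5, 0, 0.4, 0.68)$ on the
Illumina scale — the hemizygous-deletion mean of $-0.5$ matches what is
observed empirically on these arrays — with $\sigma = 0.2$,
$\varepsilon = 0.01$ and support $(l_r, u_r) = (-5, 3)$ covering the range
of thresholded LRR.

BAF for positive copy numbers follows a genotype-cluster mixture of
normals truncated to $[0,1]$ plus a uniform outlier component
(`baf_density()`); the homozygous-null state emits uniform $[0,1]$ values.
For copy number $c$ the clusters sit at B-allele fractions $g/c$,
$g = 0,\dots,c$, with binomial priors driven by the population A-allele
frequency (0.5 unless a frequency file is supplied — frequencies are
array-specific and not shipped). Clusters are keyed by their reduced
fraction so that, e.g., the heterozygous diploid cluster and the balanced
two-copy-gain cluster share parameters. Default cluster sds are 0.03
(homozygous) and 0.05 (otherwise); BAF values thresholded to exactly 0 or 1
by upstream software are absorbed by the truncated-normal mass near the
boundary plus the outlier term, without point masses.

Parameters are estimated per sample by Baum–Welch (`fit_emission_params()`)
on a marker-level five-state chain (transition 1/2 to the same state, 1/8
otherwise; uniform start). This chain exists solely to supply
responsibilities for parameter estimation — segment classification never
uses marker-level decoding. The M-step uses responsibility-weighted moments;
for the truncated normals the weighted moments are converted to location
and scale by truncated-moment matching (the exact M-step, since a truncated
normal with fixed support is an exponential family), which keeps the EM
ascent property that naive moments would break for the boundary clusters at
0 and 1. Updates are projected onto a constraint set — means within 0.3 of
their initial values and nondecreasing in copy number, sds in
$[0.05, 1.0]$, outlier probabilities in $[0, 0.1]$ — which stabilizes the
fit on arms dominated by a single state; the published constraint list
lives in an unavailable supplement, so the projection above is this
package's own. Arms with fewer than 500 markers keep the initial values.

## Sequential MAP classification

For segment $l$ with previous MAP state $\hat s_{l-1}$, the unnormalized
log-posterior of trio state $s$ sums (i) the segment log-likelihood — LRR
and BAF log densities over the three samples and the segment's markers,
conditionally independent given the states, (ii) the offspring conditional
above, and (iii) per parent, the log initial probability (1/5; first
segment) or the log transition probability (1/2 same state, 1/8 otherwise)
from $\hat s_{l-1}$. Normalization is by log-sum-exp over the 121 states
(`posterior_table()`), and segments are classified left to right, each
conditioning on the previous MAP state (`call_trio()`). Conditioning on the
MAP point rather than the full previous posterior follows the sequential
scheme the method describes; terms involving only segment $l-1$ are
constants in the argmax and drop. Ties prefer the all-diploid state 333
(conservative against false de novo calls), then the lexicographically
smallest code. De novo calls are ranked by the posterior odds of the MAP
state against 333, reported as log10 odds to avoid overflow
(`rank_calls()`).

## The simulator

`simulate_trio_chromosome()` emulates the study conditions used to
characterize the method: chromosomes of 25,000 markers (1 kb spacing)
containing four de novo and four paternally transmitted hemizygous
deletions of 10, 25, 50 and 100 markers, plus three runs of offspring
homozygosity (50, 100, 500 markers, diploid copy number) spanned by the
trough of a genomic wave shared by all three samples (half-cosine,
0 → −0.2 → 0). Trio LRR are drawn from a trivariate normal with common
correlation $\rho \in \{0, 0.2, 0.5\}$ and sd
$\sigma_r \in \{0.15, 0.20, 0.25, 0.30\}$; deletions shift the affected
means to −0.5. BAFs are Mendelian-consistent: parental genotypes are drawn
at allele frequency 0.5, the offspring inherits one allele per parent,
deletions retain the appropriate single allele (producing homozygous-only
BAF inside), and homozygosity runs force the offspring homozygous with both
parents carrying the shared allele. Observed BAFs add truncated-normal
noise (sd 0.03) around the cluster means. The full design is 25 chromosomes
per $(\rho, \sigma_r)$ cell (`simulate_study()`).

Unstated details — exact feature positions, BAF noise scale, marker
spacing, the parent of origin of transmitted deletions — are fixed here as
evenly spaced features with ≥200-marker diploid buffers, sd 0.03, 1 kb and
paternal, respectively, and are configurable. The simulator does not emulate
GC-driven wave structure along real genomes, probe-specific effects,
genotyping error, or sex chromosomes; passing the simulation-based checks
therefore demonstrates the statistical behavior of the method under its
stated noise model, not freedom from artifacts on any particular array
product.

## Evaluation

Against a simulated truth track, `marker_fp_fn()` counts false positives
(markers in truly non-de-novo regions called de novo) and false negatives
(markers in true de novo regions called not de novo), with rates normalized
by the region sizes. `feature_detection()` applies the boundary-inclusive
"50 percent or more of markers" rule per feature; homozygosity-wave regions
carry truth state 333, so any de novo call there counts as a false
positive. `concordance_at_top()` compares two ranked call lists by the
proportion shared among their top $k$, matching intervals by reciprocal
50% genomic overlap (paired greedily by decreasing overlap, which keeps the
measure symmetric); the matching rule is unstated in the original
description and fixed here.

## Problem sizes in the shipped tests

The test suite exercises the full grid at 3 chromosomes per
$(\rho, \sigma_r)$ cell for the transmitted-deletion check, 10 chromosomes
at $(\rho, \sigma_r) = (0.2, 0.15)$ for de novo recovery, and 20 replicate
null trios of 5,000 markers for the shared-wave robustness check, with
`n_perm = 1000` permutations — sizes chosen to characterize the method's
operating behavior while keeping a full run of the suite in the
tens-of-minutes range on one CPU. The defaults of the exported functions
remain the full-scale settings described above.

## Known limitations

* Autosomes only; the minimum distance is not defined for sex chromosomes.
* Markers with a missing value in any of the six signals are dropped before
  analysis (with a logged count); the original handling of missingness is
  unstated.
* Waves that invert between offspring and parents do not cancel in $d$ and
  can produce spurious segments; the posterior step usually, but not
  always, rescues these regions.
* Breakpoints of transmitted CNVs are detectable only insofar as the
  offspring's within-CNV level differs from the matched parent's.
* The pruning statistic and the Baum–Welch constraint set are principled
  stand-ins for supplementary material that is not part of the main text;
  both are exposed as parameters.
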