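---
title: "cistromeqc: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cistromeqc: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cistromeqc)
```

# Overview

`cistromeqc` implements the computational core of a uniform ChIP-seq
processing pipeline for transcription-factor binding sites:

1. **Mappability tracks** — per-position minimal unique read length (MUL)
   over a genome, computed from a suffix array, and the derived unmappable
   regions for any read length.
2. **Peak merging** — single-linkage union of peak sets from several peak
   callers (and, across experiments, clusters and meta-clusters), yielding
   the merged-peak frequency spectrum.
3. **Capture–recapture estimation** — the expected number of true binding
   sites from the frequency spectrum, treating peak callers as capture
   occasions.
4. **QC metrics** — the ENCODE library-complexity and strand
   cross-correlation metrics plus two capture–recapture controls, FNCM and
   FPCM.
5. **PWM site prediction** — log-odds scoring with an exact
   p-value-to-threshold computation.

A synthetic-data module generates genomes, peak sets and tag alignments
with exactly the statistical structure this mathematics assumes, so the
entire pipeline is testable offline.

# Mappability

Short reads cannot be placed uniquely inside repeats, so binding sites in
such regions are invisible to ChIP-seq. To delimit these "black holes" we
concatenate every chromosome and its reverse complement into one string,
each copy followed by a separator, and build a suffix array with the
linear-time SA-IS algorithm, then the LCP array with Kasai's algorithm.
For the suffix ranked $i$, with $L = \max(\mathrm{LCP}[i],
\mathrm{LCP}[i+1])$, the shortest read mapping uniquely at that position
has length $L + 1$ — unless the symbol at offset $L$ is a separator, in
which case no read of any length maps uniquely there and
$\mathrm{MUL} = -1$. Position $i$ is unmappable for read length $k$ iff
$\mathrm{MUL}[i] = -1$ or $\mathrm{MUL}[i] > k$.

Numerical/representation choices:

* **Separators are distinct symbols**, each ordered below `A < C < G < T`.
  A single repeated separator would create spurious common prefixes
  between suffixes that end at different boundaries; distinct symbols make
  cross-boundary matches impossible by construction, which is what makes
  the $L+1$ formula sound.
* **Non-ACGT bases become separators.** Aligners do not match through runs
  of `N`, so k-mers containing them are never mappable; such positions get
  $\mathrm{MUL} = -1$ and still count in the denominator of the unmappable
  fraction.
* **Matching is exact**; mismatch-tolerant mappability is out of scope.
* `LCP` beyond the last rank is taken as 0.

A caveat discovered during testing: the unmappable fraction is *not*
exactly invariant under reverse-complementing the genome. Reads extend
rightward from their start, so positions within $k-1$ bases of a
chromosome end (or an N run) can be unmappable in one orientation but not
the other — genome `AAC` has no unmappable position at $k = 2$ while its
reverse complement `GTT` has one. The property test therefore allows a
boundary term of $(k-1) \cdot \#\text{boundaries}$ positions rather than
demanding exact symmetry. Away from boundaries the two orientations agree
exactly, as the brute-force oracle confirms.

Applying this to a full genome assembly (e.g. computing the unmappable
fraction of the human primary assembly at $k = 30$) is a several-CPU-hour
computation requiring the downloaded assembly; the `mappability` CLI
subcommand performs it given a FASTA. The test suite validates the
algorithm positionwise against a brute-force occurrence-counting oracle on
small genomes with planted repeats and N runs instead.

# Peak merging and the frequency spectrum

Peaks from $K$ callers are merged by **single linkage**: any chain of
pairwise-overlapping intervals collapses into one merged peak spanning
their union. Overlap means at least one shared base under 0-based
half-open coordinates — abutting intervals (`[0,10)`, `[10,20)`) do *not*
merge. The **frequency** of a merged peak counts its constituent peaks,
not distinct callers: two overlapping peaks from the same caller
contribute 2. A per-caller presence matrix is kept alongside for the
two-source Chapman estimator.

The frequency spectrum $f_k$ = number of merged peaks with exactly $k$
constituents satisfies $\sum_k f_k = S$ (merged peaks) and
$\sum_k k f_k = $ total input peaks; both conservation laws are enforced
by property tests against a connected-components oracle.

Clusters (one TF, one caller, across experiments) and meta-clusters
(clusters merged across callers — the non-redundant binding-site set) use
the same geometry. Meta-cluster coordinates are the union span; no summit
averaging is attempted. A `min_callers` filter (default 1) optionally
retains only meta-clusters supported by several methods.

# Capture–recapture estimators

Treating callers as capture occasions, a true site captured $k \ge 1$
times appears as a merged peak of frequency $k$; the unobserved mass $f_0$
is estimated from the low-order frequencies:

* **Chao** (lower bound under heterogeneity):
  $\hat f_0 = f_1^2 / (2 f_2)$, with the bias-corrected
  $f_1(f_1-1)/(2(f_2+1))$ when $f_2 = 0$.
* **Lanumteang–Böhning** (third-order extension):
  $\hat f_0 = \frac{f_1^2}{2 f_2}\cdot\frac{3 f_1 f_3}{2 f_2^2}$.
  The correction factor equals 1 under homogeneous Poisson captures
  (where the estimator collapses to Chao's) and exceeds 1 under
  heterogeneity. Undefined when $f_1$, $f_2$ or $f_3$ is zero.
* **Zelterman**: $\hat\lambda = 2 f_2 / f_1$,
  $\hat N = S / (1 - e^{-\hat\lambda})$; undefined when $f_1$ or $f_2$
  is zero.
* **Zero-truncated-Poisson MLE**: solve
  $\lambda / (1 - e^{-\lambda}) = \bar m$ (mean capture count) by
  bisection on $(10^{-8}, 50]$ to $10^{-9}$; undefined when
  $\bar m \le 1$. Bisection is used because the function is strictly
  increasing, making convergence unconditional without derivatives.
* **Chapman** (two-source):
  $\hat N = (n_1+1)(n_2+1)/(m+1) - 1$. For $K > 2$ callers we take the
  unweighted mean over all $\binom{K}{2}$ caller pairs computed from the
  presence matrix; no weighting scheme is specified anywhere, and the
  unweighted mean is the neutral choice.

The **expected peak count** is the arithmetic mean of the estimators that
are defined on the given spectrum; undefined estimators are excluded
rather than imputed. If none is defined the function stops with a message
suggesting the observed $S$ as fallback.

# QC metrics

**ENCODE metrics.** NRF is the fraction of distinct
(chrom, 5′-position, strand) triples; PBC1 $= M_1/M_\text{distinct}$ and
PBC2 $= M_1/M_2$ ($\infty$ flagged when $M_2 = 0$); FRiP counts a tag as
in-peak by its 5′ position only (half-open containment), the simplest
defensible convention.

**Strand cross-correlation.** For shift $d \in [0, d_\max]$ we compute the
Pearson correlation between the per-position 5′-start count vectors of the
two strands, the minus strand shifted by $d$, per chromosome over the
covered span, combined by span-length-weighted averaging. The profile
peaks near the fragment length, with a "phantom" peak at the read length;
`cc_frag` is the maximum outside a ±5 bp exclusion zone around the read
length, and NSC $= cc_\text{frag}/cc_\min$,
RSC $= (cc_\text{frag}-cc_\min)/(cc_\text{read}-cc_\min)$.

On synthetic data with a genuinely uniform background, $cc_\min$ sits at
the correlation noise floor around zero and can be slightly negative, so
the NSC *ratio* can flip sign; real genomes have enough shared large-scale
coverage structure between strands to keep $cc_\min$ positive. The
formulas are implemented exactly as defined, but the simulation-based
tests assert the robust readouts (the fragment-length peak height, RSC,
and the phantom-peak response) rather than NSC ordering.

**FNCM** (false-negative control) is the ratio of a caller's observed peak
count to the capture–recapture expected count; values well below 1 mean
the caller missed sites. The same pooled $\hat N$ is used for all callers.

**FPCM** (false-positive control) compares the observed number of
unit-frequency merged peaks with its Poisson expectation
$E[f_1] = \hat N \hat\lambda e^{-\hat\lambda}$ (the Poisson pmf at 1 times
the population size); values well above 1 flag excess caller-specific
singletons. $\hat\lambda$ comes from Zelterman's estimator by default,
falling back to the ZTP MLE. The published derivation of the expected
count lives in supplementary material that is not available; the
pmf-at-1 reconstruction is this package's documented reading.

A limitation found in simulation: when singleton noise contaminates the
spectrum, re-estimating $\hat\lambda$ and $\hat N$ from that same spectrum
partially absorbs the contamination ($f_1$ deflates
$\hat\lambda = 2f_2/f_1$ and inflates $\hat N$), so FPCM computed from
re-estimated parameters does not rise monotonically with the noise rate —
at noise rates {0, 0.1, 0.3} its mean drifts slightly *below* 1. Evaluated
at the capture parameters of the signal component (known in simulation),
FPCM is monotone in the noise rate as intended. Users should read FPCM as
a contrast against a trusted $(\hat\lambda, \hat N)$ pair, not as a
standalone alarm on heavily contaminated spectra.

# PWM site prediction

Count matrices (HOCOMOCO plain-text layout) are converted to log2-odds
weights with a total pseudocount of 1 distributed by the background
composition (uniform by default; HOCOMOCO's own pseudocount scheme is not
published in the source we follow). The score threshold for a target
p-value is the smallest $t$ with
$P(\text{score of a random word} \ge t) \le p$ under the i.i.d.
background, computed by exact dynamic-programming convolution of the
per-position score distributions after discretising weights to bins of
$10^{-3}$ of the matrix score range. That bin width keeps the DP table a
few thousand cells while matching exhaustive $4^L$ enumeration within one
bin for all tested matrices up to $L = 8$.

Scanning evaluates both strands (the minus strand via the
reverse-complemented matrix), skips windows containing N, reports all
hits above threshold without greedy masking, and gives minus-strand hits
forward-strand coordinates. The genome-wide default p-value threshold is
$10^{-4}$.

# The synthetic world

`sim_config()` fixes the simulation defaults once:

| parameter | default | why |
|---|---|---|
| callers | MACS, GEM, SISSRs, PICS | the four callers of the modelled pipeline |
| capture model | Poisson($\lambda = 1.5$) | homogeneous captures are what the estimators assume; 1.5 gives a realistic ~78% detection rate |
| n_true_sites | 1000 | typical TF site count at the scale the recovery tests use |
| peak width / jitter | 200 bp / 10 bp | jitter ≪ width keeps detections of one site in one merged peak |
| genome length | 1 Mb | room for 1000 non-overlapping sites with gaps |
| fragment / read length | 180 / 36 bp | standard short-read ChIP-seq geometry |
| fragments per site, background | 30, 50% | deep enough for a clear cross-correlation peak, dirty enough for FRiP < 1 |

Under the Poisson model a site's capture count is drawn once and each
capture becomes one peak assigned to a caller uniformly at random, so the
merged-peak frequency of a detected site *equals* its Poisson count — the
estimators' assumption holds exactly, and estimator-recovery tests measure
estimator quality, not generator mismatch. The Bernoulli-per-caller model
is provided to test robustness to model misfit (frequencies are then
binomial, under which Chao's $f_0$ carries a known $K/(K-1)$ inflation —
negligible at the detection probabilities used). Caller-specific noise
peaks are uniform singletons; tags are 5′-start records from both
fragment ends, so the cross-correlation argmax estimates the fragment
length.

What the generator does **not** emulate: sequence-composition bias,
mappability holes interacting with peak calling, caller-specific width
distributions, fragment-length dispersion, or inter-site intensity
heterogeneity. A green test therefore establishes the mathematics under
its stated assumptions, not performance on any real dataset.

# Degenerate inputs and tie-breaking

* Empty peak sets produce an $S = 0$ spectrum; estimators require
  $S \ge 1$.
* Chao's bias-corrected branch avoids the $f_2 = 0$ division; Zelterman,
  Lanumteang–Böhning and the MLE return flagged-undefined objects instead
  of NaNs, and the average skips them.
* `PBC2 = Inf` is preserved and serialised as the string `"Inf"` in JSON.
* Ties in the threshold DP are resolved toward the smaller score (the
  *smallest* $t$ satisfying the tail bound); thresholds above the maximal
  achievable score mean "no hit passes" and are returned as such.
* Zero-variance count vectors make Pearson correlation undefined; the
  affected chromosome is dropped, and an error is raised only if nothing
  usable remains.
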