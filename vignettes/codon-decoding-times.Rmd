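---
title: "Characterizing codon decoding-time distributions from ribosome profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing codon decoding-time distributions from ribosome profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribodist)
```

## The model

Ribosome profiling measures, for every codon position $j$ of an ORF, a
footprint read count $RC_j$ proportional to the time ribosomes dwell there.
Because $RC_j \propto m \cdot B \cdot T_j$ — mRNA copies $m$, initiation rate
$B$, and decoding time $T_j$ — the absolute counts of different genes are not
comparable. Dividing each gene's counts by its own mean,

$$NFC_j = \frac{RC_j}{\mathrm{mean}(RC)} \propto \frac{T_j}{\mathrm{mean}(T)},$$

cancels $m$ and $B$ and leaves a per-position proxy of *relative* decoding
time. Pooling the $NFC$ values of all positions carrying the same codon, over
all analyzed genes, yields one empirical decoding-time distribution per
codon type. Everything in this package operates on those 61 distributions:
characterizing their shape, measuring distances between them, tracking them
along the ORF, comparing them across organisms, and relating their features
to tRNA availability.

### Normalization choices

Two exclusions are applied before the per-gene mean is taken: the first and
last 20 codons (footprint density is systematically inflated near ORF ends)
and positions with fewer than one read (which would deflate the mean). A
codon position excluded this way contributes neither to the mean nor to the
pooled samples. Whether sub-threshold positions should still be *pooled* (as
zeros) is genuinely open; `compute_nfc(pool_zeros = TRUE)` retains them for
sensitivity analysis, and the default drops them. Genes shorter than
`2 * exclude_terminal + 1` codons, or with no surviving position, are
dropped and counted in the log.

When a sliding window restricts pooling (the positional analysis), the
per-gene mean is still computed once over the gene's whole included region —
the window selects positions, it does not renormalize. A window-local mean
would re-introduce exactly the positional coverage differences the analysis
is trying to see.

## Distribution fitting

Each codon's pooled sample is fit by maximum likelihood to thirteen
candidate families: Beta, Birnbaum–Saunders, extreme value (minimum Gumbel),
generalized extreme value, inverse Gaussian, logistic, log-logistic,
log-normal, Nakagami, normal, Rayleigh, Rician, and t location-scale. The
registry is an ordinary named list (`nfc_families()`), so a fourteenth
family can be registered without touching package code. Normal, log-normal,
Rayleigh and inverse Gaussian use closed-form MLEs; the rest are maximized
numerically (Nelder–Mead on log-transformed scale/shape parameters, from
moment-based starting values). A fit that does not converge, or lands on a
degenerate boundary (e.g. a one-point sample), is flagged and excluded from
selection rather than aborting the run.

Two families need conventions the data do not supply. The Beta law has
support $(0,1)$, so samples are scaled by $1/\max(x)(1+10^{-6})$ and the
log-likelihood carries the Jacobian term $-n\log M$, keeping it comparable
with the unscaled families. Selection among families uses the raw maximized
log-likelihood with no parameter-count penalty — the maximum-likelihood
criterion as such. Families differ in parameter count (2 or 3), so this is
deliberately simple rather than statistically ideal; with thousands of
samples per codon the ranking is insensitive to the missing penalty.

From the log-normal fit $(\mu, \sigma)$ three closed-form features are
derived: mean $e^{\mu + \sigma^2/2}$, median $e^{\mu}$, and skewness
$(e^{\sigma^2} + 2)\sqrt{e^{\sigma^2} - 1}$. The empirical features are the
sample mean, the sample median, and the mode, estimated as the midpoint of
the tallest bin of a fixed-width histogram (0.05 NFC units on $[0, 5]$ plus
an overflow bin; ties resolve to the lowest bin). The bin width is a
configuration parameter; 0.05 resolves the bulk of NFC mass (roughly 0–2.5)
into ~50 bins while keeping per-bin counts stable at the sample sizes the
pipeline produces.

## Distances and the distinctness test

Three inter-distribution distances are implemented. Jensen–Shannon and
Hellinger operate on histograms over shared fixed bins, as both are defined
on probability functions; the energy distance operates on the raw samples,
as it is defined on random variables. JS uses base-2 logarithms and is
reported as $\sqrt{JSD}$ so that, like Hellinger, it lives on $[0, 1]$ with
1 attained on disjoint supports. Energy distance is
$\sqrt{2E|X-Y| - E|X-X'| - E|Y-Y'|}$ with expectations as means over all
pairs, computed by a sorting decomposition in $O(n \log n)$; above
$4 \times 10^8$ implied pairs each side is subsampled (seeded) to 20,000
values.

The distinctness test asks whether codon $c$'s distribution is
characteristic of $c$. Genes are split into random halves 100 times; each
partition yields one self-distance (codon $c$ in half 1 vs codon $c$ in half
2) and one cross-distance per comparison codon (codon $c$ in half 1 vs $c'$
in half 2). The reported $p$ is the fraction of (partition, $c'$) pairs in
which the self-distance is *not* smaller — a one-sided empirical exceedance
— and $c$ is declared distinct when $p < 0.01$. The comparison set can be
all other sense codons, synonymous codons only, or codons with the same
nucleotide composition (anagrams). This $p$-value construction is this
package's own definition of the test; with ~40 genes and hundreds of pooled
samples per codon it is well calibrated (≈1% of codons reach $p < 0.01$
under a common-distribution null) and has high power for planted shifts of
0.3–0.4 log units.

## Positional analysis

For each ORF end, NFC distributions are pooled in 50-codon windows sliding
one codon at a time over the first (or last) 200 codons — 151 windows. For
every codon a 151×151 window-distance matrix is computed; matrices are
averaged over codons (skipping windows where a codon has fewer than
`min_samples` values), and column means (excluding the diagonal) give the
*mean distance vector*: how different each window is, on average, from all
others. A window of 10 consecutive components is slid along this vector and
compared with all remaining components by a two-sided Wilcoxon rank-sum
test; the boundary is the start position of the first window whose test
exceeds $\alpha = 0.05$. The boundary is reported as that start index — the
first position at which the local distances stop being distinguishable from
the bulk. The same scan applied to the position-wise mean of the raw RC
values (`boundary_on_mean_rc`) separates distribution-shape effects from
plain coverage ramps: a region can shift its NFC *shape* without moving the
mean RC, and only the distribution scan will see it.

Two behaviours of this estimator are worth knowing. First, adjacent windows
share 49 of 50 positions, so their distances are small and correlated; edge
windows have fewer such neighbours and sit slightly higher in the vector —
a benign artifact at realistic sample sizes. Second, the estimator
localizes *change regions shorter than about the window length* well. A
step-shaped shifted block much longer than the window smears into a smooth
decay, and the first-non-significant scan ends near where the decay crosses
the bulk of the vector rather than at the block's end: planted blocks of 30
codons are recovered within ±10 codons, but 60- or 90-codon blocks are
systematically underestimated (around 36–43). Empirical end-region signals
are ramp-like — strongest at the terminus and fading — which is the shape
this scan reads correctly; synthetic step blocks are the worst case.

## Cross-organism comparison

Per codon, the distance between two organisms' pooled NFC distributions is
computed; the per-codon matrices are averaged over the codons present in
every organism, and the averaged matrix is clustered with neighbor joining
(`ape::nj`; three-taxon matrices are solved by the closed three-point
formulas). Negative NJ branch lengths, which arise on non-additive
matrices, are clamped to zero with the deficit moved to the sister branch
— the standard correction — and logged. The intra- vs inter-domain test
pools, over codons, all organism-pair distances labelled intra-domain
(both prokaryotes or both eukaryotes) or inter-domain and compares them
with a one-sided rank-sum test (intra smaller). The test unit is the
(codon, organism-pair) distance; these are not independent across codons,
so the $p$-value is descriptive rather than exact — the same caveat applies
to any pooled construction over codons.

## tRNA adaptiveness

`compute_tai_weights` turns tRNA gene copy numbers into per-codon relative
adaptiveness weights using the standard wobble bookkeeping: each codon
gains $(1-s)\,\times$ copies from its Watson–Crick anticodon and from the
one wobble-capable anticodon of its box, with the published selective
constraints $s$ (G:U 0.41, I:C 0.28, I:A 0.9999, U:G 0.68; Watson–Crick 0).
The input is keyed by codon — the copy number of the tRNA whose anticodon
is the codon's Watson–Crick partner — and a wobble donor that would be a
stop codon contributes nothing. Weights are normalized to the maximum, and
zero weights are replaced by the geometric mean of the nonzero ones.
`correlate_features` then reports Spearman correlations between any
per-codon feature and copies or weights; ATG and TGG can be excluded via
the caller (their weights are degenerate single-isoacceptor cases), but the
default keeps all codons.

## The TASEP generator

The synthetic-data engine is a continuous-time totally asymmetric simple
exclusion process: ribosomes with a footprint of $\ell = 10$ codons hop
codon-by-codon with exponential dwell of mean $T_j$, are blocked while the
next footprint position is occupied, initiate at rate $B$ while the first
$\ell$ codons are free, and with probability 0.01 a decoding step is a
pause with a 10× longer mean dwell. RC is the time-integrated P-site
occupancy after a burn-in (an optional snapshot mode counts ribosome
positions at evenly spaced instants instead, emulating the snapshot nature
of sequencing). The kinetic Monte Carlo core is implemented in C++ and uses
R's RNG, so `set.seed` governs everything.

The reference simulation — the package's default `tasep_config()` — uses
150 genes of 300 uniform-random sense codons; per-codon mean decoding times
drawn log-uniformly over one order of magnitude ($[1, 10]$ time units);
per-gene initiation rates log-uniform on $[0.002, 0.05]$, spanning free
flow up to several times the slow-codon carrying capacity
$1/(T_{\max}(1+\sqrt{\ell})^2) \approx 0.006$, so a fraction of genes
develop traffic jams; and 1–4 mRNA copies per gene, making coverage
proportional to copies × initiation as in real libraries. A horizon of
30,000 time units with a 3,000-unit burn-in gives every gene on the order
of a hundred completed ribosome passages. These sizes keep the full
reference run under a minute on one CPU.

On this simulation the histogram mode and the fitted log-normal median
rank-correlate with the true $T_j$ at $r \approx 0.97$–1.0, and the fitted
log-normal skewness at $r \approx -0.97$: faster codons have more
jam-skewed distributions, because blocking time is additive and weighs
relatively more on a short intrinsic dwell. The empirical median and the
fitted log-normal mean also correlate near 1.0 here — with hundreds of
pooled samples per codon their estimates are simply very precise. Real
data, and coarser simulation regimes, degrade these mean-based features
first; the mode and fitted median are the robust pair, and the skewness
sign is the robust qualitative signal. What passing the synthetic tests
shows is therefore the *mechanics* of the pipeline and the sign/ordering
structure of the features — not that any particular correlation magnitude
will be observed on experimental libraries, whose coverage, digestion
biases, and P-site calibration noise the generator does not emulate.

Two simple parametric generators provide unit-level fixtures without TASEP
dynamics: `parametric_nfc_generator` draws i.i.d. log-normal NFC samples
per codon, and `positional_shift_generator` builds gene profiles whose
first (or last) $K$ codons draw from a shifted log-normal
($\mu + \Delta\mu$, default base $\sigma = 0.4$, a realistic NFC spread)
with per-gene renormalization to mean 1.

## Numerical conventions and degenerate inputs

* Histogram bins: width 0.05 on $[0, 5]$ plus one overflow bin; all
  histogram distances require identical edges and abort otherwise.
* Ties in the mode: lowest bin wins, logged.
* Odd gene counts in the distinctness partition: halves of size
  $\lfloor n/2 \rfloor$ and $\lceil n/2 \rceil$.
* A constant mean-distance vector gives Wilcoxon $p = 1$ everywhere and a
  boundary at position 1 (no positional signal).
* Codons absent from a window or an organism are skipped with counts
  tracked, never imputed.
* All randomized steps take an explicit seed; pipeline stages derive
  per-stage substreams from the run seed so stages are independently
  reproducible.

## Known limitations

* Raw-likelihood family selection ignores parameter-count differences.
* The boundary scan underestimates step-shaped change regions longer than
  the sliding window (see above); window length is configurable when a
  longer-range scan is needed. And because step-1 windows overlap heavily,
  the mean distance vector is smooth, so the rank test is not exactly
  calibrated on signal-free data: when no real positional signal is
  present, the reported boundary reflects where the vector's slow wiggle
  first crosses its bulk level, not a controlled false-positive rate. The
  scan is an estimator for data with a dominant end-region signal, not a
  hypothesis test.
* The domain-similarity and distinctness $p$-values are empirical pooled
  constructions, not exact tests.
* The TASEP generator omits wobble kinetics, tRNA recycling and mRNA
  structure; its pause model is memoryless per decoding event.
* Profile reconstruction from raw reads (alignment, P-site offsets) is out
  of scope; the package starts from codon-resolution RC profiles.
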