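---
title: "Modeling off-target cleavage counts with ZINB posteriors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling off-target cleavage counts with ZINB posteriors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The observation model

Genome-wide off-target detection assays report, for each putative
sgRNA–target site, a cleavage read count. These counts have two properties
that break ordinary regression: an excess of zeros (most candidate loci
are either inactive or below the assay's sensitivity — *technical* zeros)
and variance far above the mean among active sites. We model both with a
zero-inflated negative binomial,

$$P(y \mid x_s, x_p) = \pi\,\delta_0(y) + (1-\pi)\,\mathrm{NB}(y;\mu,\theta),$$

where $\pi \in [0,1]$ is the zero-inflation weight, $\mu > 0$ the negative
binomial mean and $\theta > 0$ its dispersion (variance $\mu + \mu^2/\theta$).
The mixture's moments are closed-form: mean $(1-\pi)\mu$, variance
$(1-\pi)\mu(1 + \mu/\theta + \pi\mu)$; their ratio gives the coefficient of
variation used as a per-site uncertainty summary. All pmfs are evaluated in
log space through `lgamma`; the zero branch combines
$\log\pi$ and $\log(1-\pi) + \theta(\log\theta - \log(\mu+\theta))$ with a
log-sum-exp, which is required for stability when $\pi$ approaches 0 or 1.

Counts enter the likelihood as integers. Real datasets are linearly
rescaled before training (see *Normalization*), which produces non-integer
values; these are rounded once at dataset load. This is a documented
modeling choice — the alternatives (flooring, or a continuous gamma
relaxation) change the likelihood by less than the assay noise at the
count magnitudes involved, but rounding keeps the pmf a genuine
probability mass function.

Numerical floors: $\pi$ is clamped to $[10^{-6}, 1-10^{-6}]$ and $\mu,
\theta$ to $[10^{-6}, 10^{6}]$ after activation, keeping the loss finite
for any network output.

## Input encodings

**Sequence branch.** A site is a pair of 23-nt sequences (PAM-inclusive):
the sgRNA and the genomic target. Each is one-hot encoded under the fixed
channel order A, T, G, C and the two matrices are merged with an
element-wise OR: a matched position shows one set bit per column, a
mismatched position two. Because OR discards orientation, a two-bit
direction channel is appended: bit 5 is set when the sgRNA base's channel
index precedes the target base's, bit 6 otherwise. This makes the three
canonical examples `0011-10` (G→C), `0011-01` (C→G) and `0100-00` (T→T)
hold simultaneously — the channel order and the direction rule are fixed by
exactly that requirement. Ambiguous bases (N, as in an NGG search pattern)
get an all-zero one-hot, no direction bit, and are never counted as
mismatches; U is normalized to T. Only equal-length 23-nt pairs are
supported — the encoding has no insertion channel, so bulges are rejected
rather than silently mis-encoded. Column 1 is the 5' end of the written
sequence; positions 21–23 are treated as PAM-proximal when stratifying.

**Descriptor branch.** Identical interfaces at different loci can have
different activity; sequence-only models cannot separate them. For each of
the 23 site positions we take the 147-bp genomic window centered on it
(73-bp flanks; minus-strand sites use the reverse complement so windows
read 5'→3' along the site; contig edges are N-padded) and compute four
descriptors, giving a 4 × 23 matrix with fixed row order:

1. *BDM complexity*: the window is split into non-overlapping 12-bp blocks
   (remainder dropped) and the block-decomposition aggregate
   $\sum_{\text{distinct } b} \mathrm{cx}(b) + \log_2 m_b$ is taken over
   block multiplicities $m_b$. Block complexities come from a pluggable
   k-mer table; without one, a Shannon-entropy-per-block fallback
   (N as a fifth symbol) makes the descriptor self-contained. Block size
   12 balances resolution against table size and is recorded in model
   metadata.
2. *GC content* of the window (N in the denominator only).
3. and 4. *Nucleosome occupancy and affinity*. A duration-HMM nucleosome
   model is deliberately out of scope; two providers stand behind the same
   interface: per-base track files (`chrom`, 0-based `pos`, `occupancy`,
   `affinity`), and a deterministic sequence surrogate — the amplitude of
   the ~10-bp periodic component of AA/TT/TA dinucleotide placement in the
   window (the rotational positioning signal), with occupancy a logistic
   transform of that amplitude. The surrogate is a sequence-derived score
   in its own right, not an emulation of any specific published track; the
   provider identity is stored with the model.

Descriptor rows are min–max normalized to $[0,1]$ with statistics fitted
once on the training set, persisted in the model, and applied with
clipping at inference time; a degenerate row (max = min) is set to 0 with a
warning. The window value for position $j$ is computed on the window
centered at $j$, not an average over windows covering $j$ — the simplest
sliding-window reading, applied consistently. A vectorized batch path
shares cumulative sums across a site's 23 overlapping windows and is
tested for numerical agreement with the window-by-window reference path.

## The network

The sequence branch applies a width-1 convolution with 128 kernels, then a
width-3 convolution with 32 kernels ('same' padding), each batch-normalized
before rectification, the second max-pooled (window 2, stride 2, 23 → 11
positions), then a bidirectional LSTM with 128 hidden units per direction
whose two final states are concatenated, and a rectified 128-unit
projection. The descriptor branch applies one width-3, 32-kernel
convolution stage and a rectified 128-unit projection. The concatenated
256-dim encoding passes through a 64-unit joint layer into three scalar
heads: a sigmoid producing $\pi$ and exponentials producing $\mu$ and
$\theta$. Ablation heads replace the readout: ZIP $(\pi, \lambda)$, NB
$(\mu, \theta)$, Poisson $(\lambda)$.

Where the architecture leaves freedom, the choices are: 'same' convolution
padding; the LSTM summary is the concatenated final hidden states (not a
mean over positions); batch normalization sits between convolution and
rectification; weights use fan-in-scaled uniform initialization with the
run seed, LSTM forget-gate biases start at 1, head weights start at zero
(so an untrained ZINB model emits exactly $\pi = 0.5$, $\mu = \theta = 1$),
and the mean head's bias is initialized to the log of the training-mean
count, which shortcuts the long plateau of pushing $\mu$ up from 1.

Training minimizes the head's negative log-likelihood by mini-batch Adam.
Defaults follow the reference protocol: learning rate $10^{-5}$, batch
size 128, a 70/20/10 train/validation/test split (random permutation,
floor-based sizes, remainder to train), early stopping after 50 epochs
without improvement of the monitored (by default validation) loss, at most
500 epochs, returning the best-validation weights. Everything — the split,
initialization, shuffling — derives from one seed, and two runs with the
same seed are bit-identical.

Because no automatic-differentiation framework is part of this package's
dependency footprint, all layer gradients (convolutions via shifted matrix
products, batch normalization, max-pooling, BPTT through both LSTM
directions, and the ZINB/ZIP/NB/Poisson losses with respect to the raw
head outputs) are derived analytically and checked against central finite
differences in the test suite.

## Uncertainty outputs

For off-target risk only the upper tail matters, so credible intervals are
one-sided: the lower bound is pinned at 0 and the upper bound is the
level-quantile of the predictive distribution. Quantiles on discrete
support use right-continuous cdf inversion,
$Q(p) = \min\{k : F(k) \ge p\}$, making coverage conservative (never
silently below nominal). The expected value $(1-\pi)\mu$ is the point
prediction; dividing by the stored scale constant (the normalization
ceiling, 10 000) expresses it as an activity frequency in $[0,1]$.

**Calibration.** A calibrated forecaster puts N% of observations inside
its N% intervals. For *discrete* predictive distributions the naive
estimator — the fraction of $y_i$ at or below the $p$-quantile — cannot
approach the identity line: any atom larger than the level gap inflates
observed coverage (with a zero mass of 0.5, "5% intervals" cover half the
data). Both estimators are provided. `method = "quantile"` implements the
naive rule and is used to verify conservative coverage.
`method = "pit"` (default) is the randomized probability integral
transform, $u_i = F_i(y_i - 1) + V_i\,p_i(y_i)$ with $V_i \sim U(0,1)$,
standard for count forecasts: under a perfectly calibrated model the $u_i$
are exactly uniform, so the observed-vs-nominal curve is informative at
every level, atoms included. The self-consistency tests (observations
drawn from the model's own posteriors, n = 5 000, maximum deviation from
the identity ≤ 0.03) use the PIT estimator; the quantile rule is
structurally unable to meet such a bound on zero-inflated support, which
is a property of the estimator, not of the model.

## The aggregate specificity distribution

For a guide with on-target site and $M$ putative off-target sites (a
parsed genome-search output; duplicates by chrom/start/strand removed,
default search depth $N = 5$ mismatches), each site's posterior is sampled
$n_{samp}$ times (default 1 000) and

$$y_{sg}[s] = \log \frac{\sum_{i=1}^{M} d_i[s]}{\max(d_{on}[s], c)}$$

with draws $d$ and a count floor $c = 1$. The sum runs over off-target
sites only — the on-target appears solely in the denominator. The floor
guards the rare event of an on-target zero draw (the on-target posterior
has $\pi \approx 0$); the numerator is floored identically so that a guide
whose off-targets all draw zero yields a finite, strongly negative score
rather than $-\infty$. Natural log is the default; rankings are invariant
to the base. Per-site draws are independent across sites and sample
indices — coupling them through common random numbers is a variance-
reduction refinement deliberately left out. Lower $y_{sg}$ means higher
genome-wide specificity, and the spread of the distribution separates
guides with equal point aggregates.

## The synthetic study

The generator exists so that every claim above is testable offline with
known truth. It samples a uniform random contig, chooses disjoint 23-bp
slots, and for each guide plants one on-target (the contig's own sequence)
and `sites_per_guide` off-targets: the guide sequence with $m \sim
U\{1..6\}$ positions mutated, written into the contig (reverse-complemented
on minus-strand sites) so that every target sequence is literally present
at its coordinates. True parameters couple both network branches to the
outcome: $\pi = \mathrm{logit}^{-1}(\mathrm{logit}(\pi_0) + b\,m)$ and
$\mu = \mu_{on}\cdot d^{\,m}\cdot 2^{\,g\,(GC - 0.5)}$, with GC taken from
the planted site's center window, plus a per-guide log-normal factor on
$\mu_{on}$. Counts are single ZINB draws. Defaults — 40 guides × 600
sites (24 000 total, split 20 000/2 000/2 000), $\pi_0 = 0.05$, slope
$b = 0.5$, decay $d = 0.35$, $\mu_{on} = 2000$, GC coefficient 2, guide
factor sd 0.3, $\theta = 2$ — were chosen once to mimic the gross features
of genome-wide assay data: a ~28% zero fraction, activity decaying by
roughly three orders of magnitude from 0 to 6 mismatches, and
overdispersion throughout. A `corrupt_with_technical_zeros` step zeroes
positive counts independently at a chosen rate, emulating assay dropout.

What the simulation does *not* emulate: PAM constraints, sequencing-read
artifacts (PCR duplicates, mapping noise), realistic genome composition,
chromatin-driven descriptor signal, or the mismatch-position-specific
tolerance profile of Cas9. Passing the recovery tests therefore
demonstrates that the estimator works when its modeling assumptions hold —
it does not certify performance on real assay data, whose benchmark
correlations require the original corpora and full-size trained weights.

## Problem sizes and test design

The validation runs use a scaled-down architecture (16/8 convolution
kernels, LSTM width 8, 32-unit projections) with learning rate $2\times
10^{-3}$, batch 256 and at most 25 epochs — sizes chosen so a full
simulate–train–evaluate cycle completes in minutes on one CPU while
leaving wide margins on its acceptance bounds (held-out Spearman ≥ 0.8
between true and predicted mean; ZINB test NLL at or below the Poisson
head's on the same overdispersed data; calibration deviation ≤ 0.03 at
n = 5 000). Distribution-level checks run against independent oracles:
closed-form pmfs against the base-R `dnbinom`/`dpois` implementations and
explicit gamma-function formulas, the gamma–Poisson sampler against the
pmf by total-variation distance at $10^6$ draws, moments against
Monte-Carlo, and the aggregate combiner against a brute-force resampler
written directly in the tests.

## Normalization of read counts

Across guides, raw totals differ for technical reasons; within the
reference protocol counts are first equalized so every sgRNA carries the
same total signal, then linearly scaled so the global maximum is 10 000.
The equalization target is the mean per-guide total — any positive
constant gives the same result after the global step, so the choice only
fixes the stored factors. The global step is applied unconditionally,
which reproduces the stated ceiling exactly regardless of how many guides
start above or below it. Both factors are stored and invert the transform;
rounding to integers (for the discrete likelihood) happens after, and
optionally.

## Known limitations

* On-target activity prediction is out of scope by design: the model's
  uncertainty machinery is built around the abundance of candidate
  off-target sites.
* The BDM fallback is an entropy proxy, not an algorithmic-complexity
  table; supply a k-mer table for faithful BDM values.
* The nucleosome surrogate captures only the dinucleotide periodicity
  signal; use track files from a dedicated model when available.
* Checkpoints are R-native (RDS) and not portable to other frameworks.
* Training the full-size architecture (128-kernel convolutions, 128-unit
  LSTM) on corpus-scale data is possible but slow in pure R; the package
  targets method development and validation scale.
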