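# crisprZINB

Probabilistic prediction of CRISPR/Cas9 off-target cleavage activity with
full per-site uncertainty, and a genome-wide sgRNA specificity
distribution.

## The problem

Guide-RNA design needs to know not just *whether* a putative off-target
locus will be cleaved, but *how much* and *how confidently that can be
predicted*. Genome-wide cleavage assays (CHANGE-seq, GUIDE-seq, SITE-seq)
produce read counts that are extremely sparse — most putative sites show
zero reads, some because they are biologically inactive and some because a
limited-sensitivity assay missed them ("technical zeros") — and strongly
overdispersed. Point scores discard that structure. This package models the
count-generating process itself and returns a full predictive distribution
per site.

## The model

Cleavage read depth `y` at an sgRNA–target interface is modeled as
zero-inflated negative binomial:

    NB(k; mu, theta) = Gamma(k + theta) / (Gamma(theta) k!) *
                       (mu / (mu + theta))^k * (theta / (mu + theta))^theta

    P(y | x_s, x_p)  ~  pi * delta_0(y) + (1 - pi) * NB(y; mu, theta)

where `pi` (zero-inflation weight) absorbs technical zeros, and `mu`,
`theta` are the NB mean and dispersion. The three parameters are predicted
per site by a multi-output neural network

    f_w : (x_s, x_p) -> (pi, mu, theta)

with two fused input branches:

* `x_s`, a 6 × 23 binary matrix encoding the sgRNA–target interface: the
  element-wise OR of the two one-hot sequences (channel order A, T, G, C)
  plus a two-bit mismatch-direction channel — e.g. `0011-10` is the
  mismatch G→C, `0011-01` is C→G, `0100-00` the match T→T. Processed by two
  convolution stages (128 kernels of width 1, then 32 of width 3,
  batch-normalized, max-pooled 2/2) and a bidirectional LSTM (128 hidden
  units per direction).
* `x_p`, a 4 × 23 matrix of physical descriptors of the genomic context:
  for each site position, a 147-bp window (73-bp flanks) yields
  block-decomposition (BDM) sequence complexity, GC content, and nucleosome
  occupancy/affinity, min–max normalized with statistics frozen on the
  training set. Processed by one convolution stage.

Both branches are projected to 128 dimensions, concatenated (256), passed
through a 64-unit joint layer and read out by three heads: a sigmoid for
`pi` and exponentials for `mu` and `theta`. Training minimizes the ZINB
negative log-likelihood with Adam and early stopping; Poisson, NB and
zero-inflated-Poisson ablation heads are available for comparison. The
network, its analytic gradients and the optimizer are implemented in
vectorized base R and verified against finite differences in the tests.

From the per-site posterior the package derives the outputs a designer
uses: the expected activity (point prediction), a one-sided 95% credible
interval with the lower bound pinned at 0, the coefficient of variation,
and a calibration diagnostic (observed vs. nominal coverage). For a whole
guide, the specificity distribution

    y_sg = log( sum_{i=1..M} y_i / y_on )

is Monte-Carlo sampled from the per-site posteriors of the M putative
off-target sites (e.g. parsed from a genome-search output) and the
on-target site; lower scores mean higher genome-wide specificity.

A synthetic-data module simulates a genome, plants guides and mutated
off-target sites in it, and draws ZINB counts from known ground truth, so
the entire pipeline is testable offline.

## Worked example

```r
library(crisprZINB)

# simulate a study: 24 000 sites across 40 guides with known truth
sim <- simulate_sites(synthetic_spec(seed = 11))

# features: 6x23 interface encodings and normalized 4x23 descriptors
xs  <- encode_pairs(sim$sites)
xp  <- descriptor_matrices(sim$genome, sim$sites)
nrm <- fit_descriptor_norm(xp)
for (r in 1:4) xp[,,r] <- pmin(pmax((xp[,,r] - nrm$min[r]) /
                                    (nrm$max[r] - nrm$min[r]), 0), 1)

# train the ZINB head (scaled-down architecture, 20k/2k/2k split)
model <- train_model(xs, xp, sim$sites$read_count, "zinb",
                     network_config(conv1_kernels = 16, conv2_kernels = 8,
                                    lstm_hidden = 8, fc_seq = 32,
                                    fc_phys = 32, fc_joint = 32,
                                    phys_kernels = 8),
                     train_config(lr = 2e-3, max_epochs = 25, patience = 8,
                                  batch_size = 256,
                                  fractions = c(20000, 2000, 2000)/24000,
                                  seed = 7),
                     norm_stats = list(descriptor_norm = nrm))

# score held-out sites
sc <- score_sites(model, sim$sites[model$split$test[1:3], ], sim$genome)
sc[, c("pi", "mu", "theta", "mean", "cv", "ucb95", "mismatches")]
#>          pi        mu    theta      mean       cv ucb95 mismatches
#> 1 0.3286131  31.45155 1.647313 21.116156 1.200410    72          4
#> 2 0.3110602  14.18916 1.784545  9.775476 1.169264    32          5
#> 3 0.2190597 127.52153 1.661345 99.586699 1.030201   300          3
```

Each held-out site gets its zero-inflation weight, NB mean and
dispersion, the resulting expected count, coefficient of variation, and
the 95% upper credible bound (lower bound pinned at 0): activity falls
and uncertainty weight rises with mismatch load. Held-out Spearman
correlation between true and predicted mean activity on this simulation
is 0.985, and the ZINB head's test NLL (4.40/site) beats the Poisson
ablation (87.5/site).

A thin command-line wrapper over the same functions is installed at
`exec/crisprzinb` (subcommands `simulate`, `train`, `score`, `aggregate`,
`calibrate`).

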