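# circaseq

Analysis toolkit for **time-resolved transcription-factor ChIP-Seq** in
circadian designs — the kind of experiment where chromatin
immunoprecipitation of a clock transcription factor (e.g. a bHLH factor
binding E-boxes) is sequenced at six timepoints, ZT2 to ZT22 at 4-h
intervals, over one light-dark cycle, together with an input-chromatin
control. The package is aimed at computational biologists who want to go
from mapped tags to a table of point binding sites with rhythm statistics,
tandem E-box classification, transcript annotation, and inferred motif
activities — and at method developers who want every stage testable against
synthetic data with known ground truth.

## What it computes

**Strand-model deconvolution.** ChIP fragments are sequenced from their 5′
ends, so a point source at position *s* produces plus-strand tags near
*s − d* and minus-strand tags near *s + d*, where *d* follows the fragment
offset kernel *k(d)*. The kernel is estimated from the data (cross-correlation
of strand profiles pooled over strong regions, then a symmetrized density of
per-tag offsets). Within each enriched region the expected strand profiles

λ₊(x) = ½ Σⱼ wⱼ k(sⱼ − x) + β,  λ₋(x) = ½ Σⱼ wⱼ k(x − sⱼ) + β

are fitted to the observed tag counts by maximizing the Poisson likelihood
over non-negative source intensities *wⱼ* on a grid, using multiplicative
Richardson–Lucy-style updates (optionally with an L1 sparsity penalty).
Local maxima of the fitted intensities are the called binding sites;
spurious calls are rejected by tag count, fold over input, and strand
balance.

**Exact Fisher test for one specific period.** For an equally spaced series
of even length *N* covering whole periods, the statistic is the periodogram
ordinate at the period of interest divided by the sum over all positive
frequencies (Nyquist included):

g = I(24 h) / Σₖ I(fₖ).

Under Gaussian white noise the interior ordinates are χ²₂ and the Nyquist
ordinate χ²₁, which gives the closed-form tail

p(g) = (1 − g)^(m−1) · (1 + 2c)^(−1/2),  c = g/(1 − g),  m = N/2 − 1.

The 24-h Fourier amplitude (F24) and the phase (ZT hour of the fitted
cosine's maximum) come from the same harmonic. Circular-phase utilities
include the circular mean and a Rao-style test for equality of polar
dispersions across groups.

**Tandem E-box HMM.** A hidden Markov model with background, GT-repeat
filter states, a 13-position E1 block (7 flank positions + the canonical
box CACGTG), an explicit-duration spacer of 4–20 bp, and a 13-position E2
block (the non-canonical box AACGTG + 7 flank positions), mirrored on the
reverse strand through a latent orientation. Training is weighted
Baum–Welch, each site window weighted by its tags at peak binding.
Classification is by constrained Viterbi log-odds in bits against the
background path, with single/tandem thresholds recomputed from the training
corpus; spaced weight matrices (13 + spacer + 13 columns) are extracted for
scanning.

**Motif-activity inference.** Mean-centered expression E_gt is regressed per
timepoint on conservation-weighted motif site counts N_gm
(likelihood-ratio PSWM scores summed over ±2,500-bp promoter windows, each
position weighted by C^0.05 with C the product of per-base conservation
over the motif footprint):

E_gt = Σₘ N_gm · A_mt + I_t + ε.

The inferred activities A_mt come with standard errors and a cyclic-activity
p-value from the same Fisher test.

**Synthetic data.** `generate_genome()`, `plant_sites()`,
`simulate_chip_tags()` and `simulate_expression()` generate toy genomes with
planted E1/E1-E2 elements, strand-specific circadian tags
(cosine-modulated site intensities, truncated-normal offset kernel,
uniform background, an input library), and matched expression matrices —
all with exact ground truth for testing.

## Worked example

A self-contained synthetic study (200-kb genome, 20 planted sites, two ChIP
libraries plus input at 2×10⁴ tags per library-timepoint):

```r
library(circaseq)

cfg <- default_config(outdir = tempfile("circaseq_demo_"), seed = 11)
cfg$simulate <- demo_simulation(genome_length = 2e5, n_sites = 20,
                                depth = 2e4)
res <- run_pipeline(cfg)

res$sites[order(-peak_signal)][1:5,
  .(position, peak_signal = round(peak_signal), phase = round(phase, 1),
    p = signif(p, 2), motif_class, motif_spacer)]
#>    position peak_signal phase      p motif_class motif_spacer
#> 1:    25380      267319   7.5 0.0360          E1           NA
#> 2:   137470      257683   8.2 0.0170        E1E2            7
#> 3:   179410      255275   5.3 0.0044        E1E2           10
#> 4:   111430      254674   6.7 0.0130        E1E2            7
#> 5:   177090      249255   5.3 0.0039        E1E2           10
```

`peak_signal` is the maximal per-timepoint signal in the ±250-bp window, in
tags per 10⁷ per library; `phase` is the ZT hour of peak binding and `p` the
exact Fisher specific-period p-value; `motif_class`/`motif_spacer` come from
the tandem HMM trained on these 20 site windows. Comparing against the
generator's truth table (`res$truth$sites`): the median distance between
called and planted positions is 3 bp and the median phase error 0.2 h. At
this deliberately small scale the HMM's spacer decoding is imperfect (two
planted elements decode with a 10-bp spacer); at the default demo scale
(1-Mb genome, 100 sites) classification of planted tandem elements is
essentially perfect.

A single time series:

```r
rhythm_stats(c(12.1, 18.4, 9.6, 4.1, 2.9, 7.2))
#> f24_amplitude  phase  g_statistic  p_value
#>        7.087  5.121        0.902    0.022
```

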