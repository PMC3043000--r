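---
title: "circaseq: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{circaseq: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

circaseq analyzes time-resolved transcription-factor ChIP-Seq from circadian
designs: six timepoints at 4-h intervals over one light-dark cycle, two ChIP
libraries plus one input-chromatin library. This vignette documents the
models, the tunable parameters, the numerical choices, and what the
synthetic-data tests do and do not establish.

## Tag processing

Mapped tags are 5′-end points. PCR de-duplication keeps one tag per
sequencing unit, genomic position and strand, where the *unit* is a library
at one timepoint: reads from the same library sequenced at different
timepoints are distinct sequencing runs and are never collapsed against
each other. Each unit is rescaled so its tags sum to 10⁷ ("tags per 10
million mapped"), and units covering the same timepoint are summed per
position and strand. Rescaling uses the de-duplicated (non-redundant)
totals. A direct consequence is that the genome-wide signal per timepoint is
fixed at 10⁷ per library, so only *relative* differences between loci and
background survive normalization — see the remarks on the synthetic
generator below.

Window quantification sums normalized weights of both strands over the
closed interval [center − h, center + h] (default h = 250 bp), clipped at
chromosome ends. Clipping rather than discarding near-end sites is an
interpretive choice; with realistic chromosome sizes it affects essentially
nothing.

## Region detection

Detection runs on the single track merging all timepoints, in sliding
windows (default 300 bp, 150-bp step). The ChIP count in a window is tested
against a Poisson rate equal to the depth-scaled local input count, floored
at the genome-wide input rate; p-values are Benjamini–Hochberg adjusted
(default level 0.01) and surviving windows are merged when they overlap.

The fold-enrichment floor defaults to 1.2 and is intentionally weak. A
window around a genuine point source also contains background tags, which
dilute the ratio of window counts to the input rate: with a background-heavy
library a real site of a few hundred tags can show a window fold below 2
while its Poisson p-value is astronomically small. The calibrated test is
therefore the primary criterion; the fold floor only guards against
near-flat enrichment. When the input track has zero coverage the detector
falls back to a uniform genome-wide rate and says so.

## Strand kernel and deconvolution

A point source at *s* yields plus-strand 5′ ends at *s − d* and minus-strand
ends at *s + d*, with *d* drawn from the fragment offset kernel. The kernel
is estimated, not assumed: the mean offset comes from maximizing the pooled
cross-correlation between plus and minus profiles over the strongest regions
(default 50 regions with at least 10 tags per strand), and the density from
the pooled per-tag offsets about each region's center, smoothed with a
normal-reference-bandwidth density estimate on an integer grid and
symmetrized between strands. No strand asymmetry is modeled.

Deconvolution fits, per region, non-negative source intensities $w_j$ on a
grid (default 10 bp) plus a flat background, maximizing the Poisson
likelihood of the observed strand counts under
$\lambda_\pm(x) = \tfrac12\sum_j w_j k(\pm(s_j - x)) + \beta$ by
multiplicative Richardson–Lucy updates. The updates preserve non-negativity,
ascend the likelihood monotonically, and at the penalty-free fixed point
conserve the total signal exactly (the suite checks ≤ 1% after a finite
iteration budget). Convergence is declared when the relative log-likelihood
change drops below 1e-8, with a 500-iteration default budget; regions that
do not converge are flagged with a warning and their (still valid,
monotonically improved) fit is used. An L1-style penalty is available but
defaults to zero.

Two numerical caveats are documented deliberately. First, with a smooth
kernel the likelihood is nearly flat under small redistributions of
intensity among neighboring grid points, so the multiplicative updates
sharpen a single source slowly; localization of the *maximum* is accurate
long before the mass fully concentrates. Second, kernel mismatch produces
small side lobes around a strong source. Site calling therefore takes local
maxima above both an absolute intensity floor and a relative floor (default
20% of the profile maximum), merges maxima closer than 100 bp keeping the
stronger (ties: leftmost), and passes calls to rejection filters: minimum
tags in the ±250-bp window (default 10), minimum fold over depth-scaled
input (default 1.2, same rationale as detection), and strand balance (each
strand at least 20% of site tags). Every rejection is logged with a reason.

## Rhythm statistics

For a series $x_t$ at timepoints $t$ (hours), the harmonic at the period of
interest (default 24 h) gives the amplitude and the phase — the ZT hour at
which the fitted cosine peaks; a flat series has amplitude 0 and missing
phase. The series mean is removed first; the zero frequency is not a
competing period.

The Fisher specific-period statistic is
$g = I_{24} / \sum_{k>0} I_k$ with the Nyquist ordinate included. For even
$N$ the Nyquist ordinate has one degree of freedom while interior ordinates
have two, and the exact null tail is

$$p(g) = (1-g)^{m-1}\,(1+2c)^{-1/2},\qquad c = \frac{g}{1-g},\qquad
m = N/2 - 1 .$$

The formula was certified against Monte-Carlo simulation (200,000 null
series at N = 6 and N = 12: rejection at the 0.05 level within half a
percent of nominal, Kolmogorov–Smirnov uniformity p > 0.25) before being
frozen into the package, and the test suite re-checks calibration on 20,000
null series. Zero-variance series return p = 1 by convention. Raw p < 0.05
is the default rhythmicity call, matching common practice for these designs;
a Benjamini–Hochberg column is available.

The Rao-style homogeneity test for circular dispersions compares per-group
mean resultant lengths with delta-method variances through a chi-square
homogeneity statistic; it is rotation invariant, and a permutation variant
is provided for small groups. Simulated calibration at the 0.05 level was
0.053 (n = 20 per group) and 0.059 (n = 50).

## The tandem E-box model

The HMM has a background state, a two-state filter block that absorbs
GT-repeat signal, an E1 block of 13 emitting positions (7 flank positions,
then the canonical box CACGTG), an explicit-duration spacer supporting 4–20
bp, and an E2 block of 13 emitting positions (the non-canonical box AACGTG,
then 7 flank positions). With the hexamers placed at the inner edges of
their blocks, the decoded spacer duration equals the bp gap between the two
boxes, and the extracted spaced matrix is exactly E1(13) + spacer + E2(13)
columns. Explicit duration states rather than a geometric self-loop were
chosen because the biology of interest is a *specific* 6–7-bp spacer
preference that a geometric law would blur.

Training is Baum–Welch with each sequence's expected counts multiplied by
its weight (tags at peak binding). The reverse strand shares tied parameters
through a latent orientation: each window enters as an equal-prior mixture
of its forward and reverse-complement readings, and expected counts are
weighted by the posterior orientation. The weighted log-likelihood ascends
monotonically and training stops when the gain drops below 1e-3 (default
budget 50 iterations). Initialization is deterministic: hexamer emissions
at 0.7 on the consensus letter, flanks and spacer at the corpus base
composition, uniform spacer durations. Degenerate (N) bases emit neutrally
in every state. Emission updates carry a 0.1 pseudocount.

Classification scores a window by constrained Viterbi log-odds in bits
against the pure-background path, maximized over orientation: the "tandem"
score requires completing an E2 block, the "single" score an E1 block not
followed by a spacer. A window is E1E2 if the tandem score reaches the
tandem threshold, else E1 if the single score reaches the single threshold,
else NONE. Thresholds are recomputed on each training corpus as the midpoint
between the median score of decoded hits and the median score of non-hits
(configured defaults 7.2 and 10.2 bits stand in when a corpus decodes no
hits). The forward likelihood is verified against brute-force path
enumeration on short sequences, and classification is strand symmetric by
construction.

The PSWM scan used for the occupancy autocorrelation places 0.96875 on the
consensus letter per column with the remaining mass shared by the other
letters (columns normalize to 1). Occupancies are a logistic transform of
the log-odds score with the threshold at the worst single-mismatch word and
a default slope of 1 per bit. The autocorrelation null band circularly
shifts each profile; note this preserves most within-profile spacing
structure (only pairs split across the wrap contribute), so the band is
stringent — planted tandem spacings still exceed it, which is what the test
asserts.

## Annotation

Sites are points without orientation. Nearest-TSS assignment is
transcript-level, with |distance| ties broken by lexicographic transcript id
for determinism. Distances are signed in transcript orientation (negative =
upstream). Categories: promoter within ±2 kb of the TSS; upstream −10 to −2
kb; gene from +2 kb to the polyadenylation site; downstream to +10 kb;
other. Conservation is the maximum score over ±50 bp, missing positions
scoring 0. The expressed-gene filter keeps transcripts strictly above a
percentile (default the median) of the supplied expression distribution.
Target assignment keeps the nearest TSS only within 10 kb, optionally
coding-only. Control regions sit 500 bp downstream of the site in the
genome's + direction. GTF's 1-based closed coordinates are converted to
0-based at the boundary.

## Motif activities

Site counts $N_{gm}$ sum likelihood ratios of each PSWM against the
background over both strands of a promoter window, each position weighted by
$C^{0.05}$ where $C$ is the product of per-base conservation over the motif
footprint — the footprint, not the whole window, because the weight
multiplies each site's likelihood. Activities solve
$E_{gt} = \sum_m N_{gm} A_{mt} + I_t + \varepsilon$ by ordinary least
squares independently per timepoint (the model has no coupling across
time), after per-gene mean-centering of expression; standard errors come
from the per-timepoint residual variance. Because centering removes each
motif's time-mean contribution, activities are identified up to per-motif
constants; cosine-shaped activities (zero time-mean) are identified exactly,
which is also why the parameter-recovery tests use them. Rank deficiency is
reported with the offending columns. No regularized variant is provided —
the model is plain least squares by design.

## The synthetic generator and what the tests show

The generator realizes exactly the generative model the deconvolution
inverts: point sources with cosine-modulated intensities
$B\,\max(0, 1 + A\cos(2\pi(t-\phi)/24))$ (clipped at zero so intensities
stay valid rates), strand ± with probability ½, truncated-normal offsets
(default mean 100 bp, sd 25 bp — free simulation knobs, since real
fragment-length distributions vary by protocol), uniform background, and an
input library of pure background. Planted E1 sites write CACGTG; E1E2 sites
write CACGTG + spacer + AACGTG, giving exact, quotable fixtures. Default
study conditions: phases normal about ZT6 (sd 1.5 h), relative amplitudes
uniform in [0.5, 1], strengths uniform in [100, 1000] tags, spacers 6–7 bp.

Two generator-level facts shape the defaults. First, because each
library-timepoint is renormalized to 10⁷, a common rhythm shared by most
sites cancels out of the normalized signal unless site tags are a minority
of each library; the demo therefore uses a background fraction of 0.8,
which is also the realistic regime (the strongest liver sites hold on the
order of 200 tags per 10⁷ mapped). Second, at high per-site depth PCR
de-duplication saturates: unique-position counts compress the profile
shape. Kernel re-estimation from the same data absorbs this, which is why
the pipeline estimates its kernel rather than assuming the generative one.

The default demonstration — 1-Mb genome, 100 sites, two ChIP libraries at
10⁵ tags per library-timepoint — runs in about a minute on one CPU. The
reduced scales used elsewhere in the test suite (e.g. 200-kb/20-site runs,
200-sequence HMM corpora, 20,000-series null calibrations) were chosen as
the smallest sizes at which the statistical assertions are stable.

What passing tests show: the pipeline inverts its own generative model —
detection, localization (median error well under 25 bp), spacer and class
recovery, phase recovery within fractions of an hour, activity recovery
with correlation above 0.95 at realistic noise. What they do not show:
robustness to chromatin-accessibility structure in the background,
sequencing error, mappability artifacts, fragment-length heterogeneity, or
motif variants diverging from the planted consensus — none of which the
generator emulates. Results on real data depend on those factors; the
synthetic truth certifies correctness of the machinery, not field accuracy.

## Known limitations

- The deconvolution grid (default 10 bp) bounds localization precision;
  sub-grid refinement is not attempted.
- Explicit spacer durations cap at 20 bp; longer composite elements decode
  as two singles.
- The Rao chi-square test is asymptotic; for groups under ~20 phases use
  the permutation variant.
- The detector is a simplified Poisson sliding-window scan; externally
  produced region sets can be substituted upstream by calling
  `deconvolve_region()` on any region table.
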