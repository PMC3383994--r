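---
title: "Estimating embedded-ribonucleotide frequency from fragmentation gels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating embedded-ribonucleotide frequency from fragmentation gels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribofrag)
```

## The measurement problem

Replicative DNA polymerases occasionally incorporate ribonucleotides instead
of deoxyribonucleotides. In cells lacking RNase H2, the enzyme that initiates
their removal, single and double ribonucleotides accumulate in genomic DNA.
Each embedded ribonucleotide carries a 2'-OH that renders the phosphodiester
bond on its 3' side alkali-labile, so hot NaOH converts every ribonucleotide
site into a single-strand break. Running treated DNA on a denaturing gel
therefore turns an invisible chemical lesion into a measurable shift in the
fragment-size distribution, and the *excess* fragmentation of mutant relative
to control DNA counts the lesions.

The chain from gel image to frequency estimate is the core of this package:

1. densitometry of each lane gives intensity as a function of migration
   distance;
2. a ladder lane calibrates distance against log fragment size;
3. the intensity profile is transformed into a fragment-size histogram,
   exploiting that staining intensity is proportional to DNA *mass*
   (nucleotides), not molecule count;
4. each lane is scaled to a common nucleotide total (1e9 nt by default), and
   dividing each bin's mass by its fragment size converts mass to *molecule
   counts*;
5. since every additional cut creates exactly one additional fragment, the
   difference in total fragment count between mutant and control lanes *is*
   the number of extra cleavable sites per 1e9 nt.

Because the original gel scans are not public, the package pairs this
analysis chain with a forward simulator of the whole experiment, and validates
the chain by parameter recovery on synthetic data.

## The forward model

### Lesion placement

A genome is a duplex of length $L$ with lesions at 1-based coordinates; no
base sequence is stored, which keeps $10^9$-nt genomes cheap (the measurement
is purely positional). Per strand, ribonucleotide-run counts are Poisson with
mean $\lambda_r L$, nick counts Poisson with mean $\lambda_n L$, and
extraction shear contributes Poisson double-strand breaks (mean
$\lambda_s L$) stored as coincident nicks on both strands. Run lengths are 1
with probability 0.9 and 2 with probability 0.1, reflecting the enzymatic
evidence that accumulated runs are mono- or di-ribonucleotides. Overlapping
draws are resolved by rejection re-draw; at the rates involved
($\lambda \ll 1/\text{run length}$) this changes nothing statistically.

The defaults are the study conditions: $\lambda_r = 1/7600$ per nt per strand
(the measured frequency in RNase H2-null fibroblasts), shear every 30 kb
(a typical fragment size for phenol-extracted genomic DNA), no pre-existing
nicks. A `rate_multiplier` scales $\lambda_r$ and $\lambda_n$ to emulate
hydroxyurea, which raises incorporation by depleting dNTP pools; it
deliberately does not scale shear, which is a property of extraction, not of
replication.

Each simulated genome draws three independent RNG substreams (ribo, nick,
shear) from its seed. A mutant genome and its shear-only control generated
from the same seed therefore share identical shear breaks, which makes
"native gels cannot distinguish them" an exact identity rather than a
distributional statement.

### Cleavage agents

An agent either cleaves every ribo run of at least `min_run` consecutive
ribonucleotides, replacing the run by one nick, or adds sequence-nonspecific
Poisson nicks (the abstract nickase mode used for the 3.7-kb and 11-kb
fragmentation rulers):

| agent | min_run | cut side |
|---|---|---|
| alkali | 1 | 3' of the run's last ribonucleotide |
| RNase H2 | 1 | 5' of the run's first ribonucleotide |
| RNase HI | 3 | 5' |

One cut per run suffices for fragment statistics. A consequence of the
single-cut convention worth knowing: alkali and RNase H2 cut positions differ
by the run length (1 or 2 nt), so in genomic order the *interior* fragments
of the two digests differ by at most 1 nt, while the two chromosome-end
fragments of a strand can differ by up to 2 nt. The tests assert exactly
this.

### Electrophoresis modes

Denaturing mode separates strands: fragments run between consecutive nicks on
each strand, and intact ribonucleotides -- being covalent -- are not breaks.
Native mode keeps the duplex: only double-strand breaks fragment the
molecule, defined as opposing-strand nicks within `ds_break_window` nt
(default 10 nt -- small enough that random coincidence is negligible at the
simulated rates, large enough that deliberately opposed nicks register).
Per-strand fragment lengths always sum exactly to the genome length.

### Gel rendering

Migration distance is affine in log size, $d = \alpha + \beta \ln s$ with
$\beta < 0$; each fragment contributes a Gaussian band (sd `band_sigma`,
size-independent in distance units) of area proportional to its length;
uniform background and truncated-Gaussian scanner noise are added. The
defaults ($\alpha = 175$, $\beta = -12$, 512 grid points on $[5, 130]$) place
roughly 45 nt to 1.4 Mb on the grid, containing essentially all mass of both
the 30-kb control and the ~6-kb digested mutant lanes; these values were
fixed from that coverage requirement, before any recovery experiment, and
mass migrating off-grid is detected and reported rather than silently lost.
`run_config()` emulates equal lane loading -- the same total stain mass per
lane regardless of simulated genome size -- because that is how gels are
actually run, and because it keeps the signal-to-background ratio of reduced
test genomes representative of the full-scale conditions.

## The inverse chain and its numerical choices

**Background.** A single constant is subtracted per lane. The automatic level
is the lane's 5th percentile: with the band spread and grid used here the
outer ~10% of each lane is signal-free, so the 5th percentile reads the
background plus a small noise quantile. The residual error is uniform in
distance and cancels almost entirely in the mutant-minus-control subtraction.

**Calibration.** Ordinary least squares of distance on log size over the
supervised ladder peaks (`lm(distance ~ log(size))`). Extrapolation beyond
the fitted ladder range follows the same line and is flagged, not forbidden:
the largest fragments on these gels genuinely exceed the largest standard.

**Smoothing.** A cubic smoothing spline with 40 equivalent degrees of freedom
in the distance domain, applied before the size transform. On 512-point
traces, 40 df tracks every feature a real lane profile has while suppressing
scanner noise; the value is exposed because its effect depends on grid
density.

**Size transform.** Changing variables $s = e^{(d-\alpha)/\beta}$ must
conserve mass, which forces the Jacobian $|\beta|/s$; without it the
"total nucleotides" of a lane would depend on gel geometry and the fixed
nucleotide scaling would be meaningless. The implementation integrates the
trace over the distance interval corresponding to each size bin (via the
cumulative trapezoid), which applies the Jacobian implicitly and conserves
mass to within interpolation error (< 1%). Bins are log-spaced -- uniform in
migration distance, matching gel resolution -- over 200 nt to 100 kb by
default, with off-window mass accumulated into the edge bins and reported.

**Counting.** Counts per bin are mass divided by the bin's geometric mid
size, the unbiased representative for log-spaced bins.

## The two estimators

**Analytic subtraction.** After normalizing both lanes to $10^9$ nt,
$\Delta N = N_\text{mut} - N_\text{ctl}$ extra fragments means $\Delta N$
extra cuts, a rate $\Delta N / 10^9$ per nt, and a spacing
$10^9 / \Delta N$. Replicate pairs are reported as mean spacing ± SD. A
non-positive $\Delta N$ -- expected under noise when the true rate is near
zero -- reports rate 0 with a diagnostic rather than failing.

**Random-cut simulation.** The control distribution is transformed into the
mutant one by adding $n$ uniform random cuts to fragments drawn from the
control histogram, and $n$ is fitted by hill climbing (default 50
iterations) on the Manhattan (L1) distance between the smoothed simulated and
smoothed target histograms. The search uses multiplicative proposals
$n(1 \pm \text{step})$ with the step halved on rejection, initialized from
the analytic estimate. The objective is stochastic, so all evaluations share
one pre-drawn cut pool (common random numbers); this makes the objective a
deterministic function of $n$ and the accepted objective non-increasing by
construction. Smoothing is applied to both histograms in the size domain with
the same 40-df spline; smoothing the distance-domain trace instead would be
defensible, but the size domain is where the objective's histograms live.

**Per-cell arithmetic.** With $2.5 \times 10^9$ bp haploid, diploid, two
strands: $10^{10}$ nt per nucleus, so a 1 in 7,600 frequency implies
$10^{10}/7600 \approx 1.3$ million sites per cell. Mono- and di-runs are
counted once each ("sites" = "runs"). The expected number of *directly
opposed* ribonucleotide pairs under independence is
$\text{bp} \times \text{rate}^2$; the base-pair count is an explicit
parameter because the haploid and diploid versions differ by a factor of two
(about 43 vs 87 at 1 in 7,600) and the choice is a modelling decision, not a
formula.

## Motif spacing

Nicking endonucleases provide fragmentation-scale rulers: an enzyme cutting
every ~11 kb (7-base site) or ~3.7 kb (6-base site) brackets the mutant
lane's fragmentation. `scan_motif()` counts recognition sites on both strands
(overlaps included -- each site is an independent nick opportunity; `N` never
matches), and `expected_spacing_iid()` gives the closed-form expectation
$1/(2\prod_i p_i)$ for non-palindromic sites under independent bases
(factor 1 for palindromes, which coincide with their own reverse complement).
Spacing is reported per duplex with both strands pooled. At mouse-like GC
content (0.417), a 7-base site with four G/C and three A/T letters is
expected every ~10.7 kb -- the order of magnitude of the genome-derived 11 kb,
which itself depends on the reference assembly and is not an equality target.

## What the synthetic data does and does not show

The generator reproduces the features the estimators rely on: Poisson lesion
placement, agent specificity, mass-proportional staining, log-size migration
with band spread, background and scanner noise, and equal lane loading. It
deliberately omits sequence context (incorporation hotspots), partial
digestion, gel-edge compression at limiting mobility, and non-linear scanner
response (assumed linear). Parameter recovery on this synthetic data
therefore validates the *analysis chain* -- that the pipeline is unbiased
when its assumptions hold -- not the biological assumptions themselves. In
particular a real-data estimate remains a lower bound: any cleavage-resistant
or unresolved sites are uncounted.

## Problem sizes and reproducibility

Full-scale runs (the acceptance script and the end-to-end tests) use
$10^9$-nt genomes and four replicate pairs, matching the scale the method was
designed for; unit tests run on $10^7$-$10^8$-nt genomes, which is
statistically equivalent here because every lane is normalized to the same
nucleotide total before estimation. All randomness flows from one root seed
through named substreams per lane, so every artifact file is regenerable from
its configuration, and re-running with the same seed is byte-identical.

```{r example, eval = FALSE}
cfg <- run_config(seed = 1)            # 1e9 nt, 4 replicate pairs, alkali
generate_dataset(cfg, "lanes")
res <- run_pipeline("lanes", cfg)
summary(res$estimate)
```

## Known limitations

* The hill climber is a local search on a 1-D integer parameter; with common
  random numbers and an analytic initialization it converges reliably in the
  tested regimes, but a multimodal target (e.g. grossly mis-specified start
  distribution) could stall it.
* The 5th-percentile background rule assumes part of the lane is signal-free;
  a lane saturated end-to-end would be over-subtracted (the level check
  errors only when the level exceeds the lane maximum).
* Counts in the smallest size bins are the ratio of two small quantities;
  the 200-nt lower window bound exists to keep division noise bounded, and
  moving it much lower degrades the estimators.
* Native-mode double-strand-break matching is greedy two-pointer; for the
  simulated rates (coincident shear nicks, window 10 nt) it is exact, but
  pathological nick clusters denser than the window could be matched
  differently by an optimal matcher.
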