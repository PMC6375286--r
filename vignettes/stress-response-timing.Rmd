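---
title: "Timing of single-cell stress responses: model, measures and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Timing of single-cell stress responses: model, measures and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stresstiming)
```

## The statistical-kinetics model

A stress response is modelled as the completion of a chain of discrete
molecular events — stressor uptake, transcription-factor activation,
promoter binding, production of the first detectable reporter molecules.
Each step is assumed memory-less, i.e. its waiting time is exponential.
For a linear chain of $n$ equally fast irreversible steps with chain mean
$\mu$, the completion time is Erlang-distributed (gamma with integer shape
$n$ and scale $\mu/n$), with coefficient of variation $1/\sqrt{n}$. For
general architectures (reversible steps, branches, loops) the relation
weakens to an inequality: the response-time mean $\mu_t$ and standard
deviation $\sigma_t$ satisfy $\sigma_t/\mu_t \ge 1/\sqrt{n}$. Two
consequences organize the whole analysis:

* the randomness parameter $R = (\sigma_t/\mu_t)^2$ bounds the number of
  rate-limiting steps from below, $n \ge 1/R$, and `randomness_and_steps()`
  reports $\lceil 1/R \rceil$ as the effective step count (rounding *up*,
  which reproduces the three anchor cases $0.36 \to 8$, $0.54 \to 4$,
  $0.165 \to 37$);
* since $n \ge 1$, $\sigma_t \le \mu_t$ always: no response can be more
  variable than a single exponential step of the same mean. Across
  promoters the smallest observed $\sigma_t/\mu_t$ defines the precision
  limit, a line through the origin that `precision_limit()` anchors at the
  most precise promoter.

The estimate is deliberately conservative. Many fast steps (e.g. single
nucleotide additions) contribute negligible variance and are invisible to
it; only steps of comparable, slow duration register.

Model consistency is checked as in the original procedure: `fit_erlang()`
fits a gamma by maximum likelihood (digamma-based Newton iteration on the
shape, started from the closed-form approximation), rounds the shape
half-up to an integer, and `ks_consistency()` simulates many datasets of
the same size from the rounded fit, comparing each to the data with a
two-sample Kolmogorov–Smirnov test at $\alpha = 0.05$. The reported
fraction of non-rejections is biased upward because the fit is estimated
from the same data it is tested against; this is documented, not
corrected, matching the original procedure.

## Response-time measures

Expression of a tracked cell is its total fluorescence divided by its total
area, minus the per-pixel environment background and minus
autofluorescence (a constant, or a per-frame control-strain mean when
autofluorescence drifts). Corrected values may be negative and are *not*
clamped — clamping would bias threshold crossings near zero.

The primary measure follows the colony-threshold definition: among
trajectories whose maximum post-stress expression exceeds 3× their
pre-stress baseline ("responders"), the pointwise median trace is formed on
post-stress frames, and the threshold is its minimum plus 25% of its range.
The phrase "25% of the maximum expression (minus the minimum expression
after stress addition) of the median" admits more than one parse; we adopt
threshold = post-stress minimum of the median trace + 0.25 × its
post-stress range, which matches a normalized 0.25 line on
min–max-normalized traces. The 3-fold baseline is not defined in the
source procedure; we use the mean pre-stress expression floored at a
configurable $\epsilon$ (default 1 expression unit), since after
autofluorescence subtraction baselines near zero would otherwise make the
fold change explode.

Crossing times are linearly interpolated between the bracketing frames by
default (`interpolation = "frame"` reproduces frame-resolution readout); a
value exactly at threshold returns that frame's time; the first crossing
counts, with no persistence requirement. Trajectories that never reach the
threshold are flagged non-responders and excluded from timing statistics
but counted in the responder fraction. The alternative per-cell measure
(`measure = "halfmax"`) crosses half of each trajectory's own maximum.
Response times can be re-expressed in cumulative cell doublings
(`time_axis = "doublings"`), using the log2-area curve made continuous
across divisions by linear extrapolation through the last 3 pre-division
points (the "last few points" of the original description is unquantified;
3 is the default and configurable), anchored to 0 at stress addition and
smoothed with a window of 5 frames. Growth rates use Δlog(size)/Δt
smoothed with a window of 3. All moving averages are centered and shrink
symmetrically at the edges, which leaves linear series unchanged.

## Lineage-aware statistics

Every cell present at stress addition (a *founder*) spawns a subtree of
descendants whose traces share most of their history; pooling all final
cells would overstate the sample size. `subsample_trajectories()` draws,
per founder, one random root-to-leaf trajectory (uniform daughter choice at
each division) and repeats this S = 1000 times by default. `timing_summary()`
reports $\mu_t$ as the average over subsamples of per-sample means and
$\sigma_t$ as the average of per-sample standard deviations. The original
"bootstrapping in these 1,000 random samples" is ambiguous about nesting;
we bootstrap at the founder level (resampling founders with replacement,
re-averaging across the same subsamples) because founders are the units of
independence.

For dual reporters, `paired_correlation()` averages the per-subsample
Pearson coefficient and reports the median of the per-subsample two-sided
P-values. `strict_order_test()` formalizes "equally strict temporal order"
— which the source leaves implicit — as the count of founders with
$t_B > t_A$; ties count as non-ordered. Within each subsample the
channel-B times are re-paired at random (1000 permutations by default,
exhaustive enumeration when ≤ 7 pairs, where all $n! \le 5040$ pairings
are cheaper than sampling) and the fraction of pairings at least as
ordered as observed is averaged over subsamples. Note that when the two
marginal distributions do not overlap, every pairing is fully ordered and
the P-value is 1 by construction: strict order is only *evidence* of a
shared chain when the marginals overlap.

All stochastic procedures take explicit seeds; subsampling, bootstrap and
permutation streams are derived independently from a master seed with
`derive_seed()`, so no stage perturbs another's stream or the caller's RNG.

## The synthetic-data generator

`generate_dataset()` emulates what segmentation and tracking software
tabulates from microcolony movies: one row per cell per frame with lineage
links, areas and per-channel total fluorescence. Cells grow exponentially
at per-cell rates drawn from a normal truncated at zero (heterogeneity
distribution unspecified in the source; truncated normal is standard and
configurable), divide when reaching `division_size_ratio` × birth size
with lognormal ratio noise, and split into equal daughters. Frames follow
a fixed grid (default 15 min within the 10–20 min range typical of such
experiments); time zero is stress addition.

Latent activation times are a founder-lineage property: one draw per
founder from the Erlang chain (or a serial/parallel dual-chain
architecture), inherited by all descendants, optionally jittered per
division (zero-mean Gaussian, sd `lineage_jitter_sd`, truncated at 0).
How real lineages inherit response timing is not known quantitatively;
jitter 0 (perfect inheritance) is the default, and tests exercise both.
Reporters convert activation into fluorescence: constant per-cell
production starting `maturation_time` after activation (~10 min for fast
YFP/CFP variants, ~40 min mCherry-like), attenuation by
`bleach_per_frame` at every imaging frame (up to 3% per frame for YFP,
0.5% for CFP; over 40 frames at 3% the retained fraction is
$0.97^{40} \approx 0.30$), partitioning proportional to daughter size at
division (signal conservation), plus autofluorescence with optional linear
drift, constant per-pixel background, and Gaussian measurement noise on
totals. Shot noise, bleed-through, focus drift, spatial colony effects and
signal diffusion between neighbours are deliberately out of scope, so
passing tests demonstrate correctness of the *analysis logic* under the
model's assumptions, not robustness to every imaging artifact of real
data.

### The reporter's threshold-climb offset

A detected response time is the latent activation time plus a reporter
offset: the maturation delay plus the time the rendered expression needs
to climb from baseline to the colony threshold. With constant per-cell
production and ordinary division, colony-wide production scales with cell
number and per-area expression saturates on the growth timescale $1/g$,
putting the 25% threshold roughly $0.29/g$ after activation. When cells
elongate but delay division — as happens under DNA-damaging antibiotics,
where the SOS response inhibits septation and cells filament — per-cell
amount grows linearly against exponentially growing area, the trace peaks
at $1/g$, and the climb shrinks to about $0.1/g$, sub-frame for elongation
rates above ~0.5 h⁻¹. The recovery tests therefore use the filamentation
regime (division at 8× birth size): there, detected times equal latent
times up to a sub-frame offset, exactly constant across all descendants of
a founder, and the full pipeline on a true 8-step chain with 200 founders
returns a step count of 8 (the climb inflates $\mu_t$ by ~0.2 h and its
mild activation-time dependence inflates $\sigma_t$ slightly; the two
biases partially cancel in $1/R$). Under ordinary division the measured
$\mu_t$ includes a larger climb, as real measured response times do — the
step-count estimate then describes the measured response, including
reporter kinetics, rather than the latent chain alone.

## Numerical choices and degenerate inputs

* `ceiling(1/R)` is computed on a value rounded to 9 decimals first, so
  ratios exactly $1/\sqrt{k}$ return $k$ despite floating-point noise.
* $\sigma_t = 0$ yields a flagged unbounded estimate, not a number.
* Gamma ML: Newton on $\log k - \psi(k) = s$ with halving on negative
  proposals; degenerate samples (zero log-spread) are rejected with an
  error; the scale is refit at the rounded shape so the fitted mean equals
  the sample mean.
* The ordering statistic treats ties $t_A = t_B$ as non-ordered.
* Zero-variance subsamples are skipped (with a warning) in correlations;
  colonies whose responder median trace has zero range are errors naming
  the colony.
* On the $\sigma_t \le \mu_t$ bound: the *sample* CV of an exponential
  straddles 1 (a sample of a few hundred draws exceeds it almost half the
  time), so the bound is checked on measured response sets — latent Erlang
  times plus the non-negative reporter offset — where it holds for every
  chain length, rather than on raw $n = 1$ draws where no finite-sample
  guarantee exists.

## Problem sizes

The test suite and the acceptance script run at desk scale, chosen to keep
Monte-Carlo error well inside the asserted tolerances: $10^5$ draws for
CV recovery ($3/\sqrt{N} \approx 0.01$), $2 \times 10^5$ for shape-37
recovery (ML shape SE $\approx k\sqrt{2/N} \approx 0.12$, so integer
rounding is safe), 200 founders for pipeline step-count recovery, 1000 KS
simulations at $n = 100$ cells, and subsample/bootstrap counts of 50–500
in tests versus the 1000 defaults. The defaults remain the recommended
analysis settings.

## Known limitations

* The step-count bound is tight only for linear chains of equal-rate
  irreversible steps; for real regulatory cascades it is a lower bound and
  the "effective" count conflates promoter, reporter and detection steps.
* Published per-promoter values that depend on the original raw microscopy
  data (specific correlations, permutation P-values, responder fractions)
  are procedure-reproduced here on synthetic data only; the raw data are
  not deposited.
* The error bars of subsample-averaged quantities understate
  founder-to-founder variability when lineage jitter is large, since
  subsamples share founders.
* `fit_erlang()` assumes a common offset-free Erlang; measured response
  sets include the reporter offset, which inflates the fitted shape when
  the offset is comparable to the latent mean.
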