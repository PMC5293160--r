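---
title: "Living vector fields: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Living vector fields: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`galfield` analyses single-cell time-lapse trajectories of the yeast
galactose network's two positive transducers, Gal3p and Gal1p, as a flow
on their joint expression state space. This vignette is the package's
account of the underlying models, the choices behind every tunable
parameter, and the limits of what the bundled synthetic data can show.

## The scientific picture

When budding yeast meet galactose, Gal3p (and, more weakly, Gal1p)
relieve Gal80p repression of Gal4p, which drives transcription of the
GAL genes — including *GAL3* and *GAL1* themselves. Either transducer is
therefore sufficient to accelerate the induction of both: a positive
feedback loop. Cells arriving from different nutrient histories carry
different initial transducer stocks. After growth on glycerol they have
some Gal3p; after a short (~12 h) glucose interruption of a previous
induction ("reinduction") they retain Gal1p; after long-term glucose
repression (LTGR) they have essentially neither, and must wait for rare
stochastic molecular events to *bootstrap* the loop — a long, highly
variable delay that produces a transiently bimodal population.

The package's central object is the empirical ("living") vector field:
cells are placed on the (Gal3p %, Gal1p %) plane, the plane is divided
into bins, and each bin's member cells — every (cell, frame) visit that
is also tracked into the next fluorescence frame — contribute one
velocity (finite difference over one 20-min frame). The per-bin mean
velocity and the circular variance of member directions summarize the
flow. Under the bootstrapping picture the flow has an unstable fixed
point near (0%, 0%), a "sticky" corner where LTGR cells linger, and a
stable fixed point near (100%, 100%) where synthesis balances decay.

## Pipeline stages and their rules

1. **Quantification.** Per-cell pixel samples are background-corrected
   by the frame's median non-cell intensity. Puncta (small bright
   aggregates) are rejected in two steps: pixel values are scaled to
   [0, 1] and the adjusted Fisher–Pearson skewness computed; if it
   exceeds 1.5, pixels above `median + 7 * MAD` (plain median absolute
   deviation of the original values, no 1.4826 consistency factor — the
   rule is stated in raw MAD units) are removed, in a single pass. A
   constant pixel set, or one with MAD = 0, is left untouched and
   flagged: the threshold is undefined there and any removal would be
   arbitrary. Cells tracked for fewer than five bright-field frames are
   dropped as segmentation artifacts. Finally every frame is re-zeroed
   on the median of its reporter-free control cells; a frame with fewer
   than 50 controls is excluded with a logged reason, never silently
   patched.

2. **Trajectories.** Each cell's series is smoothed by a Gaussian
   kernel (sd `sigma` = 1 frame, truncated at ±3 sd) followed by
   local-linear loess with a 5-point span. Boundaries use point (odd)
   reflection about the end values, which preserves constants and
   straight lines exactly; mirror padding would bias a linear ramp at
   the edges. Series shorter than twice the span get the kernel stage
   only (a local-linear fit is ill-conditioned there); series under 3
   points are returned unsmoothed with a flag. Post-peak artifacts
   (death, photobleaching, tracking errors) are removed when, after a
   channel's global peak (earliest frame on ties), more than 80% of
   steps are decreases, or any five consecutive frames fall
   monotonically by at least half the peak value. The 100% level of an
   experiment is the median over cells of each cell's maximum in the
   plateau window (default 900–1500 min, i.e. 15–25 h); 0% is the
   control median by construction. Values above 100% (overshoot in the
   glucose-mix conditions) and below 0% (baseline noise) are expected
   and preserved.

3. **Onset (lag) statistics are computed on unsmoothed values.** The
   normalized table carries both smoothed (`pct3`, `pct1`) and
   unsmoothed (`pct3_raw`, `pct1_raw`) percent columns. First-crossing
   times are taken from the raw columns: any pre-smoothing mixes the
   steep induction front into the flat foot of the trajectory and
   shifts the apparent crossing by on the order of one frame
   (≈ sigma² × curvature), which for fast-inducing conditions is a
   20–30% bias of the median lag. Smoothing still feeds everything it
   helps: plateau estimation, post-peak truncation, and the vector
   field. With this split, doubling or halving the kernel sd and the
   loess span moves lag-distribution medians by only a few percent
   (they enter only through the plateau estimate), which the test suite
   checks.

4. **Vector field.** Bins are 6% on each side, half-open, aligned so 0%
   is an edge; negative values (baseline noise) map to negative
   indices. A cell contributes to a bin every time it visits it,
   regardless of when. Velocities are per-channel finite differences
   over one frame; cells lost before the next frame contribute no
   velocity. Circular variance is `1 − Rbar` on unit direction vectors
   (magnitudes carry no weight); zero-velocity members have no
   direction and are excluded from the circular statistics but counted
   in `n`. Plotted arrows are half the mean velocity — purely a display
   convention; stored values are unscaled.

5. **Consistency statistic.** To ask where flows from different
   histories agree, the plateau period is first largely removed: the
   experiment frame F is the first frame by which 95% of the inducing
   cells (start < 10%, reach ≥ 75% of Gal1p plateau) have induced; a
   cell with at least five frames above 85% Gal1p before F is cut at
   its fifth such frame, all others at F. In each bin with at least 10
   member directions in *every* experiment, each experiment is
   resampled 500 times with replacement at size 10 and the mean
   direction of each replicate taken; for each replicate the circular
   standard deviation `sqrt(−2 log Rbar)` across the experiments' mean
   directions is computed, and the statistic is the mean of the 500
   values. Bins failing the membership threshold are absent, not zero.
   A fine map is obtained by bilinear interpolation between defined bin
   centers, never extrapolating; runs of defined bins along a single
   row or column are interpolated linearly along that line.

6. **Population statistics.** Lags are first upward crossings of 10% of
   plateau, linearly interpolated between bracketing frames; cells that
   never cross are censored at their last observation and excluded from
   ECDFs (their count is reported). ECDF bands are pointwise percentile
   intervals from 1000 resamples of cells. Viability uses Wilson
   intervals (no method is canonical; Wilson behaves well at the
   extremes). Movement medians — a surrogate for division in a
   confluent field — use per-cell displacements between consecutive
   2-min bright-field frames with a percentile bootstrap across cells.
   The plateau variance decomposition centers each
   (experiment, timepoint) — removing the shared time trend and the
   experiment fixed effect — then splits the remaining variance into a
   between-cell and a residual component with the one-way ANOVA
   method-of-moments estimator (unbalanced `n0` correction, negative
   estimates truncated at zero). Method of moments was chosen over REML
   because the bootstrap across cells (and the recovery simulations in
   the test suite) need thousands of refits; on data of this shape the
   two agree to well under a percentage point, which a test verifies
   against an independent REML fit. The reported quantity is
   `sigma²_cell / (sigma²_cell + sigma²_resid)` with a percentile
   bootstrap interval across cells. Cell identifiers are only unique
   within an experiment; the decomposition groups by
   (experiment, cell) accordingly.

## The synthetic generator

The generator exists so that every stage can be exercised against known
ground truth. Its deterministic core is a symmetric positive-feedback
model on the percent scale,

$$\frac{dg_i}{dt} = \beta\left(b + \frac{s^n}{K^n + s^n}\right) - \delta\, g_i,
\qquad s = g_3 + g_1,$$

with half-activation `K = 30%`, Hill exponent `n = 2`, basal fraction
`b = 0.02`, decay `delta = 0.02 / min` (a ~35-min protein
half-life-plus-dilution scale), and `beta` calibrated so (100, 100) is
an exact stable fixed point. With `b > 0` the origin is not a true
fixed point but a region of very slow growth: the deterministic transit
from (0, 0) to the 10% Gal3p crossing takes ≈ 2.1 h, which is the
observed lag scale of glucose-supplemented (mix) conditions — those
cells start at the origin with a transient synthesis boost
(`1 + 0.25 e^{−t/250 min}`) that also produces their characteristic
overshoot past 100%.

History presets set initial conditions: glycerol ≈ (3%, 0), reinduction
≈ (0, 3%) (detectable but small residual transducer), LTGR and mixes
≈ (0.3%, 0.3%). LTGR cells additionally *hold* at their initial state —
drift suppressed inside a 2% sticky radius — until a per-cell
exponential escape time with hazard 0.0017/min. Escape plus transit,
filtered through the demography below, puts the median lag of inducing
LTGR cells near the ~6 h scale and its IQR several-fold above the fast
conditions'; the escape hazard is a calibration choice (no quantitative
rate is available to match), set once so the population phenomenology —
lags, transient bimodality, lineage takeover — is reproduced, and
documented here rather than tuned per analysis.

Stochasticity: intrinsic noise is additive Gaussian on the 1-min
Euler–Maruyama step (0.3 %/√min, applied after escape; pre-escape cells
hold exactly, so the sticky region is literal); measurement noise
(1.5% of plateau) is added at readout,
`au = gain · (pct · m + ε) + baseline + autofluorescence`, with
channel gains 20 and 200 AU/% (Gal1p ~10× brighter). Cell-specific
plateau multipliers `m` are lognormal with CV 0.15, correlated 0.5
between channels — each cell has its own plateau, which is what the
variance decomposition measures. Demography: uninduced LTGR cells die
with hazard 10⁻³/min; induced cells (s ≥ 100%) divide with hazard
0.0029/min, daughters inheriting state and plateau multipliers; at the
field's carrying capacity (2× the initial experimental count) each
division washes a random non-control cell out of the field, as in a
confluent microchemostat. Washout plus differential death is what turns
early escape into lineage takeover. Control cells are reporter-free
(baseline + autofluorescence + noise only), held at constant number —
the experimental design aims the control density at ≥ 50 per frame, and
a configuration that cannot reach that is flagged. A small `bad` class
mimics intensely autofluorescent debris. Pixel rendering scatters ≥ 30
pixels around the cell's intensity with sd chosen so the pixel mean
reproduces the track-level noise, and injects puncta (one pixel ≥ 10×
the cell median, ~5% of pixels) with the configured probability.

What the generator does **not** emulate: segmentation and focus-stack
artifacts beyond the `bad` class and short tracks; mechanistic
Gal80p/Gal4p/Gal2p dynamics, glucose-repression biochemistry, or
resource budgets (the mix boost is a phenomenological stand-in);
spatial structure beyond random-walk positions whose mobility tracks
the induced fraction; photobleaching (negligible in the imaging regime
this models). Passing tests on synthetic data therefore validate the
*pipeline's* statistics and contracts, not biological claims about any
particular dataset.

## Validation designs and numerical choices

* **Drift and integrator.** The fixed points and local stability are
  asserted directly; the internal Euler stepper is cross-checked
  against an independent adaptive ODE integration of the same drift,
  and a noise-free trajectory from (30%, 0) reaches (100, 100) within
  1% by 900 min.
* **Field recovery.** 500 noise-free cells started on a uniform grid
  are binned and the estimated mean direction of every bin with ≥ 20
  members compared with the drift at the bin center. This check uses
  4%-wide bins: near the stable node the drift direction rotates by
  more than 50° across a 6% bin and members are dwell-weighted, so the
  bin-center value only represents the bin when the bin is small
  enough. The analysis default stays at 6%.
* **Consistency behaviour.** The three-condition comparison is
  generated with intrinsic noise and plateau CV at zero (small
  measurement noise retained): that is the literal "one shared drift" —
  with per-cell plateau multipliers every cell has its own fixed point,
  and with intrinsic noise the near-plateau bins are direction-noise
  dominated because drift speeds vanish there. At full default noise
  the qualitative pattern survives (corner high, mid-flow near zero)
  but bins adjacent to (100, 100) can exceed 0.2 rad; this is a known
  limitation of direction statistics near fixed points, visible in the
  bundled analysis scripts' output.
* **Worked values.** The quarter-turn circular variance
  `1 − √2/2`, the circular sd `√(log 2)`, and the three-experiment
  consistency value `√(−2 log(√5/3)) ≈ 0.767` rad (zero Monte-Carlo
  variance, since every resample of a constant set is constant) are
  asserted exactly against independent enumeration.
* **Recovery simulations.** Variance decomposition: 20 replicates of
  100 cells × 30 frames with true components 4 and 1 (fraction 0.8);
  the mean estimate must land within ±0.05 and the bootstrap interval
  cover 0.8 in ≥ 18/20. ECDF bands: 200 replicates of 50 exponential
  lags; the true median must fall inside the pointwise 95% band at its
  own grid point in ≥ 90%. Problem sizes throughout the suite (250–300
  cells per condition, 25 h runs) were chosen as the smallest that
  leave the population phenomena (bimodality, takeover) clearly
  resolved.
* **Degenerate inputs.** Constant pixel sets and zero-MAD sets are
  flagged, not filtered; empty direction sets are errors; `Rbar = 0`
  (perfectly dispersed directions) is an error rather than an infinite
  circular sd; plateau estimates require at least one in-window
  observation; an isolated consistency bin interpolates to itself.
* **Determinism.** Every stochastic routine takes a mandatory seed;
  the pipeline derives per-stage seeds from one master seed, and a
  rerun with the same configuration is byte-identical (the test suite
  compares file hashes). Output tables are written with 17 significant
  digits and parsed with exact strtod, so write/read round-trips
  reproduce doubles to the last bit.

## Known limitations

The consistency statistic conflates within-experiment direction noise
with between-experiment disagreement by construction (it is a spread of
resampled means); at sample size 10 it is high-variance, and near
fixed points it reflects noise rather than memory. First-crossing lags
are interval-censored at the 20-min frame spacing; the linear
interpolation between bracketing frames is a convention, and medians of
fast conditions are only a few frames, so they should be read with
±frame-scale uncertainty. The method-of-moments variance decomposition
assumes a one-way layout after centering; it does not model serial
correlation within cells, which inflates the intercell fraction when
trajectories drift during the plateau window (late-inducing LTGR cells
do). The generator's demography (Moran-style washout at capacity) is a
caricature of microchemostat crowding chosen for its bounded population
and deterministic accounting, not a mechanical model of cell pushing.
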