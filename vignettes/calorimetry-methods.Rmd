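---
title: "Methods: isolator-housed indirect calorimetry for gnotobiotic mice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: isolator-housed indirect calorimetry for gnotobiotic mice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gnotocal)
```

## The problem

Comparing energy metabolism across germ-free (GF), gnotobiotic (here
`OLIGO`, a defined multi-strain community) and conventionally colonized
(SPF) mice is uniquely confounded by anatomy: the germ-free cecum, swollen
with water and indigestible solutes, can reach 3 g — around 10 % of body
mass — and is metabolically inert. Any analysis that divides a
mass-dependent outcome by total body mass therefore manufactures group
differences out of inert mass. This package implements the full analysis
chain for isolator-housed metabolic-cage recordings of such cohorts:
datapoint quality control, gas-exchange computation, circadian
summarization, regression-based covariate normalization, energy-balance
accounting with propagated uncertainty, and bead-normalized bacterial
densities — together with a synthetic-cohort generator so that every stage
is testable without animal data.

## Data model and Zeitgeber time

A trace record is one 24-minute cage measurement: O~2~ and CO~2~
volume-fraction differentials against a reference chamber (O~2~ recorded
reference − cage so consumption is positive; CO~2~ cage − reference so
production is positive), a hydrogen concentration differential (ppm), food
and water consumed in the interval (g), and the extraction flow (default
0.4 L/min). Clock time is converted to Zeitgeber time (ZT): hours since
lights-on, with ZT 0–12 the light (resting/fasting) phase and ZT 12–24 the
dark (active/feeding) phase. Phase membership is half-open — ZT 12.0 is
dark — because a boundary convention has to be fixed for exact phase
additivity. The lights-on wall-clock time is a required configuration item
with no default: it is a property of the animal room, not of the data
format, and anchoring ZT to the first record instead would silently shift
phases whenever a recording starts mid-cycle.

## Quality control

Cage recordings fail in characteristic ways: balances report a 0.01 g
sentinel food event as noise, leaky bottles and dropped pellets produce
implausibly large intake values, and cage-seal leaks or clogged
pre-analyzer filters collapse gas differentials toward zero. The QC pass
applies, in order: (1) discard food values equal to the 0.01 g sentinel
(matched within half the balance resolution, since values pass through
text round-trips); (2) discard negative food, water, dO~2~ or dCO~2~;
(3) per mouse, discard food or water above Q75 + 1.5 IQR; (4) per mouse,
discard dO~2~ or dCO~2~ below Q25 − 1.5 IQR. Everything before each
mouse's first ZT 0 is discarded first, and any mouse-day that loses
strictly more than 20 % of its expected records (60 at 24-minute cadence)
is discarded wholesale, so daily aggregates always rest on a comparable
circadian grid.

Numerical conventions that needed fixing: quartiles use the type-7
(linear-interpolation) definition; thresholds are computed once, per mouse
pooled across days, on the records surviving steps 1–2, not iteratively
re-estimated — a single clean-up pass, because iterated IQR trimming is
not idempotent. A record failing several rules is attributed to the first
rule in the stated order, which makes the report's bookkeeping conserve:
input = surviving + the sum of per-rule removals. Pooling across days
(rather than per-day quartiles) is recorded in the report header. Mice
with fewer than 4 eligible records skip the quartile rules and are
flagged. Because thresholds and the first-ZT 0 instant are data-derived,
re-running QC on its own output would re-derive both from filtered data;
the report therefore carries them, and `run_qc(reuse = report)` is exactly
idempotent.

## Gas exchange

In a pull-mode cage the measured extraction flow is the *outlet* flow;
the inlet flow differs whenever O~2~ uptake and CO~2~ output are unequal.
The Haldane transformation recovers the inlet flow from inert-gas
conservation,
$$F_{in}\,(1 - F^{ref}_{O_2} - F^{ref}_{CO_2}) = F_{out}\,(1 - F^{cage}_{O_2} - F^{cage}_{CO_2}),$$
after which $VO_2 = F_{in} F^{ref}_{O_2} - F_{out} F^{cage}_{O_2}$ and
$VCO_2 = F_{out} F^{cage}_{CO_2} - F_{in} F^{ref}_{CO_2}$. Reference-air
fractions default to 0.2095 / 0.0004 and are configurable. Energy
expenditure uses the abbreviated Weir equation,
$EE = 3.941\,VO_2 + 1.106\,VCO_2$ kcal (volumes in L), without the
urinary-nitrogen term — standard for metabolic cages, which collect no
nitrogen data. Air is dehumidified upstream of the sensors, so no humidity
correction is applied, and no STP correction beyond the fixed-flow model.
A worked consequence of the flow imbalance worth knowing: at cage
fractions 0.2065 / 0.0025 against the default reference, the RER is
0.648, noticeably below the naive differential ratio 0.7 — the inlet
exceeds the outlet flow, depressing VCO~2~ below flow × dCO~2~. Tests pin
the analytic solution to an independent numeric mass-balance solver (total
volume balance + two species balances) to 10^−12^ relative on
physiologically valid atmospheres; with unconstrained differentials VO~2~
can pass through zero, where relative agreement is limited by catastrophic
cancellation rather than by either solver.

## Circadian summaries

Energy expenditure over a window is the trapezoid AUC of instantaneous
values; food intake is always cumulative (interval sums, half-open
windows). Windows that share an edge tile exactly: when the series
straddles a window edge the edge value is linearly interpolated, so
light AUC + dark AUC equals the full-day AUC to rounding error. Gaps left
by QC are bridged by a single trapezoid — the documented choice for
missing-data handling; no imputation is performed.

Continuous circadian profiles (RER, hydrogen) are first averaged at each
timepoint within each mouse across its recording days — never smoothed as
raw pooled points, which would weight mice by their number of recorded
days — and then fitted with a penalized cubic regression spline
(`mgcv::gam`, shrinkage basis `"cs"`, basis dimension 10, smoothing
parameter by GCV), evaluated on a uniform ZT grid. A cyclic basis (`"cc"`)
is available for strictly periodic profiles. One numerical caveat the test
suite documents: mgcv's cubic regression bases are *natural* splines
(linear beyond the boundary knots), so at basis dimension 10 the spline
space does not contain a global cubic polynomial; exact recovery of a
noiseless cubic (to 10^−6^) is obtained in the penalty→0 interpolation
regime, i.e. with the basis dimension near the number of distinct
timepoints. For the intended use — 60-point circadian averages with noise
— the default dimension 10 tracks a unit-amplitude sinusoid to a maximum
error well under 0.05.

## Covariate normalization

Energy expenditure scales with lean mass. The regression-based (ANCOVA)
adjustment fits `value ~ lean + fat + group` — a single-slope model with
the microbiota group as a qualitative covariate and no interactions — and
replaces each value by its residual plus the model prediction at the
grand-mean covariates. Three choices were genuinely open and are fixed as
follows. The grand means are mouse-weighted (pooled over all mice), not
group-weighted; the weighting is recorded in the fit object. The
prediction retains the mouse's own group coefficient, so group effects
survive adjustment and downstream group contrasts equal the ANCOVA
adjusted means. The fat covariate is the sum of dissected depots
(iBAT + iWAT + vWAT), not a composition-scanner readout, which misreads
the fluid-filled germ-free cecum. Degenerate (zero-variance) covariates
are dropped with a warning — their adjustment is identically zero — so
identical-covariate cohorts pass through unchanged. Allometric scaling
(mass^0.75^) is deliberately out of scope.

Hydrogen production is adjusted the same way with cecal mass (a proxy for
total gut microbial biomass) as the single covariate; germ-free mice have
no hydrogen signal and no biomass, so they are excluded from the fit
rather than anchoring a meaningless slope. The classical per-mass ratios
(total, total-without-cecum, lean) are provided for the comparison that
motivates the method: on a synthetic cohort with *identical* latent EE in
all groups, the total-mass ratio yields a significant dark-phase GF–SPF
difference while ANCOVA and the lean-mass ratio do not.

Group inference is one-way ANOVA with Tukey's honest significance test
(`stats::aov` + `stats::TukeyHSD`; Tukey–Kramer under imbalance), applied
to the adjusted per-mouse summaries. Running Tukey on adjusted values
rather than within the covariate model is the study design being mirrored
and is statistically approximate: adjusted values carry slightly less
variance than raw residuals warrant, and the measured family-wise Type-I
error under the null sits near 0.06 rather than exactly 0.05.

## Energy balance and uncertainty

All balance quantities are carried as mean ± combined standard uncertainty
(`uval`), propagated by the first-order Taylor method under independence
(Gaussian, linear sources; correlations unsupported). Group-level inputs
are the mean ± standard error over mice. Daily input is intake × 3.94
kcal/g chow; excretion is dry fecal mass × bomb-calorimetry energy
density; extraction is their difference (the means conserve exactly) and
percent extraction propagates through the exact partials of
$100\,(x-y)/x$. Reporting intervals are mean ± 1.96 u. Tests require every
propagated u to match a 10^6^-draw Monte-Carlo SD within 2 % for relative
uncertainties ≤ 10 % — the regime where first-order propagation is
trustworthy; it degrades for larger relative errors or strongly nonlinear
derived quantities.

The microbial contribution to fecal energy is cell density × per-cell dry
mass (2.26 × 10^−13^ g) × energy per gram of dry bacterial mass
(4.58 kcal/g). With densities of 1.1 × 10^11^ and 1.6 × 10^11^ cells/g
this gives 0.11 and 0.17 kcal/g — the scale of the gap between germ-free
(3.7 kcal/g) and colonized (4.0 kcal/g) fecal energy densities. The
estimator applies a per-gram-wet-cecal-content density to
per-gram-dry-feces energy; this unit slippage is deliberate (it reproduces
the published arithmetic) and is surfaced as a warning.

## Cytometry

Absolute bacterial density comes from bead normalization: bacteria and
counting beads are acquired from the same stained mix, so events-per-bead
× bead concentration gives cells/µL without knowing the acquired volume;
the dilution chain (mix volume / homogenate aliquot / homogenate volume /
homogenized mass) scales to cells per gram of content. Every factor is an
explicit assay parameter — the mix volume in particular varies between
labs and has no universal default worth hard-coding. Samples at or below
the blank density (germ-free negative controls set the gates) are flagged
rather than reported as measurements.

## The synthetic cohort generator

`generate_cohort()` draws a full study: body compositions, 24-minute gas
traces, intake and fecal tables, cytometry assays and cecal metabolites,
with ground truth emitted alongside. Its defaults are the study
conditions, chosen once: cecal masses 3 / 1.5 / 0.5 g (GF / OLIGO / SPF);
germ-free intake 15 % above colonized (within the 10–20 % band); fecal
energy densities 3.7 vs 4.0 kcal/g; daily EE = 1.0 + 0.4 × lean mass
kcal/day (≈ 9 kcal/day at 20 g lean mass, matching the ~9 kcal/day all
groups extract) with a cosine circadian modulation of amplitude 0.3
peaking in the dark phase; RER profiles GF 0.74/0.80, OLIGO 0.75/0.92,
SPF 0.85/0.95 (light/dark) — free configuration values chosen to
reproduce the qualitative ordering, since the source curves are printed,
not tabulated; hydrogen proportional to cecal mass in colonized groups
only, with the gnotobiotic community at a higher per-gram rate; bacterial
densities 1.1 × 10^11^ and 1.6 × 10^11^ cells/g; feeding in bouts
concentrated in the dark phase (per-interval bout probabilities 0.6 dark /
0.2 light, gamma bout sizes with CV 0.5); fecal output per gram intake set
per group (0.40 / 0.29 / 0.27) so the energy books close near 9 kcal/day
extracted.

Traces are generated in raw gas-differential space by inverting the Weir
equation and the Haldane transformation, so the pipeline's forward
computation is exercised end to end; with noise disabled the recovered
daily EE matches the latent value to well under 0.5 %. Fault injection
mirrors the QC failure taxonomy (sentinel food events, negative
differentials, intake outliers, gas dropouts) with a ground-truth log, and
the QC rules catch every injected fault by construction.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: sensor drift and autocorrelated noise,
behavioural feeding rhythms beyond phase-level bout probabilities,
adaptation effects at the start of recording, day-to-day physiological
trends, and any mechanistic microbial ecology (metabolite tables are plain
group-mean draws). Raw-data record counts and measured group values from
any particular animal study are likewise not reproducible from synthetic
cohorts; the printed values above enter only as generator defaults.

## Problem sizes and runtime choices

The default cohort is 10 mice per group over 4 recording days (7,200
trace records), which resolves every group contrast of interest; the
parameter-recovery study uses 200 simulated cohorts at the summary level
and the null calibration 1,000, sizes at which the Monte-Carlo error of a
rejection rate (~0.7 %) is small against the 0.05 ± 0.02 acceptance band.
Uncertainty-propagation checks use 10^6^ Monte-Carlo draws. The numbered
scripts under `analysis/` run these stages end to end and write their
tables under `results/`.

## Known limitations

Single-slope ANCOVA assumes a common lean-mass slope across groups; no
interaction terms are fitted. Uncertainty propagation assumes independent
Gaussian sources. The spline smoother fixes a 24-h schedule — no cosinor
or period estimation. The Tukey-on-adjusted-values procedure is
approximate as discussed. And removal-only QC means heavy-tailed but
genuine feeding bouts are occasionally discarded (a few percent of
records on clean data); the day-completeness rule bounds the damage any
one day can take before it is dropped outright.
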