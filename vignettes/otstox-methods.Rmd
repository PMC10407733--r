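---
title: "Methods: models, estimators and design choices in otstox"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimators and design choices in otstox}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(otstox)
```

`otstox` quantifies the burden an orthogonal translation system (OTS)
places on its bacterial host, across four layers: growth kinetics,
cell-size distributions, proteome dysregulation, and translational
fidelity (amino-acid misincorporation and tRNA misrecognition). This
vignette documents the models behind each estimator, the parameters
that matter, the numerical choices, and what the synthetic-data tests
do and do not demonstrate about real data.

## Growth kinetics

### The extraction rules

Three parameters summarize a plate-reader OD600 curve:

* **Specific growth rate (μ, h⁻¹).** Natural-log-transformed OD is
  regressed by OLS over every run of `window = 3` consecutive points
  (the first `exclude_first_h = 3` hours excluded). The window slopes
  are rank-ordered; the two highest are discarded as potential
  outliers and the next five averaged (`specific_growth_rate()`).
* **Growth efficiency (OD units).** Mean of the six highest raw
  readings minus mean of the two lowest — the total population-size
  increase, insensitive to time ordering.
* **Lag-phase endpoint (Ƭλ, h).** The time where the log initial
  population density meets the line extrapolated from the maximum
  specific growth rate (`lag_time()` implements the pure
  intersection).

### Why the fit adds numerical machinery

At a realistic inoculum (OD 0.01) and plate-reader noise (SD ~0.005
OD), the log transform amplifies noise by 1/OD: near the inoculum a
single reading's log-noise SD is ~0.5, and a 3-point window slope there
has an SD of several h⁻¹ — larger than any plausible growth rate. A
rank-selection rule applied to such slopes returns noise maxima, not
growth. `fit_growth_parameters()` therefore:

1. **Estimates the noise SD** robustly from second differences
   (`median |Δ²OD| / (0.6745 √6)`); trend contributes only
   ~OD·(μΔt)² per point and the median ignores the mid-log minority.
2. **Pre-smooths** the OD series with a moving average whose width
   adapts to the relative noise of the inoculum estimate (width
   `min(15, max(1, 30·σ/OD₀))`, forced odd): clean data are left
   untouched (so noiseless curves reproduce the closed-form model
   exactly), noisy data get up to a 2.5-h window. Smoothing also
   correlates neighbouring window slopes, which tames the upward bias
   of rank selection (the effective number of independent slopes
   drops).
3. **Filters windows by SNR**: only windows whose mean OD is at least
   `snr_min = 20` noise SDs enter the ranked list. If growth never
   clears that bar, the highest-density windows are used as a
   fallback.
4. **Corrects for logistic saturation.** Under logistic growth the
   local log-slope is μ(1 − OD/K), so even the steepest usable windows
   under-estimate the intrinsic rate. The carrying capacity K is
   solved in closed form from two tail points a known rate apart
   (`od(t) = K/(1+Be^{-μt})` at two times gives K), iterated three
   times with the current μ; each window slope is divided by
   (1 − q/K), where q is the density-weighted mean OD
   ⟨OD²⟩/⟨OD⟩ over the raw points feeding that (smoothed) slope —
   the correct effective density for a span-averaged log-slope. The
   correction factor is floored at 0.5 so a mis-estimated K can never
   more than double a slope.

The ranked-slope rule itself is untouched: the corrected, eligible
slopes are passed to `specific_growth_rate()` verbatim.

### The lag construction

Two observations shaped the lag estimator. First, extrapolating a
tangent line from the curved (saturating) region biases the intercept
early; the correct line is the exponential-phase *asymptote*, which is
exactly linear in the logit transform y\* = ln(OD/(1 − OD/K)). The
asymptote is fit by weighted OLS on y\* over raw points with OD between
`max(2.5σ, 1.5·OD₀)` and 0.8K, with inverse-variance weights
(OD·(1 − OD/K))² (additive OD noise mapped through the transform).
Second, the "initial population density" must not be estimated from
the *lowest* readings: minimum statistics are biased low by ~kσ, which
at OD₀ ≈ 2σ corresponds to hours of lag error after the log transform.
Instead the lag is found by a one-parameter piecewise least-squares
fit on the early region: the model is flat at the line-implied density
for t < L and follows the (logistic-inverted) asymptote afterwards;
L is scanned on a fine grid and the SSE minimum taken. This is the
same geometric object — line ∩ plateau — estimated jointly.

On noiseless three-phase curves the fit recovers μ within 1% and the
lag to the grid resolution. Under the synthetic study conditions
(OD₀ = 0.01, noise SD 0.005, μ ∈ [0.2, 1.2] h⁻¹, lag ∈ [0.5, 4] h,
50 curves) the shipped checks verify a median relative μ error within
5% and a median lag error within one 10-min sampling interval. It is worth stating plainly that the lag tolerance of one
10-min sampling interval sits essentially at the information floor of
those conditions: the lag precision is bounded by the plateau-level
uncertainty σ/(OD₀√n_plateau)/μ, which for a median curve is itself
~0.13 h. Materially better lag recovery than one sampling interval would
require a higher inoculum, lower noise, or replicate pooling.

### What the growth simulator does and does not emulate

`simulate_growth_curve()` draws a flat-lag + logistic trajectory —
chosen over Gompertz/Baranyi because it is the simplest form exposing
all three extracted parameters distinctly — with additive, homoscedastic
Gaussian noise floored at 10⁻⁴ OD. Real plate-reader data additionally
show multiplicative noise at high density, drift, condensation
artefacts, and diauxic shoulders; passing recovery tests here
demonstrates the estimator's statistical behaviour, not robustness to
those artefacts. Model-based fits are deliberately out of scope.

## Cell size

Forward scatter (FSC) is used as a relative cell-size proxy. The mode
is taken as the centre of the maximal-count bin of a 256-bin
equal-width histogram (ties resolved to the lowest bin), mirroring how
flow-analysis software reads modes off binned displays; the bin count
is configurable. "Median SD" and "mode SD" are bootstrap standard
deviations over 200 seeded resamples — the vendor definitions are not
public, so the bootstrap is our documented interpretation; samples
under 10 events skip the bootstrap. Events are modelled log-normal
(strictly positive, right-skewed), parameterized by arithmetic mean
and CV for test readability. Gating and compensation are out of scope:
event lists are taken as given.

## Multi-parametric relative fitness

Each phenotype parameter is expressed relative to the background
strain, oriented so larger = fitter; lag is inverted (a 3× longer lag
maps to r_lag = 1/3) and cell size taken as condition/background,
treating size reduction as a stress marker. The composite is the
weighted geometric mean ∏ rᵢ^wᵢ with uniform default weights. The
geometric mean was chosen because it gives three properties a
fitness index should have: identity (background vs itself = 1, held
exactly in floating point), strict monotonicity in every ratio, and
reciprocity (fitness(A vs B)·fitness(B vs A) = 1). The published
combination rule for such heat-map values is not stated anywhere we
could follow, so ours is a documented stand-in; per-parameter ratios
are always reported alongside the composite so no information is
hidden by the aggregation. A condition with growth rate below
`mu_tol = 10⁻³` h⁻¹ (or no data) is non-viable: composite 0, rendered
"N.V.", ratios absent. A zero condition lag caps r_lag at 10 with a
flag rather than diverging.

## Differential protein abundance

Per protein, on log2 LFQ intensities, condition B minus A: an
equal-variance two-sample t-test (Welch by config) and the moderated
statistic d = Δ/(se + s0), with `s0 = 0.1` softening the denominator so
minuscule-variance proteins cannot dominate. The null distribution of
d comes from label permutations: all distinct assignments when at most
`n_permutations` exist (3v3 gives 20), random draws otherwise. The
significance cutoff is the smallest |d| threshold whose estimated
FDR — null exceedances over observed exceedances — stays at or below
the target (default 0.1). Two estimator details matter:

* the identity and complement assignments are excluded from the FDR
  null (they replay any true effects verbatim) but retained in the
  per-protein permutation p-values, keeping those exact under full
  enumeration;
* the null exceedance count per threshold is the **median** across
  permutations, not the mean: permutations that split the real groups
  unevenly partially replay true effects, and a mean is dragged by
  those contaminated permutations (we observed order-of-magnitude
  power loss with a mean over non-identity permutations, and inflated
  cutoffs with the identity included). In spike-in simulations (2000
  proteins, 5% dysregulated 4-fold, replicate SD 0.25 log2) the median
  version is calibrated: empirical FDR averages 0.095 at the 0.1
  target with recall ≥ 98%.

A protein is "dysregulated" only by the conjunction p < 0.05 **and**
|d| ≥ cutoff — the volcano plot's asymptotic lines. Missing values are
not imputed; proteins with fewer than `min_valid_per_group = 2` valid
values per condition are excluded and listed, the conservative choice.
s0 and the permutation count are exposed in `de_config()` since the
conventional defaults of proteomics platforms vary.

iBAQ abundance ranks use decreasing order with minimal tie ranks
(deterministic and order-independent); ranks are invariant under any
strictly monotone transform of the iBAQ scores. Overlap analysis is
exact set algebra with membership lists, not just counts; common-core
removal is a statistics-preserving set difference.

## Enrichment

Over-representation only: p = P[X ≥ k] for X hypergeometric(N, K, n),
BH-adjusted across categories. The universe defaults to the quantified
proteins of the experiment rather than the whole proteome — a
detection-bias control — and is overridable. Network retrieval and
clustering against external databases are out of scope; the catalog is
a user-supplied two-column table or GMT file.

## MS–READ incorporation ratios

Peak areas are trapezoidal integrals of (intensity − baseline)⁺ over
given boundary windows; the default baseline is the in-window minimum
(integration is exactly linear in intensity with baseline "none").
Ratios are formed within each replicate — variant AUC over pSer AUC of
the same sample — and then averaged, because normalizing within the
sample must precede averaging for the ratios to be scale-invariant per
replicate. Replicates with zero pSer area are excluded with a
diagnostic.

Detection: a variant is below the limit of detection when its
in-window signal fails `lod_snr = 3` times the out-of-window noise
scale. The noise scale is the 0.9-quantile absolute deviation (scaled
to SD units); a plain MAD collapses to zero when more than half the
baseline is clipped at zero intensity, which non-negative traces
routinely are. The signal statistic is the 90th-percentile in-window
intensity rather than the maximum: a genuine peak holds a sizeable
fraction of the window near its apex, while a lone noise maximum does
not, so the quantile discriminates where the max cannot. Below-LOD
variants report ratio 0 with a flag, keeping ratio tables rectangular.
Under 5% peak-height noise and 3 replicates, the shipped checks
verify that true ratios in [0.5, 5] are recovered within 10% (median
over 50 seeds).

The chromatogram simulator draws a single Gaussian elution peak per
variant on a flat baseline; real MS1 traces add tailing, co-eluting
interferences and isotope structure, and peak-boundary picking is
taken as given (a Skyline-style export), so the tests validate the
integration and normalization arithmetic, not peak detection.

## Gel densitometry yield

Band intensity is modelled linear in loaded mass. The standard curve
is an OLS line through the known-mass ladder; the sample's total mass
inverts that line; the phosphoprotein yield multiplies the total by
upper/(upper+lower) from the PhosTag bands. Noiseless simulated gels
invert exactly; saturation and background-subtraction artefacts of
real blots are out of scope (densitometry values arrive as a table).

## tRNA identity elements

tRNAs are modelled as Sprinzl-numbered base assignments with an
explicit acceptor-stem pair map (1:72 … 7:66), a discriminator (73),
an anticodon (34–36) and a variable-loop length; no structure
prediction is attempted. Watson–Crick complementarity of acceptor
pairs is enforced, G:U tolerated with a warning. Identity elements are
bases, base pairs, or structural predicates (currently the extended
variable loop, threshold ≥ 10 nt — class II serine-system tRNAs carry
arms well above it, class I tRNAs sit near 4–5).

The shipped catalog (`identity_catalog()`, an editable TSV) encodes
the characterized recognition relevant to the phosphoserine pair:
GlyRS and ThrRS each recognize G1:C72, C2:G71 and U73; SerRS requires
the extended variable loop (an essential structural element) with
literature-supplemented acceptor entries; pSerRS essentially requires
G1:C72 and U73. A `source` column separates characterized from
literature-supplemented entries. The screening rule — flag a
synthetase when at least `flag_threshold = 3` elements match *and* no
essential structural element is unmet — is our formalization of
"significant overlap": the threshold equals the number of shared
acceptor-stem/discriminator elements, and the structural veto encodes
that a missing essential feature blocks recognition outright
regardless of sequence matches. On the shipped fixture this flags
exactly GlyRS and ThrRS for the unmodified tRNA-pSer and neither after
the C2:G71 → G2:C71 flip, while both pSerRS elements stay matched.

Mutation proposal enumerates the seven acceptor-pair flips and three
discriminator substitutions, keeps candidates that preserve every
cognate element and strictly reduce total host matches, and ranks by
the reduction. The shipped tRNA-pSer model is a synthetic
reconstruction: its characterized features are faithful, the remaining
positions are generic cloverleaf filler, which suffices because every
screening decision depends only on catalogued positions.

## Reproducibility and problem sizes

Every stochastic routine takes an explicit integer seed and scopes its
RNG to the call (`withr::with_seed`), leaving global state untouched;
identical arguments and seed give byte-identical output. The test
suite exercises the estimators at the sizes the analyses are designed
for — 97-point growth curves (50 per recovery study), 10⁵-event FSC
samples, 2000-protein tables with 3v3 designs (100 null simulations
for p-value calibration, 5 spike-in runs for FDR calibration), and
50-seed chromatogram recovery — sizes chosen to estimate each rate or
median stably while keeping a full run in well under a minute per
module.

## Known limitations

* Growth: no Gompertz/Baranyi model fits, no OD→CFU calibration,
  additive-noise assumption; lag precision is inoculum-noise limited
  as derived above.
* Cytometry: no gating, compensation or fluorescence analysis; FCS
  binaries must be converted upstream.
* Proteomics: no missing-value imputation, no peptide-to-protein
  inference; the permutation FDR is an estimate whose realized error
  rate fluctuates seed to seed around the target.
* Enrichment: results depend entirely on the user-supplied catalog;
  no depletion testing.
* MS–READ: no peak picking, isotope-envelope modelling or raw-spectra
  parsing; variant identity per trace is taken as given.
* tRNA: aminoacylation kinetics, codon-anticodon decoding and
  elongation-factor interactions are not modelled; the screen is a
  sequence-element overlap heuristic, not a binding predictor.
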