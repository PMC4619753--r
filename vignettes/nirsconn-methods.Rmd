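---
title: "Methods: from raw fNIRS intensities to connectivity networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from raw fNIRS intensities to connectivity networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models, numerical choices, and design decisions
behind `nirsconn`, in the spirit of a methods section: what each stage
assumes, which parameters matter and why their defaults are what they are,
and what the synthetic-data tests do and do not demonstrate about real
recordings.

## Signal model and preprocessing

### Optical density and the modified Beer–Lambert law

A continuous-wave fNIRS channel records light intensity $I(t)$ after
diffuse passage from a source to a detector a few centimeters away. We
normalize each channel by its temporal mean and take the negative natural
logarithm,
$$\Delta OD(t) = -\ln\!\big(I(t)\,/\,\overline{I}\big),$$
which removes the unknown per-channel gain (the conversion is invariant to
rescaling a channel by any positive constant). The natural-log convention is
a documented choice; a base-10 convention would only rescale the extinction
coefficients.

The modified Beer–Lambert law relates optical-density changes at the two
wavelengths to chromophore concentration changes:
$$\Delta OD(\lambda_i) = \big[\varepsilon_{HbO}(\lambda_i)\,\Delta HbO +
\varepsilon_{HbR}(\lambda_i)\,\Delta HbR\big]\; L \; DPF(\lambda_i), \qquad i = 1,2,$$
a 2×2 linear system solved per time point and channel. Units: $\varepsilon$
in cm$^{-1}$(mol/L)$^{-1}$ (embedded published values for 690/830 nm and a
few other common wavelengths, overridable), source–detector separation $L$
in cm, DPF dimensionless (default 6.0 at both wavelengths, overridable),
concentrations reported in µmol/L. The condition number of the extinction
matrix is recorded, and a singular system is rejected. The assumptions are
the usual ones — homogeneous medium, wavelength-independent path geometry,
small perturbations — and only *changes* in concentration are meaningful;
the per-channel mean normalization absorbs a constant offset, which is why
round-trip identities hold for zero-mean inputs.

### Band-pass filtering

Resting-state hemodynamic fluctuations of neural origin concentrate in
roughly 0.01–0.1 Hz; slower components are drifts and instrument trends,
faster ones are cardiac/respiratory physiology and noise. The default filter
is therefore a band-pass from 0.01 to 0.1 Hz: a fifth-order Butterworth
high-pass and a third-order Butterworth low-pass, each applied forward and
backward (zero phase; the effective amplitude response is the squared
magnitude, and peaks are not displaced in time).

Two numerical points matter at these cutoffs:

* **Second-order sections.** At 25 Hz sampling, the 0.01 Hz high-pass has a
  normalized cutoff of 8×10⁻⁴. In transfer-function form the recursion is
  ill-conditioned — we measured linearity violations around 10⁻² on white
  noise — so the filters are designed directly as biquad cascades via the
  bilinear transform and applied section by section. In this form linearity
  holds to ~10⁻¹¹ and the realized response matches the closed-form
  Butterworth magnitude response to ~0.1%.
* **Edge handling.** Each pass uses odd-reflection padding plus exact
  steady-state handling of the starting level (filtering $x - x_1$ and
  adding back $x_1 H(1)$), so a constant input is annihilated by the
  high-pass *exactly*. The pad length scales with the filter's time constant
  (about three time constants of the cutoff, capped at the series length):
  a fixed short pad would leave edge transients that persist for hundreds
  of samples at a 0.01 Hz cutoff. Despite this, the first and last ~30 s of
  a filtered series remain less trustworthy than the interior — tests and
  the acceptance script therefore measure amplitudes on the central section
  by sinusoid regression.

### Detrending and motion correction

Detrending subtracts the per-channel ordinary-least-squares line; the
residual has zero mean and zero refit slope, and the operation is
idempotent. Note one consequence of exact OLS: a slow sinusoid over a finite
window has a nonzero projection onto the line, so "detrending a sinusoid
plus a line" returns the sinusoid only up to that projection (RMSE ≈ 0.03
for a 0.05 Hz unit sinusoid over 300 s). This is a property of least
squares, not an artifact.

Two artifact-correction methods are provided:

* **MSD + spline subtraction.** The moving standard deviation (centered
  window, default 2 s; sample sd; truncated edge windows of at least 2
  samples so the mask aligns with the time axis) is thresholded at
  mean + 5·sd of the MSD by default. Flagged samples are merged into
  segments (gaps shorter than one window are bridged), each segment is
  modeled by a smoothing cubic spline (smoothing parameter in (0,1],
  default 0.99, mapped to `smooth.spline`'s `spar` as 1 − smoothing) and
  the spline is subtracted; the corrected segment is re-leveled to the
  preceding clean baseline and the remainder of the series is shifted for
  level continuity. The continuation step is what repairs baseline *steps*,
  which flag only at their transition yet displace everything after it.
  The segment-merging gap, smoothing default, and re-leveling rule are
  package choices, documented and configurable.
* **CBSI.** With $\alpha = sd(HbO)/sd(HbR)$ per channel,
  $HbO' = (HbO - \alpha\,HbR)/2$, $HbR' = -HbO'/\alpha$. The method assumes
  genuine hemodynamics are anticorrelated between HbO and HbR while motion
  moves both together; it cancels a shared artifact well when the artifact
  dominates both signals (so $\alpha \to 1$) and enforces
  $corr(HbO', HbR') = -1$ exactly by construction — downstream analyses of
  CBSI-corrected data should therefore use one chromophore, not both.

The default pipeline order is: OD conversion → MBLL → band-pass → detrend →
CBSI. Where the order of detrending relative to filtering is concerned, both
operations are linear and near-commuting; the default follows the standard
listing, and the step list is fully user-orderable, with every applied step
recorded verbatim in the `.proc` history.

## Quality control

Three per-channel statistics are combined: raw-intensity SNR (mean/sd over
time; an optode with poor scalp contact mostly records instrument noise, so
its SNR collapses), mean |Pearson r| against all other channels on the
concentration signal (a noise-only channel correlates with nothing), and
the MSD motion-flagged time fraction. A subject fails when the flagged
channel fraction or the motion time fraction exceeds configurable ceilings
(defaults 0.2/0.2; SNR floor 20; mean-|r| floor 0.05 — the literature gives
no numeric cutoffs, so these are documented defaults, not claims).

One statistical caveat is worth stating explicitly: the mean + T·sd MSD rule
is *adaptive*, so when contamination is extensive (tens of percent of the
recording) it inflates the MSD's own mean and sd and the default T = 5 can
sit above the artifact level; flagging such data needs a lower multiplier or
an absolute threshold, both exposed in the interface. The rule is designed
for transient artifacts in mostly-clean data.

## Connectivity and group statistics

Pairwise association is Pearson (default), Spearman (Pearson on average
ranks), or normalized cross-correlation maximized over lags within ±10 s
(Pearson of the overlapping sections at each integer lag; the signed value
at the lag maximizing |r| is returned, ties broken toward the smallest |lag|
then the negative lag; at max lag 0 it reduces to Pearson exactly). Seed
mode gives one vector per seed channel; whole-brain mode the symmetric N×N
matrix. Undefined correlations (zero-variance channels) propagate as
explicit NA markers, never as silent zeros.

Group maps follow the standard Fisher-z route: per entry across subjects,
the R map is the mean r, the Z map the mean atanh(r), the Z-to-R map
tanh(Z map) (reported alongside the R map — they differ by Jensen's
inequality), and the T map the one-sample t of subject z values against 0
with df = n−1 and two-sided uncorrected p. The t-test is run on z values
(variance-stabilized) rather than raw r; no multiple-comparison correction
is applied, and p values are emitted so users can correct downstream.
Missing entries are averaged pairwise-complete with per-entry counts
reported; zero across-subject variance yields an explicitly undefined t.

## Network analysis

The FC matrix (diagonal forced to 0) is thresholded either at an r cutoff
or at a *sparsity* s: the ⌈s·N(N−1)/2⌉ strongest positive correlations
become edges (binary or weighted). Negative correlations are excluded by
default — their interpretation in hemodynamic connectivity is contested —
with an absolute-value mode available.

Metrics on the resulting graph: clustering coefficient (triangle fraction
per node; geometric-mean formulation for weighted graphs, weights normalized
by the matrix maximum), characteristic path length (mean shortest path over
*connected* ordered pairs, with the disconnected fraction reported; edge
lengths 1/w in weighted mode), global/local/nodal efficiency (1/distance
with 1/∞ = 0, so disconnection is penalized rather than skipped), Brandes
betweenness with fractional counting, Newman modularity (exhaustive
partition search up to 10 nodes — Bell(10) ≈ 1.2×10⁵ partitions is
affordable and makes the optimum exact where small graphs are analyzed;
greedy agglomeration above, with Q always rescored by the package's own
formula), and a hierarchy exponent β fit by least squares to
log c_i = const − β log k_i over nodes with degree ≥ 2 and positive
clustering (the power-law clustering–degree relation from the network
literature; an undefined marker is returned when fewer than three nodes are
eligible or degrees do not vary).

Normalized small-world coefficients compare against degree-preserving
Maslov–Sneppen rewiring: 100 null networks by default, 10 attempted edge
swaps per edge, all seeded and reproducible; γ = Cp/⟨Cp_rand⟩,
λ = Lp/⟨Lp_rand⟩, σ = γ/λ. A small-world network shows γ clearly above 1
with λ near 1. One nomenclature note: part of the literature swaps the
letters γ and λ between the two ratios; here γ is always the clustering
ratio and λ always the path-length ratio.

All metrics are validated against independent brute-force oracles
(Floyd–Warshall distances, explicit triangle counting, shortest-path
enumeration with fractional counting, exhaustive partition search) on
hundreds of seeded random graphs with n ≤ 8, to 10⁻¹², plus exact worked
values (a K4 minus one edge has Cp = 5/6; a 6-cycle has Lp = 1.8 and
global efficiency 2/3; a 4-leaf star's center has betweenness 6; two
triangles joined by a bridge have Q = 5/14).

## The synthetic-data generator

The generator emulates a whole-head continuous-wave acquisition: 46
measurement channels at 25 Hz with 690/830 nm wavelengths and 3 cm
separations by default, 300 s per subject. Channel HbO series are built from
block-shared latent sources band-limited to 0.01–0.1 Hz (so the default
filter preserves the planted structure), mixed as
$\sqrt{\rho}\,L_{block} + \sqrt{1-\rho}\,N_i$ with target within-block
correlation ρ = 0.8 and between-block 0 by default; HbR is −HbO/3 plus
independent noise (the physiological anticorrelation that makes CBSI
meaningful); per-channel linear drift (default slope ≤ 10⁻⁴ µM/s, small
enough not to dilute the planted correlations before detrending) and an
amplitude of 0.05 µM complete the concentration model. Raw intensities come
from the exact optical forward model $I = I_0 e^{-\Delta OD}$, so the
preprocessing chain inverts the generator to machine precision on zero-mean
inputs. Motion artifacts (spikes or steps, scaled in per-channel SDs, with
ground-truth masks) and dead channels (gamma-distributed intensity noise —
strictly positive, exact mean/sd ratio — at a target SNR, default 2) are
injected on top.

Two construction details keep the planted structure honest at realistic
recording lengths. A 0.09 Hz-wide band observed for 300 s has only a few
dozen effective degrees of freedom, so (a) band-limited noise is generated
with burn-in margins and trimmed, because the high-pass edge transients
would otherwise dominate the variance, and (b) the latent block sources are
orthonormalized on the sample and channel noise is projected onto their
orthogonal complement, so the between-block correlation is set by
construction instead of floating ±0.2 with sampling luck.

**What passing these tests shows — and what it does not.** The synthetic
cohort validates the *algebra* of the chain: the forward model is inverted,
planted correlation structure survives preprocessing and appears in the
group maps, planted artifacts are detected and repaired, dead channels are
flagged. Real recordings additionally contain superficial-physiology
contamination (scalp blood flow shared across channels), cardiac and
respiratory oscillations, non-Gaussian and nonstationary noise, optical
coupling drift, and spatially correlated artifacts — none of which the
generator models. Green tests here demonstrate correctness of the
computation, not that the default thresholds are optimal for any particular
instrument or population.

## Problem sizes and defaults used in validation

The bundled validation runs use a 10-subject, 20-channel, 300 s cohort for
group-map recovery; 600 s single-channel series for filter-response
measurement; a 100-node, degree-10 ring lattice rewired with probability
0.1 against 100 nulls for the small-world regime; and 200 seeded random
graphs (n ≤ 8) for oracle equivalence — sizes chosen so each property is
measured with comfortable statistical margin while the whole suite runs in
a few minutes on one core.

## Known limitations

* No short-separation regression, PCA/wavelet motion correction, or
  superficial-physiology removal; partial correlation, coherence, and
  dynamic FC are out of scope.
* Complex-valued raw data (sine–cosine demodulated acquisitions) is
  rejected with a clear error rather than handled.
* The Hitachi-style CSV dialect is a documented minimal stand-in; vendor
  exports vary and only the documented form is parsed.
* The MAT container support is a deliberate subset (uncompressed level-5,
  real double/char/struct/cell) — enough for `.nirs`/`.proc` interchange,
  not a general MAT reader.
* Group analysis assumes identical channel sets across subjects; no
  spatial registration or brain-template projection is provided.
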