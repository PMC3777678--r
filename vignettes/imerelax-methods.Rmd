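---
title: "Quantifying intramyelinic edema with multi-exponential T2, SIR-qMT and quantitative histology"
author: "imerelax"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying intramyelinic edema with multi-exponential T2, SIR-qMT and quantitative histology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imerelax)
```

## The problem

Intramyelinic edema (IME) is a white-matter pathology in which fluid
vacuoles form between the lamellae of compact myelin. On conventional
T2-weighted MRI it appears as unspecific hyperintensity. Two quantitative
MRI approaches promise more specificity:

* **Multi-exponential T2 (MET2)** analysis resolves the T2 spectrum of
  tissue water. The short-T2 class (~10-25 ms) is attributed to water
  trapped within myelin (myelin water fraction, MWF); a distinct long-T2
  class (> 100 ms) appearing with IME is attributed to vacuole water
  (edema water fraction, EWF).
* **Quantitative magnetization transfer (qMT)** by selective inversion
  recovery (SIR) estimates the macromolecular proton pool relative to free
  water (pool-size ratio, PSR) together with the exchange rate
  `kmf` and the longitudinal time constant T1.

Histology provides the reference: segmented sections give compartment
volume fractions (myelin `V_my`, intra/extra-axonal `V_ie`, edema
`V_ed`), which combine with literature water densities
(`rho_my = 0.4`, `rho_ie = 0.8`, `rho_ed = 1.0`) into a water content
fraction

W = V_my rho_my + V_ie rho_ie + V_ed rho_ed,

and per-compartment water fractions `Wx = Vx rhox / W` (which sum to 1).

The central quantitative puzzle the package is built around: the MRI EWF
correlates strongly with the histological `W_ed` but overestimates it by
about a factor of two. The explanation is inter-compartmental water
exchange, and the package ships the forward model that makes the argument
quantitative.

## The relaxation-exchange forward model

Transverse magnetization of an n-pool system with first-order exchange
follows dM/dt = A M with

* `A[i,i] = -(1/T2_i + sum_j k_ij)` and
* `A[i,j] = k_ji` (magnetization arriving in pool i from pool j),

where `k_ij` is the rate of magnetization leaving pool i for pool j, and
detailed balance `f_i k_ij = f_j k_ji` ties the rates to the equilibrium
fractions. `apparentTransverseComponents()` eigen-decomposes A: apparent
time constants are `-1/lambda_n`, and amplitudes are
`a_n = sum(v_n) (w_n . M(0))` with right/left eigenvectors `v_n`, `w_n`.
As exchange speeds up, amplitude moves from the fast-relaxing to the
slow-relaxing apparent component.

The canonical example: T2s of 50 and 150 ms, 75% of the signal in the
short pool, and a 200 ms residence time for the long pool. The observed
decay is bi-exponential with apparent T2s of 44.6 and 91.8 ms and *equal*
amplitudes — the long component carries twice the long pool's volume
fraction:

```{r worked}
f <- c(0.75, 0.25)
sys <- poolSystem(f, t2 = c(0.05, 0.15),
                  k = exchangeFromResidence(f, tau = 0.2))
apparentTransverseComponents(sys)
```

Numerical choices: eigenvalues whose relative gap is below `1e-10` are
merged (amplitude-summed); components with amplitude below
`1e-12 x sum(M(0))` are dropped; a complex eigenvalue (impossible under
detailed balance, possible for hand-built invalid rate matrices) raises
an error rather than being silently truncated.

The SIR-qMT forward model (`sirRecoverySignal()`) is the longitudinal
analogue: a free pool f and macromolecular pool m with shared rate R1,
exchange `kmf` (m to f) and `kfm = kmf x PSR` by detailed balance, and
initial condition `Mzf(0) = sf m0`, `Mzm(0) = sm PSR m0`. The rate
orientation and the fixed `sm` close the model at exactly five fitted
parameters `(m0, PSR, kmf, R1, sf)`. `sm` defaults to 0.83, a standard
value for a millisecond-scale hard inversion pulse that partially
saturates the macromolecular pool; it is configurable, not fitted.

## MET2 fitting

`fitGaussianComponents()` fits a decay to 1-3 spectral components, each a
Gaussian line on the log10(T2) axis with a common width, with
non-negative amplitudes. Fixed choices (all overridable via
`met2Options()`):

* log-T2 grid: 256 points from 1 ms to 3 s;
* common line width 0.04 decades (optionally fitted in [0.01, 0.2]);
* chi-square is unweighted SSE — appropriate for ROI-mean decays whose
  noise is near-white after averaging;
* the Rician noise floor is ignored at ROI level (averaging makes the
  noise near-Gaussian); voxel-level data keep their floor.

The amplitudes enter linearly, so the fit is a variable projection over
the component centers. The center search is *global then local*: all
1-, 2- or 3-subsets of a candidate grid (0.02 decades for 1-2 components,
0.04 for 3) are scored by closed-form subset least squares — for supports
of size <= 3, enumerating sub-supports and keeping the best feasible
(all-non-negative) solution *is* exact NNLS — and the best feasible sets
are polished by bounded quasi-Newton refinement plus seeded jittered
restarts. Ties go to the solution with fewer effective components. This
replaces a conventional multi-start heuristic with a search that cannot
miss a well-separated optimum, and it is also what makes the
model-selection results below interpretable: observed chi-square
differences reflect the model class, not optimizer noise.

One consequence of the fixed line width deserves emphasis: a pure
mono-exponential is *not* in the model class. The best 1-component fit of
a noiseless exponential leaves a relative residual of order 1e-3 (chi2 ~
1e-5 at unit amplitude). Tests therefore assert recovery at tolerances
the model class can meet (T2 and amplitude within 1%), not machine
precision.

### Model selection and its calibration

`selectNComponents()` runs sequential nested F-tests (1 vs 2, then 2 vs 3
— the ladder is switchable to exhaustive):

F = ((chi2_r - chi2_f)/dp) / (chi2_f/(n - p_f)),

adopting the larger model iff P < alpha (default 0.05), with a perfect
larger fit adopted directly. Each component contributes 2 parameters
(center, amplitude).

The classical F reference distribution assumes the extra parameters can
chase noise like free linear coefficients. They cannot: amplitudes are
constrained non-negative and the line width is fixed, so under a
mono-exponential null the 2-component fit almost always collapses onto
the 1-component optimum (delta chi-square ~ 0 — we verified this with the
exact subset enumeration). The practical effect is that the false-third-
component rate sits far *below* alpha (~0-1% at SNR 500 instead of 5%):
the selection step is conservative, which costs a little power but never
invents spectral components. The power side is tested directly: on
study-condition three-pool decays at SNR 1000 the third component is
detected in well over 90% of replicates.

### Classes and fractions

Fitted component T2s from all ROIs and animals are pooled and clustered
into short / intermediate / long classes on the log10 scale. One
dimension makes the k-means objective exactly solvable: the optimal
partition is contiguous in sorted order, so `clusterT2Classes()` uses
dynamic programming over contiguous partitions — deterministic, invariant
to input order, and globally optimal (checked against exhaustive
enumeration in the tests). The class boundaries (geometric midpoints
between adjacent class extremes) are reusable via `classifyT2()` for
voxelwise work. MWF and EWF are the short- and long-class shares of the
total fitted amplitude. Intra-ROI standard errors come from voxel-by-
voxel fits with the component count frozen at the ROI-level selection:
SE = SD(voxel values)/sqrt(N).

## SIR-qMT fitting

`fitSir()` is bounded Levenberg-Marquardt over `(m0, PSR, kmf, R1, sf)`
with bounds PSR in [0, 1], kmf in [0, 200] /s, R1 in [0.05, 5] /s, sf in
[-1, 1]. Initialization is deterministic: a 3 x 3 coarse grid over PSR
{0.05, 0.15, 0.3} and kmf {5, 20, 60} /s, R1 from a log-linear fit of the
recovery tail, sf = -0.95 and m0 from the late-time signal. The
covariance is `sigma^2 (J'J)^{-1}` with a central-difference Jacobian at
the optimum; at SNR 200 the resulting 95% intervals cover the generating
PSR and kmf at 92-96% over 200 replicates. Magnitude data are handled by
fitting once, locating the model's zero crossing, flipping the sign of
earlier points and refitting (one iteration). The acquisition's 3.5 s
repetition pre-delay exists in the generator (it scales the effective
initial condition) but is deliberately ignored by the 5-parameter fit
model, mirroring how such data are analyzed in practice; at these
parameters its effect at 10 s is far below the noise.

## Histology quantification

`preprocessImage()` applies Perona-Malik anisotropic diffusion
(exponential conductance, kappa = 0.1 intensity units, step 0.15, 20
iterations — the explicit scheme is stable for steps <= 0.25) followed by
CLAHE (8 x 8 tiles, EBImage's contrast-limit convention). Diffusion
parameters were chosen so that a noisy step edge loses >= 5x within-
region variance while its half-maximum crossing moves less than a pixel.

`segmentRegions()` grows regions from seeds: a pixel joins the 4-adjacent
region whose running mean is within a tolerance of the pixel value;
pixels left over when the queues exhaust (boundary-gradient pixels) are
attached to the neighbouring class with nearest mean in deterministic
row-major sweeps. The default tolerance is 2.5x a robust noise SD — the
median absolute deviation of intensities about the centers of an exact
1-D 3-class clustering of a pixel subsample. Because myelin rings and
lesions are many disconnected components, "semi-automatic" seeding means
many seeds: `seedsFromModes()` emulates the operator by seeding a regular
grid wherever the intensity is unambiguous (within 1.5 robust SDs of a
class center). Lesion morphometry uses 8-connected components of the
edema class, a 4-pixel minimum area, circular-equivalent diameters
`2 sqrt(A/pi)`, and density per mm^2 of tissue.

## What the generators emulate — and what they do not

`simulateRoiDecay()` / `simulateSirSeries()` sample the 40-echo scheme
(first echo 7.4 ms, 32 echoes at 9 ms spacing, 8 more at 50 ms) and 25
pseudo-log inversion times (3.5 ms to 10 s, rounded to 0.1 ms). Noise is
Rician (magnitude of complex Gaussian, per-channel SD
`S(0)/SNR/sqrt(n_avg)`) for voxel data; ROI-mean decays default to
Gaussian noise on the central-limit argument. T1 weighting of the
inversion-prepared readout is not applied (the analysis ignores it too,
and the bias it would cause runs *against* the exchange effect the study
design probes).

`generateHistologyImage()` packs lognormal-radius fibres by random
sequential adsorption (packing 0.52, g-ratio 0.68), paints myelin
annuli, and places non-overlapping circular lesions (diameter ~ Normal(
3.1, 0.4) um, centers on myelin, rejection sampling capped at 1e5
attempts per lesion) on a 1600 x 1200 grid over 120 x 90 um^2 (0.075
um/px). Rendering uses the dark-stain convention (myelin 0.20, ie 0.55,
edema 0.90), a linear illumination gradient and Gaussian noise
(SD 0.05). The lesion count is the deterministic round of density x
area, so achieved densities differ from the request only through
placement feasibility. Not emulated: staining texture, sectioning and
fixation artifacts, instance-level axon geometry (fibres may be clipped
at lesions), imaging artifacts, CSF. Passing round-trip tests therefore
demonstrates the *pipeline's* correctness on images with the right
geometry and contrast statistics, not robustness to real-slide
artifacts.

`generateStudy()` builds the full 3-group x 4-tract design. Per tract
the configuration fixes the myelin water fraction and an edema water
fraction target; per animal both are jittered lognormally (CV 0.12 for
edema, half that for myelin). The relaxation system couples the edema
pool (intrinsic T2 300 ms) to *adjacent* intra/extra-axonal water with
the 200 ms residence time, keeping a 3:1 ie:edema composition inside the
exchanging neighbourhood — the same 75/25 composition as the worked
example, which pins the apparent long-T2 amplitude at exactly twice the
edema water fraction for every tract and yields an apparent long T2 of
~132 ms, comfortably separated from the ~50-60 ms intermediate class.
Water that is far from any lesion does not exchange; this locality
assumption is the package's own modelling choice where the study design
needed one. Volume fractions follow from the water fractions through the
density formulas, so MRI truth and histology truth are mutually
consistent. Intrinsic T2/T1 presets (15/60/300 ms; T1 ~ 1.8-2 s) are
defaults for a 9.4 T rodent cord, not asserted facts. SNRs default to
1000 (ROI MET2) and 200 (SIR).

## Problem sizes in the shipped tests

The test-suite uses sizes chosen to make every stochastic statement
statistically meaningful while keeping a full run comfortably
interactive: 100 random systems for the eigen-vs-matrix-exponential
equivalence; 100 replicate decays (power and EWF recovery) and 2000
null decays (selection rate); 200 SIR replicates for coverage; two full
1600 x 1200 histology fields plus one 480 x 360 um^2 wide field
(~290 lesions) for morphometry; and a 3-animal x 4-tract x 3-group study
(36 ROI pairs) for the end-to-end regression.

## Known limitations

* The F-test ladder is conservative (see above); if maximal sensitivity
  to a faint third component matters more than specificity, raise alpha.
* Regularized continuous spectra (NNLS over the full grid) are out of
  scope by design; the discrete Gaussian-component model is the method
  under study.
* The region-growing ambiguity check only catches coincident seeds of
  different classes; seeds of different classes placed inside one truly
  homogeneous region will silently split it.
* Group comparisons are Welch t-tests with no multiplicity correction by
  default (a Holm option exists in `p.adjust` form downstream of the
  comparison table); with 5 metrics x 4 tracts x 3 pairs, expect some
  false stars at alpha = 0.05.
* No off-resonance effects, no refocusing-pulse (CPMG) imperfections, no
  diffusion contributions to T2, no B0/B1 correction.
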