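# imerelax

Quantitative MRI relaxometry and histology of **intramyelinic edema
(IME)** in white matter — the pathology in which fluid vacuoles form
between myelin lamellae, as seen in hexachlorophene or vigabatrin
intoxication.

The package is for researchers who want to relate water-compartment
MRI metrics to tissue microstructure. It implements, end to end:

* **Multi-exponential T2 (MET2) analysis** — decays are fitted to 1-3
  spectral components, each a Gaussian line on the log10(T2) axis with a
  non-negative amplitude (variable projection with an exact global
  center search); the component count is chosen by sequential nested
  F-tests; component T2s are clustered into short / intermediate / long
  classes (exact 1-D k-means); the short-class signal share is the
  **myelin water fraction (MWF)** and the long-class share the **edema
  water fraction (EWF)**, with intra-ROI standard errors from voxelwise
  fits.
* **SIR-qMT fitting** — the coupled two-pool longitudinal model for
  selective inversion recovery, fitted over the five parameters
  (m0, PSR, k_mf, R1, sf) by bounded Levenberg-Marquardt with
  Jacobian-based uncertainties.
* **An n-pool Bloch–McConnell exchange forward model** — transverse
  magnetization evolves as dM/dt = A M with
  `A[i,i] = -(1/T2_i + Σ_j k_ij)`, `A[i,j] = k_ji`; its
  eigen-decomposition gives the observed (apparent) decay components.
  This is the model that explains why the EWF *over*states the edema
  volume: exchange moves amplitude from fast- to slow-relaxing
  components.
* **Quantitative histology** — Perona–Malik diffusion + CLAHE, seeded
  region growing into myelin / intra-extra-axonal / edema classes,
  compartment volume fractions, water-content fractions
  `W = Σ V_x ρ_x`, `W_x = V_x ρ_x / W` (ρ_my = 0.4, ρ_ie = 0.8,
  ρ_ed = 1.0), and lesion density/diameter from 8-connected components.
* **Seeded synthetic-data generators** for 40-echo decays, 25-point
  pseudo-log SIR series and toluidine-blue-like histology fields with
  known ground truth, plus a study-level pipeline (`generateStudy()` /
  `runStudy()`) with Welch group comparisons and MRI-vs-histology
  regressions.

## Worked example: exchange doubles the apparent edema fraction

Consider two exchanging water pools with intrinsic T2s of 50 and 150 ms,
75% of the signal in the short-T2 pool, and a mean residence time of
200 ms in the long-T2 pool (the reverse rate follows from detailed
balance):

```r
library(imerelax)
f <- c(0.75, 0.25)
sys <- poolSystem(f, t2 = c(0.05, 0.15),
                  k = exchangeFromResidence(f, tau = 0.2))
apparentTransverseComponents(sys)
#> ApparentComponents
#>      t2_ms amplitude
#> 1 44.56294       0.5
#> 2 91.80069       0.5
```

Although the long-T2 pool holds only 25% of the water, the observed
decay is bi-exponential with **two equal components**: the slow
component's amplitude (0.50) is **2×** the long pool's volume fraction.
A MET2 analysis of such tissue will therefore report an EWF about twice
the histological edema water fraction — which is exactly the systematic
factor the study-level pipeline reproduces
(`runStudy()` on a `generateStudy()` bundle regresses fitted EWF on true
W_ed with slope ≈ 2 and r² > 0.9 at study SNR).

Fitting a synthetic SIR series round-trips the qMT parameters:

```r
ti <- makeInversionTimes()            # 25 times, 3.5 ms .. 10 s
s  <- sirRecoverySignal(qmtParams(psr = 0.15, kmf = 12,
                                  r1 = 0.55, sf = -0.9), ti)
qmtEstimates(fitSir(s, ti))
#>    m0   psr   kmf    r1    sf
#>  1.00  0.15 12.00  0.55 -0.90
```

See `vignettes/imerelax-methods.Rmd` for the model assumptions, all
tunable parameters and the design decisions.

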