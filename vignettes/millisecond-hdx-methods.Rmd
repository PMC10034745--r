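---
title: "Models and methods for millisecond HDX-MS analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for millisecond HDX-MS analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mshdx)
```

This vignette documents the models behind `mshdx`, the assumptions they
make, the tunable parameters that matter, and the numerical and design
choices taken where several defensible options existed.

## The measurement model

Backbone amide hydrogens exchange with solvent deuterium at a rate set by
local structure. In the EX2 regime assumed throughout, the observed
per-residue rate is the intrinsic (random-coil) rate divided by the
protection factor, $k_{obs,i} = k_{int,i}/P_{f,i}$. A peptide's deuterium
uptake is then a sum of exponentials over its included residues, scaled by
the D$_2$O fraction of the labeling reaction and, after the quench, by the
fraction of label that survives work-up (back-exchange retention).

Residues 1 and 2 of every peptide are excluded from the exchangeable count:
after digestion the first amide is a primary amine, and label on the second
residue is lost during chromatography. Prolines carry no amide hydrogen.
Free synthetic peptides and proteolytic fragments are treated identically —
the same exclusions and the same C-terminal charge correction — because the
chemistry of the analyzed species is the same once the peptide exists.

## Intrinsic rates

`residue_intrinsic_rates()` computes, for the amide of residue $i$,

$$k_{int,i} = k_A F_{A,i} [\mathrm{D^+}] + k_B F_{B,i} [\mathrm{OD^-}]
  + k_W F_{B,i},$$

where $F_{A,i} = 10^{\lambda_A(i) + \rho_A(i-1)}$ combines the
log-additive acid-catalysis factors of the residue's own side chain and of
its left neighbor (likewise $F_B$ for base catalysis; the water term shares
the base factors, following the reference spreadsheet convention). The
shipped parameter set (`inst/extdata/hx_sidechain_factors_v1.csv`,
`hx_reference_rates_v1.csv`) is the poly-DL-alanine reference
parameterization for exchange into D$_2$O of Bai, Milne, Mayne & Englander
(1993) *Proteins* 17:75 with the Connelly et al. (1993) side-chain factors:
$\log_{10} k_A = 1.62$, $\log_{10} k_B = 10.18$, $\log_{10} k_W = -1.50$
(per minute, molar catalyst, 293.15 K), activation energies 14/17/19
kcal mol$^{-1}$, and $pK_{D_2O} = 15.05$. The tables are versioned CSVs and
can be overridden wholesale through `intrinsic_rate_params()` if a
recalibrated compilation is preferred; the CSV is the single source of truth
for both the implementation and the independent oracle used in the tests.

Three conventions to be aware of:

* **pD correction.** Buffer pH readings in D$_2$O understate pD; the
  standard glass-electrode correction $pD = pD_{read} + 0.4$ is applied
  before any catalysis term.
* **Titratable groups.** Asp, Glu, His and the C-terminal carboxyl
  interpolate between their protonated and deprotonated factors by a
  Henderson–Hasselbalch mix at the working pD (pK values 4.48, 4.93, 7.42
  and 4.0 in D$_2$O).
* **Temperature.** Each catalytic constant is moved from 293.15 K to the
  working temperature by an Arrhenius factor; the D$_2$O ion product is held
  at its 293 K value, which is part of why conditions are restricted to
  258–323 K and pD 1–13, the validity range of the underlying tables.

## Back-exchange

Back-exchange is modeled as a single per-peptide retention scalar: the mean
maxD reference uptake divided by the theoretical maximum
$f_{D_2O} \cdot Q$. This time-invariant treatment is justified for a
turbulent-flow instrument, where measured retention shows no usable trend
with mixing time; `estimate_backexchange()` nevertheless reports the linear
regression of per-exposure retention on time (slope in fraction s$^{-1}$,
with $R^2$ and p-value) as a diagnostic, and the package's tests verify that
this test holds its nominal 5% type-I error on time-invariant synthetic
references. The regression is on linear time, matching how retention drift
would accumulate with residence time; correction is by division,
`corrected = observed / retention`. Corrected values may slightly exceed the
theoretical maximum under noise; they are flagged beyond a 5% overshoot but
deliberately not clipped, because clipping would bias the subsequent fits'
noise structure.

## Stretched-exponential fitting

Peptide-level uptake pools residues with heterogeneous rates, so
`fit_stretched_exponential()` uses

$$D(t) = \sum_{j=1}^{n} Q_j\,(1 - e^{-(k_j t)^{\beta_j}}), \qquad
  n \le 3,\; \beta_j \in (0, 1],$$

where the stretching exponent absorbs within-phase rate dispersion and
$\beta = 1$ recovers a simple exponential. Numerical choices:

* **Optimizer.** Levenberg–Marquardt with box constraints
  ($Q_j \ge 10^{-8}$, $k_j \in [10^{-8}, 10^6]$ s$^{-1}$,
  $\beta_j \in [0.05, 1]$), 200 iterations per start.
* **Multi-starts.** A deterministic grid of log-spaced rates spanning
  $[0.1/t_{max},\ 10/t_{min}]$: 16 single rates for one phase, all
  descending pairs from a 6-point grid for two, all descending triples from
  a 5-point grid for three. No randomness enters the optimizer, so fits are
  exactly reproducible. The lowest weighted RSS wins; ties at equal RSS
  resolve to the earlier (simpler-start) fit.
* **Weighting.** Replicates are collapsed to per-exposure means. When every
  exposure has $\ge 3$ replicates the fit weights by inverse squared
  standard error ($n/s^2$); otherwise it is unweighted.
* **Data sufficiency.** A fit of $n$ phases requires at least $2 \times 3n$
  observations (replicate rows counted individually, so the canonical 15
  exposures in triplicate support three phases) and strictly more than $3n$
  distinct exposures.
* **Degenerate input.** A series whose largest mean uptake is below 0.02 Da
  is reported as `uninformative` with $Q \to 0$ rather than fitted.
* **Phase order.** Phases are reported by decreasing rate,
  $k_1 > k_2 > k_3$.

`select_model()` fits 1–3 phases and keeps the smallest count that the next
richer model does not significantly improve on by the extra-sum-of-squares
F-test at $\alpha = 0.05$ ("least number of phases required"); AIC is
available as an alternative criterion through `criterion = "aic"`. On
noiseless curves the F-test always favors more phases — residuals are
pure model error — so model selection is only meaningful on data with noise;
the pipeline therefore selects the phase count on the experimental curve and
imposes it on the intrinsic fit, not the reverse.

## Protection factors

`protection_factors()` reports per-phase
$\ln P_f = \ln k_{int,j} - \ln k_{exp,j}$ after matching phases by rate rank
(by amplitude rank, with a warning, if the two fits carry different phase
counts). Per-phase ratios are exact when both fits split amplitude the same
way, but two equally good fits of the same curve can divide amplitude
between adjacent phases quite differently when phases are not well
separated. The peptide-level summary `mean_ln_pf()` is therefore defined as
the difference of amplitude-weighted mean log rates,

$$\overline{\ln P_f} = \frac{\sum_j Q^{int}_j \ln k^{int}_j}{\sum_j Q^{int}_j}
 - \frac{\sum_j Q^{exp}_j \ln k^{exp}_j}{\sum_j Q^{exp}_j},$$

which is invariant to how either fit allocates amplitude among phases and is
what `run_pipeline()` reports as `ln_pf_mean`.

## First-order decay fits (timing validation)

Mixer timing is validated with a chemical clock: base-catalyzed DNPA
hydrolysis, pseudo-first-order at fixed hydroxide
($k_{obs} = k_2 [\mathrm{OH^-}]$). `fit_first_order_decay()` fits
$A(t) = A_0 e^{-kt} + C$ and reports a linearized 95% confidence interval on
$k$. The default minimizes *relative* residuals $(y - \hat y)/\hat y$:
absorbance-detected decay traces carry signal-proportional error, and over a
40–500 ms time course the signal spans four decades, so unweighted least
squares would let the early points dominate while its variance estimate
averages in the essentially noise-free tail — a mismatch that makes the
nominal CI too narrow. With relative weighting the interval is calibrated
(the test suite checks coverage by simulation); `weighting = "none"` gives
the plain unweighted fit. Constant or non-decaying input degenerates to
$k = 0$ with an interval spanning zero and a `decaying = FALSE` flag.

## Fluidics planning

The labeling time in continuous mode is the delay-loop transit time, loop
volume over total flow; mixer dead volumes are taken as zero because no
dead-volume figures are available for the design, and a nonzero value can be
folded into the loop volume at calibration time. Turbulence through both the
labeling and quench mixers requires $Re = LV \cdot d/\nu \ge 2000$, with
$LV = F/(\pi (d/2)^2)$; at a 1:1 quench ratio the quench mixer carries twice
the labeling-mixer flow, so its Reynolds number is exactly double.

`plan_time_points()` uses continuous mode whenever some loop admits a flow
within the configured limits, choosing the smallest feasible loop because it
maximizes flow and hence mixing turbulence; the achieved time then equals
the request exactly. Beyond the longest continuous-feasible time — rather
than at a hard 500 ms threshold, since the crossover is a property of the
loop set — the planner switches to stop-flow: fill the largest loop at the
preset 2400 µL/s, hold for a delay quantized to the 1 ms timer, and push out
at 4800 µL/s through the quench mixer. The worst-case timing error is the
0.5 ms rounding of the delay. The default loop set (135 µL growing 1.75-fold
to ~2216 µL) is constructed, not measured from any physical instrument: the
published design states only a 1.5–2-fold progression, chosen so that
successive loops' continuous windows overlap (each loop covers a 2.34-fold
time span at the default flow limits, so any ratio below 2.34 is gap-free).
Ratios outside [1.5, 2] warn; outside [1.25, 2.5] they are rejected.

## The synthetic-data generator

`generate_uptake_tables()` forward-simulates exactly the model the pipeline
inverts: per-residue intrinsic rates slowed by a uniform true $\ln P_f$,
summed to peptide uptake, scaled by D$_2$O fraction and retention, plus
additive homoscedastic Gaussian noise, with a matched maxD series per
peptide. Defaults are the study conditions of the millisecond experiments:
the five-peptide reference panel, pD$_{read}$ 7.06, 23 °C, 95% D$_2$O, the
15-point exposure schedule from 0.05 to 300 s, triplicates, retention 0.9,
and noise SD 0.084 Da — the last fixed once from the requirement that 270
replicates yield a ±0.01 Da 95% confidence interval
($0.01\sqrt{270}/1.96$), which also corresponds to ~3% relative dispersion
at the ~2.8 Da 100 ms signal of a small peptide.

What the generator deliberately does **not** emulate: per-residue protection
heterogeneity within a peptide (a single $\ln P_f$ knob per peptide),
EX1/bimodal exchange, heteroscedastic or day-structured replicate variance,
isotope-envelope and spectral effects, and chromatographic back-exchange
dependence on gradient or temperature. Passing recovery tests on this
generator therefore demonstrates that the estimation chain inverts its own
forward model under realistic noise — a necessary condition — but not that
real spectra are processed correctly upstream of the uptake table, nor that
per-residue protection can be deconvolved from peptide-level data.

A workload-scale fixture, `generate_peptide_map()`, produces a
several-hundred-peptide map over a ~900-residue random protein (>90%
coverage) to exercise table handling at the scale of a large-enzyme
benchmark; its counts describe workload shape only.

## Problem sizes and determinism

The test suite and the acceptance script are sized for a laptop-class
single-core run: 500-seed decay-recovery simulations, 300-seed calibration
of the back-exchange slope test, 50-seed model-selection studies, a 300,000
point planner sweep at 1 ms steps, and one full five-peptide pipeline
round-trip, together finishing in a few minutes. All simulations take an
explicit integer seed; the fitting path itself is seed-free (deterministic
multi-starts), so identical inputs always give identical fits.

## Known limitations

* Protection factors are segment-averaged; no per-residue deconvolution.
* The EX2 assumption is untested by the package; EX1 behavior would bias
  stretched-exponential fits in ways the diagnostics do not flag.
* Intrinsic-rate accuracy is bounded by the shipped 1993 parameterization;
  users with newer compilations should supply them via
  `intrinsic_rate_params()`.
* The ion-product and pK temperature dependences are neglected relative to
  the Arrhenius terms, restricting the supported temperature window.
* Side-chain and histidine-labile hydrogens are out of scope.
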