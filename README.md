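# mshdx

Analysis toolkit for **millisecond-resolved hydrogen/deuterium-exchange mass
spectrometry (HDX-MS)** and for the quench-flow fluidics that makes it
possible.

Conventional HDX-MS samples labeling times of seconds to hours, so weakly
protected polypeptides — peptide hormones, exposed loops, intrinsically
disordered regions — finish exchanging inside the dead time and look
featureless. A rapid-mixing quench-flow instrument pushes the first time
point down to ~50 ms, but analyzing such data requires a connected chain of
computations that this package provides end to end:

1. **Intrinsic exchange rates** (`residue_intrinsic_rates()`,
   `intrinsic_uptake_curve()`): the random-coil chemical exchange rate of
   each backbone amide,

   k<sub>int,i</sub> = k<sub>A</sub>·F<sub>A,i</sub>·[D⁺] +
   k<sub>B</sub>·F<sub>B,i</sub>·[OD⁻] + k<sub>W</sub>·F<sub>B,i</sub>,

   parameterized from the published poly-DL-alanine reference rates and
   side-chain factor tables (Bai et al. 1993, *Proteins* 17:75; Connelly et
   al. 1993, *Proteins* 17:87), with glass-electrode pD correction,
   titratable-residue interpolation, and Arrhenius temperature correction.
   The theoretical maximum-exchange curve is
   D<sub>int</sub>(t) = f<sub>D₂O</sub> · Σ<sub>i</sub> (1 − e^(−k<sub>int,i</sub> t))
   over included residues (the first two residues and prolines are excluded).

2. **Back-exchange correction** (`estimate_backexchange()`,
   `correct_uptake()`, `normalize_percent()`): a per-peptide retention
   fraction estimated from maximally deuterated (maxD) references, a
   regression diagnostic for retention drift with mixing time, division-based
   correction to absolute uptake, and normalization to percent of the
   theoretical maximum.

3. **Kinetic fitting** (`fit_stretched_exponential()`, `select_model()`,
   `protection_factors()`): weighted nonlinear least-squares fits of

   D(t) = Σ<sub>j</sub> Q<sub>j</sub> (1 − exp(−(k<sub>j</sub> t)^β<sub>j</sub>)),  β<sub>j</sub> ∈ (0, 1], j = 1…3,

   with deterministic log-spaced multi-starts, extra-sum-of-squares F-test
   selection of the minimal adequate phase count, and segment-averaged
   protection factors ln P<sub>f</sub> = ln(k<sub>int</sub>/k<sub>exp</sub>).

4. **Quench-flow design math** (`reynolds_number()`,
   `loop_volume_from_dilution()`, `plan_time_points()`,
   `fit_first_order_decay()`, `simulate_dnpa()`): Reynolds-number turbulence
   constraints (Re = LV·d/ν ≥ 2000), dye-dilution loop calibration
   (V<sub>L</sub> = DV·C<sub>collected</sub>/C<sub>stock</sub>),
   continuous-flow vs stop-flow time-point planning at 1 ms resolution, and
   chemical-clock (DNPA hydrolysis) timing validation by single-exponential
   decay fitting.

5. **Synthetic data** (`simulation_truth()`, `generate_uptake_tables()`):
   uptake tables with known ground-truth protection factors, back-exchange
   and replicate noise, in the same state-data CSV schema the readers accept,
   so every stage of the pipeline is testable without instrument data.

Everything is data-frame-first: functions take tibbles and return tibbles,
fitted objects have `tidy()`, `glance()` and `autoplot()` methods.

## Worked example

Simulate the five-peptide reference panel with a uniform true protection
factor of ln P<sub>f</sub> = 2 applied to every residue, then run the full
pipeline (back-exchange estimation → correction → model selection →
protection factors):

```r
library(mshdx)

truth <- simulation_truth(ln_pf = 2, seed = 1)
tabs  <- generate_uptake_tables(truth)
obs   <- dplyr::bind_rows(tabs$observed, tabs$maxd)
res   <- run_pipeline(pipeline_config(observed = obs, seed = 1))
dplyr::select(res, protein, q, retention, n_phases, r_squared, ln_pf_mean, status)
#> # A tibble: 5 × 7
#>   protein            q retention n_phases r_squared ln_pf_mean status
#>   <chr>          <int>     <dbl>    <int>     <dbl>      <dbl> <chr>
#> 1 bradykinin         5     0.902        2     1.000       1.92 fitted
#> 2 leu_enkephalin     3     0.899        1     0.997       1.97 fitted
#> 3 cn_afp            35     0.900        2     1.000       1.98 fitted
#> 4 ctprh1            11     0.900        2     1.000       1.93 fitted
#> 5 ctprs             11     0.899        1     1.000       1.96 fitted
```

`q` is the exchangeable-amide count, `retention` the recovered back-exchange
retention (true value 0.9), and `ln_pf_mean` the amplitude-weighted peptide
ln P<sub>f</sub> — all five recover the simulated value of 2 to within a few
percent.

Planning labeling time points on the instrument:

```r
plan_time_points(c(0.05, 0.162, 5), instrument_config())
#> # A tibble: 3 × 10
#>   requested mode       loop_index loop_volume label_flow quench_flow delay achieved re_label re_quench
#>       <dbl> <chr>           <int>       <dbl>      <dbl>       <dbl> <dbl>    <dbl>    <dbl>     <dbl>
#> 1     0.05  continuous          1        135       2700        5400  NA       0.05     4690.     9380.
#> 2     0.162 continuous          2        236.      1458.       2917. NA       0.162    2533.     5066.
#> 3     5     stop_flow           6       2216.      2400        4800   4.08    5.00     4169.     8338.
```

Every plan stays in the turbulent regime (Re ≥ 2000 through both mixers) and
achieves the requested time to within 0.5 ms.

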