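# fretq — quantitative sensitized-emission FRET from three-image triplets

Measuring Förster resonance energy transfer (FRET) in living cells on an
ordinary epifluorescence microscope means acquiring three images per field
of view — donor-excited donor emission `I_DD`, donor-excited acceptor
emission `I_DA` (the sensitized-emission channel) and acceptor-excited
acceptor emission `I_AA` — and undoing everything instrumental that stands
between those counts and the underlying transfer probability. `fretq` is
for cell biologists and microscopists who want *absolute*, pixelwise FRET
efficiencies and stoichiometries that can be compared across instruments
and expression levels, without acceptor photobleaching, purified-protein
standards of known FRET, or lifetime hardware.

## The model

Each channel is written from the photophysics (excitation intensities
`L`, cross sections `σ`, quantum yields `φ`, detection efficiencies `η`),
and four ratios absorb all instrument dependence:

- `α^BT = η_Adet^Dem / η_Ddet^Dem` — donor bleedthrough,
- `δ^DE = L_D σ_Dex^A / (L_A σ_Aex^A)` — acceptor direct excitation,
- `γ^M = φ_A η_Adet^Aem / (φ_D η_Ddet^Dem)` — emission correction,
- `β^X = L_A σ_Aex^A / (L_D σ_Dex^D)` — excitation correction.

With `I_DA^corr = I_DA − α^BT I_DD − δ^DE I_AA`, the master equations

```
E = I_DA^corr / (γ^M I_DD + I_DA^corr)
S = (γ^M I_DD + I_DA^corr) / (γ^M I_DD + I_DA^corr + I_AA / β^X)
```

give the FRET probability and the donor fraction `S = n_D/(n_D+n_A)` in
every pixel. Crosstalks are medians over donor-only / acceptor-only
cells; `γ^M` and `β^X` come from a **single least-squares plane fit** in
the intensity space `{I_DD, I_DA^corr, I_AA}`, using only a sample of
known stoichiometry (`S₀ = 0.5` for intramolecular constructs) with a
sufficient spread of FRET values. The stoichiometry then doubles as a
per-pixel quality score: a Gaussian confidence index
`W = exp(−(S−S₀)²/2σ_S²)` feeds a weighted Gaussian filter
`E_filt = ((W∘E)∗G)/(W∗G)` that removes background and
anomalous-stoichiometry structures from FRET maps.

The package also ships a forward-model simulator (cells, shot noise,
dark offset, read noise, flat field) providing ground truth for every
stage, closed-form mixture trajectories for free-donor/free-acceptor
contamination, and re-implementations of two alternative calibration
schemes (a linear 1/S-vs-E fit and a two-step two-standard method) with
a benchmarking harness.

## Worked example

Simulate a complete calibration study — three 1:1 FRET standards (mean
FRET 0.503 / 0.417 / 0.351, 26 cells each, expression spanning two
decades) plus donor-only and acceptor-only cells, imaged through an
instrument with crosstalks 0.421 / 0.110 and corrections `γ^M = 2.10`,
`β^X = 1.167` — then run the full analysis chain on it:

```r
library(fretq)
sim <- simulate_fret_dataset(seed = 1)
res <- analyze_fret_study(sim, boot_reps = 100, seed = 1)
res$calibration
#> <correction_factors>
#>   alpha_BT (bleedthrough):       0.421 +/- 7.4e-05
#>   delta_DE (direct excitation):  0.11 +/- 2.3e-05
#>   gamma_M  (emission):           2.1 +/- 0.00052
#>   beta_X   (excitation):         1.167 +/- 0.00017
#>   plane fit R^2 = 1 (107914 px, 78 cells, S0 = 0.5)
res$per_construct
#>   n_cells mean_E   sem_E mean_S    sem_S construct E_generative
#> 1      26  0.505 0.00395    0.5 2.46e-05       hiE        0.503
#> 2      26  0.414 0.00397    0.5 1.95e-05      midE        0.417
#> 3      26  0.353 0.00398    0.5 2.72e-05       loE        0.351
res$diagnostics[c("rho_E_IAA", "rho_E_S")]
#> $rho_E_IAA
#> [1] 0.0002
#> $rho_E_S
#> [1] -0.016
```

Reading: all four correction factors are recovered to their generative
values; each construct's mean-of-per-cell-medians FRET lands within its
standard error of the ground truth; and the two rank-correlation
diagnostics are near zero — the calibrated `E` is independent of
concentration (`I_AA`) and decoupled from `S`, which is what
"quantitative" means operationally. On real data the same chain runs via
`read_triplet()`, `run_pipeline()` or the thin command-line front end in
`inst/cli/fretq.R` (subcommands `simulate`, `register`, `calibrate`,
`analyze`, `run`).

See `vignettes/quantitative-fret.Rmd` for the model's assumptions, the
simulator's design and its limits, and every numerical choice.

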