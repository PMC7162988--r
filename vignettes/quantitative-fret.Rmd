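---
title: "Quantitative three-image FRET: model, calibration and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative three-image FRET: model, calibration and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fretq)
```

## The measurement problem

Sensitized-emission FRET imaging acquires three images per field of view:
`I_DD` (donor excitation, donor emission), `I_DA` (donor excitation,
acceptor emission) and `I_AA` (acceptor excitation, acceptor emission).
The raw ratio of these channels is not a FRET efficiency: part of `I_DA`
is donor fluorescence bleeding through the acceptor filter, part is
acceptor fluorescence from direct excitation at the donor wavelength, and
the remainder is weighted by how efficiently each fluorophore is excited
and detected relative to the other. `fretq` models each channel from the
photophysics,

$$I_{AA} = n_A L_A \sigma_{Aex}^{A}\,\phi_A\,\eta_{Adet}^{Aem},$$
$$I_{DD} = n_D L_D \sigma_{Dex}^{D}(1-E)\,\phi_D\,\eta_{Ddet}^{Dem},$$
$$I_{DA} = n_D L_D \sigma_{Dex}^{D} E\,\phi_A\,\eta_{Adet}^{Aem}
  + n_D L_D \sigma_{Dex}^{D}(1-E)\,\phi_D\,\eta_{Adet}^{Dem}
  + n_A L_D \sigma_{Dex}^{A}\,\phi_A\,\eta_{Adet}^{Aem},$$

with $n_D$, $n_A$ the donor and acceptor numbers in a pixel (real-valued
ensemble quantities, not integers) and $E$ the FRET probability. Rather
than measuring all twelve photophysical parameters, four ratios suffice:

* `alpha_BT` — donor bleedthrough, $\eta_{Adet}^{Dem}/\eta_{Ddet}^{Dem}$;
* `delta_DE` — acceptor direct excitation,
  $L_D\sigma_{Dex}^{A}/(L_A\sigma_{Aex}^{A})$;
* `gamma_M` — emission correction,
  $\phi_A\eta_{Adet}^{Aem}/(\phi_D\eta_{Ddet}^{Dem})$;
* `beta_X` — excitation correction,
  $L_A\sigma_{Aex}^{A}/(L_D\sigma_{Dex}^{D})$.

With the crosstalk-corrected sensitized emission
$I_{DA}^{corr} = I_{DA} - \alpha^{BT} I_{DD} - \delta^{DE} I_{AA}$, the
master equations

$$E = \frac{I_{DA}^{corr}}{\gamma^M I_{DD} + I_{DA}^{corr}}, \qquad
  S = \frac{\gamma^M I_{DD} + I_{DA}^{corr}}
           {\gamma^M I_{DD} + I_{DA}^{corr} + I_{AA}/\beta^X}$$

return, pixel by pixel, an absolute FRET probability and the stoichiometry
$S = n_D/(n_D+n_A)$ — both instrument- and concentration-independent.
`beta_X` affects only $S$, never $E$ (a structural property the suite
asserts). The fourth possible image (acceptor excitation, donor emission)
carries no signal and is not modelled.

## Single-step calibration

Crosstalks come from single-fluorophore samples: the pooled per-pixel
median of `I_DA/I_DD` over donor-only cells gives `alpha_BT`, of
`I_DA/I_AA` over acceptor-only cells gives `delta_DE`. At least five cells
are recommended (the package warns below that); uncertainty is a bootstrap
over cells, which matches the cell-level framing of the variability (the
estimator behind published "±" values is generally unstated).

For the remaining two factors, a sample of known stoichiometry $S_0$ obeys

$$\beta^X \gamma^M I_{DD} + \beta^X I_{DA}^{corr}
  = \frac{S_0}{1-S_0} I_{AA},$$

a plane through the origin in the intensity space
$\{I_{DD}, I_{DA}^{corr}, I_{AA}\}$. One ordinary least-squares fit with
no intercept over all in-cell pixels yields $\beta^X\gamma^M$ and
$\beta^X$ simultaneously — a single step, on the sample of interest itself
if its stoichiometry is known by construction (intramolecular constructs:
$S_0 = 0.5$). A dataset with a single FRET level is a *line* in this
space and admits infinitely many planes; `fit_plane()` therefore aborts
when the ratio of singular values of the column-normalized design falls
below `1e-3` (the operational meaning of "the FRET values must be
sufficiently spread"). Numerical choices, all deliberate:

* pixels are pooled across cells and weighted equally (the pooled-pixel
  reading of the published procedure; a cell-weighted fit is a plausible
  alternative we did not adopt);
* the fit is unweighted OLS, exactly as stated by the source method;
* $R^2 = 1 - SS_{res}/SS_{tot}$ with $SS_{tot}$ about the mean response;
* out-of-range $E$, $S$ values are *never clipped* — noise pushes pixels
  outside $[0,1]$ and clipping would bias medians; invalidity
  (non-positive denominators, masked or non-finite pixels) is an `NA`
  sentinel propagated through all statistics.

Dataset summaries are medians per cell, then mean ± SEM across cells,
because cell-to-cell variability, not pixel statistics, dominates.

Two diagnostics close the loop: the Spearman rank correlation of $E$
against `I_AA` (a pure concentration readout — near zero means the
calibrated FRET is concentration-independent) and against $S$ (near zero
means the E–S cloud of a fixed-stoichiometry sample is horizontal; with
`gamma_M = beta_X = 1` it visibly tilts).

## Confidence weighting and spatial filtering

For fixed-stoichiometry samples, $S$ doubles as a quality score. Each
pixel gets

$$W = \exp\!\left(-\frac{(S-S_0)^2}{2\sigma_S^2}\right),$$

and the FRET map is smoothed by the normalized convolution
$E_{filt} = ((W\circ E) * G)/(W * G)$ with a Gaussian kernel $G$.
Defaults: $S_0 = 0.5$, $\sigma_S = 0.1$, kernel sd 1.5 px truncated to
7×7 — a typical working point at which pixels with $S$ outside roughly
$[0.4, 0.6]$ are strongly down-weighted. Because the Gaussian score never
reaches zero, pixels whose *own raw* weight falls below `W_th = 0.5` are
invalidated outright (the threshold applies to the pixel's local weight,
not a smoothed one). Border handling renormalizes the kernel over the
in-image support, equivalent to zero-padding $W$; a zero-weight pixel
contributes nothing to any neighbour, and each output value is a convex
combination of in-support $E$ values. Note the width parameter enters as
a standard deviation in the exponent ($\sigma_S^2$ in the denominator),
and is used as such throughout.

## Free donor and free acceptor mixtures

When free donors coexist with a 1:1 construct of intrinsic $(E_0, S_0)$
at ratio $r$ per construct donor, the apparent quantities are

$$E_{app} = \frac{1}{1 + (1-E_0+r)/E_0}, \qquad
  S_{app} = \frac{1+r}{1/S_0 + r},$$

and eliminating $r$ gives the trajectory
$S_{app} = (E_0/E_{app}) / (1/S_0 + E_0/E_{app} - 1)$ along which the
tilted E–S cloud lies; `fit_intrinsic_e0()` fits it (vertical residuals
in $S$ by default) to recover $E_0$. Free acceptors leave $E$ unchanged
and depress $S$ to $1/(1/S_0 + r)$; this formula is not printed in the
source literature and is derived here from $S = n_D/(n_D+n_A)$, so the
suite validates it against the forward model rather than trusting the
algebra. Simultaneous free-donor *and* free-acceptor deconvolution is out
of scope (the pixel-ensemble measurement cannot separate them), and
$E_{app}$ is always reported as apparent, never relabelled intrinsic.

## Alternative calibrations and the benchmark harness

Two rival schemes are re-implemented for benchmarking, both mathematically
equivalent parameterizations of the same master equations: the linear
1/S-vs-E fit (`lee_calibration`; $\gamma^M \equiv \gamma$,
$\beta^X \equiv \beta$) and the two-step two-standard scheme
(`chen_calibration`; $\gamma^M \equiv G$, $\beta^X \equiv 1/(G k)$).
Because their published algebra lives in supplements, both
implementations are *accepted only through an equivalence oracle*: on
noise-free synthetic data they must reproduce the generating instrument's
factors exactly, and the test suite enforces this. For the 1/S fit we
derived $1/S_{raw} = (1 + \beta\gamma) + \beta(1-\gamma) E_{raw}$ for 1:1
data, inverted as $\beta = \Omega + \Sigma - 1$,
$\gamma = (\Omega-1)/\beta$; pixels with $S_{raw} < 0.05$ are excluded
because $1/S$ diverges. For the two-standard scheme, step 1 uses the
constraint that the $G$-corrected total donor signal per acceptor is
construct-independent; step 2 inverts that ratio at known stoichiometry.
The harness (`compare_methods`, `compare_bootstrap`,
`reduced_range_test`) refits all three schemes on shared pixel data,
bootstraps them at matched sample sizes, and refits on construct pairs to
shrink the FRET range. A hook for injecting a deliberately off-plane
population is simply passing such pixels to the harness; no cause is
assumed for real off-plane constructs.

## What the simulator emulates — and what it does not

`generate_scene()` places non-overlapping elliptical cells on a dark
background; `render_triplet()` evaluates the signal model and applies a
camera: Poisson shot noise on expected photons, then multiplicative
flat field, then dark offset and Gaussian read noise — the forward model
whose effects the preprocessing stage removes. `simulate_fret_dataset()`
assembles a full calibration study. Its defaults are the study
conditions, chosen once:

* three 1:1 constructs with mean FRET probabilities 0.503, 0.417, 0.351
  (published benchmark values for short/medium/long linker standards);
* 26 cells per construct, 10 donor-only and 12 acceptor-only cells,
  matching the benchmark experiment's cell counts;
* cell-to-cell FRET sd 0.02 (back-computed from published SEMs of
  per-cell medians, 0.4–0.8% over ~26 cells) and pixel-level FRET sd 0.1
  (published per-construct pixelwise spreads are ~0.12);
* per-cell mean expression spanning two decades (4e3–4e5 donors/pixel,
  keeping the dimmest channel above ~500 expected photons, i.e. SNR ≳ 20),
  with 20% log-normal pixel variation within cells;
* instrument realizing crosstalks 0.421/0.110 and corrections
  $\gamma^M = 2.10$, $\beta^X = 1.167$; camera with dark offset 100, read
  noise 3 and an 8% vignetting flat field.

Expression levels are *stratified*: each construct's cells cover the same
jittered log-spaced concentration grid. An i.i.d. log-uniform draw at 26
cells per construct routinely makes one construct brighter than another
by sampling accident, which injects a spurious FRET–intensity rank
correlation that says nothing about the method; a shared expression
protocol is the realistic counterpart. Single-fluorophore cells have
$E \equiv 0$ exactly — there is no FRET partner.

Field size is 192×192 px, giving ≈1.1×10⁵ in-cell pixels per study; the
published benchmark pooled 5×10⁶ pixels. The reduced size keeps a full
simulate–calibrate–analyze cycle in a few seconds; cell-level statistics
(the dominant uncertainty) are at full scale since the cell count is
matched.

Not emulated: optical blur (no PSF — pixels are independent),
photobleaching and other kinetics, spectral variation within a channel,
sub-cellular organelles with deviant chemistry (anomalies are injected
directly into $E$/$S$ maps when testing the filter), and acceptor
emission in the donor channel (absent from the signal model). Passing
tests therefore demonstrate correctness of the estimators under the
stated noise model, not robustness to every biological artifact.

## Preprocessing choices

Camera correction is `(raw − dark) / flat`, the flat itself
dark-subtracted and normalized to mean 1; small negatives are kept.
Channel registration estimates local displacements by block
cross-correlation (FFT, sub-pixel parabolic peak interpolation) on a bead
field and fits a full affine (translation, rotation, shear,
magnification) by least squares; the donor image is warped onto the
acceptor frame, bilinear by default, nearest-neighbour available for
exactness tests. Pixels leaving the frame become `NA` and are excluded
from masks rather than zero-filled — zeros would enter the plane fit as
fake data. Segmentation is an Otsu threshold on the Gaussian-smoothed,
log-compressed sum image `log1p(I_DD + I_AA)` (log compression keeps dim
cells above threshold when expression spans decades), holes filled,
components under 100 px dropped; the mask only gates which pixels enter
statistics. Interpolation order and mask-edge policy are package choices;
the sources are silent on both.

## Worked example

```{r example, eval = FALSE}
sim <- simulate_fret_dataset(seed = 1)
res <- analyze_fret_study(sim)
res$calibration
res$per_construct
res$diagnostics
```

The acceptance script `scripts/acceptance.R` runs exactly this study at a
given seed and reports the two headline diagnostics (|Spearman rho| of E
vs I_AA and of E vs S) as JSON; the README shows the printed output.

## Known limitations

* The plane fit treats intensities as error-free regressors; at very low
  SNR errors-in-variables attenuation would bias it (negligible above
  ~30 photons SNR at the simulated expression spreads, as the suite's
  bias checks show).
* Crosstalk medians of Poisson ratios carry a small positive bias at low
  counts; the denominator noise floor (5× read noise by default) guards
  the worst of it.
* Registration assumes an affine map; nonlinear distortion is out of
  scope.
* The confidence filter assumes one expected stoichiometry per image;
  mixed-population images need masking before filtering.
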