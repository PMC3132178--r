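---
title: "Pattern-dependent response modulations in model tangential cells: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pattern-dependent response modulations in model tangential cells: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The scientific problem

Wide-field motion-sensitive neurons of the fly lobula plate (lobula-plate
tangential cells, LPTCs) pool the outputs of retinotopic arrays of
correlation-type elementary motion detectors (EMDs). Even under perfectly
constant-velocity motion of a natural scene, their response is not constant:
local image structure drives temporal modulations of the response amplitude
("pattern noise"). `flymotion` simulates this pathway end to end — panoramic
scene, compound-eye optics, photoreceptor and lamina preprocessing, four EMD
variants, and nonlinear dendritic pooling — and quantifies how the amplitude
of the pattern-dependent modulations depends on the size and shape of the
pooling receptive field.

# Model stages

## Input stage

1. **Optics.** The scene is blurred by an isotropic Gaussian whose full
   width at half maximum equals the ommatidial acceptance angle
   $\Delta\rho = 1.64^\circ$, i.e.
   $\sigma = \Delta\rho / (2\sqrt{2\ln 2}) \approx 0.696^\circ$. Azimuth is
   convolved circularly (FFT), elevation with edge replication
   (`gaussian_prefilter()`).
2. **Sampling.** Photoreceptors sit on a rectangular grid with
   inter-receptor angle $\Phi = 1.25^\circ$: 288 receptors close the
   azimuthal ring, 56 rows span $\pm 35^\circ$ of elevation. Horizontal
   image motion is simulated by stepwise displacement at 1 kHz; luminance
   at displaced positions is obtained by bilinear interpolation
   (`sample_receptors()`).
3. **Phototransduction.** A static Naka–Rushton nonlinearity
   $u = I^a / (I^a + I_0^a)$ with $a = 0.7$ and the working point $I_0$ set
   per scene to the geometric mean of its luminance (`naka_rushton()`,
   `estimate_I0()`).
4. **Lamina band-pass.** Serial recursive first-order low-pass
   ($\tau_L = 8$ ms) and high-pass ($\tau_H = 400$ ms) filters mimic lamina
   monopolar cells. Filters use the exact-exponential discretisation
   $y_t = y_{t-1} + (1 - e^{-\Delta t/\tau})(x_t - y_{t-1})$, and the
   high-pass is implemented as identity minus low-pass so that LP + HP
   reconstruct the input exactly at every step — this complementarity is a
   tested invariant, and the closed-form step responses make the unit tests
   exact.

## Correlator stage

Each EMD correlates horizontally adjacent receptor channels: the delayed
arm is a first-order low-pass with $\tau_{lp} = 40$ ms, and the two
mirror-symmetric half-detectors are half-wave rectified,

$$P^+ = \max(0,\; \mathrm{LP}_{\tau_{lp}}(x_{left}) \cdot x_{right}), \qquad
  P^- = \max(0,\; x_{left} \cdot \mathrm{LP}_{\tau_{lp}}(x_{right})),$$

so that motion toward increasing azimuth (front-to-back for the modelled
HSE cell) is the preferred direction. Four variants are available
(`emd_params()`):

* **basic** — nothing beyond the above.
* **adaptive** — a first-order high-pass in the cross (undelayed) arm whose
  time constant $\tau_h \in [0, 500]$ ms relaxes toward its maximum at rate
  $K = 0.1\,\mathrm{kHz}$ and is driven toward its minimum by
  $S = \mathrm{LP}_{\tau_S}(|L'|)$ ($\tau_S = 500$ ms), the smoothed rate of
  change of the delayed arm's low-pass signal:
  $d\tau_h/dt = K(\max_{\tau h} - \tau_h) - g\,S\,(\tau_h - \min_{\tau h})$.
  The published description fixes the boundary behaviour but not the literal
  rate law; this relaxation ODE is our reading of "speed of adaptation
  proportional to the position of $\tau_h$ in the range", with the drive
  taken locally per channel (the figure-caption reading) rather than from
  global LPTC activity. The linear ODE is integrated exactly per step
  (exponential update), which is unconditionally stable; a forward-Euler
  step oscillates against the clamp under strong drive. The gain $g$ maps
  signal scale to rate; by default it is calibrated per run so that half the
  dynamic range of $S$ (half its 95th percentile over the calibration
  window) balances the relaxation at mid-range, i.e. $g = K / S_{half}$.
* **saturation** — the band-pass output of each input line is compressed as
  $\tanh(a_{sat}\, s)$. The scale is calibrated per run as
  $a_{sat} = c/\bar{q}_{75}$ with $\bar{q}_{75}$ the mean over channels of
  each channel's 75th percentile of $|s|$ and $c = 1$, so a typical
  (75th-percentile) input lands at $\tanh(1)$. $c$ is a free constant of the
  published description; 1 is our default and can be overridden via
  `emd_params(a_sat = )`.
* **input_gain** — each input line is divided by its running mean absolute
  deviation, $\mathrm{mad}_t = \mathrm{LP}_{\tau_A}(|s_t|)$ with
  $\tau_A = 200$ ms, plus a guard $\varepsilon$ set to $10^{-6}$ of the mean
  calibration-window signal magnitude.

Both saturating transforms act on the band-pass LMC output, i.e. the last
stage before the correlator ("in the input lines of the EMDs").

## Integration stage

Half-detector outputs are pooled by the gain-control mechanism,

$$Z = \frac{E^+ \sum w\,P^+ - E^- \sum w\,P^-}
           {G_0 + \sum w\,P^+ + \sum w\,P^-},$$

with $E^+ = E^- = G_0 = 1$, so $|Z| < 1$ always and the response grows
sublinearly with the number of pooled sites. The inhibitory reversal
potential enters subtractively (hyperpolarising) — required for the strongly
directional response. Weights $w \in [0,1]$ model synaptic density and
therefore multiply $P^\pm$ in both numerator and denominator (conductance
weighting). Receptive fields are counted in receptors: a row of $n$
receptors hosts $n - 1$ EMD columns, and the closed 288-receptor ring hosts
288. Rectangular fields are centred on the horizon and the image's vertical
axis; when parity forces an off-centre placement the field is rounded
toward the equator/front. The HSE weight field is an anisotropic Gaussian
(centre $-15^\circ$ azimuth, $+2^\circ$ elevation; $\sigma_{elev} = 35^\circ$;
$\sigma_{az} = 120^\circ$ on the lateral flank and $25^\circ$ on the
frontal flank) normalised to peak 1 — peak versus unit-integral
normalisation is immaterial because the analysis normalises responses to
their mean. The published sign convention for the two azimuthal widths mixes
the azimuth and elevation symbols; we read the asymmetry as azimuthal
(lateral versus frontal of the centre), consistent with the surrounding
description.

## Stimulus and data analysis

The standard protocol (`stimulus_spec()`) rotates the panorama at
$60^\circ/\mathrm{s}$ in the preferred direction for 12 s at 1 kHz — exactly
two full rotations — and discards the first 6 s (the first rotation) to
exclude onset transients. Responses are normalised to their retained-trace
mean, $N_t = (Z_t - \bar{Z})/\bar{Z}$ (`normalize_response()`), and the
pattern-dependent modulation of a receptive field is the RMS distance to
the normalised full-field reference trace,
$s = \sqrt{\tfrac{1}{T}\sum_t (N^{m,n}_t - N^{full}_t)^2}$
(`modulation_sd()`). The pointwise subtraction (rather than subtracting only
the reference mean) is the reading under which $s$ vanishes identically at
full-field size, which the analysis requires. Population ($1/T$)
normalisation is used here and in the RMS contrast
$C_{RMS} = \sigma_L / \bar{L}$ — immaterial at $T = 6000$ but fixed for
bit-reproducibility. Percentage reductions between geometries are
$100\,(1 - s_{large}/s_{small})$.

# Synthetic panoramas

The five photographed panoramas behind the original analysis were never
deposited, so the package generates surrogates with the statistics the
analysis relies on (`generate_natural_panorama()`): Gaussian white noise is
shaped to a $1/f^\beta$ amplitude spectrum in the 2-D Fourier domain (which
makes the azimuthal wraparound exact), the upper ("sky") and lower
("ground") half-fields are reweighted to a target contrast ratio, and the
field is clipped at zero and iteratively rescaled until the global RMS
contrast (within 2%), the sky/ground contrast ratio (within 10%) and the
mean luminance are met. Defaults: 2880 x 560 px at $0.125^\circ$/px (10 px
per receptor spacing, at least 4 px per optics $\sigma$ to avoid aliasing),
$\beta = 1$, sky/ground contrast ratio 3, $C_{RMS} = 0.4$, mean luminance
100. The spectral slope and the contrast ratio follow the broadband
$1/f$-amplitude character and the pronounced ground-versus-sky contrast
asymmetry of outdoor scenes; $C_{RMS} = 0.4$ sits in the middle of the
range typical of terrestrial panoramas, and the mean is arbitrary because
the Naka–Rushton working point adapts to each scene.

What the surrogates deliberately do **not** reproduce: sparseness. A shaped
Gaussian field has no isolated high-contrast edges, no large uniform sky
patches, no heavy-tailed luminance distribution. Consequences observed in
this package's own acceptance computations: the geometry-dominated result —
pooling 256 receptors in one row removes about 97% of the single-EMD
pattern noise — transfers cleanly, but the variant-dependent square-field
statistics do not. On Gaussian scenes the tanh saturation strongly
compresses the heavy relative excursions of the *single-EMD* trace, so the
saturating variants start from a much smaller $s_{2}$ and show *smaller*
relative reductions than the basic model, the opposite ordering to that
reported on real HDR scenes, where saturation mainly equalises local
contrast across the image and steepens the decay with field size. Passing
the 1-D criterion therefore validates the pooling geometry; the square-field
variant ordering is a property of real-scene sparseness that these
surrogates cannot, and do not, reproduce.

Deterministic fixtures with closed-form statistics (drifting sine gratings,
step edges) back the analytic unit tests. For full-ring constancy checks
the grating wavelength is chosen incommensurate with the receptor spacing
(e.g. $36^\circ$, 28.8 receptors per cycle): when receptors per cycle is an
integer, every detector sits at the same set of grating phases and the
ring-sum retains a coherent ripple at the receptor-passing frequency
($v/\Phi = 48$ Hz); incommensurate wavelengths spread the phases and the
residual cancels to $\mathrm{CV} < 10^{-4}$.

# Numerical choices

* **Engine.** The per-millisecond loop (sampling, transduction, filtering,
  correlation, pooling) runs in C++ over the full receptor grid, with all
  state per channel and per-receptive-field sums accumulated streaming —
  memory scales with grid size times number of fields, not with trace
  length. A pure-R pipeline assembled from the exported per-operation
  functions is kept as the independent reference; the test suite requires
  agreement to $10^{-12}$ on all four variants.
* **Initialisation.** Filter states start at the first sample's adapted
  steady state (low-pass state = first input, high-pass output = 0,
  $\tau_h$ at its relaxed maximum), shortening transients; the discarded
  first rotation removes the rest.
* **Calibration windows.** $a_{sat}$, $\varepsilon$ and $g$ are computed on
  a front-end-only pre-pass over the first rotation, subsampled every 4 ms,
  so the retained trace sees fixed constants and the run stays
  deterministic.
* **Placement rounding.** Centred receptor index sets round toward the
  equator/front when parity forces a choice; the single-EMD reference array
  sits on the row just below the horizon ($-0.625^\circ$).
* **Degenerate inputs** are rejected with messages: non-positive contrast
  or mean in the generator, all-zero scenes in $I_0$ estimation, zero-mean
  traces in normalisation, empty calibration windows, out-of-range
  receptive fields.

# Problem sizes of the shipped study

`pattern_noise_study()` runs the full stimulus protocol on five seeded
panoramas per geometry. The 1-D protocol simulates a single receptor row
(its closed one-row ring is the reference; the whole-image reference was
verified to give the same $s$ to three decimals and the one-row run is an
order of magnitude cheaper). The square protocol simulates the full 56-row
grid with the whole-image ring as reference. The acceptance script and the
test suite recompute these from scratch; tests scale the square protocol to
three seeds.

# Known limitations

* Rectangular receptor lattice (as in the original model), not the
  hexagonal ommatidial lattice; no photoreceptor noise; no dynamic light
  adaptation beyond the static Naka–Rushton working point.
* Only horizontal constant-velocity rotation; no translational optic flow,
  no depth structure.
* The adaptive variant's rate law and the saturation constant $c$ are
  interpretations of underdetermined published descriptions (see above);
  both are configurable.
* Gaussian surrogate scenes — see the synthetic-panorama section for which
  conclusions do and do not transfer to real imagery.
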