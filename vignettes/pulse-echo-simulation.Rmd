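---
title: "Simulating pulse-echo ultrasound imaging and color Doppler with echosim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating pulse-echo ultrasound imaging and color Doppler with echosim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(echosim)
```

## The model

echosim simulates what a linear ultrasound array records when it insonifies
soft tissue modeled as a cloud of independent point scatterers in a
homogeneous, isotropic, non-dissipative medium (sound speed $c$, density
$\rho_0$). Each scatterer is an instantaneous fractional density
perturbation with amplitude $a_s = \Delta\rho/\rho_0$. Under the linear
scattering (Born) approximation, the trace received by element $j$ after
element $i$ transmits is

$$p_r(t) \;=\; \frac{\partial}{\partial t}\left[\frac{1}{2\rho_0 c^2}\,
  p_T(\vec r_i, \vec r_n, t+\tau_i) \ast p_R(\vec r_j, \vec r_n, t+\tau_j)\right] a_s,$$

summed over scatterers $n$, where $\ast$ is temporal convolution,
$\tau_i,\tau_j$ are transmit/receive delays, and $p_T$, $p_R$ are the
*intermediate fields*: the transient pressures that the transmitting and
receiving elements would produce at the scatterer location when driven with
the normal velocities $w_1(t)$ and $w_2(t)$. Splitting the excitation
$v = w_1 \ast w_2$ across the two legs lets every imaging mode be written as
sums of such pairwise convolutions.

The intermediate fields are computed by Gauss–Legendre quadrature of the
Rayleigh integral with *analytic time evaluation*:

$$p(\vec r, t) \;=\; \frac{\rho_0}{2\pi} \sum_q w_q\,
  \frac{\dot w\!\left(t - d_q/c - \tau\right)}{d_q},$$

with nodes $q$ on the element face and $d_q$ the node-to-point distance.
Because the excitation is a closed-form sinusoid burst, $\dot w$ is
evaluated exactly at every sample time — there is no sampled-impulse-response
aliasing and no interpolation on the baseline path. The delays live *inside*
the evaluation, which is what makes this the reference against which the
cached delay-shifting strategies (below) are judged.

Transmit events differ only in which elements fire with which delays and
apodization:

* **synthetic aperture** — one event per element, no delays;
* **B-mode** — a Hanning-apodized sub-aperture focused at a fixed depth,
  walking across the array, one event per scan line;
* **plane wave** — all elements with the linear delay law
  $\tau_i = x_i \sin\theta / c$, one event per steering angle.

In all modes the transmit intermediates are summed *before* the convolution
with each receive intermediate, which is what keeps the cost per event at
one convolution per (scatterer, channel) pair.

## Numerical choices

**Quadrature.** The default rule for imaging is 6 Gauss–Legendre abscissas
across the element width and a single node in elevation. Six lateral nodes
reproduce a dense $\lambda/8$ sub-element discretization of the same
aperture model to NRMSE $\sim 3\times 10^{-5}$ at 60 mm (the package's
oracle-equivalence test). One caveat is worth stating clearly: the
*elevation* axis of a tall (7 mm) element does not admit a small fixed rule
at imaging depths. The integrand there is a truncated sinusoid whose
support boundary sweeps across the element face (about 66 ns of elevation
delay spread at 60 mm against a 333 ns single-cycle pulse), so even a
$\lambda/8$ uniform elevation rule still differs from a $4\times$ denser
one by $\sim 6\times10^{-3}$ NRMSE. Pointwise elevation convergence is
therefore slow for *any* quadrature of this kind; for amplitude imaging
this only smears off-plane contributions that beamforming sums
incoherently anyway, and `element_quadrature()` lets nearfield work use a
denser rule (a 2×25 grid is a reasonable choice below ~20 mm).

The **color Doppler chain defaults to 3×12 nodes** instead: with a single
elevation node an element has no elevation directivity at all, so the
Doppler sample volume spans the vessel's entire 10 mm elevation extent and
a parabolic profile averages toward $2/3$ of its true center value.
Modeling the 7 mm height restores the element's physical elevation beam;
twelve elevation nodes keep the discretization sidelobes from inflating
the beam tails (two-way $E[y^2]$ of 3.8 mm² vs 3.6 mm² converged, against
4.4 mm² for a 6-node rule), while three lateral nodes are ample for a
0.3 mm-wide element. This is a matter of modeling the stated element
geometry, not a tunable constant.

**Delay handling.** Three interchangeable strategies implement per-event
delays: `analytic` (re-evaluate the field at shifted times; exact),
`cached_linear` (shift stored undelayed waveforms by linear interpolation on
the base grid), and `cached_upsampled` (store a 4× oversampled copy, shift
there, decimate by taking every 4th aligned sample, no anti-alias filter).
The convergence harness (`convergence_study()`) quantifies the ranking: the
upsampled cache tracks the analytic baseline closely while plain linear
shifting carries a persistent penalty, and all methods converge as the RF
sampling frequency grows. The harness's reference is the analytic path at
16× the largest test frequency with the dense uniform rule, elevation-matched
to the test quadrature so the comparison isolates delay handling.

**Time axes.** RF grids start at an exact multiple of $1/f_s$, auto-sized
from the two-way propagation span plus pulse durations, delay extremes, the
element half-diagonal, and a 10% margin. The discrete convolution carries
the $1/f_s$ integration step, and the outer time derivative is a centered
finite difference (one-sided at the ends), applied once per channel after
superposition.

**Beamforming.** Delay-and-sum with a constant f-number: at depth $z$,
channels within $z/(2 f_\#)$ of the pixel contribute, sampled by linear
interpolation at the transmit time plus the pixel-to-channel flight time
*plus the two-way pulse group delay* $(T_{tx}+T_{rx})/2$. That last term
matters more than it looks: the echo envelope is centered that long after
the geometric flight time, and without the correction every image is
registered ~0.8 mm deep (for the 4+1-cycle 2.5 MHz Doppler pulse), which
showed up in development as an antisymmetric ±0.15 m/s skew of the
parabolic flow profile across the 45° vessel. Beamforming channel data is
converted to its analytic signal first (complex frames), so envelope
detection is a modulus and slow-time phase is available for Doppler;
`envelope_logcompress()` normalizes to the global peak, compresses to dB,
and clips at the display dynamic range (default 0 to −60 dB). Coherent
compounding is a pre-envelope sum across events.

Receive apertures near the array edge can be kept *symmetric* about the
pixel (`symmetric = TRUE`, the Doppler default): when the f-number cone
runs off a small array, the surviving one-sided aperture tilts the
effective receive direction (up to ~12° for a 64-element array across a
±11 mm image) and biases Doppler phase exactly as off-axis color-flow
estimates are known to do. A 256-element aperture is f-number-limited
everywhere in its image, so symmetric truncation is also what the
full-scale geometry implies. B-mode amplitude imaging keeps the one-sided
default, where more aperture beats direction fidelity.

**B-mode receive focusing** is per-depth dynamic by default; a fixed-foci
mode freezes the receive delay law at a set of focal depths (e.g. 35–85 mm
in 10 mm steps), each applied within its axial segment, for fidelity
comparisons with hardware-style processing.

## Color Doppler

Each steering angle is acquired as its own slow-time ensemble: the flow
phantom advances by $1/f_{PRF}$ between transmissions (and across angles,
so time is continuous), static echoes are computed once per angle and added
to every frame. The chain is: wall filter (per-pixel slow-time mean
subtraction — exact for truly static clutter), magnitude threshold (4 dB
below the post-filter peak, masking noise-dominated pixels), the lag-one
autocorrelation estimator

$$\hat R = \frac{1}{K-1}\sum_{k=1}^{K-1} s_k^* s_{k+1}, \qquad
  v = \frac{c\, f_{PRF}}{4\pi f_0 \cos\theta}\,
      \operatorname{atan2}\!\big(\operatorname{Im}\hat R, \operatorname{Re}\hat R\big),$$

with $\hat R$ averaged coherently across the per-angle ensembles before the
phase is taken (inter-angle phase offsets never mix into slow time), and a
mask-normalized 2-D Hamming moving average (1.54 mm × 1.57 mm) on the
velocity map. With the conventional analytic signal
($\cos\omega t \mapsto e^{i\omega t}$) this sign convention reports flow
*toward* the array as positive — the vessel phantom's default flow
direction has a toward-array axial component so recovered speeds are
positive.

Two conventions deserve a note. First, $\theta$ is the **beam-to-flow
angle** (beam along $+z$); the alternative reading "angle to the array
tangent" would make axial flow degenerate, and for the 45° vessel both
coincide. Second, the estimator's $f_0$ is the *nominal* excitation center
frequency; the received spectrum's centroid sits slightly above it (the
outer time derivative and the broadband 1-cycle receive pulse tilt the
spectrum), so estimates carry a small (few percent) multiplicative bias
that is part of the method as defined, not a bug — the rigid-motion
identity tests therefore use a narrowband 4+4-cycle pulse pair.

The lateral profile across the vessel is computed in vessel coordinates:
pixels are binned by signed perpendicular distance from the axis and
averaged along the axis over the interior plus a 1 mm band outside the
walls. Binning by image column instead would average each A-line over a
full chord of the tilted cylinder and flatten even a parabolic profile to a
constant $2/3$ of its center value, which is clearly not what a profile
across a vessel means. The flow-recovery driver
(`flow_recovery_experiment()`) uses 0.5 mm profile bins (about twenty
points across the vessel, each pooling tens of pixels) and skips the map
smoothing before the profile — the binned averaging already pools
spatially, and pre-smoothing only flattens the peak the profile is meant
to estimate; the smoothed map remains the right thing to *display*.

Even so, the absolute parabolic peak recovery at the reduced 64-element
scale is physics-limited to roughly 0.88–0.92 of the true peak: the
unfocused 7 mm element's elevation beam at 40 mm extends over $|y|$ of
2–3 mm, so the center-of-vessel sample volume inevitably averages slower
off-plane laminae of the parabola (a plug profile is immune, which is why
the laminar experiment recovers its speed within ~2–3%). A narrowband
4-cycle transmit limits the countervailing spectral-centroid
overestimation to a few percent.

## Phantoms

Three seeded generators cover the study conditions; all randomness comes
from one documented stream order per phantom, so fields are bit-reproducible
under a fixed seed.

* `cyst_phantom()` — uniform background scatterers with standard-normal
  amplitudes; anechoic spheres zero the amplitude, hyperechoic spheres
  multiply it by 10, point targets (amplitude 20) are appended. Defaults:
  100,000 scatterers in a 50 × 10 × 60 mm block starting 30 mm from the
  array, five features of each class.
* `image_template_phantom()` — grayscale pixel values (0–255) divided by
  100, exponentiated, min-subtracted and rescaled to a configurable
  maximum weight, then multiplied by standard-normal draws: zero-mean
  speckle whose local variance follows the image. Scatterers outside the
  image extent are excluded.
* `vessel_flow_phantom()` — 50,000 moving scatterers (variance 1) uniform
  in a 5 mm-radius cylinder tilted 45° in the imaging plane, 40 mm deep,
  inside 50,000 static scatterers (variance 625) filling a 60 × 10 × 70 mm
  block that excludes the vessel. Laminar (plug) or parabolic
  (Poiseuille, $v(\rho) = v_{peak}(1-(\rho/R)^2)$) profiles; flow is along
  the axis. `advance_flow()` translates movers and wraps them around the
  cylinder ends, preserving uniform density over arbitrarily long
  ensembles.

What the generators deliberately do *not* emulate: attenuation and
frequency-dependent absorption, sound-speed heterogeneity and aberration,
nonlinear propagation, element directivity beyond the rectangular aperture,
thermal/electronic noise, and tissue motion other than the programmed flow.
Passing tests on these phantoms therefore validate the propagation model,
the beamformer, and the estimator chain — not robustness to the artifacts
real tissue adds.

## Study sizes used by the test suite

The packaged checks run a reduced-scale version of the full vessel study:
64 elements, 10,000 moving + 10,000 static scatterers, three steering
angles in [−6°, +6°], 10 frames per angle at $f_{PRF}=5$ kHz (4-cycle
transmit / 1-cycle receive at 2.5 MHz, $f_s = 20$ MHz). At this scale the
laminar plug (0.5 m/s) and the parabolic peak (1.0 m/s — note: 92% of the
1.089 m/s Nyquist velocity) are both recovered within a few percent, and a
weighted parabolic fit across the vessel interior explains well over 90% of
the profile variance. Convergence orderings use an 8-element array and a
50-scatterer cloud over 12–96 MHz against a 1536 MHz dense-rule reference.
The shipped YAML configurations reproduce the full-scale imaging setups
(128/256 elements, $10^5$–$10^6$ scatterers); they run in minutes to hours
and are meant for `inst/cli/echosim` rather than the test suite.

## Known limitations

* Elevation quadrature convergence is inherently slow for tall elements
  (see above); pointwise field accuracy in elevation is a few percent, not
  $10^{-3}$.
* The velocity estimator inherits the standard autocorrelation
  limitations: aliasing beyond the Nyquist velocity, the nominal-$f_0$
  spectral bias, and angle sensitivity for off-axis pixels. The symmetric
  receive aperture mitigates — not removes — the latter on small arrays.
* The wall filter is a pure mean subtraction: slowly *moving* clutter
  would leak through; only truly static tissue cancels exactly.
* Scatterer amplitudes are frequency-independent; there is no speckle
  decorrelation from microstructure, only from motion through the sample
  volume.
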