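---
title: "Simulating difference-frequency ultrasound voicing in tissue"
author: "beatfdtd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating difference-frequency ultrasound voicing in tissue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

After a total laryngectomy the vocal folds are gone, but the vocal tract
usually still works: speech is possible if an external source supplies the
periodic excitation the folds used to produce. Handheld electrolarynxes do
this by hammering a piston against the neck, with well-known drawbacks —
coarse pitch control, a metallic spectrum poor in low-frequency energy, and
loud airborne leakage ("self-noise"). An alternative is to inject two
*ultrasonic* carriers (around 40 kHz, inaudible and biologically benign at
moderate levels) from transducers on the neck. Where the two beams overlap,
their interference amplitude-modulates the local pressure at the
*difference frequency* $|f_1-f_2|$; tissue and the downstream hearing chain
demodulate this into an audible fundamental at, say, 200 Hz. This package
simulates that mechanism end to end and measures whether the demodulated
beat behaves like a usable voicing source.

## Wave model and discretization

We integrate the linearized acoustic equations with a momentum-damping loss
term,

$$\frac{\partial \mathbf v}{\partial t}
   = -\frac{1}{\rho}\left(\nabla p + \sigma \mathbf v\right),
 \qquad
 \frac{\partial p}{\partial t} = -\rho c^2 \, \nabla\!\cdot\!\mathbf v,$$

with spatially varying density $\rho(\mathbf x)$, sound speed
$c(\mathbf x)$ and loss coefficient $\sigma(\mathbf x)$. Longitudinal waves
only: mode conversion to shear at interfaces is subsumed into $\sigma$.
Fields live on a staggered Yee lattice — pressure at integer nodes,
velocity components at half-offset nodes — advanced leap-frog in time
(second order) with fourth-order spatial differences, the (2,4) scheme. The
fourth-order staggered first-derivative stencil is
$(27(p_{i+1}-p_i) - (p_{i+2}-p_{i-1}))/(24\delta)$; within one node of a
domain face, where the wide stencil does not fit, the solver drops to the
second-order two-point stencil. Density and $\sigma$ at a velocity node are
arithmetic means of the two adjacent pressure nodes, and the damping term is
applied semi-implicitly (Crank–Nicolson in the update factor
$(1-s)/(1+s)$, $s=\sigma\,\mathrm dt/2\rho$), which keeps the update stable
for arbitrarily large $\sigma$.

Initial conditions are quiescent (zero gauge pressure and velocity); each
step runs velocity update, pressure update, hard-source injection, then the
boundary update, and the microphones record every `decimation`-th step.

### Loss model

Tissue attenuation is tabulated in dB/cm/MHz — linear in frequency. The
continuous model above gives a plane wave decaying as $e^{-\alpha x}$ with
$\alpha = \sigma/2\rho c$ (Np/m), so we convert
$\alpha_{\mathrm{dB/cm/MHz}}$ at a reference frequency $f_{\mathrm{ref}}$
(default: the 40 kHz carrier) to Np/m and set
$\sigma = 2\rho c\,\alpha_{\mathrm{Np/m}}$. Because $\sigma$ is frozen at
$f_{\mathrm{ref}}$, the discrete medium is non-dispersive in its loss: all
spectral components decay at the carrier's rate. That is the right regime
for this experiment (the signal is a narrowband pair at 39.6–40 kHz), but it
means broadband pulses are *not* attenuated realistically. A
quadratic-in-$f$ absorption law is sometimes argued for low-frequency
ultrasound in tissue; we implement only the linear law the tabulated units
imply, and treat that as a fixed modeling decision. The choice is directly
testable: a 1D muscle column driven at 40 kHz shows an amplitude-vs-depth
slope within a few percent of the nominal $\alpha = 1.52$ Np/m (the test
suite enforces 5%).

### Stability and sampling

The classic 3D Courant bound is $\mathrm dt \le \delta/(c_{\max}\sqrt 3)$ —
122.97 ns for 1 mm voxels when teeth ($c=4695$ m/s) are present, which is
the number usually quoted for this setup, and the reference runs use
122.5 ns, giving an 8.16 MHz solver rate, 85 times the 96 kHz output rate.
The fourth-order stencil, however, has a stability region 6/7 that size
(its worst-mode symbol is 7/6 of the second-order one), and the package
exposes both (`max_stable_timestep(..., scheme = "yee22"/"yee24")`). The
distinction matters in practice: at $0.999$ of the classic bound the (2,4)
scheme amplifies 4-voxel modes by ~1.7 per step. Our own experiments
therefore choose `dt` below the (2,4) bound; specifically
`beat_experiment_config()` picks the largest `dt` of the form
$1/(96\,\mathrm{kHz}\times k)$, $k$ integer, below 95% of the (2,4) bound
for soft tissue — $k=35$, $\mathrm dt = 297.6$ ns — so that traces decimate
to exactly 96 kHz. `run_simulation()` only *warns* on a Courant violation;
the hard error is the runtime non-finite-field detector, so deliberately
unstable configurations can be used to verify that the detector fires.

Spatial sampling follows the usual 5–10 points per wavelength rule; with
air present ($c = 347$ m/s) and a 40 kHz carrier the shortest wavelength is
8.675 mm, 8.7 voxels — adequate, and `check_spatial_sampling()` warns below
5.

### Boundaries, sources, microphones

Domain faces use first-order Mur absorption on pressure,
$p_0^{n+1} = p_1^{n} + \frac{c\,\mathrm dt-\delta}{c\,\mathrm dt+\delta}
(p_1^{n+1}-p_0^{n})$, with the local sound speed per boundary node.
Normally incident plane waves reflect below 2% in amplitude (measured in
the suite); obliquely incident and tangential waves reflect more — the
cost of the simplest absorbing boundary. Individual faces can be left rigid
(`mur_faces`), which the quasi-1D oracles use to get exact plane-wave
conditions. Everything outside an absorbing face behaves as a rigid wall
(normal velocity zero), so `boundary = "rigid"` gives a closed box whose
lossless energy
$E=\sum(p^2/2\kappa + \rho|\mathbf v|^2/2)\,\delta^3$ is conserved — the
conservation oracle in the tests (the pointwise staggered-time sampling of
$E$ oscillates a few percent at large Courant numbers; drift of its
windowed mean is what conservation bounds).

Transducers are *hard* sources: every voxel of a one-voxel-thick disc
(radius 6 mm, matching common low-frequency ultrasonic transducers) has its
pressure overwritten with $A\sin(2\pi f t + \phi)$, $A$ from the drive
level in dB SPL (105 dB $\to$ 3.557 Pa). "Hard" pressure driving is the
simplest reading of a driven piston face; a velocity-source variant would
differ mainly in source impedance, not in the interference physics under
study. A 4 mm foam baffle is painted into the material fields behind each
disc (default $\rho=50$ kg/m³, $c=400$ m/s, $\alpha=100$ dB/cm/MHz —
representative closed-cell polypropylene foam, configurable) to absorb the
backward lobe, mimicking a baffled hemispherical radiator.

## Tissue model and phantoms

The bundled registry (`inst/extdata/tissue_table.csv`) covers the 26 tissue
types of a 1 mm segmented upper-body voxel model plus two air entries and a
generic soft-tissue fallback (1000 kg/m³, 1540 m/s, 0.5 dB/cm/MHz)
registered under the reserved id 255. `read_voxel_volume()` ingests
AustinMan-style flat uint8 volumes with a YAML sidecar declaring dimensions
and storage order; the anatomical dataset itself is not bundled (it is
~100 M voxels), so the package generates synthetic phantoms instead:

* `make_soft_tissue_phantom()` — a homogeneous soft-tissue block; the
  default study condition. The claim under test is beat generation in
  tissue, which does not require anatomy.
* `make_neck_phantom()` — skin/fat/muscle/cartilage layers stacked from the
  transducer face, an air-filled tracheal lumen along $z$ beyond them,
  muscle elsewhere. This reproduces the geometric features that matter — a
  few cm of layered soft tissue between transducer and an air-backed
  airway — with idealized flat interfaces.

What the phantoms deliberately omit: curved interfaces, bone and cartilage
shadowing, tissue heterogeneity at sub-mm scales, and the resonant cavity
of a real trachea. Passing tests on phantoms therefore demonstrate the
*mechanism* (beat generation, propagation, demodulation) and the solver's
numerics, not absolute in-vivo output levels; anatomical absolute levels
require the full voxel dataset, which the reader can supply via
`read_voxel_volume()`.

## The beat experiment

`beat_experiment_config(beat_hz)` reproduces the reference drive: source 1
at 40 kHz and 0°, source 2 at $40\,\mathrm{kHz} - f_b$ and 90° (the phase
as specified in the reference setup, taken as given), both at 105 dB, discs
20 mm apart on the entry face of a 64³ phantom, microphones on the midline
20–30 mm deep. Difference frequencies of 100, 200 and 400 Hz
($f_2 = 39.9/39.8/39.6$ kHz) cover male, female and child speech
fundamentals. Runs last `max(15 ms, 3 beat periods)` — long enough for the
60 mm domain to reach dynamic equilibrium (acoustic transit is ~40 µs) and
for three full beats, while staying minutes-scale on one CPU; the full
anatomical runs this emulates used 63.7 ms on GPU hardware, and the run
length is configurable upward.

Demodulation is an STFT Hilbert envelope: Hann-windowed frames (default
1024 samples ≈ 10.7 ms at 96 kHz, 75% overlap) are converted to analytic
signals by FFT half-spectrum doubling, overlap-added, weight-normalized,
and the magnitude taken. The window must hold many carrier periods (426
here); it need *not* be shorter than the beat period — for a clean AM
signal the estimator is exact regardless, and the suite checks a
closed-form AM case to 2% modulation depth. A full-signal analytic envelope
is provided as an independent cross-check. The envelope's dominant
frequency is read from a zero-padded spectrum with parabolic peak
interpolation between 50 Hz and 1 kHz; an envelope whose interior
modulation depth is below 2% is reported as "no beat" (the $f_1=f_2$
sentinel). The audible output level is quoted as the SPL of the envelope's
oscillating part, averaged over microphones with its standard error.

## Numerical choices worth knowing

* **Decimation** is a plain take-every-$k$th-sample (no anti-alias filter by
  default): the 96 kHz Nyquist of 48 kHz already clears the 40 kHz carrier.
* **WAV calibration**: 16-bit PCM carries no units, so every writer emits a
  JSON sidecar `{pa_per_full_scale}`; readers refuse uncalibrated input
  rather than guess. Clipping on write is an error naming the peak.
* **Harmonic roll-off** reads each harmonic as the spectral peak within
  $\pm f_0/4$ of $k f_0$ and averages $\mathrm{SPL}(2f)-\mathrm{SPL}(f)$
  over all in-band pairs; the exact estimator behind the reference tables
  is not documented, so a ±2 dB agreement band is used where roll-offs are
  compared. Those tables are labeled dBC; C-weighting is within ±0.2 dB of
  flat over 100 Hz–5 kHz, so unweighted and C-weighted paths differ little
  there, and both are provided.
* **Spectral correlation** uses linear, peak-normalized magnitudes on a
  common grid (Pearson), following the "normalized spectral magnitudes"
  convention; a dB-domain variant would weight valleys more heavily.
* **105 dB drive/glottal level is treated as peak** pressure, not RMS; all
  waveform comparisons are peak-normalized, so only absolute level quotes
  depend on this.
* **Degenerate inputs**: silent traces give $-\infty$ SPL sentinels;
  constant spectra are refused in correlations; unknown tissue ids are
  errors, never defaults.

## The glottal reference

The Rosenberg type-C pulse — raised-cosine opening over $T_P=40\%$ of the
period, quarter-cosine closing over $T_N=16\%$, closed otherwise — is
continuous with a discontinuous first derivative at closure, which yields
the $-12$ dB/octave asymptotic roll-off of natural voicing. Measured by our
estimator over harmonics to 8 kHz, a 1 s, 100 Hz train at 96 kHz gives
$-12.2 \pm 1.2$ dB/octave. Each period starts at glottal opening (the
standard Rosenberg phase convention).

## Known limitations

First-order Mur leaves a few-percent residual for oblique incidence;
perfectly matched layers would do better and are out of scope. The loss
model is linear-in-frequency and evaluated at one reference frequency.
Shear waves, nonlinear propagation (the physical demodulation route in a
parametric array is nonlinear; here the linear interference envelope is the
quantity of interest), vocal-tract formant filtering, and GPU-scale
anatomical runs are out of scope. Desk-scale phantom levels should not be
read as in-vivo predictions.
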