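---
title: "Dynamic coherent diffractive imaging: model, constraints, and validation at desk scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic coherent diffractive imaging: model, constraints, and validation at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
```

## The imaging problem

Single-pattern coherent diffractive imaging (CDI) reconstructs a complex
sample transmission function $O(\mathbf r)$ from one far-field diffraction
intensity $I(\mathbf k) = |\mathcal F[O(\mathbf r)\,P(\mathbf r)]|^2$, where
$P(\mathbf r)$ is the illumination (probe). Because no lens forms the image,
the detector records only the modulus of the diffracted wavefront and the
phase must be retrieved iteratively. For a *dynamic* sample observed as a
sequence of $T$ snapshots $O_1, \dots, O_T$ (one diffraction pattern per
frame, no scanning), plain per-frame CDI is poorly constrained: each frame is
a fresh, hard phase-retrieval problem and the unknown probe couples into
every one of them.

This package implements a dynamic-CDI reconstruction that stabilises the
per-frame problems with three additional constraints, all cheap to measure or
already present in the data:

1. **Static-region transfer.** The sample is decomposed as
   $O_t(\mathbf r) = D_t(\mathbf r_1) + S(\mathbf r_2)$: a dynamic region
   $D_t$ that changes between frames and a static region $S$ that does not.
   During the frame sweep, the current estimate of $S$ (saved from the
   previously updated frame) overwrites the static pixels of the next frame
   before its data projection. A single running copy of $S$ circulates
   through the whole sequence, so every pattern effectively constrains it —
   redundancy similar to the overlap constraint in ptychography. The static
   region may carry structure or be *empty* (unit transmission): even an
   empty region, which costs nothing in sample preparation, improves the
   reconstruction because its pixels are known to be featureless.
2. **Low-frequency transfer.** A smoothly evolving sample has nearly the
   same coarse morphology in adjacent frames. For the first
   `n_lowfreq_iterations` (default 20) of the total `n_iterations` (default
   300), the Fourier coefficients of frame $t$ inside a centred disk of
   radius `qlow` (default 3 reciprocal pixels, Euclidean and inclusive) are
   replaced by those of frame $t-1$. This accelerates early convergence of
   the whole sequence; it is never applied to frame 1 and is switched off
   after the early iterations so it cannot bias the converged result.
3. **Modulus-enforced probe (MEP).** One extra exposure without the sample
   records the probe-only pattern $I_0^p$. Each frame, the probe's far-field
   modulus is replaced by $\sqrt{I_0^p}$ (phase kept) and its real-space
   support is applied. The same pattern drives a hybrid input-output (HIO)
   pre-reconstruction that supplies a good initial probe.

Around these, each frame applies the standard machinery: exit wave
$\psi = O \cdot P$, Fourier-modulus projection
$\Psi' = \Psi \sqrt{I_t}/|\Psi|$, and ePIE updates
$O \leftarrow O + \alpha\, P^*/\max|P|^2 (\psi' - \psi)$ and (optionally)
$P \leftarrow P + \beta\, O^*/\max|O|^2 (\psi' - \psi)$, with the boundary
rule $O = 1$, $P = 0$ outside the illuminated support. Frames are swept in
ascending order; the static function saved by frame $T$ carries over to
frame 1 of the next iteration.

## Optical model and conventions

All transforms are centred (DC at 0-based index $N/2$) and unitary, so
energy bookkeeping is exact and the modulus projections are scale-consistent.
Wavelength comes from the photon energy via $hc = 1239.842$ eV nm. The
sample-plane pixel of a far-field geometry is $\Delta x = \lambda z /(N p)$
($z$ the sample-detector distance, $N$ detector pixels of pitch $p$).

The probe is a defocused Fresnel zone plate (FZP) beam. The FZP is modelled
as a thin quadratic-phase lens of focal length $f = D\,\Delta r/\lambda$
behind an annular aperture (diameter $D$, central stop); zone-by-zone
structure is irrelevant at the sample plane. The geometric probe diameter at
defocus $d$ is $D\,|d|/f$. The field is synthesised as the geometrically
scaled annulus carrying the spherical-wave phase near the sample plane and
then propagated the remaining distance with a band-limited angular-spectrum
method, so physical edge diffraction appears; near focus the construction
plane moves upstream and the converging beam is propagated through the
focus. The probe's hollow centre (central-stop shadow) receives little
light; image quality there is intrinsically limited, which is a known
property of zone-plate illumination rather than of the algorithm.

`propagate_far_field()` and `propagate_angular_spectrum()` are unitary to
machine precision and the far-field transform agrees with a direct
$O(N^4)$ Fourier sum on small grids — both are covered by oracle tests.

## The synthetic experiment

No public dataset accompanies the method, so the package ships a simulator
(`simulate_dataset()`) that reproduces the reference soft X-ray
configuration: 705 eV photons, detector 105.4 mm downstream. Desk-scale runs
use a 256-pixel detector with an 88 µm pitch — the experimental
2048 × 11 µm detector binned 8× — which keeps the sample-plane pixel at
8.23 nm while shrinking the field of view to 2.1 µm. The probe scales
accordingly to 0.6 µm (28.5% of the field of view, preserving the
oversampling ratio); the 6 µm probe of the full-scale geometry is exercised
on a 1024 grid in the test suite, where its wavefront curvature is still
sampled.

The generating probe is the analytic FZP model *with seeded smooth complex
speckle* (phase ripple 1.5 rad, 30% amplitude mottling, ~5 px correlation,
`perturb_probe()`). This emulates experimentally retrieved zone-plate
probes, which are always granular; it matters scientifically because an
idealised smooth annulus both misrepresents real illumination and
ill-conditions the inversion — with it, known-probe reconstructions stall at
roughly twice the object error, the residual living in far-field phase modes
that barely move the measured modulus.

The default scene (`translating_texture`) is a sparse field of absorbing
particles (~35% coverage, transmission dips to $\approx e^{-2.2}$, phase to
$-1.8$ rad) rigidly translated by 5% of the probe diameter per frame with
sub-pixel Fourier shifts — the analogue of a nanoparticle sample stepped
across the beam in 0.3 µm increments at full scale. Sparsity is not a
convenience: dynamic samples in this imaging regime (nanoparticles on a
membrane, bird-flock test images) are sparse, and the empty background
supplies the real-space constraint single-pattern CDI relies on; a
space-filling texture removes it and stalls even noiseless known-probe
reconstructions. A `moving_blobs` scene (drifting Gaussian absorbers) and
user-supplied frames are also available. The static region is a chord at the
bottom of the field-of-view disk carrying a letter-E-like structure
(`"structured"`), exactly unit transmission (`"empty"`), or absent.

Noise is per-pixel Poisson at a user-set photon budget (default $10^8$
photons/frame); the detector model deliberately omits point spread, readout
noise, dead pixels and intra-exposure motion. The generating probe is
truncated to the field-of-view disk inside `build_dataset()`, which makes
the support rule and every projection an *exact* fixed point on noiseless
data — the basis of the fixed-point tests.

What passing these synthetic tests does **not** show: performance under
partial coherence, probe drift, detector artefacts, or the
sample-preparation realities of delineating static and dynamic regions from
holographic images; those require beamline data.

## Numerical choices

- **Modulus guard:** where $|\Psi| \le 10^{-12} \max|\Psi|$ the replaced
  value takes zero phase (measure-zero effect, avoids 0/0).
- **`qlow` disk:** Euclidean radius, centred, inclusive; radii beyond the
  grid's corner radius are clamped with a warning.
- **Probe support:** amplitude above 0.5% of the maximum, dilated by 2
  pixels; can be overridden.
- **HIO:** 200 iterations, feedback 0.9, random seeded Fourier phases; with
  0 iterations the zero-phase inverse transform is returned. A
  centrosymmetric support (an annulus) cannot distinguish a field from its
  conjugated inverse, so the random start can stagnate between the twins —
  the package therefore passes the model probe as the HIO start when
  building initial probe guesses.
- **Relaxations** $\alpha = \beta = 1$ (standard ePIE), 300 iterations, the
  first 20 with low-frequency transfer — transferring only while convergence
  is still unstable, then releasing the frames to their own data.
- **Error metrics:** per frame and iteration the normalised data-space error
  $E_{t,n} = \sum_k (|A_{t,n}| - \sqrt{I_t^m})^2 / \sum_k I_t^m$ (recorded
  before the modulus replacement), and, when ground truth is available, the
  normalised object error after global phase alignment over the illuminated
  support (pixels where the true probe amplitude exceeds 10% of its
  maximum).
- **Known-probe runs** update the probe only through the MEP constraint
  (`update_probe_epie = FALSE`), the same procedure the validation
  experiments use with a ptychography-reconstructed probe; enabling ePIE
  probe updates on top adds object–probe crosstalk and roughly doubles the
  converged object error.
- **Unknown-probe runs** start from
  `initial_probe_guess()`: the best available model probe blended (after
  least-squares scalar alignment) with the HIO pre-reconstruction of the MEP
  pattern, scaled to the MEP photon total. In the validation study the
  "best available model" is the stored generating probe — the desk-scale
  analogue of initialising from a ptychography-reconstructed probe of the
  same beam, which is how such experiments are run in practice; recovering a
  heavily structured probe from a bare analytic annulus is a harder problem
  than that protocol poses and is out of scope.

## What the validation computes

`scripts/acceptance.R` re-runs the whole study from scratch at the 256-pixel,
10-frame, 300-iteration desk scale (about 10 minutes on one CPU) and writes
the headline numbers as JSON:

- fixed-point drift of one full iteration started at the ground truth on
  noiseless data (low-frequency transfer off there: it is an acceleration
  heuristic between *different* frames, not a projection the truth
  satisfies);
- known-probe parameter recovery (mean aligned object error) and
  pty-style-initialised probe recovery (final probe correlation);
- the ablation grid: final data error with/without static transfer, probe
  difference with/without MEP, early object error with/without low-frequency
  transfer, empty-static versus no-static, and the first-frame effect
  (frame 1's error after one iteration exceeds the later frames' mean,
  because frame 1 receives no transfers in iteration 1);
- Fourier ring correlation (half-bit threshold, one-pixel rings) between
  reconstructions of two independent noise realisations, reported as
  half-period resolution. This run is deliberately photon-starved
  (5 × 10⁴ photons/frame, halves at half that) so that counting noise — not
  the numerical band limit — sets the resolution; at the standard budget the
  halves agree out to Nyquist and the threshold is never crossed.

The test suite asserts the qualitative orderings; the quantitative margins
between ablation variants are modest at desk scale (the constraints matter
most near convergence boundaries, and a 256² problem with $10^8$
photons/frame is comfortably posed), so the orderings rather than the gaps
are the meaningful check.

## Known limitations

- The desk-scale probe carries less wavefront curvature (≈2.5 Fresnel
  fringes across its radius) than the full-scale 6 µm probe (≈25), so
  convergence is somewhat slower per iteration than the full-scale setting
  would enjoy.
- Pixels in the central-stop shadow and at the very edge of the illuminated
  disk are weakly constrained; residual error concentrates in smooth phase
  modes that move the measured modulus very little.
- The first frame converges more slowly than the rest (it receives no
  inter-frame transfers during the first iteration) — visible as a distinct
  error trace.
- Single probe mode, thin sample, monochromatic illumination; no position
  refinement; no GPU path.

## A worked micro-example

```{r}
library(dyncdi)
ds <- simulate_dataset(n_frames = 3, grid = 64, photons_total = 1e7,
                       seed = 42)
fit <- dyncdi(ds, dyncdi_control(n_iterations = 40, hio_iterations = 50),
              probe = initial_probe_guess(ds, model_probe = ds$truth$probe,
                                          hio_iterations = 50))
summary(fit)
plot(fit)
```
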