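---
title: "A quasi-steady blade-element model of flapping flight with body oscillations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A quasi-steady blade-element model of flapping flight with body oscillations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wingbeat)
```

## The problem

Forward-flying silk moths (and many butterflies) do not hold their bodies
still while flapping: the body pitches nose-down during the downstroke and
nose-up during the upstroke, and the whole animal bobs vertically once per
wingbeat. These body oscillations add to the wing's own rotation about the
thorax, changing the wing's orientation and velocity relative to the air.
`wingbeat` implements the modelling chain needed to quantify the
aerodynamic consequences: Fourier representation of periodic wing and body
kinematics, a strip-wise quasi-steady aerodynamic model, a bounded
trim-equilibrium search, and comparisons between body-kinematics
configurations that switch the oscillations off or shift them out of
phase.

## Kinematic representation

Every periodic parameter — the wing sweep $\phi$, deviation $\theta$,
feathering $\alpha$, stroke-plane angle $\beta$, body pitch $\chi$, and
the body velocity components $u$, $w$ — is a third-order Fourier series

$$y(t) = a_0 + \sum_{k=1}^{3} a_k \cos(2\pi k f t) + b_k \sin(2\pi k f t),$$

with $f$ the wingbeat frequency. Third order is enough to capture measured
moth wingstrokes without fitting tracking noise. Angles are degrees in all
interfaces and radians internally; derivatives used by the force model are
always the analytic series derivatives, never finite differences of
samples.

Two waveform summaries matter downstream: the *mean* (the arithmetic
average over a period, which is exactly $a_0$) and the *amplitude*,
defined as the difference between the waveform maximum and minimum over
one period. Amplitudes are located on a 2048-point grid and refined by
local univariate optimisation, so rescaling a waveform to a target
mean/amplitude (`rescale_waveform()`) is accurate to about $10^{-9}$.
Rescaling multiplies all harmonics by a common factor: the waveform
*shape* is treated as the measured quantity and the mean/amplitude as free
parameters, which is exactly how the trim search moves through parameter
space.

The phase difference between two waveforms (`phase_difference()`) is
defined on their fundamental harmonics: each fundamental is written as
$A\cos(2\pi f t - \delta)$ with $\delta = \mathrm{atan2}(b_1, a_1)$, and
the difference $\delta_b - \delta_a$ is reported in $[0, 360)$ degrees.
The definition is invariant to amplitude rescaling, and a half-period time
shift moves it by exactly 180°.

## Frames and the blade-element force model

The global frame has $x$ forward, $y$ to the animal's left, $z$ up. The
stroke-plane frame sits at the wing hinge, pitched by $\beta$ about the
global $y$-axis (at $\beta = 90^\circ$ the stroke-plane normal points along
$-x$) and rolled by the constant $\beta_r$ about its $x$-axis, mirrored
between sides. Sweep $\phi$ and deviation $\theta$ are the azimuth and
elevation of the hinge-to-wingtip direction in that frame; feathering
$\alpha$ rotates the chord about the spanwise axis, measured from the
stroke plane and composed so that the wing's inclination to the absolute
horizontal is $\alpha_h = \alpha - \beta$ (we use the exact difference; its
rate $\dot\alpha_h = \dot\alpha - \dot\beta$ is the global wing-pitching
rate used by the rotational and added-mass terms).

Each wing (the combined fore+hindwing, treated as one rigid flat plate) is
divided into `n_strips` spanwise strips of width $dr = R/n$, chord sampled
at strip centres. On a strip with chord $c$, relative airflow speed $v$
(the strip speed in the global frame under the no-wind assumption, strip
velocity evaluated on the spanwise pitching axis), the quasi-steady force
components are

* lift $\tfrac12 \rho C_L v^2 c\,dr$, perpendicular to the airflow in the
  plane spanned by the airflow and the wing normal, signed toward the
  suction side (the sign of $\hat n \cdot \hat v$), so it flips correctly
  at stroke reversal;
* drag $\tfrac12 \rho C_D v^2 c\,dr$ along the airflow;
* rotational force $\rho C_R v c^2 \dot\alpha_h\,dr$ along the wing
  normal, with $C_R = \pi(0.75 - \hat e)$ for a pitching axis at chord
  fraction $\hat e$ (default quarter-chord);
* added-mass force $\tfrac{\pi\rho}{4}\left[(\ddot\phi \sin\alpha +
  \dot\phi\,\dot\alpha_h \cos\alpha) r c^2 + \tfrac14 \ddot\alpha_h
  c^3\right] dr$ along the wing normal.

The lift and drag coefficients are the empirical flat-plate polynomials
measured on dynamically scaled hawkmoth wings,
$C_L = k_L(1.552 \sin\alpha_v \cos\alpha_v + 1.725\sin^2\alpha_v
\cos\alpha_v)$ and
$C_D = k_D(0.0596 \sin\alpha_v \cos\alpha_v + 3.598 \sin^3\alpha_v)$,
with the angle of attack $\alpha_v = \arccos(-\hat b \cdot \hat v)$
computed from the chord direction $\hat b$ (trailing to leading edge) and
the airflow direction. The scalings $k_L$, $k_D$ are free parameters of
the trim search that absorb interspecific differences from the reference
wing. When the local airflow speed is exactly zero the flow direction is
undefined; the translational force is then zero, which is also its
physical limit.

Strip forces are integrated along the wing and the left wing is obtained
by mirror symmetry (identical waveforms on both sides, zero lateral body
velocity and wind), which makes the lateral force and the roll and yaw
moments cancel exactly — the model operates in the longitudinal plane by
construction. Moments are taken about the centre of mass and include
aerodynamic terms only: gravity acts at the centre of mass and wing
inertial forces are internal to the animal.

Aerodynamic power is $P = \sum (\mathbf{dF}_D + \mathbf{dF}_{rot} +
\mathbf{dF}_{adm}) \cdot \mathbf{v}$ over strips and both wings. Lift is
perpendicular to $\mathbf v$ and contributes exactly zero; the
implementation nevertheless records the numerical lift-power residual at
every step so tests can assert the orthogonality rather than assume it.
Negative instantaneous power (work recovered from the airflow by the
rotational/added-mass terms) is preserved.

The inertial reaction of a flapping wing on the body is
$-\,(m_w/S)\,c\,dr\,\dot{\mathbf v}$ per strip (mass distributed
proportionally to strip area). Strip velocities are linear in the span
coordinate, so the wing integral reduces to two acceleration terms; these
are obtained by complex-step differentiation of the analytic velocity
field, which is exact to machine precision and free of subtractive
cancellation. Over an exact period the mean inertial force is zero — a
conservation property the test suite checks at $10^{-9}$ of the peak.

## Numerical choices

One wingstroke is evaluated on a uniform grid of `n_steps` time steps over
$[0, 1/f)$ (default 1000) with 200 strips per wing; wingstroke averages
are arithmetic grid means, which for smooth periodic integrands is a
spectrally accurate quadrature. Halving either resolution changes the
averaged vertical force by well under 0.1%, and the closed-form
steady-translation oracle (rectangular wing at fixed angle of attack)
is reproduced to machine precision because the strip sum is exact for a
uniform chord.

## Trim search

Measured (or synthetic) kinematics do not generally balance the model's
forces, so analysis happens at *trim*: parameter vectors whose
wingstroke-averaged fore-aft force, vertical force and pitch moment
satisfy $\bar F_x = 0$, $\bar F_z = mg$, $\bar M_y = 0$. The residual

$$G = \left(\frac{\bar F_{x}}{mg}\right)^2 +
      \left(\frac{\bar F_{z}}{mg} - 1\right)^2 +
      \left(\frac{\bar M_{y}}{mg\,r_2}\right)^2$$

is minimised over 14 parameters (wingbeat frequency, stroke-plane roll,
mean and amplitude of $\chi$, $\beta$, $\phi$, $\alpha$, $\theta$, and
$k_L$, $k_D$) inside per-species min–max bounds; $r_2$ is the radius of
the second moment of wing area. The optimiser is a Nelder–Mead simplex run
through a sinusoidal bound transform, so iterates can never leave the
bounds (the package ships the published per-species bound tables with a
characteristic solution per species, in which a few values sit up to 2%
of the range outside the printed bounds, reflecting the small relaxation
allowed when those solutions were produced). Because the cost surface is
non-convex, the search restarts from random in-bounds draws until a target
number (default 10) of pairwise distinct solutions is found; two solutions
are distinct when any bound-normalised parameter differs by more than 2%.
Restarts run at reduced fidelity (50 strips × 200 steps), are discarded
cheaply when they fail to approach zero there, and candidate minima are
re-evaluated — and, if needed, polished — at full fidelity
(200 strips × 1000 steps). The reported $G$ is always the full-fidelity
value, and each returned solution re-simulated from scratch reproduces its
stored residual to $10^{-10}$.

## Body-kinematics model variants

With wing angle waveforms held fixed, `make_variant()` builds:

* **model 1** — the time-varying body kinematics as given;
* **model 2** — no body oscillations: $\chi$, $\beta$, $u$, $w$ frozen at
  their wingstroke means;
* **model 3** — the same oscillations shifted by half a period
  (antiphase to the wing motion);
* **models 1a/1b** — intermediate cases isolating body-speed and
  body-pitch oscillations.

$\beta$ is grouped with the body kinematics and flattened in models 2 and
1a by default because the stroke plane rides on the pitching body; a flag
(`flatten_beta = FALSE`) disables this for sensitivity checks. Variants
reuse the model-1 trim solution without re-trimming: the comparison asks
what the same wing motion would cost under different body motion, so only
the reference configuration is an equilibrium. Performance metrics are the
mean and peak force magnitude and aerodynamic power, and the
lift-to-drag ratio defined as the ratio of the area- and time-averaged
lift and drag coefficients.

## What the synthetic-data generator emulates

`synth_moth()` draws the 14 trim parameters uniformly inside a species'
bound table and builds waveform shapes from a dominant fundamental plus
harmonics 2–3 at a relative magnitude of 0.2 with random phases — smooth,
moth-like strokes without copying any measured coefficient set. Phase
anchors follow flapping-flight phenomenology: feathering leads sweep by
roughly a quarter period (wing rotation fastest at stroke reversal), the
stroke-plane angle oscillates in phase with body pitch, and the
body-pitch-to-sweep phase difference is placed uniformly inside the
30–120° band observed in forward-flying silk moths. Body velocity
waveforms use a forward speed of 2–3 m/s and per-stroke vertical bobbing
of 0.5–1.2 m/s peak to peak, the ranges typical of wind-tunnel forward
flight. Landmark tracks place the seven tracked points (head,
thorax–abdomen junction, abdomen tip, both hinges, right wingtip, right
inner wing angle) with the same frame chain the force model uses, at 1000
frames/s, with independent Gaussian noise (default 0.1 mm) per
coordinate.

The *near-trim* mode constructs a configuration that provably has an
equilibrium inside known bounds: it minimises the scale-free imbalance
$(\bar F_x/\bar F_z)^2 + (\bar M_y/(\bar F_z r_2))^2$ inside the species
bounds and then sets the total mass to $\bar F_z / g$, so weight support
is satisfied by construction. Whether a draw can be balanced at all
depends on the waveform phases, which the bound tables do not constrain;
draws that resist balancing are discarded and redrawn from the seeded
stream, and the accepted draw must also imply a plausible total mass
(0.2–6 g). The returned configuration carries a narrowed bounds table
(±10% of each parameter range around the equilibrium) for trim-recovery
experiments.

What passing tests on synthetic moths do and do not show: they verify the
mechanics of the pipeline — conservation laws, oracles, recovery of known
inputs, and the *direction* of the power comparison — under waveforms with
the documented statistical structure. They do not certify the model
against measured moths, whose waveform shapes, planforms and masses enter
through the same file interfaces but are not bundled with the package.

## Landmark extraction and its conventions

`extract_kinematics()` computes per-frame geometric angles: body pitch
from the head-to-abdomen-tip axis, sweep/deviation from the
hinge-to-wingtip vector in the stroke-plane frame, and feathering from
the wing plane spanned by the hinge, wingtip and inner-angle points. The
stroke plane itself is defined per wingstroke as the least-squares plane
of the hinge-relative wingtip path; strokes are segmented at sweep maxima
(dorsal reversal, with parabolic sub-sample refinement — the downstroke
is the half with decreasing sweep) and the wingbeat frequency is refined
by minimising the sweep-fit residual. The plane normal is oriented by the
flight-forward convention (an inclined forward-flight stroke plane has a
backward-pointing normal), which stays stable even when the stroke plane
passes through vertical; a near-horizontal path falls back to
"normal up". Body velocities come from the analytic derivative of a
Fourier-plus-linear-drift fit to the centre-of-mass proxy (default: the
thorax–abdomen junction, configurable as a fraction along the abdomen
axis), avoiding the noise amplification of frame differencing.

One convention caveat is worth stating plainly: the decomposition of a
wingtip path into a stroke plane plus a deviation waveform is not unique.
If a track is synthesised with a nonzero deviation whose fundamental is
correlated with sweep, the least-squares plane differs from the
generating plane, and the extracted $(\beta, \theta, \phi, \alpha)$ are a
different — equivalent — decomposition of the same motion. Exact
round-trip tests therefore use zero deviation and a constant stroke
plane, where the decomposition is unambiguous and extraction is exact to
machine precision; noisy and deviation-bearing cases are covered by
tolerance-based consistency checks instead.

## Problem sizes and determinism

The package's own test and acceptance runs use 200 strips × 1000 steps
for reported quantities, 50 × 200 inside searches, three-wingstroke
landmark tracks at 1000 frames/s, and 10-solution trim searches — sizes
at which all of the above checks complete in minutes on a single core
while the discretisation error stays far below every assertion tolerance.
All randomness flows from explicit integer seeds (generator draws,
optimiser restarts, landmark noise), so every pipeline stage is exactly
reproducible from its manifest.

## Known limitations

* Rigid flat-plate wings: no bending, torsion, or fore/hindwing
  articulation; the combined planform is one plate per side.
* Quasi-steady aerodynamics only: no wake capture, no unsteady wake
  effects, no Reynolds-number dependence of the coefficient polynomials;
  body (parasitic) drag is excluded as small relative to wing drag.
* Strictly symmetric steady forward flight: lateral velocity, roll and
  yaw are zero by construction, so the model cannot represent turning or
  asymmetric strokes.
* The trim search finds zero-residual local minima inside bounds; it
  makes no claim of uniqueness, and solution families (10 by default) are
  the intended way to express that non-uniqueness.
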