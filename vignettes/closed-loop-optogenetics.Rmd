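---
title: "Closed-loop optogenetic control at the desk: models, controllers and metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-loop optogenetic control at the desk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(optoloop)
```

## What this package simulates

Feedback microscopy closes a loop around living cells: a frame is acquired,
segmented and measured on the fly, a controller compares the measurement to a
setpoint, and a spatial light modulator delivers a patterned dose of blue
light that pushes an optogenetic actuator inside the cell toward the desired
outcome. Two canonical plants cover the two main control modalities:

* **directed migration** — membrane recruitment of a RAC1 activator at the
  illuminated edge of a cell biases protrusion, so a trajectory-tracking
  controller that always illuminates the cell sector facing the next waypoint
  can steer a cell around an arbitrary guide path for hours;
* **nucleocytoplasmic transport** — a light-caged nuclear export sequence
  (uncaged by blue light) moves a tagged protein from nucleus to cytosol with
  a dose-dependent rate; a PID controller on the measured compartment
  intensity can titrate the protein level in either compartment to arbitrary
  setpoints.

`optoloop` reproduces this whole loop *in silico*: kinetic plant models stand
in for the cells, a virtual microscope renders fluorescence frames with
realistic noise, and the identical analysis/control code that could drive a
real microscope closes the loop. The goal is that control performance
measured on the simulator — path deviation, steady-state titration error,
multi-cell coordination — is produced by the same algorithmic pipeline
(segmentation, tracking, temporal filtering, PID with anti-windup and gain
scheduling) that the real experiment needs, so the controllers, not the
biology, are what is being tested.

## The migrating-cell plant

The cell is a point-like agent with position, a polarity angle
$\theta$, and a speed law

$$v = v_0 + v_{\max}\,\frac{I}{I + K_I},$$

with baseline speed $v_0$ (default 0.5 µm/min, log-normal across cells,
CV 30 %), a saturating light-induced increment $v_{\max}$ (1 µm/min) and a
half-saturation irradiance $K_I$ (0.1 µW/cm²). Saturation reflects the
observed ceiling on light-modulated speed: bright light cannot push a cell
arbitrarily fast, and dim light (0.23 µW/cm² is the workhorse dose, giving
about 70 % of $v_{\max}$) is already effective.

Polarity obeys two processes:

* **rotational diffusion** with variance $2\,\Delta t/\tau_p$ per step,
  $\tau_p$ = 30 min — the persistence time of unstimulated mesenchymal
  migration. Without light the model is a persistent random walk: ballistic
  below $\tau_p$, diffusive above it.
* **optogenetic alignment**: while part of the cell is illuminated, the
  polarity relaxes toward the direction from the centroid to the centroid of
  the illuminated region with a *separate, faster* time constant
  $\tau_a$ = 1 min. Induced protrusions form within a frame or two; modelling
  alignment with the slow intrinsic persistence time would contradict the
  rapid, localised light response the actuator is chosen for. This is the one
  place the state model has two timescales on the same variable, and it is
  deliberate.

## The nucleocytoplasmic transport plant

A three-state kinetic model: activated exporter fraction $A$, nuclear and
cytosolic concentrations $N, C$:

$$\dot A = k_{on} I (1 - A) - k_{off} (A - A_{dark}),$$
$$\dot N = k_{imp} C / \rho - k_{exp}(E)\, A\, N, \qquad
  \dot C = \rho\, k_{exp}(E)\, A\, N - k_{imp} C,$$

with nuclear-to-cytosolic volume ratio $\rho$ (0.5) and an
expression-dependent export rate

$$k_{exp}(E) = \frac{k_{exp,0}}{1 + E/K_E}.$$

The model encodes three observations about the biology: export is light-dosed
(through $A$), *higher-expressing cells export more slowly* (the saturating
inverse keeps the rate positive for any $E$, unlike a linear decrement), and
import is expression-independent ($k_{imp}$ constant). Defaults
($k_{exp,0}$ = 0.01 s⁻¹, $K_E$ = 500, $k_{imp}$ = 0.008 s⁻¹,
$k_{off}$ = 0.012 s⁻¹, $k_{on}$ = 0.05 s⁻¹ per µW/cm²) give export and
import half-times of one to two minutes, the regime in which a 15 s control
interval samples the dynamics five to eight times per time constant.

$A_{dark}$ = 0.2 is the dark-state leak of the photocage: a caged export
sequence is never perfectly caged, so a fraction of exporters stays active in
darkness and the cytosol retains a visible baseline. Besides being
biophysically expected, the leak matters operationally — with a perfectly
dark cytosol the dark-state calibration frame would contain no cytosolic
signal to segment.

With production and bleaching off (the default), the model conserves
$\rho N + C$ exactly; both terms can be enabled to emulate induction drift in
long experiments, at the cost of the conservation invariant.

**Integration.** $A$ is linear in time at constant irradiance and is advanced
with its exact exponential update; $N$ and $C$ take a classical Runge–Kutta
step with automatic substepping keeping the per-substep relative change below
5 %. Every stage derivative satisfies $\rho\,\dot N + \dot C = 0$
identically, so the integrator conserves mass to rounding error regardless of
step size — the conservation test over $10^4$ steps passes at $10^{-9}$
relative, far below the $10^{-6}$ bound asserted.

## The virtual microscope

Frames are photon-count images: each migrating cell is an anti-aliased disc
carrying a total integrated intensity equal to its expression level; each
transport cell is a cytosolic ellipse (pixel value $\propto E\,C$) with a
nuclear disc ($\propto E\,N$). Patches are blurred by a Gaussian PSF
(σ = 1–1.5 µm) *per cell*, which keeps the rendering cost proportional to
the number of cells rather than the field-of-view area, and then Poisson shot
noise and Gaussian read noise are applied at unit gain. Stage coordinates are
µm, x right / y down, matching matrix row–column order after pixel-size
scaling; masks are pixel sets on the same grid.

Illumination commands carry one binary mask, one irradiance and one PWM duty
cycle per controlled region. A plant receives a region's dose when its
sensitive region overlaps the mask, and pulse-width modulation is modelled in
the fast-PWM limit as the time-averaged dose (duty × irradiance); an explicit
on/off integration mode exists to check that limit, and agrees with the
average to better than 2 % when the PWM period is much shorter than
$1/k_{off}$. An optional scattering halo delivers a configurable fraction of
a region's dose to plants within a set distance — a placeholder for the
cross-activation of close neighbours that motivates centre-of-cell
illumination in multi-cell experiments; its geometry and magnitude are
tunables, not calibrated claims.

## On-the-fly analysis

The segmentation backend is deliberately classical — smoothing, a global
threshold, hole filling, connected components, a minimum-area filter — behind
a one-function contract (`frame → segmentation`), so a learned segmenter
could be swapped in without touching the loop. Two thresholding rules are
provided: Otsu, which suits bright-blob migration frames, and a
background-statistics rule (`median + max(k·MAD, 1 % of range)`) for
transport frames, where a single Otsu split lands between the bright nuclei
and everything else and loses the dim cytosol of low-expressing cells
entirely. Keying the threshold to the background rather than the brightest
object is what makes one global rule work across a 30 %-CV population.

Inside each cell the nucleus/cytosol split is a second Otsu on the
intensities of an eroded cell core (erosion keeps the PSF halo at the cell
boundary out of the histogram); the nucleus is the intensity class that
avoids the cell boundary — an intensity-free criterion that works whether
the nucleus is currently brighter or dimmer than the cytosol. Compartment
intensities are background-corrected **medians** over eroded compartment
masks: pixels straddling the blurred compartment boundary are systematically
dimmed, and the median recovers the plateau value where a plain mean is
biased by several percent. Round-trip accuracy (render a known state, then
measure) is ~0.1 % across the plant's reachable states.

Tracking is greedy nearest-centroid assignment with a distance gate
(`max_step`) and a patience window (`max_gap`); unmatched detections spawn
tracks, stale tracks close. Greedy matching is not globally optimal; at the
cell counts this loop controls (≤ 10) the distinction does not arise, and
adversarial configurations resolve by retiring both tracks rather than
swapping identities. Measurements are normalised per cell to the dynamic
range established by a pre-run calibration (dark-state and saturating-light
frames), and a temporal filter bridges frames whose nucleus/cytosol contrast
falls below 5 % of that range — holding the last valid value by default
(a stale-but-plausible value degrades a PID gracefully; a windowed median,
also provided, can lag setpoint transitions). Until a first valid
measurement exists the controller start is deferred with the light off.

## Controllers

**Trajectory controller.** Project the tracked centroid onto the guide path,
take the setpoint one lookahead ahead along the path, and illuminate the
front sector of the segmented cell mask facing that setpoint (top
`front_fraction` of pixels by scalar projection, ties included). The
lookahead default is 10 µm — about one cell radius. The choice is a
controller-design tradeoff: the lateral correction gain scales as
$v\,\Delta t / L$, so a long lookahead converges lazily and lets rotational
noise accumulate several µm of deviation, while a lookahead much shorter
than the cell radius aims the AOI at a point effectively inside the cell.
Design simulations across heterogeneous populations put the knee of that
tradeoff near one cell radius. On top of the fixed base value, the
*effective* lookahead shrinks with the current deviation
($L_{\mathrm{eff}} = \max(L - d,\, 0.3\,L)$) — the pure-pursuit refinement:
a cell knocked off the path by a noise excursion is aimed steeply back at
the path instead of shallowly at a distant waypoint, which roughly halves
the population's worst-case deviation without affecting on-path behaviour.

**Collision avoidance.** Track pairs are extrapolated at constant velocity
over a short horizon (5 frames); a pair whose predicted separation falls
below the collision distance (30 µm centre-to-centre, i.e. one cell diameter
plus margin) triggers a pullback: one cell of the pair — the one with the
smaller remaining arc distance to its target, falling back to the lower
track id — has its AOI flipped to the rear sector. Two details proved
essential in simulation and are part of the design: the pullback direction
is **latched** at engagement (opposing the cell's movement *when the
conflict was detected* — using the instantaneous velocity would flip the
rear sector as soon as the cell turns, stalling it on the other cell's
path), and the pullback is **held** until the pair separates beyond a
release distance (1.5 × collision distance), preventing flag/release
chatter from eroding the safety margin a few µm per cycle.

**PID with anti-windup.** The discrete law
$u = k_p e + k_i \int e\,dt + k_d \,de/dt$, output clamped to
$[0, I_{\max}]$ (light cannot be negative; $I_{\max}$ = 10.4 µW/cm² is the
saturating dose). The derivative acts on the measurement, not the error, so
setpoint steps do not kick the output. The integral only accumulates while
the output is unsaturated, or when the error drives it back into range —
without this, an unreachable or slow setpoint winds the integral up and the
loop overshoots badly once the setpoint becomes reachable.

**Error sign conventions.** Light raises cytosolic intensity and lowers
nuclear intensity. Errors are folded so the PID always sees a positive plant
gain: cytosol mode uses `setpoint − measurement`, nucleus mode
`measurement − setpoint`.

**Gain scheduling.** The plant is strongly nonlinear along its operating
range: near the dark state a tiny irradiance moves the cytosol a long way
(the activation curve is steep at $I \approx 0$), while near saturation the
incremental gain collapses. One gain set tuned mid-range is therefore
twitchy at the bottom and sluggish at the top. The schedule is an explicit
value–gain matrix at operating points {0.1, 0.3, 0.5, 0.7, 0.9} of
normalised intensity, interpolated piecewise-linearly and clamped at the
ends; the scheduling variable is the temporally filtered measurement,
additionally smoothed by a 3-frame moving average to avoid gain chatter.
Scheduling on the measurement has a known weakness — a single large setpoint
jump is traversed with the gains of the *current* state — which is why
setpoint programs in this package (as in practice) move through the range in
steps.

**Tuning.** `tune_pid()` is an overshoot-constrained search: at each
operating point the plant model is initialised at the steady state of the
previous point (the dark state for nucleus-mode points, whose approach from
above is the light-actuated direction) and stepped to the new setpoint under
each candidate from a grid of proportional gains, integral times and
derivative times; candidates that overshoot more than 5 % or fail to settle
within the horizon are discarded and the fastest settler wins, ties to the
smaller proportional gain. Classical tuning rules (Ziegler–Nichols and kin)
are avoided deliberately: they assume one linear plant, and the operating
point dependence of the gain is the entire reason a schedule exists. The
overshoot bound also has a physical root — with a one-sided actuator,
recovering from an overshoot is passive and slow.

## Post-run metrics

* **Path deviation** — distance from the measured centroid to the nearest
  point of the guide path (the projected position), per frame; summarised per
  loop by splitting the unwrapped arc position at multiples of the path
  length.
* **Projected speed** — arc distance between consecutive projected positions
  divided by the frame interval, wrap-corrected on closed paths, reported in
  µm/min.
* **CTCF** — corrected total cell fluorescence, integrated cell intensity
  minus cell area × mean background, the standard expression-level proxy.
* **One-phase decay fits** — $y = y_\infty + (y_0 - y_\infty) e^{-kt}$ by
  Levenberg–Marquardt least squares with log-linear starting values; used for
  export/import rate estimation. A constant series is reported as
  unidentifiable rather than fitted.
* **Steady-state error** — the settling point of a controlled signal is the
  first time the smoothed derivative (centred 5-point moving average,
  zero-tolerance $10^{-3}$ of the dynamic range per sample) crosses zero,
  changes sign, or falls below tolerance after a setpoint change; the mean
  absolute error from that point on is the steady-state error, cleaned of
  the transition. Reported in percent of the per-cell calibrated dynamic
  range.

## What the simulator does and does not emulate

The generator reproduces the *operational* features the controllers care
about: saturating dose–response with cell-to-cell heterogeneity (log-normal,
30 % CV on baseline speed and expression), persistence-limited directional
noise, expression-dependent export against expression-independent import,
compartment geometry, shot/read noise, and the low-contrast failure mode of
compartment segmentation. It does not emulate cell shape dynamics or
deformation on contact, division, spatial gradients inside compartments,
photobleaching of the reporter (available only as a plant-side term),
phototoxicity, or the 3-D thickness effects that make real cytosolic means
noisier than nuclear ones. Passing the closed-loop benchmarks therefore
demonstrates that the *control pipeline* meets its specifications on a
plant with realistic kinetics, noise and heterogeneity — it does not predict
the behaviour of any particular cell line.

Benchmark problem sizes were likewise chosen as the package's own working
points: guidance runs use a 40 µm-radius circle at 60 s frames (520 frames
for the two-loop single-cell benchmark; 24 × 320 frames for the population
benchmark), titration runs use 10 cells × 180 frames at 15 s with a
three-step setpoint staircase {0.25, 0.55, 0.85}, and the compute-time
scaling benchmark runs 25-frame loops at 1–8 cells with the imaged area
growing in proportion to the cell count, as it would when more cells are
brought into the field.

## Reproducibility and numerics

Every run is reproducible bit-exactly from its config and seed; population
draws take an optional independent seed and restore the caller's RNG stream.
Loop wall-clock times are logged per frame but kept out of the scientific
record. Degenerate inputs have defined behaviour throughout: an empty
segmentation is a valid (empty) result, a lost track commands light off, a
degenerate AOI direction is an error at the operation level and a handled
event in the loop, a calibration without a usable dynamic range refuses to
calibrate, and the tuner reports which constraint made a gain search
infeasible.

## Known limitations

Greedy tracking will mis-handle dense fields of similar cells; the avoidance
tie-break is pairwise and does not reason about three-way conflicts beyond
resolving each pair; measurement-scheduled gains traverse large setpoint
jumps conservatively; the scatter halo is a geometric placeholder; and the
classical segmenter assumes roughly convex, well-separated cells — all
acceptable at the ≤ 10-cell scale this loop targets, and all behind
interfaces where a stronger component could be substituted.
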