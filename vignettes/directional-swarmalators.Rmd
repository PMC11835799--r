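---
title: "Directional swarmalators: model, measures, and calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Directional swarmalators: model, measures, and calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dirswarm)
```

## The model

A *swarmalator* is an agent that both swarms — moves in space under
attraction and repulsion — and oscillates, carrying a phase that couples
to the phases of its neighbours. `dirswarm` implements a *directional*
swarmalator: each agent $s_j$ additionally carries a gaze azimuth
$\delta_j$ and a restricted visual field, so that both its spatial
attraction and its visual entrainment depend on where it is facing. The
motivating system is a dance floor: people bounce to a beat they hear
over headphones, drift toward others moving like them, and can attend
only to dancers inside their field of view.

Each agent has five state variables: position $\mathbf{x}_j \in
\mathbb{R}^2$, oscillation phase $\theta_j$, gaze azimuth $\delta_j$,
spontaneous frequency $\omega_j$, and the phase $\varphi_j$ of the
external stimulus it hears. Pairwise *proximity* is inverse Euclidean
distance, $w_{jk} = 1/|\mathbf{x}_j - \mathbf{x}_k|$.

**Translational dynamics** sum three velocity terms:

* global attraction toward the arena origin,
  $\dot{\mathbf{x}}_{Aj} = -A\,\mathbf{x}_j |\mathbf{x}_j|^{a-1}$, which
  bounds the swarm without walls;
* pairwise repulsion,
  $\dot{\mathbf{x}}_{Rj} = -\tfrac{R}{N}\sum_{k \ne j} w_{kj}^{\,r}\,
  \hat{u}_{jk}$, which prevents coalescence
  ($\hat{u}_{jk}$ is the unit vector from $j$ toward $k$);
* phase-and-gaze-dependent attraction,
  $\dot{\mathbf{x}}_{Pj} = \tfrac{P}{N}\sum_{k \ne j} w_{kj}^{\,p}\,
  \Omega(\theta_k - \theta_j)\,\Upsilon(\alpha_{kj} - \delta_j)\,
  \hat{u}_{jk}$, strongest toward agents that are in phase and in view
  ($\alpha_{kj}$ is the azimuth from $j$ to $k$).

The phase kernel is the raised cosine $\Omega(\theta) =
(1+\cos\theta)/2$. The gaze kernel is the same window raised to the
*constriction* power $c$ and normalized to unit integral over
$(-\pi,\pi]$:
$$\Upsilon(\theta; c) = \frac{\big(\tfrac{1+\cos\theta}{2}\big)^c}
{\int_{-\pi}^{\pi} \big(\tfrac{1+\cos u}{2}\big)^c\,du}.$$
$c = 0$ is omnidirectional vision; larger $c$ narrows the field of view
while keeping the kernel's mean independent of $c$.

**Rotational dynamics** rotate the gaze toward visible, in-phase,
proximal neighbours:
$$\dot\delta_j = \frac{D}{N} \sum_{k \ne j} w_{kj}^{\,d}\,
\Upsilon'(\alpha_{kj} - \delta_j)\,\Omega(\theta_k - \theta_j),$$
with $\Upsilon'(\theta) = \tfrac{c\sin\theta}{2}
\big(\tfrac{1+\cos\theta}{2}\big)^{c-1}$. $D$ is the gaze attraction
strength — the parameter called $g$ in the calibration.

**Oscillatory dynamics** sum the spontaneous frequency, auditory
entrainment to the stimulus, $U \sin(\varphi_j - \theta_j)$, and visual
entrainment to visible neighbours,
$\tfrac{V}{N}\sum_{k\neq j} w_{kj}^{\,v}\,
\Upsilon(\alpha_{kj}-\delta_j)\sin(\theta_k - \theta_j)$.

## Sign and normalization of the rotational kernel

Two reasonable readings of the rotational kernel exist, and they differ
in sign and scale. The literal derivative of the normalized gaze kernel
carries the normalization constant in its denominator and a *negative*
sign for targets counterclockwise of the gaze — under it, gaze would
rotate *away* from attractive targets. The stated behaviour of the model
is the opposite: gaze is attracted by other swarmalators. We therefore
implement the attractive form above (positive for $\theta \in (0,\pi)$,
no normalization denominator) as the default, and expose the normalized
variant through `swarm_params(normalized_gaze_derivative = TRUE)` for
sensitivity analysis. The normalized variant equals minus the exact
derivative of `gaze_coupling()`, which the test suite verifies by finite
differences.

Two numerical details. For $c < 1/2$ the kernel diverges as the target
angle approaches $\pi$; the exact floating-point antipode (where the
gaze kernel itself is exactly zero) is mapped to 0, and near-antipodal
angles keep their large finite values — with the default step size these
produce at most a brief, wrapped gaze swing. For $c = 0$ the rotational
kernel is identically zero. The normalization integral has the closed
forms $2\pi$ ($c=0$) and $\pi$ ($c=1$); other constrictions use
adaptive quadrature, cached per value of $c$.

## Parameters

Defaults are the fixed values used when the model was fitted to
silent-disco motion capture:

| parameter | meaning | default | units |
|---|---|---|---|
| `A`, `a` | attraction strength, range exponent | 0.1, 1 | 1/s, – |
| `R`, `r` | repulsion strength, decay exponent | 1.5, 2 | 1/s, – |
| `P`, `p` | phase-gaze attraction strength, decay | 0.5, 1 | 1/s, – |
| `D`, `d` | gaze strength ($g$), decay | 0.25, 1 | rad/s, – |
| `U` | auditory entrainment strength | 0.8 | rad/s |
| `V`, `v` | visual entrainment strength, decay | 0.4, 1 | rad/s, – |
| `c` | constriction (visual-field width) | 0.25 | – |
| `freq_mean`, `freq_sd` | spontaneous frequency distribution | $4\pi$, 0.2 | rad/s |
| `eps` | minimum-distance guard | $10^{-6}$ | length |

The two calibrated parameters, `c` and `D`, default to the rounded
optimum of the silent-disco fit (0.25 each). Spatial units are
dimensionless; the defaults put typical inter-agent distances at order
one. The spontaneous-frequency distribution is Normal with mean at the
$120$ BPM tactus ($4\pi$ rad/s); its SD of 0.2 rad/s is our choice —
small enough that detuning stays well inside the $|\omega - 2\pi f| <
U$ locking region, as observed in the recordings (every participant
entrained), while still making agents heterogeneous. The guard `eps`
caps proximity at $10^{6}$ so coincident agents cannot produce infinite
forces; the repulsion term keeps simulated swarms several orders of
magnitude away from it in practice.

## Integration

Trajectories use the forward Euler method with a fixed step, by default
$1/120$ s — the frame period of the motion-capture system the model was
fitted against, so simulated and recorded series share a time grid. The
stimulus phase is *prescribed*, not integrated: at every step
$\varphi_j$ is re-evaluated exactly from the schedule
($\varphi_j = 2\pi f_g t + \phi_g$, wrapped), so discretization error
never accumulates in the driving signal. Euler is first-order; the test
suite verifies the $O(\Delta t)$ endpoint convergence, and the
fixed points of the discrete map coincide with the continuous ones (the
single-agent Adler lag $\arcsin(\Delta\omega/U)$ is reproduced to
$10^{-9}$). Gaze and phase are wrapped to $(-\pi,\pi]$ after every
step. Runs abort with the frame index if any coordinate exceeds a
divergence bound (default $10^{3}$).

## Measures of self-organization

Per frame, globally and per stimulus group:

* **circularity** $\kappa$: population SD of distances from the
  centroid; exactly 0 on a circle. The population ($1/N$) form is
  deliberate — it makes the circle zero-point exact at any $N$.
* **grouping coefficient** $\rho \in [0,1]$: intracluster correlation
  of positions with clusters given by the stimulus groups. The two
  coordinates are combined by the multivariate variance decomposition
  ($\sigma_b^2$ and $\sigma_w^2$ are means of squared *Euclidean*
  deviations), which keeps $\rho$ rotation-invariant.
* **gaze locking** $\gamma \in [-1,1]$: mean cosine between each
  agent's gaze and the directions to all others.
* **centroidal alignment** $\chi \in [-1,1]$: mean cosine between gaze
  and the direction to the centroid; agents exactly on the centroid are
  skipped with a warning.
* **phase coherence** $R \in [0,1]$: norm of the Kuramoto order
  parameter.
* **local phase coherence** $R^\sigma$: Gaussian-kernel-weighted
  coherence, $K_{jk} = e^{-|\mathbf{x}_j-\mathbf{x}_k|^2/2\sigma^2}$,
  averaged over agents. The sum includes $k = j$ (self-weight 1), so
  $R^\sigma \to 1$ as $\sigma \to 0$ and $R^\sigma \to R$ as
  $\sigma \to \infty$.
* **spatial variance**: mean squared distance from the centroid
  ("group size" in the calibration error).

## Empirical state estimation

`read_marker_series()` ingests two-marker head trajectories (long
TSV/CSV; the proprietary capture formats are out of scope). Position is
the horizontal marker midpoint. Gaze is the right-to-left marker vector
rotated $-90^\circ$ — a convention, configurable to $+90^\circ$ for
opposite marker handedness. Oscillation phase uses the analytic signal
of the *vertical head velocity* (central differences at the native
rate): $\theta = \angle(\dot z + i\,H(\dot z))$, where $H$ is the
Hilbert transform, computed here by the standard FFT construction
(negative frequencies zeroed, positive doubled). Vertical head velocity
is used because in spontaneous dance it is the component most reliably
locked to the tactus-level beat. The first and last 0.5 s are flagged
and dropped: the finite-window analytic signal is unreliable at the
edges. An optional band-pass around the beat is exposed but off by
default — a pure bounce needs none, and any filtering choice should be
the analyst's, visible in the call.

## Calibration

The composite error of a candidate $(c, g)$ against a dataset is the
sum of absolute differences, at the end of a 60 s simulation started
from the dataset's observed initial configuration, of three summary
metrics: spatial variance, grouping coefficient, and centroidal
alignment. Oscillatory measures are deliberately excluded from the
error. Errors sum over datasets (rather than averaging — with a fixed
dataset collection the argmin is identical). Evaluation defaults to the
final frame; `eval_window` can average the metrics over the trailing
seconds to reduce frame-level noise. Spontaneous frequencies are stored
in each dataset's initial state, so the error surface is deterministic
and repeated evaluations at one $(c,g)$ agree exactly.

Grouping-coefficient discontinuities make the surface non-smooth, so
the optimizer is simulated annealing (`stats::optim`, method `"SANN"`)
with a Gaussian proposal (SD 0.1) clipped to the $[0,1]^2$ box,
initial temperature 1 and five evaluations per temperature level —
conservative settings scaled to an error of order one. Every evaluation
is logged and the best logged point is returned, so the result can
never be worse than the starting point; a flat landscape returns the
initial point with a warning. `error_surface()` maps the error
exhaustively on a grid for the same targets.

## Synthetic data

The generators emulate the silent-disco study conditions: 12 agents in
two groups of six, a 120 BPM stimulus, and a second group hearing it
90° or 180° phase-shifted or sped up (ratio 1.25 — the recordings'
actual speed-up is not documented, so the ratio is exposed as a
setting). Initial positions are uniform in a disc of radius 3 length
units (chosen so the default attraction/repulsion balance yields
order-one inter-agent distances), gazes uniform, phases at the assigned
stimulus phase plus 0.2 rad of jitter (participants were already
bouncing to their beat at the start of the analysed segments, but not
perfectly). Bounce-marker recordings place two markers at a fixed
head half-width about a slowly drifting position, with sinusoidal
vertical motion at the group's stimulus frequency and phase and
optional Gaussian marker noise.

What the generators do *not* emulate: erratic human visual search,
step-like repositioning, anticipation of the beat, or marker dropout
and occlusion beyond simple gaps. Passing tests on synthetic data
therefore demonstrate the correctness of the machinery — estimation,
measures, calibration recovery — not that the model captures every
feature of real dancers.

`generate_calibration_scenario()` closes the loop for validation: it
simulates with known $(c_{\mathrm{true}}, g_{\mathrm{true}})$, records
the end-of-run metrics as targets, and packages them with the initial
state, so the composite error at the truth is exactly zero and
parameter recovery can be tested against a known answer. The recovery
experiment in the test suite uses one 12-agent, 60 s dataset and a
200-evaluation annealing budget.

## Worked example

```{r, eval = FALSE}
library(dirswarm)

spec <- scenario_spec(condition = "phase_180")   # 12 agents, 120 BPM
pars <- swarm_params()                           # fitted defaults
st <- generate_initial_config(spec, pars, seed = 1)
traj <- run_simulation(st, scenario_schedule(spec), pars,
                       duration = 60, dt = 1 / 120)
ms <- measure_series(traj, sigma = 1, every = 120)  # one row per second
tail(ms[, c("time_s", "kappa", "rho", "chi", "R")], 3)
```

## Known limitations

* Euler with a fixed step is faithful to the original fitting procedure
  but first-order; stiff parameter regimes (very large couplings) need
  a smaller step. Higher-order integrators are an extension point, not
  implemented.
* Gaze is 2-D azimuth only; no elevation, no individual visual fields.
* The calibration optimizes exactly two parameters, $(c, g)$; the
  remaining constants are fixed by design, mirroring the small size of
  typical group-dance datasets.
* Group labels in empirical data are taken from the input file; the
  marker-count-based group identification of the original recordings is
  not reimplemented.
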