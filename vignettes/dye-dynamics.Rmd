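---
title: "Dye dynamics and the dynamic shift in simulated smFRET experiments"
author: "fretsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dye dynamics and the dynamic shift in simulated smFRET experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fretsim)
```

## The problem

Time-resolved confocal single-molecule FRET measures, for each molecule
that drifts through the confocal volume, a *burst* of photons.  Each burst
yields two coordinates: the intensity-based FRET efficiency
$\mathcal{E}_I = I_A/(I_A+I_D)$ and the normalized donor lifetime
$\tau = \bar\tau_{D(A)}/\tau_{D(0)}$.  A molecule whose energy-transfer
rate is constant over the burst obeys the static relation
$\mathcal{E} = 1-\tau$; any mixing of transfer rates during the burst
pushes the point *above* that line, because the mean lifetime of a rate
mixture exceeds the lifetime of the mean rate (Jensen's inequality applied
to $x \mapsto 1/x$).  The signed deviation is the *dynamic shift*.  Since
the fluorescent dyes themselves move — their tethers flex and their
transition dipoles reorient — dye motion alone produces a dynamic shift
that must be understood before any shift can be attributed to the labelled
biomolecule.

`fretsim` simulates this measurement from first-principles dye models and
quantifies the resulting shift:

* translational models: isotropic and anisotropic Ornstein–Uhlenbeck (OU)
  springs derived from the linker chemistry, and an elastic pendulum
  (a tethered mass free to swing);
* orientational model: spherical Brownian motion of each transition
  dipole;
* photophysics: a four-state continuous-time Markov chain over
  (D, A, FD, FA) whose donor exit rate $k_D + k_{ET}(t)$ is
  time-inhomogeneous because $R_0^6(t) = C\,\kappa^2(t)$ follows the
  dipole orientation factor
  $\kappa = \hat\mu_D\cdot\hat\mu_A - 3(\hat r\cdot\hat\mu_D)(\hat r\cdot\hat\mu_A)$.

## Model components and their parameters

### Linker chemistry

A carbon chain of $N$ C–C bonds (length $l = 1.54$ Å, angle
$\theta = 109.5^\circ$) acts as $N$ springs in series,
$k_\mathrm{eff} = k/N$, with an effective per-link axial length
$L = (l/2)\sqrt{2-2\cos\theta} \approx 1.26$ Å from the law of cosines.
The default chain ($N = 15$) has contour length $\approx 18.9$ Å, which
sets the pendulum's radial equilibrium.  The single-bond stiffness is
carried as a plain configuration number; the simulator's spring *rates*
(1/ns) are configured directly, because stationary widths — not absolute
stiffness — determine every observable here.

### Translational models

The OU spring obeys $dX_t = -K(X_t - X_\mathrm{eq})\,dt + \sigma\,dB_t$
with diagonal $K$; its stationary law is Gaussian with per-axis variance
$\sigma^2/2k_i$.  Because the noise is additive, the Stratonovich and Itô
readings coincide and the *exact* Gaussian transition kernel is used — no
discretisation error at any step size.  The anisotropic variant softens
two axes to $p\,k_\mathrm{eff}$ ($p = 0.5$ by default) and keeps the stiff
axis along the inter-dye separation for both dyes; with the volatility
pinned so the soft axes carry the accessible-volume width, the variance
*along* the separation halves, which is what suppresses the anisotropic
shift relative to the isotropic one.

The elastic pendulum evolves in spherical coordinates around its
attachment point:

$$dr = [-k_r(r - r_\mathrm{eq}) + c_r/r]\,dt + \sigma_r\circ dB,\qquad
  d\theta = [-k_\theta\sin\theta +
  \tfrac{\sigma_\theta^2}{2r^2\tan\theta}]\,dt +
  \tfrac{\sigma_\theta}{r}\circ dB,\qquad
  d\phi = \tfrac{\sigma_\phi}{r\sin\theta}\circ dB.$$

The bare $1/r$ radial drift is given the configurable coefficient `c_r`
(default 1, the literal reading; $\sigma_r^2$ is the noise-induced-drift
alternative).  The polar line is the standard diffusion-on-a-sphere-of-
radius-$r$ form: it reduces to free spherical Brownian motion when
$r \equiv 1$ and $k_\theta = 0$.  State-dependent noise makes the
Stratonovich convention substantive; the integrator is the Heun
predictor–corrector, which converges to the Stratonovich solution.

### Orientational model

Each dipole diffuses on the unit sphere with coefficient $D$
(physically $D = k_BT/8\pi\nu R_h^3$ for a spherical rotor, see
`rotational_diffusion_coefficient()`); the stationary law is uniform, so
$\mathbb{E}[\kappa^2] = 2/3$, the classic dynamic-averaging value.  Both
dipoles are initialized from the uniform equilibrium when a molecule
enters the confocal volume and then evolve *continuously* for the whole
burst — between excitation events and during each excited-state dwell.
The equilibrium marginal is thereby preserved at every excitation while
temporal correlation is carried across events.  (A per-excitation
re-randomization mode, `dipole_reset = "excitation"`, is provided for
comparison; it provably pins the burst-to-burst spread of the shift at
the shot-noise floor, because every burst then sees the identical
$\kappa^2$ mixture.)

### Photophysics and event sampling

Within one excitation event the inter-dye distance is frozen (the
translational relaxation times, hundreds of ns, vastly exceed the ns-scale
dwell) while the dipoles may rotate, so the donor exit hazard
$k_D + k_D C \kappa^2(t)/r^6$ is time-inhomogeneous.  Exit times are
sampled *exactly* by Lewis–Shedler thinning with the bound
$k_D(1 + 4C/r^6)$ from $\kappa^2 \le 4$; an integrated-hazard inversion
sampler on a fine grid serves as the independent oracle in the test suite,
and the two agree in distribution on random $\kappa^2$ paths.  At the
accepted exit time the branch (donor photon vs transfer) is chosen by the
instantaneous rates; a transfer adds an independent $\mathrm{Exp}(k_A)$
acceptor dwell.  At $r = 0$ the chain reduces to the two-state
acceptor-only system.

### Burst protocol

Bursts are scheduled rather than diffusion-driven: one 1-ms burst per
second over 7 h gives the canonical $\approx 25{,}000$ bursts.  Excitation
is pulsed every 50 ns; each excitation resolves into exactly one photon
(the donor rate is the *total* de-excitation rate), and detection is an
outcome-independent Bernoulli thinning with equal channel efficiencies —
which is why detection can be applied before the photophysics without
bias.  Bursts with fewer than `min_photons` (default 10) detected photons
or no donor photon are excluded from shift statistics.

## Default study conditions and their calibration

The defaults encode one fixed set of study conditions, chosen once as
follows and not revisited:

* **Photophysics**: $k_D = 0.25$/ns ($\tau_{D(0)} = 4$ ns),
  $k_A = 0.5$/ns, $R_0 = 50$ Å — textbook smFRET dye values.
* **Efficiency centring**: each configuration's attachment separation is
  set so its mean intensity efficiency sits near 0.5, where the shift
  geometry is most visible (springs: 50 Å; pendulum: 83 Å static,
  78.5 Å dynamic — the $\kappa^2$ mixture drags the mean efficiency of
  the dynamic model below its static-$\kappa$ value at equal distance,
  so its separation is slightly smaller under the same rule).
* **Accessible volume**: spring stationary width 5.6 Å per axis and the
  pendulum's stationary cloud (arm $\approx 23$ Å, polar concentration
  $\langle\cos\theta\rangle \approx 0.8$) match the several-Å accessible
  volumes of long-linker dyes in molecular-dynamics studies; the raw
  bond-stiffness value would give a sub-Å, physically unreasonable cloud.
* **Detection**: efficiency 0.25 per channel, i.e. $\sim 5000$ detected
  photons per 1-ms burst, putting the shot-noise floor of the per-burst
  shift near 0.017 — the scale of the burst-to-burst spread observed for
  static dye configurations.
* **Rotation**: the default dipole diffusion ($D = 2\times10^{-8}$
  rad²/ns) is the hindered, quasi-static regime: orientations are
  effectively frozen over one burst and sampled afresh per molecule.
  In this regime the $\kappa^2$ mixture across events is driven by the
  motion of the separation *direction* $\hat r$ (the swinging pendulum
  arms) and by molecule-to-molecule orientation draws.  This is the
  regime in which the dye-induced mean shift reaches the experimentally
  reported $\mu(\Delta) \approx 0.2$ *and* the dynamic-$\kappa$
  configuration alone develops a large shift spread; at faster rotation
  $\kappa^2$ averaging restores the static geometry and the mean shift
  cannot exceed the translational-only value ($\approx 0.12$).  The
  $\kappa^2$-path statistics module explores the faster regimes
  (10–1000 $\times$ the dye's translational angular scale
  $\sim 10^{-4}$ rad²/ns) that govern path-level temporal correlation.

With these defaults the four standard configurations give (2000 bursts,
printed-variant shift): isotropic spring $\mu \approx 0.10$, anisotropic
spring $\mu \approx 0.06$, pendulum with $\kappa^2 = 2/3$
$\mu \approx 0.12$, pendulum with dynamic $\kappa$ $\mu \approx 0.20$
with spread $\sigma \approx 0.06$ versus $\approx 0.017$ for the static
rows — the anisotropic < isotropic $\approx$ pendulum-static <
pendulum-dynamic ordering, with only the dynamic-$\kappa$ configuration
reaching the dye shift scale seen in experiments.

## The shift statistics

`dynamic_shift()` implements two variants: the *printed* form
$\Delta = (\mathcal{E}+\tau-1)/\sqrt{\mathcal{E}^2+\tau^2}$ and the
*perpendicular* form $(\mathcal{E}+\tau-1)/\sqrt 2$ (the Euclidean signed
distance to the static line).  Both vanish exactly on the line and are
positive above it.  The two formulations are genuinely inconsistent away
from the line — the claimed extreme values $\pm\tfrac12$ at the corners
$(1,1)$ and $(0,0)$ match neither (the printed form gives $1/\sqrt2$ at
$(1,1)$ and is undefined at the origin) — so both are implemented, the
printed form is the default, and the four-configuration comparison
reports both.

The *moment-difference* variant places a burst at
$(\mathcal{E}_I,\ \mathcal{E}_\tau(1-\mathcal{E}_\tau))$ and measures its
signed orthogonal distance to the parabola $y = x(1-x)$ (negative below,
where mixing pushes it); the nearest-point projection is found by
bracketed 1-D minimisation to $10^{-10}$ and is verified against a dense
grid in the tests.

The two-state exchange reference (`two_state_reference()`) simulates a
molecule switching between efficiencies $\mathcal{E}_1,\mathcal{E}_2$ at
rate $\lambda$.  Every within-burst mixture weight $w$ lies exactly on
the arc
$$\mathcal{E}(\tau) = 1 - \frac{\tau_1\tau_2}{\tau_1+\tau_2-\tau},
  \qquad \tau_i = 1-\mathcal{E}_i,$$
which follows from $m_1(\tau_1+\tau_2) - m_2 = \tau_1\tau_2$ for the
mixture moments $m_k = w\tau_1^k + (1-w)\tau_2^k$ — a short algebraic
identity that the test suite also confirms by simulation.  As
$\lambda \to 0$ bursts sit at the two static points; as
$\lambda \to \infty$ they concentrate at the fully mixed point
$\big(\tfrac{\mathcal{E}_1+\mathcal{E}_2}{2},\
\tfrac{\tau_1^2+\tau_2^2}{\tau_1+\tau_2}\big)$, off the static line.

## Numerical choices

* **OU**: exact Gaussian transition kernel (the published stationary
  variance expression $\sigma/k_\mathrm{eff}$ is read as the standard OU
  $\sigma^2/2k_\mathrm{eff}$; the exact kernel requires the latter for
  self-consistency).
* **Sphere and pendulum angles**: Stratonovich–Heun steps in angle
  coordinates away from the poles; inside a polar window of 0.3 rad
  (or five per-step standard deviations, whichever is larger) the step is
  taken in the local tangent plane and projected back.  A narrow
  $10^{-6}$-rad window is *not* sufficient: once a step can land near a
  pole, the $\cot\theta$/$\tan\theta$ drifts overshoot catastrophically.
  The wide window removes the singularity without measurable bias in the
  uniform stationary law (Kolmogorov–Smirnov checks in the suite).
* **Pendulum radius**: steps driving $r \le 0$ are rejected and retried
  with halved step size (at most 30 refinement levels, counted and
  reported).
* **Step sizes**: translational propagation between detected events at
  10 ns (all spring/pendulum rates $\le 0.01$/ns, so $k\,dt \le 0.1$);
  orientational steps capped at $2\times10^{-3}$ rad² mean-squared
  displacement per step, coarsening up to 2.5 ns for slow rotation;
  long inter-event gaps propagate dipoles at $\le 0.1$ rad² per step and
  re-draw from uniform once the accumulated displacement exceeds 8 rad²
  (fully mixed).
* **Pendulum initialisation**: each burst burns in 500 steps of 10 ns
  ($\ge 40$ radial and polar relaxation times) from the deterministic
  rest radius $r^\* = \tfrac12\big(r_\mathrm{eq} +
  \sqrt{r_\mathrm{eq}^2 + 4c_r/k_r}\big)$ with a uniform azimuth.
* **Bimodality diagnostics**: Silverman's critical-bandwidth bootstrap
  test plus kernel-density mode counting (no dip-statistic implementation
  is available in the environment; Silverman's test plays the same role
  at the same $\alpha = 0.05$).
* **Determinism**: a single master seed drives R's RNG, which also feeds
  the compiled kernels; experiments are bit-reproducible from
  (config, seed), and the RNG algorithm name is recorded in summaries.

## What the generator does and does not emulate

Emulated: pulsed excitation with time-resolved donor delays; competing
donor decay and time-inhomogeneous transfer; per-molecule dye state
renewal; detection loss; the canonical burst schedule.

Not emulated: background photons and burst noise (deliberately absent, so
every shift is attributable to dye motion); diffusion-driven burst
durations; detector dead time, afterpulsing, and instrument response
convolution; photobleaching, triplets, spectral crosstalk and direct
acceptor excitation; biomolecule conformational dynamics (the slowest
timescale is out of scope); translational–orientational coupling beyond
the geometric $\hat r(t)$ dependence of $\kappa$.

Passing tests therefore demonstrate internal correctness of the stochastic
models and estimators under these idealized conditions — not that real
instruments with background and diffusion-limited bursts will show the
same numerical shift values.

## Known limitations

* The anisotropic-spring mean shift cannot be pushed much below
  $\sim 0.05$ at $p = 0.5$: the stiff-axis variance is at most a factor
  $1/p$ below the soft axes, and any soft-plane orientation containing
  the separation axis *increases* distance mixing.  Reported anisotropic
  shifts near 0.01 would require a much stronger anisotropy or a narrower
  overall accessible volume.
* The per-burst shift spread saturates near 0.06 at 5000 photons:
  burst-to-burst drift of the $\kappa^2$-mixture composition moves points
  *along* the static line, to which the shift statistic is invariant, so
  only the burst-to-burst variation in the *amount* of within-burst
  mixing (plus shot noise) contributes.
* The pendulum's inter-dye distance distribution is at most weakly
  bimodal under this reconstruction of the Langevin system (two close,
  equal-height modes in a narrow parameter window around
  $k_\theta \approx 0.004$/ns; unimodal at the calibrated defaults).
* The quasi-static rotation default sits at the slow extreme of the
  hindered-dye regime; free organic dyes rotate on sub-ns timescales, in
  which case orientational averaging suppresses the orientational part of
  the shift (the `simulate_kappa_paths()` regimes quantify the
  transition).

## Problem sizes

The test suite and the reproduction script use 2000 bursts per
configuration (the four-configuration table), $10^4$–$10^6$ draws for
distributional checks, 20 random hazard paths for the thinning/inversion
equivalence, and ensembles of 2000–4000 one-nanosecond $\kappa^2$ paths
for the rotational-regime statistics; these sizes give Monte-Carlo errors
comfortably below the assertion tolerances while keeping a full run in
minutes.

## A minimal session

```{r example, eval = FALSE}
cfg <- fret_config("pendulum", "dynamic")
ex  <- run_experiment(cfg, seed = 1, n_bursts = 500)
summary(ex)
shift_distribution(ex)          # mu(Delta), sigma(Delta)
plot(ex)                        # burst cloud vs the static line

tab <- reproduce_table1(n_bursts = 2000, seed = 1)
print(tab)                      # the four-configuration comparison
```
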