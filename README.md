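# fretsim

Physics-based simulation of time-resolved confocal single-molecule FRET
(smFRET) experiments with explicit dye dynamics, and quantification of the
**dynamic shift** — the deviation of the joint FRET-efficiency /
donor-lifetime distribution from its static Förster relationship — that
dye motion alone produces.

## Who this is for

smFRET practitioners and modellers who need to know how much of an
observed dynamic shift is attributable to the fluorescent dyes (flexible
linkers, reorienting transition dipoles) rather than to the conformational
dynamics of the labelled biomolecule, and methods developers who want a
fast, exact stochastic simulator of the underlying photophysics.

## The model

Each excitation event is a four-state continuous-time Markov chain over
(D, A, FD, FA): the excited donor D decays to fluorescence FD at rate
`k_D` or transfers to the excited acceptor A at the Förster rate

    k_ET(r, t) = k_D (R0(t) / r)^6,      R0^6(t) = C * kappa^2(t),

where the orientation factor

    kappa = muD . muA - 3 (rhat . muD)(rhat . muA),   kappa^2 in [0, 4],

follows the instantaneous dipole orientations (uniform average 2/3).
Because the dipoles reorient while the donor is excited, the donor exit
hazard `k_D + k_ET(t)` is time-inhomogeneous; exit times are sampled
exactly by Lewis–Shedler thinning.  Dye positions follow either
Ornstein–Uhlenbeck springs (isotropic or anisotropic, with stiffness from
the C–C linker chemistry treated as springs in series) or an elastic
pendulum Langevin system in spherical coordinates (Stratonovich–Heun
integration); dipoles follow spherical Brownian motion.  Bursts (1 ms, one
molecule each, pulsed excitation, Bernoulli detection) yield per-burst
coordinates `(E_I, tau)`, and the dynamic shift of each burst is the
signed deviation from the static line `E = 1 - tau`:

    Delta(E, tau) = (E + tau - 1) / sqrt(E^2 + tau^2)     (printed variant)
    Delta(E, tau) = (E + tau - 1) / sqrt(2)               (perpendicular variant)

Jensen-gap bounds for rate mixtures, a two-state exchange reference arc,
a moment-difference shift (signed distance to the parabola `y = x(1-x)`)
and kappa^2-path ensemble statistics complete the analysis layer.  See the
methods vignette (`vignettes/dye-dynamics.Rmd`) for the full model,
parameter table and numerical choices.

## Worked example

```r
library(fretsim)

cfg <- fret_config("pendulum", "dynamic")   # elastic pendulum, dynamic kappa
ex  <- run_experiment(cfg, seed = 1, n_bursts = 300)
summary(ex)
```

```
smFRET experiment summary (pendulum, dynamic kappa)
  bursts: 300 (300 usable), 5002.3 photons/burst
  <E_I> = 0.468  <tau> = 0.705  <kappa^2> = 0.671
  dynamic shift (printed): mu = 0.2003, sigma = 0.0591
```

Three hundred simulated molecules average ~5000 detected photons each; the
mean intensity efficiency sits near 0.5 (the calibrated mid-range), the
mean normalized lifetime 0.705 lies well above the static expectation
`1 - 0.468 = 0.532`, and the resulting mean dynamic shift `mu = 0.20`
is the dye-induced shift scale reported for real experiments.  The
four standard dye configurations are compared with:

```r
reproduce_table1(n_bursts = 2000, seed = 1)
```

```
Dynamic-shift distribution by dye configuration (seed 1)
                          model   kappa    mu sigma mu_perp sigma_perp n_used
               Isotropic Spring  static 0.099 0.017   0.054      0.010   2000
             Anisotropic Spring  static 0.059 0.018   0.031      0.010   2000
 Elastic Pendulum kappa^2 = 2/3  static 0.121 0.017   0.066      0.011   2000
 Elastic Pendulum Dynamic kappa dynamic 0.199 0.056   0.120      0.036   2000
```

Translational motion alone (top three rows) produces shifts of 0.06–0.12;
only the addition of time-varying dipole orientations (bottom row) reaches
the experimentally observed ~0.2, with a markedly broader burst-to-burst
spread — the central claim this simulator lets you probe.

A thin command-line wrapper is included:

```sh
Rscript inst/scripts/fretsim simulate --model pendulum --kappa dynamic \
    --bursts 500 --seed 1 --out out/
Rscript inst/scripts/fretsim analyze --in out/bursts.tsv --out out/summary.json
Rscript inst/scripts/fretsim reproduce-table1 --bursts 2000 --seed 1
```

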