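---
title: "Estimating association rates and landscapes from coarse-grained binding trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating association rates and landscapes from coarse-grained binding trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bindkin)
```

## The estimation problem

`bindkin` analyses ensembles of independent binding trials: one receptor
and one ligand per periodic box, each trial run until the pair first
satisfies a bound-state criterion or a fixed horizon expires. The package
covers the full chain — bound-state detection, first-passage-time (FPT)
statistics, rate conversion, free-energy landscapes over collective
variables, and conformational-ensemble decomposition — together with a
synthetic Brownian-dynamics (BD) generator that produces data with exactly
the statistical structure the estimators assume.

### Bound state and first passage

Two molecules are *loosely bound* when at least 50 inter-molecular bead
pairs lie within 5.5 Å (minimum-image distances on autoimaged frames;
pairs counted once; the threshold is inclusive). The first frame meeting
the criterion defines the trial's FPT; trials that never meet it within
the horizon are *censored*. Both constants are arguments everywhere they
appear (`cutoff`, `threshold`), with 5.5 Å / 50 as defaults.

Censoring policy was a genuinely open choice: the mean-FPT estimator
excludes censored trials by default, which biases the mean low when
censoring is appreciable. `rate_estimate()` therefore reports the censored
count and a sensitivity value that treats censored trials as if they bound
exactly at the horizon — the two numbers bracket the truth, and in the
intended regime (a few percent censoring) they nearly coincide.

### From mean FPT to a rate

With one molecule of each species in a box of volume $V$, the equivalent
concentration is $[c] = 1/(N_A V)$ and

$$k_a \;=\; \frac{1}{\overline{T}_{\mathrm{fp}}\,[c]},$$

with $\overline{T}_{\mathrm{fp}}$ the mean of 1000 bootstrap resamples
(with replacement, original sample size) of the uncensored FPTs. The
bootstrap spread is reported both as the dispersion of bootstrap means and
as the analytic $s/\sqrt{n}$, because published uncertainties of this kind
are ambiguous between the two; they agree asymptotically. Coarse-grained
effective dynamics run faster than atomistic dynamics; mean FPTs are
multiplied by `timescale_factor` (default 4) *before* the rate conversion.
The default box volume is $3.375\times10^{-21}$ L, a 150 Å cube.

Exponential fits of the FPT distribution ($A e^{-\tau x}$) use the maximum
likelihood estimate $\tau = 1/\bar{x}$ — for raw per-trial FPTs, not
bootstrap means, since resampling would shrink the spread artificially —
with a Kolmogorov–Smirnov distance as the convergence statistic. Condition
comparisons use Welch's unequal-variance t-test on per-trial FPTs for the
same reason: testing on bootstrap means would inflate significance by
roughly $\sqrt{n_\mathrm{boot}}$.

### Landscapes

Frames are projected onto two collective variables: RMSD to the bound
reference complex and receptor–ligand centre-of-mass distance. The RMSD
convention (unstated in most trajectory-analysis pipelines and therefore a
documented decision here) is: Kabsch superposition on the receptor beads,
deviation scored over *all* complex beads, unweighted. Scoring everything
means an unbound ligand dominates the value, which stretches the landscape
usefully along the approach coordinate; scoring the ligand only is
available through `score_set`.

Densities use a Gaussian product kernel with Scott's-rule bandwidths
($\hat\sigma\,n^{-1/6}$ per axis, scalable via `bandwidth_scale`) on a
100×100 grid padded by one bandwidth, evaluated through `MASS::kde2d`.
Boltzmann inversion is $E_{\mathrm{PMF}} = -k_BT\ln(\rho/\rho_\min)$ with
$\rho_\min$ the smallest density among cells above $10^{-12}$ of the
maximum; cells below that floor are masked `NA` rather than assigned the
arbitrarily large energies a raw logarithm would give. The surface is
non-positive by construction and invariant to rescaling $\rho$.

Native-bound events are trials whose projection ever enters
$[0, 10\,\text{Å}] \times [0, 10\,\text{Å}]$ near the origin; both cuts are
arguments, and counting is monotone in them. The loosely-bound mask flags
projected frames at ≥ 50 contacts and, given a PMF, verifies the flagged
points sit at negative free energy.

### Radius-of-gyration ensembles

Receptor RG is collected over each trial's pre-binding window — all frames
strictly before the FPT (the full trajectory for censored trials; the
window is configurable, and a trial bound at its first frame is excluded
with a warning). The sample is decomposed into Gaussian mixtures with
unequal variances, fitted by EM for each candidate component count
(default 1–3) and selected by BIC, via `mclust`. mclust's deterministic
model-based hierarchical initialisation replaces random/k-means restarts —
it is reproducible without seed bookkeeping and, on the well-separated
mixtures this analysis targets (compact ≈ 15 Å, intermediate ≈ 17 Å,
extended ≈ 18 Å receptor states), converges to the same optimum. Parameter
recovery at these separations is tested to 0.2 Å on $10^4$-point samples.

## The synthetic generator

### What it emulates

The generator reproduces the campaign geometry the estimators expect:
a 150 Å periodic cubic box; the ligand placed with uniform random position
and orientation subject to a ≥ 40 Å minimum bead–bead distance from the
receptor; trials of 2 μs (simulation clock) ended early at first passage;
ionic strengths {0, 0.15, 0.5} M entering only through the Debye screening
length; and two linker-flexibility regimes. Per-trial seeds are
`base_seed + trial_index`, making campaigns bit-reproducible.

The receptor is two rigid domains of beads arranged as half-channels
facing each other across a short gap, so together they enclose a
cylindrical groove that the rod ligand docks into — a minimal geometry for
a two-lobed protein wrapping a helical peptide. A bead chain arched over
the groove joins the domains: harmonic bonds (rest lengths from the built
geometry, 0.5 kcal/mol/Å²) and harmonic angles whose stiffness encodes the
regime — 10 kcal/mol/rad² for the stiff helix-like linker (`"WT"`), 0.5
for the labile coil (`"labile"`). Rest angles default to the as-built arc
so construction is strain-free. Domains are idealised as perfectly rigid;
the ligand is a rigid rod (1.5 Å rise per bead), mirroring the fixed-helix
assumption for short helical binders. Net charges (default −16 receptor,
+5 ligand) are spread uniformly over beads; a `groove_charge_fraction`
flag concentrates receptor charge on the groove lining to emulate a
charge-focused binding site.

Interactions are inter-molecular only: screened Coulomb
$U = k_BT\,l_B\,q_iq_j\,e^{-r/\lambda_D}/r$ (Bjerrum length ≈ 7.1 Å at
300 K, $\varepsilon_r = 78.5$; $\lambda_D = \infty$ at zero ionic
strength), a bounded soft-core overlap repulsion
$\varepsilon(1-r/\sigma)^2$ for $r < \sigma = r_i + r_j$ (default
$\varepsilon$ = 10 kcal/mol), and a Gaussian attraction well on the ligand
centre of mass anchored at the channel centre (the midpoint of the two
domain centroids), which gives the model a fully-bound basin. The well
depth/width defaults (12 kcal/mol, 7 Å) were calibrated once, against the
generator's stated design targets: ≈ 90% of trials bound within the 2 μs
horizon at 0.15 M, with mean FPT of order $10^3$ ns in the 150 Å box.

### What it does not emulate

No explicit solvent or ions (ionic strength acts only through screening),
no hydrodynamic interactions, no force-field fidelity of any kind, no
secondary-structure dynamics, and no dissociation (the well is deep enough
that unbinding is never observed, matching the regime the estimators
assume). Passing tests therefore demonstrate that the *estimators* are
correct on data with the assumed statistical structure — exponential-ish
FPTs, screened-electrostatics salt dependence, mixture-structured RG
ensembles — not that any particular force field or real protein behaves
this way.

### Dynamics and numerical choices

Propagation is first-order Euler–Maruyama overdamped dynamics. Rigid
bodies (two domains, ligand) translate with
$D_t = k_BT/6\pi\eta r_\mathrm{eff}$ and rotate with
$D_r = k_BT/8\pi\eta r_\mathrm{eff}^3$ (Stokes–Einstein on an effective
radius $\sqrt{5/3}\,R_G$ plus half a bead radius; water viscosity at
300 K), driven by net force and torque about the centre of mass plus
isotropic Gaussian noise. Linker beads are propagated individually; their
friction uses an effective hydrodynamic radius of 35 Å — a tethered
backbone segment drags its chain, so free-bead Stokes friction would be
physically and numerically wrong (it also puts the coupled bead–bond modes
outside the Euler stability region at the default step).

The default step is $dt = 0.01$ ns with frames every 100 steps. Two
safeguards keep the explicit integrator honest: a pre-flight check fails
with a stability error if the per-axis rms thermal step
$\sqrt{2 D_\mathrm{max}\,dt}$ exceeds the smallest bead radius, and the
deterministic (force) displacement of any body is capped at half the
smallest bead radius per step, so transient overlaps kicked in by the
noise relax instead of exploding. In zero-noise test mode
(`noise_scale = 0`) the dynamics are a strict descent: total potential
energy is non-increasing, which the tests assert.

Binding is detected every frame for the contact criterion and every step
for the absorbing-sphere criterion (`bind_mode = "com"`), the latter being
the mode used for oracle validation. All randomness flows through R's RNG,
so `set.seed()` reproduces trajectories bit for bit.

### Oracle validation and what the tolerances mean

For a single-bead ligand absorbed at radius $R$ around a fixed single-bead
receptor, the infinite-dilution rate is $4\pi D R$ (Smoluchowski), and
with a pair potential $4\pi D / \int_R^\infty e^{U/k_BT} r^{-2} dr$
(Debye–Smoluchowski; evaluated by quadrature in
`debye_smoluchowski_rate()`). A periodic box is *not* infinitely dilute: a
simple-cubic array of absorbers reacts measurably faster than an isolated
one (the leading correction is of order $R/L$, about +20% at
$R/L = 10/150$), and the FPT-based estimate in a 150 Å box sits
correspondingly above the closed forms. The acceptance tests compare the
full pipeline (placement → BD → detection → bootstrap → $k_a$) against the
infinite-dilution oracles within 25% (neutral) and 30% (charged at
0.15 M), which the measured ≈ +20% finite-box excess fits inside; the test
sample sizes (2000 and 1500 trials) were chosen by a power analysis of the
FPT variance so that measurement noise does not straddle the band. The
ionic-strength property — $k_a(0) > k_a(0.15) > k_a(0.5)$ for an
oppositely charged pair (±3 e), with non-overlapping bootstrap intervals
between the extremes — uses 150 trials per condition. Smaller problem
sizes are used everywhere else: landscape recovery uses $10^5$ points from
a known harmonic well ($R^2 > 0.95$ within the 2-$k_BT$ basin after
removing the additive constant), mixtures $10^4$ draws, and structural
observables are checked against exhaustive $O(n^2)$ / 27-image /
independent-implementation (bio3d Kabsch) oracles on randomized small
instances.

## Trajectory formats

The compact dialect is one header line (`n_beads box_side`) followed by
per-frame blocks — a `frame_index time` line, then one `x y z` line per
bead (Å, ns, 0-based bead order). Multi-model PDB writes one bead per
ATOM record (1-based serials, chain `R`/`L` for receptor/ligand, bead
charge in the occupancy column), one MODEL per frame, frame times in
`REMARK 250 TIME=` records, and is read back through bio3d. Round trips
are exact to format precision (10⁻⁴ Å dialect, 10⁻³ Å PDB), and both
formats yield identical observable series.

Autoimaging translates the whole frame so the receptor centre of mass sits
at the box centre, then shifts the ligand by the lattice vector minimising
its centre-of-mass distance to the receptor — exactly the 27-image
minimum, since the componentwise nearest image minimises each coordinate
independently. The operation preserves intra-molecular distances and is
idempotent.

## Known limitations

- The mean-FPT rate assumes one-step binding from a well-mixed start; it
  does not resolve two-step (encounter-complex, then reorganisation)
  kinetics.
- Finite-box and discrete-time-detection biases are inherent to the
  estimator (quantified above); the package reports the box-defined
  concentration rather than attempting infinite-dilution extrapolation.
- The generator's bound state is held by a construction well, so
  dissociation rates are out of reach by design.
- Landscape energies are only defined up to an additive constant and only
  on sampled support; comparisons across conditions should use energy
  differences within one surface.
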