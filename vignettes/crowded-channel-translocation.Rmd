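---
title: "Driven polymer translocation through a crowded channel: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Driven polymer translocation through a crowded channel: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crowdpore)
```

## The model

`crowdpore` simulates a coarse-grained polymer driven through a cylindrical
membrane channel crowded with static spherical obstacles, the minimal
setting for questions like protein or nucleic-acid passage through a pore
whose lumen is partially occupied by other macromolecules.

The polymer is a bead-spring (Kremer–Grest type) chain. Consecutive beads
are bonded by the finitely extensible nonlinear elastic (FENE) potential

$$U_{\mathrm{FENE}}(r) = -\tfrac{1}{2} k R_0^2 \ln\!\left(1 - r^2/R_0^2\right),$$

whose divergence at $R_0$ prevents bond crossing, and all bead pairs — and
every bead–wall and bead–obstacle pair — repel through the
truncated-shifted Lennard-Jones (WCA) potential

$$U_{\mathrm{LJ}}(r) = 4\epsilon\left[(\sigma/r)^{12} - (\sigma/r)^{6}\right] + \epsilon,
\qquad r \le 2^{1/6}\sigma,$$

and exactly zero beyond the cutoff, so excluded volume is purely repulsive.
Each bead follows the Langevin equation of motion

$$m \ddot{\mathbf r}_i = -\nabla U_i - \xi \dot{\mathbf r}_i + \mathbf F + \mathbf W_i(t),$$

with the random force obeying the fluctuation–dissipation relation
$\langle \mathbf W_i(t)\cdot \mathbf W_j(t')\rangle = 6 k_B T \xi\,
\delta_{ij}\delta(t-t')$. All quantities are in reduced Lennard-Jones
units; the time unit is $t_{LJ} = (m\sigma^2/\epsilon)^{1/2}$.

The default constants are the study conditions of the model:
$\sigma = 1$, $\epsilon = 1$, $R_0 = 2\sigma$, $k = 7\epsilon$,
$\xi = 0.7$, $k_BT = 1.2\epsilon$, $m = 1$, channel length $L = 5$,
accessible channel radius $R = 2$ and obstacle diameter $d = 1$. The bead
mass is taken as $m = 1$ so that $t_{LJ} = 1$.

### Geometry

The membrane and channel are built from stationary particles of diameter
$\sigma$: staggered rings of radius $R + \sigma/2$ line the cylinder over
$z \in [0, L]$, and a triangular lattice tiles the membrane planes $z = 0$
and $z = L$ outside the pore, out to a configurable extent (default $3R$).
Ring and lattice spacings are at most $\sigma\sqrt{3}/2$, which leaves no
gap a bead of diameter $\sigma$ could pass: the only route from the *cis*
side ($z<0$) to the *trans* side ($z>L$) is the pore. Placing the lining
at $R+\sigma/2$ makes $R$ the nominal accessible radius for bead centres.
Beyond the particle lattice the membrane continues as analytic WCA planes
at $z = 0$ and $z = L$, so it is effectively infinite: without this
closure a long chain's tail can be dragged *around* the lattice rim and
reach the trans side without ever traversing the pore (observed in
testing at $N = 64$ with a $3R$ lattice), silently corrupting the event
bookkeeping.

Crowding is a set of $N_o$ static spheres of diameter $d$ with centres
drawn uniformly over the accessible cylinder
$\{0 \le z \le L,\ r_\perp \le R - d/2\}$, so every obstacle is fully
inside the channel. The crowding extent is
$\rho = N_o V_o / V_c$ with $V_o = \tfrac{4}{3}\pi (d/2)^3$ and
$V_c = \pi R^2 L$; `n_obstacles_for_rho()` rounds $\rho V_c/V_o$ to the
nearest integer (48 obstacles at $\rho = 0.4$, 72 at $\rho = 0.6$).
Obstacle–obstacle overlap is allowed deliberately: crowding extents up to
$\rho = 0.8$ (96 spheres in a volume of $20\pi$) exceed random
hard-sphere packing in this geometry, so independent uniform placement is
the only construction that realises the whole $\rho$ range. Two
placement details are worth noting:

* Because the protocol pins the first bead at the entrance (the origin),
  obstacle centres are re-drawn if they fall inside that bead's WCA
  contact zone (radius $2^{1/6}(\sigma+d)/2$ around the origin); an
  obstacle embedded in an immovable bead would make the release step
  singular. The excluded half-ball is about 8% of the placement volume.
* By default every run of an ensemble draws its own obstacle
  configuration, so ensemble averages are also disorder averages; set
  `fixed_obstacles = TRUE` to share one realisation.

## Integration

The integrator is the GJF Langevin velocity-Verlet scheme
(Grønbech-Jensen & Farago), chosen because it reproduces configurational
statistics and free diffusion exactly at finite step size. The discrete
noise impulse per component has variance $2 k_B T \xi\, \Delta t$. The
base step is $\Delta t = 0.005\,t_{LJ}$.

A fixed step is not safe in this force field: under driving, the bond
behind the pore carries a tension of order $F N_{in}$ and sits close to
the FENE divergence, where the bond stiffness grows as $2k/w^2$ with
$w = 1 - r^2/R_0^2$. The integrator therefore subdivides each base step
adaptively, with three criteria:

* *bond stiffness*: $\Delta t_s \le 0.05\, \omega^{-1}$ with
  $\omega = \sqrt{4k/m}/w$ for the tautest bond beyond $0.75 R_0$;
* *bond approach*: a stretching bond may cover at most 20% of its
  remaining margin to $R_0$ per substep, whatever the bead velocities;
* *displacement*: no bead moves more than $0.03\sigma$ per substep, so a
  fast bead cannot tunnel through a repulsive shell.

Substepping makes the scheme robust through tension spikes (for example
when the cis coil snags and releases) without paying the fine-step cost
in quiet stretches. A bond that still reaches $R_0$ — in practice only
possible through a force-field or configuration error — aborts the run,
and ensembles replace such runs from a fresh random stream (none occur
under the study conditions; the guard exists for misuse).

All randomness comes from a 64-bit Mersenne Twister with Gaussian
variates from the polar method, seeded per `(master seed, run index,
stream)` through a splitmix64 finaliser. Trajectories are therefore
bit-reproducible on any platform, runs of an ensemble are independent
streams addressable by index, and an interrupted ensemble resumes to an
identical result.

## Protocol and failure semantics

A translocation attempt follows the experiment's protocol: bead 1 is
placed at the channel entrance on the axis; beads $2..N$ are grown on the
cis side as a self-avoiding walk of bond length $\sigma$ (rejecting
placements within $0.9\sigma$ of anything); the chain equilibrates with
bead 1 tethered and the field off; the tether is released and the clock
starts. The driving force $F\hat z$ acts on beads inside the channel (a
`field_everywhere` switch applies it globally instead). The attempt ends
in one of three ways:

* **success** — every bead has crossed the exit plane $z > L$; the
  translocation time $\tau$ is the first-passage time of the last bead,
  measured from release.
* **retraction** — every bead sits a full bead diameter clear of the
  entrance on the cis side ($z < -\sigma$). The buffer matters: the
  start state itself has all beads at $z \le 0$, so the bare criterion
  would fire immediately.
* **timeout** — either a hard step cap, or (the operative condition in
  crowded channels) no bead has newly entered or exited the channel for
  `stall_time` (default $500\,t_{LJ}$). Probing jammed configurations at
  $\rho = 0.4$ shows chains that make no progress for $2\times 10^4\,
  t_{LJ}$; they are wedged against obstacles and never complete, so the
  detector only reclassifies lost causes. Timeouts count as failures in
  the translocation probability.

Equilibration defaults to $5\times10^4$ steps ($250\,t_{LJ}$); the
driver compares the first and second halves of the $R_g^2$ trace and
warns above 10% disagreement. For a chain of $N = 32$ the Rouse time at
these parameters is $\approx 20\,t_{LJ}$, so scaled studies in the test
suite use $2\times10^4$ steps ($100\,t_{LJ} \approx 5$ relaxation
times), which the trace diagnostic supports.

## Observables

Per successful event the simulator records first entry and first exit
times per bead, and, at the instant each new exit count $s$ is reached,
the beads-in-channel count and the gyration tensors of the whole chain
and of the translocated sub-chain. From these the observables module
computes:

* translocation probability with a Wilson 95% interval;
* mean translocation time with its standard error (successes only — the
  translocation time is defined only for completed passages);
* the per-bead residence-time profile $\tau(s) = t_{exit}(s) -
  t_{entry}(s)$, together with two alternative readings (waiting time
  between consecutive exits, and cumulative time to the $s$-th exit) so
  the conventions can be compared on the same data — the residence
  reading is the one whose $\tau(1)$ maximum reproduces the
  entrance-barrier signature in crowded channels;
* the mean segment time $(1/N)\sum_s \tau(s)$;
* $N_{in}(s)$, the mean beads-in-channel count at the $s$-th exit;
* the shape-factor profile $\langle\delta\rangle(s)$, with
  $$\delta = 1 - 3\,\frac{L_1^2 L_2^2 + L_2^2 L_3^2 + L_3^2
  L_1^2}{(L_1^2+L_2^2+L_3^2)^2}$$
  built from the ordered eigenvalues of the gyration tensor (0 for a
  sphere, 1 for a rod). Profiles default to the whole chain; the
  translocated-sub-chain variant is exported alongside. Internally the
  profile path evaluates $\delta$ from tensor invariants
  ($\sum_{i<j}\lambda_i\lambda_j = (\mathrm{tr}^2 -
  \mathrm{tr}A^2)/2$), which needs no eigensolve and is checked against
  an independent eigendecomposition in the tests;
* the force-scaling fit: weighted least squares of $\ln\langle\tau\rangle$
  on $\ln F$ with weights $(\langle\tau\rangle/\mathrm{sem})^2$, giving
  $\tau \sim F^{-\alpha}$ with $\alpha$ and its standard error from the
  fit covariance. The default grid is $F \in \{10, 15, 20, 25, 30\}$.

```{r example, eval = FALSE}
p <- sim_params(N = 32, rho = 0, n_equil = 2e4, max_steps = 2e6, seed = 1)
sweep <- run_force_sweep(p, target_successes = 200)
fit <- fit_scaling_exponent(sweep)
glance(fit)
autoplot(fit)
```

## What the generator does and does not emulate

The simulator *is* the study system — there is no external data — but
its idealisations bound what any result means for real pores: the
driving force is uniform inside the channel rather than a solved
electric field; solvent enters only through friction and noise (no
hydrodynamic interactions); obstacles and walls are frozen (no mobile
crowders); and the chain is fully flexible with no bending stiffness,
charge, or specific bead–pore attractions. Agreement of the scaled-down
ensembles here with the model's reference behaviour says nothing about
chemically detailed channels.

## Numerical and design choices

* **Problem sizes.** Statistical results in the tests and the acceptance
  script use scaled ensembles: at least 200 successful events per force
  for the $N = 32$ scaling fits (against 2000-run production ensembles),
  ~100 events for qualitative profile checks at $N = 32$–$64$, with
  equilibration and caps as above. Standard errors are propagated into
  the fits, so the reduced replication widens uncertainties rather than
  biasing estimates.
* **Success-time caps.** The step cap (default $10^8$) is effectively
  inactive; the stall detector is what ends jammed runs. In crowded
  channels the success-time distribution is heavy-tailed, so mean times
  condition on "completed within the stall rule"; the same rule is
  applied at every force, which is what the scaling fit compares.
* **Obstacle-placement region.** Centres are confined to
  $r_\perp \le R - d/2$ so obstacles are wholly inside the channel,
  which concentrates them in the lumen: the *local* volume fraction in
  the centre region is $\rho R^2/(R-d/2)^2 \approx 1.78\rho$. This is
  the reading consistent with counting the full $V_o$ in
  $\rho = N_oV_oV_c^{-1}$; the alternative (centres anywhere in the
  cylinder, spheres protruding into the wall) would dilute effective
  crowding.
* **Degenerate inputs.** Coincident points make the shape factor
  undefined (error); zero successes make time statistics undefined
  (error, not NaN); $\rho$ outside $[0,1)$ and non-positive constants
  are configuration errors carrying the offending key.

## Known limitations

Single pore, single chain, no hydrodynamics, no retraction-time
statistics, and no re-threading after completion. Driving far beyond the
study range (roughly $F \gtrsim 80$) combined with crowding can overwhelm
the adaptive substep guards — a bead slammed deep into an obstacle while
the chain is under extreme tension injects unphysical energy — and such
runs abort with a broken-bond error rather than continue silently; within
the study grid ($F \le 30$, all crowdings) no such aborts occur. Very high crowding
($\rho \gtrsim 0.6$) combined with weak driving produces mostly
retractions and jams; probabilities remain estimable but mean times
there rest on few successes and should be read with their standard
errors.
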