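---
title: "Multistate free energies with replica-exchange enveloping distribution sampling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multistate free energies with replica-exchange enveloping distribution sampling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reedsim)
```

## The method

`reedsim` computes all pairwise free-energy differences between N
alchemical end-states from a *single* simulation. Instead of sampling each
end-state (or a pathway between each pair), it samples one **reference
state** whose potential energy envelopes all end-states,

$$V_R(\mathbf r; s, \mathbf E^R) \;=\; -\frac{1}{\beta s}\,
  \ln\!\sum_{i=1}^{N} e^{-\beta s\,\bigl(V_i(\mathbf r) - E_i^R\bigr)},$$

where $\beta = 1/k_BT$, $s \in (0, 1]$ is the smoothness parameter and
$E_i^R$ are per-state energy offsets. At $s = 1$ the reference state is a
soft minimum of the end-states and configurations are physical; lowering
$s$ flattens the barriers between end-states so transitions become easy.
Forces on the particles are the weight-mixed end-state forces,

$$\mathbf f_k = \sum_i w_i \left(-\frac{\partial V_i}{\partial \mathbf r_k}\right),
\qquad
w_i = \frac{e^{-\beta s (V_i - E_i^R)}}{\sum_j e^{-\beta s (V_j - E_j^R)}},$$

and every pairwise difference follows from exponential (Zwanzig)
reweighting of the reference-state time series,

$$\Delta G_{BA} = -\frac1\beta \ln
  \frac{\langle e^{-\beta (V_B - V_R)}\rangle_R}
       {\langle e^{-\beta (V_A - V_R)}\rangle_R}.$$

Because each $\Delta G_{BA}$ is a difference of per-state log-averages over
the same stream, antisymmetry, a zero diagonal and exact cycle closure hold
by construction — the test suite asserts them at $10^{-10}$ kJ/mol.

A single $s$ cannot be both physical and well-mixing, so a **Hamiltonian
replica-exchange ladder** couples replicas at descending $s$ (top replica
fixed at $s = 1$, the only one used for estimation). Neighbour swaps use
the Metropolis criterion on the reference energies; at equal temperature
the kinetic terms cancel, which is why `exchange_probability()` takes only
the four cross-evaluated $V_R$ values. Because the end-state energies
$V_i$ do not depend on $s$, re-evaluating $V_R$ at a neighbour's $s$ is a
cheap log-sum-exp, not a new force-field call.

## End states: the embedded-QM contract

End-states are whole molecules superimposed in space (dual topology). In
the embedded-QM ("qmmm") coupling each end-state energy is assembled as

$$V_i = V_i^{\text{QM,EE}} - V_i^{\text{QM,vac}} + V_i^{\text{MM,vdW}},$$

the energy of the molecule embedded in the environment's point charges,
minus its vacuum energy, plus the classical Lennard-Jones coupling to the
environment. Subtracting the vacuum term removes the intramolecular
contribution from the perturbed part: intramolecular terms are never
perturbed (their forces are applied unweighted), so end-state molecules
whose weight is momentarily tiny do not fall apart. It also makes the
relative free energy of any two end-states in vacuum identically zero, so
relative *hydration* free energies come from the solvated leg alone
(`hydration_cycle(water_result)`); the classical two-simulation cycle
(`hydration_cycle(water, vacuum)`) is retained for the all-classical
coupling and is cross-checked against the single-simulation mode in the
acceptance suite.

The "QM" side is a pluggable backend contract: a function taking the QM
zone's coordinates, its parameters and an optional set of embedded point
charges, returning an energy and exact gradients for both the QM atoms and
the point charges. Two mock backends ship with the package:

* **classical-mirror** — intramolecular toy terms (harmonic/Morse bonds,
  harmonic angles) plus plain $1/r$ Coulomb between fixed atomic charges
  and the embedding charges. Because this is exactly a classical
  interaction, the embedded-QM machinery can be verified against direct
  classical evaluation to $10^{-9}$ kJ/mol ("mirror equivalence").
* **field-scaled** — as above, but each atomic charge is scaled by
  $1 + \alpha\,\kappa\,\phi_n$ with $\phi_n$ the local electrostatic
  potential from the embedding charges: a crude, fully differentiable
  polarization stand-in. Defaults $\alpha = 0.05\ e^2\,\mathrm{mol\,kJ^{-1}}$,
  $\kappa = 1$; $\alpha = 0$ recovers classical-mirror exactly.

An `external-adapter` backend documents the subprocess contract
(XYZ-with-charges in, energy/gradient table out) for attaching a real
semiempirical engine; no test depends on it.

Two deliberate bookkeeping choices, both pinned by the gradient-consistency
tests: (1) the embedding point-charge list is the union of environment
particles within $R_{\mathrm{QM\text{-}MM}}$ of *any* QM atom, and the mock
backends apply plain Coulomb to that whole list without a per-pair cutoff —
the mismatch with the classical LJ pair list is intentional and testable;
(2) embedding forces are applied back onto the point charges (Newton's
third law), and the vacuum intramolecular force of molecule $i$ is applied
unweighted, so the net intramolecular force is
$(1 - w_i)\cdot\text{vacuum} + w_i\cdot\text{embedded}$. The assembled
field is the exact negative gradient of
$V^{\mathrm{MM,env}} + \sum_i V_i^{\mathrm{QM,vac}} + V_R$ plus restraints,
verified by central differences.

In periodic boxes the embedding positions are re-imaged relative to the QM
zone's centroid before they are handed to a backend, so a backend working
on absolute coordinates sees the same geometry as the minimum-image
classical routines. This requires the box to comfortably exceed twice the
embedding cutoff plus the molecular radius — the droplet generator's
default box (3.0 nm at a 1.2 nm cutoff) satisfies it.

## Classical energetics and propagation

Units are nm, ps, u, e, kJ/mol and K with
$k_B = 0.008314462618\ \mathrm{kJ\,mol^{-1}\,K^{-1}}$. Nonbonded terms use
a single spherical cutoff (default 1.2 nm), geometric-mean Lennard-Jones
combination and Barker–Watts reaction-field electrostatics
($\epsilon_{RF} = 78.5$ in solution, 1 in vacuum); the reaction-field form
is shifted to exactly zero at the cutoff. 1-2 and 1-3 neighbours implied by
bonds are excluded from nonbonded sums. Alignment between superimposed
molecules uses harmonic distance restraints
($k = 5000\ \mathrm{kJ\,mol^{-1}\,nm^{-2}}$ on two atoms per molecule),
applied outside the EDS mixture.

Sampling uses a BAOAB-split Langevin ("stochastic dynamics") integrator,
default friction $\gamma = 20\ \mathrm{ps^{-1}}$ and
$dt = 0.5\ \mathrm{fs}$ (the step used for the embedded-QM systems; pure-MM
toys tolerate 2 fs); with $\gamma = 0$ it reduces to velocity-Verlet. A
Berendsen-thermostatted velocity-Verlet mode is available
($\lambda = \sqrt{1 + (dt/\tau_T)(T_{\mathrm{ref}}/T - 1)}$). There is no
barostat and no constraint solver: the toy solvent's stiff bonds
($4\times10^5\ \mathrm{kJ\,mol^{-1}\,nm^{-2}}$) are integrated flexibly at
the small step instead. Trajectories are bit-reproducible for a fixed seed.

## The three-phase pipeline

1. **Exploration.** One short EDS run per end-state at $s = 1$ with offsets
   biased $+500$ kJ/mol for the target state and $-500$ for the rest; the
   final frame (verified to carry weight $> 0.99$ for its state) becomes
   that state's representative configuration. The 21-point, log-spaced
   $s$-grid from 1 to $10^{-5}$ is then scanned with offsets zero and
   round-robin ("starting-state mixing") start frames; the lower bound
   $s_{\min}$ is the largest grid $s$ at which every state is the
   minimum-energy state in at least $\theta = 0.05$ of frames. If no grid
   point qualifies the scan falls back to the smallest grid value with a
   warning — on fixtures whose states differ mostly by constant offsets the
   occurrence criterion is conservative, and the fallback simply gives the
   ladder its widest range.
2. **Optimization.** Initial offsets are Zwanzig estimates
   $E_i^R \leftarrow \Delta G_{iR}$ from the lowest-$s$ replica,
   mean-centred (the "no effective samples" check is done in log space,
   since $V_R$ carries a configuration-independent $-\ln N/(\beta s)$ term
   that underflows naively at small $s$). Then, for up to ten iterations:
   run a short RE-EDS simulation, re-estimate offsets, and re-place the
   interior $s$-values by flux balancing — interior points are moved so the
   fraction of downward-moving replica labels changes evenly across the
   ladder, with the worst neighbour pair bisected whenever its acceptance
   drops below 0.05. This is a round-trip-motivated heuristic standing in
   for the published ladder-optimization algorithms, which are specified
   elsewhere and are not reimplemented here. The loop stops early once
   every state's occurrence at $s = 1$ reaches $\theta_{\mathrm{phys}} = 0.1$
   and every replica completed a round trip; otherwise the best parameters
   so far are returned with diagnostics.
3. **Production.** Ten independent repeats (velocities re-drawn per repeat
   seed) of the optimized ladder; the $s = 1$ stream of each repeat is
   estimated separately and the report is the mean with the standard
   deviation over repeats.

Per-pair uncertainties within one stream come from a seeded block bootstrap
(20 contiguous blocks, 200 resamples). On fixtures with slow well exchange
the within-run bootstrap understates the true error — visible as
over-repeat scatter exceeding the per-run bars — which is precisely why
the protocol's headline uncertainty is the SD over independent repeats,
and why the acceptance tests compare means over repeats at three standard
errors.

## Synthetic test systems and what they do (not) show

**Harmonic sets** (`make_harmonic_set()`): one particle per end-state, each
feeling only its own external well
$\tfrac12 k\,|x - x_0|^2 + c_4 |x - x_0|^4 + V_0$ through the
`harmonic-well` backend. For $c_4 = 0$ the free-energy difference has the
closed form $\Delta V_0 + \frac{d}{2\beta}\ln(k_B/k_A)$; with $c_4 \ne 0$
an adaptive-quadrature oracle replaces it. Because a spectator particle
whose state carries no weight would diffuse unboundedly (the dual-topology
reference ensemble is improper in open space), a weak state-independent
position restraint ($k_{\mathrm{conf}} = 1\ \mathrm{kJ\,mol^{-1}\,nm^{-2}}$,
centred on each particle's own minimum) is applied outside the EDS
mixture; the attached oracle accounts for it *exactly* by using
$k + k_{\mathrm{conf}}$ in the log term, a correction of order
$10^{-3}$ kJ/mol at the default stiffnesses. The standard set used in the
acceptance suite has $k = \{1000, 2000, 4000\}\ \mathrm{kJ\,mol^{-1}\,nm^{-2}}$
and offset gaps $\{0, 5, 10\}$ kJ/mol.

**Droplets** (`make_droplet()`): a cubic box (default 3.0 nm) of two-site
dipolar solvent molecules ($\pm 0.42\ e$, 0.1 nm stiff bond) on a jittered
lattice, relaxed by steepest descent, with 2–8 two-atom solute templates
(varying charges and LJ parameters) superimposed at the centre under
alignment restraints. The default 40 solvent molecules are far below
liquid-water density; the droplet emulates the *shape* of a hydration
setup — polar environment, embedding lists, periodic minimum image,
restrained dual topology — not the thermodynamics of water. Consequently,
passing tests demonstrate the correctness of the machinery (gradients,
identities, cycle consistency, null results), not hydration-free-energy
accuracy for real solutes; that would require real water models,
nanosecond sampling and a genuine quantum-chemistry backend, all outside
this package's scope.

Every generator is deterministic under its seed and attaches a manifest of
all parameters. Problem sizes throughout (0.5–10 k steps per stage, tens
of particles) were chosen once so the full verification suite runs on a
single CPU in minutes while leaving the stochastic acceptance checks with
clear 3-standard-error margins.

## Numerical choices and degenerate inputs

* Log-sum-exp with max-subtraction everywhere ($V_R$, weights, Zwanzig
  averages); verified against an independent `log1p` formulation up to
  $\beta s |V_i - E_i| = 10^6$. Weights below $10^{-300}$ after
  normalization are flushed to zero.
* Occurrence classification breaks exact ties toward the lowest state
  index (`which.min`); documented because a two-identical-state stream
  reports occurrence $(1, 0)$, not $(\tfrac12, \tfrac12)$.
* $s \le 0$ is rejected at construction; the pipeline's grid floor never
  goes below $10^{-5}$ (and configuration validation refuses anything
  below $10^{-7}$).
* Overlapping particles (closer than $10^{-6}$ nm) raise an error rather
  than returning infinities; a blown-up integration names the offending
  step and, in production, marks only that repeat failed.
* Kendall's $\tau$ is the tie-corrected $\tau_b$ (via `stats::cor`);
  $R^2$ is reported as the squared Pearson coefficient. The experimental
  anchoring shifts computed relatives so their mean matches the
  experimental mean exactly — by construction this centres the errors, so
  the reported MAE is a centred MAE.
* The restraint force constant is taken as
  $5000\ \mathrm{kJ\,mol^{-1}\,nm^{-2}}$ (the customary unit for a
  harmonic distance restraint).

## Known limitations

No Ewald/PME electrostatics, no constraint solver, no barostat, no
link-atom or covalent QM/MM boundaries (end-states are whole molecules by
design), no self-consistent polarization in the mock backends, and no
attempt at wall-clock parity with production MD engines. The flux-balancing
ladder update is a stand-in with the same objective (round trips) as the
published optimizers, not a reimplementation of them.
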