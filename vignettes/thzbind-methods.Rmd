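---
title: "Methods: oscillating-field dynamics, THz spectra, and binding energetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: oscillating-field dynamics, THz spectra, and binding energetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(thzbind)
```

# Scope and model

`thzbind` studies, at desk scale, how a terahertz-band oscillating electric
field modulates receptor–ligand binding. The field is treated classically,

$$E(t) = A\,u\,\cos(2\pi\nu t + \phi),$$

with amplitude $A$ in V/nm, unit polarization $u$ (default $z$), frequency
$\nu$ in THz and phase $\phi$; it couples to the dynamics purely through the
force $F_i(t) = q_i E(t)$ on each partial charge (1 e·V = 96.4853 kJ/mol, so
$A$ in V/nm converts directly to kJ/mol/nm per unit charge). There is no
polarizability and no field energy in the conserved quantity; a bookkeeping
term $-\sum_i q_i E(t)\cdot x_i$ is reported so that forces remain the exact
negative gradient of the reported potential.

Everything runs in the MD-standard unit system (nm, ps, u, e, kJ/mol, K),
in which $1\,\mathrm{u\,nm^2/ps^2} = 1$ kJ/mol exactly and THz = 1/ps, so
frequencies, spring constants and temperatures need no hidden conversion
factors (Coulomb constant 138.935458 kJ mol⁻¹ nm e⁻²,
$k_B = 0.0083144621$ kJ/mol/K).

## Dynamics

The engine integrates harmonic bonds and angles, a quartic double-well pair
term (used by the synthetic generator's switchable contacts),
Lennard–Jones (Lorentz–Berthelot) and truncated Coulomb interactions under
periodic minimum-image boundaries, with velocity-Verlet time stepping. The
optional Langevin thermostat uses the BAOAB splitting, which reduces exactly
to velocity Verlet at zero friction; thermostat noise comes from one
xoshiro256++ generator seeded per run and consumed in fixed atom order, so
identical seeds give bitwise-identical trajectories. 1–2 and 1–3 bonded
neighbours are excluded from the nonbonded terms.

Numerical choices worth knowing:

* **Timestep.** Defaults are 1 fs generally and 0.25 fs for the host–guest
  study (its engineered 34.5 THz mode has a 29 fs period). Spectrum fixtures
  integrate at 0.2 fs and *sample* at 1 fs: at 1 fs integration the discrete
  velocity-Verlet frequency of an 80 THz mode is biased by ~0.9 THz, far
  more than the 0.1 THz recovery tolerance; at 0.2 fs the bias is below
  0.04 THz for all probe frequencies.
* **Electrostatics.** Real-space truncation with minimum image only. The
  systems here are small, dilute toys; an Ewald mode would change nothing
  the package measures and is deliberately not offered (`electrostatics =
  "ewald"` errors). Truncated Coulomb has a step discontinuity at the
  cutoff; the host–guest analyses therefore use a 2.0 nm cutoff, beyond the
  largest charged pair distance in that system, so no pair ever crosses it.
* **Ensemble.** Production arms default to Langevin NVT (friction
  0.5 ps⁻¹ for the host–guest study); a microcanonical mode
  (`thermostat = "none"`) exists because the ensemble during irradiation is
  a genuinely open modelling question — the configuration records which was
  used.
* **Degenerate inputs.** Zero-rest-length bonds are handled as regular
  isotropic springs; overlapping atoms in any pair term raise a
  singularity error; non-finite coordinates abort with the step number.

## Absorption spectra

Group-resolved absorption follows the classical linear-response recipe: the
charge current $J(t) = \sum_{i\in g} q_i v_i(t)$, its autocorrelation
$C(\tau)$ (biased $1/N$ estimator via the Wiener–Khinchin FFT route, equal
to the direct lag sum to $10^{-10}$), and a one-sided cosine transform on
the grid $f_k = k/(N\Delta t)$ up to the Nyquist frequency. Defaults:
subtract the mean current, Hann window on the ACF, lags to $N/2$, amplitude
normalized to the band maximum. Peak positions — the quantity every test
asserts — are insensitive to these choices (windowed and unwindowed spectra
agree within a bin for well-separated peaks); amplitudes are reported in
arbitrary units. `find_peak` refines the argmax with three-point parabolic
interpolation and flags a spectrum as having no distinct peak when the band
maximum is below twice the band median — with the default $N/2$ lag cap the
noise floor of a white-noise spectrum is rough, so flat-spectrum checks use
a shorter lag cap, which is what the cap argument is for.

## Hydrogen bonds and contacts

Geometric criteria, standard MD-community conventions, all configurable:
donor–acceptor distance ≤ 0.35 nm and donor–hydrogen–acceptor angle ≥ 150°
for hydrogen bonds; apolar carbon pairs within 0.40 nm at residue-pair level
for hydrophobic contacts; "stable" means occupancy ≥ 0.5 over the analysis
window (the final 20% of each arm by default). Occupancy tables are exact
frame counts (verified against naive loops), deterministic, and pairs never
observed are absent rather than zero rows.

## Binding free energy

Single-trajectory MM-PBSA:
$$G_\mathrm{binding} = E_\mathrm{vdw} + E_\mathrm{elec} + G_\mathrm{polar} +
G_\mathrm{nonpolar},$$
per frame, with complex/receptor/ligand coordinates from the same frame and
no entropy term. The molecular-mechanics terms are full pairwise sums with
no cutoff. $G_\mathrm{polar}$ comes from a finite-difference linearized
Poisson–Boltzmann solver written for this package: edge-centred dielectric
with a signed-distance harmonic-mean smoothing window one grid cell wide
(which makes the Born-ion energy converge monotonically under grid
refinement — an abrupt midpoint assignment oscillates), trilinear charge
spreading, analytic screened-Coulomb Dirichlet boundaries, SOR iteration,
and a homogeneous reference solve on the same grid so the discrete
self-energy cancels exactly. Defaults $\varepsilon_\mathrm{solute} = 2$,
$\varepsilon_\mathrm{solvent} = 80$, zero ionic strength (optional
Debye–Hückel $\kappa$), 0.05 nm grid, 0.8 nm margin. $G_\mathrm{nonpolar} =
\gamma\,\mathrm{SASA} + b$ with Shrake–Rupley golden-spiral sphere points
(960/atom) and $\gamma = 2.27$ kJ/mol/nm² (the common 0.0227 kJ/mol/Å²),
$b = 0$.

Averages carry seeded bootstrap standard errors (1000 frame resamples).
Per-residue decomposition attributes each receptor–ligand pair term to the
receptor atom's residue and each solvation term per atom through the PB
per-atom reaction field and per-atom SASA, so contributions partition the
total exactly; the closure residual is asserted below $10^{-6}$ kJ/mol on
every run. Field-on minus field-off differences propagate bootstrap SEs in
quadrature and refuse to compare runs with different settings.

# The synthetic tier

The generators produce systems whose ground truth is known by construction
and recorded in a JSON manifest, so every pipeline stage has something
assertable. None of them emulate a real receptor's geometry or force field;
they emulate the *statistical structure* the analyses assume.

**Harmonic probe** — a charged dimer along $z$ with stretch eigenfrequency
exactly $f_0$ ($k = \mu(2\pi f_0)^2$), started with a small stretch so an
NVE run oscillates deterministically. Used for spectrum validation: the
spectral peak must land within 0.1 THz of $f_0$ for
$f_0 \in \{10, 34.5, 80\}$ THz.

**Charged well** — a charged particle in an isotropic harmonic well
(zero-rest-length spring to a quasi-immobile anchor). This is the
driven-absorption reference at finite temperature: a free dimer tumbles,
and thermal reorientation detunes a polarized drive, whereas every
direction of the isotropic well resonates at $f_0$. Driven at resonance it
reaches the analytic steady-state amplitude $F/(m\gamma\omega)$; driven at
twice the frequency it stays thermal. (The $2f_0$ comparison is meaningful
for this *linear* well; anharmonic wells are parametrically excited at
$2f_0$, which is why the host–guest off-resonance control uses 50 THz.)

**Host–guest pocket** — a rigid receptor scaffold (atoms of mass $10^{12}$
u: genuine position restraints; lighter "heavy" atoms still random-walk
tens of picometres over 40 ps under Langevin, which ruins engineered
geometry) enclosing a semi-rigid polar ligand. Exactly `n_donors` persistent
hydrogen bonds (restraint-held at 0.29 nm, donors collinear with their
fixed acceptors and first-order orientation-anchored so the ligand cannot
rigid-rotate) and `n_hydrophobic` apolar contacts at 0.37 nm are pre-formed.
Lennard–Jones depths, and all charges except the driven acceptor's, are
rescaled so the direct-space interaction energy at $t_0$ equals
`well_depth` (within 5%). Residue labels mirror a glutamate-receptor
pocket: TYR32, GLN78, GLU111, TYR186, THR187, ligand LIG.

**The switchable contact.** The field-responsive element is one bistable
acceptor (GLN78; charge −4 e, mass 2 u, PB radius 0.45 nm) riding a quartic
double-well bond on the field axis. Two nested numerical calibrations run
on the fully assembled system after charge scaling: the quartic stiffness
is bisected until the metastable-well curvature gives a 34.5 THz
small-oscillation frequency, and the barrier position is bisected until the
measured barrier is 30 kJ/mol (≈12 kT at 300 K: the field-off state
survives ≥60 ps runs with occupancy 0 across seeds). Under the resonant
field at 0.5 V/nm the driven mode energy boosts the thermally-assisted
crossing rate enough that the acceptor drops into its deep state within a
40 ps arm, and there it simultaneously satisfies the criteria of *two*
designated donors — one on the ligand, one a rigid receptor donor (THR187)
aimed at the calibrated deep position. Both "added" contacts therefore
appear as a single cooperative event: the network difference reports
exactly those two, across independent seeds, and neither a field-off arm
nor a 50 THz drive produces them.

Two design lessons are worth recording because they shape what the toy can
and cannot show. First, coherent pumping at a fixed frequency cannot push a
mode over a barrier many $kT$ high on its own: the double-well softens as
the amplitude grows, the mode detunes, and the coherent amplitude saturates
near $2$–$3\sigma_\mathrm{thermal}$ — the switch is a *thermally assisted*,
resonance-*boosted* crossing, not a deterministic field-driven trajectory.
Second, the acceptor's charge and radius are a coupled choice: the charge
sets the field coupling at the 0.5 V/nm study amplitude, and the large
soft-ion PB radius keeps the desolvation penalty of burying that charge
from masking the electrostatic binding gain. With them, the field-on minus
field-off binding energy is negative (binding strengthened) and dominated
by the electrostatic component, which is the qualitative decomposition the
method is meant to surface.

**Ion box** — monovalent point ions at the pair count
$\mathrm{round}(c N_A V)$ (46 pairs at 0.15 M in the 8 nm box), anion count
adjusted for neutrality, placed uniformly with a 0.25 nm clearance. The
toy systems are implicit-solvent throughout; there is no explicit water
(solvation lives entirely in the PB/SASA terms), so passing tests say
nothing about explicit-solvent kinetics, dielectric relaxation, or real
protein energetics.

# Study conditions and problem sizes

The pipeline (`run_pipeline`) equilibrates 4 ps, runs field-off and
field-on production arms of 40 ps with common random numbers (same seed)
sampled every 2.5 fs, computes the pocket spectrum from the field-off arm
(resolution 0.025 THz), occupancy tables over the final 20% of each arm
(subsampled to ≤600 frames), and the binding difference from frames at
1 ps intervals (41 frames/arm) with the 0.05 nm PB grid. The intensity
sweep uses 20 ps arms — short enough that the time-to-switch differences
between amplitudes remain visible in the window average — and a 0.06 nm
grid. Field defaults are the study conditions: $\nu = 34.5$ THz,
$A = 0.5$ V/nm, $u = (0,0,1)$, $\phi = 0$; the sweep covers 0–2.0 V/nm.
All of these sizes are deliberate scale-downs chosen so a complete analysis
runs on one CPU in minutes; consequences of the scale-down (stochastic
switch timing, bootstrap SEs of a few kJ/mol on 41 frames) are visible in
the reported uncertainties.

# Known limitations

* The engine has no constraints, barostat, PME, or explicit solvent; it is
  a toy-system engine, not a general-purpose MD code.
* Classical spectra carry no quantum corrections; amplitudes are arbitrary
  units and only peak positions are interpreted.
* The PB solver is linearized, zero-ionic-strength by default, with a
  dielectric boundary from atom spheres; it is validated against the Born
  ion (≤5% at 0.025 nm spacing, monotone convergence), not against
  biomolecular reference solvers.
* The switchable contact is engineered: its thermodynamics (barrier, well
  depths, charges) are calibrated constructs, so the field-response
  *magnitudes* are properties of the toy, not predictions for any real
  receptor. What the package demonstrates is the method chain — resonant,
  frequency-selective absorption producing a detectable, reproducible
  change in the contact network and a binding-energy shift with the
  expected electrostatic signature.
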