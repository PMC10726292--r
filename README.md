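# thzbind

Molecular dynamics simulations have been used to argue that narrow-band
terahertz irradiation near 34.5 THz is selectively absorbed by the
glutamate-binding pocket of the NMDA receptor's NR2B subunit, strengthening
glutamate binding: new hydrogen bonds appear at the pocket and the binding
free energy drops by tens of kJ/mol, mostly through its electrostatic
component. `thzbind` re-implements that computational chain as a tested,
desk-scale R package for people who want to study resonance-driven binding
modulation mechanistically — on synthetic receptor–ligand toys with known
ground truth rather than on a 100 ns explicit-solvent protein simulation.

The package provides, end to end:

* an MD engine (velocity Verlet, Langevin/BAOAB thermostat, periodic
  minimum-image boundaries) with a classical oscillating-field coupling
  `E(t) = A u cos(2πνt + φ)` acting on atomic partial charges,
  `F_i = q_i E(t)`;
* group-resolved absorption spectra from the Fourier transform of the
  charge-current autocorrelation, `J(t) = Σ_i q_i v_i(t)`;
* geometric hydrogen-bond and hydrophobic-contact analysis with occupancy
  statistics and field-on/field-off network differencing;
* an MM-PBSA-style binding free energy,
  `G_binding = E_vdw + E_elec + G_polar + G_nonpolar`, with a
  finite-difference Poisson–Boltzmann solver, Shrake–Rupley surface areas,
  per-residue decomposition and bootstrap uncertainties;
* synthetic generators (harmonic probes, a driven charged well, a
  host–guest pocket with engineered persistent and field-switchable
  contacts, an ion box) whose ground truth is written to JSON manifests;
* a pipeline that runs the whole comparison — equilibrate, field-off and
  field-on arms with common random numbers, spectra, network diff, ΔG —
  under one seeded configuration, plus an intensity sweep.

The methods vignette (`vignettes/thzbind-methods.Rmd`) documents the model,
the numerical choices and the design of the synthetic systems.

## Worked example

The central experiment — the host–guest pocket with and without a resonant
34.5 THz, 0.5 V/nm field:

```r
library(thzbind)

cfg <- run_config(out_dir = "results/field_effect", seed = 1)
rep <- run_pipeline(cfg)
print(rep)
```

```
<run_report> config 77dfe339
  generate     ok
  equilibrate  ok
  simulate     ok
  spectrum     ok
  contacts     ok
  binding      ok
  peak: 34.451 THz (pocket)
  stable H-bonds off/on: 4/6; added: hbond:LIG1.36>GLN78.40, hbond:THR187.38>GLN78.40
  delta G_binding: -34.06 kJ/mol
```

Reading this: the field-free pocket spectrum has its fingerprint peak at
34.45 THz (the engineered pocket mode; the drive is resonant with it). The
field-off arm shows exactly the four persistent hydrogen bonds the
generator built (to TYR32, GLN78, GLU111, TYR186); under the field the
bistable pocket acceptor locks in and exactly the two designated contacts
appear — one from a ligand donor, one from the THR187 receptor donor, both
to the GLN78 acceptor. Binding strengthens by 34.1 ± 1.9 kJ/mol over the
post-transition half of the arms, and the decomposition attributes the
change to the electrostatic component (ΔE_elec ≈ −37.5 kJ/mol; polar
solvation, van der Waals and surface terms are each within a few kJ/mol).
A 50 THz drive of the same strength, or a zero-field arm, produces no
added contacts.

The intensity sweep applies a 20 ps resonant pulse per amplitude followed
by a 20 ps field-free relaxation, and measures the persistent binding
change against a shared field-off baseline (common random numbers):

```r
sw <- intensity_sweep(run_config(out_dir = "results/sweep", seed = 3,
                                 sim = list(prod_ps = 20)), c(0, 0.5, 1, 2))
```

```
  amplitude  dG_total   dE_elec se_total
1       0.0      0.00      0.00     2.50
2       0.5    -33.16    -35.81     2.46
3       1.0    -33.25    -35.84     2.63
4       2.0    -33.21    -35.95     2.89
```

|ΔG| jumps once the field is strong enough to drive the contact switch
within the pulse and then saturates: every amplitude at or above
0.5 V/nm leaves the same locked, more tightly bound state, so the arms
tie within their bootstrap uncertainties.

The numbered scripts under `analysis/` run the same stages as a narrative
workflow (generation, probe-spectrum recovery, driven-absorption frequency
scan, the field-effect comparison, the intensity sweep) and write their
tables under `results/`.

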