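# helifil

Desk-scale computational machinery for **de novo pH-responsive helical
protein filaments**: the geometry, filtering, thermodynamics, and kinetics
that sit behind the design and single-fibre characterization of engineered
fibres that fall apart — sharply and reversibly — when the pH drops.

The package is for protein designers and biophysicists who want to

* generate and analyse **helical assemblies** as screw operations
  (rise `h` in Å, twist `ω` in degrees per subunit): propagate a subunit
  into a filament, refit `(h, ω)` from coordinates alone, count ring
  subunits in cross-section, detect n-start strand structure and
  antiparallel (D1) arrangements, and scan candidate docks on a grid;
* connect oligomeric protomers into single chains by **fragment-based loop
  closure** (joint Kabsch superposition of fragment termini onto the
  junction, 0.35 Å RMSD acceptance);
* score interfaces with the standard **design filters** — buried
  solvent-accessible surface area (Shrake–Rupley), Lawrence–Colman shape
  complementarity `Sc`, buried-unsatisfied-polar counts, and a transparent
  contact pseudo-energy gap — and run the four-criterion filter pipeline
  (`ΔE < −15`, area `> 700 Å²`, `Sc > 0.62`, unsat `< 5`) over design
  record tables;
* model the **cooperative pH switch**: with `n` buried histidines per
  subunit that can only protonate in the disassembled state, the assembled
  fraction is

  ```
  f(pH) = 1 / (1 + 10^(log10K + n (pKa − pH)))
  ```

  with midpoint `pKa + log10K / n` and 10–90% width `log10(81) / n` —
  0.318 pH units for `n = 6`, i.e. a transition over ~0.3 pH units;
* simulate **stochastic fibre disassembly** (exact event-driven per-end
  depolymerization plus fragmentation under a pH schedule) and analyse the
  traces the way single-fibre TIRFM/AFM time-lapses are analysed: linear
  rate fits on the longest remaining fragment, per-end recession with the
  fibre centre as the second end, and cross-sectional ensemble summaries.

Everything runs on a synthetic, fully deterministic test surface: idealized
poly-alanine helical-bundle subunits, a preset filament symmetry
(`DpHF19`: rise 8.4 Å, twist −148.9°), fragment mini-databases, design
record tables, and seeded fibre traces. No structure downloads required.

## Worked example

```r
library(helifil)

# an idealized 3-helix-bundle subunit, and a 40-subunit fibre
subunit  <- make_bundle_subunit(n_helices = 3, residues_per_helix = 20,
                                bundle_radius = 7, seed = 1)
filament <- propagate(subunit, get_preset("DpHF19"), n = 40)

# refit the symmetry from the coordinates alone
fit_helical_params(filament$structure)
#> helical_params: rise 8.4000 A, twist -148.9000 deg (left-handed)
ring_count(fit_helical_params(filament$structure))
#> [1] 5        # five subunits per cross-section ring (24.5 deg residual)

# the cooperative pH switch for six buried histidines
m <- protonation_model(n_sites = 6, pKa = 6.5, log10_K = -21)
m
#> protonation_model: 6 sites/subunit, pKa 6.50, log10_K -21.00
#>   -> midpoint 3.00, width 0.318

# a disassembling fibre at full pH activation, and its fitted rate
p  <- kinetic_params(k_end = 64.3)           # subunits/min per end
tr <- simulate_fibre(L0 = 2000, p, ph_constant(3), t_end = 5,
                     dt_record = 0.5, seed = 1)
estimate_rate(tr)$rate
#> [1] 102.4    # nm/min for this seed; the 200-seed ensemble mean is
#>              # 108.4 (s.e. 0.34), i.e. 2 x 64.3 x 0.84 nm/min
```

The fitted rise (8.4 Å) and twist (−148.9°) are the preset's generating
parameters recovered from bare coordinates; the ring count of 5 is the
cross-section subunit count implied by that twist; the width 0.318 is the
closed-form 10–90% span of the six-site switching curve; and the fitted
disassembly rate is the two-ends-times-rise Poisson expectation of the
simulator.

A command-line front end covers the same operations
(`exec/helifil convert|propagate|fitsym|dock|closeloop|metrics|filter|phcurve|simulate|fixtures`).

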