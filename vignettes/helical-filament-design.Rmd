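---
title: "Models and methods behind helifil"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind helifil}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(helifil)
```

helifil packages the computational side of designing and characterizing
pH-responsive helical protein fibres. This vignette is the package's own
account of the models it implements: what each one assumes, which
parameters matter, and where the synthetic test surface does and does not
resemble real data.

## Coordinate and symmetry conventions

Coordinates are Angstrom throughout, in a right-handed frame; the filament
axis convention is +z. A filament is generated by repeatedly applying one
rigid transform to a subunit, and every proper rigid transform is a screw
operation (Chasles): a rotation (*twist*, degrees) about an axis plus a
translation (*rise*, Å) along it.

Two conventions remove all sign ambiguity:

* the twist follows the right-hand rule about `axis_direction`;
* `axis_direction` is chosen so the rise is non-negative (axis and twist
  flip together when needed), and the twist is wrapped to (−180°, 180°].

Under these rules the stored `DpHF19` symmetry — rise 8.4 Å, twist
−148.9° — is a *left-handed per-step rotation* about the rise-positive
axis. Users comparing against deposited conventions should keep this in
mind: a deposited right-handed one-start description of the same lattice
can differ by a sign and a 360° wrap.

`screw_decompose()` recovers the parameters from a transform
(pure translations become twist 0 with the axis along the translation; the
identity has no axis and errors). `fit_helical_params()` recovers them
from coordinates: the Kabsch least-squares transform is computed for every
consecutive subunit pair, the rotations are averaged and projected back
onto SO(3) by SVD, and the average transform is screw-decomposed.
Averaging over all consecutive pairs rather than using a single pair is a
robustness choice; noise is handled by plain least squares with no outlier
rejection, which is adequate for the coordinate-level noise this package
is used with (tests verify recovery at σ = 0.1 Å to within 0.05 Å rise
and 0.5° twist on a 40-subunit fibre).

`ring_count()` scans n = 2..24 for the smallest cumulative twist within
`angle_tol` of a full number of turns. The 30° default is deliberate: a
twist of −148.9° leaves a residual of 24.5° at n = 5 (which should
qualify — five subunits per cross-section ring) and 62.2° at n = 2 (which
should not). The result is invariant to twist sign and whole-turn shifts.

`strand_step()` reports the smallest index offset at which subunits make
heavy-atom contact (4.5 Å default), computed from a central subunit so
edge effects do not intrude; an offset of k > 1 means k parallel strands.
`detect_antiparallel()` signs each subunit's principal CA axis
(disambiguated N→C) against the filament axis; both signs present means an
antiparallel, D1-style arrangement. Note the package's two-strand and
antiparallel examples are *constructions* — the synthetic subunit placed
so that the property holds by design — because the radial packing of the
real fibres is not part of the symmetry presets.

`sample_docks()` evaluates a deterministic grid (rise × twist × radial
offset × axial spin, `expand.grid` order with rise varying fastest) over
the first five copies, flagging clashes below 2.4 Å and counting contacts
at 4.5 Å — common structural-biology defaults, both configurable. Scoring
beyond clash/contact counting is deliberately left to the interface
metrics, keeping dock enumeration cheap and transparent.

## The synthetic test surface

All inputs the tests need are generated, deterministically, from explicit
seeds; no global RNG state is touched (`with_seed` restores the caller's
state).

* `make_bundle_subunit()` builds poly-alanine helical bundles from ideal
  internal coordinates (NeRF chain construction with φ = −57°, ψ = −47°,
  ω = 180°, standard bond lengths and angles), giving ~1.5 Å rise and
  ~100° rotation per residue and 3.80 Å CA–CA steps. Each helix is
  aligned to +z using its exact per-residue screw axis (covariance-based
  axes are measurably biased for short helices). Helices sit on a circle,
  alternating up/down; CB atoms are present so burial and contact metrics
  are meaningful. The three-helix default mirrors a trimer-derived monomer
  whose three protomers have been joined into one chain; the real
  monomer's helix count after loop connection is not asserted — the
  fixture is a stand-in, not a structural claim.
* `make_fragment_db()` emits 3–8-residue backbone fragments with ideal
  helical torsions at both terminal residues and loop-like torsions in
  between — a miniature analogue of a fragment database spanning two
  helical regions.
* `make_design_records()` draws metric columns from uniform ranges chosen
  to straddle every filter threshold (energy gap U(−30, 0), area
  U(300, 1200) Å², Sc U(0.3, 0.9), unsat 0..10), so the filter pipeline
  partitions tables non-trivially.

What this surface does **not** emulate: real side chains and rotamers,
sequence profiles, solvent, or the packing of any deposited fibre. Tests
passing on it demonstrate the correctness of the geometry, the metrics,
and the pipelines — not the designability of any particular sequence.

## Loop closure

Protomers are joined by fragment lookup: a fragment's first and last
residues (backbone N, CA, C, O — one residue per side by default,
configurable to 2–3) are superposed *jointly* onto the upstream chain's
C-terminal residue and the downstream chain's N-terminal residue, and
candidates within 0.35 Å RMSD are kept, sorted by RMSD with lexical ties.
One residue per side is the minimal reading of "terminal residues"; the
atom set and residue count are exposed as configuration because reasonable
alternatives exist.

Ranking is pure RMSD: a transparent surrogate for score-based ranking,
which would require a force field that is out of scope. For the same
reason, torsion-space relaxation is replaced by rigid placement plus a
hard geometry check: `close_chain()` verifies each loop's endpoints sit
within 0.5 Å of the junction, renumbers residues consecutively, and
requires every junction peptide C–N bond to lie in [1.2, 1.5] Å. Stitched
loops keep poly-alanine identity.

## Interface metrics and the filter pipeline

All metrics are heavy-atom only (design-stage models are typically
hydrogen-free); radii are C 1.7, N 1.55, O 1.52, S 1.8 Å, probe 1.4 Å.

**SASA** is Shrake–Rupley with a deterministic golden-spiral quadrature,
960 points per sphere by default (~1% accuracy against closed-form sphere
and two-sphere cap areas). The quadrature points are generated in a
canonical molecule frame (principal axes sign-fixed by third moments), so
rigidly moving a molecule moves its quadrature with it and the total area
is invariant under rigid motion; genuinely degenerate point clouds fall
back to the lab frame, where invariance holds only to quadrature jitter.

**Interface area** is the both-sides total
`sasa(i) + sasa(j) − sasa(i∪j)`. Whether the conventional 700 Å²
threshold refers to total or per-side burial is ambiguous in common usage;
the total is the default here because the threshold then matches the usual
reporting, and `per_side = TRUE` gives the half value.

**Shape complementarity** follows Lawrence–Colman: exposed van der Waals
dot surfaces (10 dots/Å²), interface patches taken as dots within 2.8 Å
(2 × probe) of the partner's surface, a 1.5 Å peripheral band trimmed from
the patch edge, nearest-partner-dot scoring `exp(−w d²)(n̂_a · −n̂_b)`
with w = 0.5 Å⁻², and the mean of the two directional medians. The
dot-level core (`sc_dots()`) is exported separately so the planar closed
form — parallel planes at gap g score `exp(−w g²)` — can be verified
directly; ideal infinite planes are not representable as atomic
structures.

**Unsatisfied polars** are counted at residue level: an interface residue
counts if it has a polar heavy atom that is buried in the complex
(per-atom SASA < 5 Å²) yet has no other polar heavy atom within 3.5 Å.
Donor hydrogens are waived (heavy-atom proxy). Residues are counted across
both subunits of the pair; per-subunit counting is a configuration away
(pass a single side).

**Energy gap** is a documented contact pseudo-energy: −1 per inter-subunit
heavy-atom pair within 4.5 Å, capped at −3 per residue pair, +10 per
clashing pair below 2.4 Å; the rigid monomer defines zero. Its absolute
scale is a package convention — the −15-unit filter threshold is
configuration, and the filter tests exercise the pipeline on crafted
record tables rather than the surrogate's absolute values.

**Filters** use strict inequalities throughout (gap < −15, area > 700,
Sc > 0.62, unsat < 5), matching the exceeding/surpassing/below phrasing
such criteria are usually stated with; `apply_filters()` reports
per-criterion independent attrition, and `select_top_per_dock()` keeps the
minimal-gap record per docked configuration with lexical tie-breaks.

## The cooperative pH switch

The package's equilibrium model is the minimal thermodynamically
consistent reading of the design mechanism: `n` buried histidines per
subunit cannot protonate while the subunit is assembled. Wyman linkage
over an all-or-none per-subunit two-state equilibrium then gives

$$f(\mathrm{pH}) = \frac{1}{1 + 10^{\log_{10}K + n\,(pK_a - \mathrm{pH})}}$$

with midpoint $pK_a + \log_{10}K / n$ and 10–90% width $\log_{10}(81)/n$,
independent of both $K$ and $pK_a$. This is presented as a *model*, not a
fit: no quantitative switching model accompanies the measured transitions,
and `log10_K` (the per-subunit disassembly constant at the deprotonated
limit) is a free calibration parameter. With the histidine solution pKa at
its default 6.5 (monomeric precursors of these designs titrate between
about 4 and 6.5) and `log10_K = −21`, six sites put the midpoint at pH
3.0 — consistent with the observed ordering of disassembly pH across the
six- and nine-histidine designs, which is the only claim made. The width,
by contrast, is parameter-free: 1.91 pH units for one site, 0.318 for six
(the ~0.3 pH-unit sharpness), 0.212 for nine, strictly decreasing in `n`.
Consistency between width and slope is exact: width × (df/dpH at midpoint)
= ln(81)/4.

Fibre-level cooperativity beyond per-subunit linkage
(nucleation–elongation across hundreds of subunits) is not modelled: no
equations for it are available, and adding an undocumented sharpening
exponent by default would misrepresent the model. The kinetic coupling
law below is the hook where such effects would enter.

## Disassembly kinetics

No kinetic law accompanies the observed fibre disassembly, so the
simulator makes one documented choice: disassembly rates are multiplied by
the equilibrium model's *disassembled-state weight*,
$10^x/(1+10^x)$ with $x = n\,(pK_{a,\mathrm{eff}} - \mathrm{pH})$,
saturating at 1 far below the transition and ~0 above it (a bare
exponential law is available as configuration). With n = 6 and an
effective midpoint of 3.25 this reproduces the observed regime split —
rapid shortening at pH 3.1, stability at pH 3.4 — as a rate ratio of ~50.

The simulation itself is exact event-driven Gillespie: per-end removal as
a Poisson process (`k_end` per active end, optionally asymmetric left and
right — the one-end-immobilized toggle for surface-pinned fibres),
fragmentation per junction (`k_frag`), piecewise-constant pH segments
simulated exactly with memoryless resampling at boundaries, and
exponential pH approaches discretized onto a fine piecewise-constant grid
(0.05 min default). After fragmentation, every fragment end is active and
inherits the left/right rate of its side; the recording grid is separate
from the event process, and identical seeds give bit-identical traces.
Sub-second disassembly at strong activation is treated as a regime
statement (coupling ≈ 1), not a fitted rate.

Trace analysis mirrors single-fibre practice:

* `estimate_rate()` fits an OLS slope to the *longest remaining fragment*
  versus time (the single-fibre length convention) and reports the
  sign-flipped rate with its residual standard error;
* `per_end_recession()` reports each original end's recession rate, with
  the fibre centre (half the initial length) as the far limit of each
  end — recessions are capped at L0/2, matching the convention that
  assigns the centre as the second end;
* `ensemble_summary()` gives cross-sectional mean ± s.d. of the longest
  fragment, excluding fully disassembled fibres by default (matching
  declining object counts in ensemble imaging), with zero-counting as an
  option.

Parameter recovery is verified at the two observed rate regimes: with
`k_end = 64.3` subunits/min/end the expected total loss is
2 × 64.3 × 0.84 ≈ 108 nm/min, and 200-seed ensembles recover both the
108 and the 21 nm/min regimes within three standard errors. The default
length conversion, 0.84 nm per subunit, is the filament rise.

## Problem sizes and numerical choices

The test suite runs at deliberately desk-scale sizes: 40-subunit
filaments for symmetry fits, 100-fragment databases for loop search,
single-helix pairs for the interface metrics (hundreds of atoms per SASA
call at 960 quadrature points), 1000-row record tables for the filter
pipeline, and 200-seed ensembles of a few hundred events each for the
kinetics. These sizes keep every oracle comparison exact or
tight (brute-force scans, closed forms, quaternion-method superposition)
while the full suite completes in well under a minute.

Degenerate inputs are handled explicitly: identity transforms have no
screw axis (error), collinear point sets have no unique superposition
(error), near-spherical subunits have no principal axis (error),
non-contacting pairs have zero interface area (not an error), empty buried
patches make Sc undefined (error), and empty candidate lists are a valid
search result. Ties are deterministic everywhere: lexical ids for loop
candidates and top-per-dock selection, first occurrence for altloc
resolution at equal occupancy.

## Known limitations

* The energy surrogate is a contact count; it orders docks sensibly but
  its scale is not transferable to force-field energies.
* The Sc patch definition (distance-to-surface cutoff plus edge-band trim
  on discrete dots) approximates the buried-patch construction of the
  original statistic; agreement is verified against closed forms on
  planes, not against reference implementations on real complexes.
* The pH model is per-subunit and all-or-none; it cannot produce
  hysteresis or fibre-length-dependent transitions.
* The simulator has no elongation mode: whether real fibres regrow
  symmetrically from both tips is not quantified in the data this package
  mirrors, so growth is deliberately omitted rather than guessed.
* Photoacid scenarios are pH schedules only; photochemical kinetics are
  out of scope.
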