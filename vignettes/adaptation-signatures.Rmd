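---
title: "Profiling halophilic and psychrophilic adaptation signatures"
author: "adaptsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling halophilic and psychrophilic adaptation signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific question

Enzymes from organisms living in cold hypersaline environments face two
conflicting demands. High salt dehydrates proteins and strengthens the
hydrophobic effect, which halophilic proteins counter with an acidic,
weakly hydrophobic surface: an excess of aspartate and glutamate over
lysine and arginine, concentrated on the solvent-exposed shell, keeps the
protein hydrated and soluble. Cold, on the other hand, slows conformational
dynamics, and psychrophilic proteins compensate with flexibility: more
small residues, fewer secondary-structure-stabilising hydrogen bonds, and
long disordered surface loops. A polyextremophilic enzyme must blend both
signatures in one fold.

`adaptsig` measures these signatures at three levels:

1. **Sequence** — residue-class composition, grand average of hydropathy
   (GRAVY), isoelectric point (pI), molar extinction coefficient, and the
   acidic excess (percentage points of D+E over R+K+H).
2. **Structure** — solvent-accessible surface area (SASA), classification
   of residues as surface or buried at a relative-accessibility threshold,
   the residue-class composition of the surface, hydrogen bonds and salt
   bridges (intra- and inter-chain), secondary-structure fractions, and the
   surface area buried in an oligomer interface.
3. **Dynamics** — from multi-temperature trajectories: windowed backbone
   RMSD, the regression slope of window-mean RMSD on temperature (the
   thermal-sensitivity descriptor), per-residue RMSF, and the change in
   RMSF between temperatures with a significance threshold.

A grouped comparison driver (`run_comparison()`) evaluates the full panel
for members of labelled groups (e.g. halophilic / psychrophilic /
mesophilic / thermophilic homologs), averages within groups (unweighted
means, the convention of published comparison tables), and renders
TSV/JSON reports.

## Models and procedures

### Sequence indices

GRAVY is the arithmetic mean of Kyte–Doolittle hydropathy values; the
scale ships as data (`kyte_doolittle_scale()`) and can be replaced. The pI
models each ionisable group (termini plus D, E, C, Y, H, K, R) with a
Henderson–Hasselbalch term under a Bjellqvist-compatible pKa set
(`pka_bjellqvist()`); because modelled net charge is strictly decreasing in
pH, the root is found by bisection on pH 0–14 to |charge| < 1e-4. The
extinction coefficient uses the Pace increments (5500 per Trp, 1490 per
Tyr, optionally 125 per cystine). The default `cystine_mode` is
`"reduced"`; published "calculated" values are often in the all-paired
convention, which `"all_paired"` reproduces. Ambiguous letters (X, B, Z)
are excluded from numerator and denominator alike, with a warning.

Residue classes are configuration (`residue_scheme()`), not hard-coded:
published tables disagree about edge membership (is His aromatic? is Gly
polar?), so each class is an explicit letter set the caller may override.
Defaults: aromatic = {F, W, Y} without His, polar-uncharged = {S, T, N, Q}
without Gly or Cys. These defaults keep class sums consistent with the
partition checks in the test suite; they are a documented choice, not a
claim about any particular published table.

### SASA and surface classification

SASA uses the Shrake–Rupley construction: each heavy atom's van der Waals
sphere is inflated by the probe radius (default 1.4 Å) and sampled with a
deterministic Fibonacci-spiral point set (default 960 points); the
accessible area is the unoccluded fraction times the expanded sphere area.
The spiral is deterministic, so results are reproducible to the last bit
across runs and platforms — at the cost that areas are exactly
rotation-invariant only up to sampling resolution (about 1% at 960
points, which is also the accuracy against the analytic isolated-sphere
area). Radii are a united-atom set (C 1.70, N 1.55, O 1.52, S 1.80 Å),
table-swappable. Water is excluded; ligands and nonstandard residues
occlude but are not reported as protein residues.

Relative accessibility divides a residue's SASA by a theoretical
Gly-X-Gly maximum (`max_asa_theoretical()`, Tien-style values). A residue
is *surface* when relative accessibility exceeds 10% (strictly), the
conventional cut; the threshold is a parameter. Surface composition
percentages use surface residues as the denominator.

### Contacts

Hydrogen bonds use a geometric criterion: donor and acceptor heavy atoms
(N/O from a donor/acceptor dictionary) within 3.5 Å, plus a directionality
test. Backbone amide hydrogens are inferred from the preceding peptide
unit (1 Å from N along the bisector of the N–CA and N–C(prev) directions)
and must give a D–H···A angle of at least 120°; side-chain donors, whose
hydrogens are rotatable, use a 90° antecedent–donor–acceptor test instead.
Covalently adjacent backbone N/O pairs are excluded. Salt bridges pair
Lys/Arg (His optional, default off) side-chain nitrogens with Asp/Glu
carboxylate oxygens at a 3.2 Å N–O cutoff, counted once per residue pair.
All cutoffs are parameters: the tools behind published counts rarely state
their criteria, so counts are comparable only under a stated parameter
set, which every report logs. `contact_counts()` emits both atom-pair and
residue-pair hydrogen-bond counts, and per-chain inter-chain counts (the
number of inter-chain contacts touching each chain), since published
"per chain" numbers do not state their convention. Note that an ion pair
at salt-bridge distance also satisfies the hydrogen-bond criterion, so the
two lists overlap by design.

### Secondary structure

A simplified Kabsch–Sander assignment: the electrostatic hydrogen-bond
energy `27.888 * (1/rON + 1/rCH − 1/rOH − 1/rCN)` kcal/mol with a −0.5
cutoff, i→i+4 turn patterns for helix and the parallel/antiparallel
bridge patterns for strand; everything else is coil. This two-pattern
reduction omits 3-10/π helices and turn states, so helix percentages read
slightly low on kinked helices relative to full eight-state DSSP; the
deviation is deliberate and documented. Chains split into segments at
peptide-bond breaks (C–N > 2.5 Å) and patterns never span a break.

### Trajectory descriptors

Superposition is the Kabsch SVD solution with the reflection guard
(`det = +1`); degenerate (collinear) atom masks are an error. RMSD series
superpose every frame onto a fixed reference — the first frame by default,
or any frame index or external coordinate set (e.g. a generator's
noiseless mean) — over a backbone (N, CA, C) mask. With a
`window_schedule()` mapping frame ranges to temperatures, window means are
taken over only the trailing `analysis_fraction` of each window, treating
the leading remainder as re-equilibration after the temperature step (the
convention of analysing the final stretch of each temperature window).
`temperature_regression()` averages window means across replicas before an
ordinary least-squares fit of mean RMSD on temperature (°C); the slope in
Å/°C is the thermal-sensitivity descriptor, and per-replica slopes are
kept for dispersion. RMSF uses one Cα per residue and a two-pass
superposition (fit to first frame, compute mean, refit to the mean,
refresh the mean). Superposition is per-window; a global-reference variant
is available by passing explicit frame sets. `delta_rmsf()` reports
per-residue RMSF changes between two windows and flags changes at or above
0.5 Å — the customary significance cut for a comparable temperature rise —
optionally restricted to named residue panels (catalytic, substrate
binding).

## The synthetic-data module

No deposited structure or trajectory ships with the package; instead the
generators create inputs with planted ground truth.

`make_structure()` builds ideal backbones (helix −57/−47, extended
−139/135, or a closed ring) from standard bond geometry, then plants
contacts by re-typing residue pairs and attaching minimal side-chain atoms
at exactly the requested heavy-atom distance (Ser OG → Asn OD1 for
hydrogen bonds, Lys NZ → Asp OD1 for salt bridges), lifted off the
inter-anchor line so they clear the backbone. Distances inside the
detector cutoffs plant positives, outside plant negatives; the manifest
records the expected counts. Planted burial encloses a residue in a
two-shell glycine cage dense enough that no probe-sized sphere reaches it.

`make_trajectory()` draws frames `r_i(t) = R(t)(mu_i + eta_i(t)) + d(t)`:
per-residue isotropic Gaussian fluctuations with per-coordinate standard
deviation `sigma_i(T) = a_i + b_i (T − T0)`, contaminated with per-frame
rigid-body rotation and translation that correct superposition must
remove. The manifest carries the closed forms an analysis should recover:
`E[RMSF_i] = sigma_i sqrt(3)`, `E[mean RMSD] = sqrt(3 mean_i sigma_i^2)`
against the noiseless mean, and the OLS slope of the expected window
means on temperature (for uniform `b`, `b sqrt(3)`). Defaults emulate the
four-temperature design of the study this package's analyses follow:
windows at 10/27/47/72 °C, 625 frames each with the trailing 80% analysed
(500 analysis frames), a = 0.1 Å, b = 0.005 Å/°C — a thermal response
whose expected slope (≈0.0087 Å/°C) sits in the range reported for real
enzymes of this family. Seeding is a single integer through R's default
Mersenne-Twister generator; one seed gives byte-identical output.

`synthetic_deposit()` is the package's stand-in for a deposited
polyextremophilic β-galactosidase entry, and it is labelled synthetic
everywhere. It emulates the *reported statistics* of such an entry, not
its coordinates: a 700-residue sequence whose composition reproduces the
reference column (Asp 11.7%, D+E 18.6%, G+A 18.9%, Pro 7.1%, Arg 7.7%,
GRAVY −0.55, pI ≈ 4.4, ε₂₈₀ = 157,845 M⁻¹cm⁻¹ in the all-paired
convention), 668 modelled residues with disordered regions 532–543,
657–672 and 697–700 left coordinate-free, an acidic-rich surface planted
at ≈33.6% acidic / 14.8% basic of surface residues (arginine-over-lysine,
as in halophiles), C3 assembly operators in REMARK 350 form, and trimer
interfaces carrying exactly 18 inter-chain hydrogen bonds and 4
inter-chain salt bridges per chain (14 non-ionic pairs plus 4 ion pairs
per chain; the ion pairs satisfy both detectors). Geometrically it is a
lattice ball of backbone clusters, not a fold: residues are assigned to
sites so that every residue's surface/buried classification is *guaranteed*
by construction (type-aware margins around the 10% threshold, verified and
repaired against the package's own deterministic SASA at generation time).

**What passing tests on synthetic data do and do not show.** They show the
measurement pipeline is correct: planted quantities are recovered exactly
(contacts, burial, parse layout) or within stated statistical tolerance
(slope and RMSF within 5%). They do not show anything about real crystal
structures — the stand-in has no fold, its secondary structure is
meaningless, its interface is smaller and cleaner than a real trimer's,
and its B-factors, altlocs and heteroatoms are trivial. Real-data use
enters through `read_pdb()`/`read_trajectory()` on the user's own files.

## Numerical choices and degenerate inputs

* Altloc resolution keeps the highest occupancy, ties broken by altloc
  letter; `"first"` is available.
* Hydrogens in input are ignored for SASA and contacts; amide hydrogens
  are inferred where an angle test needs them.
* Author residue numbering is preserved everywhere; unmodelled residues
  are absent rows, never renumbered.
* Bisection for pI needs at least one ionisable group; sequences without
  one are an error, as are empty/unknown-element SASA inputs, inconsistent
  trajectory frames (error names the frame), overlapping or
  non-monotone window schedules, and degenerate superposition masks.
* Rounding: all statistics are computed at full precision and rounded only
  in rendered reports (one decimal, published-table style).
* Problem sizes in the shipped tests — a 668-residue monomer / 9,903-atom
  trimer for structural checks and 100 residues × 4 windows × 500 analysis
  frames × 3 replicas for dynamics — were chosen to make sampling error
  comfortably smaller than the stated tolerances while keeping the whole
  suite fast on one CPU.

## Known limitations

* Two-state secondary structure (no 3-10/π, no turn/bend states).
* The SASA point grid is fixed in space, so areas are rotation-invariant
  only to sampling resolution; increase `n_points` where that matters.
* Contact detection without explicit hydrogens is geometric, not
  energetic; counts are parameter-relative.
* `build_assembly()` applies REMARK 350 / user operators; it does not
  infer assemblies from crystal symmetry.
* The comparison driver averages groups unweighted; weighted averaging
  over user-defined member lists is the caller's responsibility (group
  membership is fully user-specified).
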