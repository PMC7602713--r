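# adaptsig

Sequence, structure and flexibility signatures of extremophilic protein
adaptation, in one R package.

Proteins from halophiles carry an acidic, weakly hydrophobic surface that
keeps them hydrated in molar salt; proteins from psychrophiles carry
flexibility features — small residues, fewer stabilising hydrogen bonds,
long disordered loops — that keep them moving in the cold. `adaptsig`
measures both families of signatures so that a protein of interest can be
compared against groups of homologs:

* **Sequence:** residue-class composition, grand average of hydropathy
  (GRAVY, Kyte–Doolittle), isoelectric point (Henderson–Hasselbalch
  bisection over a Bjellqvist-compatible pKa set), molar extinction
  coefficient (Pace increments), acidic excess (D+E minus R+K+H, in
  percentage points).
* **Structure:** Shrake–Rupley solvent-accessible surface area with a
  deterministic spiral point set; surface/buried classification at a
  relative-accessibility threshold (default >10% of a theoretical
  Gly-X-Gly maximum); surface residue-class percentages; hydrogen-bond and
  salt-bridge enumeration with intra/inter-chain flags; simplified
  Kabsch–Sander secondary structure; biological-assembly construction from
  REMARK 350 operators; interface burial.
* **Dynamics:** Kabsch superposition; windowed backbone RMSD over a
  temperature schedule; the thermal-sensitivity descriptor (OLS slope of
  window-mean RMSD on temperature, in Å/°C — lower slope, less
  heat-induced flexibility gain); per-residue RMSF (Cα, two-pass mean
  superposition); ΔRMSF between temperatures with a 0.5 Å significance
  threshold and named residue panels (catalytic / substrate-binding).
* **Synthetic data:** generators for structures with planted hydrogen
  bonds, salt bridges and buried residues of known counts, and for
  multi-temperature trajectories with per-residue Gaussian fluctuations
  (σ linear in temperature) plus rigid-body contamination, each with a
  manifest of closed-form expected results. `synthetic_deposit()` builds a
  labelled-synthetic stand-in for a deposited polyextremophilic
  β-galactosidase entry: 700-residue sequence, 668 modelled residues with
  three disordered gaps, an acidic-rich planted surface and a C3 trimer
  with exactly 18 inter-chain hydrogen bonds and 4 inter-chain salt
  bridges per chain.

## Worked example

```r
library(adaptsig)

dep <- synthetic_deposit(seed = 42)   # synthetic reference bundle
composition(dep$sequence)
#> Composition profile over 700 canonical residues
#>   GRAVY -0.55 | pI 4.4 | eps280 157,220 M-1cm-1 | acidic excess 7.1 pts
#>   nonpolar            51.9%
#>   aliphatic           27.4%
#>   ...
#>   aspartate           11.7%
#>   positive            11.4%
#>   arginine             7.7%
#>   proline              7.1%
#>   lysine               1.0%
```

The profile shows the halophilic sequence signature: GRAVY −0.55 (strongly
hydrophilic), pI 4.4, a 7-point excess of acidic over basic residues, and
arginine outnumbering lysine nearly eight-fold. (The extinction
coefficient above is the reduced-cysteine value;
`extinction_coefficient(dep$sequence, "all_paired")` gives 157,845
M⁻¹cm⁻¹, the all-cystine convention of published "calculated" values.)

```r
surf <- classify_surface(sasa(dep$model))
surf
#> surface_profile: 183 surface / 485 buried residues (rel. acc. > 10%)
#>   acidic 33.3% | basic 14.8% | nonpolar 36.6% | aromatic 5.5%
```

A third of the surface is acidic — twice its share of the whole sequence —
which is the structural face of salt adaptation.

```r
trimer <- build_assembly(dep$model)     # applies the stored C3 operators
contact_counts(hydrogen_bonds(trimer), salt_bridges(trimer))$hbond_inter_per_chain
#>  A  B  C
#> 18 18 18
```

Each chain contributes 18 inter-chain hydrogen bonds (and 4 salt bridges)
to the trimer interfaces, exactly as planted by the generator.

```r
spec <- synth_traj_spec(seed = 42)      # 10/27/47/72 degC, 500 analysis frames each
reps <- make_replicas(spec, 3)
series <- lapply(seq_along(reps), function(r)
  rmsd_series(reps[[r]]$trajectory, reference = reps[[r]]$reference,
              schedule = reps[[r]]$schedule, replica = r))
temperature_regression(series)
#> temp_regression: slope 0.00856 A/degC, intercept 0.086, R^2 1.0000
#>  temperature_C mean_rmsd
#>             10 0.1713553
#>             27 0.3172786
#>             47 0.4886430
#>             72 0.7021089
```

The fitted thermal-sensitivity slope (0.00856 Å/°C) recovers the
generator's closed-form expectation (0.00866 Å/°C) within 1%; on real
trajectories this slope is the descriptor that separates thermophilic
(flattest), polyextremophilic and mesophilic (steepest) homologs.

A command-line driver with `seq`, `struct`, `traj`, `compare` and `synth`
subcommands is installed at `inst/scripts/adaptsig`; grouped comparisons
are configured in YAML (see `?read_compare_config`).

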