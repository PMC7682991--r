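# amyloidIMS

Ion-mobility mass-spectrometry (IM-MS) analysis of amyloid-beta (Abeta42)
oligomerization, for mass spectrometrists and aggregation researchers who
work with native IM-MS of small protein oligomers.

Abeta42 oligomers grow along two pathways: stacking on a single S-shaped
monomer (monomer-based, **MB**) or on a C2-symmetric planar dimer
(dimer-based, **DB**, the route to fibrils). The package implements the
full desk-side analysis that distinguishes them:

* **Isotope-resolved assignment** — detect features on a driftscope
  (m/z x drift time) map, infer the charge from the isotopologue spacing
  (`z = round(1.0034/spacing)`), then the oligomer order `n` from
  `m/z = (nM + z·1.00728)/z`. This breaks m/z degeneracies such as
  monomer<sup>2+</sup> / dimer<sup>4+</sup> / trimer<sup>6+</sup>, which
  all floor to m/z 2258.
* **TWIMS CCS calibration** — the power-law protocol:
  `t' = t_D − c·√(m/z)/1000`, `Ω' = Ω/(z·√(1/m_ion + 1/m_gas))`,
  `ln Ω' = ln A + B·ln t'`.
* **Growth models** — isotropic `Ω(n) = Ω_ref (n/n_ref)^(2/3)` versus
  linear `Ω(n) = a + bn`, with detection of the crossover order n\* and
  the MB/DB signature (equal slopes, distinct intercepts).
* **CIU/CID stability** — capped-logistic fits of unfolding and
  dissociation versus lab-frame energy `E = z·V`, cap-limited flagging
  (ligand-bound dimers unfold at most 15% before dissociating),
  energy-gap regime analysis, free-versus-bound comparison, fingerprint
  heat maps.
* **LILBID kinetics** — 10-min binning, replicate averaging, and the
  monomer-over-oligomer statistic `M/O = I₁ / Σ n·Iₙ`.
* **Structure-based CCS** — crop fibril PDB structures into MB/DB oligomer
  series and compute projection-approximation CCS by Monte Carlo.
* **Synthetic instrument** — seeded generators for driftscope frames,
  CE-ramped CIU/CID series, LILBID time courses and toy fibril PDBs, so
  every stage is testable end to end without raw data.

## Worked example

Masses and the degenerate peak at m/z 2258:

```r
library(amyloidIMS)
comp <- composition_from_sequence(ABETA42_SEQUENCE)
comp
#> H311 C203 N55 O60 S1
average_mass(comp)
#> [1] 4514.106
nominal_mz(ion_species(ABETA42_SEQUENCE, 2, 5), "average")   # 5+ dimer
#> [1] 1806
```

Simulate the three-species overlap at 2258 and resolve it by isotope
spacing:

```r
frame <- simulate_driftscope(
  list(species_spec(ion_species(ABETA42_SEQUENCE, 1, 2), drift_ms = 6),
       species_spec(ion_species(ABETA42_SEQUENCE, 2, 4), drift_ms = 10),
       species_spec(ion_species(ABETA42_SEQUENCE, 3, 6), drift_ms = 14)),
  mz_grid = seq(2253, 2270, by = 0.01), drift_grid = seq(1, 25, by = 0.1),
  noise = noise_model(0.02, seed = 1))
ft <- assign_species(detect_features(frame), ABETA42_SEQUENCE)
ft[order(ft$drift_ms), c("mz", "drift_ms", "spacing", "z", "n")]
#>     mz drift_ms spacing z n
#> 1 2258        6  0.5013 2 1
#> 2 2258       10  0.2506 4 2
#> 3 2258       14  0.1654 6 3
```

The three co-located peaks separate into monomer/dimer/trimer purely from
their isotope spacings (≈ 1.0034/z).

Fit the dimer's unfolding and dissociation transitions from a CE-ramped
series (5–50 V at charge 5, i.e. 25–250 eV lab frame):

```r
truth <- ciu_ground_truth(e50_ciu = 85, width_ciu = 10,
                          e50_cid = 125, width_cid = 10)
curve <- simulate_ciu_series(truth, seq(5, 50, by = 5), z = 5,
                             noise = noise_model(0.02, seed = 2))
fit_transition(curve, "CIU")
#> CIU transition [z=5, free]: E50 = 84.73 eV (se 0.03), width 9.76 eV, cap 0.999
fit_transition(curve, "CID")
#> CID transition [z=5, free]: E50 = 124.83 eV (se 0.06), width 9.85 eV, cap 1.000
```

Both midpoints come back within a fraction of an eV of the generating
truth (85 and 125 eV) despite 2% noise on a 10-point ramp.

The whole chain — assignment, calibration, growth fits, CIU/CID ladder,
kinetics, structure CCS — runs as one reproducible workflow:

```r
report <- run_replica(replica_config(seed = 1, inhibitor = TRUE))
report
#> replica report
#>   assignment: 10 features, 10 assigned
#>   calibration R^2 = 1.000000
#>   growth: Delta-slope 24.6, Delta-intercept 181
#>   crossover n* = 4
#>   gap regimes: 99.9 eV then 50.0 eV (breakpoint n = 4)
#>   kinetics: final max order free 12, inhibited 6
```

Read: every simulated oligomer ion is assigned; the MB and DB CCS series
share a slope within uncertainty but differ in intercept (the two-pathway
signature); growth departs from the isotropic model after the tetramer;
the unfolding-energy gaps shrink after the tetramer; and the inhibitor
caps aggregation at the hexamer while the free run reaches dodecamers.

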