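---
title: "Methods: ion-mobility MS analysis of amyloid-beta oligomerization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ion-mobility MS analysis of amyloid-beta oligomerization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amyloidIMS)
```

## The scientific problem

Amyloid-beta 42 (Abeta42) aggregation proceeds through small oligomers whose
structures decide whether the end point is an ordered fibril or an amorphous
aggregate. Native ion-mobility mass spectrometry (IM-MS) separates oligomer
ions both by mass-to-charge and by shape (drift time), which makes it
possible to ask structural questions about species as transient as a dimer.
This package implements the complete desk-side analysis chain for such
experiments: assigning oligomer order and charge from isotopically resolved
driftscope maps, calibrating traveling-wave drift times to collision cross
sections (CCS), discriminating isotropic (globular) from linear (fibrillar)
growth, quantifying gas-phase stability by collision-induced unfolding and
dissociation (CIU/CID), tracking aggregation kinetics through the
monomer-over-oligomer ratio, and computing theoretical CCS of fibril-derived
oligomer models by the projection approximation.

The central scientific picture the pipeline supports is a two-pathway model:
oligomers either stack on a single S-shaped monomer (monomer-based, MB) or
grow on a C2-symmetric planar dimer (dimer-based, DB). The two families
share the per-monomer CCS increment (same stacking unit) but differ in their
intercept (different base), and only the DB family is on-pathway to fibrils.

## Mass and isotope conventions

Peptide compositions come from a bundled residue table plus one water;
masses use IUPAC standard atomic weights (average) or most-abundant-isotope
masses (monoisotopic). The m/z of an n-mer carrying z protons is
`(n*M + z*1.00728)/z`, and "nominal m/z" is the floor of that value,
matching the integer peak labels customary on spectra. For the canonical
Abeta42 sequence this puts the 5+ dimer at nominal m/z 1806 and makes the
monomer 2+, dimer 4+ and trimer 6+ coincide at 2258 — the degeneracy the
assignment stage must break.

Isotope patterns are computed by element-wise convolution of the isotope
tables (polynomial expansion) and aggregated by neutron-count index: each
peak is the abundance-weighted centroid of all isotopologues with the same
number of extra neutrons. Fine structure is deliberately out of scope. One
consequence worth knowing: the centroided spacing between adjacent peaks of
a peptide envelope is slightly below the 13C shift (about 1.0030 Da rather
than 1.0034 Da) because the 15N and 17O channels pull the +1 centroid down.
The spacing-to-charge inversion `z = round(1.0034/spacing)` is unaffected —
the deviation is two orders of magnitude smaller than the spacing gap
between adjacent charges up to z = 20 — but exact-valued tests of the
spacing identity only hold to 1e-4 on pure-carbon compositions.

## Feature detection and assignment

`detect_features()` segments the m/z axis into signal windows (merging gaps
smaller than 1.2 Th so an isotope envelope stays whole), then finds local
maxima of each window's drift profile above a noise floor estimated by the
median absolute deviation of the frame. The assignment logic follows the
order the experiment dictates: the isotope spacing (autocorrelation maximum
over the physically plausible lag range, with parabolic interpolation)
fixes the charge first; the oligomer order is then the integer minimizing
the m/z residual within a tolerance (default 0.1 Th). A feature whose
isotopes are unresolved at a degenerate m/z is flagged with its full
candidate set — `2/5;4/10;...` — never silently collapsed to the reduced
pair.

Feature m/z centroids are intensity-weighted means of the envelope, so they
estimate the *average-mass* m/z, not the monoisotopic one; the assignment
therefore compares centroids against average-mass predictions by default.

Within each assigned species, conformers are ordered by drift time: the
most compact structured state is labeled MB and the second DB (the
convention that MB drifts faster, adopted from the observed 8 ms / 11 ms
ordering of the 5+ dimer), with states more than 4 ms beyond the most
compact labeled extended (unfolding products). A species with a single
structured state is flagged `db-missing` — the observable that identifies
both the F19P mutant and inhibitor-bound Abeta42.

## CCS calibration

Traveling-wave drift times have no first-principles CCS relation, so the
package implements the standard power-law calibration: drift times are
corrected for the mass-dependent transit delay
(`t' = t_D - c*sqrt(m/z)/1000`, EDC coefficient default 1.41), literature
CCS values of denatured calibrants are reduced by charge and reduced mass
(`Omega' = Omega/(z*sqrt(1/m_ion + 1/m_gas))`, nitrogen gas, 28.0134 Da),
and `ln Omega'` is regressed on `ln t'`. Applying the fit inverts these
steps. Calibrant reference values are user-supplied — the bundled table
under `inst/extdata/` is synthetic (generated from an exact power law) and
exists only to document the format and to demonstrate round trips. The
pipeline refuses to apply calibrations with R^2 below 0.98 unless that
guard is explicitly relaxed. Uncertainty is propagated to first order from
the drift-centroid uncertainty and the fit's coefficient covariance.

## Growth models and the crossover

The isotropic model `Omega(n) = Omega_ref (n/n_ref)^(2/3)` (volume-to-area
scaling, anchored at the dimer) describes unstructured, globular growth;
the linear model `Omega(n) = a + b*n` describes fibrillar stacking. The
exponent 2/3 is fixed, not fitted. `detect_crossover()` reports the largest
order n\* below which every point is consistent with the isotropic curve
and above which the linear model fits better.

Two numerical choices matter here. First, because the isotropic curve is
anchored at the *observed* dimer CCS, the prediction at order m inherits
the dimer's noise; the consistency band therefore uses the propagated
uncertainty `sqrt(sigma_m^2 + ((m/2)^(2/3) sigma_2)^2)`. Second, the band
is 3 sigma by default: with the few-percent uncertainties typical of
charge-state-averaged CCS, a 2 sigma band would false-flag an isotropic
point in roughly one series in ten, which is too flaky for a decision rule
applied once per data set. The two-regime synthetic fixture
(`two_regime_series()`) uses a linear branch of 520 A^2 per monomer —
about twice the isotropic tangent at the crossover — because a
tangent-slope continuation is statistically indistinguishable from the
isotropic curve over the first orders after the break at realistic noise;
the fixture is meant to exercise the detector under a clear regime change,
not to mimic any particular measured slope.

`compare_series()` implements the two-pathway signature: fit both families
linearly over their common orders and report whether the slope difference
is consistent with zero while the intercept difference is not (equal
stacking unit, different base). Exact-fit degeneracies (zero-width
confidence intervals) are handled with relative-magnitude floors.

## CIU / CID analysis

Trap collision voltages are converted to lab-frame energy as `E = z*V`
(single-collision convention; it reproduces 50% dimer unfolding at 85 eV
from 17 V at charge 5, consistent with the 5-50 V ramp in 5 V steps).
Transitions are modeled as logistics with a free amplitude (cap):

* CIU fits the extended fraction *among surviving ions*
  (`extended/(compact+extended)`), so the overlapping dissociation decline
  cannot bias the unfolding midpoint;
* CID fits total survival as a declining logistic.

E50 is the energy of half the transition's own amplitude. When the fitted
cap is below 0.5 the absolute-50% level is never reached and the fit is
flagged cap-limited — the distinction forced by ligand-bound dimers whose
unfolding saturates at 15% before dissociation removes the precursor. A
species whose unfolded fraction never rises above 5% of survivors is
reported as having no unfolding transition at all (the DB dimer
dissociates without prior unfolding). Midpoint uncertainties come from a
seeded residual bootstrap (200 resamples) summarized by the median absolute
deviation; case resampling is deliberately avoided because dropping
transition-region points from a 10-point ramp produces unbounded midpoint
estimates.

`gap_analysis()` takes per-order unfolding midpoints, forms first
differences, and fits a two-segment constant-gap model with the breakpoint
chosen by exhaustive least squares — the series are short, so exhaustive
search is exact. Statistically uniform gaps are reported as degenerate with
a single gap value.

## Kinetics and the M/O ratio

LILBID time courses are binned (10 min default) with replicate averaging
(4 replicates default), and aggregation progress is tracked by the
monomer-over-oligomer ratio `M/O = I_1 / sum(n*I_n)`. The denominator's sum
includes the n = 1 term by default, which bounds M/O by 1 (exactly 1 for a
monomer-only spectrum) and reads naturally as the monomeric fraction of
peptide mass; the convention excluding the monomer is also implemented
because the defining formula leaves the sum's range unstated. Condition
comparisons report per-bin differences in M/O and in the maximum observed
order (threshold 1% of total intensity), with bootstrap confidence
intervals over replicates when replicate-level rows are retained.

The synthetic kinetics generator is a deterministic mass-action assembly
chain integrated with `deSolve`: monomers nucleate into dimers (rate split
between a DB and an MB channel) and chains elongate by monomer addition.
Elongation is 40 times faster than nucleation by default — growth must be
nucleation-limited for double-digit orders to appear while monomer remains,
which reproduces the observed endpoints (free aggregation reaching
dodecamers by 200 min; an inhibitor that suppresses the DB channel and
caps growth at the hexamer). The noiseless trajectory conserves total
peptide mass to integrator tolerance, and M/O is monotone non-increasing
on the free run. This chain is synthetic scaffolding for testing the
analysis — it is not a mechanistic claim about Abeta42; the time courses
it emulates are empirical.

## Structure-based theoretical CCS

Fibril models are read from PDB files (via `bio3d`), and oligomers are
cropped out of them by a chain/layer map: MB oligomers take n consecutive
layers of one protofilament, DB oligomers take whole two-monomer layers
(odd orders drop one unpaired monomer, flagged). The toy fibril generator
writes rigid stacks of S-shaped carbon traces (4.7 A rise, C2-duplicated
for DB) so the full structure stage is testable without downloads;
synthetic structures are labeled as such.

Theoretical CCS uses the projection approximation only: the
orientation-averaged shadow area of atoms drawn as hard disks of radius
(van der Waals + buffer gas, default 1.5 A for nitrogen-like gas),
estimated by Monte Carlo — uniform quaternion orientations, hit-or-miss
area sampling in the projected bounding box (defaults 300 orientations x
5000 rays, seeded). PA is exactly verifiable against closed forms (a
single atom's CCS is pi*(r_atom+r_gas)^2) and suffices for the
slope/intercept comparison the pipeline needs; trajectory-method CCS and
the molecular-dynamics relaxation used for publication-grade absolute
values are out of scope, and cropped structures are used as-is, with
`read_structure()` accepting externally relaxed coordinates when available.

## The replica workflow and problem sizes

`run_replica()` chains every stage on synthetic fixtures: per-oligomer
driftscope frames (dimer through hexamer at one representative charge
state each, MB at 8 ms + 1.5 ms per added monomer and DB 3 ms slower, at
2% multiplicative noise), a synthetic calibrant ladder, growth fits and
the crossover, the CIU midpoint ladder (85 to 435 eV with the gap regime
change after the tetramer), free-versus-bound dimer comparisons (15% cap),
free and inhibited kinetics, and the toy-fibril PA series. The replica
frames use a resolving power of 60,000 so isotope resolution extends to
the hexamer — at 20,000 the isotopologue spacing falls below the peak
width for species above roughly 27 kDa, which is the physically honest
outcome but leaves nothing for the degeneracy-resolution stage to do at
high orders. Everything derives from one master seed and the report is
bit-reproducible; a full run takes well under a minute on one CPU, and the
default test suite and acceptance script each finish in about a minute —
sizes chosen so the whole analysis is comfortably desk-scale.

## What the synthetic generators do and do not show

The generators reproduce the *statistical structure* the analysis assumes:
exact isotope envelopes under separable Gaussian peak shapes,
logistic-in-energy two-state transitions, mass-conserving assembly
kinetics, rigid stacked geometries. They do not emulate traveling-wave ion
dynamics, ESI charging, detector saturation, chemical noise, or LILBID
peak shapes. Passing tests therefore demonstrate that the analysis
recovers known ground truth under its stated model — they do not
demonstrate robustness to instrument artifacts absent from the model.
Parameters that are conventions of the study design (the 5-50 V ramp, the
10-minute bins, 4 replicates, the 8/11 ms dimer drift anchors, the 15%
cap) are fixed as defaults; parameters with no stated value (noise level
2%, drift peak width 0.4 ms, the kinetics rate constants) were chosen once
to look like routine data of this kind.

## Known limitations

* Assignment assumes isotopic resolution; unresolved features are flagged,
  not deconvolved (no Bayesian charge-mixture deconvolution).
* The CCS calibration is the power-law protocol only; no drift-tube
  first-principles route, no temperature/pressure corrections.
* PA CCS systematically underestimates large concave structures relative
  to trajectory methods; only slope/intercept comparisons should be read
  from it, not absolute values.
* The kinetics chain is irreversible and spatially homogeneous; it cannot
  represent secondary nucleation or fragmentation.
* Negative-ion-mode specifics and vendor raw-file ingestion are out of
  scope; all I/O is delimited text, JSON, FASTA and PDB.
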