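## Test helpers: independent oracles and fixture builders.

## Brute-force isotope pattern by exhaustive multinomial enumeration over
## isotope assignments, aggregated by neutron-count shift (the same
## representation the package uses). Only feasible for tiny compositions.
enumerate_pattern <- function(counts) {
  stopifnot(sum(counts) <= 10)
  ## per-element isotope tables with neutron shifts
  parts <- list(list(shift = 0L, mass = 0, prob = 1))
  for (el in names(counts)[counts > 0]) {
    iso <- amyloidIMS::element_data[[el]]$isotopes
    shift <- as.integer(round(iso$mass - iso$mass[1]))
    for (atom in seq_len(counts[[el]])) {
      acc <- list()
      for (p in parts) {
        for (r in seq_len(nrow(iso))) {
          acc[[length(acc) + 1]] <- list(
            shift = p$shift + shift[r],
            mass = p$mass + iso$mass[r],
            prob = p$prob * iso$abundance[r]
          )
        }
      }
      parts <- acc
    }
  }
  shifts <- vapply(parts, `[[`, integer(1), "shift")
  masses <- vapply(parts, `[[`, numeric(1), "mass")
  probs <- vapply(parts, `[[`, numeric(1), "prob")
  ks <- sort(unique(shifts))
  data.frame(
    shift = ks,
    mass = vapply(ks, function(k) {
      w <- probs[shifts == k]
      sum(w * masses[shifts == k]) / sum(w)
    }, numeric(1)),
    abundance = vapply(ks, function(k) sum(probs[shifts == k]), numeric(1))
  )
}

## Single-conformer driftscope fixture around one oligomer ion.
make_single_species_frame <- function(n = 2, z = 5, drift = 8, noise = NULL,
                                      resolving_power = 20000,
                                      peptide = amyloidIMS::ABETA42_SEQUENCE) {
  ion <- amyloidIMS::ion_species(peptide, n, z)
  mz0 <- amyloidIMS::mz_of_species(ion, "monoisotopic")
  amyloidIMS::simulate_driftscope(
    list(amyloidIMS::species_spec(ion, drift_ms = drift)),
    mz_grid = seq(mz0 - 2, mz0 + 5, by = 0.01),
    drift_grid = seq(1, 20, by = 0.1),
    noise = noise, resolving_power = resolving_power)
}

## The m/z-degenerate overlap fixture: monomer 2+, dimer 4+, trimer 6+.
make_overlap_frame <- function(noise = NULL,
                               peptide = amyloidIMS::ABETA42_SEQUENCE) {
  comp <- amyloidIMS::composition_from_sequence(peptide)
  specs <- list(
    amyloidIMS::species_spec(amyloidIMS::ion_species(comp, 1, 2), drift_ms = 6),
    amyloidIMS::species_spec(amyloidIMS::ion_species(comp, 2, 4), drift_ms = 10),
    amyloidIMS::species_spec(amyloidIMS::ion_species(comp, 3, 6), drift_ms = 14))
  mz0 <- amyloidIMS::mz_of_species(amyloidIMS::ion_species(comp, 1, 2), "monoisotopic")
  amyloidIMS::simulate_driftscope(
    specs, mz_grid = seq(mz0 - 3, mz0 + 6, by = 0.01),
    drift_grid = seq(1, 25, by = 0.1), noise = noise)
}

## Synthetic one-atom / few-atom structures for PA tests.
make_point_structure <- function(xyz, element = "C") {
  xyz <- matrix(xyz, ncol = 3)
  structure(list(element = rep_len(element, nrow(xyz)), xyz = xyz,
                 chain = rep("A", nrow(xyz)), resno = seq_len(nrow(xyz)),
                 source = list(file = "synthetic", model = 1L)),
            class = "ims_structure")
}
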