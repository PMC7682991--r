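test_that("sequence compositions follow the residue table plus one water", {
  g <- composition_from_sequence("G")
  expect_equal(unclass(g)[c("C", "H", "N", "O", "S")],
               c(C = 2L, H = 5L, N = 1L, O = 2L, S = 0L),
               ignore_attr = TRUE)
  gg <- composition_from_sequence("GG")
  expect_equal(unclass(gg)[c("C", "H", "N", "O")],
               c(C = 4L, H = 8L, N = 2L, O = 3L), ignore_attr = TRUE)
  ## independent brute-force element tally of the Abeta42 sequence
  tally <- Reduce(`+`, lapply(strsplit(ABETA42_SEQUENCE, "")[[1]], function(r) {
    amyloidIMS:::residue_compositions[[r]]
  })) + c(C = 0, H = 2, N = 0, O = 1, S = 0)
  ab <- composition_from_sequence(ABETA42_SEQUENCE)
  expect_equal(as.numeric(ab), as.numeric(tally[names(ab)]))
  expect_equal(as.numeric(unclass(ab)),
               c(C = 203, H = 311, N = 55, O = 60, S = 1)[names(ab)],
               ignore_attr = TRUE)
})

test_that("invalid residue codes are rejected with position", {
  expect_error(composition_from_sequence("GAX"), "X.*position 3")
  expect_error(composition_from_sequence(""), "non-empty")
})

test_that("average and monoisotopic masses reproduce reference values", {
  water <- elemental_composition(H = 2, O = 1)
  expect_equal(average_mass(water), 18.015, tolerance = 1e-4)
  expect_equal(monoisotopic_mass(water), 18.0106, tolerance = 1e-4)
  expect_equal(monoisotopic_mass(elemental_composition(C = 1)), 12.0)
  expect_equal(average_mass(elemental_composition()), 0)
  ab <- composition_from_sequence(ABETA42_SEQUENCE)
  expect_equal(average_mass(ab), 4514.1, tolerance = 1e-4)
  expect_equal(monoisotopic_mass(ab), 4511.3, tolerance = 1e-4)
})

test_that("m/z arithmetic reproduces the printed dimer and overlap labels", {
  d5 <- ion_species(ABETA42_SEQUENCE, 2, 5)
  expect_equal(nominal_mz(d5, "average"), 1806L)
  overl <- vapply(list(c(1, 2), c(2, 4), c(3, 6)), function(p) {
    nominal_mz(ion_species(ABETA42_SEQUENCE, p[1], p[2]), "average")
  }, integer(1))
  expect_true(all(overl == 2258L))
  m1 <- ion_species(ABETA42_SEQUENCE, 1, 1)
  expect_equal(mz_of_species(m1, "average"),
               average_mass(composition_from_sequence(ABETA42_SEQUENCE)) + 1.00728)
})

test_that("m/z degeneracy is exact for scaled (n, z) pairs", {
  comp <- composition_from_sequence("ACDEFGHIKLMNPQRSTVWY")
  for (k in 1:4) {
    expect_equal(mz_of_species(ion_species(comp, 2 * k, 5 * k), "average"),
                 mz_of_species(ion_species(comp, 2, 5), "average"))
    expect_equal(mz_of_species(ion_species(comp, k, 3 * k), "monoisotopic"),
                 mz_of_species(ion_species(comp, 1, 3), "monoisotopic"))
  }
})

test_that("isotope patterns match carbon table and neutron-spacing identity", {
  c1 <- isotope_pattern(elemental_composition(C = 1), z = 1, n_peaks = 2)
  expect_equal(c1$abundance, c(0.9893, 0.0107), tolerance = 1e-9)
  ## pure-carbon envelope: spacing is exactly the 13C shift, within 1e-4
  cpat <- isotope_pattern(elemental_composition(C = 10), z = 1, n_peaks = 4)
  expect_true(all(abs(diff(cpat$mz) - NEUTRON_SPACING) < 1e-4))
  ## peptide envelopes: centroided spacing sits within 1e-3/z of 1.0034/z
  ## (the 15N/17O channels pull the +1 centroid a few 1e-4 below the 13C
  ## shift), which still pins the charge uniquely up to z = 20
  for (z in c(1L, 2L, 5L)) {
    pat <- isotope_pattern(composition_from_sequence("GAVLF"), z, n_peaks = 6)
    expect_true(all(abs(diff(pat$mz) - NEUTRON_SPACING / z) < 1e-3 / z))
    expect_equal(round(NEUTRON_SPACING / mean(diff(pat$mz))), z)
  }
})

test_that("patterns are normalized and truncation renormalizes", {
  ab <- composition_from_sequence(ABETA42_SEQUENCE)
  for (np in c(3L, 8L, 30L)) {
    pat <- isotope_pattern(ab, z = 5, n_peaks = np)
    expect_equal(sum(pat$abundance), 1, tolerance = 1e-9)
    expect_true(all(diff(pat$mass) > 0))
    expect_lte(nrow(pat), np)
  }
})

test_that("convolution equals exhaustive multinomial enumeration", {
  fixtures <- list(
    c(C = 3, H = 4, O = 2),
    c(C = 2, N = 2, S = 1),
    c(H = 5, O = 3, S = 1)
  )
  for (cnt in fixtures) {
    oracle <- enumerate_pattern(cnt)
    pat <- isotope_pattern(do.call(elemental_composition, as.list(cnt)),
                           z = 1, n_peaks = nrow(oracle))
    k <- seq_len(min(nrow(oracle), nrow(pat)))
    expect_equal(pat$abundance[k], oracle$abundance[k] / sum(oracle$abundance[k]),
                 tolerance = 1e-9)
    expect_equal(pat$mass[k], oracle$mass[k], tolerance = 1e-9)
  }
})

test_that("n-mer pattern equals n-fold self-convolution of the monomer", {
  cnt <- elemental_composition(C = 2, O = 1)
  for (n in c(2L, 3L)) {
    direct <- isotope_pattern(nmer_composition(cnt, n), z = 1, n_peaks = 8)
    ## self-convolution oracle via the enumeration on the scaled composition
    oracle <- enumerate_pattern(unclass(nmer_composition(cnt, n))[c("C", "O")])
    k <- seq_len(min(nrow(direct), nrow(oracle)))
    expect_equal(direct$abundance[k],
                 oracle$abundance[k] / sum(oracle$abundance[k]), tolerance = 1e-9)
  }
})

test_that("FASTA and pattern serialization round-trip", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">ab42", ABETA42_SEQUENCE, ">toy", "GAVLF"), fa)
  seqs <- read_fasta_sequences(fa)
  expect_equal(unname(seqs["ab42"]), ABETA42_SEQUENCE)
  pat <- isotope_pattern(composition_from_sequence("GAVLF"), z = 2, n_peaks = 5)
  tf <- tempfile(fileext = ".tsv")
  write_isotope_pattern(pat, tf)
  back <- read_isotope_pattern(tf)
  expect_equal(back$mass, pat$mass, tolerance = 1e-9)
  expect_equal(back$abundance, pat$abundance, tolerance = 1e-9)
  expect_equal(attr(back, "charge"), 2L)
  unlink(c(fa, tf))
})
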