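test_that("a noiseless single-species frame yields one feature at truth", {
  frame <- make_single_species_frame(n = 2, z = 5, drift = 8)
  ft <- detect_features(frame)
  expect_equal(nrow(ft), 1)
  expect_equal(ft$drift_ms, 8, tolerance = 0.1)   # one grid step
  expect_equal(ft$mz, mz_of_species(ion_species(ABETA42_SEQUENCE, 2, 5), "average"),
               tolerance = 0.05)
})

test_that("the overlap fixture resolves into three charge-distinct features", {
  ft <- detect_features(make_overlap_frame(noise = noise_model(0.02, seed = 5)))
  expect_equal(nrow(ft), 3)
  ft <- assign_species(ft, ABETA42_SEQUENCE)
  ft <- ft[order(ft$drift_ms), ]
  expect_equal(ft$z, c(2L, 4L, 6L))
  expect_equal(ft$n, c(1L, 2L, 3L))
  expect_equal(ft$spacing, NEUTRON_SPACING / c(2, 4, 6), tolerance = 0.01)
  expect_true(all(ft$flags == ""))
})

test_that("blank noise frames produce no features at SNR 5", {
  hits <- vapply(1:100, function(s) {
    intensity <- with(list(), {
      set.seed(s)
      matrix(abs(rnorm(80 * 60, 0, 1)), 80, 60)
    })
    fr <- driftscope_frame(seq(1000, by = 0.05, length.out = 80),
                           seq(1, by = 0.2, length.out = 60), intensity)
    nrow(detect_features(fr, min_snr = 5))
  }, numeric(1))
  expect_gte(mean(hits == 0), 0.95)
})

test_that("isotope spacing estimation matches the charge ladder", {
  for (z in c(4L, 5L)) {
    ion <- ion_species(ABETA42_SEQUENCE, 1, z)
    mz0 <- mz_of_species(ion, "monoisotopic")
    fr <- simulate_driftscope(list(species_spec(ion, 8)),
                              seq(mz0 - 2, mz0 + 3, by = 0.005),
                              seq(1, 15, by = 0.1))
    ft <- detect_features(fr)
    prof <- attr(ft, "profiles")[[1]]
    est <- estimate_isotope_spacing(prof$mz, prof$mz_profile)
    expect_true(est$resolved)
    expect_equal(est$spacing, NEUTRON_SPACING / z, tolerance = 0.002)
  }
})

test_that("profiles without three resolved peaks are flagged unresolved", {
  mz <- seq(1800, 1810, by = 0.01)
  smooth <- exp(-0.5 * ((mz - 1805) / 1.5)^2)  # single broad hump
  est <- estimate_isotope_spacing(mz, smooth)
  expect_false(est$resolved)
  expect_true(is.na(est$spacing))
})

test_that("assignment recovers every generated (n, z) pair noiselessly", {
  comp <- composition_from_sequence(ABETA42_SEQUENCE)
  cases <- expand.grid(n = 1:9, z_off = c(2, 3))
  ## one representative pair per order, charges in the observed z ~ n range;
  ## resolving power chosen so isotopes stay resolved at every order
  for (i in seq_len(nrow(cases))) {
    n <- cases$n[i]; z <- n + cases$z_off[i]
    ion <- ion_species(comp, n, z)
    mz0 <- mz_of_species(ion, "monoisotopic")
    fr <- simulate_driftscope(list(species_spec(ion, 8)),
                              seq(mz0 - 2, mz0 + 14, by = 0.01),
                              seq(1, 15, by = 0.1),
                              resolving_power = 80000)
    ft <- assign_species(detect_features(fr), comp, n_max = 12L)
    expect_equal(nrow(ft), 1)
    expect_equal(ft$z, z)
    expect_equal(ft$n, n)
  }
})

test_that("assignment is invariant to uniform intensity scaling", {
  fr <- make_overlap_frame(noise = noise_model(0.02, seed = 9))
  fr1000 <- driftscope_frame(fr$mz, fr$drift_ms, fr$intensity * 1000, fr$meta)
  a1 <- assign_species(detect_features(fr), ABETA42_SEQUENCE)
  a2 <- assign_species(detect_features(fr1000), ABETA42_SEQUENCE)
  expect_equal(a1$n, a2$n)
  expect_equal(a1$z, a2$z)
  expect_equal(a1$mz, a2$mz, tolerance = 1e-9)
})

test_that("unresolved degenerate features report their ambiguous set", {
  ion <- ion_species(ABETA42_SEQUENCE, 2, 5)
  mz0 <- mz_of_species(ion, "monoisotopic")
  ## resolving power too low to separate isotopes
  fr <- simulate_driftscope(list(species_spec(ion, 8)),
                            seq(mz0 - 6, mz0 + 9, by = 0.01),
                            seq(1, 15, by = 0.1), resolving_power = 500)
  ft <- assign_species(detect_features(fr), ABETA42_SEQUENCE, n_max = 12L)
  expect_true(is.na(ft$n[1]))
  expect_match(ft$flags[1], "ambiguous:2/5")
  expect_match(ft$flags[1], "4/10")
})

test_that("conformer grouping labels MB, DB and extended states", {
  ion <- ion_species(ABETA42_SEQUENCE, 2, 5)
  mz0 <- mz_of_species(ion, "monoisotopic")
  fr <- simulate_driftscope(
    list(species_spec(ion, drift_ms = c(8, 11, 13), abundance = c(1, 0.8, 0.5))),
    seq(mz0 - 2, mz0 + 4, by = 0.01), seq(1, 20, by = 0.1))
  ft <- group_conformers(assign_species(detect_features(fr), ABETA42_SEQUENCE))
  ft <- ft[order(ft$drift_ms), ]
  expect_equal(ft$conformer, c("MB", "DB", "extended-MB"))
})

test_that("a lone conformer is flagged single and DB-missing", {
  ## the F19P-style case: structured MB plus its unfolding product only
  ion <- ion_species(ABETA42_SEQUENCE, 2, 5)
  mz0 <- mz_of_species(ion, "monoisotopic")
  fr <- simulate_driftscope(
    list(species_spec(ion, drift_ms = c(8, 13), abundance = c(1, 0.5))),
    seq(mz0 - 2, mz0 + 4, by = 0.01), seq(1, 20, by = 0.1))
  ft <- group_conformers(assign_species(detect_features(fr), ABETA42_SEQUENCE))
  ft <- ft[order(ft$drift_ms), ]
  expect_equal(ft$conformer, c("MB", "extended-MB"))
  expect_match(ft$flags[1], "db-missing")
})

test_that("driftscope text serialization round-trips", {
  fr <- make_single_species_frame(noise = noise_model(0.02, seed = 4))
  path <- tempfile(fileext = ".tsv")
  write_driftscope(fr, path)
  back <- read_driftscope(path)
  expect_equal(back$mz, fr$mz, tolerance = 1e-9)
  expect_equal(back$drift_ms, fr$drift_ms, tolerance = 1e-9)
  expect_equal(back$intensity, fr$intensity, tolerance = 1e-7, ignore_attr = TRUE)
  expect_equal(back$meta$seed, 4L)
  unlink(path)
})
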