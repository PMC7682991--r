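test_that("lab-frame energy is charge times voltage", {
  expect_equal(lab_frame_energy(17, 5), 85)
  expect_equal(lab_frame_energy(5, 1), 5)
  expect_equal(lab_frame_energy(12, 6), 2 * lab_frame_energy(12, 3))
})

test_that("transition fit round-trips a noiseless logistic", {
  tr <- ciu_ground_truth(e50_ciu = 85, width_ciu = 10, e50_cid = 1e5)
  cv <- simulate_ciu_series(tr, seq(5, 50, by = 5), z = 5)
  fit <- fit_transition(cv, "CIU", n_boot = 0)
  expect_equal(fit$e50, 85, tolerance = 1e-6)
  expect_equal(fit$width, 10, tolerance = 1e-4)
  expect_equal(fit$cap, 1, tolerance = 1e-4)
  expect_false(fit$cap_limited)
  ## absolute-50% energy coincides with E50 when cap = 1
  expect_equal(fit$e50_absolute, 85, tolerance = 1e-4)
})

test_that("CID fit recovers the dissociation midpoint", {
  tr <- ciu_ground_truth(e50_ciu = 85, width_ciu = 10, e50_cid = 125,
                         width_cid = 10)
  cv <- simulate_ciu_series(tr, seq(5, 50, by = 5), z = 5)
  fit <- fit_transition(cv, "CID", n_boot = 0)
  expect_equal(fit$e50, 125, tolerance = 1e-4)
})

test_that("the 15% cap case is flagged cap-limited", {
  tr <- ciu_ground_truth(e50_ciu = 85, width_ciu = 10, e50_cid = 135,
                         width_cid = 10, cap = 0.15)
  cv <- simulate_ciu_series(tr, seq(5, 50, by = 5), z = 5,
                            noise = noise_model(0.02, seed = 3))
  fit <- fit_transition(cv, "CIU", n_boot = 0)
  expect_true(fit$cap_limited)
  expect_lt(fit$cap, 0.25)
  expect_true(is.na(fit$e50_absolute))
  expect_lte(max(cv$extended), 0.2)
})

test_that("cap-limited flagging is stable away from the 0.5 boundary", {
  for (cap in c(0.30, 0.40, 0.60, 0.70)) {
    hits <- vapply(1:20, function(s) {
      tr <- ciu_ground_truth(e50_ciu = 85, width_ciu = 10, e50_cid = 1e5,
                             cap = cap)
      cv <- simulate_ciu_series(tr, seq(5, 60, by = 5), z = 5,
                                noise = noise_model(0.02, seed = s))
      fit_transition(cv, "CIU", n_boot = 0)$cap_limited
    }, logical(1))
    if (cap < 0.45) expect_true(all(hits)) else expect_false(any(hits))
  }
})

test_that("a DB-style dimer dissociating without unfolding is flagged absent", {
  ## unfolding midpoint far above dissociation: no CIU signal ever rises
  tr <- ciu_ground_truth(e50_ciu = 1e4, width_ciu = 10, e50_cid = 85,
                         width_cid = 10)
  cv <- simulate_ciu_series(tr, seq(5, 50, by = 5), z = 5,
                            noise = noise_model(0.01, seed = 2))
  cid <- fit_transition(cv, "CID", n_boot = 0)
  expect_equal(cid$e50, 85, tolerance = 3)
  ciu <- fit_transition(cv, "CIU", n_boot = 0)
  expect_true(ciu$absent)
})

test_that("E50 recovery bias stays below 2 eV at 2% noise on the 5 V grid", {
  biases <- vapply(1:100, function(s) {
    tr <- ciu_ground_truth(e50_ciu = 85, width_ciu = 10, e50_cid = 1e5)
    cv <- simulate_ciu_series(tr, seq(5, 50, by = 5), z = 5,
                              noise = noise_model(0.02, seed = s))
    fit_transition(cv, "CIU", n_boot = 0)$e50 - 85
  }, numeric(1))
  expect_lt(abs(median(biases)), 2)
})

test_that("gap analysis finds the constructed two-regime breakpoint", {
  tab <- data.frame(n = 2:7, e50 = c(85, 185, 285, 335, 385, 435))
  g <- gap_analysis(tab)
  expect_false(g$degenerate)
  expect_equal(g$breakpoint, 4L)
  expect_equal(g$gap_lower, 100)
  expect_equal(g$gap_upper, 50)
})

test_that("equidistant gaps are reported degenerate with a single value", {
  tab <- data.frame(n = 2:7, e50 = seq(85, by = 70, length.out = 6))
  g <- gap_analysis(tab)
  expect_true(g$degenerate)
  expect_equal(g$gap_lower, 70)
  expect_equal(g$gap_upper, 70)
  expect_error(gap_analysis(data.frame(n = 2:4, e50 = c(85, 185, 285))),
               "at least 4")
})

test_that("gap breakpoint detection holds for gap contrasts of 25%", {
  ## lower gap 100, upper gap 75 (25% contrast), noiseless
  tab <- data.frame(n = 2:8, e50 = c(85, 185, 285, 360, 435, 510, 585))
  g <- gap_analysis(tab)
  expect_equal(g$breakpoint, 4L)
  expect_equal(g$gap_lower, 100)
  expect_equal(g$gap_upper, 75)
})

test_that("bound-free comparison classifies the observed ligand effects", {
  mk <- function(e50, cap = 1, cap_limited = FALSE, kind = "CIU",
                 se = 0.5) {
    structure(list(e50 = e50, width = 10, cap = cap, e50_se = se,
                   cap_limited = cap_limited, absent = FALSE,
                   e50_absolute = e50, kind = kind, species = "D5+",
                   ligand = "x", n_points = 10), class = "transition_fit")
  }
  expect_equal(compare_bound_free(mk(85), mk(85))$class, "unchanged")
  expect_equal(compare_bound_free(mk(125, kind = "CID"),
                                  mk(135, kind = "CID"))$class, "CID-stabilized")
  expect_equal(compare_bound_free(mk(85), mk(85, cap = 0.15,
                                             cap_limited = TRUE))$class,
               "CIU-suppressed")
  expect_error(compare_bound_free(mk(85), mk(85, kind = "CID")), "kinds differ")
})

test_that("fingerprints are row-normalized with a ridge hand-off", {
  drift <- seq(1, 20, by = 0.1)
  volts <- seq(5, 50, by = 5)
  tr <- ciu_ground_truth(e50_ciu = 85, width_ciu = 10, e50_cid = 1e5)
  frames <- lapply(volts, function(v) {
    E <- lab_frame_energy(v, 5)
    u <- 1 / (1 + exp(-(E - tr$e50_ciu) / tr$width_ciu))
    prof <- (1 - u) * dnorm(drift, 8, 0.4) + u * dnorm(drift, 13, 0.4)
    list(trap_v = v, profile = prof)
  })
  fp <- build_fingerprint(frames, drift, z = 5)
  expect_equal(unname(rowSums(fp)), rep(1, length(volts)), tolerance = 1e-9)
  ## ridge sits at the folded drift below the midpoint, extended above
  peak_drift <- drift[apply(fp, 1, which.max)]
  E <- 5 * volts
  expect_true(all(peak_drift[E < 75] == peak_drift[1]))
  expect_true(all(peak_drift[E > 95] == peak_drift[length(volts)]))
  expect_gt(peak_drift[length(volts)], peak_drift[1])
  ## single conformer: one constant ridge
  frames1 <- lapply(volts, function(v) list(trap_v = v,
                                            profile = dnorm(drift, 8, 0.4)))
  fp1 <- build_fingerprint(frames1, drift, z = 5)
  expect_true(all(drift[apply(fp1, 1, which.max)] == 8))
  expect_error(build_fingerprint(list(list(trap_v = 5, profile = 1:3)), drift),
               "inconsistent drift grids")
})
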