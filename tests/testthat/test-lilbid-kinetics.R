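make_raw_table <- function(times = seq(0, 199, by = 2), reps = 4,
                           n_max = 6, fill = function(t, r) {
                             c(100 - 0.3 * t, 0.1 * t, 0.05 * t,
                               rep(0, n_max - 3))
                           }) {
  rows <- do.call(rbind, lapply(times, function(t) {
    do.call(rbind, lapply(seq_len(reps), function(r) {
      iv <- fill(t, r)
      data.frame(time_min = t, replicate = r,
                 as.list(stats::setNames(iv, paste0("I_", seq_len(n_max)))))
    }))
  }))
  kinetics_table(rows, condition = "free")
}

test_that("10-minute binning of a 200-minute run gives 20 bins", {
  raw <- make_raw_table()
  b <- bin_and_average(raw, 10)
  expect_equal(nrow(b), 20)
  expect_equal(sort(unique(floor(b$time_min / 10))), 0:19)
})

test_that("bin means match the closed-form average of a linear drift", {
  raw <- make_raw_table(times = 0:99, reps = 1,
                        fill = function(t, r) c(2 * t, 5, 0, 0, 0, 0))
  b <- bin_and_average(raw, 10)
  ## I_1 = 2t: mean over t in {10k..10k+9} is 2*(10k + 4.5)
  expect_equal(b$I_1, 2 * (10 * (0:9) + 4.5), tolerance = 1e-12)
  expect_true(all(b$I_2 == 5))
})

test_that("binning is idempotent on already-aligned bins", {
  raw <- make_raw_table(times = seq(5, 195, by = 10), reps = 1)
  b1 <- bin_and_average(raw, 10)
  b2 <- bin_and_average(b1, 10)
  icols <- grep("^I_", names(b1), value = TRUE)
  expect_equal(b2[icols], b1[icols], tolerance = 1e-12)
})

test_that("replicate vectors are averaged within bins", {
  raw <- make_raw_table(times = c(0, 2), reps = 2,
                        fill = function(t, r) c(10 * r, r, 0, 0, 0, 0))
  b <- bin_and_average(raw, 10)
  expect_equal(nrow(b), 1)
  expect_equal(b$I_1, 15)  # mean of replicates 1 and 2: (10+20)/2
  bk <- bin_and_average(raw, 10, collapse_replicates = FALSE)
  expect_equal(nrow(bk), 2)
  expect_equal(sort(bk$I_1), c(10, 20))
})

test_that("normalization returns fractions summing to one", {
  expect_equal(normalize_spectrum(c(2, 2)), c(0.5, 0.5))
  iv <- c(3, 1, 0, 6)
  expect_equal(sum(normalize_spectrum(iv)), 1, tolerance = 1e-12)
  expect_equal(normalize_spectrum(10 * iv), normalize_spectrum(iv))
  expect_error(normalize_spectrum(c(0, 0)), "all-zero")
})

test_that("M/O follows its defining arithmetic and conventions", {
  expect_equal(m_over_o(c(50, 0, 0)), 1.0)
  expect_equal(m_over_o(c(50, 25)), 0.5)
  expect_equal(m_over_o(c(50, 25)), m_over_o(7 * c(50, 25)))
  ## n >= 2 denominator convention excludes the monomer term
  expect_equal(m_over_o(c(50, 25), denominator = "n_ge_2"), 1.0)
  expect_error(m_over_o(c(0, 0)), "zero denominator")
  ## bounded by 1 under the default convention; 1 iff monomer-only
  for (s in 1:20) {
    set.seed(s)
    iv <- runif(8)
    expect_lte(m_over_o(iv), 1)
    expect_gt(m_over_o(iv), 0)
  }
})

test_that("max order present respects the threshold", {
  expect_equal(max_order_present(c(10, 5, 0.4, 0, 0, 3), 0.01)$n_max_observed, 6)
  expect_equal(max_order_present(c(10, 0, 0, 0, 0, 0), 0.01)$n_max_observed, 1)
  res <- max_order_present(c(0, 0, 0), 0.5)
  expect_equal(res$n_max_observed, 0)
  expect_true(res$none)
  ## hexamer-capped fixture
  ki <- simulate_lilbid_timeseries(kinetics_ground_truth(inhibitor = TRUE),
                                   replicates = 1)
  iv <- as.numeric(ki[nrow(ki), grep("^I_", names(ki))])
  expect_equal(max_order_present(iv, 0.01)$n_max_observed, 6)
})

test_that("M/O is monotone non-increasing on the noiseless free run", {
  kt <- simulate_lilbid_timeseries(kinetics_ground_truth(), replicates = 1)
  icols <- grep("^I_", names(kt), value = TRUE)
  mos <- apply(kt[icols], 1, m_over_o)
  expect_true(all(diff(mos) <= 1e-12))
})

test_that("inhibitor comparison shows higher M/O at every timepoint", {
  times <- seq(0, 200, by = 5)
  free <- bin_and_average(
    simulate_lilbid_timeseries(kinetics_ground_truth(), times,
                               replicates = 4, noise = noise_model(0.02, seed = 21)),
    10, collapse_replicates = FALSE)
  inh <- bin_and_average(
    simulate_lilbid_timeseries(kinetics_ground_truth(inhibitor = TRUE), times,
                               replicates = 4, noise = noise_model(0.02, seed = 22)),
    10, collapse_replicates = FALSE)
  cmp <- compare_conditions(free, inh, n_boot = 30, seed = 5)
  expect_true(all(cmp$delta_mo >= -1e-6))       # M/O(+inh) >= M/O(free)
  expect_true(attr(cmp, "replicate_ci"))
  expect_true(all(is.finite(cmp$delta_mo_lo)))
  ## identical tables give zero differences
  same <- compare_conditions(free, free, n_boot = 0)
  expect_true(all(same$delta_mo == 0))
  expect_true(all(same$delta_max_order == 0))
})

test_that("single-replicate tables flag CIs unavailable and misalignment errors", {
  t1 <- bin_and_average(
    simulate_lilbid_timeseries(kinetics_ground_truth(), seq(0, 100, 5),
                               replicates = 1), 10)
  cmp <- compare_conditions(t1, t1, n_boot = 50)
  expect_false(attr(cmp, "replicate_ci"))
  expect_true(all(is.na(cmp$delta_mo_lo)))
  t2 <- bin_and_average(
    simulate_lilbid_timeseries(kinetics_ground_truth(), seq(0, 60, 5),
                               replicates = 1), 10)
  expect_error(compare_conditions(t1, t2), "misaligned")
})

test_that("kinetics CSV round-trips with its condition tag", {
  kt <- simulate_lilbid_timeseries(kinetics_ground_truth(inhibitor = TRUE),
                                   seq(0, 50, 10), replicates = 2)
  path <- tempfile(fileext = ".csv")
  write_kinetics(kt, path)
  back <- read_kinetics(path)
  expect_equal(attr(back, "condition"), "+inhibitor")
  expect_equal(back$I_2, kt$I_2, tolerance = 1e-9)
  unlink(path)
})
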