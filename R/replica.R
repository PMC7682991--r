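## End-to-end replica workflow on synthetic fixtures: simulate -> assign ->
## calibrate -> growth fit -> CIU/CID -> kinetics -> structure CCS, with a
## single structured report. Serves as the orchestration layer; each stage
## is the exported module function.

#' Configuration for the replica workflow
#'
#' All stage parameters with their defaults, a master seed, and the
#' convention switches. The effective configuration is echoed into the
#' report so every tolerance and seed is logged.
#'
#' @param seed Master seed; all stage seeds derive from it.
#' @param peptide Monomer sequence (default the Abeta42 sequence).
#' @param n_max Largest oligomer order simulated/assigned.
#' @param noise_sigma Multiplicative noise fraction for all generators.
#' @param mz_tolerance Assignment m/z tolerance (Th).
#' @param min_snr Feature-detection SNR threshold.
#' @param drift_excess_ms Conformer-grouping extension threshold (ms).
#' @param edc_coefficient TWIMS EDC coefficient.
#' @param db_present Simulate the DB conformer family (FALSE emulates the
#'   F19P / inhibitor-bound case where the DB channel is absent).
#' @param inhibitor Run the kinetics stage with the inhibitor ground truth.
#' @param mass_convention m/z convention for simulation and assignment.
#' @param mo_denominator M/O denominator convention.
#' @param out_dir Optional directory for CSV/JSON stage outputs.
#' @return A list of class `"replica_config"`.
#' @export
replica_config <- function(seed = 1L, peptide = ABETA42_SEQUENCE,
                           n_max = 6L, noise_sigma = 0.02,
                           mz_tolerance = 0.1, min_snr = 3,
                           drift_excess_ms = 4, edc_coefficient = 1.41,
                           db_present = TRUE, inhibitor = FALSE,
                           mass_convention = "monoisotopic",
                           mo_denominator = "n_ge_1", out_dir = NULL) {
  structure(as.list(environment()), class = "replica_config")
}

## Synthetic drift-time ladder used by the replica: MB below DB, both
## growing with order, anchored at the observed dimer values 8 / 11 ms.
replica_drift_truth <- function(n) {
  list(MB = 8 + 1.5 * (n - 2), DB = 11 + 1.5 * (n - 2))
}

#' Run the end-to-end replica workflow
#'
#' Generates synthetic fixtures at the configured noise level and chains
#' all analysis stages: driftscope assignment per oligomer, power-law CCS
#' calibration (synthetic calibrant ladder), MB/DB growth fits with
#' crossover detection and the slope/intercept comparison, CIU/CID
#' transition fits with the energy-gap analysis and a free-vs-bound
#' comparison, M/O kinetics with and without the inhibitor, and the toy
#' fibril PA-CCS series. Deterministic for a fixed seed.
#'
#' @param config A [replica_config()].
#' @return A list of class `"replica_report"` with one entry per stage and
#'   the echoed configuration. Any stage failure aborts with a
#'   stage-tagged error.
#' @export
run_replica <- function(config = replica_config()) {
  stopifnot(inherits(config, "replica_config"))
  report <- list(config = unclass(config)[setdiff(names(config), "out_dir")])
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  comp <- composition_from_sequence(config$peptide)
  m1 <- monoisotopic_mass(comp)

  ## --- assignment stage: one narrow frame per oligomer ------------------
  report$assignment <- stage("assign", {
    rows <- list()
    for (n in 2:config$n_max) {
      z <- n + 3L  # one representative charge state per order
      ion <- ion_species(comp, n, z)
      mz0 <- mz_of_species(ion, config$mass_convention)
      dt <- replica_drift_truth(n)
      confs <- if (config$db_present) {
        species_spec(ion, drift_ms = c(dt$MB, dt$DB),
                     abundance = c(1, 0.8), conformer = c("MB", "DB"))
      } else {
        species_spec(ion, drift_ms = dt$MB, abundance = 1, conformer = "MB")
      }
      frame <- simulate_driftscope(
        list(confs),
        mz_grid = seq(mz0 - 3, mz0 + 6, by = 0.01),
        drift_grid = seq(1, 30, by = 0.1),
        noise = noise_model(config$noise_sigma, baseline = 0,
                            seed = config$seed + 100L + n),
        resolving_power = 60000,  # isotope resolution out to the hexamer
        mass_convention = config$mass_convention)
      feats <- detect_features(frame, min_snr = config$min_snr)
      feats <- assign_species(feats, comp, n_max = config$n_max + 3L,
                              mz_tolerance = config$mz_tolerance)
      feats <- group_conformers(feats, drift_excess_ms = config$drift_excess_ms)
      rows[[length(rows) + 1]] <- as.data.frame(feats)
    }
    do.call(rbind, rows)
  })

  ## --- calibration stage: synthetic power-law calibrant ladder ----------
  report$calibration <- stage("calibrate", {
    A <- 400; B <- 0.55
    td <- seq(4, 16, length.out = 8)
    zc <- rep(c(7, 8, 9, 10), 2)
    mc <- rep(c(8560, 12360, 16950, 8560), 2)
    mzc <- (mc + zc * PROTON_MASS) / zc
    tp <- corrected_drift(td, mzc, config$edc_coefficient)
    omega_red <- A * tp^B
    ccs_lit <- omega_red * zc * sqrt(1 / mc + 1 / N2_MASS)
    ## synthetic calibrant table (not literature values)
    entries <- calibrant_table(sprintf("cal%02d", seq_along(td)), zc, mc,
                               ccs_lit, td)
    fit <- fit_calibration(entries, edc_coefficient = config$edc_coefficient)
    fit
  })

  ## --- growth stage: calibrated MB/DB CCS series ------------------------
  report$growth <- stage("growth", {
    assigned <- report$assignment[!is.na(report$assignment$n), ]
    cal <- apply_calibration(report$calibration, assigned, comp,
                             td_sigma_ms = 0.05,
                             mass_convention = config$mass_convention)
    mb <- ccs_series_from_features(cal, "MB")
    out <- list(mb_series = as.data.frame(mb))
    out$mb_fit <- fit_linear(mb, n_min = 2)
    if (config$db_present) {
      db <- ccs_series_from_features(cal, "DB")
      out$db_series <- as.data.frame(db)
      out$comparison <- compare_series(mb, db)
      out$db_absent <- FALSE
    } else {
      out$db_absent <- TRUE
    }
    ## crossover on a two-regime series at the experimental scale
    series <- two_regime_series(n_star = 4, seed = config$seed + 300L,
                                sigma_frac = config$noise_sigma)
    out$crossover <- detect_crossover(series)
    out
  })

  ## --- CIU/CID stage ----------------------------------------------------
  report$ciu <- stage("ciu", {
    ladder <- data.frame(n = 2:7, e50 = c(85, 185, 285, 335, 385, 435))
    fits <- lapply(seq_len(nrow(ladder)), function(i) {
      z <- ladder$n[i] + 3L
      volts <- seq(5, ceiling(ladder$e50[i] * 1.8 / z / 5) * 5, by = 5)
      truth <- ciu_ground_truth(e50_ciu = ladder$e50[i], width_ciu = 10,
                                e50_cid = ladder$e50[i] * 2.5, width_cid = 20)
      curve <- simulate_ciu_series(truth, volts, z = z,
                                   noise = noise_model(config$noise_sigma,
                                                       seed = config$seed + 400L + i))
      fit_transition(curve, "CIU", n_boot = 50L, seed = config$seed + 500L + i)
    })
    e50_tab <- data.frame(n = ladder$n,
                          e50 = vapply(fits, `[[`, numeric(1), "e50"))
    ## free vs CLR01-bound dimer: cap-limited unfolding, slightly higher CID
    free_truth <- ciu_ground_truth(e50_ciu = 85, width_ciu = 10,
                                   e50_cid = 125, width_cid = 10)
    bound_truth <- ciu_ground_truth(e50_ciu = 85, width_ciu = 10,
                                    e50_cid = 135, width_cid = 10, cap = 0.15)
    volts <- seq(5, 50, by = 5)
    free_c <- simulate_ciu_series(free_truth, volts, z = 5L,
                                  noise = noise_model(config$noise_sigma,
                                                      seed = config$seed + 600L))
    bound_c <- simulate_ciu_series(bound_truth, volts, z = 5L,
                                   noise = noise_model(config$noise_sigma,
                                                       seed = config$seed + 601L))
    attr(bound_c, "ligand") <- "CLR01"
    free_ciu <- fit_transition(free_c, "CIU", n_boot = 50L, seed = config$seed + 610L)
    bound_ciu <- fit_transition(bound_c, "CIU", n_boot = 50L, seed = config$seed + 611L)
    free_cid <- fit_transition(free_c, "CID", n_boot = 50L, seed = config$seed + 612L)
    bound_cid <- fit_transition(bound_c, "CID", n_boot = 50L, seed = config$seed + 613L)
    list(e50_table = e50_tab,
         gap = gap_analysis(e50_tab),
         bound_free_ciu = compare_bound_free(free_ciu, bound_ciu),
         bound_free_cid = compare_bound_free(free_cid, bound_cid),
         bound_cap = bound_ciu$cap, bound_cap_limited = bound_ciu$cap_limited)
  })

  ## --- kinetics stage ---------------------------------------------------
  report$kinetics <- stage("kinetics", {
    free_truth <- kinetics_ground_truth(inhibitor = FALSE)
    inh_truth <- kinetics_ground_truth(inhibitor = TRUE)
    noise_f <- noise_model(config$noise_sigma, seed = config$seed + 700L)
    noise_i <- noise_model(config$noise_sigma, seed = config$seed + 701L)
    free_raw <- simulate_lilbid_timeseries(free_truth, noise = noise_f)
    free_b <- bin_and_average(free_raw, 10, collapse_replicates = FALSE)
    last <- function(tab) {
      sel <- tab[tab$time_min == max(tab$time_min), intensity_columns(tab)]
      colMeans(sel)
    }
    out <- list(
      mo_free = vapply(sort(unique(free_b$time_min)), function(t) {
        m_over_o(colMeans(free_b[free_b$time_min == t, intensity_columns(free_b)]),
                 config$mo_denominator)
      }, numeric(1)),
      times = sort(unique(free_b$time_min)),
      max_order_free = max_order_present(last(free_b))$n_max_observed
    )
    if (config$inhibitor) {
      inh_raw <- simulate_lilbid_timeseries(inh_truth, noise = noise_i)
      inh_b <- bin_and_average(inh_raw, 10, collapse_replicates = FALSE)
      out$comparison <- compare_conditions(free_b, inh_b, n_boot = 50L,
                                           seed = config$seed + 710L,
                                           denominator = config$mo_denominator)
      out$max_order_inhibited <- max_order_present(last(inh_b))$n_max_observed
    }
    out
  })

  ## --- structure stage --------------------------------------------------
  report$structure <- stage("structure", {
    pdb_path <- tempfile(fileext = ".pdb")
    on.exit(unlink(pdb_path), add = TRUE)
    make_toy_fibril_pdb(5, "DB", pdb_path)
    fibril <- read_structure(pdb_path)
    lm5 <- toy_layer_map(5, "DB")
    mb <- ccs_series_from_fibril(fibril, "MB", 1:5, lm5,
                                 n_orientations = 60L, n_rays = 1500L,
                                 seed = config$seed + 800L)
    db <- ccs_series_from_fibril(fibril, "DB", seq(2, 10, by = 2), lm5,
                                 n_orientations = 60L, n_rays = 1500L,
                                 seed = config$seed + 801L)
    list(mb_series = as.data.frame(mb), db_series = as.data.frame(db),
         mb_fit = suppressWarnings(fit_linear(mb, n_min = 2)),
         db_fit = suppressWarnings(fit_linear(db, n_min = 2)))
  })

  class(report) <- "replica_report"
  if (!is.null(config$out_dir)) write_replica_report(report, config$out_dir)
  report
}

#' Two-regime synthetic CCS series
#'
#' Builds the constructed crossover fixture: isotropic growth up to
#' `n_star`, then linear growth continuing from the crossover value with a
#' distinctly steeper per-monomer increment (fibrillar stacking adds more
#' cross-section per subunit than the flattening isotropic curve), with
#' multiplicative Gaussian noise.
#'
#' @param n_star Crossover order (default 4).
#' @param n_max Largest order (default 9).
#' @param ccs_ref Dimer reference CCS (default 900 Angstrom^2).
#' @param slope Linear-branch CCS increment per monomer (default 520
#'   Angstrom^2, about twice the isotropic tangent at the crossover so the
#'   regimes separate cleanly at the few-percent noise level).
#' @param sigma_frac Noise fraction of each CCS value (default 0.02);
#'   also used as the series' sigma.
#' @param seed RNG seed; `NULL` for a noiseless series.
#' @return A [ccs_series()] over orders 2..n_max.
#' @export
two_regime_series <- function(n_star = 4, n_max = 9, ccs_ref = 900,
                              slope = 520, sigma_frac = 0.02, seed = NULL) {
  n <- 2:n_max
  iso <- isotropic_model(n, 2, ccs_ref)
  at_star <- isotropic_model(n_star, 2, ccs_ref)
  ccs <- ifelse(n <= n_star, iso, at_star + slope * (n - n_star))
  if (!is.null(seed)) {
    ccs <- with_seed(seed, ccs * (1 + sigma_frac * stats::rnorm(length(ccs))))
  }
  ccs_series(n, ccs, sigma = pmax(sigma_frac, 1e-6) * ccs, tag = "DB")
}

#' @export
print.replica_report <- function(x, ...) {
  cat("replica report\n")
  cat(sprintf("  assignment: %d features, %d assigned\n",
              nrow(x$assignment), sum(!is.na(x$assignment$n))))
  cat(sprintf("  calibration R^2 = %.6f\n", x$calibration$r2))
  if (isTRUE(x$growth$db_absent)) {
    cat("  growth: DB absent; MB-only fit\n")
  } else {
    cat(sprintf("  growth: Delta-slope %.3g, Delta-intercept %.3g\n",
                x$growth$comparison$delta_slope, x$growth$comparison$delta_intercept))
  }
  if (x$growth$crossover$crossover) {
    cat(sprintf("  crossover n* = %d\n", x$growth$crossover$n_star))
  }
  cat(sprintf("  gap regimes: %.1f eV then %.1f eV (breakpoint n = %s)\n",
              x$ciu$gap$gap_lower, x$ciu$gap$gap_upper,
              ifelse(x$ciu$gap$degenerate, "none", x$ciu$gap$breakpoint)))
  if (!is.null(x$kinetics$max_order_inhibited)) {
    cat(sprintf("  kinetics: final max order free %d, inhibited %d\n",
                x$kinetics$max_order_free, x$kinetics$max_order_inhibited))
  }
  invisible(x)
}

#' Write a replica report's tables to disk
#'
#' Emits the figure-analog outputs (assigned features, CCS-vs-n tables,
#' E50 table, M/O curve) as CSV plus a JSON summary.
#'
#' @param report A `"replica_report"`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_replica_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    features = file.path(dir, "features.csv"),
    e50 = file.path(dir, "e50_by_order.csv"),
    mo = file.path(dir, "mo_curve.csv"),
    summary = file.path(dir, "summary.json")
  )
  utils::write.csv(report$assignment, paths["features"], row.names = FALSE)
  utils::write.csv(report$ciu$e50_table, paths["e50"], row.names = FALSE)
  utils::write.csv(data.frame(time_min = report$kinetics$times,
                              mo = report$kinetics$mo_free),
                   paths["mo"], row.names = FALSE)
  summary <- list(
    calibration_r2 = report$calibration$r2,
    crossover_n = report$growth$crossover$n_star,
    gap_lower = report$ciu$gap$gap_lower,
    gap_upper = report$ciu$gap$gap_upper,
    gap_breakpoint = report$ciu$gap$breakpoint,
    db_absent = isTRUE(report$growth$db_absent),
    max_order_free = report$kinetics$max_order_free,
    max_order_inhibited = report$kinetics$max_order_inhibited
  )
  jsonlite::write_json(summary, paths["summary"], auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(paths)
}
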