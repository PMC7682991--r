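## Seeded synthetic-data generators emulating the instrument: driftscope
## frames, CE-ramped CIU/CID series, LILBID time courses and toy fibril
## structures. Defaults mirror the observed study conditions (dimer MB/DB
## drift centroids 8/11 ms, trap ramp 5-50 V in 5 V steps, 10-min kinetics
## bins over 200 min, 4 replicate spectra).

#' Noise model for synthetic data
#'
#' @param sigma Multiplicative Gaussian noise fraction (>= 0).
#' @param baseline Additive baseline level (same units as the intensities).
#' @param seed Integer random seed; identical seeds give bit-identical output.
#' @return A list of class `"noise_model"`.
#' @export
noise_model <- function(sigma = 0.02, baseline = 0, seed = 1L) {
  stopifnot(sigma >= 0, baseline >= 0)
  structure(list(sigma = sigma, baseline = baseline, seed = as.integer(seed)),
            class = "noise_model")
}

apply_noise <- function(x, noise) {
  if (is.null(noise)) return(x)
  y <- x * (1 + noise$sigma * stats::rnorm(length(x))) +
    noise$baseline * abs(stats::rnorm(length(x)))
  y[y < 0] <- 0
  if (is.matrix(x)) dim(y) <- dim(x)
  y
}

#' Species specification for the driftscope simulator
#'
#' One oligomer ion together with its drift-time conformers. By convention
#' the MB (monomer-based) family sits at smaller drift than the DB family,
#' with unfolded (extended) states beyond both.
#'
#' @param species An [ion_species()].
#' @param drift_ms Drift-time centroids (ms), one per conformer.
#' @param drift_width_ms Gaussian drift peak widths (sd, ms); recycled.
#' @param abundance Relative conformer abundances (>= 0); recycled.
#' @param conformer Labels from `"MB"`, `"DB"`, `"extended-MB"`,
#'   `"extended-DB"`; recycled.
#' @return A list of class `"species_spec"`.
#' @export
species_spec <- function(species, drift_ms, drift_width_ms = 0.4,
                         abundance = 1, conformer = "MB") {
  stopifnot(inherits(species, "ion_species"), all(abundance >= 0),
            all(drift_width_ms > 0))
  k <- length(drift_ms)
  structure(list(
    species = species,
    drift_ms = drift_ms,
    drift_width_ms = rep_len(drift_width_ms, k),
    abundance = rep_len(abundance, k),
    conformer = rep_len(conformer, k)
  ), class = "species_spec")
}

#' Simulate a driftscope frame
#'
#' Builds the 2D intensity map over (m/z, drift time) for a set of species.
#' Each conformer contributes a separable peak: the exact isotope pattern of
#' its n-mer ion along m/z (Gaussian peaks at the instrument's resolving
#' power) times a unit-sum Gaussian along drift, so the noiseless marginal
#' over drift reproduces the summed isotope envelopes exactly.
#'
#' @param specs List of [species_spec()] objects.
#' @param mz_grid,drift_grid Strictly increasing grids (Th, ms).
#' @param noise A [noise_model()] or `NULL` for noiseless output.
#' @param resolving_power m/z resolving power (FWHM-based), default 20000.
#' @param mass_convention Mass convention for peak positions.
#' @return A [driftscope_frame()] whose metadata records the seed and the
#'   per-conformer ground truth.
#' @export
simulate_driftscope <- function(specs, mz_grid, drift_grid, noise = NULL,
                                resolving_power = 20000,
                                mass_convention = "monoisotopic") {
  stop_if_not_increasing(mz_grid, "mz_grid")
  stop_if_not_increasing(drift_grid, "drift_grid")
  if (!length(specs)) stop("specs must be non-empty")
  if (inherits(specs, "species_spec")) specs <- list(specs)

  intensity <- matrix(0, nrow = length(mz_grid), ncol = length(drift_grid))
  truth <- list()
  for (sp in specs) {
    ion <- sp$species
    comp_n <- nmer_composition(ion$composition, ion$n)
    pat <- isotope_pattern(comp_n, z = ion$z, n_peaks = 40L)
    if (mass_convention == "average") {
      ## recentre the envelope on the average-mass m/z, keeping spacings
      pat$mz <- pat$mz + (mz_of_species(ion, "average") - sum(pat$mz * pat$abundance))
    }
    if (min(pat$mz) < min(mz_grid) || max(pat$mz) > max(mz_grid)) {
      stop(sprintf("isotope envelope of species n=%d z=%d falls outside mz_grid [%.2f, %.2f]",
                   ion$n, ion$z, min(mz_grid), max(mz_grid)))
    }
    mz_profile <- numeric(length(mz_grid))
    for (p in seq_len(nrow(pat))) {
      sd_mz <- fwhm_to_sd(pat$mz[p] / resolving_power)
      mz_profile <- mz_profile + pat$abundance[p] * grid_gaussian(mz_grid, pat$mz[p], sd_mz)
    }
    for (k in seq_along(sp$drift_ms)) {
      dt_profile <- grid_gaussian(drift_grid, sp$drift_ms[k], sp$drift_width_ms[k])
      intensity <- intensity + sp$abundance[k] * (mz_profile %o% dt_profile)
      truth[[length(truth) + 1]] <- data.frame(
        n = ion$n, z = ion$z, drift_ms = sp$drift_ms[k],
        abundance = sp$abundance[k], conformer = sp$conformer[k]
      )
    }
  }
  if (!is.null(noise)) {
    intensity <- with_seed(noise$seed, apply_noise(intensity, noise))
  }
  driftscope_frame(mz_grid, drift_grid, intensity,
                   meta = list(seed = if (is.null(noise)) NA_integer_ else noise$seed,
                               source = "simulate_driftscope",
                               truth = do.call(rbind, truth)))
}

#' Ground truth for a CIU/CID simulation
#'
#' @param e50_ciu Unfolding midpoint (eV, lab frame).
#' @param width_ciu Logistic width of the unfolding transition (eV).
#' @param e50_cid Dissociation midpoint (eV, lab frame).
#' @param width_cid Logistic width of the dissociation transition (eV).
#' @param cap Maximum unfolded fraction among surviving ions, in (0, 1].
#' @return A list of class `"ciu_ground_truth"`.
#' @export
ciu_ground_truth <- function(e50_ciu = 85, width_ciu = 10,
                             e50_cid = 125, width_cid = 10, cap = 1) {
  stopifnot(width_ciu > 0, width_cid > 0, e50_ciu > 0, e50_cid > 0,
            cap > 0, cap <= 1)
  structure(list(e50_ciu = e50_ciu, width_ciu = width_ciu,
                 e50_cid = e50_cid, width_cid = width_cid, cap = cap),
            class = "ciu_ground_truth")
}

logistic_rise <- function(x, mid, width) 1 / (1 + exp(-(x - mid) / width))

#' Simulate a CE-ramped CIU/CID series
#'
#' Converts trap voltages to lab-frame energy (E = z * V) and emits the
#' compact / extended / dissociated fractions at each energy. The extended
#' fraction among survivors follows a rising logistic capped at
#' `truth$cap`; total survival follows a declining logistic.
#'
#' @param truth A [ciu_ground_truth()].
#' @param trap_voltages Increasing positive trap collision voltages (V);
#'   default the 5-50 V ramp in 5 V steps.
#' @param z Charge state of the ion.
#' @param noise A [noise_model()] or `NULL`.
#' @return A [stability_curve()] with columns `energy_ev`, `compact`,
#'   `extended`, `dissociated`.
#' @export
simulate_ciu_series <- function(truth, trap_voltages = seq(5, 50, by = 5),
                                z = 5L, noise = NULL) {
  stopifnot(inherits(truth, "ciu_ground_truth"), all(trap_voltages > 0))
  stop_if_not_increasing(trap_voltages, "trap_voltages")
  E <- lab_frame_energy(trap_voltages, z)
  unfolded_cond <- truth$cap * logistic_rise(E, truth$e50_ciu, truth$width_ciu)
  survival <- 1 - logistic_rise(E, truth$e50_cid, truth$width_cid)
  compact <- survival * (1 - unfolded_cond)
  extended <- survival * unfolded_cond
  dissociated <- 1 - survival
  if (!is.null(noise)) {
    frac <- with_seed(noise$seed, {
      cbind(apply_noise(compact, noise), apply_noise(extended, noise),
            apply_noise(dissociated, noise))
    })
    tot <- rowSums(frac)
    frac[tot > 1, ] <- frac[tot > 1, ] / tot[tot > 1]
    compact <- frac[, 1]; extended <- frac[, 2]; dissociated <- frac[, 3]
  }
  stability_curve(energy_ev = E, compact = compact, extended = extended,
                  dissociated = dissociated,
                  species = sprintf("z=%d", z), ligand = "free",
                  meta = list(seed = if (is.null(noise)) NA_integer_ else noise$seed,
                              truth = truth, trap_voltages = trap_voltages, z = z))
}

#' Ground truth for the LILBID kinetics simulator
#'
#' Parameters of the deterministic mass-action assembly chain used as a
#' stand-in for the empirical aggregation time course: monomers add to the
#' growing oligomer one at a time, with the dimerization step split between
#' a DB (planar-dimer) channel and an MB channel. An inhibitor suppresses
#' the DB channel and caps the attainable oligomer order.
#'
#' @param monomer_pool Initial monomer concentration (arbitrary units).
#' @param rate Dimerization rate constant (per unit concentration per min).
#' @param elongation Ratio of the monomer-addition (elongation) rate to the
#'   dimerization rate; values above 1 make growth nucleation-limited, so
#'   high orders appear while monomer remains (default 40).
#' @param n_max Largest oligomer order carried by the model.
#' @param db_weight Fraction of dimerization flux through the DB channel.
#' @param inhibitor Logical; apply the inhibitor effects below.
#' @param db_suppression Multiplier (in \[0, 1\]) on the DB-channel rate when
#'   the inhibitor is present.
#' @param order_cap Largest order formed when the inhibitor is present.
#' @return A list of class `"kinetics_ground_truth"`.
#' @export
kinetics_ground_truth <- function(monomer_pool = 100, rate = 2e-5,
                                  elongation = 40, n_max = 12L,
                                  db_weight = 0.6,
                                  inhibitor = FALSE, db_suppression = 0.05,
                                  order_cap = 6L) {
  stopifnot(monomer_pool > 0, rate >= 0, elongation > 0, n_max >= 2,
            db_weight >= 0, db_weight <= 1,
            db_suppression >= 0, db_suppression <= 1, order_cap >= 1)
  structure(list(monomer_pool = monomer_pool, rate = rate,
                 elongation = elongation,
                 n_max = as.integer(n_max), db_weight = db_weight,
                 inhibitor = inhibitor, db_suppression = db_suppression,
                 order_cap = as.integer(order_cap)),
            class = "kinetics_ground_truth")
}

kinetics_ode <- function(t, state, p) {
  I <- state
  n_max <- length(I)
  ## dimerization rate: DB channel suppressed by the inhibitor
  k2 <- p$rate * (p$db_weight * p$db_sup + (1 - p$db_weight))
  ## elongation (monomer addition onto n >= 2) is faster than nucleation
  grow_to <- rep(p$rate * p$elongation, n_max)  # rate of step n-1 -> n
  grow_to[2] <- k2
  if (p$cap < n_max) grow_to[seq.int(p$cap + 1L, n_max)] <- 0
  dI <- numeric(n_max)
  ## monomer consumed by dimerization (2 per event) and by each addition
  add_flux <- grow_to[-1] * I[1] * I[-n_max]   # flux n -> n+1 for n = 1..n_max-1
  dI[1] <- -2 * add_flux[1] - sum(add_flux[-1])
  for (n in 2:n_max) {
    dI[n] <- add_flux[n - 1] - (if (n < n_max) add_flux[n] else 0)
  }
  list(dI)
}

#' Simulate a LILBID aggregation time course
#'
#' Integrates the deterministic mass-action chain of
#' [kinetics_ground_truth()] with `deSolve` and emits per-timepoint,
#' per-replicate oligomer intensity vectors. The noiseless trajectory
#' conserves total peptide mass (sum of n * I_n).
#'
#' @param truth A [kinetics_ground_truth()].
#' @param timepoints Increasing sampling times (min); default 0-200 min
#'   every 2 min.
#' @param replicates Replicate spectra per timepoint (default 4).
#' @param noise A [noise_model()] or `NULL`.
#' @return A [kinetics_table()] with one row per (timepoint, replicate).
#' @export
simulate_lilbid_timeseries <- function(truth, timepoints = seq(0, 200, by = 2),
                                       replicates = 4L, noise = NULL) {
  stopifnot(inherits(truth, "kinetics_ground_truth"), replicates >= 1)
  stop_if_not_increasing(timepoints, "timepoints")
  n_max <- truth$n_max
  p <- list(rate = truth$rate, elongation = truth$elongation,
            db_weight = truth$db_weight,
            db_sup = if (truth$inhibitor) truth$db_suppression else 1,
            cap = if (truth$inhibitor) truth$order_cap else n_max)
  y0 <- c(truth$monomer_pool, numeric(n_max - 1))
  times <- if (timepoints[1] == 0) timepoints else c(0, timepoints)
  sol <- deSolve::ode(y = y0, times = times, func = kinetics_ode, parms = p,
                      method = "lsoda", rtol = 1e-10, atol = 1e-12)
  sol <- sol[match(timepoints, sol[, "time"]), -1, drop = FALSE]
  rows <- do.call(rbind, lapply(seq_len(replicates), function(r) sol))
  out <- data.frame(
    time_min = rep(timepoints, times = replicates),
    replicate = rep(seq_len(replicates), each = length(timepoints))
  )
  imat <- rows
  if (!is.null(noise)) {
    imat <- with_seed(noise$seed, apply_noise(rows, noise))
  }
  colnames(imat) <- paste0("I_", seq_len(n_max))
  out <- cbind(out, as.data.frame(imat))
  out <- out[order(out$time_min, out$replicate), ]
  rownames(out) <- NULL
  kinetics_table(out,
                 condition = if (truth$inhibitor) "+inhibitor" else "free",
                 meta = list(seed = if (is.null(noise)) NA_integer_ else noise$seed,
                             truth = truth))
}

## --- toy fibril structures -----------------------------------------------

## Fixed S-shaped C-alpha trace (xy-plane, Angstrom): two joined half-turns,
## a rigid stand-in for the S-shaped amyloid monomer fold.
s_shape_template <- function() {
  t1 <- seq(pi / 2, -pi / 2, length.out = 8)
  t2 <- seq(pi / 2, 3 * pi / 2, length.out = 8)
  r <- 6
  xy <- rbind(
    cbind(r * cos(t1), r + r * sin(t1)),
    cbind(r * cos(t2), -r + r * sin(t2))[-1, ]
  )
  cbind(xy, 0)
}

#' Write a toy fibril structure as PDB text
#'
#' Builds a rigid stack of S-shaped dummy monomers (C-alpha-only carbon
#' traces, 4.7 Angstrom inter-layer rise). With `base = "DB"` each layer
#' holds a C2-symmetric pair of monomers (two protofilaments), mirroring a
#' dimer-based fibril; with `base = "MB"` a single protofilament.
#'
#' @param n_layers Number of stacked layers (>= 1).
#' @param base `"MB"` (one monomer per layer) or `"DB"` (two).
#' @param path Optional file path; when given the text is written there.
#' @return Invisibly, the PDB text as a character vector (one line per
#'   record). Chain identifiers are `A`, `B`, ... in layer-major order.
#' @export
make_toy_fibril_pdb <- function(n_layers, base = c("MB", "DB"), path = NULL) {
  base <- match.arg(base)
  stopifnot(n_layers >= 1, n_layers == round(n_layers))
  template <- s_shape_template()
  rise <- 4.7
  lines <- character(0)
  serial <- 0L
  chain_idx <- 0L
  for (layer in seq_len(n_layers)) {
    copies <- if (base == "DB") 2L else 1L
    for (p in seq_len(copies)) {
      chain_idx <- chain_idx + 1L
      xyz <- template
      if (p == 2L) {  # C2 rotation about the fibril (z) axis, then offset
        xyz[, 1] <- -xyz[, 1]
        xyz[, 2] <- -xyz[, 2]
        xyz[, 1] <- xyz[, 1] + 16
      }
      xyz[, 3] <- xyz[, 3] + (layer - 1) * rise
      chain <- LETTERS[(chain_idx - 1L) %% 26 + 1L]
      for (a in seq_len(nrow(xyz))) {
        serial <- serial + 1L
        lines <- c(lines, sprintf(
          "ATOM  %5d  CA  ALA %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
          serial, chain, a, xyz[a, 1], xyz[a, 2], xyz[a, 3]))
      }
    }
  }
  lines <- c(lines, "END")
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Layer map for a toy fibril
#'
#' Chain-to-layer bookkeeping matching [make_toy_fibril_pdb()]'s chain
#' order, as consumed by [crop_oligomer()].
#' @inheritParams make_toy_fibril_pdb
#' @return Data frame with columns `chain`, `layer`, `protofilament`.
#' @export
toy_layer_map <- function(n_layers, base = c("MB", "DB")) {
  base <- match.arg(base)
  copies <- if (base == "DB") 2L else 1L
  n_chain <- n_layers * copies
  data.frame(
    chain = LETTERS[(seq_len(n_chain) - 1L) %% 26 + 1L],
    layer = rep(seq_len(n_layers), each = copies),
    protofilament = rep(seq_len(copies), times = n_layers)
  )
}
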