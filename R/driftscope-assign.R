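## Driftscope frames and the isotope-resolved assignment stage: feature
## detection on the (m/z x drift) map, charge from isotope spacing, oligomer
## order from m/z, and conformer grouping into MB / DB / extended families.

#' A driftscope frame
#'
#' Intensity over an (m/z grid x drift-time grid), the central raw-data
#' object of the pipeline.
#'
#' @param mz m/z grid (Th), strictly increasing.
#' @param drift_ms Drift-time grid (ms), strictly increasing.
#' @param intensity Non-negative matrix, `length(mz)` rows by
#'   `length(drift_ms)` columns.
#' @param meta List of metadata (seed, source, ground truth, ...).
#' @return A list of class `"driftscope_frame"`.
#' @export
driftscope_frame <- function(mz, drift_ms, intensity, meta = list()) {
  stop_if_not_increasing(mz, "mz grid")
  stop_if_not_increasing(drift_ms, "drift grid")
  intensity <- as.matrix(intensity)
  if (nrow(intensity) != length(mz) || ncol(intensity) != length(drift_ms)) {
    stop("intensity matrix dimensions must match the grids")
  }
  if (any(intensity < 0)) stop("intensity must be non-negative")
  structure(list(mz = mz, drift_ms = drift_ms, intensity = intensity,
                 meta = meta), class = "driftscope_frame")
}

#' @export
print.driftscope_frame <- function(x, ...) {
  cat(sprintf("driftscope frame: %d m/z x %d drift points, m/z [%.2f, %.2f], drift [%.2f, %.2f] ms\n",
              length(x$mz), length(x$drift_ms), min(x$mz), max(x$mz),
              min(x$drift_ms), max(x$drift_ms)))
  invisible(x)
}

#' Write / read a driftscope frame as delimited text
#'
#' Tab-delimited matrix with `#`-prefixed `key=value` header lines carrying
#' the seed and the drift grid; the first column is the m/z grid.
#' @param frame A [driftscope_frame()].
#' @param path File path.
#' @export
write_driftscope <- function(frame, path) {
  con <- file(path, "w")
  on.exit(close(con))
  seed <- frame$meta$seed
  writeLines(c(
    sprintf("# seed=%s", if (is.null(seed) || is.na(seed)) "NA" else seed),
    sprintf("# source=%s", if (is.null(frame$meta$source)) "unknown" else frame$meta$source),
    sprintf("# drift_ms=%s", paste(format(frame$drift_ms, digits = 12), collapse = ","))
  ), con)
  tab <- cbind(mz = frame$mz, frame$intensity)
  utils::write.table(tab, con, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
}

#' @rdname write_driftscope
#' @export
read_driftscope <- function(path) {
  all_lines <- readLines(path)
  header <- grep("^#", all_lines, value = TRUE)
  get_val <- function(key) {
    hit <- grep(paste0("^# *", key, "="), header, value = TRUE)
    if (!length(hit)) return(NA_character_)
    sub(paste0("^# *", key, "="), "", hit[1])
  }
  drift <- as.numeric(strsplit(get_val("drift_ms"), ",")[[1]])
  tab <- utils::read.table(text = all_lines[!grepl("^#", all_lines)], sep = "\t")
  driftscope_frame(tab[[1]], drift, as.matrix(tab[, -1, drop = FALSE]),
                   meta = list(seed = suppressWarnings(as.integer(get_val("seed"))),
                               source = get_val("source")))
}

## Robust frame noise scale: mad of the positive-support matrix (zero-heavy
## frames fall back to a small fraction of the maximum).
frame_noise_scale <- function(intensity) {
  s <- stats::mad(intensity, center = stats::median(intensity))
  if (s <= 0) s <- max(intensity) * 1e-9 + .Machine$double.eps
  s
}

#' Detect 2D features in a driftscope frame
#'
#' Segments the m/z axis into signal windows (contiguous runs of the
#' drift-summed m/z profile above the noise floor), then finds local maxima
#' of each window's drift profile. Each feature carries its drift and m/z
#' profile extracts for downstream isotope-spacing estimation.
#'
#' @param frame A [driftscope_frame()].
#' @param min_snr Minimum peak signal-to-noise ratio (default 3).
#' @param min_separation_ms Minimum drift separation between features
#'   (default 1 ms).
#' @param mz_gap_th m/z gap (Th) below which signal regions are merged
#'   into one window (default 1.2, just above the widest isotopologue
#'   spacing so an isotope envelope stays in one window).
#' @return A data frame of class `"feature_table"` with one row per feature
#'   (columns `mz`, `drift_ms`, `intensity`, `window`) and attribute
#'   `profiles`: per-feature lists with `mz`, `mz_profile`, `drift`,
#'   `drift_profile`.
#' @export
detect_features <- function(frame, min_snr = 3, min_separation_ms = 1,
                            mz_gap_th = 1.2) {
  stopifnot(inherits(frame, "driftscope_frame"))
  empty <- data.frame(mz = numeric(0), drift_ms = numeric(0),
                      intensity = numeric(0), window = integer(0))
  attr(empty, "profiles") <- list()
  class(empty) <- c("feature_table", "data.frame")
  if (all(frame$intensity == 0)) return(empty)

  noise <- frame_noise_scale(frame$intensity)
  n_drift <- ncol(frame$intensity)
  ## m/z profile: drift-summed; its noise scale grows ~ sqrt(n_drift)
  mz_profile_all <- rowSums(frame$intensity)
  mz_thresh <- stats::median(mz_profile_all) + min_snr * noise * sqrt(n_drift)
  above <- mz_profile_all > mz_thresh
  if (!any(above)) return(empty)
  ## contiguous m/z windows; gaps smaller than mz_gap_th (the isotopologue
  ## spacing scale) are merged so one envelope gives one window
  r <- rle(above)
  idx_end <- cumsum(r$lengths)
  idx_start <- idx_end - r$lengths + 1L
  wins <- cbind(idx_start[r$values], idx_end[r$values])
  mz_step <- stats::median(diff(frame$mz))
  gap_pts <- max(3L, round(mz_gap_th / mz_step))
  if (nrow(wins) > 1) {
    merged <- list(wins[1, ])
    for (i in 2:nrow(wins)) {
      last <- merged[[length(merged)]]
      if (wins[i, 1] - last[2] <= gap_pts) {
        merged[[length(merged)]] <- c(last[1], wins[i, 2])
      } else merged[[length(merged) + 1]] <- wins[i, ]
    }
    wins <- do.call(rbind, merged)
  }

  drift_step <- stats::median(diff(frame$drift_ms))
  min_sep_pts <- max(1L, round(min_separation_ms / drift_step))
  rows <- list(); profiles <- list()
  for (w in seq_len(nrow(wins))) {
    ridx <- wins[w, 1]:wins[w, 2]
    dprof <- colSums(frame$intensity[ridx, , drop = FALSE])
    dnoise <- noise * sqrt(length(ridx))
    dbase <- stats::median(dprof)
    peaks <- local_maxima(dprof, min_sep_pts)
    peaks <- peaks[(dprof[peaks] - dbase) / dnoise >= min_snr]
    for (pk in peaks) {
      ## drift centroid: intensity-weighted mean over the peak's vicinity
      span <- max(1L, pk - min_sep_pts):min(length(dprof), pk + min_sep_pts)
      wgt <- pmax(dprof[span] - dbase, 0)
      d_centroid <- if (sum(wgt) > 0) sum(frame$drift_ms[span] * wgt) / sum(wgt)
                    else frame$drift_ms[pk]
      ## m/z profile at this conformer: rows of the window, drift columns near peak
      cid <- max(1L, pk - min_sep_pts):min(n_drift, pk + min_sep_pts)
      mzprof <- rowSums(frame$intensity[ridx, cid, drop = FALSE])
      mz_centroid <- sum(frame$mz[ridx] * mzprof) / sum(mzprof)
      rows[[length(rows) + 1]] <- data.frame(
        mz = mz_centroid, drift_ms = d_centroid,
        intensity = sum(frame$intensity[ridx, cid]), window = w
      )
      profiles[[length(profiles) + 1]] <- list(
        mz = frame$mz[ridx], mz_profile = mzprof,
        drift = frame$drift_ms, drift_profile = dprof
      )
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "profiles") <- profiles
  class(out) <- c("feature_table", "data.frame")
  out
}

local_maxima <- function(x, min_sep = 1L) {
  n <- length(x)
  if (n < 3) return(integer(0))
  cand <- which(x[2:(n - 1)] >= x[1:(n - 2)] & x[2:(n - 1)] > x[3:n]) + 1L
  if (!length(cand)) return(integer(0))
  cand <- cand[order(x[cand], decreasing = TRUE)]
  kept <- integer(0)
  for (c0 in cand) {
    if (!length(kept) || all(abs(kept - c0) >= min_sep)) kept <- c(kept, c0)
  }
  sort(kept)
}

#' Estimate isotope spacing of a feature's m/z profile
#'
#' Finds the periodic isotopologue spacing by the maximum of the profile's
#' autocorrelation over the physically plausible lag range
#' `[1.0034/z_max, 1.0034]` Th, with parabolic interpolation of the maximum
#' and an uncertainty from the autocorrelation peak curvature. Profiles with
#' fewer than three resolved isotope peaks are flagged unresolved.
#'
#' @param mz m/z grid of the profile (uniformly spaced).
#' @param intensity Intensity profile on that grid.
#' @param z_max Largest charge considered (default 20).
#' @return A list with `spacing` (Th), `se`, `resolved` (logical) and
#'   `n_peaks` (count of resolved isotope peaks).
#' @export
estimate_isotope_spacing <- function(mz, intensity, z_max = 20L) {
  stopifnot(length(mz) == length(intensity), length(mz) >= 8)
  step <- stats::median(diff(mz))
  y <- intensity - stats::median(intensity)
  thr <- 0.05 * max(y)
  pk <- local_maxima(y, min_sep = max(1L, floor((NEUTRON_SPACING / z_max / 2) / step)))
  pk <- pk[y[pk] > thr]
  if (length(pk) < 3) {
    return(list(spacing = NA_real_, se = NA_real_, resolved = FALSE,
                n_peaks = length(pk)))
  }
  lag_min <- max(2L, floor((NEUTRON_SPACING / z_max) / step * 0.8))
  lag_max <- min(length(y) - 2L, ceiling(NEUTRON_SPACING / step * 1.2))
  if (lag_max <= lag_min) {
    return(list(spacing = NA_real_, se = NA_real_, resolved = FALSE,
                n_peaks = length(pk)))
  }
  lags <- lag_min:lag_max
  ac <- vapply(lags, function(L) {
    a <- y[seq_len(length(y) - L)]
    b <- y[seq.int(L + 1L, length(y))]
    sum(a * b)
  }, numeric(1))
  i <- which.max(ac)
  ## parabolic interpolation around the discrete maximum
  if (i > 1 && i < length(ac)) {
    denom <- ac[i - 1] - 2 * ac[i] + ac[i + 1]
    delta <- if (denom < 0) 0.5 * (ac[i - 1] - ac[i + 1]) / denom else 0
    curv <- -denom / step^2
  } else {
    delta <- 0
    curv <- NA_real_
  }
  spacing <- (lags[i] + delta) * step
  se <- if (is.finite(curv) && curv > 0) sqrt(ac[i] / curv) / max(ac[i], 1) * step else step / 2
  list(spacing = spacing, se = se, resolved = TRUE, n_peaks = length(pk))
}

#' Assign oligomer order and charge to detected features
#'
#' The assignment logic: isotope spacing fixes the charge
#' (`z = round(1.0034 / spacing)`), then the oligomer order is the integer
#' minimizing the m/z residual against `mz_of_species(n, z)` within
#' `mz_tolerance`. Features whose isotopes are unresolved at an
#' m/z-degenerate position are flagged ambiguous with the full reduced-pair
#' candidate set rather than silently collapsed.
#'
#' @param features A feature table from [detect_features()].
#' @param peptide Monomer sequence string or [elemental_composition()].
#' @param n_max,z_max Search bounds for order and charge.
#' @param mz_tolerance Acceptance window on the m/z residual (Th).
#' @param mass_convention Mass convention for the theoretical m/z. The
#'   default `"average"` is correct for feature centroids, because the
#'   intensity-weighted centroid of an isotope envelope estimates the
#'   abundance-weighted (i.e. average-mass) m/z, not the monoisotopic one.
#' @return The feature table with columns `spacing`, `spacing_se`, `z`, `n`,
#'   `mz_residual` and `flags` added (`flags` is a `;`-separated string;
#'   empty when clean). Unassigned features are retained with `NA` order.
#' @export
assign_species <- function(features, peptide, n_max = 12L, z_max = 20L,
                           mz_tolerance = 0.1,
                           mass_convention = "average") {
  stopifnot(inherits(features, "feature_table"))
  comp <- if (is.character(peptide)) composition_from_sequence(peptide) else as_composition(peptide)
  profiles <- attr(features, "profiles")
  k <- nrow(features)
  features$spacing <- NA_real_; features$spacing_se <- NA_real_
  features$z <- NA_integer_; features$n <- NA_integer_
  features$mz_residual <- NA_real_; features$flags <- ""
  if (!k) return(features)

  theo_mz <- function(n, z) {
    mz_of_species(ion_species(comp, n, z), mass_convention)
  }
  for (i in seq_len(k)) {
    prof <- profiles[[i]]
    sp <- estimate_isotope_spacing(prof$mz, prof$mz_profile, z_max = z_max)
    if (sp$resolved) {
      features$spacing[i] <- sp$spacing
      features$spacing_se[i] <- sp$se
      z <- as.integer(round(NEUTRON_SPACING / sp$spacing))
      if (z < 1 || z > z_max) {
        features$flags[i] <- "charge-out-of-range"
        next
      }
      features$z[i] <- z
      resid <- vapply(seq_len(n_max), function(n) {
        abs(features$mz[i] - theo_mz(n, z))
      }, numeric(1))
      ok <- which(resid <= mz_tolerance)
      if (!length(ok)) {
        features$flags[i] <- "unassigned"
        next
      }
      if (length(ok) > 1) {
        features$flags[i] <- paste0("multiple-n-candidates:",
                                    paste(ok, collapse = ","))
      }
      n_best <- ok[which.min(resid[ok])]
      if (length(ok) > 1) n_best <- min(ok)  # tie-break: smaller n, warned above
      features$n[i] <- n_best
      features$mz_residual[i] <- features$mz[i] - theo_mz(n_best, z)
    } else {
      ## unresolved: enumerate reduced-pair multiples consistent with the m/z
      cands <- character(0)
      base <- NULL
      for (z in seq_len(z_max)) {
        for (n in seq_len(n_max)) {
          if (abs(features$mz[i] - theo_mz(n, z)) <= mz_tolerance) {
            if (is.null(base)) base <- c(n, z)
            cands <- c(cands, sprintf("%d/%d", n, z))
          }
        }
      }
      features$flags[i] <- if (length(cands) > 1) {
        paste0("ambiguous:", paste(unique(cands), collapse = ";"))
      } else if (length(cands) == 1) {
        paste0("unresolved-single:", cands)
      } else "unresolved"
    }
  }
  features
}

#' Group assigned features into conformer families
#'
#' Within each assigned (n, z) species, features are ordered by drift time.
#' Features within `drift_excess_ms` of the most compact one are the
#' structured states: the first is labeled MB (monomer-based, more compact)
#' and the second DB (dimer-based), following the interpretive convention
#' that the MB family drifts faster. Features beyond the excess threshold
#' are the unfolded states, labeled `extended-MB` / `extended-DB` in drift
#' order. A species with a single structured state is flagged `single` and
#' `db-missing`.
#'
#' @param features An assigned feature table from [assign_species()].
#' @param drift_excess_ms Drift excess over the most compact structured
#'   state beyond which a feature counts as extended (default 4 ms).
#' @return The feature table with a `conformer` column added and per-species
#'   flags amended.
#' @export
group_conformers <- function(features, drift_excess_ms = 4) {
  stopifnot(is.data.frame(features))
  if (!nrow(features)) {
    features$conformer <- character(0)
    return(features)
  }
  features$conformer <- NA_character_
  assigned <- !is.na(features$n) & !is.na(features$z)
  key <- paste(features$n, features$z)
  for (k in unique(key[assigned])) {
    idx <- which(assigned & key == k)
    idx <- idx[order(features$drift_ms[idx])]
    d0 <- features$drift_ms[idx[1]]
    structured <- idx[features$drift_ms[idx] - d0 <= drift_excess_ms]
    extended <- setdiff(idx, structured)
    labels <- c("MB", "DB")
    for (j in seq_along(structured)) {
      features$conformer[structured[j]] <- if (j <= 2) labels[j] else
        sprintf("structured-%d", j)
    }
    if (length(structured) == 1) {
      add <- "single;db-missing"
      features$flags[structured[1]] <- paste0(
        ifelse(nzchar(features$flags[structured[1]]),
               paste0(features$flags[structured[1]], ";"), ""), add)
    }
    ext_labels <- c("extended-MB", "extended-DB")
    for (j in seq_along(extended)) {
      features$conformer[extended[j]] <- if (j <= 2) ext_labels[j] else
        sprintf("extended-%d", j)
    }
  }
  features
}

#' Write an assigned feature table as CSV
#' @param features Feature table.
#' @param path Output path.
#' @export
write_features <- function(features, path) {
  utils::write.csv(as.data.frame(features), path, row.names = FALSE)
}
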