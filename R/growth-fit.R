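## Isotropic vs linear growth models over per-oligomer CCS series, regime
## crossover detection, and the MB/DB slope/intercept signature.

#' Per-oligomer CCS series
#'
#' @param n Oligomer orders, strictly increasing.
#' @param ccs_a2 Mean CCS per order (Angstrom^2), positive.
#' @param sigma Per-order CCS uncertainties; default 1 (unweighted).
#' @param tag Series tag: `"MB"`, `"DB"` or `"untagged"`.
#' @return Data frame of class `"ccs_series"`.
#' @export
ccs_series <- function(n, ccs_a2, sigma = 1, tag = "untagged") {
  stop_if_not_increasing(n, "oligomer orders")
  stopifnot(all(ccs_a2 > 0), all(sigma > 0))
  out <- data.frame(n = as.integer(n), ccs_a2 = ccs_a2,
                    sigma = rep_len(sigma, length(n)))
  attr(out, "tag") <- tag
  class(out) <- c("ccs_series", "data.frame")
  out
}

#' Average calibrated features into a CCS series
#'
#' One CCS per (oligomer order, conformer family): the mean over charge
#' states, with the standard deviation across charge states as sigma
#' (a single contributing charge state gets the propagated per-feature
#' uncertainty instead).
#'
#' @param features Calibrated feature table (from [apply_calibration()])
#'   with a `conformer` column.
#' @param conformer Which conformer family to collect (e.g. `"MB"`).
#' @return A [ccs_series()] tagged with the conformer.
#' @export
ccs_series_from_features <- function(features, conformer = "MB") {
  sel <- features[!is.na(features$conformer) & features$conformer == conformer &
                    !is.na(features$ccs_a2), ]
  if (!nrow(sel)) stop("no calibrated features for conformer ", conformer)
  agg <- lapply(split(sel, sel$n), function(g) {
    s <- if (nrow(g) > 1) stats::sd(g$ccs_a2) else g$ccs_sigma[1]
    if (!is.finite(s) || s <= 0) s <- max(g$ccs_a2 * 1e-3, 1e-6)
    data.frame(n = g$n[1], ccs_a2 = mean(g$ccs_a2), sigma = s)
  })
  agg <- do.call(rbind, agg)
  agg <- agg[order(agg$n), ]
  ccs_series(agg$n, agg$ccs_a2, agg$sigma, tag = conformer)
}

#' Isotropic growth model
#'
#' CCS of an n-mer growing isotropically (volume-to-area scaling):
#' `Omega(n) = Omega_ref * (n / n_ref)^(2/3)`. The reference is the dimer
#' by default.
#'
#' @param n Oligomer order(s).
#' @param n_ref Reference order (default 2).
#' @param ccs_ref Reference CCS (Angstrom^2).
#' @return Predicted CCS.
#' @export
isotropic_model <- function(n, n_ref = 2, ccs_ref) {
  stopifnot(all(n >= 1), n_ref >= 1, ccs_ref > 0)
  ccs_ref * (n / n_ref)^(2 / 3)
}

#' Weighted linear growth fit
#'
#' Weighted least squares (weights 1/sigma^2) of CCS on oligomer order over
#' orders `n >= n_min`, the linear (fibrillar) growth model.
#'
#' @param series A [ccs_series()].
#' @param n_min Smallest order entering the fit (default 2).
#' @return A list of class `"growth_fit"`: `slope` (Angstrom^2 per
#'   monomer), `intercept`, their covariance, residuals and the orders
#'   used. Two points give an interpolating line with a warning.
#' @export
fit_linear <- function(series, n_min = 2) {
  stopifnot(inherits(series, "ccs_series"))
  sel <- series[series$n >= n_min, ]
  if (nrow(sel) < 2) stop("need at least 2 points with n >= n_min")
  if (nrow(sel) == 2) warning("only 2 points: interpolating line, variance unavailable")
  fit <- stats::lm(ccs_a2 ~ n, data = sel, weights = 1 / sel$sigma^2)
  cf <- stats::coef(fit)
  vc <- if (nrow(sel) > 2) suppressWarnings(stats::vcov(fit)) else matrix(Inf, 2, 2)
  structure(list(slope = unname(cf[2]), intercept = unname(cf[1]),
                 vcov = vc, residuals = stats::residuals(fit),
                 n_used = sel$n, tag = attr(series, "tag")),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("linear growth fit [%s]: Omega = %.4g + %.4g * n  (orders %s)\n",
              x$tag, x$intercept, x$slope,
              paste(range(x$n_used), collapse = "-")))
  invisible(x)
}

#' @export
coef.growth_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
predict.growth_fit <- function(object, n, ...) {
  object$intercept + object$slope * n
}

#' Detect the isotropic-to-linear crossover order
#'
#' Finds the largest order n* such that every order m <= n* in the series
#' stays within `tolerance_sigma` standard deviations of the isotropic
#' model anchored at the reference order. The comparison uses the
#' propagated uncertainty `sqrt(sigma_m^2 + ((m/n_ref)^(2/3) sigma_ref)^2)`
#' because the anchored prediction inherits the reference order's noise.
#' Orders above n* must fit the linear model better (smaller absolute
#' residual than the isotropic model) or a no-crossover sentinel is
#' returned. A series consistent with the isotropic model throughout is
#' also reported as no-crossover.
#'
#' @param series A [ccs_series()] with at least 4 orders.
#' @param n_ref Reference order anchoring the isotropic curve (default 2);
#'   its CCS is taken from the series.
#' @param tolerance_sigma Tolerance multiplier (default 3, keeping the
#'   per-series false-violation rate below 1% across the low orders).
#' @return A list of class `"crossover"`: `n_star` (integer, or `NA` for
#'   no-crossover), `crossover` (logical), per-order residuals of both
#'   models, and the tolerance used.
#' @export
detect_crossover <- function(series, n_ref = 2, tolerance_sigma = 3) {
  stopifnot(inherits(series, "ccs_series"))
  if (nrow(series) < 4) stop("need at least 4 oligomer orders")
  ref_row <- which(series$n == n_ref)
  if (!length(ref_row)) stop("reference order n_ref not present in the series")
  iso <- isotropic_model(series$n, n_ref, series$ccs_a2[ref_row])
  resid_iso <- series$ccs_a2 - iso
  ## anchored prediction carries the reference point's uncertainty too
  sigma_pred <- sqrt(series$sigma^2 +
                       ((series$n / n_ref)^(2 / 3) * series$sigma[ref_row])^2)
  sigma_pred[ref_row] <- series$sigma[ref_row]
  ok_iso <- abs(resid_iso) <= tolerance_sigma * sigma_pred

  result <- function(n_star, crossed) {
    lin_resid <- rep(NA_real_, nrow(series))
    if (crossed) {
      above <- series$n > n_star
      if (sum(above) >= 2) {
        lf <- suppressWarnings(
          fit_linear(ccs_series(series$n[above], series$ccs_a2[above],
                                series$sigma[above]), n_min = 0))
        lin_resid[above] <- series$ccs_a2[above] - predict(lf, series$n[above])
        ## linear model must improve on the isotropic one above n*
        if (!all(abs(lin_resid[above]) < abs(resid_iso[above]))) {
          return(structure(list(n_star = NA_integer_, crossover = FALSE,
                                resid_isotropic = resid_iso,
                                resid_linear = lin_resid,
                                tolerance_sigma = tolerance_sigma),
                           class = "crossover"))
        }
      }
    }
    structure(list(n_star = if (crossed) as.integer(n_star) else NA_integer_,
                   crossover = crossed,
                   resid_isotropic = resid_iso, resid_linear = lin_resid,
                   tolerance_sigma = tolerance_sigma),
              class = "crossover")
  }

  if (all(ok_iso)) return(result(NA, FALSE))
  first_bad <- min(which(!ok_iso))
  if (first_bad == 1) return(result(series$n[1], TRUE))  # diverges immediately
  result(series$n[first_bad - 1], TRUE)
}

#' @export
print.crossover <- function(x, ...) {
  if (x$crossover) {
    cat(sprintf("growth regime crossover at n* = %d (tolerance %.3g sigma)\n",
                x$n_star, x$tolerance_sigma))
  } else cat("no growth-regime crossover detected\n")
  invisible(x)
}

#' Compare MB and DB growth fits (slope/intercept signature)
#'
#' Fits both series linearly over their common order range and reports the
#' slope and intercept differences with normal-approximation confidence
#' intervals. The dual-pathway signature is an indistinguishable slope
#' (same monomer stacking) with distinct intercepts (different growth
#' base): `Delta-slope` CI containing 0 while the `Delta-intercept` CI
#' excludes 0.
#'
#' @param mb,db Two [ccs_series()] objects with overlapping order ranges.
#' @param n_min Smallest order entering the fits (default 2).
#' @param level Confidence level (default 0.95).
#' @return A list of class `"series_comparison"` with `delta_slope`,
#'   `delta_intercept`, their CIs, and `signature` (logical).
#' @export
compare_series <- function(mb, db, n_min = 2, level = 0.95) {
  common <- intersect(mb$n[mb$n >= n_min], db$n[db$n >= n_min])
  if (length(common) < 2) stop("series share no overlapping order range")
  sub <- function(s) ccs_series(s$n[s$n %in% common], s$ccs_a2[s$n %in% common],
                                s$sigma[s$n %in% common], attr(s, "tag"))
  f1 <- fit_linear(sub(mb), n_min = 0)
  f2 <- fit_linear(sub(db), n_min = 0)
  q <- stats::qnorm(1 - (1 - level) / 2)
  ds <- f2$slope - f1$slope
  di <- f2$intercept - f1$intercept
  se_s <- sqrt(f1$vcov[2, 2] + f2$vcov[2, 2])
  se_i <- sqrt(f1$vcov[1, 1] + f2$vcov[1, 1])
  ci_s <- ds + c(-1, 1) * q * se_s
  ci_i <- di + c(-1, 1) * q * se_i
  ## negligibility floors guard against zero-variance exact fits, where a
  ## CI of machine-epsilon width can spuriously exclude zero
  eps_s <- 1e-8 * max(abs(f1$slope), abs(f2$slope))
  eps_i <- 1e-8 * max(abs(f1$intercept), abs(f2$intercept), 1)
  slope_equal <- (ci_s[1] <= 0 && ci_s[2] >= 0) || abs(ds) < eps_s
  intercept_distinct <- (ci_i[1] > eps_i || ci_i[2] < -eps_i)
  structure(list(
    delta_slope = ds, delta_intercept = di,
    ci_slope = ci_s, ci_intercept = ci_i,
    fit_mb = f1, fit_db = f2,
    signature = slope_equal && intercept_distinct
  ), class = "series_comparison")
}

#' @export
print.series_comparison <- function(x, ...) {
  cat(sprintf("Delta-slope = %.4g [%.4g, %.4g]; Delta-intercept = %.4g [%.4g, %.4g]\n",
              x$delta_slope, x$ci_slope[1], x$ci_slope[2],
              x$delta_intercept, x$ci_intercept[1], x$ci_intercept[2]))
  cat(if (x$signature) "MB/DB signature: equal slopes, distinct intercepts\n"
      else "MB/DB signature not detected\n")
  invisible(x)
}

#' Read / write a CCS series as CSV
#' @param series A [ccs_series()].
#' @param path CSV path (columns n, ccs_a2, sigma, tag).
#' @export
write_ccs_series <- function(series, path) {
  out <- as.data.frame(series)
  out$tag <- attr(series, "tag")
  utils::write.csv(out, path, row.names = FALSE)
}

#' @rdname write_ccs_series
#' @export
read_ccs_series <- function(path) {
  tab <- utils::read.csv(path)
  ccs_series(tab$n, tab$ccs_a2, tab$sigma,
             tag = if ("tag" %in% names(tab)) tab$tag[1] else "untagged")
}
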