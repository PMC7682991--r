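## CIU/CID transition analysis: lab-frame energy convention, logistic
## transition fits with a cap (amplitude) parameter, the two-segment
## energy-gap regime analysis, free-vs-bound comparisons and fingerprint
## heat maps.

#' Lab-frame collision energy
#'
#' Converts a trap collision voltage to lab-frame energy using the
#' single-collision convention `E = z * V` — the charge correction that
#' puts different charge states on a common energy axis.
#'
#' @param trap_voltage Trap collision voltage(s) (V), positive.
#' @param z Charge state (positive integer).
#' @return Energy in eV.
#' @examples
#' lab_frame_energy(17, 5)  # 85 eV
#' @export
lab_frame_energy <- function(trap_voltage, z) {
  stopifnot(all(trap_voltage > 0), all(z > 0))
  z * trap_voltage
}

#' Stability curve of a species under collisional activation
#'
#' Fractions of the compact, extended (unfolded) and dissociated
#' populations on an increasing lab-frame energy grid.
#'
#' @param energy_ev Increasing lab-frame energies (eV).
#' @param compact,extended,dissociated Per-energy fractions in \[0, 1\];
#'   their sum may not exceed 1 + 1e-6 at any energy.
#' @param species Species identity string (e.g. `"D5+"`).
#' @param ligand `"free"` or a ligand name.
#' @param meta Metadata list.
#' @return Data frame of class `"stability_curve"`.
#' @export
stability_curve <- function(energy_ev, compact, extended, dissociated,
                            species = "unknown", ligand = "free",
                            meta = list()) {
  stop_if_not_increasing(energy_ev, "energy grid")
  frac <- cbind(compact, extended, dissociated)
  if (any(frac < 0)) stop("fractions must be non-negative")
  if (any(rowSums(frac) > 1 + 1e-6)) stop("fractions sum above 1 at some energy")
  out <- data.frame(energy_ev = energy_ev, compact = compact,
                    extended = extended, dissociated = dissociated)
  attr(out, "species") <- species
  attr(out, "ligand") <- ligand
  attr(out, "meta") <- meta
  class(out) <- c("stability_curve", "data.frame")
  out
}

## Capped logistic fit of y on x: y = cap / (1 + exp(-(x - e50)/w)).
## Returns NULL on total failure.
fit_capped_logistic <- function(x, y, rising = TRUE) {
  if (!rising) return(fit_capped_logistic(x, 1 - y, rising = TRUE))
  cap0 <- min(max(max(y), 0.05), 1)
  half <- cap0 / 2
  above <- which(y >= half)
  e50_0 <- if (length(above)) x[min(above)] else stats::median(x)
  w0 <- diff(range(x)) / 10
  df <- data.frame(x = x, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ cap / (1 + exp(-(x - e50) / w)), data = df,
                      start = list(cap = cap0, e50 = e50_0, w = w0),
                      lower = c(1e-3, min(x) - diff(range(x)), 1e-3),
                      upper = c(1, max(x) + diff(range(x)), diff(range(x))),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  cf <- stats::coef(fit)
  list(cap = unname(cf["cap"]), e50 = unname(cf["e50"]), w = unname(cf["w"]),
       fit = fit)
}

#' Fit a CIU or CID transition
#'
#' CIU: fits a rising logistic with a free amplitude (cap) to the extended
#' fraction *among surviving ions* (`extended / (compact + extended)`), so
#' the dissociation decline does not bias the unfolding midpoint. CID: fits
#' a declining logistic to total survival (`compact + extended`). E50 is
#' the energy of half the transition's own amplitude; when the cap is below
#' 0.5 the absolute-50% level is never reached and the fit is flagged
#' cap-limited. Uncertainties come from a seeded nonparametric bootstrap
#' over energy points.
#'
#' @param curve A [stability_curve()].
#' @param kind `"CIU"` or `"CID"`.
#' @param n_boot Bootstrap resamples (default 200); 0 disables.
#' @param seed Bootstrap seed.
#' @return An object of class `"transition_fit"`: `e50` (eV), `width`
#'   (eV), `cap`, `e50_se`, `cap_limited`, `e50_absolute` (energy where
#'   the absolute 50% level is crossed, `NA` when not reached), `kind`,
#'   `species`, `ligand`. CIU fits where unfolding never rises above the
#'   noise floor are flagged `absent`.
#' @export
fit_transition <- function(curve, kind = c("CIU", "CID"), n_boot = 200L,
                           seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(inherits(curve, "stability_curve"))
  if (nrow(curve) < 5) stop("need at least 5 energy points")
  x <- curve$energy_ev
  surv <- curve$compact + curve$extended
  if (all(surv < 1e-9) && all(curve$dissociated < 1e-9)) {
    stop("all-zero signal: nothing to fit")
  }
  if (kind == "CIU") {
    denom <- pmax(surv, 1e-9)
    y <- ifelse(surv > 0.02, curve$extended / denom, NA_real_)
    keep <- !is.na(y)
    x <- x[keep]; y <- y[keep]
    ## no unfolding ever rises above the noise floor: the species
    ## dissociates without prior unfolding (DB-dimer behavior)
    if (!length(y) || max(y) < 0.05) {
      return(structure(list(e50 = NA_real_, width = NA_real_, cap = NA_real_,
                            e50_se = NA_real_, cap_limited = FALSE,
                            absent = TRUE, e50_absolute = NA_real_,
                            kind = kind, species = attr(curve, "species"),
                            ligand = attr(curve, "ligand"),
                            n_points = length(x)),
                       class = "transition_fit"))
    }
    if (length(y) < 5) stop("fewer than 5 energies with surviving signal")
    absent <- FALSE
  } else {
    y <- surv
    if (all(y < 1e-6)) stop("all-zero survival signal")
    absent <- FALSE
  }
  rising <- kind == "CIU"
  if (rising && any(diff(y) < -0.2) ) {
    warning("non-monotone transition beyond noise tolerance; fitting anyway")
  }
  f <- fit_capped_logistic(x, y, rising = rising)
  if (is.null(f)) stop("logistic fit failed to converge")
  cap <- if (rising) f$cap else f$cap  # CID fitted on 1 - survival
  e50 <- f$e50; width <- f$w
  cap_limited <- rising && cap < 0.5
  ## absolute-50% convention: energy where the curve itself crosses 0.5
  e50_abs <- if (cap >= 0.5) {
    e50 + width * log(cap / 0.5 - 1 + 1e-12) * -1  # solve cap/(1+exp(-(x-e50)/w)) = 0.5
  } else NA_real_
  e50_se <- NA_real_
  if (n_boot > 0) {
    ## residual bootstrap: the energy design is fixed and short, so
    ## case resampling would routinely drop the transition region
    yhat <- if (rising) {
      f$cap / (1 + exp(-(x - f$e50) / f$w))
    } else {
      1 - f$cap / (1 + exp(-(x - f$e50) / f$w))
    }
    res <- y - yhat
    boots <- with_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        yb <- yhat + sample(res, replace = TRUE)
        fb <- fit_capped_logistic(x, pmin(pmax(yb, 0), 1), rising = rising)
        if (is.null(fb)) NA_real_ else fb$e50
      }, numeric(1))
    })
    ## robust spread: stray non-converged resamples must not inflate it
    e50_se <- stats::mad(boots, na.rm = TRUE)
  }
  structure(list(e50 = e50, width = width, cap = cap, e50_se = e50_se,
                 cap_limited = cap_limited, absent = absent,
                 e50_absolute = e50_abs, kind = kind,
                 species = attr(curve, "species"),
                 ligand = attr(curve, "ligand"), n_points = length(x)),
            class = "transition_fit")
}

#' @export
print.transition_fit <- function(x, ...) {
  cat(sprintf("%s transition [%s, %s]: E50 = %.2f eV (se %.2f), width %.2f eV, cap %.3f%s%s\n",
              x$kind, x$species, x$ligand, x$e50,
              ifelse(is.na(x$e50_se), NA, x$e50_se), x$width, x$cap,
              if (x$cap_limited) " [cap-limited: 50% level not reached]" else "",
              if (x$absent) " [transition absent]" else ""))
  invisible(x)
}

#' @export
coef.transition_fit <- function(object, ...) {
  c(e50 = object$e50, width = object$width, cap = object$cap)
}

#' Energy-gap regime analysis across oligomer orders
#'
#' Takes per-order unfolding midpoints, forms the first differences
#' `dE50(n)`, and fits a two-segment constant-gap model with a single
#' breakpoint chosen by exhaustive least squares over the interior orders.
#' Reports the breakpoint order (the last order of the lower segment) and
#' the two gap values. A series whose gaps are statistically uniform is
#' flagged degenerate and a single gap is reported.
#'
#' @param e50_by_order Data frame with columns `n` (consecutive orders) and
#'   `e50` (eV); at least 4 orders.
#' @param degenerate_tol Relative SSE improvement below which the
#'   breakpoint is declared degenerate (default 0.05).
#' @return A list of class `"gap_analysis"`: `breakpoint` (order after
#'   which the gap changes; `NA` if degenerate), `gap_lower`, `gap_upper`
#'   (eV), `gaps` (the first differences) and `degenerate`.
#' @export
gap_analysis <- function(e50_by_order, degenerate_tol = 0.05) {
  stopifnot(is.data.frame(e50_by_order), all(c("n", "e50") %in% names(e50_by_order)))
  tab <- e50_by_order[order(e50_by_order$n), ]
  if (nrow(tab) < 4) stop("need at least 4 oligomer orders")
  gaps <- diff(tab$e50)
  gap_n <- tab$n[-1]  # gap i is the step arriving at order gap_n[i]
  sse1 <- sum((gaps - mean(gaps))^2)
  best <- NULL
  for (k in seq_len(length(gaps) - 1)) {   # lower segment = gaps 1..k
    g1 <- mean(gaps[1:k]); g2 <- mean(gaps[(k + 1):length(gaps)])
    sse <- sum((gaps[1:k] - g1)^2) + sum((gaps[(k + 1):length(gaps)] - g2)^2)
    if (is.null(best) || sse < best$sse) {
      best <- list(k = k, g1 = g1, g2 = g2, sse = sse)
    }
  }
  degenerate <- sse1 <= 1e-12 || (sse1 - best$sse) / max(sse1, 1e-12) < degenerate_tol
  structure(list(
    breakpoint = if (degenerate) NA_integer_ else as.integer(tab$n[best$k + 1]),
    gap_lower = if (degenerate) mean(gaps) else best$g1,
    gap_upper = if (degenerate) mean(gaps) else best$g2,
    gaps = stats::setNames(gaps, gap_n),
    degenerate = degenerate
  ), class = "gap_analysis")
}

#' @export
print.gap_analysis <- function(x, ...) {
  if (x$degenerate) {
    cat(sprintf("equidistant energy gaps: %.2f eV (no breakpoint)\n", x$gap_lower))
  } else {
    cat(sprintf("energy-gap regimes: %.2f eV up to n = %d, then %.2f eV\n",
                x$gap_lower, x$breakpoint, x$gap_upper))
  }
  invisible(x)
}

#' Compare a ligand-bound transition fit against the free one
#'
#' Reports the midpoint shift with propagated uncertainty and a
#' qualitative class: `"CID-stabilized"` (bound dissociation midpoint
#' higher), `"CIU-suppressed"` (bound unfolding cap-limited while the free
#' one is not), `"unchanged"`, or `"destabilized"`.
#'
#' @param free,bound Two `"transition_fit"` objects of the same species
#'   and transition kind.
#' @param min_shift_ev Shift magnitude (beyond uncertainty) below which
#'   the pair counts as unchanged (default 2 eV).
#' @return A list of class `"bound_free_comparison"` with `delta_e50`,
#'   `se`, and `class`.
#' @export
compare_bound_free <- function(free, bound, min_shift_ev = 2) {
  stopifnot(inherits(free, "transition_fit"), inherits(bound, "transition_fit"))
  if (free$kind != bound$kind) stop("transition kinds differ")
  if (!identical(free$species, bound$species)) stop("species differ")
  d <- bound$e50 - free$e50
  se <- sqrt(sum(c(free$e50_se, bound$e50_se)^2, na.rm = TRUE))
  cls <- if (free$kind == "CIU" && bound$cap_limited && !free$cap_limited) {
    "CIU-suppressed"
  } else if (abs(d) <= max(min_shift_ev, 2 * se)) {
    "unchanged"
  } else if (d > 0) {
    if (free$kind == "CID") "CID-stabilized" else "CIU-stabilized"
  } else "destabilized"
  structure(list(delta_e50 = d, se = se, class = cls,
                 kind = free$kind, species = free$species),
            class = "bound_free_comparison")
}

#' @export
print.bound_free_comparison <- function(x, ...) {
  cat(sprintf("%s [%s]: Delta-E50 = %+.2f eV (se %.2f) -> %s\n",
              x$kind, x$species, x$delta_e50, x$se, x$class))
  invisible(x)
}

#' Build a CIU fingerprint heat map
#'
#' Stacks arrival-time profiles recorded at increasing trap voltages into
#' an (energy x drift) matrix with each row normalized to its total
#' intensity.
#'
#' @param frames A list of entries, each `list(trap_v = , profile = )`,
#'   sharing one drift grid.
#' @param drift_ms The common drift grid.
#' @param z Charge (rows are labeled with lab-frame energy `z * trap_v`).
#' @return A matrix of class `"ciu_fingerprint"` with rownames the
#'   lab-frame energies and colnames the drift times; rows sum to 1.
#' @export
build_fingerprint <- function(frames, drift_ms, z = 1L) {
  stopifnot(length(frames) >= 1)
  nd <- length(drift_ms)
  profs <- lapply(frames, function(f) {
    if (length(f$profile) != nd) stop("inconsistent drift grids across frames")
    f$profile
  })
  volts <- vapply(frames, function(f) f$trap_v, numeric(1))
  ord <- order(volts)
  mat <- do.call(rbind, profs[ord])
  tot <- rowSums(mat)
  if (any(tot <= 0)) stop("a frame has zero total intensity")
  mat <- mat / tot
  rownames(mat) <- format(lab_frame_energy(volts[ord], z), trim = TRUE)
  colnames(mat) <- format(drift_ms, trim = TRUE)
  class(mat) <- c("ciu_fingerprint", class(mat))
  mat
}
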