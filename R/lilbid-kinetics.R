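## Time-resolved LILBID oligomer-distribution analysis: replicate
## averaging and binning, spectrum normalization, the monomer-over-oligomer
## (M/O) statistic, maximum-order tracking and inhibitor comparisons.

#' Kinetics table of per-timepoint oligomer intensities
#'
#' @param data Data frame with columns `time_min`, `replicate` and
#'   intensity columns `I_1` ... `I_nmax` (all non-negative).
#' @param condition Condition tag, `"free"` or `"+inhibitor"` style.
#' @param meta Metadata list.
#' @return The data frame with class `"kinetics_table"`.
#' @export
kinetics_table <- function(data, condition = "free", meta = list()) {
  stopifnot(is.data.frame(data), all(c("time_min", "replicate") %in% names(data)))
  icols <- grep("^I_\\d+$", names(data), value = TRUE)
  if (!length(icols)) stop("no intensity columns I_1..I_n found")
  if (any(data[icols] < 0)) stop("intensities must be non-negative")
  attr(data, "condition") <- condition
  attr(data, "meta") <- meta
  attr(data, "n_max") <- max(as.integer(sub("I_", "", icols)))
  class(data) <- c("kinetics_table", "data.frame")
  data
}

intensity_columns <- function(tab) grep("^I_\\d+$", names(tab), value = TRUE)

#' Bin and replicate-average a kinetics table
#'
#' Averages the replicate intensity vectors within consecutive time bins
#' (default 10 min, the instrument's averaging window). Bins with no data
#' are dropped with a warning. With `collapse_replicates = FALSE` the
#' replicate vectors are kept (averaged only over timestamps within the
#' bin), enabling replicate-based confidence intervals downstream.
#'
#' @param raw A [kinetics_table()] with sorted timestamps.
#' @param bin_width_min Bin width in minutes (> 0), default 10.
#' @param collapse_replicates Average over replicates too (default TRUE).
#' @return A binned [kinetics_table()]; `time_min` holds bin centers.
#' @export
bin_and_average <- function(raw, bin_width_min = 10, collapse_replicates = TRUE) {
  stopifnot(inherits(raw, "kinetics_table"), bin_width_min > 0)
  if (is.unsorted(raw$time_min)) stop("timestamps must be sorted")
  icols <- intensity_columns(raw)
  bin <- floor(raw$time_min / bin_width_min)
  centers <- (bin + 0.5) * bin_width_min
  key <- if (collapse_replicates) bin else paste(bin, raw$replicate)
  pieces <- split(seq_len(nrow(raw)), key)
  rows <- lapply(pieces, function(idx) {
    out <- data.frame(time_min = mean(centers[idx]),
                      replicate = if (collapse_replicates) NA_integer_
                                  else raw$replicate[idx[1]])
    out[icols] <- as.list(colMeans(raw[idx, icols, drop = FALSE]))
    out
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$time_min, out$replicate), ]
  rownames(out) <- NULL
  all_bins <- seq(min(bin), max(bin))
  if (length(setdiff(all_bins, unique(bin)))) {
    warning("empty time bins dropped: ",
            paste((setdiff(all_bins, unique(bin)) + 0.5) * bin_width_min,
                  collapse = ", "), " min")
  }
  kinetics_table(out, condition = attr(raw, "condition"),
                 meta = c(attr(raw, "meta"), list(bin_width_min = bin_width_min)))
}

#' Normalize an intensity vector to fractions
#'
#' @param intensity Non-negative intensity vector with positive sum.
#' @return `intensity / sum(intensity)`.
#' @export
normalize_spectrum <- function(intensity) {
  s <- sum(intensity)
  if (s <= 0) stop("cannot normalize an all-zero spectrum")
  intensity / s
}

#' Monomer-over-oligomer ratio
#'
#' The aggregation-progress statistic `M/O = I_1 / sum(n * I_n)`. The
#' denominator sum includes the monomer term by default, bounding M/O by 1
#' (exactly 1 when only monomer is present); the convention excluding n = 1
#' from the denominator is also available.
#'
#' @param intensity Intensity vector `I_1 ... I_nmax` (index = oligomer
#'   order).
#' @param denominator `"n_ge_1"` (default) or `"n_ge_2"`.
#' @return The M/O value. Errors on a zero denominator.
#' @examples
#' m_over_o(c(50, 25))  # 50 / (50 + 50) = 0.5
#' @export
m_over_o <- function(intensity, denominator = c("n_ge_1", "n_ge_2")) {
  denominator <- match.arg(denominator)
  n <- seq_along(intensity)
  terms <- n * intensity
  denom <- if (denominator == "n_ge_1") sum(terms) else sum(terms[-1])
  if (denom <= 0) stop("zero denominator in M/O")
  intensity[1] / denom
}

#' Largest oligomer order present above a threshold
#'
#' @param intensity Intensity vector `I_1 ... I_nmax`.
#' @param threshold_fraction Fraction of total intensity below which a
#'   peak does not count (default 0.01), in \[0, 1).
#' @return A list: `n_max_observed` (0 when nothing passes) and `none`
#'   (logical flag).
#' @export
max_order_present <- function(intensity, threshold_fraction = 0.01) {
  stopifnot(threshold_fraction >= 0, threshold_fraction < 1)
  if (sum(intensity) <= 0) return(list(n_max_observed = 0L, none = TRUE))
  frac <- normalize_spectrum(intensity)
  hit <- which(frac > threshold_fraction)
  if (!length(hit)) return(list(n_max_observed = 0L, none = TRUE))
  list(n_max_observed = max(hit), none = FALSE)
}

#' Compare two kinetics conditions
#'
#' Per-timepoint differences in M/O and in maximum observed order between
#' two aligned (binned) kinetics tables, with bootstrap confidence
#' intervals over replicates where replicate-level rows are available.
#'
#' @param a,b Two [kinetics_table()]s with identical time bins (e.g. free
#'   and +inhibitor).
#' @param threshold_fraction Threshold for [max_order_present()].
#' @param n_boot Bootstrap resamples over replicates (default 200).
#' @param seed Bootstrap seed.
#' @param denominator M/O denominator convention.
#' @return A data frame of class `"condition_comparison"`: per-timepoint
#'   `mo_a`, `mo_b`, `delta_mo` (b - a), `delta_mo_lo/hi` (CI, `NA` when
#'   replicates are unavailable), `max_order_a`, `max_order_b`,
#'   `delta_max_order`.
#' @export
compare_conditions <- function(a, b, threshold_fraction = 0.01,
                               n_boot = 200L, seed = 1L,
                               denominator = "n_ge_1") {
  stopifnot(inherits(a, "kinetics_table"), inherits(b, "kinetics_table"))
  ta <- sort(unique(a$time_min)); tb <- sort(unique(b$time_min))
  if (!isTRUE(all.equal(ta, tb))) stop("time bins are misaligned between conditions")
  icols_a <- intensity_columns(a); icols_b <- intensity_columns(b)
  has_reps <- function(tab) length(unique(tab$replicate[!is.na(tab$replicate)])) > 1
  reps_ok <- has_reps(a) && has_reps(b)

  stat_at <- function(tab, icols, t, rows = NULL) {
    sel <- tab[tab$time_min == t, , drop = FALSE]
    if (!is.null(rows)) sel <- sel[rows, , drop = FALSE]
    iv <- colMeans(sel[, icols, drop = FALSE])
    list(mo = m_over_o(iv, denominator),
         mx = max_order_present(iv, threshold_fraction)$n_max_observed)
  }
  out <- lapply(ta, function(t) {
    sa <- stat_at(a, icols_a, t); sb <- stat_at(b, icols_b, t)
    ci <- c(NA_real_, NA_real_)
    if (reps_ok && n_boot > 0) {
      na <- sum(a$time_min == t); nb <- sum(b$time_min == t)
      ci <- with_seed(seed + as.integer(t), {
        d <- vapply(seq_len(n_boot), function(i) {
          stat_at(b, icols_b, t, sample(nb, replace = TRUE))$mo -
            stat_at(a, icols_a, t, sample(na, replace = TRUE))$mo
        }, numeric(1))
        stats::quantile(d, c(0.025, 0.975), names = FALSE)
      })
    }
    data.frame(time_min = t, mo_a = sa$mo, mo_b = sb$mo,
               delta_mo = sb$mo - sa$mo,
               delta_mo_lo = ci[1], delta_mo_hi = ci[2],
               max_order_a = sa$mx, max_order_b = sb$mx,
               delta_max_order = sb$mx - sa$mx)
  })
  out <- do.call(rbind, out)
  attr(out, "replicate_ci") <- reps_ok
  class(out) <- c("condition_comparison", "data.frame")
  out
}

#' Read / write a kinetics table as CSV
#' @param tab A [kinetics_table()].
#' @param path CSV path (columns time_min, replicate, I_1..I_n, condition).
#' @export
write_kinetics <- function(tab, path) {
  out <- as.data.frame(tab)
  out$condition <- attr(tab, "condition")
  utils::write.csv(out, path, row.names = FALSE)
}

#' @rdname write_kinetics
#' @export
read_kinetics <- function(path) {
  tab <- utils::read.csv(path)
  cond <- if ("condition" %in% names(tab)) tab$condition[1] else "free"
  tab$condition <- NULL
  kinetics_table(tab, condition = cond)
}
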