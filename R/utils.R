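## Internal helpers.

## Run code under a fixed RNG seed, restoring the caller's RNG state.
## All generator determinism contracts rest on this.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

stop_if_not_increasing <- function(x, what) {
  if (length(x) < 1 || any(diff(x) <= 0)) {
    stop(what, " must be strictly increasing")
  }
  invisible(x)
}

## Gaussian profile normalized to unit sum on a discrete grid (so marginals
## over that axis reproduce the per-peak weights exactly).
grid_gaussian <- function(grid, center, sd) {
  g <- exp(-0.5 * ((grid - center) / sd)^2)
  s <- sum(g)
  if (s == 0) g else g / s
}

fwhm_to_sd <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))
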