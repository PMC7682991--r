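## Structure-based theoretical CCS: PDB reading, cropping fibril structures
## into MB/DB oligomer series, and the projection-approximation (PA) CCS by
## Monte-Carlo orientation averaging of the hard-disk shadow area.

#' Read a structure from a PDB file
#'
#' Thin wrapper over `bio3d::read.pdb` extracting one model's protein
#' atoms (heteroatoms excluded) with element symbols resolved against the
#' bundled radius table.
#'
#' @param path Path to a PDB file.
#' @param model Model number to extract (default 1).
#' @return A list of class `"ims_structure"`: `element`, `xyz` (N x 3
#'   matrix, Angstrom), `chain`, `resno`, `source`.
#' @export
read_structure <- function(path, model = 1L) {
  pdb <- tryCatch(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
                  error = function(e) stop("cannot parse PDB: ", conditionMessage(e)))
  sel <- pdb$atom$type == "ATOM"
  if (!any(sel)) stop("no ATOM records in PDB")
  n_models <- nrow(pdb$xyz)
  if (model < 1 || model > n_models) {
    stop(sprintf("model %d not present (file has %d model(s))", model, n_models))
  }
  xyz_all <- matrix(pdb$xyz[model, ], ncol = 3, byrow = TRUE)
  xyz <- xyz_all[sel, , drop = FALSE]
  elem <- pdb$atom$elesy[sel]
  missing_el <- is.na(elem) | !nzchar(trimws(elem))
  if (any(missing_el)) {
    ## fall back to the first letter of the atom name
    elem[missing_el] <- substr(trimws(pdb$atom$elety[sel][missing_el]), 1, 1)
  }
  elem <- toupper(trimws(elem))
  unknown <- setdiff(unique(elem), names(vdw_radii))
  if (length(unknown)) {
    stop("unknown element(s) without a radius entry: ",
         paste(unknown, collapse = ", "))
  }
  structure(list(element = elem, xyz = xyz,
                 chain = pdb$atom$chain[sel], resno = pdb$atom$resno[sel],
                 source = list(file = path, model = as.integer(model))),
            class = "ims_structure")
}

#' @export
print.ims_structure <- function(x, ...) {
  cat(sprintf("structure: %d atoms, %d chain(s) [%s]\n",
              nrow(x$xyz), length(unique(x$chain)),
              paste(unique(x$chain), collapse = "")))
  invisible(x)
}

#' Crop an oligomer out of a fibril structure
#'
#' Extracts an n-mer from a fibril whose monomer copies are indexed by the
#' `layer_map` (columns `chain`, `layer`, `protofilament`). MB oligomers
#' take n consecutive layers of protofilament 1; DB oligomers take whole
#' two-monomer layers (both protofilaments), so an odd n uses
#' `ceiling(n/2)` layers with one unpaired monomer dropped from the last
#' layer (flagged in the result).
#'
#' @param fibril An `"ims_structure"`.
#' @param n Oligomer order (monomer count) to extract.
#' @param base `"MB"` or `"DB"`.
#' @param layer_map Data frame mapping chains to layers and protofilaments
#'   (e.g. [toy_layer_map()]).
#' @return An `"ims_structure"` of the cropped atoms with attributes
#'   `n`, `base` and `unpaired` (logical).
#' @export
crop_oligomer <- function(fibril, n, base = c("MB", "DB"), layer_map) {
  base <- match.arg(base)
  stopifnot(inherits(fibril, "ims_structure"), n >= 1, n == round(n),
            all(c("chain", "layer", "protofilament") %in% names(layer_map)))
  n_layers <- max(layer_map$layer)
  unpaired <- FALSE
  if (base == "MB") {
    if (n > n_layers) {
      stop(sprintf("requested %d-mer exceeds the %d available layers", n, n_layers))
    }
    pick <- layer_map[layer_map$protofilament == 1 & layer_map$layer <= n, ]
  } else {
    layers_needed <- ceiling(n / 2)
    if (layers_needed > n_layers || max(layer_map$protofilament) < 2) {
      stop(sprintf("requested DB %d-mer exceeds the available %d paired layers",
                   n, n_layers))
    }
    pick <- layer_map[layer_map$layer <= layers_needed, ]
    if (n %% 2 == 1) {
      unpaired <- TRUE
      drop <- pick$layer == layers_needed & pick$protofilament == 2
      pick <- pick[!drop, ]
    }
  }
  keep <- fibril$chain %in% pick$chain
  if (sum(keep) == 0) stop("layer_map chains not found in the structure")
  out <- structure(list(element = fibril$element[keep],
                        xyz = fibril$xyz[keep, , drop = FALSE],
                        chain = fibril$chain[keep], resno = fibril$resno[keep],
                        source = fibril$source),
                   class = "ims_structure")
  attr(out, "n") <- as.integer(n)
  attr(out, "base") <- base
  attr(out, "unpaired") <- unpaired
  out
}

## Uniform random rotation matrices via uniform unit quaternions.
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

#' Projection-approximation CCS by Monte Carlo
#'
#' Estimates the orientation-averaged shadow area of the structure's atoms
#' modeled as hard disks of radius (van der Waals radius + buffer-gas
#' radius). For each uniformly random orientation (quaternion sampling on
#' SO(3)) the projected union-of-disks area is estimated by hit-or-miss
#' sampling inside the projected bounding box; the CCS is the mean over
#' orientations and the standard error the spread across orientations.
#'
#' @param s An `"ims_structure"` with at least one atom.
#' @param gas_radius Buffer-gas collision radius (Angstrom), default 1.5
#'   (nitrogen-like).
#' @param n_orientations Number of random orientations (default 300).
#' @param n_rays Hit-or-miss sample points per orientation (default 5000).
#' @param seed RNG seed.
#' @return A list of class `"pa_result"`: `ccs_a2`, `se`, `n_orientations`,
#'   `n_rays`, `gas_radius`, `seed`.
#' @export
pa_ccs <- function(s, gas_radius = 1.5, n_orientations = 300L,
                   n_rays = 5000L, seed = 1L) {
  stopifnot(inherits(s, "ims_structure"), nrow(s$xyz) >= 1,
            n_orientations >= 1, n_rays >= 1, gas_radius >= 0)
  radii <- unname(vdw_radii[s$element]) + gas_radius
  xyz <- s$xyz
  areas <- with_seed(seed, {
    vapply(seq_len(n_orientations), function(o) {
      R <- random_rotation()
      p <- xyz %*% t(R)
      px <- p[, 1]; py <- p[, 2]
      xlim <- range(px - radii, px + radii)
      ylim <- range(py - radii, py + radii)
      box <- diff(xlim) * diff(ylim)
      sx <- stats::runif(n_rays, xlim[1], xlim[2])
      sy <- stats::runif(n_rays, ylim[1], ylim[2])
      hits <- logical(n_rays)
      ## per-atom accumulation avoids an n_rays x n_atoms matrix
      for (a in seq_along(radii)) {
        miss <- which(!hits)
        if (!length(miss)) break
        d2 <- (sx[miss] - px[a])^2 + (sy[miss] - py[a])^2
        hits[miss[d2 <= radii[a]^2]] <- TRUE
      }
      box * mean(hits)
    }, numeric(1))
  })
  structure(list(ccs_a2 = mean(areas),
                 se = stats::sd(areas) / sqrt(n_orientations),
                 n_orientations = as.integer(n_orientations),
                 n_rays = as.integer(n_rays),
                 gas_radius = gas_radius, seed = as.integer(seed)),
            class = "pa_result")
}

#' @export
print.pa_result <- function(x, ...) {
  cat(sprintf("PA CCS = %.2f +/- %.2f A^2 (%d orientations x %d rays, gas radius %.2f A)\n",
              x$ccs_a2, x$se, x$n_orientations, x$n_rays, x$gas_radius))
  invisible(x)
}

#' Theoretical CCS series from a fibril structure
#'
#' Crops the fibril into MB or DB oligomers over `n_range` and computes
#' the PA CCS of each, assembled into a [ccs_series()] consumable by the
#' growth-model fits.
#'
#' @param fibril An `"ims_structure"`.
#' @param base `"MB"` or `"DB"`.
#' @param n_range Oligomer orders to extract.
#' @param layer_map Chain/layer map (see [crop_oligomer()]).
#' @param ... Passed to [pa_ccs()] (gas radius, sampling sizes, seed).
#' @return A [ccs_series()] tagged with `base`; sigma holds the
#'   Monte-Carlo standard errors.
#' @export
ccs_series_from_fibril <- function(fibril, base = c("MB", "DB"), n_range,
                                   layer_map, ...) {
  base <- match.arg(base)
  res <- lapply(n_range, function(n) {
    olig <- crop_oligomer(fibril, n, base, layer_map)
    pa <- pa_ccs(olig, ...)
    c(n = n, ccs = pa$ccs_a2, se = pa$se)
  })
  res <- do.call(rbind, res)
  ccs_series(res[, "n"], res[, "ccs"], pmax(res[, "se"], 1e-9), tag = base)
}
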