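## Static IUPAC element data used by all mass arithmetic in the package.
## Atomic weights: IUPAC 2021 conventional values. Isotope masses/abundances:
## AME2020 / IUPAC isotopic-composition tables, truncated to the isotopes
## relevant for peptides (C, H, N, O, S).

#' Element data bundled with the package
#'
#' A single versioned table of standard atomic weights, monoisotopic
#' (most-abundant-isotope) masses, and isotope mass/abundance lists for the
#' elements occurring in unmodified peptides (C, H, N, O, S).
#'
#' @format A list keyed by element symbol; each entry has `weight` (standard
#'   atomic weight, Da), `mono` (most abundant isotope mass, Da) and
#'   `isotopes`, a data frame with columns `mass` (Da) and `abundance`
#'   (fractions summing to 1).
#' @export
element_data <- list(
  H = list(
    weight = 1.008, mono = 1.0078250319,
    isotopes = data.frame(
      mass = c(1.0078250319, 2.0141017780),
      abundance = c(0.999885, 0.000115)
    )
  ),
  C = list(
    weight = 12.011, mono = 12.0,
    isotopes = data.frame(
      mass = c(12.0, 13.0033548378),
      abundance = c(0.9893, 0.0107)
    )
  ),
  N = list(
    weight = 14.007, mono = 14.0030740052,
    isotopes = data.frame(
      mass = c(14.0030740052, 15.0001088984),
      abundance = c(0.99636, 0.00364)
    )
  ),
  O = list(
    weight = 15.999, mono = 15.9949146221,
    isotopes = data.frame(
      mass = c(15.9949146221, 16.9991315, 17.9991604),
      abundance = c(0.99757, 0.00038, 0.00205)
    )
  ),
  S = list(
    weight = 32.06, mono = 31.97207069,
    isotopes = data.frame(
      mass = c(31.97207069, 32.97145850, 33.96786683, 35.96708088),
      abundance = c(0.9499, 0.0075, 0.0425, 0.0001)
    )
  )
)

#' Proton mass used for m/z arithmetic (Da)
#' @export
PROTON_MASS <- 1.00728

#' Mass of the neutron-count spacing between isotopologue peaks (Da)
#'
#' The nominal mass difference between adjacent aggregated isotope peaks;
#' divided by the charge it gives the m/z spacing used for charge inference.
#' @export
NEUTRON_SPACING <- 1.0034

## Residue elemental compositions (residue = amino acid minus one water).
## Standard one-letter codes; L and I share a formula.
residue_compositions <- list(
  G = c(C = 2, H = 3, N = 1, O = 1, S = 0),
  A = c(C = 3, H = 5, N = 1, O = 1, S = 0),
  S = c(C = 3, H = 5, N = 1, O = 2, S = 0),
  P = c(C = 5, H = 7, N = 1, O = 1, S = 0),
  V = c(C = 5, H = 9, N = 1, O = 1, S = 0),
  T = c(C = 4, H = 7, N = 1, O = 2, S = 0),
  C = c(C = 3, H = 5, N = 1, O = 1, S = 1),
  L = c(C = 6, H = 11, N = 1, O = 1, S = 0),
  I = c(C = 6, H = 11, N = 1, O = 1, S = 0),
  N = c(C = 4, H = 6, N = 2, O = 2, S = 0),
  D = c(C = 4, H = 5, N = 1, O = 3, S = 0),
  Q = c(C = 5, H = 8, N = 2, O = 2, S = 0),
  K = c(C = 6, H = 12, N = 2, O = 1, S = 0),
  E = c(C = 5, H = 7, N = 1, O = 3, S = 0),
  M = c(C = 5, H = 9, N = 1, O = 1, S = 1),
  H = c(C = 6, H = 7, N = 3, O = 1, S = 0),
  F = c(C = 9, H = 9, N = 1, O = 1, S = 0),
  R = c(C = 6, H = 12, N = 4, O = 1, S = 0),
  Y = c(C = 9, H = 9, N = 1, O = 2, S = 0),
  W = c(C = 11, H = 10, N = 2, O = 1, S = 0)
)

## Bondi van-der-Waals radii (Angstrom) for the projection-approximation CCS.
#' Van der Waals radii used by the projection approximation
#'
#' Bondi radii in Angstrom for the elements found in protein structures.
#' @export
vdw_radii <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80)

#' Canonical 42-residue amyloid-beta peptide sequence
#'
#' One-letter amino-acid sequence of Abeta42, the aggregating peptide this
#' package's analyses target.
#' @export
ABETA42_SEQUENCE <- "DAEFRHDSGYEVHHQKLVFFAEDVGSNKGAIIGLMVGGVVIA"

#' Mass of molecular nitrogen, the drift gas (Da)
#' @export
N2_MASS <- 28.0134
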