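## Elemental composition, mass and isotope-pattern arithmetic for n-mer
## peptide ions. Patterns are aggregated by neutron-count index (the usual
## centroided isotopologue representation); fine structure is out of scope.

#' Elemental composition of a molecule
#'
#' Constructs a named count vector over the supported elements (C, H, N, O,
#' S). Counts must be non-negative integers.
#'
#' @param ... Named element counts, e.g. `elemental_composition(C = 2, H = 5,
#'   N = 1, O = 2)`. Omitted elements default to zero.
#' @return A named integer vector of class `"elemental_composition"` with one
#'   entry per supported element.
#' @examples
#' elemental_composition(H = 2, O = 1)  # water
#' @export
elemental_composition <- function(...) {
  counts <- c(...)
  elems <- names(element_data)
  if (length(counts)) {
    if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
      stop("element counts must be named")
    }
    unknown <- setdiff(names(counts), elems)
    if (length(unknown)) {
      stop("unsupported element(s): ", paste(unknown, collapse = ", "))
    }
    if (any(counts < 0) || any(counts != round(counts))) {
      stop("element counts must be non-negative integers")
    }
  }
  out <- stats::setNames(integer(length(elems)), elems)
  out[names(counts)] <- as.integer(counts)
  class(out) <- "elemental_composition"
  out
}

#' @export
print.elemental_composition <- function(x, ...) {
  nz <- x[x > 0]
  if (!length(nz)) {
    cat("<empty composition>\n")
  } else {
    cat(paste0(names(nz), nz, collapse = " "), "\n")
  }
  invisible(x)
}

#' Elemental composition of a peptide from its sequence
#'
#' Sums the residue compositions of a one-letter amino-acid sequence and adds
#' one water for the termini.
#'
#' @param sequence Non-empty string of canonical one-letter residue codes.
#' @return An [elemental_composition()].
#' @examples
#' composition_from_sequence("G")   # glycine, C2H5NO2
#' composition_from_sequence(ABETA42_SEQUENCE)
#' @export
composition_from_sequence <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(trimws(sequence))
  if (!nzchar(sequence)) stop("sequence must be non-empty")
  codes <- strsplit(sequence, "")[[1]]
  bad <- which(!codes %in% names(residue_compositions))
  if (length(bad)) {
    stop(sprintf("unknown residue code '%s' at position %d", codes[bad[1]], bad[1]))
  }
  total <- Reduce(`+`, residue_compositions[codes])
  total["H"] <- total["H"] + 2L  # one water for the termini
  total["O"] <- total["O"] + 1L
  do.call(elemental_composition, as.list(total))
}

#' Average (standard-atomic-weight) mass of a composition
#'
#' @param composition An [elemental_composition()].
#' @return Mass in Da: sum of count times IUPAC standard atomic weight.
#' @export
average_mass <- function(composition) {
  composition <- as_composition(composition)
  weights <- vapply(element_data, `[[`, numeric(1), "weight")
  sum(as.numeric(composition) * weights[names(composition)])
}

#' Monoisotopic mass of a composition
#'
#' @param composition An [elemental_composition()].
#' @return Mass in Da using the most abundant isotope of each element.
#' @export
monoisotopic_mass <- function(composition) {
  composition <- as_composition(composition)
  monos <- vapply(element_data, `[[`, numeric(1), "mono")
  sum(as.numeric(composition) * monos[names(composition)])
}

as_composition <- function(x) {
  if (inherits(x, "elemental_composition")) return(x)
  if (is.numeric(x) && !is.null(names(x))) return(do.call(elemental_composition, as.list(x)))
  stop("expected an elemental_composition or a named count vector")
}

## --- isotope pattern machinery -------------------------------------------
## A pattern is stored as parallel vectors over the neutron-shift index k =
## 0, 1, 2, ...: abundance[k] and the abundance-weighted mean mass of all
## isotopologues with k extra neutrons. Convolution of two patterns adds
## shifts, multiplies abundances, and mass-averages within each shift.

pattern_convolve <- function(a, b, prune = 1e-15) {
  na <- length(a$abundance); nb <- length(b$abundance)
  nk <- na + nb - 1L
  ab <- numeric(nk)
  wm <- numeric(nk)  # abundance-weighted mass accumulator
  for (i in seq_len(na)) {
    j <- seq_len(nb)
    k <- i + j - 1L
    w <- a$abundance[i] * b$abundance
    ab[k] <- ab[k] + w
    wm[k] <- wm[k] + w * (a$mass[i] + b$mass)
  }
  keep <- ab > prune * max(ab)
  last <- max(which(keep))
  idx <- seq_len(last)
  list(abundance = ab[idx], mass = ifelse(ab[idx] > 0, wm[idx] / ab[idx], 0))
}

pattern_power <- function(p, n, prune = 1e-15) {
  ## binary exponentiation of pattern self-convolution
  result <- NULL
  base <- p
  while (n > 0) {
    if (n %% 2 == 1) {
      result <- if (is.null(result)) base else pattern_convolve(result, base, prune)
    }
    base <- pattern_convolve(base, base, prune)
    n <- n %/% 2
  }
  if (is.null(result)) list(abundance = 1, mass = 0) else result
}

element_pattern <- function(symbol) {
  iso <- element_data[[symbol]]$isotopes
  ## index isotopes by neutron shift relative to the lightest
  shift <- as.integer(round(iso$mass - iso$mass[1]))
  nk <- max(shift) + 1L
  ab <- numeric(nk); wm <- numeric(nk)
  for (r in seq_len(nrow(iso))) {
    k <- shift[r] + 1L
    ab[k] <- ab[k] + iso$abundance[r]
    wm[k] <- wm[k] + iso$abundance[r] * iso$mass[r]
  }
  list(abundance = ab, mass = ifelse(ab > 0, wm / ab, 0))
}

neutral_pattern <- function(composition, prune = 1e-15) {
  composition <- as_composition(composition)
  parts <- lapply(names(composition)[composition > 0], function(el) {
    pattern_power(element_pattern(el), composition[[el]], prune)
  })
  if (!length(parts)) return(list(abundance = 1, mass = 0))
  Reduce(function(a, b) pattern_convolve(a, b, prune), parts)
}

#' Isotope pattern of a composition at a given charge
#'
#' Computes the aggregated (centroided) isotopologue pattern by element-wise
#' convolution of the isotope tables — the polynomial-expansion method — and
#' converts it to m/z for a protonated ion of charge `z`. Peaks are kept
#' until the cumulative abundance reaches 0.9999, capped at `n_peaks`, and
#' renormalized to sum to one.
#'
#' @param composition An [elemental_composition()] (the neutral molecule).
#' @param z Positive integer charge (protonation assumed).
#' @param n_peaks Maximum number of peaks to keep (>= 1).
#' @return A data frame of class `"isotope_pattern"` with columns `mass`
#'   (neutral isotopologue mass, Da), `mz` and `abundance`, and attribute
#'   `charge`.
#' @examples
#' isotope_pattern(elemental_composition(C = 1), z = 1, n_peaks = 2)
#' @export
isotope_pattern <- function(composition, z = 1L, n_peaks = 12L) {
  stopifnot(z >= 1, z == round(z), n_peaks >= 1)
  p <- neutral_pattern(composition)
  ab <- p$abundance / sum(p$abundance)
  keep <- min(which(cumsum(ab) >= 0.9999))
  keep <- min(keep, n_peaks)
  idx <- seq_len(keep)
  out <- data.frame(
    mass = p$mass[idx],
    mz = (p$mass[idx] + z * PROTON_MASS) / z,
    abundance = ab[idx] / sum(ab[idx])
  )
  attr(out, "charge") <- as.integer(z)
  class(out) <- c("isotope_pattern", "data.frame")
  out
}

#' An (oligomer order, charge) ion of a peptide
#'
#' Describes the `[nM + zH]^z+` ion of an n-mer of a peptide, carrying both
#' the average and monoisotopic neutral masses of the n-mer.
#'
#' @param peptide Either a one-letter sequence string or an
#'   [elemental_composition()] of the monomer.
#' @param n Oligomer order (>= 1).
#' @param z Charge (>= 1).
#' @param label Optional species label (e.g. `"D5+"`).
#' @return A list of class `"ion_species"` with fields `n`, `z`,
#'   `composition` (monomer), `mass_avg`, `mass_mono` (n-mer neutral masses)
#'   and `label`.
#' @export
ion_species <- function(peptide, n, z, label = NULL) {
  stopifnot(n >= 1, n == round(n), z >= 1, z == round(z))
  comp <- if (is.character(peptide)) composition_from_sequence(peptide) else as_composition(peptide)
  structure(list(
    n = as.integer(n), z = as.integer(z), composition = comp,
    mass_avg = n * average_mass(comp),
    mass_mono = n * monoisotopic_mass(comp),
    label = label
  ), class = "ion_species")
}

#' @export
print.ion_species <- function(x, ...) {
  cat(sprintf("ion species: n=%d z=%d  m/z(avg)=%.4f  m/z(mono)=%.4f\n",
              x$n, x$z, mz_of_species(x, "average"), mz_of_species(x, "monoisotopic")))
  invisible(x)
}

#' m/z of an oligomer ion
#'
#' Evaluates `(n*M + z*m_proton)/z` with the proton mass fixed at 1.00728 Da.
#'
#' @param species An [ion_species()].
#' @param convention `"average"` or `"monoisotopic"` neutral mass.
#' @return The m/z value (Th).
#' @export
mz_of_species <- function(species, convention = c("average", "monoisotopic")) {
  convention <- match.arg(convention)
  stopifnot(inherits(species, "ion_species"))
  if (species$z == 0) stop("charge must be non-zero")
  M <- if (convention == "average") species$mass_avg else species$mass_mono
  (M + species$z * PROTON_MASS) / species$z
}

#' Nominal (integer) m/z of an oligomer ion
#'
#' The floor of [mz_of_species()], matching the integer peak labels used on
#' native-MS spectra.
#' @inheritParams mz_of_species
#' @return Integer m/z.
#' @export
nominal_mz <- function(species, convention = c("average", "monoisotopic")) {
  as.integer(floor(mz_of_species(species, convention)))
}

#' Composition of an n-mer
#'
#' Elemental composition of a non-covalent n-mer: n times the monomer
#' composition (no condensation).
#' @param composition Monomer [elemental_composition()].
#' @param n Oligomer order.
#' @return An [elemental_composition()].
#' @export
nmer_composition <- function(composition, n) {
  composition <- as_composition(composition)
  stopifnot(n >= 1, n == round(n))
  out <- unclass(composition) * as.integer(n)
  do.call(elemental_composition, as.list(out))
}

#' Read peptide sequences from a FASTA file
#'
#' @param path Path to a FASTA file of amino-acid sequences.
#' @return Named character vector of sequences.
#' @export
read_fasta_sequences <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(set), names(set))
}

#' Write / read an isotope pattern as delimited text
#'
#' Serialization to a two-column (mass, abundance) tab-delimited table with
#' `#`-prefixed key=value header lines carrying the charge.
#' @param pattern An [isotope_pattern()].
#' @param path Output file path.
#' @export
write_isotope_pattern <- function(pattern, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# charge=%d", attr(pattern, "charge")), con)
  utils::write.table(pattern[, c("mass", "abundance")], con, sep = "\t",
                     row.names = FALSE, quote = FALSE)
}

#' @rdname write_isotope_pattern
#' @export
read_isotope_pattern <- function(path) {
  header <- grep("^#", readLines(path), value = TRUE)
  z <- 1L
  m <- regmatches(header, regexec("charge=(\\d+)", header))
  for (hit in m) if (length(hit) == 2) z <- as.integer(hit[2])
  tab <- utils::read.delim(path, comment.char = "#")
  out <- data.frame(mass = tab$mass,
                    mz = (tab$mass + z * PROTON_MASS) / z,
                    abundance = tab$abundance)
  attr(out, "charge") <- z
  class(out) <- c("isotope_pattern", "data.frame")
  out
}
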