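# Sequence-to-mass chemistry for DNA oligonucleotides: elemental
# composition, average/monoisotopic masses, terminal groups, cation
# adducts and m/z in either ionization polarity.

# Embedded atomic mass tables (Da). Average values follow the IUPAC 2021
# abridged standard atomic weights; monoisotopic values are the masses of
# the principal isotopes.
.ATOMIC_MASSES <- list(
  average = c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
              P = 30.973761998, Na = 22.98976928, K = 39.0983),
  monoisotopic = c(H = 1.0078250319, C = 12.0, N = 14.0030740052,
                   O = 15.9949146221, P = 30.97376151,
                   Na = 22.98976928, K = 38.9637064864)
)

# Mass of the charge-carrying proton (Da). Fixed constant, see mz_of().
.PROTON_MASS <- 1.00728

# Elemental formulae of the 2'-deoxyribonucleoside 5'-monophosphates.
# A chain of n residues with a 5'-phosphate and 3'-hydroxyl has
# composition sum(dNMP) - (n - 1) * H2O.
.DNMP_FORMULAE <- list(
  A = c(C = 10, H = 14, N = 5, O = 6, P = 1),
  C = c(C = 9,  H = 14, N = 3, O = 7, P = 1),
  G = c(C = 10, H = 14, N = 5, O = 7, P = 1),
  T = c(C = 10, H = 15, N = 2, O = 8, P = 1)
)

.H2O  <- c(C = 0, H = 2, N = 0, O = 1, P = 0)
.HPO3 <- c(C = 0, H = 1, N = 0, O = 3, P = 1)

.ELEMENTS <- c("C", "H", "N", "O", "P")

#' Embedded atomic mass table
#'
#' Returns the atomic mass table used throughout the package. All
#' computed masses are average (chemical) masses by default, matching the
#' ~15 kDa strands and ~91-277 kDa assemblies this package targets, where
#' isotope envelopes are unresolved; a monoisotopic table is available.
#'
#' @param type `"average"` (default) or `"monoisotopic"`.
#' @return Named numeric vector of atomic masses in Da.
#' @export
atomic_masses <- function(type = c("average", "monoisotopic")) {
  type <- match.arg(type)
  .ATOMIC_MASSES[[type]]
}

#' Define a DNA strand with explicit terminal groups
#'
#' @param label Short identifier, e.g. `"I"`.
#' @param bases Sequence string over the alphabet A/C/G/T.
#' @param terminal5,terminal3 Terminal state of the 5' and 3' ends, either
#'   `"phosphate"` or `"hydroxyl"`. There is no implicit default: both must
#'   be stated because the terminal phosphate contributes 79.98 Da and its
#'   absence is diagnostic (synthesis products may lack it).
#' @return An object of class `oligo_sequence`.
#' @examples
#' oligo_sequence("I", "ACGT", "phosphate", "hydroxyl")
#' @export
oligo_sequence <- function(label, bases, terminal5, terminal3) {
  stopifnot(is.character(label), length(label) == 1L,
            is.character(bases), length(bases) == 1L)
  terminal5 <- match.arg(terminal5, c("phosphate", "hydroxyl"))
  terminal3 <- match.arg(terminal3, c("phosphate", "hydroxyl"))
  if (nchar(bases) == 0L)
    stop("empty sequence for strand '", label, "'")
  chars <- strsplit(toupper(bases), "")[[1]]
  bad <- which(!chars %in% names(.DNMP_FORMULAE))
  if (length(bad) > 0L)
    stop("invalid character '", chars[bad[1]], "' at position ", bad[1],
         " in strand '", label, "' (alphabet is A/C/G/T)")
  structure(
    list(label = label, bases = paste(chars, collapse = ""),
         terminal5 = terminal5, terminal3 = terminal3),
    class = "oligo_sequence")
}

#' @export
print.oligo_sequence <- function(x, ...) {
  cat(sprintf("<oligo_sequence> %s: %d nt, 5'-%s / 3'-%s\n",
              x$label, nchar(x$bases), x$terminal5, x$terminal3))
  invisible(x)
}

#' Elemental composition of a DNA strand
#'
#' Sums the residue formulae of the sequence (one phosphodiester-linked
#' nucleotide each, i.e. dNMP minus water for internal linkages) and
#' adjusts for the declared terminal groups. The baseline chain carries a
#' 5'-phosphate and 3'-hydroxyl; a hydroxyl 5' end removes one HPO3, a
#' phosphate 3' end adds one.
#'
#' @param seq An [oligo_sequence()].
#' @return Named integer vector of class `elemental_composition` with
#'   counts for C, H, N, O, P.
#' @export
composition_of <- function(seq) {
  stopifnot(inherits(seq, "oligo_sequence"))
  chars <- strsplit(seq$bases, "")[[1]]
  n <- length(chars)
  comp <- Reduce(`+`, .DNMP_FORMULAE[chars])
  comp <- comp[.ELEMENTS] - (n - 1L) * .H2O[.ELEMENTS]
  if (seq$terminal5 == "hydroxyl") comp <- comp - .HPO3[.ELEMENTS]
  if (seq$terminal3 == "phosphate") comp <- comp + .HPO3[.ELEMENTS]
  elemental_composition(comp)
}

#' Construct an elemental composition
#'
#' @param counts Named numeric vector with (a subset of) C, H, N, O, P.
#' @return Named integer vector of class `elemental_composition`.
#' @export
elemental_composition <- function(counts) {
  full <- setNames(integer(length(.ELEMENTS)), .ELEMENTS)
  if (length(counts) > 0) {
    stopifnot(!is.null(names(counts)), all(names(counts) %in% .ELEMENTS))
    full[names(counts)] <- as.integer(round(counts))
  }
  if (any(full < 0))
    stop("negative element count in composition")
  structure(full, class = "elemental_composition")
}

#' Average (or monoisotopic) mass of an elemental composition
#'
#' Dot product of element counts with the embedded atomic mass table.
#' Full precision is kept internally; round to 2 decimals for display.
#'
#' @param comp An [elemental_composition()] (or named count vector).
#' @param type Mass table, `"average"` (default) or `"monoisotopic"`.
#' @return Mass in Da.
#' @examples
#' average_mass(elemental_composition(c(H = 1, P = 1, O = 3)))  # 79.98
#' @export
average_mass <- function(comp, type = "average") {
  if (!inherits(comp, "elemental_composition"))
    comp <- elemental_composition(comp)
  masses <- atomic_masses(type)
  sum(unclass(comp) * masses[.ELEMENTS])
}

#' Average mass of a strand
#'
#' Convenience wrapper: `average_mass(composition_of(seq))`.
#' @inheritParams composition_of
#' @param type Mass table passed to [average_mass()].
#' @return Mass in Da.
#' @export
strand_mass <- function(seq, type = "average") {
  average_mass(composition_of(seq), type = type)
}

# Built-in registry of signed mass deltas. Neutral losses remove the
# neutral molecule; cation adducts replace one proton (charge bookkeeping
# is unchanged). The adenosine entry is the 2'-deoxyribonucleoside; the
# nucleotide-level loss is registered separately because observed
# "loss of adenosine" signals do not distinguish the two.
.modification_registry <- function() {
  am <- .ATOMIC_MASSES$average
  f <- function(v) sum(am[names(v)] * v)
  list(
    loss_terminal_phosphate   = -f(c(H = 1, P = 1, O = 3)),
    loss_adenine              = -f(c(C = 5, H = 5, N = 5)),
    loss_adenosine_unit       = -f(c(C = 10, H = 13, N = 5, O = 3)),
    loss_adenosine_nucleotide = -f(c(C = 10, H = 12, N = 5, O = 5, P = 1)),
    sodium_adduct             = f(c(Na = 1)) - f(c(H = 1)),
    potassium_adduct          = f(c(K = 1)) - f(c(H = 1)),
    ammonium_adduct           = f(c(N = 1, H = 4)) - f(c(H = 1))
  )
}

.mod_env <- new.env(parent = emptyenv())

.get_registry <- function() {
  if (is.null(.mod_env$registry)) .mod_env$registry <- .modification_registry()
  .mod_env$registry
}

#' Signed mass delta of a named modification
#'
#' Looks up the signed average-mass delta for a strand modification or
#' adduct. Cation adducts are modelled as the cation replacing one proton
#' on the phosphate backbone (so a sodium adduct is +21.98 Da and does not
#' change the charge state); base and nucleoside losses are neutral
#' removals.
#'
#' @param name One of the registered names, see [list_modifications()].
#' @return Signed mass delta in Da.
#' @examples
#' modification_delta("loss_terminal_phosphate")  # -79.98
#' modification_delta("sodium_adduct")            # +21.98
#' @export
modification_delta <- function(name) {
  reg <- .get_registry()
  if (!name %in% names(reg))
    stop("unknown modification '", name, "'; known: ",
         paste(names(reg), collapse = ", "))
  reg[[name]]
}

#' @rdname modification_delta
#' @export
list_modifications <- function() names(.get_registry())

#' @rdname modification_delta
#' @param delta Signed mass delta (Da) to register under `name`.
#' @export
register_modification <- function(name, delta) {
  stopifnot(is.character(name), length(name) == 1L, is.numeric(delta))
  reg <- .get_registry()
  reg[[name]] <- delta
  .mod_env$registry <- reg
  invisible(delta)
}

#' Define an ion species
#'
#' @param neutral_mass Neutral mass M in Da.
#' @param z Positive integer charge.
#' @param polarity `"positive"` or `"negative"`.
#' @param adducts Named integer vector of adduct counts, names from the
#'   modification registry (e.g. `c(sodium_adduct = 2)`); may be empty.
#' @return An object of class `ion_species`.
#' @export
ion_species <- function(neutral_mass, z, polarity = c("positive", "negative"),
                        adducts = integer()) {
  polarity <- match.arg(polarity)
  stopifnot(is.numeric(neutral_mass), neutral_mass > 0,
            z == as.integer(z), z >= 1)
  if (length(adducts) > 0) {
    stopifnot(!is.null(names(adducts)), all(adducts >= 0))
    for (nm in names(adducts)) modification_delta(nm)  # validate names
  }
  structure(list(neutral_mass = neutral_mass, z = as.integer(z),
                 polarity = polarity, adducts = adducts),
            class = "ion_species")
}

#' Mass-to-charge ratio of an ion
#'
#' Positive mode: (M + z * m_p + sum of adduct deltas) / z; negative mode
#' replaces + z * m_p with - z * m_p. The proton mass m_p is fixed at
#' 1.00728 Da. Adducts are proton replacements and therefore enter as
#' plain mass deltas.
#'
#' @param ion An [ion_species()], or a neutral mass in Da (then `z` and
#'   the remaining arguments are used).
#' @param z,polarity,adducts Used only when `ion` is a bare mass.
#' @return m/z in Thomson.
#' @examples
#' mz_of(15397.98, z = 6)  # 2567.337
#' @export
mz_of <- function(ion, z = NULL, polarity = "positive", adducts = integer()) {
  if (inherits(ion, "ion_species")) {
    M <- ion$neutral_mass; z <- ion$z; polarity <- ion$polarity
    adducts <- ion$adducts
  } else {
    stopifnot(is.numeric(ion), !is.null(z), all(z == as.integer(z)), all(z >= 1))
    M <- ion
    polarity <- match.arg(polarity, c("positive", "negative"))
  }
  delta <- 0
  if (length(adducts) > 0) {
    stopifnot(!is.null(names(adducts)), all(adducts >= 0))
    delta <- sum(vapply(names(adducts), modification_delta, 0) *
                   as.numeric(adducts))
  }
  sign <- if (polarity == "positive") 1 else -1
  mz <- (M + sign * z * .PROTON_MASS + delta) / z
  if (any(mz <= 0))
    stop("non-physical m/z (", signif(mz[mz <= 0][1], 4), ") for M = ",
         M[1], ", z = ", z[which(mz <= 0)[1]])
  mz
}

#' Invert m/z to a neutral mass
#'
#' @param mz m/z in Thomson.
#' @param z Integer charge.
#' @param polarity `"positive"` or `"negative"`.
#' @return Neutral mass in Da (assuming no adducts).
#' @export
neutral_mass_of <- function(mz, z, polarity = "positive") {
  sign <- if (polarity == "positive") 1 else -1
  z * mz - sign * z * .PROTON_MASS
}

#' Read strand definitions from CSV or FASTA
#'
#' The CSV must have columns `label`, `sequence`, `terminal5`, `terminal3`
#' (and may carry a `cycle_order` column used by [connectivity_map()]).
#' FASTA input is accepted via `Biostrings::readDNAStringSet()`, but FASTA
#' cannot carry terminal-group flags, so they must be supplied.
#'
#' @param path File path.
#' @param format `"csv"` (default) or `"fasta"`.
#' @param terminal5,terminal3 Terminal flags applied to every FASTA record.
#' @return List of [oligo_sequence()] objects, named by label.
#' @export
read_strands <- function(path, format = c("csv", "fasta"),
                         terminal5 = NULL, terminal3 = NULL) {
  format <- match.arg(format)
  if (format == "csv") {
    df <- read.csv(path, stringsAsFactors = FALSE)
    need <- c("label", "sequence", "terminal5", "terminal3")
    if (!all(need %in% names(df)))
      stop("strand CSV must have columns: ", paste(need, collapse = ", "))
    out <- lapply(seq_len(nrow(df)), function(i)
      oligo_sequence(df$label[i], df$sequence[i], df$terminal5[i], df$terminal3[i]))
  } else {
    if (!requireNamespace("Biostrings", quietly = TRUE))
      stop("FASTA ingest requires the Biostrings package")
    if (is.null(terminal5) || is.null(terminal3))
      stop("FASTA cannot carry terminal groups; supply terminal5/terminal3")
    ss <- Biostrings::readDNAStringSet(path)
    out <- lapply(seq_along(ss), function(i)
      oligo_sequence(names(ss)[i], as.character(ss[[i]]), terminal5, terminal3))
  }
  names(out) <- vapply(out, function(s) s$label, "")
  out
}
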