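# The 14 targeted lipid classes and their headgroup glycan compositions,
# following Svennerholm nomenclature along the biosynthetic pathway:
# GM/GD/GT/GQ carry 1/2/3/4 NeuAc; the trailing digit encodes the neutral
# core (3 = lactosyl, 2 = + GalNAc, 1 = + Gal). GA2 is asialo-GM2.
# Sialylated classes ionize in negative mode with the dehydrated sialic acid
# fragment as quantifier; neutral classes in positive mode with the
# dehydrated sphingosine fragment.

.CLASS_TABLE <- data.frame(
  class     = c("GlcCer", "LacCer", "Gb3", "GA2",
                "GM3", "GM2", "GM1",
                "GD3", "GD2", "GD1",
                "GT3", "GT2", "GT1", "GQ1"),
  n_hex     = c(1L, 2L, 3L, 2L,  2L, 2L, 3L,  2L, 2L, 3L,  2L, 2L, 3L, 3L),
  n_hexnac  = c(0L, 0L, 0L, 1L,  0L, 1L, 1L,  0L, 1L, 1L,  0L, 1L, 1L, 1L),
  n_neuac   = c(0L, 0L, 0L, 0L,  1L, 1L, 1L,  2L, 2L, 2L,  3L, 3L, 3L, 4L),
  stringsAsFactors = FALSE
)
.CLASS_TABLE$polarity <- ifelse(.CLASS_TABLE$n_neuac >= 1L, "negative", "positive")
# Default charge states: [M+H]+ for neutral classes, [M-H]- for monosialo,
# [M-2H]2- for classes with two or more sialic acids. Overridable per panel
# entry.
.CLASS_TABLE$default_charge <- ifelse(.CLASS_TABLE$n_neuac == 0L, 1L,
                               ifelse(.CLASS_TABLE$n_neuac == 1L, -1L, -2L))

#' The targeted glycosphingolipid class table
#'
#' Headgroup glycan composition (Hex / HexNAc / NeuAc counts), detection
#' polarity and default precursor charge state for the 14 targeted classes:
#' 10 ganglioside classes (GM3, GM2, GM1, GD3, GD2, GD1, GT3, GT2, GT1, GQ1)
#' and 4 neutral glycosphingolipid classes (GlcCer, LacCer, Gb3, GA2).
#'
#' @return data.frame with columns `class`, `n_hex`, `n_hexnac`, `n_neuac`,
#'   `polarity`, `default_charge`.
#' @examples
#' gsl_classes()
#' @export
gsl_classes <- function() .CLASS_TABLE

.class_row <- function(class) {
  i <- match(class, .CLASS_TABLE$class)
  if (is.na(i)) {
    stop("unknown lipid class: '", class, "' (known: ",
         paste(.CLASS_TABLE$class, collapse = ", "), ")", call. = FALSE)
  }
  .CLASS_TABLE[i, ]
}

#' Construct a panel species
#'
#' A species is one lipid class paired with one ceramide, in the role of
#' analyte or internal standard. Internal standards must be distinguishable
#' from endogenous analytes: a deuterium label or an odd-carbon acyl chain.
#'
#' @param class Class name from [gsl_classes()].
#' @param ceramide Ceramide shorthand or `ceramide_spec`.
#' @param role `"analyte"` or `"internal_standard"`.
#' @return A `lipid_species` with fields `class`, `ceramide`, `role`, `id`.
#' @examples
#' lipid_species("GM3", "d18:1/18:0")
#' lipid_species("GM1", "d18:1/17:0", role = "internal_standard")
#' @export
lipid_species <- function(class, ceramide, role = c("analyte", "internal_standard")) {
  role <- match.arg(role)
  .class_row(class) # validates
  if (is.character(ceramide)) ceramide <- parse_ceramide(ceramide)
  stopifnot(inherits(ceramide, "ceramide_spec"))
  if (role == "internal_standard" &&
      ceramide$label == 0L && ceramide$acyl_c %% 2L == 0L) {
    stop("internal standard ", class, "(", format(ceramide), ") carries ",
         "neither a deuterium label nor an odd-carbon acyl chain", call. = FALSE)
  }
  structure(list(class = class, ceramide = ceramide, role = role,
                 id = paste0(class, "(", format(ceramide), ")")),
            class = "lipid_species")
}

#' @export
print.lipid_species <- function(x, ...) {
  cat(x$id, "-", x$role, "\n")
  invisible(x)
}

#' Elemental formula of a glycosphingolipid species
#'
#' Intact species = ceramide + nHex * Hex residue + nHexNAc * HexNAc residue
#' + nNeuAc * NeuAc residue, all residues dehydrated (one water lost per
#' glycosidic bond).
#'
#' @param species A `lipid_species`, or a class name (then `ceramide` must be
#'   given).
#' @param ceramide Optional ceramide shorthand/spec when `species` is a class
#'   name.
#' @return A `gsl_formula`.
#' @examples
#' format(species_formula("GM3", "d18:1/18:0")) # C59H108N2O21
#' @export
species_formula <- function(species, ceramide = NULL) {
  if (inherits(species, "lipid_species")) {
    cls <- species$class
    cer <- species$ceramide
  } else {
    cls <- species
    cer <- ceramide
  }
  row <- .class_row(cls)
  f <- ceramide_formula(cer)
  if (row$n_hex > 0)    for (i in seq_len(row$n_hex))    f <- f + .HEX
  if (row$n_hexnac > 0) for (i in seq_len(row$n_hexnac)) f <- f + .HEXNAC
  if (row$n_neuac > 0)  for (i in seq_len(row$n_neuac))  f <- f + .NEUAC
  f
}

#' Monoisotopic precursor m/z
#'
#' m/z = (M + z * m_proton) / |z| for positive charges and
#' (M - |z| * m_proton) / |z| for negative charges, with monoisotopic
#' neutral mass M. Charge sign must match the class's detection polarity:
#' +1 for neutral classes; -1, -2 or -3 for gangliosides.
#'
#' @param species A `lipid_species` or class name.
#' @param charge Signed integer charge; defaults to the class's default
#'   (`+1` neutral, `-1` monosialo, `-2` for two or more NeuAc).
#' @param ceramide Ceramide shorthand/spec when `species` is a class name.
#' @return m/z value.
#' @examples
#' precursor_mz("GM3", charge = -1, ceramide = "d18:1/18:0") # 1179.737
#' @export
precursor_mz <- function(species, charge = NULL, ceramide = NULL) {
  cls <- if (inherits(species, "lipid_species")) species$class else species
  row <- .class_row(cls)
  if (is.null(charge)) charge <- row$default_charge
  charge <- as.integer(charge)
  if (charge == 0L) stop("charge must be non-zero", call. = FALSE)
  if (row$polarity == "positive" && charge != 1L) {
    stop(cls, " is detected in positive mode; charge must be +1", call. = FALSE)
  }
  if (row$polarity == "negative" && !(charge %in% c(-1L, -2L, -3L))) {
    stop(cls, " is detected in negative mode; charge must be -1, -2 or -3",
         call. = FALSE)
  }
  M <- formula_mass(species_formula(species, ceramide))
  (M + charge * PROTON_MASS) / abs(charge)
}

#' Quantifier fragment m/z for a species
#'
#' Sialylated classes fragment to the dehydrated sialic acid anion
#' [NeuAc - H2O - H]- (computed from free NeuAc C11H19NO9), the dominant
#' negative-mode product ion (rounds to m/z 290.1). Neutral classes fragment
#' to the dehydrated sphingosine cation [d18:1 base + H - 2 H2O]+ (from
#' C18H37NO2; rounds to m/z 264.3). Acyl-chain deuterium labels do not shift
#' either fragment; a base label would, but no such standard is used.
#'
#' @param species A `lipid_species` or class name.
#' @return Fragment m/z (singly charged: -1 for the sialic acid fragment,
#'   +1 for sphingosine).
#' @examples
#' round(quantifier_fragment_mz("GM2"), 1) # 290.1
#' round(quantifier_fragment_mz("GlcCer"), 1) # 264.3
#' @export
quantifier_fragment_mz <- function(species) {
  cls <- if (inherits(species, "lipid_species")) species$class else species
  row <- .class_row(cls)
  if (row$n_neuac >= 1L) {
    neuac_free <- .NEUAC + .WATER # C11H19NO9
    formula_mass(neuac_free - .WATER) - PROTON_MASS
  } else {
    sphingosine <- gsl_formula(C = 18, H = 37, N = 1, O = 2)
    formula_mass(sphingosine) + PROTON_MASS - 2 * formula_mass(.WATER)
  }
}
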