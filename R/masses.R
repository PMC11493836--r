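# Monoisotopic mass arithmetic for glycosphingolipid compositions.
#
# All masses are monoisotopic (most abundant isotope), in unified atomic mass
# units. The proton mass used for m/z charge adjustment is the physical proton
# mass, not the mass of a hydrogen atom: an [M-H]- ion has lost a proton and
# kept an electron.

.ATOMIC_MASS <- c(
  C = 12.0,
  H = 1.00782503207,
  D = 2.01410177785, # 2H; deuterium labels replace H one-for-one
  N = 14.0030740048,
  O = 15.9949146196
)

#' Monoisotopic atomic masses used by the package
#'
#' Returns the monoisotopic atomic mass table (CODATA/IUPAC values, in u) on
#' which every composition and m/z computation in the package is based.
#' Deuterium (`D`) is carried as its own element so that isotope-labelled
#' internal standards stay distinguishable from their unlabelled analytes.
#'
#' @return Named numeric vector of monoisotopic masses for C, H, D, N and O.
#' @examples
#' atomic_masses()[["H"]]
#' @export
atomic_masses <- function() .ATOMIC_MASS

#' Mass of a proton in u, used for m/z charge-state arithmetic
#' @export
PROTON_MASS <- 1.00727646

#' Construct an elemental formula
#'
#' An elemental formula is a named integer vector of atom counts over the
#' supported elements (C, H, D, N, O). Formulas support `+` and `-`
#' (element-wise; subtraction that would produce a negative count is an
#' error), [formula_mass()], and a conventional Hill-style `format()`.
#'
#' @param C,H,D,N,O Non-negative integer atom counts. `D` counts deuterium
#'   atoms (each replacing one H relative to the unlabelled species).
#' @return Object of class `gsl_formula`.
#' @examples
#' gsl_formula(C = 36, H = 71, N = 1, O = 3) # ceramide d18:1/18:0
#' @export
gsl_formula <- function(C = 0, H = 0, D = 0, N = 0, O = 0) {
  x <- c(C = C, H = H, D = D, N = N, O = O)
  if (any(is.na(x)) || any(x < 0)) {
    stop("formula counts must be non-negative integers", call. = FALSE)
  }
  if (any(abs(x - round(x)) > 1e-9)) {
    stop("formula counts must be whole numbers", call. = FALSE)
  }
  structure(as.integer(round(x)), names = names(x), class = "gsl_formula")
}

#' @export
`+.gsl_formula` <- function(e1, e2) {
  stopifnot(inherits(e1, "gsl_formula"), inherits(e2, "gsl_formula"))
  structure(unclass(e1) + unclass(e2), names = names(e1), class = "gsl_formula")
}

#' @export
`-.gsl_formula` <- function(e1, e2) {
  stopifnot(inherits(e1, "gsl_formula"), inherits(e2, "gsl_formula"))
  out <- unclass(e1) - unclass(e2)
  if (any(out < 0)) {
    bad <- names(out)[out < 0]
    stop("formula subtraction yields negative count for: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(out, names = names(e1), class = "gsl_formula")
}

#' Monoisotopic mass of an elemental formula
#'
#' @param f A `gsl_formula`.
#' @return Monoisotopic mass in u (0 for the empty formula).
#' @examples
#' formula_mass(gsl_formula(H = 2, O = 1)) # water, 18.0106
#' @export
formula_mass <- function(f) {
  stopifnot(inherits(f, "gsl_formula"))
  sum(unclass(f) * .ATOMIC_MASS[names(f)])
}

#' @export
format.gsl_formula <- function(x, ...) {
  n <- unclass(x)
  parts <- character(0)
  for (el in c("C", "H", "D", "N", "O")) {
    if (n[[el]] > 0) {
      parts <- c(parts, paste0(el, if (n[[el]] > 1) n[[el]] else ""))
    }
  }
  if (!length(parts)) "(empty)" else paste(parts, collapse = "")
}

#' @export
print.gsl_formula <- function(x, ...) {
  cat(format(x), sprintf(" (monoisotopic %.4f u)\n", formula_mass(x)))
  invisible(x)
}

# Dehydrated (in-chain) glycan residue formulas: each glycosidic bond costs
# one water, so residue = free monosaccharide - H2O.
.WATER  <- gsl_formula(H = 2, O = 1)
.HEX    <- gsl_formula(C = 6, H = 10, O = 5)           # hexose residue
.HEXNAC <- gsl_formula(C = 8, H = 13, N = 1, O = 5)    # N-acetylhexosamine residue
.NEUAC  <- gsl_formula(C = 11, H = 17, N = 1, O = 8)   # N-acetylneuraminic acid residue

#' Dehydrated glycan residue formulas
#'
#' In-chain residue compositions (free sugar minus one water) for the three
#' monosaccharides occurring in ganglioside and neutral glycosphingolipid
#' headgroups.
#'
#' @param residue One of `"Hex"`, `"HexNAc"`, `"NeuAc"`.
#' @return A `gsl_formula`.
#' @examples
#' formula_mass(glycan_residue("NeuAc")) # 291.0954
#' @export
glycan_residue <- function(residue = c("Hex", "HexNAc", "NeuAc")) {
  switch(match.arg(residue), Hex = .HEX, HexNAc = .HEXNAC, NeuAc = .NEUAC)
}
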