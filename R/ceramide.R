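# Ceramide shorthand: "d18:1/18:0" is a dihydroxy ("d") sphingoid base with 18
# carbons and 1 double bond, N-acylated with an 18:0 fatty acid. A "-d3"/"-d5"
# suffix marks deuterium labelling of the acyl chain. The summed form "d36:1"
# carries chain totals only; it is resolved against a fixed d18:1 base, the
# base shared by every commercial standard the panel uses.

#' Parse ceramide shorthand
#'
#' Accepts the full form `d<base C>:<base DB>/<acyl C>:<acyl DB>` and the
#' summed form `d<total C>:<total DB>`, each optionally suffixed with `-d3`
#' or `-d5` for a deuterated acyl chain. Summed shorthand is resolved by
#' fixing the sphingoid base at d18:1 and assigning the remaining carbons and
#' double bonds to the N-acyl chain.
#'
#' @param shorthand Character scalar, e.g. `"d18:1/18:0"`, `"d36:1"`,
#'   `"d18:1/16:0-d3"`.
#' @return A `ceramide_spec`: list with `base_c`, `base_db`, `acyl_c`,
#'   `acyl_db`, `label` (deuterium count: 0, 3 or 5).
#' @examples
#' parse_ceramide("d18:1/18:0")
#' parse_ceramide("d34:1") # resolves to d18:1/16:0
#' @export
parse_ceramide <- function(shorthand) {
  stopifnot(is.character(shorthand), length(shorthand) == 1L)
  txt <- trimws(shorthand)

  label <- 0L
  m <- regmatches(txt, regexec("-d([35])$", txt))[[1]]
  if (length(m)) {
    label <- as.integer(m[2])
    txt <- sub("-d[35]$", "", txt)
  }

  full <- regmatches(txt, regexec("^d([0-9]+):([0-9]+)/([0-9]+):([0-9]+)$", txt))[[1]]
  summed <- regmatches(txt, regexec("^d([0-9]+):([0-9]+)$", txt))[[1]]

  if (length(full)) {
    v <- as.integer(full[-1])
    spec <- list(base_c = v[1], base_db = v[2], acyl_c = v[3], acyl_db = v[4],
                 label = label)
  } else if (length(summed)) {
    tot_c <- as.integer(summed[2])
    tot_db <- as.integer(summed[3])
    if (tot_db < 1L) {
      stop("summed shorthand '", shorthand,
           "' implies a d18:1 base but has no double bond", call. = FALSE)
    }
    spec <- list(base_c = 18L, base_db = 1L, acyl_c = tot_c - 18L,
                 acyl_db = tot_db - 1L, label = label)
  } else {
    stop("cannot parse ceramide shorthand: '", shorthand, "'", call. = FALSE)
  }

  if (spec$base_c < 12L || spec$acyl_c < 12L) {
    stop("ceramide '", shorthand, "': chains must have >= 12 carbons",
         call. = FALSE)
  }
  if (spec$label > 0L && 2L * spec$acyl_c < spec$label) {
    stop("ceramide '", shorthand, "': acyl chain too short for label",
         call. = FALSE)
  }
  structure(spec, class = "ceramide_spec")
}

#' Render a ceramide spec as shorthand
#'
#' @param x A `ceramide_spec`.
#' @param style `"full"` for `d18:1/18:0` or `"summed"` for `d36:1`.
#' @param ... Unused.
#' @return Character scalar; round-trips through [parse_ceramide()] in the
#'   full style.
#' @export
format.ceramide_spec <- function(x, style = c("full", "summed"), ...) {
  style <- match.arg(style)
  suffix <- if (x$label > 0) paste0("-d", x$label) else ""
  if (style == "full") {
    sprintf("d%d:%d/%d:%d%s", x$base_c, x$base_db, x$acyl_c, x$acyl_db, suffix)
  } else {
    sprintf("d%d:%d%s", x$base_c + x$acyl_c, x$base_db + x$acyl_db, suffix)
  }
}

#' @export
print.ceramide_spec <- function(x, ...) {
  cat("ceramide", format(x), sprintf("(summed %s)\n", format(x, "summed")))
  invisible(x)
}

#' Elemental formula of an intact ceramide
#'
#' Ceramide = dihydroxy sphingoid base + fatty acid - H2O (the amide bond).
#' A base with n carbons and k double bonds is CnH(2n+3-2k)NO2; an m:j fatty
#' acid is CmH(2m-2j)O2. Deuterium labels replace that many acyl hydrogens.
#'
#' @param spec A `ceramide_spec` or shorthand string.
#' @return A `gsl_formula`.
#' @examples
#' formula_mass(ceramide_formula("d18:1/18:0")) # 565.5434
#' @export
ceramide_formula <- function(spec) {
  if (is.character(spec)) spec <- parse_ceramide(spec)
  stopifnot(inherits(spec, "ceramide_spec"))
  base <- gsl_formula(C = spec$base_c, H = 2 * spec$base_c + 3 - 2 * spec$base_db,
                      N = 1, O = 2)
  acyl <- gsl_formula(C = spec$acyl_c, H = 2 * spec$acyl_c - 2 * spec$acyl_db,
                      O = 2)
  f <- base + acyl - .WATER
  if (spec$label > 0) {
    f <- f - gsl_formula(H = spec$label) + gsl_formula(D = spec$label)
  }
  f
}
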