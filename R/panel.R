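# Scheduled MRM panel construction: 84 analyte transitions over 14 classes
# plus 4 internal-standard transitions, each monitored in a 1-min
# retention-time window within a 15-min gradient, with polarity switching
# between the (negative-mode) gangliosides and (positive-mode) neutral
# glycosphingolipids.

#' Retention-time model for panel scheduling
#'
#' A deliberately simple linear elution model used to place scheduled
#' windows: RT = class base time + chain_slope * (total ceramide carbons -
#' 36) - unsat_slope * total double bonds. Base times encode the observed
#' elution order on a phenyl-hexyl column: the more sialic acids, the
#' earlier the class elutes (GQ1 first, the monosialo GM classes last among
#' gangliosides, neutral classes after). Within a class, longer acyl chains
#' elute later and double bonds slightly earlier. The base values reproduce
#' the elution ordering only; they are scheduling inputs, not predictions of
#' absolute retention.
#'
#' @param base_min Named numeric vector of class base times (min).
#' @param chain_slope_min_per_c Retention shift per ceramide carbon
#'   (min; default 0.05, i.e. 0.1 min per 2 CH2).
#' @param unsat_slope_min_per_db Retention shift per double bond (min).
#' @return List of model parameters.
#' @export
rt_model <- function(base_min = c(
                       GQ1 = 2.8,
                       GT3 = 3.6, GT2 = 3.8, GT1 = 4.0,
                       GD3 = 5.2, GD2 = 5.4, GD1 = 5.6,
                       GM3 = 7.0, GM2 = 7.2, GM1 = 7.4,
                       GA2 = 8.6, Gb3 = 9.0, LacCer = 9.4, GlcCer = 9.8),
                     chain_slope_min_per_c = 0.05,
                     unsat_slope_min_per_db = 0.05) {
  list(base_min = base_min,
       chain_slope_min_per_c = chain_slope_min_per_c,
       unsat_slope_min_per_db = unsat_slope_min_per_db)
}

#' Predict retention time for panel scheduling
#'
#' @param class Class name.
#' @param ceramide Ceramide shorthand or spec.
#' @param model An [rt_model()].
#' @param gradient_min Run length; predicted RT outside (0, gradient_min]
#'   is a configuration error.
#' @return Retention time in minutes.
#' @examples
#' predict_rt("GM3", "d18:1/18:0") > predict_rt("GQ1", "d18:1/18:0")
#' @export
predict_rt <- function(class, ceramide, model = rt_model(), gradient_min = 15) {
  if (!class %in% names(model$base_min)) {
    stop("rt model has no base time for class '", class, "'", call. = FALSE)
  }
  if (is.character(ceramide)) ceramide <- parse_ceramide(ceramide)
  tot_c <- ceramide$base_c + ceramide$acyl_c
  tot_db <- ceramide$base_db + ceramide$acyl_db
  rt <- model$base_min[[class]] +
    model$chain_slope_min_per_c * (tot_c - 36) -
    model$unsat_slope_min_per_db * tot_db
  if (rt <= 0 || rt > gradient_min) {
    stop("predicted RT ", round(rt, 2), " min for ", class, "(",
         format(ceramide), ") falls outside the ", gradient_min,
         "-min run", call. = FALSE)
  }
  rt
}

#' Default internal-standard to class assignment
#'
#' Each analyte class is quantified against the internal standard with the
#' closest chemical structure among the four spiked standards
#' (GM3 d18:1/18:0-d5, GM1 d18:1/17:0, GlcCer d18:1/16:0-d3,
#' Gb3 d18:1/18:0-d3): same class where available, otherwise shared
#' headgroup series (GM3-d5 covers the lactosyl-core gangliosides GD3/GT3;
#' GM1 d18:1/17:0 covers the GalNAc-bearing gangliosides and GA2; GlcCer-d3
#' covers LacCer; Gb3-d3 covers Gb3).
#'
#' @return Named character vector mapping each class to an internal-standard
#'   species id.
#' @export
default_is_map <- function() {
  c(GM3 = "GM3(d18:1/18:0-d5)", GD3 = "GM3(d18:1/18:0-d5)",
    GT3 = "GM3(d18:1/18:0-d5)",
    GM1 = "GM1(d18:1/17:0)", GM2 = "GM1(d18:1/17:0)",
    GD1 = "GM1(d18:1/17:0)", GD2 = "GM1(d18:1/17:0)",
    GT1 = "GM1(d18:1/17:0)", GT2 = "GM1(d18:1/17:0)",
    GQ1 = "GM1(d18:1/17:0)", GA2 = "GM1(d18:1/17:0)",
    GlcCer = "GlcCer(d18:1/16:0-d3)", LacCer = "GlcCer(d18:1/16:0-d3)",
    Gb3 = "Gb3(d18:1/18:0-d3)")
}

#' Default panel configuration
#'
#' Reconstructs the 84-analyte panel as six ceramide species per class
#' (d34:1, d36:1, d38:1, d40:1, d41:1, d42:1 across all 14 classes;
#' 14 x 6 = 84), plus the four internal standards. The per-class species
#' roster is configuration data, not code: replace `ceramides_by_class`
#' (or charge/RT overrides) to match an instrument method exactly.
#'
#' @param ceramides_by_class Named list (class -> character vector of
#'   ceramide shorthands) for analytes.
#' @param internal_standards data.frame with columns `class`, `ceramide`.
#' @param is_map Named character vector, class -> internal-standard species
#'   id (see [default_is_map()]).
#' @param rt_mod An [rt_model()].
#' @param gradient_min Gradient length in minutes.
#' @param rt_window_min Scheduled window width (min); the acquisition
#'   default is 1.0.
#' @param charge_overrides Named integer vector (species id -> charge)
#'   overriding class default charges.
#' @param rt_overrides Named numeric vector (species id -> RT min) replacing
#'   modelled RTs.
#' @return A `panel_config` list.
#' @export
default_panel_config <- function(
    ceramides_by_class = NULL,
    internal_standards = data.frame(
      class = c("GM3", "GM1", "GlcCer", "Gb3"),
      ceramide = c("d18:1/18:0-d5", "d18:1/17:0", "d18:1/16:0-d3",
                   "d18:1/18:0-d3"),
      stringsAsFactors = FALSE),
    is_map = default_is_map(),
    rt_mod = rt_model(),
    gradient_min = 15,
    rt_window_min = 1.0,
    charge_overrides = NULL,
    rt_overrides = NULL) {
  if (is.null(ceramides_by_class)) {
    default_set <- c("d34:1", "d36:1", "d38:1", "d40:1", "d41:1", "d42:1")
    ceramides_by_class <- stats::setNames(
      rep(list(default_set), nrow(gsl_classes())), gsl_classes()$class)
  }
  structure(list(ceramides_by_class = ceramides_by_class,
                 internal_standards = internal_standards,
                 is_map = is_map,
                 rt_model = rt_mod,
                 gradient_min = gradient_min,
                 rt_window_min = rt_window_min,
                 charge_overrides = charge_overrides,
                 rt_overrides = rt_overrides),
            class = "panel_config")
}

.panel_row <- function(sp, cfg) {
  charge <- cfg$charge_overrides[[sp$id]]
  if (is.null(charge)) charge <- .class_row(sp$class)$default_charge
  rt <- cfg$rt_overrides[[sp$id]]
  if (is.null(rt)) {
    rt <- predict_rt(sp$class, sp$ceramide, cfg$rt_model, cfg$gradient_min)
  }
  data.frame(
    transition_id = sp$id,
    species_id = sp$id,
    class = sp$class,
    ceramide = format(sp$ceramide),
    polarity = .class_row(sp$class)$polarity,
    precursor_mz = precursor_mz(sp, charge = charge),
    precursor_charge = as.integer(charge),
    product_mz = quantifier_fragment_mz(sp),
    rt_min = rt,
    rt_window_min = cfg$rt_window_min,
    role = sp$role,
    stringsAsFactors = FALSE)
}

#' Build the scheduled MRM transition panel
#'
#' Expands a panel configuration into one transition per species (analytes
#' and internal standards), with computed precursor and quantifier m/z,
#' class-determined polarity and charge, and a scheduled window centred on
#' the modelled retention time.
#'
#' @param cfg A `panel_config` from [default_panel_config()].
#' @return data.frame with one row per transition and columns
#'   `transition_id`, `species_id`, `class`, `ceramide`, `polarity`,
#'   `precursor_mz`, `precursor_charge`, `product_mz`, `rt_min`,
#'   `rt_window_min`, `role`.
#' @examples
#' p <- build_panel(default_panel_config())
#' sum(p$role == "analyte") # 84
#' @export
build_panel <- function(cfg = default_panel_config()) {
  stopifnot(inherits(cfg, "panel_config"))
  rows <- list()
  for (cls in names(cfg$ceramides_by_class)) {
    if (!cls %in% names(cfg$is_map)) {
      stop("no internal standard assigned for class '", cls, "'",
           call. = FALSE)
    }
    for (cer in cfg$ceramides_by_class[[cls]]) {
      rows[[length(rows) + 1L]] <- .panel_row(lipid_species(cls, cer), cfg)
    }
  }
  for (i in seq_len(nrow(cfg$internal_standards))) {
    sp <- lipid_species(cfg$internal_standards$class[i],
                        cfg$internal_standards$ceramide[i],
                        role = "internal_standard")
    rows[[length(rows) + 1L]] <- .panel_row(sp, cfg)
  }
  panel <- do.call(rbind, rows)
  dup <- panel$transition_id[duplicated(panel$transition_id)]
  if (length(dup)) {
    stop("duplicate transition id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  lo <- panel$rt_min - panel$rt_window_min / 2
  hi <- panel$rt_min + panel$rt_window_min / 2
  if (any(lo <= 0) || any(hi > cfg$gradient_min)) {
    bad <- panel$transition_id[lo <= 0 | hi > cfg$gradient_min]
    stop("scheduled window outside the run for: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  rownames(panel) <- NULL
  panel
}

.NATIVE_COLS <- c("transition_id", "species_id", "class", "ceramide",
                  "polarity", "precursor_mz", "precursor_charge",
                  "product_mz", "rt_min", "rt_window_min", "role")

#' Write a transition list
#'
#' The native dialect is a lossless CSV round-trip of all transition fields.
#' The Skyline dialect exports the small-molecule column layout (Molecule
#' List Name, Precursor Name, Precursor Adduct, Precursor m/z, Precursor
#' Charge, Product m/z, Explicit Retention Time) for import into Skyline;
#' it is export-only.
#'
#' @param panel Transition data.frame from [build_panel()].
#' @param path Output CSV path.
#' @param dialect `"native"` or `"skyline"`.
#' @return `path`, invisibly.
#' @export
write_transition_list <- function(panel, path, dialect = c("native", "skyline")) {
  dialect <- match.arg(dialect)
  if (dialect == "native") {
    missing_cols <- setdiff(.NATIVE_COLS, names(panel))
    if (length(missing_cols)) {
      stop("panel is missing column(s): ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    utils::write.csv(panel[, .NATIVE_COLS], path, row.names = FALSE)
  } else {
    adduct <- ifelse(panel$precursor_charge > 0,
                     ifelse(panel$precursor_charge == 1, "[M+H]",
                            sprintf("[M+%dH]", panel$precursor_charge)),
                     ifelse(panel$precursor_charge == -1, "[M-H]",
                            sprintf("[M-%dH]", abs(panel$precursor_charge))))
    sky <- data.frame(
      `Molecule List Name` = panel$class,
      `Precursor Name` = panel$species_id,
      `Precursor Adduct` = adduct,
      `Precursor m/z` = panel$precursor_mz,
      `Precursor Charge` = panel$precursor_charge,
      `Product m/z` = panel$product_mz,
      `Explicit Retention Time` = panel$rt_min,
      check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.csv(sky, path, row.names = FALSE)
  }
  invisible(path)
}

#' Read a native-dialect transition list
#'
#' Validates the column set, m/z numericity and transition-id uniqueness;
#' errors name the offending row or id.
#'
#' @param path CSV path written by [write_transition_list()] (native
#'   dialect).
#' @return Transition data.frame.
#' @export
read_transition_list <- function(path) {
  panel <- utils::read.csv(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  unknown <- setdiff(names(panel), .NATIVE_COLS)
  if (length(unknown)) {
    stop("unknown column(s) in transition list: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  missing_cols <- setdiff(.NATIVE_COLS, names(panel))
  if (length(missing_cols)) {
    stop("transition list missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  panel <- panel[, .NATIVE_COLS]
  for (col in c("precursor_mz", "product_mz", "rt_min", "rt_window_min")) {
    v <- suppressWarnings(as.numeric(panel[[col]]))
    bad <- which(is.na(v) & !is.na(panel[[col]]) & nzchar(panel[[col]]))
    if (length(bad)) {
      stop("non-numeric ", col, " at row ", bad[1], ": '",
           panel[[col]][bad[1]], "'", call. = FALSE)
    }
    panel[[col]] <- v
  }
  panel$precursor_charge <- as.integer(panel$precursor_charge)
  dup <- panel$transition_id[duplicated(panel$transition_id)]
  if (length(dup)) {
    stop("duplicate transition id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  panel
}
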