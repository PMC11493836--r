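# Extracted-ion-chromatogram quantification: peak integration, internal-
# standard normalization, calibration and back-calculation. The integration
# algorithm is deterministic and fully specified so that closed-form areas
# can test it: 3-point median smoothing locates the apex, the local noise is
# estimated from the quietest quarter of the window, boundaries fall where
# the smoothed signal returns to baseline + 1 x noise, and the area is the
# trapezoidal integral above baseline between the boundaries.

#' Integrate one chromatographic peak
#'
#' @param time_min Time points (min) inside one transition's scheduled
#'   window.
#' @param intensity Intensities at those points.
#' @return A one-row data.frame (`peak_result`): `apex_rt`, `height`,
#'   `left_min`, `right_min`, `area`, `baseline`, `noise`, `snr`,
#'   `detected`. An empty or featureless trace gives `area = 0` with
#'   `detected = FALSE`, never an error. Detection requires at least one
#'   smoothed point above baseline + 3 x noise.
#' @examples
#' t <- seq(0, 1, by = 1/60)
#' y <- 5 * dnorm(t, 0.5, 0.05)
#' integrate_peak(t, y)$area # ~5
#' @export
integrate_peak <- function(time_min, intensity) {
  nd <- data.frame(apex_rt = NA_real_, height = 0, left_min = NA_real_,
                   right_min = NA_real_, area = 0, baseline = NA_real_,
                   noise = NA_real_, snr = NA_real_, detected = FALSE)
  ok <- is.finite(time_min) & is.finite(intensity)
  time_min <- time_min[ok]; intensity <- intensity[ok]
  if (length(time_min) < 3L) return(nd)
  o <- order(time_min)
  t <- time_min[o]; y <- intensity[o]

  sm <- as.numeric(stats::runmed(y, 3, endrule = "median"))
  lowq <- sm[sm <= stats::quantile(sm, 0.25)]
  baseline <- stats::median(lowq)
  noise <- stats::mad(lowq)

  apex_i <- which.max(sm)
  if (!(sm[apex_i] > baseline + 3 * noise)) {
    nd$baseline <- baseline; nd$noise <- noise
    return(nd)
  }
  thr <- baseline + noise
  below_left <- which(sm[seq_len(apex_i)] <= thr)
  left_i <- if (length(below_left)) max(below_left) else 1L
  right_part <- which(sm[apex_i:length(sm)] <= thr)
  right_i <- if (length(right_part)) apex_i + min(right_part) - 1L else length(sm)

  idx <- left_i:right_i
  yy <- y[idx] - baseline
  tt <- t[idx]
  area <- sum(diff(tt) * (utils::head(yy, -1) + utils::tail(yy, -1)) / 2)
  area <- max(area, 0)
  height <- sm[apex_i] - baseline
  data.frame(apex_rt = t[apex_i], height = height, left_min = t[left_i],
             right_min = t[right_i], area = area, baseline = baseline,
             noise = noise,
             snr = if (noise > 0) height / noise else Inf,
             detected = TRUE)
}

#' Match a species to its internal standard
#'
#' @param class Analyte class name (or a `lipid_species`).
#' @param is_map Named map class -> internal-standard species id; see
#'   [default_is_map()].
#' @return Internal-standard species id.
#' @export
match_internal_standard <- function(class, is_map = default_is_map()) {
  if (inherits(class, "lipid_species")) class <- class$class
  if (!class %in% names(is_map)) {
    stop("no internal standard mapped for class '", class, "'", call. = FALSE)
  }
  is_map[[class]]
}

#' Fit a calibration curve and limit of detection
#'
#' Unweighted ordinary least squares of response ratio on amount. The
#' residual standard deviation Sy uses the n - 2 denominator, and
#' LOD = 3.3 * Sy / S with slope S. By default Sy comes from the full
#' curve; `lod_levels` restricts the Sy estimate to the lowest k distinct
#' levels (the levels approximating the LOD), with the full-curve slope.
#'
#' @param amount Known amounts (fmol).
#' @param response Measured response ratios (analyte area / IS area).
#' @param weighting `"none"` (default, plain OLS) or `"1/x"` (weights
#'   1/amount). Over a wide dynamic range with signal-proportional noise,
#'   the unweighted intercept is dominated by the top levels and can bias
#'   back-calculation near the bottom of the curve; 1/x weighting is the
#'   conventional remedy and is what the cohort workflow uses.
#' @param lod_levels Optional integer: number of lowest distinct levels
#'   used for Sy.
#' @param species_id Optional label carried on the fit.
#' @return A `calibration_fit`: `species_id`, `slope`, `intercept`, `r2`,
#'   `sy`, `lod`, `range`, `n`, and `usable` (TRUE iff the slope is
#'   positive).
#' @examples
#' f <- fit_calibration(c(1, 2, 4, 8), 0.11 * c(1, 2, 4, 8))
#' f$lod # 0: an exact line has Sy = 0
#' @export
fit_calibration <- function(amount, response, weighting = c("none", "1/x"),
                            lod_levels = NULL, species_id = NA_character_) {
  weighting <- match.arg(weighting)
  keep <- is.finite(amount) & is.finite(response)
  amount <- amount[keep]; response <- response[keep]
  if (length(unique(amount)) < 3L) {
    stop("calibration needs at least 3 distinct levels", call. = FALSE)
  }
  if (stats::sd(amount) == 0) stop("zero-variance amounts", call. = FALSE)
  fit <- if (weighting == "1/x") {
    stats::lm(response ~ amount, weights = 1 / amount)
  } else {
    stats::lm(response ~ amount)
  }
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  res <- stats::residuals(fit)
  n <- length(res)
  sy <- sqrt(sum(res^2) / (n - 2))
  ss_tot <- sum((response - mean(response))^2)
  r2 <- if (ss_tot > 0) 1 - sum(res^2) / ss_tot else 1
  if (!is.null(lod_levels)) {
    lv <- sort(unique(amount))
    low <- amount %in% lv[seq_len(min(lod_levels, length(lv)))]
    if (sum(low) >= 3L) sy <- sqrt(sum(res[low]^2) / (sum(low) - 2))
  }
  structure(list(species_id = species_id, slope = slope,
                 intercept = intercept, r2 = r2, sy = sy,
                 lod = 3.3 * sy / slope, range = range(amount), n = n,
                 usable = slope > 0),
            class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf("calibration %s: y = %.4g x + %.4g, r2 = %.4f, Sy = %.4g, LOD = %.4g fmol\n",
              if (is.na(x$species_id)) "" else x$species_id,
              x$slope, x$intercept, x$r2, x$sy, x$lod))
  invisible(x)
}

#' Quantify one sample's chromatograms
#'
#' Integrates every panel transition's trace, normalizes analyte peak areas
#' to the matched internal standard's area, and back-calculates amounts as
#' (ratio - intercept) / slope where a calibration fit is supplied.
#' Negative back-calculations are floored at 0 and flagged. If an internal
#' standard is not detected, every analyte assigned to it is flagged
#' `is_not_detected` and left unquantified (no division).
#'
#' @param chrom Long-format chromatogram table (one sample): `sample_id`,
#'   `transition_id`, `time_min`, `intensity`.
#' @param panel Transition data.frame from [build_panel()].
#' @param is_map Class -> internal-standard species id map.
#' @param calibrations Optional named list of [fit_calibration()] results,
#'   keyed by species id.
#' @return data.frame of quantification records: `sample_id`, `species_id`,
#'   `class`, `ceramide`, `area`, `is_id`, `is_area`, `response_ratio`,
#'   `amount_fmol`, `flags`.
#' @export
quantify_sample <- function(chrom, panel, is_map = default_is_map(),
                            calibrations = NULL) {
  sid <- unique(chrom$sample_id)
  if (length(sid) != 1L) {
    stop("quantify_sample expects exactly one sample (got ",
         length(sid), "); use quantify_samples()", call. = FALSE)
  }
  peaks <- lapply(split(chrom, chrom$transition_id), function(d) {
    integrate_peak(d$time_min, d$intensity)
  })
  peak_area <- function(id) {
    p <- peaks[[id]]
    if (is.null(p)) data.frame(area = 0, detected = FALSE) else p
  }
  analytes <- panel[panel$role == "analyte", , drop = FALSE]
  is_rows <- panel[panel$role == "internal_standard", , drop = FALSE]

  out <- vector("list", nrow(analytes))
  for (i in seq_len(nrow(analytes))) {
    a <- analytes[i, ]
    pk <- peak_area(a$transition_id)
    is_id <- match_internal_standard(a$class, is_map)
    if (!is_id %in% is_rows$species_id) {
      stop("internal standard '", is_id, "' is not in the panel", call. = FALSE)
    }
    is_pk <- peak_area(is_rows$transition_id[is_rows$species_id == is_id])
    flags <- character(0)
    if (!pk$detected) flags <- c(flags, "not_detected")
    ratio <- NA_real_
    amount <- NA_real_
    if (!is_pk$detected || is_pk$area <= 0) {
      flags <- c(flags, "is_not_detected")
    } else {
      ratio <- pk$area / is_pk$area
      cal <- calibrations[[a$species_id]]
      if (!is.null(cal)) {
        amount <- (ratio - cal$intercept) / cal$slope
        if (amount < 0) {
          amount <- 0
          flags <- c(flags, "below_zero")
        }
      }
    }
    out[[i]] <- data.frame(
      sample_id = sid, species_id = a$species_id, class = a$class,
      ceramide = a$ceramide, area = pk$area,
      is_id = is_id, is_area = if (is_pk$detected) is_pk$area else NA_real_,
      response_ratio = ratio, amount_fmol = amount,
      flags = paste(flags, collapse = ","), stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Quantify a multi-sample chromatogram table
#'
#' @inheritParams quantify_sample
#' @return Row-bound quantification records for every sample.
#' @export
quantify_samples <- function(chrom, panel, is_map = default_is_map(),
                             calibrations = NULL) {
  parts <- lapply(split(chrom, chrom$sample_id), quantify_sample,
                  panel = panel, is_map = is_map, calibrations = calibrations)
  res <- do.call(rbind, parts)
  rownames(res) <- NULL
  res
}

#' Fit calibrations for every species in a calibrator series
#'
#' @param records Quantification records of calibrator samples (from
#'   [quantify_samples()]).
#' @param levels Named numeric: sample id -> spiked amount (fmol).
#' @param min_detected_fraction Minimum fraction of a species' calibrator
#'   injections with a detected peak for a curve to be fitted; screens out
#'   unspiked panel species whose blank traces occasionally cross the
#'   detection threshold.
#' @param ... Passed to [fit_calibration()].
#' @return Named list of `calibration_fit`s, keyed by species id (species
#'   not detected consistently, or with fewer than 3 usable levels, are
#'   skipped).
#' @export
calibrate_from_series <- function(records, levels,
                                  min_detected_fraction = 0.5, ...) {
  records$amount_true <- levels[records$sample_id]
  fits <- list()
  for (sp in unique(records$species_id)) {
    all_r <- records[records$species_id == sp, ]
    det <- !grepl("not_detected", all_r$flags)
    if (mean(det) < min_detected_fraction) next
    r <- all_r[det & is.finite(all_r$response_ratio), ]
    if (nrow(r) == 0L || length(unique(r$amount_true)) < 3L) next
    fits[[sp]] <- fit_calibration(r$amount_true, r$response_ratio,
                                  species_id = sp, ...)
  }
  fits
}
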