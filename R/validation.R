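# Bioanalytical method-validation metrics: precision (CV%), extraction
# yield, matrix factor, and storage-stability verdicts. These are exact
# ratio/summary computations on quantification tables; all percentages are
# on the 0-100 scale.

#' Intra- and inter-assay precision
#'
#' CV% = 100 * SD / mean per species per QC level. Intra-assay summarises
#' same-day replicates; inter-assay summarises the full multi-day design,
#' either pooled over all measurements (default; 5/day x 5 days = 25) or
#' over the per-day means (`method = "day_means"`).
#'
#' @param records data.frame with columns `species_id`, `level`, `day`,
#'   `replicate` and `value` (typically the response ratio).
#' @param design `"intra"` (within one day; `records` may contain several
#'   days, each summarised separately and then averaged) or `"inter"`.
#' @param method Inter-assay aggregation: `"pooled"` or `"day_means"`.
#' @return data.frame: `species_id`, `level`, `design`, `n`, `mean`, `sd`,
#'   `cv_pct`.
#' @export
assay_precision <- function(records, design = c("intra", "inter"),
                            method = c("pooled", "day_means")) {
  design <- match.arg(design)
  method <- match.arg(method)
  needed <- c("species_id", "level", "day", "value")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols)) {
    stop("records missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  cells <- split(records, records[c("species_id", "level")], drop = TRUE)
  out <- lapply(cells, function(d) {
    if (design == "intra") {
      per_day <- split(d$value, d$day)
      per_day <- per_day[lengths(per_day) >= 2L]
      if (!length(per_day)) stop("need >= 2 replicates per day", call. = FALSE)
      cvs <- vapply(per_day, function(v) 100 * stats::sd(v) / mean(v), 0)
      m <- mean(vapply(per_day, mean, 0))
      s <- mean(vapply(per_day, stats::sd, 0))
      data.frame(species_id = d$species_id[1], level = d$level[1],
                 design = "intra", n = min(lengths(per_day)),
                 mean = m, sd = s, cv_pct = mean(cvs),
                 stringsAsFactors = FALSE)
    } else {
      v <- if (method == "pooled") d$value else
        vapply(split(d$value, d$day), mean, 0)
      if (length(v) < 2L) stop("need >= 2 values for inter-assay CV",
                               call. = FALSE)
      data.frame(species_id = d$species_id[1], level = d$level[1],
                 design = "inter", n = length(v),
                 mean = mean(v), sd = stats::sd(v),
                 cv_pct = 100 * stats::sd(v) / mean(v),
                 stringsAsFactors = FALSE)
    }
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Extraction yield per standard
#'
#' yield% = 100 * (calculated amount spiked before extraction) /
#' (calculated amount spiked after extraction), paired by standard.
#'
#' @param before,after Named numeric vectors (standard -> calculated
#'   amount), with identical names.
#' @return Named numeric vector of yields (%).
#' @examples
#' extraction_yield(c(GM3 = 0.9), c(GM3 = 1.0)) # 90
#' @export
extraction_yield <- function(before, after) {
  if (!setequal(names(before), names(after))) {
    stop("'before' and 'after' must cover the same standards", call. = FALSE)
  }
  after <- after[names(before)]
  if (any(after <= 0)) stop("'after' amounts must be positive", call. = FALSE)
  100 * before / after
}

#' Matrix factor per standard
#'
#' matrix factor% = 100 * (peak area in matrix) / (peak area in neat
#' solvent), paired by standard (and computed separately per QC level).
#'
#' @param matrix_areas,neat_areas Named numeric vectors with identical
#'   names.
#' @return Named numeric vector of matrix factors (%).
#' @export
matrix_factor <- function(matrix_areas, neat_areas) {
  if (!setequal(names(matrix_areas), names(neat_areas))) {
    stop("'matrix_areas' and 'neat_areas' must cover the same standards",
         call. = FALSE)
  }
  neat_areas <- neat_areas[names(matrix_areas)]
  if (any(neat_areas <= 0)) stop("neat areas must be positive", call. = FALSE)
  100 * matrix_areas / neat_areas
}

#' Storage-stability verdict per class and time point
#'
#' Relative recovery% = 100 * value / baseline value, on per-class summed
#' IS-normalized response ratios. A class is unstable at a time point iff
#' its recovery changed by strictly more than the threshold from baseline
#' (|recovery - 100| > threshold); a change of exactly the threshold is
#' still stable.
#'
#' @param series data.frame with columns `class`, `time` and `value`
#'   (per-class summed normalized response); `time == 0` rows are the
#'   baseline and must be present for every class.
#' @param threshold Instability threshold in percentage points
#'   (default 15).
#' @return data.frame: `class`, `time`, `recovery_pct`, `stable`.
#' @export
stability_verdict <- function(series, threshold = 15) {
  stopifnot(threshold > 0,
            all(c("class", "time", "value") %in% names(series)))
  out <- lapply(split(series, series$class), function(d) {
    base <- d$value[d$time == 0]
    if (length(base) != 1L) {
      stop("class '", d$class[1], "' needs exactly one baseline (time 0) value",
           call. = FALSE)
    }
    if (base <= 0) stop("baseline value must be positive for class '",
                        d$class[1], "'", call. = FALSE)
    rec <- 100 * d$value / base
    data.frame(class = d$class, time = d$time, recovery_pct = rec,
               stable = abs(rec - 100) <= threshold,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$class, res$time), ]
}

#' Per-class summed normalized response from quantification records
#'
#' Helper that aggregates a quantification table to class level by summing
#' the IS-normalized response ratios of the targeted subspecies, the unit
#' used by the stability assessment.
#'
#' @param records Quantification records with `class` and `response_ratio`.
#' @return data.frame `class`, `value`.
#' @export
class_response_sums <- function(records) {
  r <- records[is.finite(records$response_ratio), ]
  agg <- stats::aggregate(list(value = r$response_ratio),
                          by = list(class = r$class), FUN = sum)
  agg[order(agg$class), ]
}
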