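# Synthetic scheduled-MRM acquisition. The simulator is the package's stand-in
# for instrument output: it generates long-format chromatogram tables with the
# statistical structure the downstream analysis assumes -- points only inside
# each transition's scheduled window, Gaussian (optionally tailed) peaks whose
# areas are linear in spiked amount below saturation, additive plus
# signal-proportional point noise, and an injection-level amplitude term that
# carries the run-to-run variability real QC replicates show.

#' Acquisition model for the chromatogram simulator
#'
#' @param cycle_s MRM cycle time in seconds; sets the chromatogram point
#'   spacing.
#' @param peak_sigma_s Gaussian peak width (sigma) in seconds.
#' @param shape `"gaussian"` or `"emg"` (exponentially modified Gaussian
#'   with decay `tau_s`, giving a tailing peak).
#' @param tau_s EMG tail time constant in seconds (ignored for
#'   `"gaussian"`).
#' @param baseline Constant baseline level (counts).
#' @param noise_sd Additive Gaussian point noise sigma (counts).
#' @param noise_prop Signal-proportional point noise (fraction of the
#'   noiseless signal at each point).
#' @param peak_cv Injection-level log-normal amplitude variability (sdlog)
#'   applied once per peak; this is what dominates replicate-to-replicate
#'   area CVs, as point noise largely averages out on integration.
#' @param response_factor Peak area units per fmol, scalar or named per
#'   class.
#' @param saturation Detector cap (counts); intensities are clipped here.
#' @param rt_jitter_sd_min Per-sample retention-time jitter sigma (min).
#'   Jitter is drawn from the sample identity, not the noise seed, so two
#'   noise seeds give identical peak locations.
#' @return An `acquisition_model` list.
#' @export
acquisition_model <- function(cycle_s = 1, peak_sigma_s = 3,
                              shape = c("gaussian", "emg"), tau_s = 2,
                              baseline = 50, noise_sd = 20,
                              noise_prop = 0.01, peak_cv = 0.02,
                              response_factor = 100, saturation = 5e6,
                              rt_jitter_sd_min = 0.02) {
  shape <- match.arg(shape)
  stopifnot(cycle_s > 0, peak_sigma_s > 0, baseline >= 0, noise_sd >= 0,
            noise_prop >= 0, peak_cv >= 0, all(response_factor > 0),
            saturation > 0, rt_jitter_sd_min >= 0)
  structure(list(cycle_s = cycle_s, peak_sigma_s = peak_sigma_s,
                 shape = shape, tau_s = tau_s, baseline = baseline,
                 noise_sd = noise_sd, noise_prop = noise_prop,
                 peak_cv = peak_cv, response_factor = response_factor,
                 saturation = saturation,
                 rt_jitter_sd_min = rt_jitter_sd_min),
            class = "acquisition_model")
}

#' Plan one simulated injection
#'
#' A sample plan carries everything one injection needs: per-species true
#' amounts (fmol, per-injection equivalents), the internal-standard spike,
#' and the sample-level distortions the validation experiments probe
#' (matrix factor, extraction efficiency). Internal standards are spiked at
#' reconstitution, so their extraction efficiency defaults to 1.
#'
#' @param sample_id Unique sample identifier.
#' @param amounts Named numeric vector: species id -> true amount (fmol).
#'   Species absent from the vector are simulated at amount 0.
#' @param group Sample group label (e.g. `"control"`, `"Tay-Sachs"`,
#'   `"Sandhoff"`, `"QC-low"`, `"QC-high"`, `"calibrator"`, `"blank"`).
#' @param is_amount Internal-standard spike (fmol), scalar or named per IS
#'   species id.
#' @param matrix_factor Ion suppression/enhancement factor applied to all
#'   peak areas in this sample (1 = neat solvent).
#' @param extraction_efficiency Fraction of analyte surviving sample
#'   preparation.
#' @param is_extraction_efficiency Same for the internal standards
#'   (default 1: spiked after extraction).
#' @param day,replicate Optional run-design coordinates (used by the
#'   precision experiments).
#' @param seed Integer seed for this injection's noise.
#' @return A `sample_plan` list.
#' @export
sample_plan <- function(sample_id, amounts, group = "control",
                        is_amount = 1000, matrix_factor = 1,
                        extraction_efficiency = 0.973,
                        is_extraction_efficiency = 1,
                        day = 1L, replicate = 1L, seed = 1L) {
  stopifnot(is.numeric(amounts), !is.null(names(amounts)) || length(amounts) == 0,
            all(amounts >= 0), all(is_amount >= 0),
            matrix_factor > 0, matrix_factor <= 1.2,
            extraction_efficiency > 0, extraction_efficiency <= 1.2)
  structure(list(sample_id = sample_id, group = group, amounts = amounts,
                 is_amount = is_amount, matrix_factor = matrix_factor,
                 extraction_efficiency = extraction_efficiency,
                 is_extraction_efficiency = is_extraction_efficiency,
                 day = day, replicate = replicate, seed = as.integer(seed)),
            class = "sample_plan")
}

# Deterministic small hash of a string, for sample-identity RNG streams.
.id_seed <- function(x) {
  v <- utf8ToInt(as.character(x))
  s <- 0
  for (ch in v) s <- (s * 31 + ch) %% 2147483.0
  as.integer(s) + 1L
}

# Area-normalized exponentially modified Gaussian (tailing peak shape).
# erfc(x) = 2 * pnorm(x * sqrt(2), lower.tail = FALSE)
.emg_density <- function(t, mu, sigma, tau) {
  l <- 1 / tau
  z <- (mu + l * sigma^2 - t) / (sqrt(2) * sigma)
  0.5 * l * exp(0.5 * l * (2 * mu + l * sigma^2 - 2 * t)) *
    2 * stats::pnorm(z * sqrt(2), lower.tail = FALSE)
}

#' Simulate scheduled-MRM chromatograms for one injection
#'
#' Produces a time/intensity trace per panel transition, with points only
#' inside the transition's scheduled window. The (noise-free) peak area in
#' intensity x minutes equals `amount x response factor x matrix factor x
#' extraction efficiency`; integrating the trace and dividing by the
#' response factor therefore recovers the effective on-column amount.
#' Identical seed and plan give bit-identical output.
#'
#' @param panel Transition data.frame from [build_panel()].
#' @param plan A [sample_plan()].
#' @param acq An [acquisition_model()].
#' @return Long-format data.frame: `sample_id`, `transition_id`,
#'   `time_min`, `intensity`.
#' @export
simulate_chromatograms <- function(panel, plan, acq = acquisition_model()) {
  stopifnot(inherits(plan, "sample_plan"), inherits(acq, "acquisition_model"))
  unknown <- setdiff(names(plan$amounts), panel$species_id)
  if (length(unknown)) {
    stop("plan species absent from panel: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  sigma_min <- acq$peak_sigma_s / 60
  dt <- acq$cycle_s / 60

  # RT jitter from the sample identity so noise seeds do not move peaks.
  set.seed(.id_seed(plan$sample_id))
  jitter <- stats::rnorm(nrow(panel), 0, acq$rt_jitter_sd_min)

  set.seed(plan$seed)
  out <- vector("list", nrow(panel))
  for (i in seq_len(nrow(panel))) {
    tr <- panel[i, ]
    if (tr$role == "internal_standard") {
      amt <- if (length(plan$is_amount) > 1L) {
        v <- unname(plan$is_amount[tr$species_id])
        if (is.na(v)) 0 else v
      } else plan$is_amount
      amt <- amt * plan$is_extraction_efficiency * plan$matrix_factor
    } else {
      amt <- unname(plan$amounts[tr$species_id])
      if (length(amt) != 1L || is.na(amt)) amt <- 0
      amt <- amt * plan$extraction_efficiency * plan$matrix_factor
    }
    rf <- if (length(acq$response_factor) > 1L) {
      acq$response_factor[[tr$class]]
    } else acq$response_factor

    area <- amt * rf
    if (area > 0 && acq$peak_cv > 0) {
      area <- area * exp(stats::rnorm(1, 0, acq$peak_cv))
    }
    half <- tr$rt_window_min / 2
    t <- seq(tr$rt_min - half, tr$rt_min + half, by = dt)
    mu <- tr$rt_min + jitter[i]
    signal <- if (area > 0) {
      if (acq$shape == "emg" && acq$tau_s > 0) {
        area * .emg_density(t, mu, sigma_min, acq$tau_s / 60)
      } else {
        area * stats::dnorm(t, mu, sigma_min)
      }
    } else {
      rep(0, length(t))
    }
    y <- signal + acq$baseline
    if (acq$noise_sd > 0) y <- y + stats::rnorm(length(t), 0, acq$noise_sd)
    if (acq$noise_prop > 0) {
      y <- y + stats::rnorm(length(t), 0, acq$noise_prop * pmax(signal, 0))
    }
    y <- pmin(pmax(y, 0), acq$saturation)
    out[[i]] <- data.frame(sample_id = plan$sample_id,
                           transition_id = tr$transition_id,
                           time_min = t, intensity = y,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Simulate a list of planned injections
#'
#' @param panel Transition data.frame.
#' @param plans List of [sample_plan()]s.
#' @param acq An [acquisition_model()].
#' @return Row-bound long-format chromatogram table.
#' @export
simulate_plans <- function(panel, plans, acq = acquisition_model()) {
  do.call(rbind, lapply(plans, simulate_chromatograms, panel = panel, acq = acq))
}

#' The eleven calibration standards
#'
#' The standard mixture used for calibration curves and QC samples: one
#' d18:1/18:0 species for each of GM3, GM2, GM1, GD3, GD2, GD1 and GT1,
#' plus GlcCer d18:1/16:0, LacCer d18:1/18:0, LacCer d18:1/24:0 and Gb3
#' d18:1/18:0.
#'
#' @return data.frame with columns `class`, `ceramide`, `species_id`.
#' @export
standard_species <- function() {
  df <- data.frame(
    class = c("GM3", "GM2", "GM1", "GD3", "GD2", "GD1", "GT1",
              "GlcCer", "LacCer", "LacCer", "Gb3"),
    ceramide = c(rep("d18:1/18:0", 7), "d18:1/16:0", "d18:1/18:0",
                 "d18:1/24:0", "d18:1/18:0"),
    stringsAsFactors = FALSE)
  df$species_id <- paste0(df$class, "(", df$ceramide, ")")
  df
}

#' Plan a calibration dilution series
#'
#' One plan per level and replicate, with all eleven standards spiked at
#' the level amount plus the fixed internal-standard spike, in
#' matrix-matched (serum-substitute) conditions.
#'
#' @param levels Strictly positive amounts (fmol), in ascending or
#'   descending order (e.g. a 1:4 serial dilution from 5000 fmol).
#' @param replicates Replicate injections per level.
#' @param is_amount Internal-standard spike (fmol).
#' @param seed Base seed; each plan gets a distinct derived seed.
#' @return List of [sample_plan()]s with group `"calibrator"`.
#' @export
make_calibration_series <- function(levels, replicates = 1, is_amount = 1000,
                                    seed = 1) {
  if (!length(levels)) stop("no calibration levels given", call. = FALSE)
  if (any(levels <= 0)) stop("calibration levels must be positive", call. = FALSE)
  if (length(levels) > 1 && !(all(diff(levels) > 0) || all(diff(levels) < 0))) {
    stop("calibration levels must be strictly ascending or descending",
         call. = FALSE)
  }
  std <- standard_species()
  plans <- list()
  k <- 0L
  for (li in seq_along(levels)) {
    for (r in seq_len(replicates)) {
      k <- k + 1L
      amounts <- stats::setNames(rep(levels[li], nrow(std)), std$species_id)
      plans[[k]] <- sample_plan(
        sample_id = sprintf("CAL_L%02d_R%02d", li, r),
        amounts = amounts, group = "calibrator", is_amount = is_amount,
        replicate = r, seed = seed + k)
    }
  }
  plans
}

#' Plan QC replicate injections for precision experiments
#'
#' Low/high QC mixtures (defaults 50 and 1000 fmol of every standard) run
#' `replicates` times per day over `days` days. A per-day log-normal batch
#' factor (sdlog `day_cv`) is applied to the analyte amounts so that
#' inter-assay variability exceeds intra-assay variability, as it does on a
#' real instrument. Matrix factors default to the low/high QC serum
#' substitute values.
#'
#' @param levels Named amounts per QC level, default `c(low = 50,
#'   high = 1000)` fmol.
#' @param replicates Injections per level per day.
#' @param days Number of days.
#' @param day_cv Between-day log-normal sdlog.
#' @param matrix_factors Named per-level matrix factor, default
#'   `c(low = 0.795, high = 0.875)`.
#' @param is_amount Internal-standard spike (fmol).
#' @param seed Base seed.
#' @return List of [sample_plan()]s with groups `"QC-low"` / `"QC-high"`.
#' @export
make_qc_plans <- function(levels = c(low = 50, high = 1000), replicates = 5,
                          days = 1, day_cv = 0.04,
                          matrix_factors = c(low = 0.795, high = 0.875),
                          is_amount = 1000, seed = 1) {
  stopifnot(all(levels > 0), replicates >= 2, days >= 1)
  std <- standard_species()
  set.seed(seed)
  day_scale <- exp(stats::rnorm(days, 0, day_cv))
  plans <- list()
  k <- 0L
  for (d in seq_len(days)) {
    for (lv in names(levels)) {
      for (r in seq_len(replicates)) {
        k <- k + 1L
        amounts <- stats::setNames(
          rep(levels[[lv]] * day_scale[d], nrow(std)), std$species_id)
        mf <- if (lv %in% names(matrix_factors)) matrix_factors[[lv]] else 1
        plans[[k]] <- sample_plan(
          sample_id = sprintf("QC_%s_D%02d_R%02d", lv, d, r),
          amounts = amounts, group = paste0("QC-", lv),
          is_amount = is_amount, matrix_factor = mf,
          day = d, replicate = r, seed = seed + 100L + k)
      }
    }
  }
  plans
}

#' Plan a storage-stability series
#'
#' Amounts decay first-order with storage time (`exp(-rate x days)`), or
#' geometrically with freeze-thaw cycles (`(1 - loss)^cycles`). The
#' baseline (time 0) plan is always included. Decay rates are configuration,
#' per condition and optionally per class.
#'
#' @param base_amounts Named baseline amounts (species id -> fmol).
#' @param times Days of storage (or cycle counts for `"freeze_thaw"`);
#'   0 is prepended if absent.
#' @param condition One of `"room"`, `"fridge"`, `"freezer"`,
#'   `"freeze_thaw"`, `"autosampler"`.
#' @param rate_per_day First-order decay rate (1/day), scalar or named per
#'   class; ignored for `"freeze_thaw"`.
#' @param loss_per_cycle Fractional loss per freeze-thaw cycle.
#' @param is_amount Internal-standard spike (fmol).
#' @param seed Base seed.
#' @return List of [sample_plan()]s; each carries the storage time in its
#'   `day` field.
#' @export
make_stability_series <- function(base_amounts, times,
                                  condition = c("room", "fridge", "freezer",
                                                "freeze_thaw", "autosampler"),
                                  rate_per_day = 0, loss_per_cycle = 0.02,
                                  is_amount = 1000, seed = 1) {
  condition <- match.arg(condition)
  stopifnot(all(base_amounts >= 0), all(times >= 0))
  times <- sort(unique(c(0, times)))
  classes <- sub("\\(.*$", "", names(base_amounts))
  plans <- vector("list", length(times))
  for (i in seq_along(times)) {
    tt <- times[i]
    decay <- if (condition == "freeze_thaw") {
      rep((1 - loss_per_cycle)^tt, length(base_amounts))
    } else if (length(rate_per_day) > 1L) {
      exp(-unname(rate_per_day[classes]) * tt)
    } else {
      rep(exp(-rate_per_day * tt), length(base_amounts))
    }
    plans[[i]] <- sample_plan(
      sample_id = sprintf("STAB_%s_T%03g", condition, tt),
      amounts = base_amounts * decay, group = "stability",
      is_amount = is_amount, day = tt, seed = seed + i)
  }
  plans
}
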