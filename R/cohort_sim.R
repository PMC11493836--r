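# Case-control serum cohort simulation. Control concentrations are
# log-normal per class, with location/scale fitted by log-moment matching to
# the packaged reference cohort (amounts are positive and right-skewed
# there). Patient profiles multiply the control draw by per-class fold
# factors: strong GM2 accumulation, GM1 elevation, GM3 depletion in both
# GM2-gangliosidosis phenotypes, and GA2 elevation only in Sandhoff disease
# (beta-hexosaminidase B also degrades GA2). Classes without a printed fold
# factor default to 1.

#' Fit a cohort model from a reference cohort table
#'
#' @param table Cohort data.frame in the layout of [gsl_cohort()] (a
#'   `group` column plus one amount column per class); per-class log-normal
#'   parameters are fitted to its control rows. Classes not present in the
#'   table can be added via `extra_classes`.
#' @param multipliers Named fold factors applied to every patient draw
#'   (defaults: GM2 x10, GM1 x6, GM3 x0.57).
#' @param sandhoff_multipliers Additional fold factors applied only to
#'   Sandhoff samples (default GA2 x2.4).
#' @param n_control,n_tay_sachs,n_sandhoff Group sizes (defaults 36/2/1).
#' @param extra_classes Optional data.frame (`class`, `meanlog`, `sdlog`)
#'   for classes absent from `table`.
#' @return A `cohort_model` list with the fitted per-class `meanlog` /
#'   `sdlog` and the group design.
#' @export
cohort_model <- function(table = gsl_cohort(),
                         multipliers = c(GM2 = 10, GM1 = 6, GM3 = 0.57),
                         sandhoff_multipliers = c(GA2 = 2.4),
                         n_control = 36, n_tay_sachs = 2, n_sandhoff = 1,
                         extra_classes = NULL) {
  stopifnot(n_control >= 1, n_tay_sachs + n_sandhoff >= 1)
  meta <- c("sample_id", "sex", "age", "group")
  classes <- setdiff(names(table), meta)
  ctl <- table[table$group == "control", , drop = FALSE]
  if (nrow(ctl) < 3) stop("need at least 3 control rows to fit", call. = FALSE)
  fit <- data.frame(class = classes,
                    meanlog = vapply(classes, function(s) mean(log(ctl[[s]])), 0),
                    sdlog = vapply(classes, function(s) stats::sd(log(ctl[[s]])), 0),
                    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(extra_classes)) {
    stopifnot(all(c("class", "meanlog", "sdlog") %in% names(extra_classes)))
    fit <- rbind(fit, extra_classes[, c("class", "meanlog", "sdlog")])
  }
  if (anyDuplicated(fit$class)) stop("duplicated class in model", call. = FALSE)
  mult <- stats::setNames(rep(1, nrow(fit)), fit$class)
  mult[names(multipliers)[names(multipliers) %in% fit$class]] <-
    multipliers[names(multipliers) %in% fit$class]
  sd_mult <- stats::setNames(rep(1, nrow(fit)), fit$class)
  sd_mult[names(sandhoff_multipliers)[names(sandhoff_multipliers) %in% fit$class]] <-
    sandhoff_multipliers[names(sandhoff_multipliers) %in% fit$class]
  if (any(mult <= 0) || any(sd_mult <= 0)) {
    stop("fold multipliers must be positive", call. = FALSE)
  }
  structure(list(fit = fit, multipliers = mult,
                 sandhoff_multipliers = sd_mult,
                 n_control = n_control, n_tay_sachs = n_tay_sachs,
                 n_sandhoff = n_sandhoff),
            class = "cohort_model")
}

#' Draw per-sample true amounts from a cohort model
#'
#' Fast truth-only path (no injection plans), used for large property
#' checks. Column names are the model's class names.
#'
#' @param model A [cohort_model()].
#' @param seed Integer seed.
#' @return data.frame with `sample_id`, `group` and one amount column per
#'   class.
#' @export
draw_cohort_truth <- function(model, seed = 1) {
  stopifnot(inherits(model, "cohort_model"))
  set.seed(seed)
  groups <- c(rep("control", model$n_control),
              rep("Tay-Sachs", model$n_tay_sachs),
              rep("Sandhoff", model$n_sandhoff))
  ids <- c(sprintf("SIM_CS%02d", seq_len(model$n_control)),
           sprintf("SIM_TSD%02d", seq_len(model$n_tay_sachs)),
           sprintf("SIM_SD%02d", seq_len(model$n_sandhoff)))
  n <- length(groups)
  out <- data.frame(sample_id = ids, group = groups, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(model$fit))) {
    cls <- model$fit$class[i]
    x <- stats::rlnorm(n, model$fit$meanlog[i], model$fit$sdlog[i])
    patient <- groups != "control"
    x[patient] <- x[patient] * model$multipliers[[cls]]
    x[groups == "Sandhoff"] <- x[groups == "Sandhoff"] *
      model$sandhoff_multipliers[[cls]]
    out[[cls]] <- x
  }
  out
}

#' Simulate a case-control cohort
#'
#' Draws per-sample true amounts from the model and wraps each sample in an
#' injection plan (amounts keyed to the d18:1/18:0 species of each class,
#' the species the reference cohort quantifies). The returned truth table
#' is the ground truth for quantification-recovery tests.
#'
#' @param model A [cohort_model()].
#' @param seed Integer seed; sample draws and per-plan noise seeds all
#'   derive from it.
#' @param is_amount Internal-standard spike (fmol) for the plans.
#' @return List with `truth` (data.frame; class-named amount columns) and
#'   `plans` (list of [sample_plan()]s whose amounts are keyed by species
#'   id).
#' @export
make_cohort <- function(model = cohort_model(), seed = 1, is_amount = 1000) {
  truth <- draw_cohort_truth(model, seed)
  classes <- model$fit$class
  species_ids <- stats::setNames(paste0(classes, "(d18:1/18:0)"), classes)
  plans <- vector("list", nrow(truth))
  for (i in seq_len(nrow(truth))) {
    amounts <- stats::setNames(as.numeric(truth[i, classes]),
                               species_ids[classes])
    plans[[i]] <- sample_plan(sample_id = truth$sample_id[i],
                              amounts = amounts, group = truth$group[i],
                              is_amount = is_amount, seed = seed + 1000L + i)
  }
  list(truth = truth, plans = plans)
}
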