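# Biomarker statistics on quantified cohorts: Grubbs outlier filtering,
# two-group comparisons with multiplicity adjustment, GM2/GM3 ratios, PCA
# and heatmap-ready z-scores.

.COHORT_META <- c("sample_id", "sex", "age", "group")
.GROUP_LEVELS <- c("control", "Tay-Sachs", "Sandhoff")

#' Load the packaged reference serum cohort
#'
#' Quantified serum ganglioside amounts (fmol per injection) for 36
#' unaffected pediatric controls, two Tay-Sachs patients and one Sandhoff
#' patient: the d18:1/18:0 species of GM3, GM2, GM1, GD3, GD2, GD1 and GT1.
#'
#' @param path Optional path to a cohort CSV in the same layout
#'   (`sample_id`, `sex`, `age`, `group`, one amount column per species).
#' @return Validated cohort data.frame.
#' @examples
#' tab <- gsl_cohort()
#' table(tab$group)
#' @export
gsl_cohort <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "gm2_cohort_serum_fmol.csv",
                        package = "gslquant", mustWork = TRUE)
  }
  tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.COHORT_META, names(tab))
  if (length(missing_cols)) {
    stop("cohort table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unique(tab$group), .GROUP_LEVELS)
  if (length(bad)) {
    stop("unknown group label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  species <- setdiff(names(tab), .COHORT_META)
  for (s in species) {
    if (!is.numeric(tab[[s]]) || any(tab[[s]] < 0, na.rm = TRUE)) {
      stop("amount column '", s, "' must be numeric and non-negative",
           call. = FALSE)
    }
  }
  tab
}

#' Two-sided Grubbs critical value
#'
#' G_crit(n, alpha) = ((n - 1) / sqrt(n)) * sqrt(t^2 / (n - 2 + t^2)) with
#' t the upper alpha/(2n) quantile of Student's t on n - 2 degrees of
#' freedom.
#'
#' @param n Sample size (>= 3).
#' @param alpha Two-sided significance level.
#' @return Critical value for G = max |x - mean| / sd.
#' @examples
#' round(grubbs_critical(10, 0.05), 3) # 2.290
#' @export
grubbs_critical <- function(n, alpha = 0.05) {
  stopifnot(n >= 3)
  tq <- stats::qt(alpha / (2 * n), n - 2, lower.tail = FALSE)
  (n - 1) / sqrt(n) * sqrt(tq^2 / (n - 2 + tq^2))
}

#' Iterative two-sided Grubbs outlier filter
#'
#' Repeatedly tests the single most extreme point (G = max |x - mean| / sd
#' against [grubbs_critical()]), removes it if rejected, and stops at the
#' first non-rejection or when fewer than 3 points remain. With n < 3
#' nothing is filtered and a warning is raised.
#'
#' @param x Numeric values.
#' @param alpha Two-sided significance level (default 0.05).
#' @param ids Optional identifiers parallel to `x`, reported for removed
#'   points.
#' @return List: `values` (retained), `removed` (ids or indices removed, in
#'   removal order), `n_removed`.
#' @examples
#' grubbs_filter(c(1, 1, 1, 1, 100))$removed # index 5
#' @export
grubbs_filter <- function(x, alpha = 0.05, ids = NULL) {
  if (is.null(ids)) ids <- seq_along(x)
  stopifnot(length(ids) == length(x))
  if (length(x) < 3L) {
    warning("n < 3: Grubbs filtering skipped")
    return(list(values = x, removed = ids[0], n_removed = 0L))
  }
  keep <- rep(TRUE, length(x))
  removed <- ids[0]
  repeat {
    n <- sum(keep)
    if (n < 3L) break
    v <- x[keep]
    s <- stats::sd(v)
    if (s == 0) break
    g <- abs(v - mean(v)) / s
    i <- which.max(g)
    if (g[i] > grubbs_critical(n, alpha)) {
      idx <- which(keep)[i]
      removed <- c(removed, ids[idx])
      keep[idx] <- FALSE
    } else break
  }
  list(values = x[keep], removed = removed, n_removed = length(removed))
}

#' Patient-vs-control comparison per species
#'
#' For each species column: Grubbs-filters the control and patient groups
#' independently (unless `grubbs_alpha = NULL`), runs a two-tailed
#' Student's t-test (pooled variance by default; `var_equal = FALSE` for
#' Welch), and reports group centers, mean- and median-based fold-changes
#' (patient / control) and multiplicity-adjusted p-values across species.
#'
#' @param tab Cohort data.frame ([gsl_cohort()] layout); patients are all
#'   rows with `group != "control"`.
#' @param species Species columns to test (default: every non-metadata
#'   column).
#' @param adjust p-value adjustment method: `"BH"` (default) or
#'   `"bonferroni"`.
#' @param var_equal Pooled-variance t-test if TRUE (default).
#' @param grubbs_alpha Alpha for outlier removal, or NULL to skip
#'   filtering.
#' @return data.frame per species: group means/medians, `fc_mean`,
#'   `fc_median`, `t`, `df`, `p`, `p_adj`, `n_control`, `n_patient`,
#'   `removed` (comma-joined sample ids).
#' @export
group_compare <- function(tab, species = NULL,
                          adjust = c("BH", "bonferroni"),
                          var_equal = TRUE, grubbs_alpha = 0.05) {
  adjust <- match.arg(adjust)
  if (is.null(species)) species <- setdiff(names(tab), .COHORT_META)
  is_pat <- tab$group != "control"
  if (sum(!is_pat) < 2 || sum(is_pat) < 2) {
    stop("need >= 2 samples per group", call. = FALSE)
  }
  rows <- lapply(species, function(s) {
    ctl <- tab[[s]][!is_pat]
    pat <- tab[[s]][is_pat]
    ctl_ids <- tab$sample_id[!is_pat]
    pat_ids <- tab$sample_id[is_pat]
    removed <- character(0)
    if (!is.null(grubbs_alpha)) {
      gc <- grubbs_filter(ctl, grubbs_alpha, ids = ctl_ids)
      gp <- grubbs_filter(pat, grubbs_alpha, ids = pat_ids)
      ctl <- gc$values; pat <- gp$values
      removed <- c(gc$removed, gp$removed)
    }
    if (length(ctl) < 2 || length(pat) < 2) {
      stop("fewer than 2 values left after filtering for '", s, "'",
           call. = FALSE)
    }
    tt <- stats::t.test(pat, ctl, var.equal = var_equal)
    data.frame(species = s,
               control_mean = mean(ctl), control_median = stats::median(ctl),
               patient_mean = mean(pat), patient_median = stats::median(pat),
               fc_mean = mean(pat) / mean(ctl),
               fc_median = stats::median(pat) / stats::median(ctl),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value,
               n_control = length(ctl), n_patient = length(pat),
               removed = paste(removed, collapse = ","),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$p_adj <- stats::p.adjust(res$p, method = adjust)
  res <- res[, c("species", "control_mean", "control_median", "patient_mean",
                 "patient_median", "fc_mean", "fc_median", "t", "df", "p",
                 "p_adj", "n_control", "n_patient", "removed")]
  rownames(res) <- NULL
  res
}

#' Per-sample GM2/GM3 ratios and their group fold-change
#'
#' Both GM2-gangliosidosis phenotypes accumulate GM2 and deplete GM3, so
#' the per-sample GM2/GM3 quotient amplifies the group difference. The
#' fold-change of the ratio is reported both as patient mean / control mean
#' and patient median / control median.
#'
#' @param tab Cohort data.frame.
#' @param gm2,gm3 Column names of the GM2 and GM3 amounts.
#' @return List: `samples` (data.frame `sample_id`, `group`, `ratio`) and
#'   `fold_change` (named vector `mean`, `median`).
#' @examples
#' gm2_gm3_ratio(gsl_cohort())$fold_change
#' @export
gm2_gm3_ratio <- function(tab, gm2 = "GM2", gm3 = "GM3") {
  missing_cols <- setdiff(c(gm2, gm3), names(tab))
  if (length(missing_cols)) {
    stop("cohort table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (any(tab[[gm3]] <= 0)) stop("GM3 amounts must be positive", call. = FALSE)
  ratio <- tab[[gm2]] / tab[[gm3]]
  pat <- tab$group != "control"
  list(samples = data.frame(sample_id = tab$sample_id, group = tab$group,
                            ratio = ratio, stringsAsFactors = FALSE),
       fold_change = c(mean = mean(ratio[pat]) / mean(ratio[!pat]),
                       median = stats::median(ratio[pat]) /
                                stats::median(ratio[!pat])))
}

#' Principal component analysis of a cohort
#'
#' Columns are autoscaled (mean 0, SD 1) by default, then decomposed by
#' SVD. For reproducible score signs, each loading vector is oriented so
#' its largest-magnitude element is positive.
#'
#' @param tab Cohort data.frame.
#' @param species Species columns to include (>= 2; default GM1, GM2, GM3).
#' @param autoscale Scale columns to unit variance (default TRUE; columns
#'   are always centered).
#' @return A `gsl_pca` list: `scores` (samples x components, rownames =
#'   sample ids), `loadings` (species x components), `explained_variance`
#'   (fractions, non-increasing), `groups`.
#' @export
cohort_pca <- function(tab, species = c("GM1", "GM2", "GM3"),
                       autoscale = TRUE) {
  missing_cols <- setdiff(species, names(tab))
  if (length(missing_cols)) {
    stop("cohort table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (length(species) < 2) stop("need >= 2 species", call. = FALSE)
  x <- as.matrix(tab[, species])
  if (nrow(x) < 3) stop("need >= 3 samples", call. = FALSE)
  sds <- apply(x, 2, stats::sd)
  if (autoscale && any(sds == 0)) {
    stop("constant species column(s): ",
         paste(species[sds == 0], collapse = ", "), call. = FALSE)
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = autoscale)
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  rotation <- sweep(pc$rotation, 2, flip, `*`)
  scores <- sweep(pc$x, 2, flip, `*`)
  rownames(scores) <- tab$sample_id
  structure(list(scores = scores, loadings = rotation,
                 explained_variance = pc$sdev^2 / sum(pc$sdev^2),
                 groups = tab$group),
            class = "gsl_pca")
}

#' @export
print.gsl_pca <- function(x, ...) {
  cat("PCA:", nrow(x$scores), "samples x", nrow(x$loadings), "species;",
      "explained:", paste0(round(100 * x$explained_variance, 1), "%",
                           collapse = ", "), "\n")
  invisible(x)
}

#' Per-species z-scores for heatmap export
#'
#' z = (x - species mean) / species SD over all samples. Export only; no
#' rendering.
#'
#' @param tab Cohort data.frame.
#' @param species Species columns (default: all non-metadata columns).
#' @return Matrix (samples x species) of z-scores, rownames = sample ids;
#'   every column has mean 0 and SD 1.
#' @export
heatmap_zscores <- function(tab, species = NULL) {
  if (is.null(species)) species <- setdiff(names(tab), .COHORT_META)
  missing_cols <- setdiff(species, names(tab))
  if (length(missing_cols)) {
    stop("cohort table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x <- as.matrix(tab[, species, drop = FALSE])
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant species column(s): ",
         paste(species[sds == 0], collapse = ", "), call. = FALSE)
  }
  z <- scale(x)
  attr(z, "scaled:center") <- NULL
  attr(z, "scaled:scale") <- NULL
  rownames(z) <- tab$sample_id
  z
}
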