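fixture <- gsl_cohort()

test_that("the packaged cohort loads with the expected design", {
  expect_equal(nrow(fixture), 39L)
  expect_equal(sum(fixture$group == "control"), 36L)
  expect_setequal(setdiff(names(fixture), c("sample_id", "sex", "age", "group")),
                  c("GM3", "GM2", "GM1", "GD3", "GD2", "GD1", "GT1"))
  expect_true(all(as.matrix(fixture[, 5:11]) >= 0))
  # validation rejects malformed tables
  bad <- fixture
  bad$group[1] <- "case"
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(bad, path, row.names = FALSE)
  expect_error(gsl_cohort(path), "unknown group")
})

test_that("Grubbs critical values reproduce published tables", {
  for (alpha in names(oracle_grubbs_table)) {
    tab <- oracle_grubbs_table[[alpha]]
    for (n in names(tab)) {
      expect_equal(grubbs_critical(as.integer(n), as.numeric(alpha)),
                   tab[[n]], tolerance = 5e-4,
                   label = paste0("n=", n, ", alpha=", alpha))
    }
  }
  expect_equal(round(grubbs_critical(10, 0.05), 3), 2.290)
})

test_that("Grubbs critical values are sane over n = 3..50", {
  for (alpha in c(0.01, 0.05)) {
    g <- vapply(3:50, grubbs_critical, 0, alpha = alpha)
    # monotone increasing in n, and bounded by the algebraic maximum of G
    expect_true(all(diff(g) > 0))
    expect_true(all(g < (3:50 - 1) / sqrt(3:50)))
    expect_true(all(g > 1))
  }
  # stricter alpha -> larger critical value
  expect_gt(grubbs_critical(20, 0.01), grubbs_critical(20, 0.05))
})

test_that("iterative Grubbs filtering removes gross outliers and stops", {
  r <- grubbs_filter(c(1, 1, 1, 1, 100))
  expect_equal(r$removed, 5L)
  expect_equal(r$values, rep(1, 4))

  # symmetric data with no extreme point: nothing removed
  r2 <- grubbs_filter(c(2, 4, 6, 8, 10, 12))
  expect_equal(r2$n_removed, 0L)

  # n < 3: warn, keep everything
  expect_warning(r3 <- grubbs_filter(c(1, 100)), "n < 3")
  expect_equal(r3$values, c(1, 100))

  # ids are reported in removal order
  r4 <- grubbs_filter(c(5, 5.1, 4.9, 5.2, 50, 5.05), ids = letters[1:6])
  expect_equal(r4$removed, "e")
})

test_that("Grubbs filtering matches an independent step-by-step oracle", {
  oracle_grubbs <- function(x, alpha) {
    removed <- integer(0)
    repeat {
      keep <- setdiff(seq_along(x), removed)
      n <- length(keep)
      if (n < 3) break
      v <- x[keep]
      if (sd(v) == 0) break
      g <- abs(v - mean(v)) / sd(v)
      tq <- qt(1 - alpha / (2 * n), n - 2)
      gcrit <- (n - 1) / sqrt(n) * sqrt(tq^2 / (n - 2 + tq^2))
      i <- which.max(g)
      if (g[i] > gcrit) removed <- c(removed, keep[i]) else break
    }
    sort(removed)
  }
  set.seed(99)
  for (rep in 1:30) {
    n <- sample(3:50, 1)
    x <- rnorm(n)
    if (rep %% 3 == 0) x[1] <- x[1] + sample(3:8, 1) # plant an outlier
    for (alpha in c(0.01, 0.05)) {
      got <- grubbs_filter(x, alpha)
      expect_equal(sort(got$removed), oracle_grubbs(x, alpha),
                   label = paste("n =", n, "alpha =", alpha))
    }
  }
})

test_that("group comparison reproduces the reference fold-changes", {
  res <- group_compare(fixture)
  gm2 <- res[res$species == "GM2", ]
  expect_equal(round(gm2$fc_mean, 1), 10.0)
  expect_gt(gm2$patient_mean, gm2$control_mean)
  expect_lt(gm2$p_adj, 0.01)
  gm3 <- res[res$species == "GM3", ]
  expect_lt(gm3$fc_mean, 1) # GM3 depleted in patients
  expect_true(all(res$p_adj >= res$p))

  # t statistic agrees with the stats::t.test oracle on unfiltered data
  raw <- group_compare(fixture, grubbs_alpha = NULL)
  for (s in c("GM2", "GM1", "GD2")) {
    tt <- t.test(fixture[[s]][fixture$group != "control"],
                 fixture[[s]][fixture$group == "control"], var.equal = TRUE)
    expect_equal(raw$p[raw$species == s], tt$p.value, tolerance = 1e-12)
    expect_equal(raw$t[raw$species == s], unname(tt$statistic),
                 tolerance = 1e-12)
  }
})

test_that("identical groups give fold-change 1 and p near 1", {
  tab <- data.frame(sample_id = sprintf("S%02d", 1:12),
                    sex = "F", age = "1",
                    group = rep(c("control", "Tay-Sachs"), each = 6),
                    GM2 = rep(c(1, 2, 3, 4, 5, 6), 2))
  res <- group_compare(tab, species = "GM2", grubbs_alpha = NULL)
  expect_equal(res$fc_mean, 1)
  expect_equal(res$fc_median, 1)
  expect_equal(res$p, 1, tolerance = 1e-9)
})

test_that("p-values are uniform under label permutation", {
  set.seed(123)
  x <- fixture$GD2 # a column with no real group difference
  groups <- fixture$group
  ps <- replicate(500, {
    g <- sample(groups)
    t.test(x[g != "control"], x[g == "control"], var.equal = TRUE)$p.value
  })
  # compare against the package's own test on the same permutations
  set.seed(123)
  ps_pkg <- replicate(500, {
    tab <- data.frame(sample_id = fixture$sample_id, sex = "F", age = "1",
                      group = sample(groups), GD2 = x)
    group_compare(tab, species = "GD2", grubbs_alpha = NULL)$p
  })
  expect_equal(ps_pkg, ps, tolerance = 1e-12)
  # duplicated label splits produce tied p-values; the KS p is still usable
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
})

test_that("GM2/GM3 ratios match direct arithmetic on the reference cohort", {
  r <- gm2_gm3_ratio(fixture)
  tsd01 <- r$samples$ratio[r$samples$sample_id == "TSD01"]
  expect_equal(tsd01, 2905.3 / 251.7, tolerance = 1e-12)
  expect_equal(round(tsd01, 2), 11.54)
  expect_equal(r$fold_change[["mean"]], 16.4, tolerance = 0.01)
  expect_equal(r$fold_change[["median"]], 21.1, tolerance = 0.01)

  # GM2 == GM3 everywhere -> all ratios 1, fold-change 1
  eq <- fixture
  eq$GM2 <- eq$GM3
  req <- gm2_gm3_ratio(eq)
  expect_true(all(req$samples$ratio == 1))
  expect_equal(unname(req$fold_change), c(1, 1))
})

test_that("PCA separates patients from controls on the GM species", {
  pca <- cohort_pca(fixture, species = c("GM1", "GM2", "GM3"))
  pc1 <- pca$scores[, 1]
  pat <- fixture$group != "control"
  expect_true(min(pc1[pat]) > max(pc1[!pat]) ||
                max(pc1[pat]) < min(pc1[!pat]))
  expect_true(all(diff(pca$explained_variance) <= 1e-12))
  expect_lte(sum(pca$explained_variance), 1 + 1e-9)
  # loadings orthonormal
  expect_equal(crossprod(pca$loadings), diag(3), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("PCA reconstruction and scaling identities hold", {
  pca <- cohort_pca(fixture, species = c("GM1", "GM2", "GM3"))
  x <- scale(as.matrix(fixture[, c("GM1", "GM2", "GM3")]))
  recon <- pca$scores %*% t(pca$loadings)
  expect_lt(max(abs(recon - x)), 1e-8)
  # autoscaled total variance equals the number of species
  expect_equal(sum(apply(x, 2, var)), 3, tolerance = 1e-12)
  # one informative column dominates PC1
  tab <- data.frame(sample_id = sprintf("S%d", 1:10), sex = "F", age = "1",
                    group = "control",
                    A = seq(1, 10), B = rep(c(5, 5.000001), 5))
  p1 <- cohort_pca(tab, species = c("A", "B"), autoscale = FALSE)
  expect_equal(p1$explained_variance[1], 1, tolerance = 1e-6)
})

test_that("heatmap z-scores are column-standardized and flag constants", {
  z <- heatmap_zscores(fixture, species = c("GM3", "GM2", "GM1"))
  expect_equal(colMeans(z), c(GM3 = 0, GM2 = 0, GM1 = 0), tolerance = 1e-12)
  expect_equal(apply(z, 2, sd), c(GM3 = 1, GM2 = 1, GM1 = 1),
               tolerance = 1e-12)
  # the most GM2-laden sample is the first Tay-Sachs patient
  expect_equal(rownames(z)[which.max(z[, "GM2"])], "TSD01")
  cst <- fixture
  cst$GM1 <- 5
  expect_error(heatmap_zscores(cst, species = c("GM3", "GM1")), "GM1")
})
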