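panel <- build_panel(default_panel_config())
quiet_acq <- acquisition_model(baseline = 0, noise_sd = 0, noise_prop = 0,
                               peak_cv = 0, rt_jitter_sd_min = 0)

test_that("zero amount with zero baseline and noise gives an all-zero trace", {
  plan <- sample_plan("blank", stats::setNames(numeric(0), character(0)),
                      group = "blank", is_amount = 0, seed = 1)
  ch <- simulate_chromatograms(panel, plan, quiet_acq)
  expect_true(all(ch$intensity == 0))
  # points exist only inside each transition's scheduled window
  for (id in unique(ch$transition_id)) {
    tr <- panel[panel$transition_id == id, ]
    tt <- ch$time_min[ch$transition_id == id]
    expect_true(all(tt >= tr$rt_min - 0.5 & tt <= tr$rt_min + 0.5))
  }
})

test_that("noise-free areas recover the spiked amount to within discretization", {
  amt <- 250
  plan <- sample_plan("clean", c("GM3(d18:1/18:0)" = amt),
                      extraction_efficiency = 1, seed = 1)
  ch <- simulate_chromatograms(panel, plan, quiet_acq)
  d <- ch[ch$transition_id == "GM3(d18:1/18:0)", ]
  # trapezoid integration of the whole window
  area <- sum(diff(d$time_min) *
                (head(d$intensity, -1) + tail(d$intensity, -1)) / 2)
  rf <- quiet_acq$response_factor
  expect_equal(area / rf, amt, tolerance = 0.005)
})

test_that("areas scale linearly with amount below saturation", {
  amts <- c(10, 100, 1000)
  areas <- vapply(amts, function(a) {
    plan <- sample_plan("lin", c("GM3(d18:1/18:0)" = a),
                        extraction_efficiency = 0.9, matrix_factor = 0.8,
                        seed = 1)
    ch <- simulate_chromatograms(panel, plan, quiet_acq)
    d <- ch[ch$transition_id == "GM3(d18:1/18:0)", ]
    sum(diff(d$time_min) * (head(d$intensity, -1) + tail(d$intensity, -1)) / 2)
  }, 0)
  expect_equal(cor(areas, amts)^2, 1, tolerance = 1e-9)
  # slope = response factor x matrix factor x extraction efficiency
  expect_equal(unname(coef(lm(areas ~ amts))[2]), 100 * 0.8 * 0.9,
               tolerance = 0.005)
})

test_that("seeds control noise but not peak locations; output is deterministic", {
  acq <- acquisition_model()
  plan1 <- sample_plan("S1", c("GM3(d18:1/18:0)" = 100), seed = 1)
  plan2 <- sample_plan("S1", c("GM3(d18:1/18:0)" = 100), seed = 2)
  ch1 <- simulate_chromatograms(panel, plan1, acq)
  ch2 <- simulate_chromatograms(panel, plan2, acq)
  expect_false(identical(ch1$intensity, ch2$intensity))
  d1 <- ch1[ch1$transition_id == "GM3(d18:1/18:0)", ]
  d2 <- ch2[ch2$transition_id == "GM3(d18:1/18:0)", ]
  expect_equal(d1$time_min[which.max(d1$intensity)],
               d2$time_min[which.max(d2$intensity)])
  # bit-identical under the same seed
  expect_identical(ch1, simulate_chromatograms(panel, plan1, acq))
})

test_that("calibration series enumerates levels x replicates over the standards", {
  levels <- 5000 / 4^(0:6)
  plans <- make_calibration_series(rev(levels), replicates = 1, seed = 3)
  expect_length(plans, 7L)
  plans3 <- make_calibration_series(rev(levels), replicates = 3, seed = 3)
  expect_length(plans3, 21L)
  expect_length(unique(vapply(plans3, `[[`, "", "sample_id")), 21L)
  expect_length(unique(vapply(plans3, `[[`, 0L, "seed")), 21L)
  std <- standard_species()
  expect_equal(nrow(std), 11L)
  expect_setequal(names(plans[[1]]$amounts), std$species_id)
  expect_true(all(plans[[1]]$amounts == rev(levels)[1]))
  expect_error(make_calibration_series(numeric(0)), "no calibration levels")
  expect_error(make_calibration_series(c(5, -1)), "positive")
  expect_error(make_calibration_series(c(1, 5, 2)), "ascending or descending")
})

test_that("cohort generator reproduces the reference design and fold factors", {
  model <- cohort_model()
  co <- make_cohort(model, seed = 9)
  expect_length(co$plans, 39L)
  expect_equal(sum(co$truth$group == "control"), 36L)
  expect_equal(sum(co$truth$group == "Tay-Sachs"), 2L)
  expect_equal(sum(co$truth$group == "Sandhoff"), 1L)
  expect_setequal(names(co$plans[[1]]$amounts),
                  paste0(model$fit$class, "(d18:1/18:0)"))

  # GM2 multiplier 10 -> patient/control mean ratio ~10 at large n
  big <- cohort_model(n_control = 2000, n_tay_sachs = 1000, n_sandhoff = 1000)
  truth <- draw_cohort_truth(big, seed = 4)
  pat <- truth$group != "control"
  expect_equal(mean(truth$GM2[pat]) / mean(truth$GM2[!pat]), 10,
               tolerance = 0.1)
  expect_equal(mean(truth$GM3[pat]) / mean(truth$GM3[!pat]), 0.57,
               tolerance = 0.05)
  # GD2 has no printed fold factor and stays at 1
  expect_equal(mean(truth$GD2[pat]) / mean(truth$GD2[!pat]), 1,
               tolerance = 0.05)
})

test_that("unit multipliers make patient and control draws identical in law", {
  model <- cohort_model(multipliers = c(GM2 = 1),
                        sandhoff_multipliers = c(GM2 = 1),
                        n_control = 3000, n_tay_sachs = 1500,
                        n_sandhoff = 1500)
  truth <- draw_cohort_truth(model, seed = 5)
  pat <- truth$group != "control"
  for (cls in model$fit$class) {
    expect_gt(suppressWarnings(
      ks.test(truth[[cls]][pat], truth[[cls]][!pat])$p.value), 0.01)
  }
})

test_that("simulated control class means track the reference cohort", {
  fixture <- gsl_cohort()
  ctl <- fixture[fixture$group == "control", ]
  model <- cohort_model(fixture)
  classes <- model$fit$class
  sims <- sapply(1:10, function(s) {
    truth <- draw_cohort_truth(model, seed = s)
    colMeans(truth[truth$group == "control", classes])
  })
  for (cls in classes) {
    se <- sd(ctl[[cls]]) / sqrt(nrow(ctl))
    expect_lt(abs(mean(sims[cls, ]) - mean(ctl[[cls]])), 2 * se, label = cls)
  }
})

test_that("stability series decay follows the configured kinetics", {
  base <- c("GM3(d18:1/18:0)" = 100, "GM2(d18:1/18:0)" = 50)
  # no decay: amounts unchanged at every time point
  p0 <- make_stability_series(base, times = c(1, 3, 7), rate_per_day = 0)
  expect_length(p0, 4L) # baseline included
  expect_true(all(vapply(p0, function(p) all(p$amounts == base), TRUE)))
  # first-order decay reaching 80% at day 7
  rate <- -log(0.8) / 7
  p1 <- make_stability_series(base, times = 7, rate_per_day = rate)
  expect_equal(unname(p1[[2]]$amounts / base), c(0.8, 0.8), tolerance = 1e-12)
  # freeze-thaw: 2% loss per cycle over 4 cycles -> 92.2% recovery
  p2 <- make_stability_series(base, times = 4, condition = "freeze_thaw",
                              loss_per_cycle = 0.02)
  expect_equal(unname(p2[[2]]$amounts / base), rep(0.98^4, 2),
               tolerance = 1e-12)
  expect_equal(round(100 * 0.98^4, 1), 92.2)
})

test_that("plans referencing unknown species are rejected", {
  plan <- sample_plan("bad", c("GM3(d20:1/18:0)" = 5), seed = 1)
  expect_error(simulate_chromatograms(panel, plan, quiet_acq),
               "absent from panel")
})
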