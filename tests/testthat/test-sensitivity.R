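dlg_levels <- c(0.1, 0.155, 0.17, 0.19, 0.23)

noise_free_sweep <- function(parameter = "dlg_cm", levels = dlg_levels,
                             structures = data.frame(
                               name = "PTV1", slope = 25, crossing = 0.2,
                               noise_pct = 0),
                             n = 25, seed = 1) {
  generate_sweep(sweep_spec(parameter, levels, structures, n, seed))
}

test_that("sweep grouping produces sorted per-level cohorts and guards", {
  sw <- noise_free_sweep(n = 30)
  gs <- group_sweep(sw, "dlg_cm")
  expect_equal(gs$levels, dlg_levels)
  expect_length(gs$cohorts, 5)
  expect_true(all(vapply(gs$cohorts, nrow, 0L) == 30))
  expect_equal(gs$held_constant, 0.02)

  # confounded: the held parameter takes two values
  sw2 <- sw
  sw2$mlc_tf[1:10] <- 0.03
  expect_error(group_sweep(sw2, "dlg_cm"), "confounded sweep")
  # unannotated rows
  sw3 <- sw
  sw3$dlg_cm[5] <- NA
  expect_error(group_sweep(sw3, "dlg_cm"), "unannotated")
  # two levels only
  sw4 <- sw[sw$dlg_cm %in% dlg_levels[1:2], ]
  expect_error(group_sweep(sw4, "dlg_cm"), ">= 3")
})

test_that("noise-free linear response is fit exactly", {
  # mean response 25 * (dlg - 0.2) %, no noise
  gs <- group_sweep(noise_free_sweep(), "dlg_cm")
  fit <- suppressWarnings(fit_parameter_response(gs, "PTV1", min_points = 20))
  mean_line <- fit$lines[fit$lines$statistic == "mean", ]
  expect_equal(mean_line$slope, 25, tolerance = 1e-9)
  expect_equal(mean_line$r_squared, 1, tolerance = 1e-9)
  expect_equal(fit$zero_crossing, 0.2, tolerance = 1e-9)
  expect_equal(mean_line$rate_per_step, 2.5, tolerance = 1e-9)
  expect_equal(fit$step, 0.1)
  # noise-free: ucl/lcl coincide with the mean line
  expect_equal(fit$lines$slope, rep(25, 3), tolerance = 1e-9)
})

test_that("constant response yields zero slope and an undefined crossing", {
  gs <- group_sweep(noise_free_sweep(structures = data.frame(
    name = "brain", slope = 0, crossing = 0.2, noise_pct = 0)), "dlg_cm")
  fit <- suppressWarnings(fit_parameter_response(gs, "brain", min_points = 20))
  expect_equal(fit$lines$slope, rep(0, 3))
  expect_false(fit$zero_defined)
  expect_true(is.na(fit$zero_crossing))
})

test_that("fitted lines match an independently recomputed least-squares solution", {
  sw <- generate_sweep(sweep_spec("mlc_tf", c(0.0118, 0.0145, 0.0158, 0.0165),
                                  data.frame(name = "larynx", slope = 246,
                                             crossing = 0.02, noise_pct = 0.4),
                                  n_per_level = 30, seed = 5))
  gs <- group_sweep(sw, "mlc_tf")
  fit <- fit_parameter_response(gs, "larynx")
  expect_equal(fit$step, 0.01)
  ls <- fit$level_stats
  for (stat in c("ucl", "mean", "lcl")) {
    y <- switch(stat, ucl = ls$ucl, mean = ls$mu, lcl = ls$lcl)
    x <- ls$level
    b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
    a <- mean(y) - b * mean(x)
    row <- fit$lines[fit$lines$statistic == stat, ]
    expect_equal(row$slope, b, tolerance = 1e-10)
    expect_equal(row$intercept, a, tolerance = 1e-10)
  }
})

test_that("fitting DLG in mm scales the slope 10x but not the crossing position", {
  sw_cm <- noise_free_sweep(structures = data.frame(
    name = "PTV1", slope = 25, crossing = 0.2, noise_pct = 0.3), seed = 7)
  gs_cm <- group_sweep(sw_cm, "dlg_cm")
  fit_cm <- fit_parameter_response(gs_cm, "PTV1", min_points = 20)
  # identical cohort re-annotated in mm (values untouched)
  sw_mm <- sw_cm
  sw_mm$dlg_cm <- sw_mm$dlg_cm * 10
  gs_mm <- group_sweep(sw_mm, "dlg_cm")
  fit_mm <- fit_parameter_response(gs_mm, "PTV1", min_points = 20)
  m_cm <- fit_cm$lines[fit_cm$lines$statistic == "mean", ]
  m_mm <- fit_mm$lines[fit_mm$lines$statistic == "mean", ]
  expect_equal(m_mm$slope, m_cm$slope / 10, tolerance = 1e-9)
  expect_equal(fit_mm$zero_crossing, fit_cm$zero_crossing * 10, tolerance = 1e-9)
})

test_that("recovered rate and crossing track the generator truth under noise", {
  # 2.5 %/0.1 cm truth, sigma 0.2 %, 30 cases/level
  sw <- generate_sweep(sweep_spec("dlg_cm", dlg_levels,
                                  data.frame(name = "PTV1", slope = 25,
                                             crossing = 0.2, noise_pct = 0.2),
                                  n_per_level = 30, seed = 9))
  fit <- fit_parameter_response(group_sweep(sw, "dlg_cm"), "PTV1")
  rate <- fit$lines$rate_per_step[fit$lines$statistic == "mean"]
  expect_lt(abs(rate - 2.5), 0.3)
  expect_lt(abs(fit$zero_crossing - 0.2), 0.01)
})

test_that("zero-crossing summary applies the physical-range rule as computed by hand", {
  st <- data.frame(name = c("PTV1", "larynx", "mandible", "lens"),
                   slope = c(20, 25, 30, 15),
                   crossing = c(0.19, 0.20, 0.21, 0.80),
                   noise_pct = 0)
  gs <- group_sweep(noise_free_sweep(structures = st, seed = 11), "dlg_cm")
  fits <- lapply(st$name, function(s) suppressWarnings(
    fit_parameter_response(gs, s, min_points = 20)))
  summ <- summarize_zero_crossings(fits)
  expect_equal(summ$crossings$excluded, c(FALSE, FALSE, FALSE, TRUE))
  expect_match(summ$crossings$reason[4], "outside")
  # hand computation over the retained triple {0.19, 0.20, 0.21}
  expect_equal(summ$mean_retained, 0.20, tolerance = 1e-9)
  expect_equal(summ$sd_retained, 0.01, tolerance = 1e-9)
  # the skewed all-structure summary includes the 0.80 outlier
  expect_equal(summ$mean_all, mean(c(0.19, 0.2, 0.21, 0.8)), tolerance = 1e-9)

  # no outliers -> retained and all summaries coincide
  summ2 <- summarize_zero_crossings(fits[1:3])
  expect_equal(summ2$mean_all, summ2$mean_retained)
  expect_equal(summ2$sd_all, summ2$sd_retained)
  expect_false(any(summ2$crossings$excluded))

  # identical crossings -> SD exactly 0
  st3 <- data.frame(name = c("a", "b", "c"), slope = c(10, 20, 30),
                    crossing = 0.2, noise_pct = 0)
  gs3 <- group_sweep(noise_free_sweep(structures = st3, seed = 12), "dlg_cm")
  fits3 <- lapply(st3$name, function(s) suppressWarnings(
    fit_parameter_response(gs3, s, min_points = 20)))
  summ3 <- summarize_zero_crossings(fits3)
  expect_equal(summ3$mean_retained, 0.2, tolerance = 1e-9)
  expect_equal(summ3$sd_retained, 0, tolerance = 1e-9)

  # MAD rule also isolates the extreme crossing
  summ4 <- summarize_zero_crossings(fits, outlier_rule = "mad")
  expect_equal(summ4$crossings$excluded, c(FALSE, FALSE, FALSE, TRUE))
})

test_that("sensitivity export writes deterministic tables with one row per structure", {
  st <- data.frame(name = c("PTV1", "larynx", "brain"),
                   slope = c(25, 24, 2), crossing = c(0.2, 0.2, 0.21),
                   noise_pct = c(0.3, 0.3, 0.1))
  gs <- group_sweep(noise_free_sweep(structures = st, seed = 13), "dlg_cm")
  fits <- lapply(st$name, function(s) suppressWarnings(
    fit_parameter_response(gs, s, min_points = 20)))
  summ <- summarize_zero_crossings(fits)
  dir <- tempfile()
  export_sensitivity(fits, summ, dir, plot = FALSE)
  rates <- utils::read.csv(file.path(dir, "rates_dlg_cm.csv"))
  expect_equal(nrow(rates), 3)
  expect_setequal(names(rates)[4:6], c("rate_ucl", "rate_mean", "rate_lcl"))
  b1 <- readLines(file.path(dir, "rates_dlg_cm.csv"))
  export_sensitivity(fits, summ, dir, plot = FALSE)
  expect_identical(readLines(file.path(dir, "rates_dlg_cm.csv")), b1)
  cross <- utils::read.csv(file.path(dir, "crossings_dlg_cm.csv"))
  expect_equal(nrow(cross), 3)
  # a plot export exercises the figure path
  export_sensitivity(fits[1], summ, dir, plot = TRUE)
  expect_true(file.exists(file.path(dir, "response_dlg_cm_PTV1.png")))
})
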