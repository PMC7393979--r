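design_114 <- function() {
  augment_design(half_fraction_design(6), TRUE, 5, 3)
}

test_that("calibrated draws are reproducible and keyed per row", {
  d <- design_114()
  a <- simulate_function_calibrated(d, seed = 7)
  b <- simulate_function_calibrated(d, seed = 7)
  expect_identical(a, b)
  expect_false(identical(a, simulate_function_calibrated(d, seed = 8)))

  # adding rows never perturbs existing draws: simulate a subset of the
  # design and compare shared rows with the full run
  sub <- d[d$run_id %in% c("run01", "run05", "full"), ]
  s <- simulate_function_calibrated(sub, seed = 7)
  shared <- dplyr::semi_join(a, s, by = c("ecosystem_id", "replicate", "time_h"))
  expect_equal(as.data.frame(dplyr::arrange(s, ecosystem_id, replicate, time_h)),
               as.data.frame(dplyr::arrange(shared, ecosystem_id, replicate, time_h)))
})

test_that("zero-SD calibration reproduces the means exactly", {
  cal <- default_calibration()
  cal$scod_re_sd <- cal$od600_sd <- 0
  attr(cal, "scod_initial_sd") <- 0
  d <- design_114()
  fn <- simulate_function_calibrated(d, cal, seed = 1)
  r <- response_table(fn) |>
    dplyr::inner_join(dplyr::select(d, ecosystem_id = "run_id",
                                    "replicate", "richness"),
                      by = c("ecosystem_id", "replicate")) |>
    dplyr::filter(.data$richness > 0)
  expected <- cal$scod_re_mean[match(r$richness, cal$richness)]
  expect_equal(r$scod_re, expected, tolerance = 1e-12)
  expected_od <- cal$od600_mean[match(r$richness, cal$richness)]
  expect_equal(r$od600, expected_od, tolerance = 1e-12)
})

test_that("calibration must cover every biotic richness level", {
  cal <- default_calibration()[1:2, ]
  expect_error(simulate_function_calibrated(design_114(), cal),
               "lacks richness level")
})

test_that("abiotic controls sit near zero removal and optical density", {
  d <- design_114()
  fn <- simulate_function_calibrated(d, seed = 3)
  r <- suppressWarnings(response_table(fn))
  ctrl <- r[grepl("^ctrl", r$ecosystem_id), ]
  expect_true(all(abs(ctrl$scod_re) < 0.05))
  expect_true(all(ctrl$od600 < 0.01))
})

test_that("group means converge to the calibration at 1/sqrt(n) rate", {
  base <- augment_design(half_fraction_design(6), TRUE, 0, 800) |>
    dplyr::filter(.data$role == "full_community")
  fn <- simulate_function_calibrated(base, seed = 11)
  re <- response_table(fn)$scod_re
  errs <- vapply(c(50, 200, 800), function(n) abs(mean(re[1:n]) - 0.822),
                 double(1))
  # errors shrink with n and stay within a few standard errors throughout
  expect_true(all(errs < 4 * 0.019 / sqrt(c(50, 200, 800))))
})

test_that("mechanistic model collapses and orders as its structure dictates", {
  d <- augment_design(half_fraction_design(6), TRUE, 0, 1)
  eff <- setNames(rep(0.4, 6), design_species(d))

  # gamma = 0, sigma = 0, equal effects: every community identical, LRmean 0
  fn <- simulate_function_mechanistic(d, eff, beta0 = -1, gamma = 0,
                                      sigma = 0, seed = 1)
  r <- response_table(fn)
  expect_equal(var(r$scod_re), 0, tolerance = 1e-20)
  lrr <- overyielding_ratios(d, r)
  expect_equal(lrr$lr_mean, rep(0, nrow(lrr)), tolerance = 1e-12)

  # unequal effects, no complementarity: every polyculture below its best
  # member (logit of the mean < logit of the max)
  eff2 <- setNames(seq(-0.6, 0.9, length.out = 6), design_species(d))
  fn2 <- simulate_function_mechanistic(d, eff2, beta0 = -0.5, gamma = 0,
                                       sigma = 0, seed = 1)
  lrr2 <- overyielding_ratios(d, response_table(fn2))
  expect_true(all(lrr2$lr_max < 0))
})

test_that("mean transgressive overyielding rises with the complementarity knob", {
  d <- augment_design(half_fraction_design(6), TRUE, 0, 1)
  eff <- setNames(rnorm(6, 0, 0.2), design_species(d))
  mean_lrmax <- vapply(c(0, 0.3, 0.6), function(gamma) {
    vals <- vapply(1:25, function(s) {
      fn <- simulate_function_mechanistic(d, eff, beta0 = -0.3, gamma = gamma,
                                          sigma = 0.05, seed = 1000 + s)
      lrr <- overyielding_ratios(d, response_table(fn))
      mean(lrr$lr_max[lrr$richness == 3 & lrr$response == "scod_re"])
    }, double(1))
    mean(vals)
  }, double(1))
  expect_true(all(diff(mean_lrmax) > 0))
})

test_that("simulated pools are ultrametric with bookkeeping identities", {
  pool <- simulate_pool(6, seed = 5)
  expect_true(ape::is.ultrametric(pool$tree, tol = 1e-9))
  expect_equal(faith_pd(pool$tree, pool$species), sum(pool$tree$edge.length))
  expect_true(all(pool$eeq$eeq > 0))
  prof <- normalize_plate(pool$plate, pool$eeq)
  expect_equal(rowMeans(prof[, -1]), rep(1, 6), tolerance = 1e-9,
               ignore_attr = TRUE)

  p1 <- simulate_pool(1, seed = 2)
  expect_equal(length(p1$tree$tip.label), 1)
  expect_equal(faith_pd(p1$tree, p1$species, include_root = FALSE), 0)

  expect_identical(simulate_pool(4, seed = 9)$plate,
                   simulate_pool(4, seed = 9)$plate)
})
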