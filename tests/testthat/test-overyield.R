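test_that("log response ratios match hand arithmetic and their ordering", {
  expect_equal(log_ratio_mean(0.3, c(0.2, 0.3, 0.4)), 0)
  expect_equal(log_ratio_mean(exp(1) * 0.3, c(0.2, 0.3, 0.4)), 1)
  expect_equal(log_ratio_mean(0.6, c(0.2, 0.3, 0.4)), log(2))
  expect_equal(log_ratio_max(0.4, c(0.2, 0.3, 0.4)), 0)
  expect_equal(log_ratio_max(0.8, c(0.2, 0.3, 0.4)), log(2))

  expect_error(log_ratio_mean(0, c(0.2)), class = "befmix_undefined_lrr")
  expect_error(log_ratio_max(0.5, c(0.2, -0.1)),
               class = "befmix_undefined_lrr")

  # LRmax <= LRmean always, equal iff all monocultures equal
  set.seed(31)
  for (i in 1:50) {
    poly <- runif(1, 0.05, 1)
    monos <- runif(sample(2:6, 1), 0.05, 1)
    expect_lte(log_ratio_max(poly, monos), log_ratio_mean(poly, monos))
  }
  expect_equal(log_ratio_max(0.5, c(0.2, 0.2)), log_ratio_mean(0.5, c(0.2, 0.2)))
})

test_that("overyielding_ratios references member monoculture replicate means", {
  # the positive-sign k=3 fraction holds the three monocultures + triculture
  d <- augment_design(half_fraction_design(3, sign = "pos"),
                      add_full_community = TRUE,
                      n_controls = 0, n_replicates = 2)
  members <- design_members(d)
  mono_value <- c(sp1 = 0.2, sp2 = 0.3, sp3 = 0.4)
  resp <- tibble::tibble(
    ecosystem_id = d$run_id, replicate = d$replicate,
    od600 = 0.1,
    scod_re = vapply(members, function(m)
      if (length(m) == 1) mono_value[[m]] else 0.6, double(1))
  )
  fn <- make_function_tbl(resp)
  lrr <- overyielding_ratios(d, response_table(fn))

  full <- dplyr::filter(lrr, .data$ecosystem_id == "full",
                        .data$response == "scod_re")
  expect_equal(full$lr_mean, rep(log(0.6 / 0.3), 2))
  expect_equal(full$lr_max, rep(log(0.6 / 0.4), 2))
  expect_true(all(lrr$richness >= 2))
})

test_that("undefined ratios are excluded with an explicit count", {
  d <- augment_design(half_fraction_design(3, sign = "pos"),
                      add_full_community = TRUE,
                      n_controls = 0, n_replicates = 1)
  resp <- tibble::tibble(
    ecosystem_id = d$run_id, replicate = d$replicate,
    od600 = 0.1, scod_re = 0.5
  )
  resp$od600[resp$ecosystem_id == "full"] <- 0  # nonpositive polyculture
  fn <- make_function_tbl(resp)
  expect_warning(
    lrr <- overyielding_ratios(d, response_table(fn)),
    "Undefined log response ratios"
  )
  expect_equal(unname(attr(lrr, "dropped")["od600"]), 1)
  expect_true(is.na(lrr$lr_mean[lrr$ecosystem_id == "full" &
                                lrr$response == "od600"]))
})

test_that("a design without monocultures warns and returns no ratios", {
  # the negative-sign k=3 fraction has no monocultures at all
  d <- augment_design(half_fraction_design(3), TRUE, 0, 1)
  resp <- tibble::tibble(ecosystem_id = d$run_id, replicate = d$replicate,
                         od600 = 0.1, scod_re = 0.5)
  expect_warning(lrr <- overyielding_ratios(d, resp), "no monocultures")
  expect_equal(nrow(lrr), 0)
})

test_that("per-richness tests detect clear overyielding and ignore zero spread", {
  # all ratios exactly zero: no group differs from 0
  z <- tibble::tibble(richness = rep(c(3L, 5L), each = 5),
                      lr_max = 0, lr_mean = 0, response = "scod_re")
  t0 <- overyielding_tests(z, "lr_max")
  expect_true(all(t0$per_group$p_value == 1))
  expect_equal(t0$omnibus$family, "none")

  # a strong positive shift is detected essentially always
  hits <- vapply(1:20, function(s) {
    set.seed(s)
    d <- tibble::tibble(richness = 3L, lr_max = rnorm(20, 0.5, 0.01),
                        lr_mean = 0, response = "scod_re")
    suppressWarnings(overyielding_tests(d, "lr_max"))$per_group$p_value < 0.05
  }, logical(1))
  expect_true(all(hits))

  # disjoint supports: the omnibus rejects
  dj <- tibble::tibble(
    richness = rep(c(3L, 5L), each = 12),
    lr_max = c(runif(12, 0, 0.1), runif(12, 1, 1.1)),
    lr_mean = 0, response = "scod_re"
  )
  tdj <- overyielding_tests(dj, "lr_max")
  expect_lt(tdj$omnibus$p_value, 0.001)

  # undersized groups are skipped with a warning
  mix <- tibble::tibble(richness = c(3L, 3L, 3L, 5L),
                        lr_max = c(0.1, 0.2, 0.15, 0.9),
                        lr_mean = 0, response = "scod_re")
  expect_warning(tm <- overyielding_tests(mix, "lr_max"), "skipped")
  expect_equal(tm$per_group$richness, 3L)
})

test_that("forced families route to the requested machinery", {
  set.seed(2)
  d <- tibble::tibble(richness = rep(c(1L, 3L, 5L), each = 10),
                      lr_max = rnorm(30, rep(c(0, 0.3, 0.5), each = 10), 0.2),
                      lr_mean = 0)
  for (fam in c("anova", "welch", "kruskal")) {
    res <- suppressWarnings(overyielding_tests(d, "lr_max", family = fam))
    expect_equal(res$omnibus$family, fam)
    expect_true(nrow(res$posthoc) >= 1)
  }
})
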