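test_that("wholemount cleaning filters the analysis window and flags females", {
  wm <- tibble::tibble(female_id = "F1", diameter_um = c(90, 150, 400))
  out <- clean_wholemount(wm)
  expect_equal(out$data$diameter_um, c(150, 400))
  expect_true(out$report$flagged)

  wm2 <- tibble::tibble(female_id = "F1", diameter_um = c(150, 1200))
  out2 <- clean_wholemount(wm2)
  expect_equal(out2$data$diameter_um, 150)
  expect_equal(out2$report$n_above, 1)
  expect_false(out2$report$flagged)

  wm3 <- tibble::tibble(female_id = "F1", diameter_um = c(150, 400))
  out3 <- clean_wholemount(wm3)
  expect_equal(nrow(out3$data), 2)
  expect_false(out3$report$flagged)

  all_small <- tibble::tibble(female_id = "F1", diameter_um = c(50, 60))
  expect_error(clean_wholemount(all_small), "no analysable oocytes")
})

test_that("oocyte ratio counts the diameter split", {
  wm <- tibble::tibble(
    female_id = "F1",
    diameter_um = c(rep(150, 10), rep(400, 5), rep(700, 5))
  )
  or <- compute_or(wm)
  expect_equal(or$n_pvo, 10)
  expect_equal(or$n_dev, 10)
  expect_equal(or$or, 1.0)

  only_pvo <- tibble::tibble(female_id = "F1", diameter_um = rep(150, 8))
  expect_equal(compute_or(only_pvo)$or, Inf)
  only_dev <- tibble::tibble(female_id = "F1", diameter_um = rep(400, 8))
  expect_equal(compute_or(only_dev)$or, 0)
  expect_error(compute_or(only_dev[0, ]), "empty")
})

test_that("ORC boundaries match the rule table exactly", {
  expect_equal(
    classify_orc(c(1, 1.01, 3, 3.01, 15, 15.01, Inf)),
    c(1L, 2L, 2L, 3L, 3L, 4L, 4L)
  )
  expect_equal(classify_orc(2), 2L)
  expect_equal(classify_orc(0), 1L)
  # prespawning metadata overrides any ratio
  expect_equal(classify_orc(c(0.4, 20), prespawning_flag = TRUE), c(0L, 0L))
  expect_error(classify_orc(-1), "non-negative")
})

test_that("OR is monotone in composition and ORC non-decreasing in OR", {
  set.seed(21)
  for (i in 1:20) {
    d <- runif(sample(20:60, 1), 100, 1100)
    wm <- tibble::tibble(female_id = "F", diameter_um = d)
    base <- compute_or(wm)$or
    plus_pvo <- compute_or(
      tibble::tibble(female_id = "F", diameter_um = c(d, 150))
    )$or
    plus_dev <- compute_or(
      tibble::tibble(female_id = "F", diameter_um = c(d, 400))
    )$or
    expect_gte(plus_pvo, base)
    expect_lte(plus_dev, base)
  }
  ors <- sort(runif(50, 0, 40))
  expect_true(all(diff(classify_orc(ors)) >= 0))
})

test_that("EM recovers a known gamma/normal mixture and its crossing", {
  # oracle: numeric crossing of the true weighted densities
  truth_cross <- uniroot(
    function(x) 0.7 * dgamma(x, 25, scale = 6) - 0.3 * dnorm(x, 400, 60),
    c(24 * 6, 400), tol = 1e-10
  )$root

  set.seed(42)
  n1 <- rbinom(1, 2000, 0.7)
  d <- c(rgamma(n1, 25, scale = 6), rnorm(2000 - n1, 400, 60))
  fit <- fit_gamma_gaussian_mixture(d)
  expect_true(fit$converged)
  expect_lt(abs(fit$threshold_um - truth_cross), 15)
  expect_lt(abs(fit$weight - 0.7), 0.05)
  expect_lt(abs(fit$normal_mean - 400), 10)

  # log-likelihood is non-decreasing along the EM trace
  expect_true(all(diff(fit$loglik_trace) > -1e-8))

  # threshold lies strictly between the component modes
  expect_gt(fit$threshold_um, (fit$gamma_shape - 1) * fit$gamma_scale)
  expect_lt(fit$threshold_um, fit$normal_mean)

  td <- tidy(fit)
  expect_equal(td$estimate[td$term == "threshold_um"], fit$threshold_um)
  expect_true(glance(fit)$converged)
})

test_that("well-separated point masses put the threshold in the gap", {
  d <- c(runif(100, 120, 190), runif(100, 620, 700))
  fit <- suppressWarnings(fit_gamma_gaussian_mixture(d))
  expect_gt(fit$threshold_um, 200)
  expect_lt(fit$threshold_um, 600)
})

test_that("degenerate or tiny samples are rejected", {
  expect_error(fit_gamma_gaussian_mixture(rnorm(30, 200, 10)), "at least 50")
  # unimodal cloud far on one side of every candidate split
  expect_error(fit_gamma_gaussian_mixture(rnorm(200, 800, 20)),
               "init_split_range|unimodal")
})

test_that("threshold summary gives the t-interval across females", {
  s <- threshold_summary(c(190, 194))
  expect_equal(s$mean_threshold_um, 192)
  ident <- threshold_summary(c(200, 200, 200))
  expect_equal(ident$ci_lo, ident$ci_hi)
  expect_error(threshold_summary(201), "at least 2")
})

test_that("threshold summary CI covers the true crossing across cohorts", {
  truth_cross <- uniroot(
    function(x) 0.7 * dgamma(x, 25, scale = 6) - 0.3 * dnorm(x, 400, 60),
    c(24 * 6, 400), tol = 1e-10
  )$root
  set.seed(77)
  covered <- 0
  n_rep <- 30
  for (r in seq_len(n_rep)) {
    ths <- vapply(1:8, function(i) {
      n1 <- rbinom(1, 400, 0.7)
      d <- c(rgamma(n1, 25, scale = 6), rnorm(400 - n1, 400, 60))
      suppressWarnings(fit_gamma_gaussian_mixture(d))$threshold_um
    }, numeric(1))
    s <- threshold_summary(ths)
    covered <- covered + (s$ci_lo <= truth_cross && truth_cross <= s$ci_hi)
  }
  expect_gte(covered / n_rep, 0.9)
})

test_that("smoothed OSFD is a proper density with the expected modes", {
  wm <- tibble::tibble(female_id = "F1",
                       diameter_um = c(rnorm(400, 150, 20),
                                       rnorm(200, 420, 40)))
  osfd <- smoothed_osfd(wm)
  step <- diff(osfd$diameter_um[1:2])
  expect_equal(sum(osfd$density) * step, 1, tolerance = 1e-3)

  # modes near the component means (within a bandwidth)
  bw <- stats::bw.nrd0(wm$diameter_um)
  dens <- osfd$density
  local_max <- which(diff(sign(diff(dens))) == -2) + 1
  modes <- osfd$diameter_um[local_max]
  expect_true(any(abs(modes - 150) < bw + 10))
  expect_true(any(abs(modes - 420) < bw + 10))

  expect_error(smoothed_osfd(wm, bandwidth = -5), "bandwidth")
  tiny <- tibble::tibble(female_id = "F", diameter_um = c(200, 210))
  expect_error(smoothed_osfd(tiny), "at least 5")
})

test_that("orc_table joins cleaning, ratio and classification", {
  ds <- small_sim(n = 30)
  orc <- orc_table(ds$wholemount, ds$females)
  expect_setequal(orc$female_id, ds$females$female_id)
  expect_true(all(orc$orc %in% 0:4))
  # flagged prespawning females are ORC0 regardless of ratio
  pres <- ds$females$female_id[ds$females$prespawning_flag]
  expect_true(all(orc$orc[orc$female_id %in% pres] == 0))
})
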