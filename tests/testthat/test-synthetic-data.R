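test_that("identical config and seed give identical synthetic output", {
  a <- simulate_dataset(sim_config(n_females = 15, seed = 123))
  b <- simulate_dataset(sim_config(n_females = 15, seed = 123))
  expect_identical(a$females, b$females)
  expect_identical(a$wholemount, b$wholemount)
  expect_identical(a$histology_hits, b$histology_hits)
  expect_identical(a$histology_axes, b$histology_axes)
  c <- simulate_dataset(sim_config(n_females = 15, seed = 124))
  expect_false(identical(a$wholemount, c$wholemount))
})

test_that("generated tables satisfy the input schemas", {
  ds <- small_sim(n = 12)
  expect_equal(nrow(validate_table(ds$females, "females")), 0)
  expect_equal(nrow(validate_table(ds$wholemount, "wholemount")), 0)
  expect_equal(nrow(validate_table(ds$histology_hits, "histology_hits")), 0)
  expect_equal(nrow(validate_table(ds$histology_axes, "histology_axes")), 0)
  # grid hits always total the configured points
  per <- tapply(ds$histology_hits$hits, ds$histology_hits$female_id, sum)
  expect_true(all(per == 500))
})

test_that("single-female population produces valid minimal output", {
  ds <- simulate_dataset(sim_config(n_females = 1, seed = 5))
  expect_equal(nrow(ds$females), 1)
  expect_gt(nrow(ds$wholemount), 0)
  expect_equal(nrow(validate_table(ds$females, "females")), 0)
})

test_that("true packing densities follow the reported magnitude ordering", {
  ds <- small_sim(n = 60, seed = 42)
  by_phase <- tapply(ds$truth$phases$opd_true, ds$truth$phases$phase, mean)
  early_pvo <- mean(by_phase[c("PVO2", "PVO3")])
  late_pvo <- mean(by_phase[c("PVO4a", "PVO4b", "PVO4c")])
  developing <- mean(by_phase[c("CA", "VO1", "VO2", "VO3", "GVM", "GVBD")])
  expect_gt(early_pvo, 5 * late_pvo)
  expect_gt(late_pvo, 2 * developing)
})

test_that("zero-influx null keeps prespawning and spent PVO4c levels equal", {
  cfg <- sim_config(n_females = 120, seed = 31, pvo4c_influx = 0)
  pop <- generate_population(cfg)
  tp <- pop$truth$phases[pop$truth$phases$phase == "PVO4c", ]
  m0 <- mean(tp$rf_true[tp$stage == 0])
  m4 <- mean(tp$rf_true[tp$stage == 4])
  se <- sqrt(var(tp$rf_true[tp$stage == 0]) / sum(tp$stage == 0) +
               var(tp$rf_true[tp$stage == 4]) / sum(tp$stage == 4))
  expect_lt(abs(m0 - m4), 3 * se)
  expect_error(sim_config(pvo4c_influx = 1e5), "inconsistent config")
})

test_that("running the density equation on expected fractions closes the loop", {
  cfg <- sim_config(n_females = 8, seed = 9)
  pop <- generate_population(cfg)
  vv <- expected_volume_fractions(pop$truth, pop$females, cfg)
  joined <- merge(vv, pop$truth$phases, by = c("female_id", "phase"))
  joined <- joined[joined$opd_true > 0 &
                     joined$phase %in% oocyte_phases(opd_only = TRUE), ]
  ph <- cfg$phases
  m <- ph$mean_d_um[match(joined$phase, ph$phase)]
  s <- ph$sd_d_um[match(joined$phase, ph$phase)]
  k_bar <- 1 + cfg$shape_k$mean_excess
  rho <- specific_gravity_for_stage(
    pop$females$maturity_stage[match(joined$female_id,
                                     pop$females$female_id)]
  )
  cod_v <- (m^3 + 3 * m * s^2)^(1 / 3) # cubic-mean diameter of the phase
  est <- opd(joined$v_v_expected, rho, k_bar, cod_v,
             constant_mode = "exact")$opd
  expect_equal(est, joined$opd_true, tolerance = 5e-3)
})

test_that("Delesse estimates are unbiased and scale as 1/sqrt(grid points)", {
  # 2-D sections with known area fractions, counted by random point grids
  p_true <- c(PVO2 = 0.2, VO1 = 0.35, OTHERS = 0.45)
  set.seed(51)
  n_rep <- 300
  est500 <- matrix(NA_real_, n_rep, 3)
  est1000 <- matrix(NA_real_, n_rep, 3)
  for (r in seq_len(n_rep)) {
    h5 <- drop(rmultinom(1, 500, p_true))
    h10 <- drop(rmultinom(1, 1000, p_true))
    tb5 <- tibble::tibble(female_id = "F", structure = names(p_true),
                          hits = as.integer(h5), total_points = 500L)
    est500[r, ] <- delesse_volume_fractions(tb5)$v_v
    tb10 <- tibble::tibble(female_id = "F", structure = names(p_true),
                           hits = as.integer(h10), total_points = 1000L)
    est1000[r, ] <- delesse_volume_fractions(tb10)$v_v
  }
  # unbiasedness: mean within 3 standard errors of truth
  se <- sqrt(p_true * (1 - p_true) / 500 / n_rep)
  expect_true(all(abs(colMeans(est500) - p_true) < 3 * se))
  # variance scaling: doubling the grid points halves the variance
  ratio <- apply(est500, 2, var) / apply(est1000, 2, var)
  expect_true(all(ratio > 1.5 & ratio < 2.7))
})

test_that("wholemount simulation respects detection probabilities", {
  # all-equal detection: observed PVO/developing ratio tracks the true one
  cfg <- sim_config(n_females = 30, seed = 63)
  det1 <- cfg$detection
  det1[] <- 1
  cfg1 <- sim_config(n_females = 30, seed = 63, detection = det1)
  pop <- generate_population(cfg1)
  wm <- simulate_wholemount(pop$truth, cfg1)

  pvo_phases <- c("PVO1", "PVO2", "PVO3", "PVO4a", "PVO4b", "PVO4c")
  tp <- pop$truth$phases
  true_ratio <- sum(tp$rf_true[tp$phase %in% pvo_phases]) /
    sum(tp$rf_true[!tp$phase %in% pvo_phases])
  # classify observed diameters by nearest phase-band, using the true split
  # of each phase's diameter distribution is unavailable; compare total
  # counts through the multinomial expectation instead
  n_tot <- nrow(wm)
  exp_pvo_share <- sum(tp$rf_true[tp$phase %in% pvo_phases]) /
    sum(tp$rf_true)
  # binomial tolerance at 3 sigma on the pooled sample
  obs_share_bound <- 3 * sqrt(exp_pvo_share * (1 - exp_pvo_share) / n_tot)
  # diameters below ~250 um are overwhelmingly previtellogenic here
  obs_share <- mean(wm$diameter_um <= 250)
  expect_lt(abs(obs_share - exp_pvo_share), obs_share_bound + 0.02)

  # halving detection of previtellogenic phases halves their observed share
  det_half <- det1
  det_half[pvo_phases] <- 0.5
  cfg2 <- sim_config(n_females = 30, seed = 63, detection = det_half)
  wm2 <- simulate_wholemount(pop$truth, cfg2)
  or1 <- sum(wm$diameter_um <= 250) / sum(wm$diameter_um > 250)
  or2 <- sum(wm2$diameter_um <= 250) / sum(wm2$diameter_um > 250)
  expect_equal(or2 / or1, 0.5, tolerance = 0.12)
})

test_that("spent females show mostly previtellogenic wholemounts", {
  ds <- small_sim(n = 40, seed = 17)
  spent <- ds$truth$females$female_id[ds$truth$females$stage == 4]
  wm <- ds$wholemount[ds$wholemount$female_id %in% spent, ]
  expect_gt(mean(wm$diameter_um <= 250), 0.9)
})
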