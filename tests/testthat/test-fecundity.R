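make_fec_fixture <- function() {
  fem <- tibble::tibble(
    female_id = c("A", "B", "C", "D"),
    capture_date = as.Date(c("2019-01-10", "2019-05-10", "2019-05-12",
                             "2019-06-20")),
    total_length_cm = 35, body_weight_g = 500, ovary_weight_g = 50,
    maturity_stage = c(5L, 6L, 6L, 7L),
    prespawning_flag = c(TRUE, FALSE, FALSE, FALSE)
  )
  opd_tbl <- tidyr::expand_grid(
    female_id = fem$female_id,
    phase = factor(oocyte_phases(opd_only = TRUE),
                   levels = oocyte_phases(opd_only = TRUE))
  )
  opd_tbl$opd <- 0
  opd_tbl$opd[opd_tbl$phase == "PVO4c"] <- c(2000, 1500, 1200, 400)[
    match(opd_tbl$female_id[opd_tbl$phase == "PVO4c"], fem$female_id)
  ]
  opd_tbl$opd[opd_tbl$phase == "VO1"] <- c(1000, 1500, 1300, 0)[
    match(opd_tbl$female_id[opd_tbl$phase == "VO1"], fem$female_id)
  ]
  orc <- tibble::tibble(
    female_id = fem$female_id, n_pvo = 1, n_dev = 1,
    or = c(0.5, 0.8, 2, 20), orc = c(0L, 1L, 2L, 4L)
  )
  list(females = fem, opd = opd_tbl, orc = orc)
}

test_that("fecundity measures follow NO = OPD x OW, RF = NO/W", {
  fx <- make_fec_fixture()
  fec <- fecundity_table(fx$opd, fx$females)
  a_pvo4c <- fec[fec$female_id == "A" & fec$phase == "PVO4c", ]
  expect_equal(a_pvo4c$no, 2000 * 50)
  expect_equal(a_pvo4c$rf, 2000 * 50 / 500)
  expect_equal(a_pvo4c$rf_tl, 100 * 2000 * 50 / 35^3.13)

  # zeros propagate, and doubling NO doubles RF_TL
  expect_true(all(fec$no[fec$phase == "GVM"] == 0))
  fec2 <- fecundity_table(dplyr::mutate(fx$opd, opd = opd * 2), fx$females)
  expect_equal(fec2$rf_tl, 2 * fec$rf_tl)

  # conservation: sum of NO per female equals OW * sum of opd
  tot <- dplyr::summarise(dplyr::group_by(fec, female_id),
                          no = sum(no), .groups = "drop")
  opd_tot <- dplyr::summarise(dplyr::group_by(fx$opd, female_id),
                              s = sum(opd), .groups = "drop")
  expect_equal(tot$no, opd_tot$s * 50)

  orphan <- dplyr::mutate(fx$opd, female_id = paste0("X", female_id))
  expect_error(fecundity_table(orphan, fx$females), "missing")
})

test_that("RF-by-ORC cells carry means, CIs and single-female flags", {
  fx <- make_fec_fixture()
  fec <- fecundity_table(fx$opd, fx$females)
  s <- rf_by_orc(fec, fx$orc, fx$females)
  pvo4c_1 <- s[s$phase == "PVO4c" & s$orc == 1, ]
  expect_equal(pvo4c_1$mean_rf, 1500 * 50 / 500)
  expect_true(pvo4c_1$single_female)
  expect_true(is.na(pvo4c_1$se))

  two_cell <- tibble::tibble(
    female_id = c("B", "C"), phase = "PVO4c", opd = 1,
    no = 1, rf = c(100, 200), rf_tl = 1
  )
  s2 <- rf_by_orc(two_cell,
                  fx$orc[fx$orc$female_id %in% c("B", "C"), ] |>
                    dplyr::mutate(orc = 2L),
                  fx$females)
  expect_equal(s2$mean_rf, 150)
  s3 <- rf_by_orc(dplyr::mutate(two_cell, rf = 100),
                  fx$orc[fx$orc$female_id %in% c("B", "C"), ] |>
                    dplyr::mutate(orc = 2L),
                  fx$females)
  expect_equal(s3$ci_lo, s3$ci_hi) # constant cell -> zero-width CI
})

test_that("de novo influx subtracts the spent cell from the prespawning cell", {
  s <- tibble::tibble(
    phase = "PVO4c", orc = c(0L, 4L), year = 2019L, n = c(5L, 5L),
    mean_rf = c(200, 40), se = c(5, 2),
    ci_lo = NA, ci_hi = NA, single_female = FALSE
  )
  influx <- denovo_influx(s)
  expect_equal(influx$influx, 160)
  expect_equal(influx$se, sqrt(25 + 4))

  equal <- dplyr::mutate(s, mean_rf = 100)
  expect_equal(denovo_influx(equal)$influx, 0)

  neg <- dplyr::mutate(s, mean_rf = c(40, 200))
  expect_warning(denovo_influx(neg), "determinate")

  missing_cell <- s[1, ]
  expect_error(denovo_influx(missing_cell), "cannot quantify influx")
})

test_that("batch calculus reproduces totals and roundings", {
  b <- total_potential_and_batches(528, 160, c(40, 30, 34))
  expect_equal(unique(b$total_potential_rf), 688)
  expect_equal(b$n_batches, c(17L, 23L, 20L))
  one <- total_potential_and_batches(40, 0, 40)
  expect_equal(one$n_batches, 1L)
  expect_error(total_potential_and_batches(500, 100, -40), "positive")

  # unit consistency: per-kg RF with per-kg batch fecundity gives the same count
  per_g <- total_potential_and_batches(528, 160, 40)
  per_kg <- total_potential_and_batches(528e3, 160e3, 40e3)
  expect_equal(per_g$n_batches, per_kg$n_batches)
})

test_that("threshold sensitivity averages per-female reductions by year", {
  fem <- make_fec_fixture()$females
  orc <- make_fec_fixture()$orc
  phases <- oocyte_phases(opd_only = TRUE)
  fec <- tidyr::expand_grid(female_id = c("B", "C"), phase = phases)
  fec$rf <- 0
  # B: PVO4a 10, PVO4b 10, PVO4c 30, VO1 50 -> reduction 20/100 = 20%
  fec$rf[fec$female_id == "B" &
           fec$phase %in% c("PVO4a", "PVO4b")] <- 10
  fec$rf[fec$female_id == "B" & fec$phase == "PVO4c"] <- 30
  fec$rf[fec$female_id == "B" & fec$phase == "VO1"] <- 50
  # C: no PVO4a/PVO4b mass -> 0% reduction
  fec$rf[fec$female_id == "C" & fec$phase == "PVO4c"] <- 40
  fec$rf[fec$female_id == "C" & fec$phase == "VO2"] <- 60
  sens <- threshold_sensitivity(fec, orc, fem)
  expect_equal(sens$mean_reduction_pct, mean(c(20, 0)))
  expect_equal(sens$n_dropped, 0L)

  # a female with only PVO4a drops out of the pairing
  fec$rf[fec$female_id == "C"] <- 0
  fec$rf[fec$female_id == "C" & fec$phase == "PVO4a"] <- 25
  sens2 <- threshold_sensitivity(fec, orc, fem)
  expect_equal(sens2$n, 1L)
  expect_equal(sens2$n_dropped, 1L)
  expect_equal(sens2$mean_reduction_pct, 20)
})

test_that("standard individual sums grand means with exact contributions", {
  s <- tibble::tibble(
    phase = rep(c("PVO4c", "VO1"), 2), orc = rep(c(1L, 2L), each = 2),
    year = 2019L, n = 3L,
    mean_rf = c(100, 200, 50, 80), se = 1, ci_lo = NA, ci_hi = NA,
    single_female = FALSE
  )
  std <- standard_individual(s)
  expect_equal(unique(std$total_rf[std$orc == 1]), 300)
  expect_equal(unique(std$total_rf[std$orc == 2]), 130)
  sums <- dplyr::summarise(dplyr::group_by(std, orc),
                           s = sum(contribution_rf),
                           t = total_rf[1], .groups = "drop")
  expect_equal(sums$s, sums$t) # contributions conserve the total
})

test_that("structure prevalence counts presence shares and mean fractions", {
  fr <- tibble::tibble(
    female_id = c("A", "B", "C"), structure = "ATR_PVO",
    v_v = c(0.08, 0.08, 0.08)
  )
  groups <- tibble::tibble(female_id = c("A", "B", "C"), orc = 0L)
  p <- structure_prevalence(fr, groups)
  expect_equal(p$prevalence_pct, 100)
  expect_equal(p$mean_v_v, 0.08)

  none <- dplyr::mutate(fr, v_v = 0)
  p0 <- structure_prevalence(none, groups)
  expect_equal(p0$prevalence_pct, 0)
  expect_equal(p0$mean_v_v, 0)

  # duplicating every female leaves prevalence invariant
  dup <- dplyr::bind_rows(fr, dplyr::mutate(fr, female_id = paste0(female_id, "2")))
  gdup <- dplyr::bind_rows(groups,
                           dplyr::mutate(groups, female_id = paste0(female_id, "2")))
  expect_equal(structure_prevalence(dup, gdup)$prevalence_pct, 100)
})

test_that("simulated threshold sensitivity matches the expected band early in spawning", {
  ds <- small_sim(n = 80, seed = 57)
  orc <- orc_table(ds$wholemount, ds$females)
  opd_tbl <- opd_table(ds$histology_hits, ds$histology_axes, ds$females)
  fec <- fecundity_table(opd_tbl, ds$females)
  # early-spawning females carry the full developing pool: the window
  # narrowing from PVO4a to PVO4c costs a modest share of the aggregate
  early <- threshold_sensitivity(fec, orc, ds$females, orcs = 1)
  expect_gt(early$mean_reduction_pct, 15)
  expect_lt(early$mean_reduction_pct, 45)
  # as spawning progresses the developing pool drains and the same window
  # change removes an ever larger share
  by_orc <- vapply(1:4, function(o) {
    threshold_sensitivity(fec, orc, ds$females, orcs = o)$mean_reduction_pct
  }, numeric(1))
  expect_true(all(diff(by_orc) > 0))
})
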