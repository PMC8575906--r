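#' Configuration for the synthetic-ovary generator
#'
#' Defines a seeded synthetic population of spawning females with known
#' ground truth, emulating the study design the pipeline is built for: a
#' latent spawning-progress stage per female (0 = prespawning through 4 =
#' spent), phase-specific true relative fecundities following the observed
#' seasonal pattern (small previtellogenic phases omnipresent at thousands
#' per gram body weight; the final previtellogenic phase PVO4c depleted
#' across spawning by a programmed de novo influx; a dome-shaped developing
#' pool), and two observation channels: wholemount diameter measurement
#' (with phase-specific under-detection of previtellogenic oocytes, which
#' hide around and under the large vitellogenic ones) and Weibel-grid
#' histology (multinomial 500-point counts over expected volume fractions
#' plus prolate-spheroid axis profiles at histology scale).
#'
#' Defaults are the package's fixed study conditions, chosen to mirror the
#' magnitudes reported for an indeterminate serial spawner; see the methods
#' vignette for the rationale behind each value. Detection probabilities are
#' calibrated so that the expected observed oocyte ratio of each latent
#' stage falls inside that stage's classification band.
#'
#' @param n_females Number of females.
#' @param seed Integer seed; identical config + seed gives byte-identical
#'   output tables.
#' @param pvo4c_influx True PVO4c depletion (oocytes g^-1 body weight)
#'   between prespawning and spent stages; 0 gives a determinate-spawner
#'   null population.
#' @param stage_proportions Allocation of females over stages 0--4
#'   (prespawning and spent oversampled by default: the two stages that
#'   pin down the influx).
#' @param rf_trajectories Optional full override: matrix (phase x 5 stages)
#'   of true relative fecundities.
#' @param gsi_by_stage True median GSI_TL per stage. Prespawning (primary
#'   vitellogenesis) and spent females carry genuinely small ovaries.
#' @param wholemount_n Oocytes measured per female across the wholemount
#'   images.
#' @param grid_points Weibel-grid points per female.
#' @param profiles_per_phase Through-the-nucleus axis profiles measured per
#'   phase.
#' @param shrinkage_factor True linear histology shrinkage (histology scale
#'   = formalin scale / factor).
#' @param detection Named per-phase wholemount detection probabilities.
#' @return A list of class `ovodyn_sim_config`.
#' @export
sim_config <- function(n_females = 150,
                       seed = 1,
                       pvo4c_influx = 160,
                       stage_proportions = c(0.30, 0.14, 0.13, 0.13, 0.30),
                       rf_trajectories = NULL,
                       gsi_by_stage = c(1.5, 6, 5, 3, 0.9),
                       wholemount_n = 600,
                       grid_points = 500,
                       profiles_per_phase = 3,
                       shrinkage_factor = 1.11,
                       detection = NULL) {
  stopifnot(n_females >= 1, length(stage_proportions) == 5,
            abs(sum(stage_proportions) - 1) < 1e-8,
            grid_points >= 50, profiles_per_phase >= 1,
            shrinkage_factor > 0, pvo4c_influx >= 0)
  phases <- tibble::tibble(
    phase = c("PVO1", "PVO2", "PVO3", "PVO4a", "PVO4b", "PVO4c",
              "CA", "VO1", "VO2", "VO3", "GVM", "GVBD"),
    mean_d_um = c(70, 110, 140, 185, 210, 218, 280, 350, 500, 700, 850, 950),
    sd_d_um = c(8, 12, 14, 15, 15, 10, 22, 30, 45, 60, 60, 60)
  )
  if (is.null(rf_trajectories)) {
    pvo4c_orc0 <- 200
    if (pvo4c_influx > pvo4c_orc0) {
      abort("inconsistent config: influx exceeds the prespawning PVO4c level")
    }
    rf_trajectories <- rbind(
      PVO1 = rep(4000, 5),
      PVO2 = rep(2500, 5),
      PVO3 = rep(2000, 5),
      PVO4a = rep(250, 5),
      PVO4b = rep(220, 5),
      PVO4c = pvo4c_orc0 - pvo4c_influx * c(0, 0.25, 0.5, 0.75, 1),
      CA = c(120, 110, 50, 8, 0.8),
      VO1 = c(208, 290, 70, 12, 0.7),
      VO2 = c(0, 190, 40, 10, 0.3),
      VO3 = c(0, 120, 25, 7, 0.2),
      GVM = c(0, 23, 8, 3, 0.07),
      GVBD = c(0, 12, 5, 1.5, 0.03)
    )
  }
  stopifnot(identical(rownames(rf_trajectories), phases$phase),
            ncol(rf_trajectories) == 5, all(rf_trajectories >= 0))
  if (is.null(detection)) {
    detection <- c(
      PVO1 = 0, PVO2 = 0.05, PVO3 = 0.10, PVO4a = 0.20, PVO4b = 0.30,
      PVO4c = 0.50, CA = 0.95, VO1 = 0.95, VO2 = 0.95, VO3 = 0.95,
      GVM = 0.95, GVBD = 0.95
    )
  }
  stopifnot(all(detection >= 0 & detection <= 1),
            identical(names(detection), phases$phase))
  structure(
    list(
      n_females = as.integer(n_females),
      seed = as.integer(seed),
      pvo4c_influx = pvo4c_influx,
      stage_proportions = stage_proportions,
      phases = phases,
      rf_trajectories = rf_trajectories,
      gsi_by_stage = gsi_by_stage,
      gsi_sdlog = 0.12,
      rf_sdlog = 0.15,
      length_weight = list(a = 0.006, b = 3.13, sdlog = 0.13),
      tl = list(mean = 34, sd = 3, min = 25, max = 45),
      shape_k = list(mean_excess = 0.12, sd = 0.05),
      shrinkage_factor = shrinkage_factor,
      grid_points = as.integer(grid_points),
      profiles_per_phase = as.integer(profiles_per_phase),
      wholemount_n = as.integer(wholemount_n),
      detection = detection,
      # structure presence probability per stage 0..4 and section volume
      # fraction when present
      structures = list(
        POF = list(prob = c(0, 0.2, 0.5, 0.6, 0.4), v_v = 0.02),
        ATR_EARLY_ALPHA = list(prob = c(0, 0.05, 0.1, 0.3, 0.3), v_v = 0.008),
        ATR_LATE_ALPHA = list(prob = c(0, 0.1, 0.2, 0.3, 0.35), v_v = 0.01),
        ATR_PVO = list(prob = c(0.1, 0, 0, 0, 0), v_v = 0.02)
      ),
      stage_dates = as.Date(c("2019-01-15", "2019-03-20", "2019-04-20",
                              "2019-05-20", "2019-06-20")),
      stage_maturity = c(5L, 6L, 6L, 6L, 7L)
    ),
    class = "ovodyn_sim_config"
  )
}

# deterministic largest-remainder-ish allocation of n over proportions
allocate_stages <- function(n, prop) {
  counts <- diff(c(0L, round(cumsum(prop) * n)))
  rep(0:4, times = counts)
}

#' Generate a synthetic population with ground truth
#'
#' Draws biometrics (length, allometric weight with lognormal scatter, ovary
#' weight from a stage-specific GSI model) and true per-phase relative
#' fecundities (stage trajectory times median-centred lognormal biological
#' scatter). True packing densities follow as `RF * W / OW`.
#'
#' @param config A [sim_config()].
#' @return A list with `females` (the canonical females table) and `truth`
#'   (a list: `phases` -- long tibble of true `rf_true` and `opd_true` per
#'   female and phase; `females` -- per-female stage, true GSI and K_n;
#'   `influx_true` -- the programmed PVO4c depletion).
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "ovodyn_sim_config"))
  set.seed(config$seed)
  n <- config$n_females
  stage <- allocate_stages(n, config$stage_proportions)
  id <- sprintf("SF%04d", seq_len(n))

  tl <- pmin(pmax(rnorm(n, config$tl$mean, config$tl$sd),
                  config$tl$min), config$tl$max)
  lw <- config$length_weight
  cond_noise <- exp(rnorm(n, 0, lw$sdlog)) # median 1 -> median K_n ~ 1
  w <- lw$a * tl^lw$b * cond_noise
  # biological scatter truncated at +/-2 sigma: within-stage GSI variation is
  # bounded in real fish
  gsi <- config$gsi_by_stage[stage + 1] *
    exp(pmin(pmax(rnorm(n, 0, config$gsi_sdlog), -2 * config$gsi_sdlog),
             2 * config$gsi_sdlog))
  ow <- gsi * tl^lw$b / 1e4
  capture_date <- config$stage_dates[stage + 1] +
    sample(-10:10, n, replace = TRUE)

  traj <- config$rf_trajectories
  sdl <- config$rf_sdlog
  phase_names <- rownames(traj)
  truth_phases <- tidyr::expand_grid(
    female_id = id, phase = phase_names
  ) |>
    dplyr::mutate(
      stage = rep(stage, each = length(phase_names)),
      rf_expected = traj[cbind(match(.data$phase, phase_names),
                               .data$stage + 1)],
      rf_true = .data$rf_expected *
        exp(pmin(pmax(rnorm(dplyr::n(), 0, sdl), -3 * sdl), 3 * sdl) -
              sdl^2 / 2)
    )

  # physical floor on ovary weight: the ovary must at least hold its oocytes
  # at no more than 80% volume occupancy, so implied volume fractions can
  # never exceed 1
  ph <- config$phases
  k_bar <- 1 + config$shape_k$mean_excess
  vol_cm3 <- (pi / 6) * (8 * k_bar / (1 + k_bar)^3) *
    (ph$mean_d_um^3 + 3 * ph$mean_d_um * ph$sd_d_um^2) * 1e-12
  oocyte_vol_per_g_body <- tapply(
    truth_phases$rf_true * vol_cm3[match(truth_phases$phase, ph$phase)],
    truth_phases$female_id, sum
  )[id]
  rho <- specific_gravity_for_stage(config$stage_maturity[stage + 1])
  ow_min <- as.numeric(oocyte_vol_per_g_body) * w * rho / 0.80
  ow <- pmax(ow, ow_min)

  females <- tibble::tibble(
    female_id = id,
    capture_date = capture_date,
    total_length_cm = round(tl, 1),
    body_weight_g = round(w, 1),
    ovary_weight_g = round(ow, 3),
    maturity_stage = config$stage_maturity[stage + 1],
    prespawning_flag = stage == 0L
  )

  ratio <- setNames(
    females$body_weight_g / females$ovary_weight_g, females$female_id
  )
  truth_phases$opd_true <- truth_phases$rf_true * ratio[truth_phases$female_id]

  list(
    females = females,
    truth = list(
      phases = dplyr::select(truth_phases, "female_id", "stage", "phase",
                             "rf_expected", "rf_true", "opd_true"),
      females = tibble::tibble(
        female_id = id, stage = stage, gsi_true = gsi,
        k_n_true = cond_noise
      ),
      influx_true = config$pvo4c_influx
    )
  )
}

#' Simulate the wholemount observation channel
#'
#' Samples `wholemount_n` measured oocytes per female from a multinomial
#' over phases with probabilities proportional to true relative fecundity
#' times the phase detection probability, then draws each oocyte's
#' formalin-scale diameter from its phase's normal distribution. Measured
#' diameters below the 100 um analytic floor remain in the output -- the
#' cleaning step is expected to remove and report them.
#'
#' @param truth Ground truth from [generate_population()].
#' @param config The same [sim_config()].
#' @return A wholemount tibble (`female_id, image_no, diameter_um`).
#' @export
simulate_wholemount <- function(truth, config) {
  stopifnot(inherits(config, "ovodyn_sim_config"))
  set.seed(config$seed + 1L)
  ph <- config$phases
  det <- config$detection
  out <- truth$phases |>
    tidyr::nest(.by = "female_id") |>
    dplyr::mutate(sample = purrr::map(.data$data, function(df) {
      wgt <- df$rf_true * det[df$phase]
      counts <- drop(rmultinom(1, config$wholemount_n, wgt))
      m <- ph$mean_d_um[match(df$phase, ph$phase)]
      s <- ph$sd_d_um[match(df$phase, ph$phase)]
      d <- rnorm(sum(counts), rep(m, counts), rep(s, counts))
      tibble::tibble(diameter_um = pmax(d, 1))
    })) |>
    dplyr::select("female_id", "sample") |>
    tidyr::unnest("sample")
  out |>
    dplyr::group_by(.data$female_id) |>
    dplyr::mutate(image_no = rep_len(1:3, dplyr::n()), .after = "female_id") |>
    dplyr::ungroup()
}

#' Expected phase volume fractions implied by the ground truth
#'
#' Inverts the packing-density equation: a phase with true density `opd`
#' (oocytes g^-1) in an ovary of specific gravity `rho` occupies the volume
#' fraction `opd * rho * (pi/6) * (8k/(1+k)^3) * E[D^3] * 1e-12`, with
#' `E[D^3] = m^3 + 3 m sigma^2` the exact third moment of the phase's
#' normal diameter distribution (formalin scale) and `k` the mean shape
#' factor. This is the noiseless quantity around which the grid counts are
#' multinomial, and the closed-loop oracle for the packing-density
#' estimator.
#'
#' @param truth Ground truth from [generate_population()].
#' @param females The matching females table.
#' @param config The same [sim_config()].
#' @return Tibble `female_id, phase, v_v_expected`.
#' @export
expected_volume_fractions <- function(truth, females, config) {
  ph <- config$phases
  k_bar <- 1 + config$shape_k$mean_excess
  shape_term <- 8 * k_bar / (1 + k_bar)^3
  rho <- setNames(
    specific_gravity_for_stage(females$maturity_stage), females$female_id
  )
  truth$phases |>
    dplyr::mutate(
      m = ph$mean_d_um[match(.data$phase, ph$phase)],
      s = ph$sd_d_um[match(.data$phase, ph$phase)],
      ed3 = .data$m^3 + 3 * .data$m * .data$s^2,
      v_v_expected = .data$opd_true * rho[.data$female_id] *
        (pi / 6) * shape_term * .data$ed3 * 1e-12
    ) |>
    dplyr::select("female_id", "phase", "v_v_expected")
}

#' Simulate the histology observation channel
#'
#' Grid hits are multinomial over the expected phase volume fractions (see
#' [expected_volume_fractions()]), stage-dependent structure fractions
#' (postovulatory follicles, atresia) and an OTHERS bucket absorbing the
#' residual probability so hits always total `grid_points`. Axis profiles
#' are drawn per packing-density phase with a true count: the oocyte's
#' formalin diameter from the phase distribution, divided by the shrinkage
#' factor to histology scale, then split into long and short axes via a
#' random prolate shape factor (`S = 2 D /(1 + k)`, `L = k S`).
#'
#' @inheritParams expected_volume_fractions
#' @return A list with `hits` and `axes` tibbles in the canonical schemas.
#' @export
simulate_histology <- function(truth, females, config) {
  stopifnot(inherits(config, "ovodyn_sim_config"))
  set.seed(config$seed + 2L)
  ph <- config$phases
  vv <- expected_volume_fractions(truth, females, config)
  stage_of <- setNames(truth$females$stage, truth$females$female_id)

  hits_list <- list()
  axes_list <- list()
  for (fid in females$female_id) {
    st <- stage_of[[fid]]
    f_vv <- vv[vv$female_id == fid, ]
    s_names <- names(config$structures)
    s_vv <- vapply(config$structures, function(sc) {
      rbinom(1, 1, sc$prob[st + 1]) * sc$v_v * runif(1, 0.5, 1.5)
    }, numeric(1))
    p <- c(setNames(f_vv$v_v_expected, f_vv$phase), s_vv)
    p_others <- 1 - sum(p)
    if (p_others <= 0) abort("overpacked ovary: expected volume fractions exceed 1")
    p <- c(p, OTHERS = p_others)
    hh <- drop(rmultinom(1, config$grid_points, p))
    hits_list[[fid]] <- tibble::tibble(
      female_id = fid,
      structure = names(p),
      hits = as.integer(hh),
      total_points = config$grid_points,
      section_area_mm2 = round(runif(1, 30, 120), 1)
    )

    tp <- truth$phases[truth$phases$female_id == fid, ]
    tp <- tp[tp$opd_true > 0 & tp$phase %in% oocyte_phases(opd_only = TRUE), ]
    if (nrow(tp)) {
      nprof <- config$profiles_per_phase
      m <- ph$mean_d_um[match(tp$phase, ph$phase)]
      s <- ph$sd_d_um[match(tp$phase, ph$phase)]
      d_formalin <- rnorm(nrow(tp) * nprof, rep(m, each = nprof),
                          rep(s, each = nprof))
      d_formalin <- pmax(d_formalin, 10)
      k <- 1 + abs(rnorm(length(d_formalin), config$shape_k$mean_excess,
                         config$shape_k$sd))
      d_hist <- d_formalin / config$shrinkage_factor
      s_axis <- 2 * d_hist / (1 + k)
      axes_list[[fid]] <- tibble::tibble(
        female_id = fid,
        phase = rep(tp$phase, each = nprof),
        long_axis_um = k * s_axis,
        short_axis_um = s_axis
      )
    }
  }
  list(
    hits = dplyr::bind_rows(hits_list),
    axes = dplyr::bind_rows(axes_list)
  )
}

#' Generate a complete synthetic data set
#'
#' Runs [generate_population()], [simulate_wholemount()] and
#' [simulate_histology()] under one configuration and returns the four
#' canonical tables plus the ground truth.
#'
#' @param config A [sim_config()].
#' @return List `females, wholemount, histology_hits, histology_axes, truth`.
#' @examples
#' ds <- simulate_dataset(sim_config(n_females = 10, seed = 7))
#' names(ds)
#' @export
simulate_dataset <- function(config = sim_config()) {
  pop <- generate_population(config)
  wm <- simulate_wholemount(pop$truth, config)
  hist <- simulate_histology(pop$truth, pop$females, config)
  list(
    females = pop$females,
    wholemount = wm,
    histology_hits = hist$hits,
    histology_axes = hist$axes,
    truth = pop$truth
  )
}

#' True previtellogenic/developing diameter density crossing
#'
#' The population-level "true threshold" against which mixture-based
#' estimates are compared: the diameter at which the detection-weighted
#' density of previtellogenic oocytes (truncated below the 100 um analytic
#' floor, as in the observed data) crosses the detection-weighted density of
#' developing oocytes, among females at the given latent stages.
#'
#' @param truth Ground truth from [generate_population()].
#' @param config The same [sim_config()].
#' @param stages Latent stages whose females enter the weighting.
#' @param interval Search interval (um).
#' @return The crossing diameter (um).
#' @export
true_threshold <- function(truth, config, stages = 1:2,
                           interval = c(120, 420)) {
  ph <- config$phases
  det <- config$detection
  wgt <- truth$phases |>
    dplyr::filter(.data$stage %in% stages) |>
    dplyr::group_by(.data$phase) |>
    dplyr::summarise(w = sum(.data$rf_true), .groups = "drop") |>
    dplyr::mutate(
      w = .data$w * det[.data$phase],
      m = ph$mean_d_um[match(.data$phase, ph$phase)],
      s = ph$sd_d_um[match(.data$phase, ph$phase)],
      # probability mass surviving the 100 um floor
      w = .data$w * (1 - stats::pnorm(100, .data$m, .data$s)),
      pvo = .data$phase %in% c("PVO1", "PVO2", "PVO3", "PVO4a", "PVO4b",
                               "PVO4c")
    )
  dens_side <- function(x, side) {
    rows <- wgt[wgt$pvo == side & wgt$w > 0, ]
    vapply(x, function(xx) {
      sum(rows$w * dnorm(xx, rows$m, rows$s) /
            (1 - stats::pnorm(100, rows$m, rows$s)))
    }, numeric(1))
  }
  f <- function(x) dens_side(x, TRUE) - dens_side(x, FALSE)
  xs <- seq(interval[1], interval[2], length.out = 512)
  fx <- f(xs)
  i <- which(fx[-length(fx)] > 0 & fx[-1] <= 0)[1]
  if (is.na(i)) abort("no density crossing inside the search interval")
  uniroot(f, c(xs[i], xs[i + 1]), tol = 1e-8)$root
}
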