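#' Clean raw wholemount diameter measurements
#'
#' Restricts measurements to the analysable window. Below 100 um the smallest
#' oocytes are unreliably retained through the washing procedure, so 100 um
#' is the minimum analytic threshold -- and any female whose raw data contain
#' sub-100 um detections is flagged, since such females were excluded from
#' the field protocol. Above ~1150 um the follicle layer detaches, so
#' 1100 um is the working maximum.
#'
#' @param wholemount Wholemount table (`female_id`, `diameter_um`, ...).
#' @param min_d,max_d Analysis window in um.
#' @return A list with `data` (rows within the window) and `report` (per
#'   female: `n_raw`, `n_below`, `n_above`, `n_kept`, `flagged` -- `TRUE`
#'   when sub-`min_d` detections were present).
#' @examples
#' wm <- tibble::tibble(female_id = "F1", diameter_um = c(90, 150, 400))
#' clean_wholemount(wm)$report
#' @export
clean_wholemount <- function(wholemount, min_d = 100, max_d = 1100) {
  report <- wholemount |>
    dplyr::group_by(.data$female_id) |>
    dplyr::summarise(
      n_raw = dplyr::n(),
      n_below = sum(.data$diameter_um < min_d),
      n_above = sum(.data$diameter_um > max_d),
      n_kept = sum(.data$diameter_um >= min_d & .data$diameter_um <= max_d),
      flagged = .data$n_below > 0,
      .groups = "drop"
    )
  if (any(report$n_kept == 0)) {
    abort(paste0("no analysable oocytes for female ",
                 report$female_id[report$n_kept == 0][1]))
  }
  kept <- dplyr::filter(
    wholemount,
    .data$diameter_um >= min_d, .data$diameter_um <= max_d
  )
  list(data = kept, report = report)
}

#' Oocyte ratio from cleaned diameters
#'
#' The oocyte ratio OR is the count of previtellogenic oocytes divided by
#' the count of developing oocytes (cortical alveoli + vitellogenic +
#' final maturation), split purely on diameter in wholemount data:
#' `OR = #(d <= pvo_max) / #(d > pvo_max)`. When no developing oocytes are
#' present OR is `+Inf` by convention.
#'
#' @param wholemount Cleaned wholemount table (diameters within the analysis
#'   window; see [clean_wholemount()]).
#' @param pvo_max Maximum previtellogenic diameter, um (default 230, the
#'   PVO4c landmark).
#' @return Tibble `female_id, n_pvo, n_dev, or`.
#' @examples
#' wm <- tibble::tibble(
#'   female_id = "F1",
#'   diameter_um = c(rep(150, 10), rep(400, 5), rep(700, 5))
#' )
#' compute_or(wm) # OR = 10/10 = 1
#' @export
compute_or <- function(wholemount, pvo_max = 230) {
  if (!nrow(wholemount)) abort("empty wholemount input")
  wholemount |>
    dplyr::group_by(.data$female_id) |>
    dplyr::summarise(
      n_pvo = sum(.data$diameter_um <= pvo_max),
      n_dev = sum(.data$diameter_um > pvo_max),
      or = ifelse(.data$n_dev > 0, .data$n_pvo / .data$n_dev, Inf),
      .groups = "drop"
    )
}

#' Classify the oocyte ratio into a spawning-stage category
#'
#' Rule-based "stage of spawning" classes: ORC1 early-spawning (OR <= 1),
#' ORC2 mid-spawning (1 < OR <= 3), ORC3 late-spawning (3 < OR <= 15) and
#' ORC4 very late- or post-spawning (OR > 15, including the `+Inf`
#' all-previtellogenic case). ORC0 (prespawning) carries no OR range and is
#' assigned only via `prespawning_flag` metadata (e.g. females sampled
#' before the spawning season, in primary vitellogenesis); the flag is
#' authoritative and overrides OR.
#'
#' @param or Oocyte ratio(s) (`>= 0` or `Inf`).
#' @param prespawning_flag Logical, recycled; `TRUE` forces ORC0.
#' @return Integer vector of categories 0--4.
#' @examples
#' classify_orc(c(1, 1.01, 3, 3.01, 15, 15.01, Inf))
#' @export
classify_orc <- function(or, prespawning_flag = FALSE) {
  if (any(is.na(or))) abort("OR must not be missing")
  if (any(or < 0)) abort("OR must be non-negative")
  n <- max(length(or), length(prespawning_flag))
  or <- rep_len(or, n)
  prespawning_flag <- rep_len(prespawning_flag, n)
  out <- ifelse(or <= 1, 1L, ifelse(or <= 3, 2L, ifelse(or <= 15, 3L, 4L)))
  out[prespawning_flag] <- 0L
  out
}

#' Per-female spawning-stage table from raw wholemount data
#'
#' Composes [clean_wholemount()], [compute_or()] and [classify_orc()] with
#' the prespawning metadata from the females table.
#'
#' @inheritParams clean_wholemount
#' @inheritParams compute_or
#' @param females Females table providing `prespawning_flag`.
#' @return Tibble `female_id, n_pvo, n_dev, or, orc`.
#' @export
orc_table <- function(wholemount, females, pvo_max = 230,
                      min_d = 100, max_d = 1100) {
  cleaned <- clean_wholemount(wholemount, min_d = min_d, max_d = max_d)
  or_tbl <- compute_or(cleaned$data, pvo_max = pvo_max)
  joined <- dplyr::left_join(
    or_tbl,
    dplyr::select(females, "female_id", "prespawning_flag"),
    by = "female_id"
  )
  if (any(is.na(joined$prespawning_flag))) {
    abort(paste0("female ",
                 joined$female_id[is.na(joined$prespawning_flag)][1],
                 " missing from females table"))
  }
  joined |>
    dplyr::mutate(orc = classify_orc(.data$or, .data$prespawning_flag)) |>
    dplyr::select("female_id", "n_pvo", "n_dev", "or", "orc")
}

#' Smoothed oocyte size frequency distribution
#'
#' Gaussian kernel density of each female's diameters on a common grid over
#' the analysis window, renormalised to integrate to one over the grid.
#' Bandwidth defaults to Silverman's rule (`stats::bw.nrd0`).
#'
#' @param wholemount Cleaned wholemount table.
#' @param bandwidth Kernel bandwidth in um, or `NULL` for Silverman's rule.
#' @param grid_min,grid_max,n_grid Evaluation grid.
#' @return Tibble `female_id, diameter_um, density`.
#' @export
smoothed_osfd <- function(wholemount, bandwidth = NULL,
                          grid_min = 100, grid_max = 1100, n_grid = 512) {
  if (!is.null(bandwidth) && bandwidth <= 0) {
    abort("bandwidth must be positive")
  }
  wholemount |>
    dplyr::group_by(.data$female_id) |>
    dplyr::group_modify(function(df, key) {
      d <- df$diameter_um
      if (length(d) < 5) abort("need at least 5 diameters per female")
      bw <- bandwidth %||% stats::bw.nrd0(d)
      dens <- stats::density(d, bw = bw, from = grid_min, to = grid_max,
                             n = n_grid)
      step <- dens$x[2] - dens$x[1]
      area <- sum(dens$y) * step
      tibble::tibble(diameter_um = dens$x, density = dens$y / area)
    }) |>
    dplyr::ungroup()
}
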