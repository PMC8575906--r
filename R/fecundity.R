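#' Phase-specific fecundity measures per female
#'
#' Converts packing densities into counts and relative fecundities:
#' `NO = OPD * OW` (absolute number of phase-i oocytes in the ovary),
#' `RF = NO / W` (oocytes per gram of body weight) and
#' `RF_TL = 100 * NO / TL^b` (length-based analogue, b from the pooled
#' length--weight fit).
#'
#' @param opd_tbl Output of [opd_table()] (linear-scale `opd` column).
#' @param females Females table.
#' @param b Allometric exponent for `RF_TL` (default 3.13).
#' @return Tibble `female_id, phase, opd, no, rf, rf_tl`.
#' @export
fecundity_table <- function(opd_tbl, females, b = 3.13) {
  joined <- dplyr::left_join(
    opd_tbl,
    dplyr::select(females, "female_id", "total_length_cm",
                  "body_weight_g", "ovary_weight_g"),
    by = "female_id"
  )
  if (any(is.na(joined$body_weight_g))) {
    abort(paste0("female ", joined$female_id[is.na(joined$body_weight_g)][1],
                 " missing from females table"))
  }
  joined |>
    dplyr::mutate(
      no = .data$opd * .data$ovary_weight_g,
      rf = .data$no / .data$body_weight_g,
      rf_tl = 100 * .data$no / .data$total_length_cm^b
    ) |>
    dplyr::select("female_id", "phase", "opd", "no", "rf", "rf_tl")
}

#' Mean relative fecundity by phase, spawning stage and year
#'
#' Cell means with normal-approximation 95% confidence intervals
#' (mean +/- 1.96 SE). Cells with a single female get an undefined CI and
#' are flagged rather than bootstrapped.
#'
#' @param fecundity Output of [fecundity_table()].
#' @param orc Output of [orc_table()].
#' @param females Females table (provides `capture_date` for the year).
#' @param measure `"rf"` (per g body weight) or `"rf_tl"`.
#' @return Tibble `phase, orc, year, n, mean_rf, se, ci_lo, ci_hi,
#'   single_female` (logical flag for n = 1 cells).
#' @export
rf_by_orc <- function(fecundity, orc, females, measure = c("rf", "rf_tl")) {
  measure <- match.arg(measure)
  joined <- fecundity |>
    dplyr::inner_join(dplyr::select(orc, "female_id", "orc"),
                      by = "female_id") |>
    dplyr::left_join(
      dplyr::transmute(
        females, .data$female_id,
        year = as.integer(format(as.Date(.data$capture_date), "%Y"))
      ),
      by = "female_id"
    )
  if (!nrow(joined)) abort("empty join between fecundity and ORC tables")
  joined |>
    dplyr::group_by(.data$phase, .data$orc, .data$year) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_rf = mean(.data[[measure]]),
      se = ifelse(.data$n > 1, sd(.data[[measure]]) / sqrt(.data$n), NA_real_),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      ci_lo = .data$mean_rf - 1.96 * .data$se,
      ci_hi = .data$mean_rf + 1.96 * .data$se,
      single_female = .data$n == 1L
    )
}

#' De novo influx of a previtellogenic phase across spawning
#'
#' The depletion of a phase's relative fecundity over the spawning period,
#' measured as the prespawning (ORC0) cell mean minus the spent (ORC4) cell
#' mean. For a determinate spawner this difference is ~0; a clearly positive
#' influx for the final previtellogenic phase (PVO4c) is the quantitative
#' signature of de novo recruitment, i.e. indeterminate fecundity. A
#' negative estimate is reported with a warning, not clamped, so the
#' determinate case remains detectable. The standard error combines the two
#' cell SEs in quadrature.
#'
#' @param summary Output of [rf_by_orc()].
#' @param phase Phase whose depletion is quantified (default `"PVO4c"`).
#' @param year Optional year filter; by default each year with both cells is
#'   summarised.
#' @return Tibble `year, phase, rf_orc0, rf_orc4, influx, se, ci_lo, ci_hi`.
#' @export
denovo_influx <- function(summary, phase = "PVO4c", year = NULL) {
  cells <- summary |>
    dplyr::filter(.data$phase == !!phase, .data$orc %in% c(0L, 4L))
  if (!is.null(year)) cells <- dplyr::filter(cells, .data$year %in% !!year)
  wide <- cells |>
    dplyr::select("year", "orc", "mean_rf", "se") |>
    tidyr::pivot_wider(names_from = "orc", values_from = c("mean_rf", "se"))
  if (!all(c("mean_rf_0", "mean_rf_4") %in% names(wide))) {
    abort("cannot quantify influx: missing ORC0 or ORC4 cell")
  }
  wide <- dplyr::filter(wide, !is.na(.data$mean_rf_0), !is.na(.data$mean_rf_4))
  if (!nrow(wide)) {
    abort("cannot quantify influx: missing ORC0 or ORC4 cell")
  }
  out <- wide |>
    dplyr::transmute(
      year = .data$year, phase = !!phase,
      rf_orc0 = .data$mean_rf_0, rf_orc4 = .data$mean_rf_4,
      influx = .data$mean_rf_0 - .data$mean_rf_4,
      se = sqrt(.data$se_0^2 + .data$se_4^2),
      ci_lo = .data$influx - 1.96 * .data$se,
      ci_hi = .data$influx + 1.96 * .data$se
    )
  if (any(out$influx < 0)) {
    warn("negative influx estimate: consistent with determinate fecundity")
  }
  out
}

#' Prespawning aggregated relative fecundity baseline
#'
#' The ORC0 baseline feeding the batch-number calculus: the aggregated
#' relative fecundity over a phase range (default PVO4c--GVBD, the
#' recommended enumeration window). Both candidate aggregates are reported:
#' the mean over females of per-female phase sums (`mean_female_sum`, the
#' primary one) and the sum of per-phase means (`sum_phase_means`); the two
#' coincide for balanced data.
#'
#' @param fecundity Output of [fecundity_table()].
#' @param orc Output of [orc_table()].
#' @param females Females table (for the year).
#' @param phases Phase codes to aggregate.
#' @param at_orc Spawning-stage category of the baseline (default 0).
#' @return Tibble `year, orc, n, mean_female_sum, sum_phase_means`.
#' @export
orc0_baseline <- function(fecundity, orc, females,
                          phases = phase_range("PVO4c", "GVBD"),
                          at_orc = 0L) {
  joined <- fecundity |>
    dplyr::filter(.data$phase %in% phases) |>
    dplyr::inner_join(dplyr::select(orc, "female_id", "orc"),
                      by = "female_id") |>
    dplyr::filter(.data$orc == at_orc) |>
    dplyr::left_join(
      dplyr::transmute(
        females, .data$female_id,
        year = as.integer(format(as.Date(.data$capture_date), "%Y"))
      ),
      by = "female_id"
    )
  if (!nrow(joined)) {
    abort(paste0("no females at ORC", at_orc, " for the baseline"))
  }
  per_female <- joined |>
    dplyr::group_by(.data$year, .data$female_id) |>
    dplyr::summarise(rf_sum = sum(.data$rf), .groups = "drop")
  phase_means <- joined |>
    dplyr::group_by(.data$year, .data$phase) |>
    dplyr::summarise(m = mean(.data$rf), .groups = "drop") |>
    dplyr::group_by(.data$year) |>
    dplyr::summarise(sum_phase_means = sum(.data$m), .groups = "drop")
  per_female |>
    dplyr::group_by(.data$year) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_female_sum = mean(.data$rf_sum),
      .groups = "drop"
    ) |>
    dplyr::left_join(phase_means, by = "year") |>
    dplyr::mutate(orc = at_orc, .after = "year")
}

#' Total potential relative fecundity and number of batches
#'
#' The season's total potential relative fecundity is the prespawning
#' aggregated baseline plus the de novo influx; dividing by a batch
#' fecundity (eggs per gram body weight per batch) gives the number of
#' batches a typical female releases. The unrounded ratio is reported
#' alongside its nearest-integer rounding.
#'
#' @param rf_orc0_aggregate Prespawning aggregated relative fecundity
#'   (oocytes g^-1 body weight), e.g. `mean_female_sum` from
#'   [orc0_baseline()].
#' @param influx De novo influx (oocytes g^-1 body weight).
#' @param batch_fecundities One or more batch fecundities (oocytes g^-1
#'   body weight per batch).
#' @return Tibble `batch_fecundity, total_potential_rf, batches_exact,
#'   n_batches`.
#' @examples
#' total_potential_and_batches(528, 160, c(40, 30, 34))
#' @export
total_potential_and_batches <- function(rf_orc0_aggregate, influx,
                                        batch_fecundities = c(40, 30, 34)) {
  if (rf_orc0_aggregate < 0 || influx < 0) {
    abort("baseline and influx must be non-negative")
  }
  if (any(batch_fecundities <= 0)) abort("batch fecundity must be positive")
  total <- rf_orc0_aggregate + influx
  tibble::tibble(
    batch_fecundity = batch_fecundities,
    total_potential_rf = total,
    batches_exact = total / batch_fecundities,
    n_batches = as.integer(round(total / batch_fecundities))
  )
}

#' Sensitivity of aggregated fecundity to the lower diameter threshold
#'
#' Compares the aggregated relative fecundity under the historical lower
#' threshold (185 um, i.e. counting from PVO4a) against the revised one
#' (230 um, counting from PVO4c). Per female, RF is summed over
#' PVO4a--GVBD and over PVO4c--GVBD and the percent reduction
#' `100 * (1 - sum_c / sum_a)` computed; per-female reductions are then
#' averaged within year (paired design). Females whose PVO4c--GVBD sum is
#' zero (e.g. spent fish retaining only PVO4a) drop out of the pairing.
#'
#' @param fecundity Output of [fecundity_table()].
#' @param orc Output of [orc_table()].
#' @param females Females table (for the year).
#' @param lower_phase_a,lower_phase_b Lower phases of the two enumeration
#'   windows (defaults PVO4a and PVO4c).
#' @param upper_phase Common upper phase (default GVBD).
#' @param orcs Spawning-stage categories included (default 1--4, the active
#'   spawning period).
#' @return Tibble `year, n, mean_reduction_pct, n_dropped`.
#' @export
threshold_sensitivity <- function(fecundity, orc, females,
                                  lower_phase_a = "PVO4a",
                                  lower_phase_b = "PVO4c",
                                  upper_phase = "GVBD",
                                  orcs = 1:4) {
  ph_a <- phase_range(lower_phase_a, upper_phase)
  ph_b <- phase_range(lower_phase_b, upper_phase)
  joined <- fecundity |>
    dplyr::inner_join(dplyr::select(orc, "female_id", "orc"),
                      by = "female_id") |>
    dplyr::filter(.data$orc %in% orcs) |>
    dplyr::left_join(
      dplyr::transmute(
        females, .data$female_id,
        year = as.integer(format(as.Date(.data$capture_date), "%Y"))
      ),
      by = "female_id"
    )
  per_female <- joined |>
    dplyr::group_by(.data$year, .data$female_id) |>
    dplyr::summarise(
      sum_a = sum(.data$rf[.data$phase %in% ph_a]),
      sum_b = sum(.data$rf[.data$phase %in% ph_b]),
      .groups = "drop"
    )
  dropped <- per_female |>
    dplyr::filter(.data$sum_b == 0, .data$sum_a > 0)
  paired <- per_female |>
    dplyr::filter(.data$sum_a > 0, .data$sum_b > 0) |>
    dplyr::mutate(reduction_pct = 100 * (1 - .data$sum_b / .data$sum_a))
  if (!nrow(paired)) abort("no paired females for the threshold comparison")
  paired |>
    dplyr::group_by(.data$year) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_reduction_pct = mean(.data$reduction_pct),
      .groups = "drop"
    ) |>
    dplyr::left_join(
      dplyr::count(dropped, .data$year, name = "n_dropped"),
      by = "year"
    ) |>
    dplyr::mutate(n_dropped = dplyr::coalesce(.data$n_dropped, 0L))
}

#' Standard-individual aggregated relative fecundity per spawning stage
#'
#' For each spawning-stage category (and year), sums the grand mean of
#' phase-specific relative fecundities over a phase range -- the fecundity
#' profile of a "standard individual". Per-phase contributions are retained
#' for stacked reporting; they sum exactly to the total.
#'
#' @param summary Output of [rf_by_orc()].
#' @param phases Phase codes to include (default PVO4c--GVBD).
#' @return Tibble `year, orc, phase, contribution_rf, total_rf` (the total
#'   is repeated across the phase rows of a cell).
#' @export
standard_individual <- function(summary,
                                phases = phase_range("PVO4c", "GVBD")) {
  out <- summary |>
    dplyr::filter(.data$phase %in% phases) |>
    dplyr::group_by(.data$year, .data$orc) |>
    dplyr::mutate(total_rf = sum(.data$mean_rf)) |>
    dplyr::ungroup() |>
    dplyr::select("year", "orc", "phase",
                  contribution_rf = "mean_rf", "total_rf")
  out
}

#' Prevalence and mean volume fraction of ovarian structures
#'
#' Share of females in which a structure (postovulatory follicles, atresia)
#' is present on the section, and the group mean volume fraction (over all
#' females in the group, including zeros).
#'
#' @param fractions Structure volume fractions, e.g. [structure_fractions()]
#'   output (`female_id, structure, v_v`).
#' @param groups Data frame mapping `female_id` to a grouping column.
#' @param group_col Name of the grouping column in `groups` (e.g. `"orc"` or
#'   a month label).
#' @return Tibble `structure, <group_col>, n, prevalence_pct, mean_v_v`.
#' @export
structure_prevalence <- function(fractions, groups, group_col = "orc") {
  joined <- dplyr::inner_join(
    fractions,
    dplyr::select(groups, "female_id", dplyr::all_of(group_col)),
    by = "female_id"
  )
  if (!nrow(joined)) {
    warn("empty group join: no structure prevalence computed")
    return(tibble::tibble())
  }
  joined |>
    dplyr::group_by(.data$structure, .data[[group_col]]) |>
    dplyr::summarise(
      n = dplyr::n(),
      prevalence_pct = 100 * mean(.data$v_v > 0),
      mean_v_v = mean(.data$v_v),
      .groups = "drop"
    )
}
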