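#' Unit-conversion constant of the packing-density equation
#'
#' The packing-density equation counts spheroids measured in micrometres
#' inside ovary tissue whose specific gravity is expressed in g cm^-3. The
#' unit bridge is the constant `log10((6/pi) * 1e12)`: `6/pi` inverts the
#' sphere-volume factor `pi/6`, and `1e12` converts um^3 to cm^3. Published
#' applications print this constant rounded to 12.28; `"printed"` mode uses
#' that rounded value for exact reproduction of published densities,
#' `"exact"` mode uses the analytic value (12.28101...). The two differ by a
#' constant multiplicative factor of about 0.23% on the linear scale.
#'
#' @param mode `"printed"` (12.28) or `"exact"` (`log10((6/pi) * 1e12)`).
#' @return The constant, in log10 units.
#' @examples
#' opd_constant("exact")
#' round(opd_constant("exact"), 2) # 12.28
#' @export
opd_constant <- function(mode = c("printed", "exact")) {
  mode <- match.arg(mode)
  if (mode == "printed") 12.28 else log10((6 / pi) * 1e12)
}

#' Oocyte shape factor from section axes
#'
#' Ratio of the long to the short axis of a through-the-nucleus oocyte
#' profile, `k = L/S`. A sphere gives `k = 1`; prolate profiles give `k > 1`.
#'
#' @param long_axis_um,short_axis_um Axis lengths in micrometres. Vectorised.
#' @return Numeric vector of shape factors (`>= 1`).
#' @examples
#' shape_factor(300, 200) # 1.5
#' @export
shape_factor <- function(long_axis_um, short_axis_um) {
  if (any(short_axis_um <= 0)) abort("short axis must be > 0")
  if (any(long_axis_um < short_axis_um)) {
    abort("long axis < short axis: axes swapped upstream is a data error")
  }
  long_axis_um / short_axis_um
}

#' Volume-based mean oocyte diameter
#'
#' Cubic-mean diameter `(mean(OD^3))^(1/3)` over the measured oocytes of one
#' phase. Cubing before averaging weights each oocyte by its volume, which is
#' the relevant mean when converting a volume fraction into a count; by the
#' power-mean inequality it is never below the arithmetic mean.
#'
#' @param diameters_um Per-oocyte diameters in micrometres, typically
#'   `(L + S) / 2` from axis measurements.
#' @return Volume-based mean diameter (um).
#' @examples
#' volume_based_diameter(c(100, 200)) # (4.5e6)^(1/3) ~ 165.1
#' @export
volume_based_diameter <- function(diameters_um) {
  if (!length(diameters_um)) abort("no measurements for phase")
  if (any(diameters_um <= 0)) abort("diameters must be > 0")
  mean(diameters_um^3)^(1 / 3)
}

#' Correct histology diameters for processing shrinkage
#'
#' Dehydration and resin embedding shrink oocytes relative to their
#' formalin-preserved size; all downstream diameters are expressed on the
#' formalin scale, so histology measurements are multiplied by a linear
#' correction factor. The default 1.11 corresponds to roughly 10% linear
#' shrinkage, typical for resin histology; it is a configurable stand-in, as
#' the appropriate factor depends on the laboratory protocol, and should be
#' overridden whenever a protocol-specific calibration exists.
#'
#' @param diameter_um Histology-scale diameter(s), um.
#' @param correction_factor Multiplicative linear factor (> 0).
#' @return Formalin-scale diameter(s), um.
#' @examples
#' shrinkage_correct(200, 1.11) # 222
#' @export
shrinkage_correct <- function(diameter_um, correction_factor = 1.11) {
  if (!is.numeric(correction_factor) || length(correction_factor) != 1 ||
      correction_factor <= 0) {
    abort("shrinkage correction factor must be a single positive number")
  }
  diameter_um * correction_factor
}

#' Ovary specific gravity by maturity stage
#'
#' Calibrated by submersion of whole ovaries: maturing females (stages 3-5)
#' have a specific gravity of 1.020 g cm^-3 and spawning, spent and
#' resting/recovering females (stages 6-8) 1.047 g cm^-3. Juvenile stages
#' (1-2) have no measurable ovary and raise an error.
#'
#' @param maturity_stage Integer stage(s) on the 8-point scale.
#' @return Specific gravity in g cm^-3.
#' @examples
#' specific_gravity_for_stage(4) # 1.020
#' specific_gravity_for_stage(7) # 1.047
#' @export
specific_gravity_for_stage <- function(maturity_stage) {
  if (any(!maturity_stage %in% 1:8)) {
    abort("maturity stage must be in 1..8")
  }
  if (any(maturity_stage %in% 1:2)) {
    abort("no specific gravity defined for juveniles (stages 1-2)")
  }
  ifelse(maturity_stage <= 5, 1.020, 1.047)
}

#' Ovary specific gravity from a submersion measurement
#'
#' Direct density from ovary weight and displaced volume (whole-ovary
#' submersion in saline).
#'
#' @param ovary_weight_g Weight in g.
#' @param ovary_volume_cm3 Displaced volume in cm^3.
#' @return Specific gravity, g cm^-3.
#' @examples
#' specific_gravity_from_submersion(10.47, 10.0) # 1.047
#' @export
specific_gravity_from_submersion <- function(ovary_weight_g, ovary_volume_cm3) {
  if (any(ovary_volume_cm3 <= 0)) abort("ovary volume must be > 0")
  if (any(ovary_weight_g <= 0)) abort("ovary weight must be > 0")
  ovary_weight_g / ovary_volume_cm3
}

#' Delesse volume fractions from grid counts
#'
#' By the Delesse principle the areal fraction of a structure on a random
#' section equals its volume fraction, so point-grid hit shares estimate
#' volume fractions directly: `V_V(s) = hits(s) / sum(hits)`.
#'
#' @param hits A histology hits table (`female_id`, `structure`, `hits`, and
#'   optionally `total_points`).
#' @return Tibble `female_id, structure, v_v`; fractions sum to 1 within each
#'   female.
#' @examples
#' h <- tibble::tibble(
#'   female_id = "F1",
#'   structure = c("PVO2", "VO1", "OTHERS"),
#'   hits = c(100L, 150L, 250L), total_points = 500L
#' )
#' delesse_volume_fractions(h)
#' @export
delesse_volume_fractions <- function(hits) {
  totals <- dplyr::summarise(
    dplyr::group_by(hits, .data$female_id),
    total = sum(.data$hits), .groups = "drop"
  )
  if (any(totals$total <= 0)) {
    abort(paste0("empty grid count for female ",
                 totals$female_id[totals$total <= 0][1]))
  }
  hits |>
    dplyr::group_by(.data$female_id) |>
    dplyr::mutate(v_v = .data$hits / sum(.data$hits)) |>
    dplyr::ungroup() |>
    dplyr::select("female_id", "structure", "v_v")
}

#' Oocyte packing density from stereological quantities
#'
#' Converts a volume fraction into a number of oocytes per gram of ovary.
#' Oocytes are modelled as prolate spheroids with axes (L, S, S); writing
#' `OD = (L + S)/2` and `k = L/S`, a single oocyte occupies
#' `(pi/6) * 8k/(1+k)^3 * OD^3` um^3, so the count per gram is
#'
#' \deqn{OPD = V_V \times \frac{1}{\rho_o} \times \frac{(1+k)^3}{8k}
#'   \times \frac{6}{\pi} \times 10^{12} \times cOD_v^{-3}}
#'
#' computed on the log10 scale as
#' `log10(V_V * (1/rho) * (1+k)^3/(8k)) + C - 3*log10(cOD_v)` with `C` from
#' [opd_constant()]. For a sphere (`k = 1`) the shape term `(1+k)^3/(8k)`
#' is exactly 1.
#'
#' @param v_v Volume fraction in `[0, 1]`. Zero fractions yield a density of
#'   0 (with a `-Inf` log density), so spent ovaries process cleanly.
#' @param rho_o Ovary specific gravity, g cm^-3.
#' @param k Mean shape factor (`>= 1`).
#' @param cod_v_um Shrinkage-corrected volume-based mean diameter, um
#'   (formalin scale).
#' @param constant_mode Passed to [opd_constant()].
#' @return Tibble with `opd_log10` (log10 oocytes g^-1) and `opd`
#'   (oocytes g^-1). Vectorised over all numeric arguments.
#' @examples
#' opd(0.5, 1.047, 1, 1000, constant_mode = "exact") # ~912 oocytes per g
#' @export
opd <- function(v_v, rho_o, k, cod_v_um,
                constant_mode = c("printed", "exact")) {
  constant_mode <- match.arg(constant_mode)
  if (any(v_v < 0 | v_v > 1)) abort("volume fraction must lie in [0, 1]")
  if (any(k < 1)) abort("shape factor must be >= 1")
  if (any(cod_v_um <= 0)) abort("volume-based diameter must be > 0")
  if (any(rho_o <= 0)) abort("specific gravity must be > 0")
  cc <- opd_constant(constant_mode)
  n <- max(length(v_v), length(rho_o), length(k), length(cod_v_um))
  v_v <- rep_len(v_v, n); rho_o <- rep_len(rho_o, n)
  k <- rep_len(k, n); cod_v_um <- rep_len(cod_v_um, n)
  shape_term <- (1 + k)^3 / (8 * k)
  lg <- ifelse(
    v_v == 0, -Inf,
    log10(v_v * (1 / rho_o) * shape_term) + cc - 3 * log10(cod_v_um)
  )
  tibble::tibble(opd_log10 = lg, opd = ifelse(v_v == 0, 0, 10^lg))
}

#' Per-female, per-phase packing density table
#'
#' Composes the stereological steps for every packing-density phase (PVO2
#' through GVBD): Delesse volume fractions from grid hits, mean shape factor
#' and volume-based diameter from axis measurements, shrinkage correction,
#' stage-based specific gravity, and the packing-density equation. PVO1 and
#' HYD are excluded by design (too few hits, and irregular post-dehydration
#' shape, respectively); structure annotations (atresia, POFs, OTHERS) retain
#' a volume fraction but no density -- see [delesse_volume_fractions()].
#'
#' Phases with grid hits but no axis measurements raise an error naming the
#' phase and female; phases with zero hits get a density of zero.
#'
#' @param hits Histology hits table.
#' @param axes Histology axes table (histology-scale um).
#' @param females Females table (provides `maturity_stage` for the specific
#'   gravity).
#' @param shrinkage_factor Linear shrinkage correction (see
#'   [shrinkage_correct()]).
#' @param constant_mode Passed to [opd_constant()].
#' @return Tibble `female_id, phase, v_v, k_mean, cod_v_um, rho_o,
#'   opd_log10, opd` with one row per female and packing-density phase.
#' @export
opd_table <- function(hits, axes, females,
                      shrinkage_factor = 1.11,
                      constant_mode = c("printed", "exact")) {
  constant_mode <- match.arg(constant_mode)
  vv <- delesse_volume_fractions(hits)
  phases <- oocyte_phases(opd_only = TRUE)

  axis_summ <- axes |>
    dplyr::filter(.data$phase %in% phases) |>
    dplyr::group_by(.data$female_id, .data$phase) |>
    dplyr::summarise(
      k_mean = mean(shape_factor(.data$long_axis_um, .data$short_axis_um)),
      od_v_hist = volume_based_diameter(
        (.data$long_axis_um + .data$short_axis_um) / 2
      ),
      .groups = "drop"
    )

  grid <- tidyr::expand_grid(
    female_id = unique(hits$female_id),
    phase = phases
  )
  out <- grid |>
    dplyr::left_join(vv, by = c("female_id", "phase" = "structure")) |>
    dplyr::mutate(v_v = dplyr::coalesce(.data$v_v, 0)) |>
    dplyr::left_join(axis_summ, by = c("female_id", "phase")) |>
    dplyr::left_join(
      dplyr::select(females, "female_id", "maturity_stage"),
      by = "female_id"
    )
  if (any(is.na(out$maturity_stage))) {
    abort(paste0("female ", out$female_id[is.na(out$maturity_stage)][1],
                 " missing from females table"))
  }
  orphan <- out$v_v > 0 & is.na(out$od_v_hist)
  if (any(orphan)) {
    abort(paste0(
      "phase ", out$phase[orphan][1], " of female ",
      out$female_id[orphan][1],
      " has grid hits but no axis measurements"
    ))
  }
  out <- out |>
    dplyr::mutate(
      cod_v_um = shrinkage_correct(.data$od_v_hist, shrinkage_factor),
      rho_o = specific_gravity_for_stage(.data$maturity_stage)
    )
  dens <- opd(
    out$v_v, out$rho_o,
    ifelse(is.na(out$k_mean), 1, out$k_mean),
    ifelse(is.na(out$cod_v_um), 1, out$cod_v_um),
    constant_mode = constant_mode
  )
  out |>
    dplyr::mutate(
      opd_log10 = dens$opd_log10,
      opd = dens$opd,
      phase = factor(.data$phase, levels = phases)
    ) |>
    dplyr::select(
      "female_id", "phase", "v_v", "k_mean", "cod_v_um", "rho_o",
      "opd_log10", "opd"
    ) |>
    dplyr::arrange(.data$female_id, .data$phase)
}

#' Volume fractions of non-oocyte structures
#'
#' Convenience filter of [delesse_volume_fractions()] down to atresia,
#' postovulatory follicles and the OTHERS bucket, used for prevalence
#' summaries.
#'
#' @inheritParams delesse_volume_fractions
#' @param include_others Keep the OTHERS bucket.
#' @return Tibble `female_id, structure, v_v`.
#' @export
structure_fractions <- function(hits, include_others = FALSE) {
  keep <- structure_codes(include_others = include_others)
  vv <- delesse_volume_fractions(hits)
  grid <- tidyr::expand_grid(
    female_id = unique(hits$female_id), structure = keep
  )
  grid |>
    dplyr::left_join(vv, by = c("female_id", "structure")) |>
    dplyr::mutate(v_v = dplyr::coalesce(.data$v_v, 0))
}
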