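#' Validate an input table against its schema invariants
#'
#' Checks one of the four canonical input tables and returns a tibble of
#' violations instead of raising, so that all problems in a file can be
#' reported at once. An empty result means the table satisfies every
#' invariant.
#'
#' Invariants checked per table:
#' \describe{
#'   \item{females}{required columns present; `female_id` unique and
#'     non-missing; `total_length_cm > 0`; `body_weight_g > 0`;
#'     `0 <= ovary_weight_g < body_weight_g`; `maturity_stage` in 1--8;
#'     `capture_date` parseable.}
#'   \item{wholemount}{`diameter_um > 0`; `female_id` non-missing.}
#'   \item{histology_hits}{`hits` non-negative integers; known structure
#'     codes; per female, `sum(hits) <= total_points`; one `total_points`
#'     value per female.}
#'   \item{histology_axes}{known oocyte phase codes;
#'     `long_axis_um >= short_axis_um > 0`.}
#' }
#'
#' @param data A data frame.
#' @param type One of `"females"`, `"wholemount"`, `"histology_hits"`,
#'   `"histology_axes"`.
#' @return A tibble with columns `row` (first offending row, `NA` for
#'   table-level problems), `field` and `reason`; zero rows when valid.
#' @examples
#' f <- tibble::tibble(
#'   female_id = "F1", capture_date = as.Date("2019-05-10"),
#'   total_length_cm = 34, body_weight_g = 420, ovary_weight_g = 500,
#'   maturity_stage = 6, prespawning_flag = FALSE
#' )
#' validate_table(f, "females") # ovary heavier than the fish -> one violation
#' @export
validate_table <- function(data,
                           type = c("females", "wholemount",
                                    "histology_hits", "histology_axes")) {
  type <- match.arg(type)
  required <- switch(type,
    females = c("female_id", "capture_date", "total_length_cm",
                "body_weight_g", "ovary_weight_g", "maturity_stage",
                "prespawning_flag"),
    wholemount = c("female_id", "diameter_um"),
    histology_hits = c("female_id", "structure", "hits", "total_points"),
    histology_axes = c("female_id", "phase", "long_axis_um", "short_axis_um")
  )
  v <- list()
  add <- function(row, field, reason) {
    v[[length(v) + 1]] <<- tibble::tibble(
      row = as.integer(row), field = field, reason = reason
    )
  }
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols)) {
    for (col in missing_cols) add(NA, col, "required column missing")
    return(dplyr::bind_rows(v))
  }
  first_bad <- function(ok) which(!ok & !is.na(ok))[1]
  flag <- function(ok, field, reason) {
    if (any(!ok, na.rm = TRUE)) add(first_bad(ok), field, reason)
  }
  if (any(is.na(data$female_id)) ||
      any(!nzchar(as.character(data$female_id)), na.rm = TRUE)) {
    add(which(is.na(data$female_id) |
                !nzchar(as.character(data$female_id)))[1],
        "female_id", "missing or empty identifier")
  }

  if (type == "females") {
    if (anyDuplicated(data$female_id)) {
      add(anyDuplicated(data$female_id), "female_id", "duplicated identifier")
    }
    flag(data$total_length_cm > 0, "total_length_cm", "must be > 0 (cm)")
    flag(data$body_weight_g > 0, "body_weight_g", "must be > 0 (g)")
    flag(data$ovary_weight_g >= 0, "ovary_weight_g", "must be >= 0 (g)")
    flag(data$ovary_weight_g < data$body_weight_g, "ovary_weight_g",
         "ovary weight must be less than body weight")
    flag(data$maturity_stage %in% 1:8, "maturity_stage",
         "must be an integer maturity stage in 1..8")
    dates <- suppressWarnings(as.Date(data$capture_date))
    flag(!is.na(dates), "capture_date", "not an ISO-8601 date")
  } else if (type == "wholemount") {
    flag(data$diameter_um > 0, "diameter_um", "must be > 0 (um)")
  } else if (type == "histology_hits") {
    flag(data$hits >= 0, "hits", "must be >= 0")
    flag(data$hits == round(data$hits), "hits", "must be whole counts")
    known <- phase_codes()$code
    flag(data$structure %in% known, "structure",
         "unknown phase/structure code")
    per <- dplyr::summarise(
      dplyr::group_by(data, .data$female_id),
      total = sum(.data$hits),
      points = .data$total_points[1],
      consistent = dplyr::n_distinct(.data$total_points) == 1L,
      .groups = "drop"
    )
    if (any(!per$consistent)) {
      add(NA, "total_points", paste0(
        "inconsistent total_points within female ",
        per$female_id[!per$consistent][1]
      ))
    }
    over <- per$total > per$points
    if (any(over, na.rm = TRUE)) {
      add(NA, "hits", paste0(
        "sum of hits exceeds total grid points for female ",
        per$female_id[which(over)[1]]
      ))
    }
  } else { # histology_axes
    flag(data$phase %in% oocyte_phases(), "phase", "unknown oocyte phase code")
    flag(data$short_axis_um > 0, "short_axis_um", "must be > 0 (um)")
    flag(data$long_axis_um >= data$short_axis_um, "long_axis_um",
         "long axis must be >= short axis (axes swapped upstream?)")
  }
  if (!length(v)) {
    tibble::tibble(row = integer(), field = character(), reason = character())
  } else {
    dplyr::bind_rows(v)
  }
}

#' Stop on any schema violation
#'
#' Thin wrapper around [validate_table()] that raises a single error listing
#' every violation found, for use at pipeline entry points.
#'
#' @inheritParams validate_table
#' @param label Name used in the error message (defaults to `type`).
#' @return `data`, invisibly, when valid.
#' @export
assert_valid <- function(data, type, label = type) {
  viol <- validate_table(data, type)
  if (nrow(viol)) {
    msgs <- paste0(viol$field, ": ", viol$reason,
                   ifelse(is.na(viol$row), "", paste0(" (row ", viol$row, ")")))
    abort(c(paste0("invalid ", label, " table"), msgs))
  }
  invisible(data)
}
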