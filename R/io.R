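#' Read and write the canonical CSV tables
#'
#' Four plain-text CSV schemas carry all input data (header row mandatory,
#' UTF-8, "." decimal separator):
#'
#' * `females.csv`: `female_id, capture_date, total_length_cm, body_weight_g,
#'   ovary_weight_g, maturity_stage, prespawning_flag` -- one row per fish;
#'   ovary weight is formalin-preserved; maturity stage on the 8-point scale
#'   (1-2 juvenile, 3-5 maturing, 6 spawning, 7 spent, 8 resting).
#' * `wholemount.csv`: `female_id, image_no, diameter_um` -- one row per
#'   measured oocyte (formalin-preserved diameter).
#' * `histology_hits.csv`: `female_id, structure, hits, total_points,
#'   section_area_mm2` -- Weibel-grid point counts per annotated structure.
#' * `histology_axes.csv`: `female_id, phase, long_axis_um, short_axis_um` --
#'   axis measurements of through-the-nucleus-sectioned oocytes, at
#'   histology (post-dehydration) scale.
#'
#' @param path File path.
#' @param validate Raise on schema violations (default `TRUE`).
#' @return A tibble with typed columns.
#' @name ovodyn_io
NULL

#' @rdname ovodyn_io
#' @export
read_females <- function(path, validate = TRUE) {
  out <- readr::read_csv(path, col_types = readr::cols(
    female_id = readr::col_character(),
    capture_date = readr::col_date(),
    total_length_cm = readr::col_double(),
    body_weight_g = readr::col_double(),
    ovary_weight_g = readr::col_double(),
    maturity_stage = readr::col_integer(),
    prespawning_flag = readr::col_logical()
  ))
  if (validate) assert_valid(out, "females")
  out
}

#' @rdname ovodyn_io
#' @export
read_wholemount <- function(path, validate = TRUE) {
  out <- readr::read_csv(path, col_types = readr::cols(
    female_id = readr::col_character(),
    image_no = readr::col_integer(),
    diameter_um = readr::col_double()
  ))
  if (validate) assert_valid(out, "wholemount")
  out
}

#' @rdname ovodyn_io
#' @export
read_histology_hits <- function(path, validate = TRUE) {
  out <- readr::read_csv(path, col_types = readr::cols(
    female_id = readr::col_character(),
    structure = readr::col_character(),
    hits = readr::col_integer(),
    total_points = readr::col_integer(),
    section_area_mm2 = readr::col_double()
  ))
  if (validate) assert_valid(out, "histology_hits")
  out
}

#' @rdname ovodyn_io
#' @export
read_histology_axes <- function(path, validate = TRUE) {
  out <- readr::read_csv(path, col_types = readr::cols(
    female_id = readr::col_character(),
    phase = readr::col_character(),
    long_axis_um = readr::col_double(),
    short_axis_um = readr::col_double()
  ))
  if (validate) assert_valid(out, "histology_axes")
  out
}

#' @rdname ovodyn_io
#' @param data Tibble to write.
#' @export
write_ovodyn_csv <- function(data, path) {
  readr::write_csv(data, path)
  invisible(path)
}
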