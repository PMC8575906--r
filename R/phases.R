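#' Controlled vocabulary of oocyte phases and ovarian structures
#'
#' The classification scheme distinguishes 13 oocyte categories ordered by
#' development -- six previtellogenic phases (PVO1, PVO2, PVO3, PVO4a, PVO4b,
#' PVO4c), cortical alveoli (CA), three vitellogenic phases (VO1--VO3) and
#' three final-maturation phases (germinal vesicle migration GVM, germinal
#' vesicle breakdown GVBD, hydrating HYD) -- plus non-oocyte structure
#' annotations used on histological sections: previtellogenic atresia
#' (ATR_PVO), early and late alpha (vitellogenic) atresia, postovulatory
#' follicles (POF), and a catch-all OTHERS bucket (ovarian wall, stroma,
#' blood cells, follicle layers, beta atresia / late POFs).
#'
#' `opd_measurable` marks the phases for which a packing density is computed:
#' PVO2 through GVBD. PVO1 oocytes are too scarce on grid counts to
#' quantify, and hydrating oocytes are not measured because their shape is
#' irregular after histological dehydration.
#'
#' @return A tibble with columns `code`, `group` (`"PVO"`, `"CA_VO"`, `"FOM"`
#'   or `"STRUCTURE"`), `order` (developmental rank, `NA` for structures) and
#'   `opd_measurable` (logical).
#' @examples
#' phase_codes()
#' @export
phase_codes <- function() {
  tibble::tibble(
    code = c(
      "PVO1", "PVO2", "PVO3", "PVO4a", "PVO4b", "PVO4c",
      "CA", "VO1", "VO2", "VO3",
      "GVM", "GVBD", "HYD",
      "ATR_PVO", "ATR_EARLY_ALPHA", "ATR_LATE_ALPHA", "POF", "OTHERS"
    ),
    group = c(
      rep("PVO", 6), rep("CA_VO", 4), rep("FOM", 3), rep("STRUCTURE", 5)
    ),
    order = c(1:13, rep(NA_integer_, 5)),
    opd_measurable = c(FALSE, rep(TRUE, 11), FALSE, rep(FALSE, 5))
  )
}

#' Ordered oocyte phase levels
#'
#' @param opd_only If `TRUE`, restrict to the phases that receive a packing
#'   density (PVO2 through GVBD).
#' @return Character vector of phase codes in developmental order.
#' @examples
#' oocyte_phases()
#' oocyte_phases(opd_only = TRUE)
#' @export
oocyte_phases <- function(opd_only = FALSE) {
  ph <- phase_codes()
  ph <- ph[!is.na(ph$order), ]
  if (opd_only) ph <- ph[ph$opd_measurable, ]
  ph$code[order(ph$order)]
}

#' Structure annotation codes
#'
#' @param include_others Keep the catch-all `OTHERS` bucket.
#' @return Character vector of structure codes.
#' @export
structure_codes <- function(include_others = TRUE) {
  out <- phase_codes()
  out <- out$code[out$group == "STRUCTURE"]
  if (!include_others) out <- setdiff(out, "OTHERS")
  out
}

#' Phases spanning a developmental range
#'
#' Returns the contiguous run of packing-density phases from `from` to `to`
#' inclusive, in developmental order. Used for aggregated fecundity sums such
#' as PVO4c--GVBD (the recommended enumeration range) or PVO4a--GVBD (the
#' historical 185 um range).
#'
#' @param from,to Phase codes bounding the range.
#' @return Character vector of phase codes.
#' @examples
#' phase_range("PVO4c", "GVBD")
#' @export
phase_range <- function(from = "PVO4c", to = "GVBD") {
  lv <- oocyte_phases(opd_only = TRUE)
  i <- match(from, lv)
  j <- match(to, lv)
  if (is.na(i) || is.na(j) || i > j) {
    abort("`from` and `to` must be packing-density phases in developmental order.")
  }
  lv[i:j]
}
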