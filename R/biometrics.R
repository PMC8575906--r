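#' Allometric length--weight power fit
#'
#' Fits `W = a * TL^b` by ordinary least squares on the log10--log10 scale.
#' No back-transform bias correction is applied: downstream the fit is only
#' used as the denominator of the relative-condition ratio, which is
#' self-centring (median K_n ~ 1 over the fitting sample) under this
#' convention.
#'
#' @param data Data frame with the length and weight columns.
#' @param length_col,weight_col Column names (cm and g respectively).
#' @return An object of class `length_weight_fit` with elements `a`
#'   (g cm^-b), `b`, `b_ci95` (half-width of the slope's 95% t-interval),
#'   `r_squared`, `n` and the underlying `lm` fit.
#' @examples
#' d <- tibble::tibble(tl = seq(25, 45, length.out = 50),
#'                     w = 0.004 * seq(25, 45, length.out = 50)^3.13)
#' fit <- fit_length_weight(d, "tl", "w")
#' glance(fit) # b = 3.13, R^2 = 1
#' @export
fit_length_weight <- function(data, length_col = "total_length_cm",
                              weight_col = "body_weight_g") {
  tl <- data[[length_col]]
  w <- data[[weight_col]]
  keep <- is.finite(tl) & is.finite(w)
  tl <- tl[keep]; w <- w[keep]
  if (length(tl) < 3) abort("need at least 3 females for the power fit")
  if (any(tl <= 0) || any(w <= 0)) abort("lengths and weights must be > 0")
  if (diff(range(tl)) == 0) abort("degenerate fit: all lengths equal")
  fit <- lm(log10(w) ~ log10(tl))
  sm <- summary(fit)
  structure(
    list(
      a = 10^coef(fit)[[1]],
      b = coef(fit)[[2]],
      b_ci95 = qt(0.975, fit$df.residual) * sm$coefficients[2, 2],
      r_squared = sm$r.squared,
      n = length(tl),
      fit = fit
    ),
    class = "length_weight_fit"
  )
}

#' @export
print.length_weight_fit <- function(x, ...) {
  cat(sprintf(
    "Length-weight power fit: W = %.5f * TL^%.3f (b 95%% CI +/- %.3f, R2 = %.3f, n = %d)\n",
    x$a, x$b, x$b_ci95, x$r_squared, x$n
  ))
  invisible(x)
}

#' @rdname fit_length_weight
#' @param x A `length_weight_fit`.
#' @param ... Unused.
#' @export
tidy.length_weight_fit <- function(x, ...) {
  tibble::tibble(
    term = c("a", "b"),
    estimate = c(x$a, x$b),
    ci95_half_width = c(NA_real_, x$b_ci95)
  )
}

#' @rdname fit_length_weight
#' @export
glance.length_weight_fit <- function(x, ...) {
  tibble::tibble(a = x$a, b = x$b, b_ci95 = x$b_ci95,
                 r_squared = x$r_squared, n = x$n)
}

#' Relative condition factor
#'
#' `K_n = W_observed / W_expected` with the expected weight from the
#' population power fit, `a * TL^b`. Preferred over Fulton's K (which fixes
#' b = 3) whenever the allometric exponent deviates from 3.
#'
#' @param weight_g Observed body weight(s), g.
#' @param length_cm Total length(s), cm.
#' @param fit A [fit_length_weight()] object.
#' @return Numeric vector of K_n values (dimensionless).
#' @export
relative_condition <- function(weight_g, length_cm, fit) {
  stopifnot(inherits(fit, "length_weight_fit"))
  weight_g / (fit$a * length_cm^fit$b)
}

#' Length-based gonadosomatic index
#'
#' `GSI_TL = 1e4 * OW / TL^b` with b from the population length--weight fit
#' (default 3.13). Length-based rather than weight-based so that somatic
#' condition does not leak into the index.
#'
#' @param ovary_weight_g Formalin-preserved ovary weight(s), g.
#' @param length_cm Total length(s), cm.
#' @param b Allometric exponent.
#' @return Numeric vector of GSI_TL values.
#' @examples
#' gsi_tl(50, 35) # ~7.3
#' @export
gsi_tl <- function(ovary_weight_g, length_cm, b = 3.13) {
  if (any(length_cm <= 0)) abort("total length must be > 0 (cm)")
  if (any(ovary_weight_g < 0)) abort("ovary weight must be >= 0 (g)")
  1e4 * ovary_weight_g / length_cm^b
}

#' Condition and gonadosomatic indices per female
#'
#' Adds `k_n` and `gsi_tl` columns to a females table. When `fit` is `NULL`
#' the length--weight fit is computed from the table itself (pooled fit).
#'
#' @param females Females table.
#' @param fit Optional [fit_length_weight()] object.
#' @param b Exponent for GSI_TL; defaults to the fit's slope.
#' @return The females tibble with `k_n` and `gsi_tl` columns appended.
#' @export
biometrics_table <- function(females, fit = NULL, b = NULL) {
  fit <- fit %||% fit_length_weight(females)
  b <- b %||% fit$b
  females |>
    dplyr::mutate(
      k_n = relative_condition(.data$body_weight_g, .data$total_length_cm, fit),
      gsi_tl = gsi_tl(.data$ovary_weight_g, .data$total_length_cm, b = b)
    )
}
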