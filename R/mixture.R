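#' Fit a gamma/Gaussian mixture to oocyte diameters
#'
#' Models a wholemount diameter sample as a two-component mixture
#' `w * Gamma(shape, scale) + (1 - w) * Normal(mean, sd)`: the right-skewed
#' gamma component captures the previtellogenic mode and the Gaussian the
#' developing (cortical alveoli and beyond) mode. Parameters are estimated by
#' expectation--maximisation; the gamma M-step solves the weighted maximum
#' likelihood equations by Newton iteration on the shape parameter. The
#' log-likelihood is recorded at every iteration and asserted non-decreasing.
#'
#' The diameter threshold separating the two cell pools is the smallest
#' diameter between the two component modes at which the posterior
#' probability of the Gaussian component reaches 0.5 -- equivalently, where
#' the weighted component densities cross. Crossings outside the inter-mode
#' interval are ignored.
#'
#' Initialisation is deterministic: the sample is split at the empirical
#' density minimum inside `init_split_range`, and each side is initialised by
#' the method of moments, so fits are reproducible without randomness; the
#' `seed` argument is accepted for interface stability and reserved for
#' future stochastic restarts.
#'
#' @param diameters_um Numeric vector of cleaned diameters (um); at least 50
#'   values with at least 10 on each side of the initial split (a crude
#'   bimodality precondition).
#' @param init_split_range Interval (um) searched for the initial density
#'   minimum between the two modes.
#' @param tol Convergence tolerance on the log-likelihood increment.
#' @param max_iter Maximum EM iterations; non-convergence yields
#'   `converged = FALSE` with a warning rather than an error.
#' @param seed Unused at present (kept for interface stability).
#' @return An object of class `gg_mixture`: a list with `gamma_shape`,
#'   `gamma_scale`, `normal_mean`, `normal_sd`, `weight` (gamma mixing
#'   proportion), `threshold_um`, `log_likelihood`, `loglik_trace`,
#'   `n_iter`, `converged`, `n`.
#' @examples
#' set.seed(1)
#' d <- c(rgamma(700, 25, scale = 6), rnorm(300, 400, 60))
#' fit <- fit_gamma_gaussian_mixture(d)
#' tidy(fit)
#' @export
fit_gamma_gaussian_mixture <- function(diameters_um,
                                       init_split_range = c(150, 400),
                                       tol = 1e-6, max_iter = 500,
                                       seed = NULL) {
  d <- diameters_um[is.finite(diameters_um) & diameters_um > 0]
  n <- length(d)
  if (n < 50) abort("need at least 50 diameters to fit the mixture")

  # deterministic multi-start: the empirical density minimum inside
  # init_split_range plus fixed fallback split points; the run with the
  # best final log-likelihood wins
  dens <- stats::density(d, n = 512)
  in_range <- dens$x >= init_split_range[1] & dens$x <= init_split_range[2]
  if (!any(in_range)) abort("no data support inside init_split_range")
  split_min <- dens$x[in_range][which.min(dens$y[in_range])]
  candidates <- unique(c(
    split_min,
    seq(init_split_range[1], init_split_range[2], length.out = 5)
  ))
  candidates <- candidates[
    vapply(candidates,
           function(sp) sum(d <= sp) >= 10 && sum(d > sp) >= 10, logical(1))
  ]
  if (!length(candidates)) {
    abort("unimodal data: fewer than 10 points on one side of the initial split")
  }

  runs <- lapply(candidates, function(sp) {
    tryCatch(
      em_gamma_gaussian(d, sp, tol = tol, max_iter = max_iter),
      error = function(e) NULL
    )
  })
  runs <- runs[!vapply(runs, is.null, logical(1))]
  if (!length(runs)) abort("unimodal data: degenerate fit")
  best <- runs[[which.max(vapply(runs, function(r) r$log_likelihood,
                                 numeric(1)))]]
  if (!best$converged) {
    warn(paste0("EM did not converge in ", max_iter, " iterations"))
  }

  gamma_mode <- if (best$gamma_shape > 1) {
    (best$gamma_shape - 1) * best$gamma_scale
  } else {
    min(d)
  }
  threshold <- mixture_crossing(
    best$gamma_shape, best$gamma_scale, best$normal_mean, best$normal_sd,
    best$weight, lower = gamma_mode, upper = best$normal_mean
  )

  structure(
    c(best, list(threshold_um = threshold, n = n)),
    class = "gg_mixture"
  )
}

# One EM run from a given split point; method-of-moments initialisation on
# each side. Returns parameter list with the log-likelihood trace.
em_gamma_gaussian <- function(d, split, tol = 1e-6, max_iter = 500) {
  n <- length(d)
  lo <- d[d <= split]
  hi <- d[d > split]
  if (length(lo) < 10 || length(hi) < 10) {
    abort("unimodal data: fewer than 10 points on one side of the initial split")
  }
  shape <- mean(lo)^2 / max(var(lo), 1e-8)
  scale <- max(var(lo), 1e-8) / mean(lo)
  mu <- mean(hi)
  sg <- max(sd(hi), 1e-3)
  w <- length(lo) / n

  comp_ll <- function(shape, scale, mu, sg, w) {
    sum(log(w * dgamma(d, shape = shape, scale = scale) +
              (1 - w) * dnorm(d, mu, sg) + 1e-300))
  }

  ll <- comp_ll(shape, scale, mu, sg, w)
  trace <- ll
  converged <- FALSE
  iter <- 0L
  logd <- log(d)
  for (iter in seq_len(max_iter)) {
    # E-step
    fg <- w * dgamma(d, shape = shape, scale = scale)
    fn <- (1 - w) * dnorm(d, mu, sg)
    r <- fg / (fg + fn + 1e-300)

    # M-step
    w_new <- mean(r)
    if (w_new < 1e-3 || w_new > 1 - 1e-3) abort("unimodal data: degenerate fit")
    sw <- sum(r)
    m_g <- sum(r * d) / sw
    l_g <- sum(r * logd) / sw
    s <- log(m_g) - l_g # >= 0 by Jensen
    s <- max(s, 1e-10)
    a <- (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s) # standard init
    for (it in 1:25) { # Newton on log(a) - digamma(a) = s
      step <- (log(a) - digamma(a) - s) / (1 / a - trigamma(a))
      a_new <- a - step
      if (a_new <= 0) a_new <- a / 2
      if (abs(a_new - a) < 1e-10 * a) { a <- a_new; break }
      a <- a_new
    }
    shape <- a
    scale <- m_g / a
    s1 <- sum(1 - r)
    mu <- sum((1 - r) * d) / s1
    sg <- sqrt(sum((1 - r) * (d - mu)^2) / s1)
    sg <- max(sg, 1e-3)
    w <- w_new

    ll_new <- comp_ll(shape, scale, mu, sg, w)
    trace <- c(trace, ll_new)
    if (abs(ll_new - ll) < tol) {
      ll <- ll_new
      converged <- TRUE
      break
    }
    ll <- ll_new
  }
  list(
    gamma_shape = shape, gamma_scale = scale,
    normal_mean = mu, normal_sd = sg, weight = w,
    log_likelihood = ll, loglik_trace = trace,
    n_iter = iter, converged = converged
  )
}

# Smallest crossing of w*gamma and (1-w)*normal densities inside (lower, upper).
mixture_crossing <- function(shape, scale, mu, sg, w, lower, upper) {
  if (!is.finite(lower) || !is.finite(upper) || lower >= upper) return(NA_real_)
  f <- function(x) {
    w * dgamma(x, shape = shape, scale = scale) - (1 - w) * dnorm(x, mu, sg)
  }
  xs <- seq(lower, upper, length.out = 512)
  fx <- f(xs)
  sign_change <- which(fx[-length(fx)] > 0 & fx[-1] <= 0)
  if (!length(sign_change)) return(NA_real_)
  i <- sign_change[1]
  uniroot(f, c(xs[i], xs[i + 1]), tol = 1e-8)$root
}

#' @export
print.gg_mixture <- function(x, ...) {
  cat("Gamma/Gaussian diameter mixture (n =", x$n, ")\n")
  cat(sprintf("  gamma:  shape %.3f, scale %.3f (mode %.1f um)\n",
              x$gamma_shape, x$gamma_scale,
              max(0, (x$gamma_shape - 1)) * x$gamma_scale))
  cat(sprintf("  normal: mean %.1f um, sd %.1f um\n",
              x$normal_mean, x$normal_sd))
  cat(sprintf("  weight (gamma): %.3f\n", x$weight))
  cat(sprintf("  threshold: %.1f um  [%s, %d iterations]\n",
              x$threshold_um,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  invisible(x)
}

#' @rdname fit_gamma_gaussian_mixture
#' @param x A `gg_mixture` object.
#' @param ... Unused.
#' @export
tidy.gg_mixture <- function(x, ...) {
  tibble::tibble(
    term = c("gamma_shape", "gamma_scale", "normal_mean", "normal_sd",
             "weight", "threshold_um"),
    estimate = c(x$gamma_shape, x$gamma_scale, x$normal_mean, x$normal_sd,
                 x$weight, x$threshold_um)
  )
}

#' @rdname fit_gamma_gaussian_mixture
#' @export
glance.gg_mixture <- function(x, ...) {
  tibble::tibble(
    log_likelihood = x$log_likelihood,
    n_iter = x$n_iter,
    converged = x$converged,
    n = x$n
  )
}

#' Summarise per-female mixture thresholds
#'
#' Across-female mean of the fitted previtellogenic/developing diameter
#' thresholds with a t-distribution 95% confidence interval (the estimator
#' context in which a cohort-level threshold such as "192 um (187-196)" is
#' reported).
#'
#' @param fits A list of `gg_mixture` objects, or a numeric vector of
#'   thresholds. Non-converged fits and `NA` thresholds are dropped.
#' @return One-row tibble `n, mean_threshold_um, ci_lo, ci_hi`.
#' @examples
#' threshold_summary(c(190, 194)) # mean 192
#' @export
threshold_summary <- function(fits) {
  if (is.list(fits) && !is.data.frame(fits)) {
    fits <- fits[vapply(fits, function(f) isTRUE(f$converged), logical(1))]
    th <- vapply(fits, function(f) f$threshold_um, numeric(1))
  } else {
    th <- as.numeric(fits)
  }
  th <- th[is.finite(th)]
  n <- length(th)
  if (n < 2) abort("need at least 2 converged fits to summarise thresholds")
  m <- mean(th)
  half <- qt(0.975, n - 1) * sd(th) / sqrt(n)
  tibble::tibble(
    n = n, mean_threshold_um = m, ci_lo = m - half, ci_hi = m + half
  )
}
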