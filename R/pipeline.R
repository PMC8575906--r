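#' Run the full oocyte-recruitment analysis
#'
#' Orchestrates every stage on the four canonical tables: spawning-stage
#' classification from wholemount diameters, per-female mixture thresholds,
#' biometrics (length--weight fit, K_n, GSI_TL), stereological packing
#' densities, fecundity measures, the relative-fecundity-by-stage grid, the
#' de novo PVO4c influx, total potential fecundity and batch numbers, the
#' lower-threshold sensitivity comparison, the standard-individual profile
#' and structure prevalence. Warnings raised along the way (non-convergent
#' mixture fits, single-female cells, negative influx) are collected into
#' the report's caveats section.
#'
#' @param females,wholemount,hits,axes The four canonical input tables (see
#'   [read_females()] and friends).
#' @param pvo_max Previtellogenic/developing diameter split, um.
#' @param min_d,max_d Wholemount analysis window, um.
#' @param shrinkage_factor Histology shrinkage correction.
#' @param constant_mode Packing-density constant mode (see [opd_constant()]).
#' @param b Allometric exponent for GSI_TL and RF_TL; `NULL` uses the pooled
#'   length--weight fit's slope.
#' @param batch_fecundities Batch fecundities (oocytes g^-1 per batch) for
#'   the batch-number calculus.
#' @param fit_mixture Fit per-female gamma/Gaussian mixtures and summarise
#'   the diameter threshold.
#' @param n_mixture_females Maximum number of females used for the mixture
#'   threshold estimate.
#' @param mixture_max_d Upper diameter bound (um) for the mixture fit. The
#'   two-component model addresses the boundary between the previtellogenic
#'   and early-developing pools; late-vitellogenic and final-maturation
#'   modes violate its single-Gaussian upper component and are excluded.
#' @return A list of class `ovodyn_pipeline` with elements `orc`,
#'   `lw_fit`, `biometrics`, `opd`, `fecundity`, `rf_summary`, `baseline`,
#'   `influx`, `batches`, `sensitivity`, `standard_individual`,
#'   `structure_prevalence`, `threshold`, `mixture_fits`, `caveats` and
#'   `report` (a Markdown string).
#' @export
run_pipeline <- function(females, wholemount, hits, axes,
                         pvo_max = 230, min_d = 100, max_d = 1100,
                         shrinkage_factor = 1.11,
                         constant_mode = c("printed", "exact"),
                         b = NULL,
                         batch_fecundities = c(40, 30, 34),
                         fit_mixture = TRUE,
                         n_mixture_females = 28,
                         mixture_max_d = 500) {
  constant_mode <- match.arg(constant_mode)
  assert_valid(females, "females")
  assert_valid(wholemount, "wholemount")
  assert_valid(hits, "histology_hits")
  assert_valid(axes, "histology_axes")

  caveats <- character()
  note <- function(msg) caveats <<- c(caveats, msg)

  orc <- orc_table(wholemount, females, pvo_max = pvo_max,
                   min_d = min_d, max_d = max_d)

  lw_fit <- fit_length_weight(females)
  b_use <- b %||% lw_fit$b
  biom <- biometrics_table(females, fit = lw_fit, b = b_use)

  opd_tbl <- opd_table(hits, axes, females,
                       shrinkage_factor = shrinkage_factor,
                       constant_mode = constant_mode)
  fec <- fecundity_table(opd_tbl, females, b = b_use)
  rf_summary <- rf_by_orc(fec, orc, females)
  if (any(rf_summary$single_female)) {
    note("some phase x ORC x year cells contain a single female (no CI)")
  }

  influx <- withCallingHandlers(
    tryCatch(denovo_influx(rf_summary, phase = "PVO4c"),
             error = function(e) { note(conditionMessage(e)); NULL }),
    warning = function(w) { note(conditionMessage(w)); invokeRestart("muffleWarning") }
  )
  baseline <- tryCatch(
    orc0_baseline(fec, orc, females),
    error = function(e) { note(conditionMessage(e)); NULL }
  )
  batches <- NULL
  if (!is.null(influx) && !is.null(baseline)) {
    yr <- intersect(baseline$year, influx$year)
    if (length(yr)) {
      y <- yr[1]
      batches <- total_potential_and_batches(
        baseline$mean_female_sum[baseline$year == y],
        max(influx$influx[influx$year == y], 0),
        batch_fecundities
      )
      if (any(influx$influx[influx$year == y] < 0)) {
        note("negative influx clamped to 0 for the batch calculus only")
      }
    }
  }
  sensitivity <- tryCatch(
    threshold_sensitivity(fec, orc, females),
    error = function(e) { note(conditionMessage(e)); NULL }
  )
  std_ind <- standard_individual(rf_summary)
  prevalence <- structure_prevalence(
    structure_fractions(hits), orc, group_col = "orc"
  )

  threshold <- NULL
  mixture_fits <- list()
  if (fit_mixture) {
    cleaned <- clean_wholemount(wholemount, min_d = min_d, max_d = max_d)
    active <- orc$female_id[orc$orc %in% 1:2]
    use <- utils::head(active, n_mixture_females)
    for (fid in use) {
      d <- cleaned$data$diameter_um[cleaned$data$female_id == fid]
      d <- d[d <= mixture_max_d]
      fit <- withCallingHandlers(
        tryCatch(fit_gamma_gaussian_mixture(d), error = function(e) NULL),
        warning = function(w) invokeRestart("muffleWarning")
      )
      if (!is.null(fit)) mixture_fits[[fid]] <- fit
    }
    n_conv <- sum(vapply(mixture_fits, function(f) f$converged, logical(1)))
    if (n_conv >= 2) {
      threshold <- threshold_summary(mixture_fits)
    } else {
      note("fewer than 2 converged mixture fits: no threshold summary")
    }
    if (length(mixture_fits) < length(use)) {
      note(paste0(length(use) - length(mixture_fits),
                  " mixture fit(s) failed and were skipped"))
    }
  }

  out <- list(
    orc = orc, lw_fit = lw_fit, biometrics = biom, opd = opd_tbl,
    fecundity = fec, rf_summary = rf_summary, baseline = baseline,
    influx = influx, batches = batches, sensitivity = sensitivity,
    standard_individual = std_ind, structure_prevalence = prevalence,
    threshold = threshold, mixture_fits = mixture_fits,
    caveats = caveats
  )
  out$report <- pipeline_report(out)
  class(out) <- "ovodyn_pipeline"
  out
}

#' @export
print.ovodyn_pipeline <- function(x, ...) {
  cat(x$report)
  invisible(x)
}

# Markdown report assembled from computed tables only.
pipeline_report <- function(res) {
  fmt <- function(x, d = 1) formatC(x, format = "f", digits = d)
  lines <- c(
    "# Oocyte recruitment analysis report", "",
    paste0("Females analysed: ", nrow(res$biometrics),
           "; length-weight fit b = ", fmt(res$lw_fit$b, 3),
           " (95% CI +/- ", fmt(res$lw_fit$b_ci95, 3),
           "), R2 = ", fmt(res$lw_fit$r_squared, 3), "."), ""
  )
  orc_freq <- table(res$orc$orc)
  lines <- c(lines, "## Spawning-stage (ORC) frequencies", "",
             paste0("- ORC", names(orc_freq), ": ", as.integer(orc_freq),
                    " females"), "")
  if (!is.null(res$threshold)) {
    lines <- c(lines, "## Diameter threshold (gamma/Gaussian mixture)", "",
               paste0("Mean threshold ",
                      fmt(res$threshold$mean_threshold_um),
                      " um (95% CI ", fmt(res$threshold$ci_lo), "-",
                      fmt(res$threshold$ci_hi), " um, n = ",
                      res$threshold$n, " females)."), "")
  }
  if (!is.null(res$influx)) {
    lines <- c(lines, "## De novo PVO4c recruitment", "",
               paste0("- ", res$influx$year, ": influx ",
                      fmt(res$influx$influx), " oocytes g^-1 body weight ",
                      "(ORC0 ", fmt(res$influx$rf_orc0), " - ORC4 ",
                      fmt(res$influx$rf_orc4), "; 95% CI ",
                      fmt(res$influx$ci_lo), " to ",
                      fmt(res$influx$ci_hi), ")"), "")
  }
  if (!is.null(res$batches)) {
    lines <- c(lines, "## Total potential fecundity and batches", "",
               paste0("- total ", fmt(res$batches$total_potential_rf[1]),
                      " oocytes g^-1; batch fecundity ",
                      res$batches$batch_fecundity, " -> ~",
                      res$batches$n_batches, " batches (",
                      fmt(res$batches$batches_exact), ")"), "")
  }
  if (!is.null(res$sensitivity)) {
    lines <- c(lines, "## Lower-threshold sensitivity (PVO4a vs PVO4c window)",
               "",
               paste0("- ", res$sensitivity$year, ": mean reduction ",
                      fmt(res$sensitivity$mean_reduction_pct),
                      "% (n = ", res$sensitivity$n, ", dropped ",
                      res$sensitivity$n_dropped, ")"), "")
  }
  if (length(res$caveats)) {
    lines <- c(lines, "## Caveats", "", paste0("- ", unique(res$caveats)), "")
  }
  paste(lines, collapse = "\n")
}

#' Write all pipeline output tables to a directory
#'
#' @param results An `ovodyn_pipeline` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pipeline_outputs <- function(results, dir) {
  stopifnot(inherits(results, "ovodyn_pipeline"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tables <- list(
    orc = results$orc, biometrics = results$biometrics, opd = results$opd,
    fecundity = results$fecundity, rf_summary = results$rf_summary,
    structure_prevalence = results$structure_prevalence
  )
  for (nm in names(tables)) {
    if (!is.null(tables[[nm]])) {
      readr::write_csv(tables[[nm]], file.path(dir, paste0(nm, ".csv")))
    }
  }
  writeLines(results$report, file.path(dir, "report.md"))
  invisible(dir)
}
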