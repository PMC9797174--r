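# Linear response of chart statistics (UCL, mean, LCL) to the MLC
# machine-model parameters. Each sweep varies one parameter (dosimetric leaf
# gap or MLC transmission factor) over >= 3 levels while the other is held
# constant; charts are built per level and ordinary least squares is fit to
# the per-level statistics. Rates of change are reported per canonical step
# (0.1 cm of DLG, 0.01 of MLC-TF) and the mean line's zero crossing gives
# the parameter value at which the local calculation matches the reference.

canonical_step <- function(parameter) {
  switch(parameter, dlg_cm = 0.1, mlc_tf = 0.01,
         stop(sprintf("unknown parameter '%s'", parameter)))
}

#' Group annotated comparisons into a parameter sweep
#'
#' @param comparisons comparison table whose every row carries `dlg_cm` and
#'   `mlc_tf` annotations.
#' @param parameter swept parameter, `"dlg_cm"` or `"mlc_tf"`.
#' @return A `parameter_sweep`: `parameter`, ascending `levels`, `cohorts`
#'   (list of per-level comparison tables) and `held_constant` (the other
#'   parameter's fixed value).
#' @export
group_sweep <- function(comparisons, parameter = c("dlg_cm", "mlc_tf")) {
  parameter <- match.arg(parameter)
  other <- setdiff(c("dlg_cm", "mlc_tf"), parameter)
  stopifnot(all(c("case_id", "structure", "pct_diff") %in% names(comparisons)))
  if (!all(c("dlg_cm", "mlc_tf") %in% names(comparisons)) ||
      anyNA(comparisons$dlg_cm) || anyNA(comparisons$mlc_tf)) {
    stop("group_sweep: unannotated comparisons (dlg_cm/mlc_tf required on every row)")
  }
  if (length(unique(comparisons[[other]])) != 1) {
    stop(sprintf("group_sweep: confounded sweep ('%s' not held constant)", other))
  }
  levels <- sort(unique(comparisons[[parameter]]))
  if (length(levels) < 3) {
    stop(sprintf("group_sweep: %d level(s) of %s; >= 3 required",
                 length(levels), parameter))
  }
  cohorts <- lapply(levels, function(l) {
    comparisons[comparisons[[parameter]] == l, , drop = FALSE]
  })
  names(cohorts) <- as.character(levels)
  structure(list(parameter = parameter, levels = levels, cohorts = cohorts,
                 held_constant = comparisons[[other]][1]),
            class = "parameter_sweep")
}

#' @export
print.parameter_sweep <- function(x, ...) {
  cat(sprintf("<parameter_sweep> %s at %d levels (%s); other parameter fixed at %g\n",
              x$parameter, length(x$levels),
              paste(x$levels, collapse = ", "), x$held_constant))
  invisible(x)
}

#' Fit the linear response of chart statistics to a machine parameter
#'
#' For each sweep level, an individual control chart is estimated for the
#' structure from that level's cohort; ordinary least squares then regresses
#' each chart statistic (UCL, mean, LCL) on the parameter value across
#' levels. The rate of change per canonical step (0.1 cm DLG / 0.01 MLC-TF)
#' and the mean line's zero crossing are derived from the fits.
#'
#' @param sweep a `parameter_sweep` from [group_sweep].
#' @param structure structure name, present at every level.
#' @param estimator,min_points,max_iter chart settings per level (see
#'   [estimate_limits]).
#' @return A `sensitivity_fit`: `structure`, `parameter`, `step`,
#'   `level_stats` (per-level `level`, `mu`, `ucl`, `lcl`), `lines`
#'   (per-statistic `slope` %/unit, `intercept` %, `r_squared`,
#'   `rate_per_step` %/step), `zero_crossing` (parameter value where the
#'   fitted mean is 0 %; `NA` with `zero_defined = FALSE` when the mean
#'   slope is zero).
#' @export
fit_parameter_response <- function(sweep, structure,
                                   estimator = c("sd", "moving-range"),
                                   min_points = 20, max_iter = 10) {
  stopifnot(inherits(sweep, "parameter_sweep"))
  estimator <- match.arg(estimator)
  stats_rows <- lapply(seq_along(sweep$levels), function(i) {
    cohort <- sweep$cohorts[[i]]
    vals <- cohort$pct_diff[cohort$structure == structure]
    if (length(vals) == 0) {
      stop(sprintf("fit_parameter_response: structure '%s' absent at %s = %g",
                   structure, sweep$parameter, sweep$levels[i]))
    }
    ch <- tryCatch(
      estimate_limits(vals, estimator = estimator, min_points = min_points,
                      max_iter = max_iter, structure = structure),
      error = function(e) stop(sprintf(
        "fit_parameter_response: chart not establishable for '%s' at %s = %g: %s",
        structure, sweep$parameter, sweep$levels[i], conditionMessage(e))))
    data.frame(level = sweep$levels[i], mu = ch$mu, ucl = ch$ucl, lcl = ch$lcl)
  })
  level_stats <- do.call(rbind, stats_rows)
  step <- canonical_step(sweep$parameter)
  lines <- do.call(rbind, lapply(c("ucl", "mean", "lcl"), function(stat) {
    y <- switch(stat, ucl = level_stats$ucl, mean = level_stats$mu,
                lcl = level_stats$lcl)
    fit <- stats::lm(y ~ level, data = data.frame(level = level_stats$level, y = y))
    co <- stats::coef(fit)
    r2 <- summary(fit)$r.squared
    data.frame(statistic = stat, slope = unname(co[2]),
               intercept = unname(co[1]),
               r_squared = if (is.nan(r2)) 1 else r2,
               rate_per_step = unname(co[2]) * step,
               stringsAsFactors = FALSE)
  }))
  mean_line <- lines[lines$statistic == "mean", ]
  zero_defined <- mean_line$slope != 0
  zero_crossing <- if (zero_defined) -mean_line$intercept / mean_line$slope else NA_real_
  structure(list(structure = structure, parameter = sweep$parameter,
                 step = step, level_stats = level_stats, lines = lines,
                 zero_crossing = zero_crossing, zero_defined = zero_defined),
            class = "sensitivity_fit")
}

#' @export
print.sensitivity_fit <- function(x, ...) {
  cat(sprintf("<sensitivity_fit> %s vs %s (%d levels)\n",
              x$structure, x$parameter, nrow(x$level_stats)))
  for (i in seq_len(nrow(x$lines))) {
    cat(sprintf("  %-5s %+0.3f %% per %g (r2 %.3f)\n", x$lines$statistic[i],
                x$lines$rate_per_step[i], x$step, x$lines$r_squared[i]))
  }
  cat(if (x$zero_defined) sprintf("  zero crossing at %s = %.4g\n",
                                  x$parameter, x$zero_crossing)
      else "  zero crossing undefined (zero mean slope)\n")
  invisible(x)
}

default_physical_range <- function(parameter) {
  # plausible crossing interval; values outside it indicate a structure whose
  # small volume makes the fitted response unphysical
  switch(parameter, dlg_cm = c(0, 0.5), mlc_tf = c(0, 0.05))
}

#' Summarize zero crossings across structures with outlier exclusion
#'
#' Aggregates the per-structure zero crossings of one parameter and reports
#' mean and sample SD over all structures and over the retained (non-outlier)
#' set. Two exclusion rules are available: `"physical-range"` removes
#' crossings outside a plausible interval (default DLG (0, 0.5] cm, MLC-TF
#' (0, 0.05]); `"mad"` removes crossings farther than `k` (scaled) median
#' absolute deviations from the median. Fits with an undefined crossing are
#' always excluded, with reason `"undefined"`.
#'
#' @param fits list of `sensitivity_fit` objects for one parameter.
#' @param outlier_rule `"physical-range"` (default) or `"mad"`.
#' @param range interval for the physical-range rule; default per parameter.
#' @param k multiplier for the MAD rule (default 3).
#' @return A `sensitivity_summary`: `parameter`, `crossings` (per-structure
#'   `structure`, `zero_crossing`, `excluded`, `reason`), `mean_all`,
#'   `sd_all`, `mean_retained`, `sd_retained`, `rule`.
#' @export
summarize_zero_crossings <- function(fits,
                                     outlier_rule = c("physical-range", "mad"),
                                     range = NULL, k = 3) {
  outlier_rule <- match.arg(outlier_rule)
  stopifnot(length(fits) > 0,
            all(vapply(fits, inherits, TRUE, "sensitivity_fit")))
  parameter <- fits[[1]]$parameter
  if (!all(vapply(fits, `[[`, "", "parameter") == parameter)) {
    stop("summarize_zero_crossings: fits mix parameters")
  }
  df <- data.frame(
    structure = vapply(fits, `[[`, "", "structure"),
    zero_crossing = vapply(fits, `[[`, 0, "zero_crossing"),
    excluded = FALSE, reason = NA_character_, stringsAsFactors = FALSE)
  undef <- is.na(df$zero_crossing)
  df$excluded[undef] <- TRUE
  df$reason[undef] <- "undefined"
  if (sum(!undef) < 3) {
    stop("summarize_zero_crossings: fewer than 3 defined crossings")
  }
  x <- df$zero_crossing
  if (outlier_rule == "physical-range") {
    if (is.null(range)) range <- default_physical_range(parameter)
    out <- !undef & (x <= range[1] | x > range[2])
    df$excluded[out] <- TRUE
    df$reason[out] <- sprintf("outside (%g..%g]", range[1], range[2])
  } else {
    med <- stats::median(x[!undef])
    madv <- stats::mad(x[!undef])
    out <- !undef & abs(x - med) > k * madv
    df$excluded[out] <- TRUE
    df$reason[out] <- sprintf("beyond %g MAD from median", k)
  }
  if (all(df$excluded)) stop("summarize_zero_crossings: all crossings excluded")
  defined <- x[!undef]
  retained <- x[!df$excluded]
  structure(
    list(parameter = parameter, crossings = df,
         mean_all = mean(defined),
         sd_all = if (length(defined) > 1) stats::sd(defined) else 0,
         mean_retained = mean(retained),
         sd_retained = if (length(retained) > 1) stats::sd(retained) else 0,
         rule = outlier_rule),
    class = "sensitivity_summary")
}

#' @export
print.sensitivity_summary <- function(x, ...) {
  cat(sprintf("<sensitivity_summary> %s, %d structures (%d excluded, rule '%s')\n",
              x$parameter, nrow(x$crossings), sum(x$crossings$excluded), x$rule))
  cat(sprintf("  zero crossing, all:      %.4g +/- %.4g\n", x$mean_all, x$sd_all))
  cat(sprintf("  zero crossing, retained: %.4g +/- %.4g\n",
              x$mean_retained, x$sd_retained))
  invisible(x)
}

#' Rate-of-change table across structures
#'
#' One row per structure with the per-step rates of change of UCL, mean and
#' LCL — the layout conventionally used to report machine-parameter
#' sensitivity of chart statistics.
#'
#' @param fits list of `sensitivity_fit` objects for one parameter.
#' @return `data.frame`: `structure`, `parameter`, `step`, `rate_ucl`,
#'   `rate_mean`, `rate_lcl`, `r2_ucl`, `r2_mean`, `r2_lcl`,
#'   `zero_crossing`.
#' @export
rate_table <- function(fits) {
  stopifnot(length(fits) > 0)
  do.call(rbind, lapply(fits, function(f) {
    ln <- f$lines
    g <- function(stat, col) ln[[col]][ln$statistic == stat]
    data.frame(structure = f$structure, parameter = f$parameter, step = f$step,
               rate_ucl = g("ucl", "rate_per_step"),
               rate_mean = g("mean", "rate_per_step"),
               rate_lcl = g("lcl", "rate_per_step"),
               r2_ucl = g("ucl", "r_squared"),
               r2_mean = g("mean", "r_squared"),
               r2_lcl = g("lcl", "r_squared"),
               zero_crossing = f$zero_crossing,
               stringsAsFactors = FALSE)
  }))
}

#' Export sensitivity fits and crossing summary
#'
#' Writes `rates_<parameter>.csv` (the [rate_table]),
#' `crossings_<parameter>.csv` (per-structure crossings with exclusion
#' reasons plus the all/retained mean +/- SD) and, unless `plot = FALSE`,
#' one `response_<parameter>_<structure>.png` per fit showing the per-level
#' chart statistics and their fitted lines. CSV output is deterministic.
#'
#' @param fits list of `sensitivity_fit` objects for one parameter.
#' @param summary a `sensitivity_summary` for the same parameter.
#' @param dir output directory (created if needed).
#' @param plot write plots? (default TRUE)
#' @return Invisibly, the paths written.
#' @export
export_sensitivity <- function(fits, summary, dir, plot = TRUE) {
  stopifnot(inherits(summary, "sensitivity_summary"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  parameter <- summary$parameter
  paths <- character()
  rt <- rate_table(fits)
  p1 <- file.path(dir, sprintf("rates_%s.csv", parameter))
  utils::write.csv(rt, p1, row.names = FALSE, quote = FALSE)
  cr <- summary$crossings
  cr$mean_all <- summary$mean_all; cr$sd_all <- summary$sd_all
  cr$mean_retained <- summary$mean_retained; cr$sd_retained <- summary$sd_retained
  p2 <- file.path(dir, sprintf("crossings_%s.csv", parameter))
  utils::write.csv(cr, p2, row.names = FALSE, quote = FALSE)
  paths <- c(p1, p2)
  if (plot) {
    for (f in fits) {
      p <- plot_sensitivity(f)
      fn <- file.path(dir, sprintf("response_%s_%s.png", parameter,
                                   gsub("[^A-Za-z0-9_.-]", "_", f$structure)))
      grDevices::png(fn, width = 720, height = 480, type = "cairo")
      print(p)
      grDevices::dev.off()
      paths <- c(paths, fn)
    }
  }
  invisible(paths)
}

#' Plot one structure's chart-statistic response to a machine parameter
#'
#' @param fit a `sensitivity_fit`.
#' @return A ggplot object: per-level UCL/mean/LCL points with their
#'   least-squares lines (dotted).
#' @export
plot_sensitivity <- function(fit) {
  stopifnot(inherits(fit, "sensitivity_fit"))
  ls <- fit$level_stats
  long <- rbind(
    data.frame(level = ls$level, value = ls$ucl, statistic = "ucl"),
    data.frame(level = ls$level, value = ls$mu, statistic = "mean"),
    data.frame(level = ls$level, value = ls$lcl, statistic = "lcl"))
  ggplot2::ggplot(long, ggplot2::aes(x = level, y = value, colour = statistic)) +
    ggplot2::geom_point(shape = 3, size = 2.5) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linetype = "dotted", linewidth = 0.6) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::labs(title = sprintf("%s vs %s", fit$structure, fit$parameter),
                  x = fit$parameter, y = "percent mean-dose difference (%)") +
    ggplot2::theme_minimal()
}
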