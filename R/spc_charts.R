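# Individual (I-) control charts for per-structure percent mean-dose
# differences. Control limits are the classical 3-sigma limits
#   UCL = mu + 3*sigma,   LCL = mu - 3*sigma
# with mu and sigma estimated after removing observations that fall outside
# the limits; the removal is iterated to a fixed point so the rule is
# idempotent (each pass re-screens *all* observations against the previous
# pass's limits).

chart_sigma <- function(v, estimator) {
  if (length(v) < 2) return(0)
  switch(estimator,
         "sd" = stats::sd(v),
         "moving-range" = mean(abs(diff(v))) / 1.128)
}

#' Estimate individual-control-chart limits with iterative outlier exclusion
#'
#' Pass 0 computes the chart mean and standard deviation over all
#' observations and sets `UCL = mu + 3*sigma`, `LCL = mu - 3*sigma`. Each
#' subsequent pass recomputes mu and sigma over the observations lying inside
#' the previous pass's limits (values exactly on a limit count as inside),
#' until the retained set stops changing or `max_iter` re-estimation passes
#' have run. Setting `max_iter = 1` gives the single-pass variant.
#'
#' @param values ordered numeric series of percent differences (one value per
#'   case, in acquisition order). All values must be finite.
#' @param estimator `"sd"` (sample standard deviation, n-1 denominator;
#'   default) or `"moving-range"` (mean absolute successive difference
#'   divided by 1.128, the conventional individuals-chart estimate).
#' @param min_points minimum observations required, before and after
#'   exclusion (default 20).
#' @param max_iter maximum re-estimation passes (default 10).
#' @param case_ids optional case labels (default `"case_1"`, ...).
#' @param structure optional structure name carried on the chart.
#' @return An object of class `control_chart` with elements `mu`, `sigma`,
#'   `ucl`, `lcl`, `observations` (data.frame `case_id`, `value`),
#'   `excluded` (integer indices removed during estimation), `n_used`,
#'   `estimator`, `iterations` (re-estimation passes performed) and
#'   `converged`.
#' @examples
#' set.seed(1)
#' ch <- estimate_limits(c(rnorm(29), 50), min_points = 10)
#' ch$excluded   # the gross outlier
#' @export
estimate_limits <- function(values, estimator = c("sd", "moving-range"),
                            min_points = 20, max_iter = 10,
                            case_ids = NULL, structure = NA_character_) {
  estimator <- match.arg(estimator)
  values <- as.numeric(values)
  n <- length(values)
  if (anyNA(values) || any(!is.finite(values))) {
    stop("estimate_limits: all values must be finite")
  }
  if (n < min_points) {
    stop(sprintf("estimate_limits: %d observations < min_points (%d)",
                 n, min_points))
  }
  if (is.null(case_ids)) case_ids <- paste0("case_", seq_len(n))
  stopifnot(length(case_ids) == n)

  included <- rep(TRUE, n)
  iterations <- 0L
  converged <- FALSE
  repeat {
    v <- values[included]
    mu <- mean(v)
    sigma <- chart_sigma(v, estimator)
    ucl <- mu + 3 * sigma
    lcl <- mu - 3 * sigma
    new_included <- values >= lcl & values <= ucl
    if (identical(new_included, included)) { converged <- TRUE; break }
    if (iterations >= max_iter) break
    included <- new_included
    iterations <- iterations + 1L
  }
  if (sigma == 0 && n > 1) {
    warning("estimate_limits: zero-variance series; control limits collapse to the mean")
  }
  n_used <- sum(included)
  if (n_used < min_points) {
    stop(sprintf(
      "estimate_limits: chart not establishable (%d of %d points retained < min_points %d)",
      n_used, n, min_points))
  }
  structure(
    list(structure = structure,
         observations = data.frame(case_id = as.character(case_ids),
                                   value = values, stringsAsFactors = FALSE),
         mu = mu, sigma = sigma, ucl = ucl, lcl = lcl,
         excluded = which(!included), n_used = n_used,
         estimator = estimator, iterations = iterations,
         converged = converged),
    class = "control_chart")
}

#' @export
print.control_chart <- function(x, ...) {
  # human-readable statistics rounded to 2 decimals, as conventional in
  # published chart tables; full precision is kept on the object
  cat(sprintf("<control_chart>%s n = %d (%d excluded, %d pass(es))\n",
              if (is.na(x$structure)) "" else paste0(" ", x$structure),
              nrow(x$observations), length(x$excluded), x$iterations))
  cat(sprintf("  mean %.2f %%  sigma %.2f %%  limits (%.2f, %.2f) %%  [%s]\n",
              x$mu, x$sigma, x$lcl, x$ucl, x$estimator))
  invisible(x)
}

#' Build one control chart per structure from a comparison table
#'
#' @param comparisons comparison table (see [percent_difference]); rows are
#'   taken in order as the observation series of each structure.
#' @param estimator,min_points,max_iter passed to [estimate_limits].
#' @return Named list of `control_chart` objects (one per chartable
#'   structure), with attribute `"unchartable"` listing structures observed
#'   fewer than `min_points` times.
#' @export
build_charts <- function(comparisons, estimator = c("sd", "moving-range"),
                         min_points = 20, max_iter = 10) {
  estimator <- match.arg(estimator)
  stopifnot(all(c("case_id", "structure", "pct_diff") %in% names(comparisons)))
  charts <- list()
  unchartable <- character()
  for (s in unique(comparisons$structure)) {
    sub <- comparisons[comparisons$structure == s, , drop = FALSE]
    if (nrow(sub) < min_points) {
      unchartable <- c(unchartable, s)
      next
    }
    charts[[s]] <- estimate_limits(sub$pct_diff, estimator = estimator,
                                   min_points = min_points, max_iter = max_iter,
                                   case_ids = sub$case_id, structure = s)
  }
  if (length(unchartable)) {
    message(sprintf("build_charts: %d structure(s) below min_points (%d): %s",
                    length(unchartable), min_points,
                    paste(unchartable, collapse = ", ")))
  }
  attr(charts, "unchartable") <- unchartable
  charts
}

#' Chart summary table
#'
#' @param charts named list of `control_chart` objects (see [build_charts]).
#' @return `data.frame` with one row per chart: `structure`, `mu`, `sigma`,
#'   `lcl`, `ucl`, `n_used`, `iterations`.
#' @export
chart_summary <- function(charts) {
  stopifnot(length(charts) > 0)
  do.call(rbind, lapply(names(charts), function(s) {
    ch <- charts[[s]]
    data.frame(structure = s, mu = ch$mu, sigma = ch$sigma,
               lcl = ch$lcl, ucl = ch$ucl, n_used = ch$n_used,
               iterations = ch$iterations, stringsAsFactors = FALSE)
  }))
}

#' Evaluate a new case against established charts
#'
#' A structure is flagged iff its value lies strictly outside the chart's
#' `[LCL, UCL]` interval (a value exactly on a limit is in-control).
#' Structures without an established chart are skipped with a warning.
#'
#' @param charts named list of `control_chart` objects.
#' @param case one-case comparison table (columns `case_id`, `structure`,
#'   `pct_diff`).
#' @return `data.frame` of out-of-control reports: `structure`, `case_id`,
#'   `value_pct`, `violated` (`"above_ucl"` / `"below_lcl"`), `mu`, `lcl`,
#'   `ucl`. Zero rows when the case is in control.
#' @export
evaluate_case <- function(charts, case) {
  stopifnot(all(c("case_id", "structure", "pct_diff") %in% names(case)))
  if (length(unique(case$case_id)) > 1) {
    stop("evaluate_case: 'case' must contain a single case_id")
  }
  reports <- list()
  for (i in seq_len(nrow(case))) {
    s <- case$structure[i]
    ch <- charts[[s]]
    if (is.null(ch)) {
      warning(sprintf("evaluate_case: no chart for structure '%s'; skipped", s))
      next
    }
    v <- case$pct_diff[i]
    violated <- if (v > ch$ucl) "above_ucl" else if (v < ch$lcl) "below_lcl" else NA
    if (!is.na(violated)) {
      reports[[length(reports) + 1L]] <- data.frame(
        structure = s, case_id = case$case_id[i], value_pct = v,
        violated = violated, mu = ch$mu, lcl = ch$lcl, ucl = ch$ucl,
        stringsAsFactors = FALSE)
    }
  }
  if (length(reports) == 0) {
    return(data.frame(structure = character(), case_id = character(),
                      value_pct = numeric(), violated = character(),
                      mu = numeric(), lcl = numeric(), ucl = numeric(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, reports)
}

#' Export a control chart as CSV and plot
#'
#' Writes `<path>.csv` (columns `structure`, `case_index`, `case_id`,
#' `value_pct`, `status` with status `retained` or `excluded`) and, unless
#' `plot = FALSE`, `<path>.<format>` showing the observations, the chart mean
#' (solid line) and the control limits (dashed lines). The CSV is
#' byte-deterministic for a given chart.
#'
#' @param chart a `control_chart`.
#' @param path output path *without* extension.
#' @param plot write the plot file too? (default TRUE)
#' @param format plot format, `"png"` or `"svg"`.
#' @return Invisibly, the CSV path.
#' @export
export_chart <- function(chart, path, plot = TRUE, format = c("png", "svg")) {
  stopifnot(inherits(chart, "control_chart"))
  format <- match.arg(format)
  obs <- chart$observations
  df <- data.frame(structure = chart$structure,
                   case_index = seq_len(nrow(obs)),
                   case_id = obs$case_id,
                   value_pct = obs$value,
                   status = ifelse(seq_len(nrow(obs)) %in% chart$excluded,
                                   "excluded", "retained"),
                   stringsAsFactors = FALSE)
  csv <- paste0(path, ".csv")
  utils::write.csv(df, csv, row.names = FALSE, quote = FALSE)
  if (plot) {
    p <- plot_chart(chart)
    dev <- if (format == "png") grDevices::png else grDevices::svg
    args <- if (format == "png") {
      list(filename = paste0(path, ".png"), width = 720, height = 480,
           type = "cairo")
    } else {
      list(filename = paste0(path, ".svg"), width = 7.5, height = 5)
    }
    do.call(dev, args)
    print(p)
    grDevices::dev.off()
  }
  invisible(csv)
}

#' Plot a control chart
#'
#' Observations as points (excluded points hollow), the chart mean as a solid
#' line and the 3-sigma control limits as dashed lines.
#'
#' @param chart a `control_chart`.
#' @return A ggplot object.
#' @export
plot_chart <- function(chart) {
  stopifnot(inherits(chart, "control_chart"))
  obs <- chart$observations
  df <- data.frame(case_index = seq_len(nrow(obs)), value = obs$value,
                   status = ifelse(seq_len(nrow(obs)) %in% chart$excluded,
                                   "excluded", "retained"))
  ggplot2::ggplot(df, ggplot2::aes(x = case_index, y = value, shape = status)) +
    ggplot2::geom_hline(yintercept = chart$mu, colour = "darkgreen") +
    ggplot2::geom_hline(yintercept = c(chart$lcl, chart$ucl),
                        colour = "red", linetype = "dashed") +
    ggplot2::geom_point(colour = "steelblue", size = 2) +
    ggplot2::scale_shape_manual(values = c(retained = 16, excluded = 1),
                                drop = FALSE) +
    ggplot2::labs(title = if (is.na(chart$structure)) "Individual control chart"
                  else chart$structure,
                  x = "case", y = "percent mean-dose difference (%)") +
    ggplot2::theme_minimal()
}
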