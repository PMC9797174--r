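# Seeded synthetic cohorts with the statistical structure the monitoring
# method assumes: per-structure systematic offsets with Gaussian (optionally
# heavy-tailed) case-to-case noise, linear dependence of the offset on one
# machine parameter, and deliberately injected outliers. Only the statistics
# of the percent differences are emulated, not the physics of dose
# calculation.

with_seed <- function(seed, expr) {
  # evaluate expr under a local RNG state so generators are pure functions of
  # their spec (seed included) and never disturb the caller's stream
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Specify a synthetic in-control cohort
#'
#' Each structure `s` has a systematic percent-difference offset `offset_pct`
#' and case-to-case noise `noise_pct`; case values are drawn
#' `Normal(offset, noise^2)` (or Student-t scaled to that SD when
#' `df` is finite). Outliers listed in `outliers` overwrite the sampled
#' value for one (case, structure) cell after sampling.
#'
#' @param structures `data.frame` with columns `name`, `offset_pct`,
#'   `noise_pct` (`noise_pct >= 0`).
#' @param n_cases number of cases (>= 1).
#' @param seed integer RNG seed.
#' @param outliers optional `data.frame` with columns `case` (index in
#'   `1:n_cases`), `structure`, `value_pct`.
#' @param params optional [machine_parameters] stamped on every case.
#' @param df degrees of freedom for heavy-tailed noise; `Inf` (default) gives
#'   Gaussian noise.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(structures, n_cases, seed, outliers = NULL,
                        params = NULL, df = Inf) {
  stopifnot(is.data.frame(structures),
            all(c("name", "offset_pct", "noise_pct") %in% names(structures)))
  if (anyDuplicated(structures$name)) stop("cohort_spec: duplicate structure name")
  if (any(structures$noise_pct < 0)) stop("cohort_spec: noise_pct must be >= 0")
  n_cases <- as.integer(n_cases)
  if (n_cases < 1) stop("cohort_spec: n_cases must be >= 1")
  if (!is.null(outliers)) {
    stopifnot(all(c("case", "structure", "value_pct") %in% names(outliers)))
    if (any(outliers$case < 1 | outliers$case > n_cases)) {
      stop("cohort_spec: outlier case index out of range")
    }
    if (!all(outliers$structure %in% structures$name)) {
      stop("cohort_spec: outlier names an unknown structure")
    }
  }
  if (!is.null(params)) stopifnot(inherits(params, "machine_parameters"))
  structure(list(structures = structures, n_cases = n_cases,
                 seed = as.integer(seed), outliers = outliers,
                 params = params, df = df),
            class = "cohort_spec")
}

#' Generate a synthetic cohort of percent mean-dose differences
#'
#' Deterministic in the spec: the same spec (seed included) always yields the
#' same table.
#'
#' @param spec a [cohort_spec].
#' @return A comparison table (`case_id`, `structure`, `pct_diff`, `dlg_cm`,
#'   `mlc_tf`, `algorithm`).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  st <- spec$structures
  vals <- with_seed(spec$seed, {
    sapply(seq_len(nrow(st)), function(i) {
      noise <- if (is.finite(spec$df)) {
        scale <- if (spec$df > 2) sqrt((spec$df - 2) / spec$df) else 1
        stats::rt(spec$n_cases, df = spec$df) * scale
      } else {
        stats::rnorm(spec$n_cases)
      }
      st$offset_pct[i] + st$noise_pct[i] * noise
    })
  })
  vals <- matrix(vals, nrow = spec$n_cases)
  if (!is.null(spec$outliers)) {
    for (r in seq_len(nrow(spec$outliers))) {
      j <- match(spec$outliers$structure[r], st$name)
      vals[spec$outliers$case[r], j] <- spec$outliers$value_pct[r]
    }
  }
  case_ids <- sprintf("case_%03d", seq_len(spec$n_cases))
  out <- new_comparison_table(
    case_id = rep(case_ids, each = nrow(st)),
    structure = rep(st$name, times = spec$n_cases),
    pct_diff = as.numeric(t(vals)),
    params = spec$params)
  rownames(out) <- NULL
  out
}

#' Specify a synthetic machine-parameter sweep
#'
#' Per structure, the expected percent difference responds linearly to the
#' swept parameter and vanishes at that structure's `crossing`:
#' `value ~ Normal(slope * (level - crossing), noise^2)`. Structures meant to
#' exercise outlier exclusion are simply given crossings outside the
#' physically plausible range.
#'
#' @param parameter `"dlg_cm"` or `"mlc_tf"`.
#' @param levels at least 3 distinct parameter values.
#' @param structures `data.frame` with columns `name`, `slope` (% per
#'   parameter unit), `crossing` (parameter value of 0 % response),
#'   `noise_pct`.
#' @param n_per_level cases per level.
#' @param seed integer RNG seed.
#' @param held_constant value of the non-swept parameter stamped on the
#'   annotations; defaults to the reference calculation's values (DLG 0.2 cm,
#'   MLC-TF 0.02).
#' @param algorithm annotation label (default "synthetic").
#' @return An object of class `sweep_spec`.
#' @export
sweep_spec <- function(parameter = c("dlg_cm", "mlc_tf"), levels, structures,
                       n_per_level, seed, held_constant = NULL,
                       algorithm = "synthetic") {
  parameter <- match.arg(parameter)
  levels <- sort(unique(as.numeric(levels)))
  if (length(levels) < 3) stop("sweep_spec: >= 3 distinct levels required")
  stopifnot(is.data.frame(structures),
            all(c("name", "slope", "crossing", "noise_pct") %in% names(structures)))
  if (any(!is.finite(structures$slope))) stop("sweep_spec: non-finite slope")
  if (any(structures$noise_pct < 0)) stop("sweep_spec: noise_pct must be >= 0")
  if (is.null(held_constant)) {
    held_constant <- if (parameter == "dlg_cm") 0.02 else 0.2
  }
  structure(list(parameter = parameter, levels = levels,
                 structures = structures, n_per_level = as.integer(n_per_level),
                 seed = as.integer(seed), held_constant = held_constant,
                 algorithm = algorithm),
            class = "sweep_spec")
}

#' Generate a synthetic annotated parameter sweep
#'
#' @param spec a [sweep_spec].
#' @return A comparison table annotated with `dlg_cm` and `mlc_tf` on every
#'   row, suitable for [group_sweep].
#' @export
generate_sweep <- function(spec) {
  stopifnot(inherits(spec, "sweep_spec"))
  st <- spec$structures
  rows <- with_seed(spec$seed, {
    out <- list()
    for (li in seq_along(spec$levels)) {
      level <- spec$levels[li]
      for (si in seq_len(nrow(st))) {
        mu <- st$slope[si] * (level - st$crossing[si])
        vals <- stats::rnorm(spec$n_per_level, mean = mu, sd = st$noise_pct[si])
        out[[length(out) + 1L]] <- data.frame(
          case_id = sprintf("L%02d_case_%03d", li, seq_len(spec$n_per_level)),
          structure = st$name[si], pct_diff = vals, level = level,
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, out)
  })
  df <- data.frame(case_id = rows$case_id, structure = rows$structure,
                   pct_diff = rows$pct_diff, stringsAsFactors = FALSE)
  if (spec$parameter == "dlg_cm") {
    df$dlg_cm <- rows$level; df$mlc_tf <- spec$held_constant
  } else {
    df$mlc_tf <- rows$level; df$dlg_cm <- spec$held_constant
  }
  df$algorithm <- spec$algorithm
  df[, comparison_cols]
}

#' Generate a paired dose-grid fixture with known percent differences
#'
#' Builds a reference grid following `dose_law` (constant, or linear in x),
#' a local grid obtained by `local = scale * reference + shift`, and a
#' structure set of axis-aligned rectangular structures contoured on every
#' grid plane they span. For a pure scale perturbation the percent mean-dose
#' difference of every structure is exactly `100 * (scale - 1)` %, giving a
#' closed-form expectation for pipeline tests.
#'
#' @param origin,spacing,shape grid geometry (see [dose_grid]).
#' @param boxes `data.frame` of rectangular structures: `name`, `x0`, `x1`,
#'   `y0`, `y1`, `z0`, `z1` (mm, patient coordinates).
#' @param dose_law `list(type = "constant", c = <Gy>)` or
#'   `list(type = "linear", g = <Gy/mm>, c = <Gy>)` (dose `g*x + c`).
#' @param scale,shift local-grid perturbation (`local = scale * ref + shift`,
#'   shift in Gy).
#' @param frame_id frame-of-reference label shared by both grids and the
#'   structure set.
#' @return `list(reference, local, structures)`.
#' @export
generate_grid_fixture <- function(origin, spacing, shape, boxes,
                                  dose_law = list(type = "constant", c = 2),
                                  scale = 1, shift = 0, frame_id = "FOR-1") {
  shape <- as.integer(shape)
  xs <- origin[1] + (seq_len(shape[1]) - 1) * spacing[1]
  vals_x <- switch(dose_law$type,
                   constant = rep(dose_law$c, shape[1]),
                   linear = dose_law$g * xs + dose_law$c,
                   stop("generate_grid_fixture: unknown dose_law type"))
  if (any(vals_x < 0)) stop("generate_grid_fixture: dose_law negative on grid")
  ref_vals <- array(rep(vals_x, times = shape[2] * shape[3]), dim = shape)
  reference <- dose_grid(origin, spacing, shape, ref_vals, frame_id)
  loc_vals <- scale * ref_vals + shift
  if (any(loc_vals < 0)) stop("generate_grid_fixture: perturbation yields negative dose")
  local <- dose_grid(origin, spacing, shape, loc_vals, frame_id)
  zs <- origin[3] + (seq_len(shape[3]) - 1) * spacing[3]
  structures <- lapply(seq_len(nrow(boxes)), function(i) {
    b <- boxes[i, ]
    planes <- zs[zs >= b$z0 & zs <= b$z1]
    if (length(planes) == 0) {
      stop(sprintf("generate_grid_fixture: structure '%s' spans no grid plane",
                   b$name))
    }
    rect <- matrix(c(b$x0, b$y0, b$x1, b$y0, b$x1, b$y1, b$x0, b$y1),
                   ncol = 2, byrow = TRUE)
    rt_structure(b$name, lapply(planes, function(z) list(z = z, vertices = rect)))
  })
  list(reference = reference, local = local,
       structures = structure_set(structures, frame_id))
}
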