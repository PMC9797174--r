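# ---- voxel masks ------------------------------------------------------------

#' @export
print.voxel_mask <- function(x, ...) {
  cat(sprintf("<voxel_mask> %d / %d voxels included\n",
              sum(x$included), length(x$included)))
  invisible(x)
}

points_in_polygons_evenodd <- function(px, py, polys) {
  # crossing-number parity summed over all polygons on the plane (even-odd
  # rule, so an inner polygon carves a hole out of an outer one)
  crossings <- integer(length(px))
  for (v in polys) {
    n <- nrow(v)
    x1 <- v[, 1]; y1 <- v[, 2]
    x2 <- v[c(2:n, 1), 1]; y2 <- v[c(2:n, 1), 2]
    for (e in seq_len(n)) {
      straddles <- (y1[e] > py) != (y2[e] > py)
      if (!any(straddles)) next
      xs <- x1[e] + (py[straddles] - y1[e]) / (y2[e] - y1[e]) * (x2[e] - x1[e])
      hit <- xs > px[straddles]
      idx <- which(straddles)[hit]
      crossings[idx] <- crossings[idx] + 1L
    }
  }
  crossings %% 2L == 1L
}

#' Rasterize a planar-contour structure onto a dose grid
#'
#' A voxel is included iff its center lies within half a slice spacing of the
#' structure's nearest contour plane and falls inside that plane's polygons
#' under the even-odd rule (so concentric contours produce rings/holes).
#' Voxel-center semantics match DICOM ImagePositionPatient conventions.
#'
#' @param structure an [rt_structure].
#' @param grid a [dose_grid].
#' @return A `voxel_mask` (logical array over the grid's voxels).
#' @export
rasterize_structure <- function(structure, grid) {
  stopifnot(inherits(structure, "rt_structure"), inherits(grid, "dose_grid"))
  zs <- axis_coords(grid, 3)
  xs <- axis_coords(grid, 1)
  ys <- axis_coords(grid, 2)
  plane_z <- vapply(structure$contours, `[[`, 0, "z")
  planes <- sort(unique(plane_z))
  included <- array(FALSE, dim = grid$shape)
  pts <- expand.grid(x = xs, y = ys)  # x varies fastest, matching array layout
  for (k in seq_along(zs)) {
    d <- abs(planes - zs[k])
    nearest <- which.min(d)
    if (d[nearest] > grid$spacing[3] / 2 + 1e-9) next
    polys <- lapply(structure$contours[plane_z == planes[nearest]],
                    `[[`, "vertices")
    inside <- points_in_polygons_evenodd(pts$x, pts$y, polys)
    if (any(inside)) included[, , k] <- inside
  }
  if (!any(included)) {
    stop(sprintf("rasterize_structure: empty mask for structure '%s'",
                 structure$name))
  }
  structure(list(shape = grid$shape, included = included), class = "voxel_mask")
}

# ---- resampling -------------------------------------------------------------

#' Resample a dose grid onto a target geometry by trilinear interpolation
#'
#' Target voxel centers falling outside the source grid's support receive
#' `NA`, which downstream mean-dose computation excludes. An identity target
#' geometry returns the values unchanged.
#'
#' @param grid source [dose_grid].
#' @param origin,spacing,shape target geometry (same conventions as
#'   [dose_grid]).
#' @return A list with the target geometry and interpolated `values` array
#'   (class `resampled_dose`); `NA` marks out-of-support voxels.
#' @export
resample_dose <- function(grid, origin, spacing, shape) {
  stopifnot(inherits(grid, "dose_grid"))
  origin <- as.numeric(origin); spacing <- as.numeric(spacing)
  shape <- as.integer(shape)
  if (any(spacing <= 0) || any(shape < 1L)) {
    stop("resample_dose: invalid target geometry")
  }
  if (identical(origin, grid$origin) && identical(spacing, grid$spacing) &&
      identical(shape, grid$shape)) {
    return(structure(list(origin = origin, spacing = spacing, shape = shape,
                          values = grid$values, frame_id = grid$frame_id),
                     class = "resampled_dose"))
  }
  # fractional (1-based) source indices of the target voxel centers, per axis
  fidx <- lapply(1:3, function(a) {
    tc <- origin[a] + (seq_len(shape[a]) - 1) * spacing[a]
    (tc - grid$origin[a]) / grid$spacing[a] + 1
  })
  n <- grid$shape
  lo <- lapply(1:3, function(a) {
    i <- floor(fidx[[a]])
    # clamp to a valid cell; out-of-support points are masked via `oob`
    pmax(1L, pmin(as.integer(i), n[a] - 1L))
  })
  frac <- lapply(1:3, function(a) fidx[[a]] - lo[[a]])
  oob <- lapply(1:3, function(a) fidx[[a]] < 1 - 1e-9 | fidx[[a]] > n[a] + 1e-9)
  # degenerate single-voxel axes: nearest (the only) slice
  for (a in 1:3) {
    if (n[a] == 1L) {
      lo[[a]][] <- 1L; frac[[a]][] <- 0
      oob[[a]] <- abs(fidx[[a]] - 1) > 0.5 + 1e-9
    }
  }
  ii <- rep(seq_len(shape[1]), times = shape[2] * shape[3])
  jj <- rep(rep(seq_len(shape[2]), each = shape[1]), times = shape[3])
  kk <- rep(seq_len(shape[3]), each = shape[1] * shape[2])
  i0 <- lo[[1]][ii]; j0 <- lo[[2]][jj]; k0 <- lo[[3]][kk]
  tx <- frac[[1]][ii]; ty <- frac[[2]][jj]; tz <- frac[[3]][kk]
  i1 <- pmin(i0 + 1L, n[1]); j1 <- pmin(j0 + 1L, n[2]); k1 <- pmin(k0 + 1L, n[3])
  V <- grid$values
  vals <-
    (1 - tx) * (1 - ty) * (1 - tz) * V[cbind(i0, j0, k0)] +
    tx       * (1 - ty) * (1 - tz) * V[cbind(i1, j0, k0)] +
    (1 - tx) * ty       * (1 - tz) * V[cbind(i0, j1, k0)] +
    tx       * ty       * (1 - tz) * V[cbind(i1, j1, k0)] +
    (1 - tx) * (1 - ty) * tz       * V[cbind(i0, j0, k1)] +
    tx       * (1 - ty) * tz       * V[cbind(i1, j0, k1)] +
    (1 - tx) * ty       * tz       * V[cbind(i0, j1, k1)] +
    tx       * ty       * tz       * V[cbind(i1, j1, k1)]
  vals[oob[[1]][ii] | oob[[2]][jj] | oob[[3]][kk]] <- NA_real_
  if (all(is.na(vals))) stop("resample_dose: target entirely outside source support")
  structure(list(origin = origin, spacing = spacing, shape = shape,
                 values = array(vals, dim = shape), frame_id = grid$frame_id),
            class = "resampled_dose")
}

# ---- mean dose --------------------------------------------------------------

#' Mean dose over a voxel mask
#'
#' Unweighted arithmetic mean of the dose at included voxel centers. `NA`
#' voxels (out-of-support sentinels from [resample_dose]) are excluded.
#'
#' @param grid a [dose_grid] or `resampled_dose`.
#' @param mask a `voxel_mask` with matching shape.
#' @return Mean dose in Gy.
#' @export
mean_dose <- function(grid, mask) {
  stopifnot(inherits(mask, "voxel_mask"))
  if (!identical(as.integer(grid$shape), as.integer(mask$shape))) {
    stop("mean_dose: grid and mask shapes differ")
  }
  v <- grid$values[mask$included]
  v <- v[!is.na(v)]
  if (length(v) == 0) stop("mean_dose: empty mask")
  mean(v)
}

#' Summarize per-structure mean doses for one plan
#'
#' @param grid a [dose_grid] (or `resampled_dose` carrying the same fields).
#' @param ss a [structure_set] whose `frame_id` matches the grid's.
#' @param case_id,source,params passed to [plan_dose_summary].
#' @return A [plan_dose_summary]. Structures with an empty mask are omitted
#'   with a warning rather than an error.
#' @export
summarize_plan <- function(grid, ss, case_id, source, params = NULL) {
  stopifnot(inherits(ss, "structure_set"))
  if (!identical(grid$frame_id, ss$frame_id)) {
    stop(sprintf("summarize_plan: frame mismatch ('%s' vs '%s')",
                 grid$frame_id, ss$frame_id))
  }
  doses <- c()
  for (s in ss$structures) {
    m <- tryCatch(rasterize_structure(s, grid), error = function(e) NULL)
    if (is.null(m)) {
      warning(sprintf("summarize_plan: structure '%s' has empty mask; omitted",
                      s$name))
      next
    }
    doses[s$name] <- mean_dose(grid, m)
  }
  if (length(doses) == 0) stop("summarize_plan: no structure produced a mean dose")
  plan_dose_summary(case_id, source, doses, params = params)
}

# ---- percent differences ----------------------------------------------------

comparison_cols <- c("case_id", "structure", "pct_diff",
                     "dlg_cm", "mlc_tf", "algorithm")

new_comparison_table <- function(case_id, structure, pct_diff, params = NULL) {
  data.frame(case_id = case_id, structure = structure, pct_diff = pct_diff,
             dlg_cm = if (is.null(params)) NA_real_ else params$dlg_cm,
             mlc_tf = if (is.null(params)) NA_real_ else params$mlc_tf,
             algorithm = if (is.null(params)) NA_character_ else params$algorithm,
             stringsAsFactors = FALSE)
}

#' Percent mean-dose difference between a local and a reference plan
#'
#' For each structure present in both summaries, computes
#' `100 * (mean_local - mean_ref) / mean_ref` — the monitored statistic, with
#' differences expressed relative to the reference (automated) plan.
#' Structures whose reference mean dose is at or below `dose_floor` are
#' skipped with a warning to keep the ratio numerically meaningful.
#'
#' @param local [plan_dose_summary] with `source = "local"`.
#' @param reference [plan_dose_summary] with `source = "reference"`.
#' @param dose_floor minimum reference mean dose (Gy) for a valid percent
#'   difference; default 0.01 Gy.
#' @return A comparison table (`data.frame` with columns `case_id`,
#'   `structure`, `pct_diff`, `dlg_cm`, `mlc_tf`, `algorithm`), carrying the
#'   local plan's machine parameters when present.
#' @export
percent_difference <- function(local, reference, dose_floor = 0.01) {
  stopifnot(inherits(local, "plan_dose_summary"),
            inherits(reference, "plan_dose_summary"))
  if (!identical(local$case_id, reference$case_id)) {
    stop(sprintf("percent_difference: case mismatch ('%s' vs '%s')",
                 local$case_id, reference$case_id))
  }
  shared <- intersect(names(local$mean_dose_by_structure),
                      names(reference$mean_dose_by_structure))
  if (length(shared) == 0) stop("percent_difference: no shared structures")
  ref <- reference$mean_dose_by_structure[shared]
  loc <- local$mean_dose_by_structure[shared]
  ok <- ref > dose_floor
  if (any(!ok)) {
    warning(sprintf(
      "percent_difference: reference mean dose at/below floor (%g Gy) for %s; skipped",
      dose_floor, paste(shared[!ok], collapse = ", ")))
  }
  if (!any(ok)) stop("percent_difference: no structure above dose floor")
  new_comparison_table(local$case_id, shared[ok],
                       100 * (loc[ok] - ref[ok]) / ref[ok],
                       params = local$params)
}

#' Write / read comparison tables as CSV
#'
#' Comparison tables are tidy `data.frame`s with one row per (case,
#' structure) and columns `case_id`, `structure`, `pct_diff` and the optional
#' machine-parameter annotations `dlg_cm`, `mlc_tf`, `algorithm`.
#'
#' @param comparisons a comparison table.
#' @param path CSV path.
#' @return `path` (write) or the comparison table (read).
#' @export
write_comparisons <- function(comparisons, path) {
  miss <- setdiff(c("case_id", "structure", "pct_diff"), names(comparisons))
  if (length(miss)) stop(sprintf("write_comparisons: missing column(s) %s",
                                 paste(miss, collapse = ", ")))
  for (col in comparison_cols) {
    if (!col %in% names(comparisons)) comparisons[[col]] <- NA
  }
  utils::write.csv(comparisons[, comparison_cols], path,
                   row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_comparisons
#' @export
read_comparisons <- function(path) {
  if (!file.exists(path)) stop(sprintf("read_comparisons: no such file '%s'", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("case_id", "structure", "pct_diff"), names(df))
  if (length(miss)) stop(sprintf("read_comparisons: missing column(s) %s",
                                 paste(miss, collapse = ", ")))
  if (anyNA(df$pct_diff) || any(!is.finite(df$pct_diff))) {
    stop("read_comparisons: non-finite pct_diff")
  }
  for (col in c("dlg_cm", "mlc_tf")) {
    if (!col %in% names(df)) df[[col]] <- NA_real_
  }
  if (!"algorithm" %in% names(df)) df$algorithm <- NA_character_
  df[, comparison_cols]
}
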