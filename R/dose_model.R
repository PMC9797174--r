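# ---- dose grids -------------------------------------------------------------

#' Construct a dose grid
#'
#' A `dose_grid` is a regular, axis-aligned 3-D scalar dose field in patient
#' coordinates. `origin` is the position of the *center* of the first voxel
#' (mm), `spacing` the voxel pitch per axis (mm), and `values` the dose in Gy,
#' stored as an array with the x index varying fastest.
#'
#' @param origin numeric(3), mm. Position of the first voxel center.
#' @param spacing numeric(3), mm. Strictly positive voxel pitch per axis.
#' @param shape integer(3). Voxel counts per axis, each >= 1.
#' @param values numeric array of dimension `shape` (or a vector of
#'   `prod(shape)` values, x fastest). Doses in Gy, finite and >= 0.
#' @param frame_id character scalar. Opaque frame-of-reference label; a
#'   structure set can only be evaluated against a grid with a matching label.
#' @return An object of class `dose_grid`.
#' @examples
#' g <- dose_grid(c(0, 0, 0), c(2, 2, 2), c(5, 5, 5), rep(1.5, 125))
#' mean(g$values)
#' @export
dose_grid <- function(origin, spacing, shape, values, frame_id = "FOR-1") {
  origin <- as.numeric(origin)
  spacing <- as.numeric(spacing)
  shape <- as.integer(shape)
  if (length(origin) != 3L || anyNA(origin) || any(!is.finite(origin))) {
    stop("dose_grid: 'origin' must be 3 finite numbers (mm)")
  }
  if (length(spacing) != 3L || anyNA(spacing) || any(spacing <= 0)) {
    stop("dose_grid: non-positive spacing")
  }
  if (length(shape) != 3L || anyNA(shape) || any(shape < 1L)) {
    stop("dose_grid: 'shape' must be 3 counts >= 1")
  }
  values <- as.numeric(values)
  if (length(values) != prod(shape)) {
    stop(sprintf("dose_grid: 'values' has %d entries, expected %d",
                 length(values), prod(shape)))
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop("dose_grid: all doses must be finite")
  }
  if (any(values < 0)) stop("dose_grid: negative dose values")
  structure(
    list(origin = origin, spacing = spacing, shape = shape,
         values = array(values, dim = shape),
         frame_id = as.character(frame_id)[1]),
    class = "dose_grid"
  )
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf("<dose_grid> %d x %d x %d voxels, spacing (%g, %g, %g) mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  origin (%g, %g, %g) mm, frame '%s'\n",
              x$origin[1], x$origin[2], x$origin[3], x$frame_id))
  cat(sprintf("  dose range [%.4g, %.4g] Gy\n",
              min(x$values), max(x$values)))
  invisible(x)
}

#' Voxel-center coordinates along one grid axis
#'
#' @param grid a `dose_grid`.
#' @param axis 1 (x), 2 (y) or 3 (z).
#' @return Numeric vector of voxel-center positions in mm.
#' @export
axis_coords <- function(grid, axis) {
  stopifnot(inherits(grid, "dose_grid"), axis %in% 1:3)
  grid$origin[axis] + (seq_len(grid$shape[axis]) - 1) * grid$spacing[axis]
}

# ---- structures -------------------------------------------------------------

segments_intersect <- function(p1, p2, p3, p4) {
  # proper crossing test for open segments (shared endpoints not counted)
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
     ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
}

polygon_self_intersects <- function(v) {
  n <- nrow(v)
  if (n < 4) return(FALSE)
  for (i in seq_len(n)) {
    a1 <- v[i, ]; a2 <- v[if (i == n) 1L else i + 1L, ]
    for (j in seq_len(n)) {
      if (abs(i - j) <= 1 || abs(i - j) == n - 1) next
      b1 <- v[j, ]; b2 <- v[if (j == n) 1L else j + 1L, ]
      if (segments_intersect(a1, a2, b1, b2)) return(TRUE)
    }
  }
  FALSE
}

polygon_area <- function(v) {
  # shoelace; signed area in mm^2
  x <- v[, 1]; y <- v[, 2]
  0.5 * sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)
}

#' Construct a named planar-contour structure
#'
#' A structure is a set of closed planar polygons, each lying on a constant
#' axial (z) plane in patient coordinates. Contours with fewer than 3 vertices
#' or zero area are rejected; self-intersecting polygons are rejected.
#'
#' @param name nonempty structure label (e.g. "PTV1", "larynx").
#' @param contours list of contours, each a list with elements `z` (axial
#'   plane position, mm) and `vertices` (n x 2 matrix of x, y in mm, n >= 3).
#' @return An object of class `rt_structure`.
#' @export
rt_structure <- function(name, contours) {
  name <- as.character(name)[1]
  if (is.na(name) || !nzchar(name)) stop("rt_structure: name must be nonempty")
  if (length(contours) == 0) stop(sprintf("rt_structure '%s': no contours", name))
  contours <- lapply(contours, function(ct) {
    v <- ct$vertices
    if (is.null(dim(v))) v <- matrix(v, ncol = 2, byrow = TRUE)
    v <- matrix(as.numeric(v), ncol = 2)
    if (nrow(v) < 3) stop(sprintf("rt_structure '%s': contour with < 3 vertices", name))
    if (abs(polygon_area(v)) <= 0) stop(sprintf("rt_structure '%s': zero-area contour", name))
    if (polygon_self_intersects(v)) {
      stop(sprintf("rt_structure '%s': self-intersecting contour", name))
    }
    list(z = as.numeric(ct$z)[1], vertices = v)
  })
  structure(list(name = name, contours = contours), class = "rt_structure")
}

#' Construct a structure set
#'
#' @param structures list of [rt_structure] objects with unique names.
#' @param frame_id frame-of-reference label; must match the `dose_grid` the
#'   set is evaluated against.
#' @return An object of class `structure_set`.
#' @export
structure_set <- function(structures, frame_id = "FOR-1") {
  if (length(structures) == 0) stop("structure_set: no structures")
  stopifnot(all(vapply(structures, inherits, TRUE, "rt_structure")))
  nms <- vapply(structures, `[[`, "", "name")
  if (anyDuplicated(nms)) {
    stop(sprintf("structure_set: duplicate structure name '%s'",
                 nms[duplicated(nms)][1]))
  }
  names(structures) <- nms
  structure(list(structures = structures, frame_id = as.character(frame_id)[1]),
            class = "structure_set")
}

#' @export
print.structure_set <- function(x, ...) {
  cat(sprintf("<structure_set> %d structures, frame '%s'\n",
              length(x$structures), x$frame_id))
  for (s in x$structures) {
    cat(sprintf("  %s: %d contour(s)\n", s$name, length(s$contours)))
  }
  invisible(x)
}

# ---- machine parameters -----------------------------------------------------

#' Machine-model parameters of a dose calculation
#'
#' The dosimetric leaf gap (DLG, cm) and the MLC transmission factor (MLC-TF,
#' dimensionless fraction) are the MLC beam-model parameters whose influence
#' on the monitored dose differences this package characterizes.
#'
#' @param dlg_cm dosimetric leaf gap in cm, in (0, 1).
#' @param mlc_tf MLC transmission factor, in (0, 0.1).
#' @param algorithm free-text dose algorithm label (e.g. "AAA", "Acuros",
#'   "CCC"); may be `NA`.
#' @return An object of class `machine_parameters`.
#' @export
machine_parameters <- function(dlg_cm, mlc_tf, algorithm = NA_character_) {
  dlg_cm <- as.numeric(dlg_cm)[1]
  mlc_tf <- as.numeric(mlc_tf)[1]
  if (is.na(dlg_cm) || dlg_cm <= 0 || dlg_cm >= 1) {
    stop("machine_parameters: dlg_cm must lie in (0, 1) cm")
  }
  if (is.na(mlc_tf) || mlc_tf <= 0 || mlc_tf >= 0.1) {
    stop("machine_parameters: mlc_tf must lie in (0, 0.1)")
  }
  structure(list(dlg_cm = dlg_cm, mlc_tf = mlc_tf,
                 algorithm = as.character(algorithm)[1]),
            class = "machine_parameters")
}

# ---- plan dose summaries ----------------------------------------------------

#' Per-structure mean doses for one plan calculation
#'
#' @param case_id cohort-unique case label.
#' @param source role of this calculation: `"reference"` (the autoplan) or
#'   `"local"` (the recalculation being monitored).
#' @param mean_dose_by_structure named numeric vector of mean doses (Gy),
#'   finite and >= 0, with unique structure names.
#' @param params optional [machine_parameters] of the calculation.
#' @return An object of class `plan_dose_summary`.
#' @export
plan_dose_summary <- function(case_id, source, mean_dose_by_structure,
                              params = NULL) {
  source <- match.arg(source, c("reference", "local"))
  md <- mean_dose_by_structure
  if (is.null(names(md)) || any(!nzchar(names(md)))) {
    stop("plan_dose_summary: mean doses must be named by structure")
  }
  if (anyDuplicated(names(md))) {
    stop("plan_dose_summary: duplicate structure name")
  }
  if (anyNA(md) || any(!is.finite(md))) stop("plan_dose_summary: non-finite mean dose")
  if (any(md < 0)) stop("plan_dose_summary: negative mean dose")
  if (!is.null(params)) stopifnot(inherits(params, "machine_parameters"))
  structure(list(case_id = as.character(case_id)[1], source = source,
                 mean_dose_by_structure = md, params = params),
            class = "plan_dose_summary")
}

# ---- fixture readers / writers ---------------------------------------------

#' Read a dose grid from file
#'
#' Two dialects are supported. `"fixture"` is the package's plain-text JSON
#' format (fields `origin`, `spacing`, `shape`, `frame_id`, `values` with the
#' x index varying fastest). `"dicom-rtdose"` reads a DICOM RT Dose object
#' (dose scaled to Gy via DoseGridScaling, geometry from
#' ImagePositionPatient / PixelSpacing / GridFrameOffsetVector); see
#' [dicom_to_fixture] for the conversion mechanics.
#'
#' @param path file path.
#' @param dialect `"fixture"` or `"dicom-rtdose"`.
#' @return A [dose_grid].
#' @export
read_dose_grid <- function(path, dialect = c("fixture", "dicom-rtdose")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop(sprintf("read_dose_grid: no such file '%s'", path))
  if (dialect == "dicom-rtdose") {
    path <- dicom_to_fixture(path, "rtdose")
  }
  j <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                error = function(e) stop(sprintf(
                  "read_dose_grid: cannot parse '%s': %s", path, conditionMessage(e))))
  for (f in c("origin", "spacing", "shape", "values")) {
    if (is.null(j[[f]])) stop(sprintf("read_dose_grid: missing field '%s'", f))
  }
  dose_grid(j$origin, j$spacing, j$shape, j$values,
            frame_id = if (is.null(j$frame_id)) "FOR-1" else j$frame_id)
}

#' Write a dose grid in the fixture format
#'
#' @param grid a [dose_grid].
#' @param path output path (JSON).
#' @return `path`, invisibly.
#' @export
write_dose_grid <- function(grid, path) {
  stopifnot(inherits(grid, "dose_grid"))
  jsonlite::write_json(
    list(origin = grid$origin, spacing = grid$spacing, shape = grid$shape,
         frame_id = grid$frame_id, values = as.numeric(grid$values)),
    path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' Read a structure set from file
#'
#' Dialect `"fixture"` is a JSON list of named polygons (see
#' [write_structure_set]); `"dicom-rtstruct"` reads a DICOM RT Structure Set.
#' Degenerate contours (< 3 vertices or zero area) are dropped with a warning;
#' a file whose contours are all degenerate is an error.
#'
#' @param path file path.
#' @param dialect `"fixture"` or `"dicom-rtstruct"`.
#' @return A [structure_set].
#' @export
read_structure_set <- function(path, dialect = c("fixture", "dicom-rtstruct")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop(sprintf("read_structure_set: no such file '%s'", path))
  if (dialect == "dicom-rtstruct") {
    path <- dicom_to_fixture(path, "rtstruct")
  }
  j <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                error = function(e) stop(sprintf(
                  "read_structure_set: cannot parse '%s': %s", path, conditionMessage(e))))
  if (is.null(j$structures) || length(j$structures) == 0) {
    stop("read_structure_set: no structures")
  }
  nms <- vapply(j$structures, function(s) as.character(s$name), "")
  if (anyDuplicated(nms)) {
    stop(sprintf("read_structure_set: duplicate structure name '%s'",
                 nms[duplicated(nms)][1]))
  }
  structures <- list()
  for (s in j$structures) {
    kept <- list()
    for (ct in s$contours) {
      v <- do.call(rbind, lapply(ct$vertices, function(p) as.numeric(unlist(p))))
      if (is.null(v) || nrow(v) < 3 || abs(polygon_area(v)) <= 0) {
        warning(sprintf("read_structure_set: dropping degenerate contour in '%s'",
                        s$name))
        next
      }
      kept[[length(kept) + 1L]] <- list(z = as.numeric(ct$z), vertices = v)
    }
    if (length(kept) == 0) {
      warning(sprintf("read_structure_set: structure '%s' has no valid contours; dropped",
                      s$name))
      next
    }
    structures[[length(structures) + 1L]] <- rt_structure(s$name, kept)
  }
  if (length(structures) == 0) stop("read_structure_set: all contours degenerate")
  structure_set(structures,
                frame_id = if (is.null(j$frame_id)) "FOR-1" else j$frame_id)
}

#' Write a structure set in the fixture format
#'
#' @param ss a [structure_set].
#' @param path output path (JSON).
#' @return `path`, invisibly.
#' @export
write_structure_set <- function(ss, path) {
  stopifnot(inherits(ss, "structure_set"))
  out <- list(
    frame_id = ss$frame_id,
    structures = lapply(unname(ss$structures), function(s) list(
      name = s$name,
      contours = lapply(s$contours, function(ct) list(
        z = ct$z,
        vertices = lapply(seq_len(nrow(ct$vertices)),
                          function(i) as.numeric(ct$vertices[i, ]))))
    )))
  jsonlite::write_json(out, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

# ---- summary CSV ------------------------------------------------------------

summary_csv_cols <- c("case_id", "source", "structure", "mean_dose_gy",
                      "dlg_cm", "mlc_tf", "algorithm")

#' Read per-structure mean-dose summaries from CSV
#'
#' The CSV must carry columns `case_id`, `source`, `structure`,
#' `mean_dose_gy` and may carry `dlg_cm`, `mlc_tf`, `algorithm`. One
#' [plan_dose_summary] is returned per (`case_id`, `source`) pair.
#' Round-trips losslessly with [write_summaries].
#'
#' @param path CSV path (UTF-8, header row).
#' @return List of [plan_dose_summary] objects.
#' @export
read_summaries <- function(path) {
  if (!file.exists(path)) stop(sprintf("read_summaries: no such file '%s'", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("case_id", "source", "structure", "mean_dose_gy")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop(sprintf("read_summaries: missing column(s) %s",
                                 paste(miss, collapse = ", ")))
  if (anyDuplicated(df[, c("case_id", "source", "structure")])) {
    stop("read_summaries: duplicate (case_id, source, structure) rows")
  }
  if (any(df$mean_dose_gy < 0)) stop("read_summaries: negative dose")
  has_params <- all(c("dlg_cm", "mlc_tf") %in% names(df))
  key <- paste(df$case_id, df$source, sep = "\r")
  out <- lapply(split(seq_len(nrow(df)), factor(key, levels = unique(key))),
                function(idx) {
    sub <- df[idx, , drop = FALSE]
    params <- NULL
    if (has_params && !is.na(sub$dlg_cm[1]) && !is.na(sub$mlc_tf[1])) {
      alg <- if ("algorithm" %in% names(sub)) sub$algorithm[1] else NA_character_
      params <- machine_parameters(sub$dlg_cm[1], sub$mlc_tf[1], alg)
    }
    plan_dose_summary(sub$case_id[1], sub$source[1],
                      stats::setNames(sub$mean_dose_gy, sub$structure),
                      params = params)
  })
  unname(out)
}

#' Write plan dose summaries to CSV
#'
#' @param summaries list of [plan_dose_summary] objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_summaries <- function(summaries, path) {
  stopifnot(length(summaries) > 0,
            all(vapply(summaries, inherits, TRUE, "plan_dose_summary")))
  rows <- do.call(rbind, lapply(summaries, function(s) {
    p <- s$params
    data.frame(case_id = s$case_id, source = s$source,
               structure = names(s$mean_dose_by_structure),
               mean_dose_gy = unname(s$mean_dose_by_structure),
               dlg_cm = if (is.null(p)) NA_real_ else p$dlg_cm,
               mlc_tf = if (is.null(p)) NA_real_ else p$mlc_tf,
               algorithm = if (is.null(p)) NA_character_ else p$algorithm,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
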