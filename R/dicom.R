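# DICOM RT ingestion. Parsing the DICOM encoding is delegated to pydicom
# through a small bundled converter script; the converted JSON then flows
# through the ordinary fixture readers, so both dialects share one code path.

find_python <- function() {
  py <- Sys.which("python")
  if (!nzchar(py)) py <- Sys.which("python3")
  if (!nzchar(py)) {
    stop("DICOM support requires a 'python' interpreter with pydicom on PATH")
  }
  py
}

#' Convert a DICOM RT object to the package's JSON fixture format
#'
#' Runs the bundled pydicom converter on one DICOM RT Dose or RT Structure
#' Set file and returns the path of the resulting JSON fixture (in
#' `tempdir()` unless `out` is given). Used internally by [read_dose_grid]
#' and [read_structure_set] for the DICOM dialects.
#'
#' @param path DICOM file path.
#' @param what `"rtdose"` or `"rtstruct"`.
#' @param out optional output JSON path.
#' @return Path of the JSON fixture.
#' @export
dicom_to_fixture <- function(path, what = c("rtdose", "rtstruct"), out = NULL) {
  what <- match.arg(what)
  if (!file.exists(path)) stop(sprintf("dicom_to_fixture: no such file '%s'", path))
  script <- system.file("python", "dicom_to_fixture.py", package = "rtspc")
  if (!nzchar(script)) stop("dicom_to_fixture: converter script not installed")
  if (is.null(out)) out <- tempfile(fileext = ".json")
  res <- suppressWarnings(system2(find_python(), c(shQuote(script), what,
                                                   shQuote(path), shQuote(out)),
                                  stdout = TRUE, stderr = TRUE))
  status <- attr(res, "status")
  if (!is.null(status) && status != 0) {
    stop(sprintf("dicom_to_fixture: conversion of '%s' failed: %s",
                 path, paste(res, collapse = " ")))
  }
  out
}
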