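#' Planar structure sets
#'
#' A `structure_set` holds named structures, each a stack of planar polygon
#' contours in physical millimetres — the geometry model of a radiotherapy
#' structure set (RTSS), where every target (here, every metastasis) is
#' delineated slice by slice as closed polygons. Polygons are implicitly
#' closed (the last vertex joins the first) and must have at least three
#' vertices, each sharing one z-plane.
#'
#' @param patient_id Patient identifier string.
#' @param structures Named list; each element is a list of polygons, each
#'   polygon an n x 3 numeric matrix of (x, y, z) vertices in mm.
#' @param frame_of_reference Frame-of-reference identifier (may be `""`).
#' @return An object of class `structure_set`.
#' @examples
#' sq <- cbind(c(0, 20, 20, 0), c(0, 0, 20, 20), 0)
#' ss <- structure_set("P001", list(Met_01 = list(sq)))
#' @export
structure_set <- function(patient_id, structures, frame_of_reference = "") {
  patient_id <- as.character(patient_id)
  nms <- names(structures)
  if (length(structures) > 0L && (is.null(nms) || any(!nzchar(nms))))
    stop("`structures` must be a named list", call. = FALSE)
  structures <- lapply(seq_along(structures), function(s) {
    polys <- structures[[s]]
    lapply(seq_along(polys), function(p) {
      poly <- as_point_matrix(polys[[p]])
      if (nrow(poly) < 3L)
        stop(sprintf(
          "structure '%s', contour %d: polygon has fewer than 3 vertices",
          nms[s], p), call. = FALSE)
      if (any(!is.finite(poly)))
        stop(sprintf("structure '%s', contour %d: non-finite vertex",
                     nms[s], p), call. = FALSE)
      storage.mode(poly) <- "double"
      dimnames(poly) <- NULL
      poly
    })
  })
  names(structures) <- nms
  structure(
    list(patient_id = patient_id, structures = structures,
         frame_of_reference = as.character(frame_of_reference)),
    class = "structure_set"
  )
}

#' @export
print.structure_set <- function(x, ...) {
  cat(sprintf("<structure_set> patient %s: %d structure(s)\n",
              x$patient_id, length(x$structures)))
  for (nm in names(x$structures))
    cat(sprintf("  %s: %d contour(s)\n", nm, length(x$structures[[nm]])))
  invisible(x)
}

#' Read a structure set
#'
#' Two dialects are supported: `json-contours`, a plain-text JSON schema
#' defined by this package (see Details), and `dicom-rtss`, the standard
#' DICOM RT Structure Set, read through a bundled pydicom bridge.
#'
#' @details The json-contours schema (version 1.0) is
#' ```
#' {"format": "json-contours", "version": "1.0",
#'  "patient_id": "...", "frame_of_reference": "...",
#'  "structures": [{"name": "...",
#'                  "contours": [[[x,y,z], [x,y,z], ...], ...]}]}
#' ```
#' with all coordinates in physical millimetres. Polygons are closed
#' implicitly and listed one z-plane each.
#'
#' @param path Path to the file.
#' @param dialect `"json-contours"` (default) or `"dicom-rtss"`.
#' @return A [structure_set()].
#' @export
read_structure_set <- function(path,
                               dialect = c("json-contours", "dicom-rtss")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path))
    stop(sprintf("structure-set file not found: %s", path), call. = FALSE)
  if (dialect == "dicom-rtss") {
    tmp <- tempfile(fileext = ".json")
    on.exit(unlink(tmp), add = TRUE)
    rtss_bridge("to-json", path, tmp)
    path <- tmp
  }
  doc <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) stop(sprintf("cannot parse '%s': %s", path,
                                     conditionMessage(e)), call. = FALSE)
  )
  if (!identical(doc$format, "json-contours"))
    stop(sprintf("'%s' is not a json-contours file", path), call. = FALSE)
  structures <- list()
  for (s in doc$structures) {
    polys <- lapply(s$contours, function(poly) {
      do.call(rbind, lapply(poly, function(v) as.numeric(unlist(v))))
    })
    structures[[s$name]] <- polys
  }
  structure_set(doc$patient_id %||% "", structures,
                doc$frame_of_reference %||% "")
}

#' Write a structure set
#'
#' @param x A [structure_set()].
#' @param path Output path.
#' @param dialect `"json-contours"` (default) or `"dicom-rtss"`.
#' @return `path`, invisibly.
#' @export
write_structure_set <- function(x, path,
                                dialect = c("json-contours", "dicom-rtss")) {
  stopifnot(inherits(x, "structure_set"))
  dialect <- match.arg(dialect)
  doc <- list(
    format = "json-contours",
    version = "1.0",
    patient_id = x$patient_id,
    frame_of_reference = x$frame_of_reference,
    structures = lapply(names(x$structures), function(nm) {
      list(name = nm,
           contours = lapply(x$structures[[nm]], function(poly) {
             lapply(seq_len(nrow(poly)), function(i) poly[i, ])
           }))
    })
  )
  if (dialect == "json-contours") {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  } else {
    tmp <- tempfile(fileext = ".json")
    on.exit(unlink(tmp), add = TRUE)
    jsonlite::write_json(doc, tmp, auto_unbox = TRUE, digits = NA)
    rtss_bridge("from-json", tmp, path)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

rtss_bridge <- function(verb, infile, outfile) {
  script <- system.file("python", "rtss_bridge.py", package = "lesionwise")
  if (!nzchar(script))
    stop("bundled RTSS bridge script not found", call. = FALSE)
  python <- Sys.which("python")
  if (!nzchar(python))
    stop("DICOM RTSS support requires `python` with pydicom on the PATH",
         call. = FALSE)
  res <- suppressWarnings(
    system2(python, c(script, verb, shQuote(infile), shQuote(outfile)),
            stdout = TRUE, stderr = TRUE)
  )
  status <- attr(res, "status") %||% 0L
  if (status != 0L)
    stop(sprintf("RTSS bridge failed (%s): %s", verb,
                 paste(res, collapse = "; ")), call. = FALSE)
  invisible(outfile)
}
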