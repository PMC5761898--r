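# File formats: measurement tables and per-core tables as CSV (comma, dot
# decimal, UTF-8, mandatory header), ROI polygons as GeoJSON in micrometre
# coordinates, run configs as flat JSON.

#' Write / read a section-measurement table
#'
#' CSV with header `patient_id, group, section, percent_cd8, n_cells,
#' tissue_loss`; `tissue_loss` is stored as 0/1. Reading validates ranges and
#' the (patient, section) key, reporting offending row numbers.
#'
#' @param measurements data.frame as produced by
#'   [generate_section_measurements()].
#' @param path file path.
#' @return `read_measurements` returns the validated data.frame;
#'   `write_measurements` returns `path` invisibly.
#' @export
write_measurements <- function(measurements, path) {
  m <- measurements
  m$tissue_loss <- as.integer(m$tissue_loss)
  utils::write.csv(m, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_measurements
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) stop("measurement file not found: ", path)
  m <- utils::read.csv(path, stringsAsFactors = FALSE,
                       fileEncoding = "UTF-8")
  req <- c("patient_id", "group", "section", "percent_cd8", "n_cells",
           "tissue_loss")
  miss <- setdiff(req, names(m))
  if (length(miss))
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "))
  m$tissue_loss <- as.logical(m$tissue_loss)
  validate_measurements(m)
  m
}

#' Write / read slide geometry and cells
#'
#' Geometry goes to GeoJSON (a FeatureCollection of Polygon features with
#' vertices in micrometres; rings are closed on write and unclosed on read);
#' cells go to a CSV with header `x_um, y_um, positive` (0/1).
#'
#' @param slide a `slide` from [generate_slide()], or any list with
#'   `geometry` and `cells` in the same shape.
#' @param geojson_path,cells_path output paths.
#' @return `read_slide` returns a `slide` list; writers return their path
#'   invisibly.
#' @export
write_slide <- function(slide, geojson_path, cells_path) {
  feats <- lapply(slide$geometry$roi_polygons, function(p) {
    ring <- rbind(p, p[1L, , drop = FALSE])       # close the ring
    list(type = "Feature", properties = list(units = "um"),
         geometry = list(type = "Polygon",
                         coordinates = list(unname(
                           lapply(seq_len(nrow(ring)),
                                  function(i) as.numeric(ring[i, ]))))))
  })
  gj <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(gj, geojson_path, auto_unbox = TRUE, digits = NA)
  cells <- slide$cells
  cells$positive <- as.integer(cells$positive)
  utils::write.csv(cells, cells_path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(geojson_path)
}

#' @rdname write_slide
#' @export
read_slide <- function(geojson_path, cells_path) {
  if (!file.exists(geojson_path)) stop("GeoJSON file not found: ", geojson_path)
  if (!file.exists(cells_path)) stop("cell table not found: ", cells_path)
  gj <- jsonlite::read_json(geojson_path)
  if (!identical(gj$type, "FeatureCollection"))
    stop("expected a GeoJSON FeatureCollection in ", geojson_path)
  polys <- lapply(gj$features, function(f) {
    if (!identical(f$geometry$type, "Polygon"))
      stop("expected Polygon features in ", geojson_path)
    ring <- f$geometry$coordinates[[1L]]
    m <- do.call(rbind, lapply(ring, function(v) as.numeric(unlist(v))))
    # drop the closing vertex
    if (nrow(m) > 1L && all(m[1L, ] == m[nrow(m), ]))
      m <- m[-nrow(m), , drop = FALSE]
    colnames(m) <- c("x", "y")
    validate_polygon(m)
    m
  })
  cells <- utils::read.csv(cells_path, stringsAsFactors = FALSE,
                           fileEncoding = "UTF-8")
  miss <- setdiff(c("x_um", "y_um", "positive"), names(cells))
  if (length(miss))
    stop("missing column(s) in ", cells_path, ": ",
         paste(miss, collapse = ", "))
  bad <- which(!is.finite(cells$x_um) | !is.finite(cells$y_um))
  if (length(bad))
    stop("non-finite cell coordinates at row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "))
  cells$positive <- as.logical(cells$positive)
  structure(list(geometry = list(roi_polygons = polys,
                                 bounding_box = polygon_bbox(polys)),
                 cells = cells),
            class = "slide")
}

#' Write a per-core table
#'
#' @param cores scored core table from [score_cores()].
#' @param slide_id identifier recorded in the first column.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_cores <- function(cores, slide_id, path) {
  out <- cbind(slide_id = slide_id, as.data.frame(cores))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
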