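# Virtual core biopsies: tessellate the slide into rectangles of ~2 mm^2,
# keep those with enough annotated-tumor overlap, and score percent CD8
# within each retained core.

#' Core-grid configuration
#'
#' @param core_area tile area in square millimetres (default 2.0).
#' @param min_overlap minimum ROI overlap per tile, square millimetres
#'   (default 0.7).
#' @param min_tumor_fraction minimum overlap_area / core_area (default 0.33).
#' @param aspect tile width:height ratio (default 1, i.e. squares of side
#'   sqrt(2) mm).
#' @param anchor_dx,anchor_dy grid anchor offset from the ROI bounding-box
#'   minimum corner, micrometres (default 0; exposed for anchor-sensitivity
#'   checks).
#' @return list of class `core_grid_config`.
#' @export
core_grid_config <- function(core_area = 2.0, min_overlap = 0.7,
                             min_tumor_fraction = 0.33, aspect = 1.0,
                             anchor_dx = 0, anchor_dy = 0) {
  if (!is.finite(core_area) || core_area <= 0) stop("core_area must be > 0")
  if (!is.finite(min_overlap) || min_overlap <= 0 || min_overlap > core_area)
    stop("min_overlap must be in (0, core_area]")
  if (!is.finite(min_tumor_fraction) || min_tumor_fraction < 0 ||
      min_tumor_fraction > 1)
    stop("min_tumor_fraction must be in [0, 1]")
  if (!is.finite(aspect) || aspect <= 0) stop("aspect must be > 0")
  structure(list(core_area = core_area, min_overlap = min_overlap,
                 min_tumor_fraction = min_tumor_fraction, aspect = aspect,
                 anchor_dx = anchor_dx, anchor_dy = anchor_dy),
            class = "core_grid_config")
}

#' Tessellate a slide into candidate core rectangles
#'
#' Non-overlapping axis-aligned tiling of the ROI bounding box by rectangles
#' of area `core_area` (width `sqrt(core_area * aspect)` mm), anchored at the
#' bounding-box minimum corner plus the configured offset, indexed row-major
#' from (1, 1). Each tile's ROI overlap is the exact polygon-clip area
#' against the union of ROI polygons; by default only tiles with
#' `overlap >= min_overlap` and `overlap / core_area >= min_tumor_fraction`
#' are returned.
#'
#' @param geometry slide geometry: list with `roi_polygons` (list of vertex
#'   matrices, micrometres) and optionally `bounding_box`.
#' @param config a [core_grid_config()].
#' @param keep_all return every tile (with a `retained` column) instead of
#'   only the retained ones; used for partition/coverage checks.
#' @return data.frame of class `core_grid` with columns row, col, x0_um,
#'   y0_um, x1_um, y1_um, overlap_mm2, tumor_fraction (and `retained` when
#'   `keep_all`). Grid geometry is attached as attribute `"grid"`.
#' @export
generate_core_grid <- function(geometry, config = core_grid_config(),
                               keep_all = FALSE) {
  stopifnot(inherits(config, "core_grid_config"))
  polys <- geometry$roi_polygons
  if (is.matrix(polys)) polys <- list(polys)
  if (length(polys) == 0L) {
    out <- data.frame(row = integer(0), col = integer(0), x0_um = numeric(0),
                      y0_um = numeric(0), x1_um = numeric(0),
                      y1_um = numeric(0), overlap_mm2 = numeric(0),
                      tumor_fraction = numeric(0))
    class(out) <- c("core_grid", "data.frame")
    return(out)
  }
  lapply(polys, validate_polygon)
  total_area <- sum(vapply(polys, polygon_area, numeric(1L)))
  if (total_area <= 0) stop("ROI has zero area")
  bb <- polygon_bbox(polys)
  w_um <- sqrt(config$core_area * config$aspect) * 1000
  h_um <- sqrt(config$core_area / config$aspect) * 1000
  x0 <- bb["xmin"] + config$anchor_dx
  y0 <- bb["ymin"] + config$anchor_dy
  n_col <- max(1L, ceiling((bb["xmax"] - x0) / w_um - 1e-9))
  n_row <- max(1L, ceiling((bb["ymax"] - y0) / h_um - 1e-9))
  grid <- expand.grid(col = seq_len(n_col), row = seq_len(n_row))
  gx0 <- x0 + (grid$col - 1L) * w_um
  gy0 <- y0 + (grid$row - 1L) * h_um
  overlap_um2 <- mapply(function(a, b)
    rect_roi_overlap_area(polys, a, b, a + w_um, b + h_um), gx0, gy0)
  out <- data.frame(row = grid$row, col = grid$col,
                    x0_um = unname(gx0), y0_um = unname(gy0),
                    x1_um = unname(gx0 + w_um), y1_um = unname(gy0 + h_um),
                    overlap_mm2 = unname(overlap_um2) / 1e6)
  out$tumor_fraction <- out$overlap_mm2 / config$core_area
  retained <- out$overlap_mm2 >= config$min_overlap &
    out$tumor_fraction >= config$min_tumor_fraction
  if (keep_all) out$retained <- retained else out <- out[retained, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "grid") <- list(x0 = unname(x0), y0 = unname(y0),
                            w_um = unname(w_um), h_um = unname(h_um),
                            n_col = n_col, n_row = n_row, config = config)
  class(out) <- c("core_grid", "data.frame")
  out
}

# Assign in-ROI cells to grid tiles with a half-open tie rule: a cell exactly
# on the shared edge of two tiles belongs to the tile with the smaller
# row-major index (the left/upper one), so partition counts are conserved.
assign_cells_to_tiles <- function(x, y, grid) {
  col <- floor((x - grid$x0) / grid$w_um)
  on_edge <- (x - grid$x0) == col * grid$w_um & col > 0
  col[on_edge] <- col[on_edge] - 1L
  row <- floor((y - grid$y0) / grid$h_um)
  on_edge <- (y - grid$y0) == row * grid$h_um & row > 0
  row[on_edge] <- row[on_edge] - 1L
  data.frame(row = as.integer(row) + 1L, col = as.integer(col) + 1L)
}

#' Score cores: cell counts and percent CD8 within each core
#'
#' Counts only cells inside the rectangle intersected with the ROI (cells in
#' a tile but outside the annotated region do not count). Tile membership
#' uses the half-open shared-edge tie rule so a cell is never counted in two
#' tiles. Retained cores that contain zero cells get an undefined percent and
#' are dropped with a warning, since they cannot enter core resampling.
#'
#' @param cores a `core_grid` from [generate_core_grid()].
#' @param cells cell table (x_um, y_um, positive).
#' @param geometry the slide geometry the grid was built from.
#' @param drop_empty drop zero-cell cores (default TRUE).
#' @return the core table with n_cells, n_positive, percent_cd8 columns
#'   added.
#' @export
score_cores <- function(cores, cells, geometry, drop_empty = TRUE) {
  grid <- attr(cores, "grid")
  if (is.null(grid)) stop("cores must come from generate_core_grid()")
  polys <- geometry$roi_polygons
  if (is.matrix(polys)) polys <- list(polys)
  in_roi <- rep(FALSE, nrow(cells))
  for (p in polys)
    in_roi <- in_roi | point_in_polygon(cells$x_um, cells$y_um, p)
  cx <- cells$x_um[in_roi]; cy <- cells$y_um[in_roi]
  cpos <- as.logical(cells$positive)[in_roi]
  idx <- assign_cells_to_tiles(cx, cy, grid)
  key <- paste(idx$row, idx$col)
  n_tot <- tapply(rep(1L, length(key)), key, sum)
  n_pos <- tapply(as.integer(cpos), key, sum)
  core_key <- paste(cores$row, cores$col)
  cores$n_cells <- as.integer(ifelse(core_key %in% names(n_tot),
                                     n_tot[core_key], 0L))
  cores$n_positive <- as.integer(ifelse(core_key %in% names(n_pos),
                                        n_pos[core_key], 0L))
  cores$percent_cd8 <- percent_positive(cores$n_cells, cores$n_positive)
  if (drop_empty && !("retained" %in% names(cores)) && any(is.na(cores$percent_cd8))) {
    n_drop <- sum(is.na(cores$percent_cd8))
    warning(sprintf("dropping %d retained core(s) with zero cells", n_drop))
    cores <- cores[!is.na(cores$percent_cd8), , drop = FALSE]
    rownames(cores) <- NULL
  }
  cores
}
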