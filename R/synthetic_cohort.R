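# Synthetic cohorts: section-level percent-CD8 tables and full spatial slides
# (cell coordinates + tumor-ROI polygons) with controlled patient, section and
# spatial variability.

#' Specify one tumor group of a synthetic cohort
#'
#' A group is a set of patients sharing a percent-CD8 distribution: each
#' patient's latent block-level value is drawn from
#' Normal(`mean_percent`, `between_patient_sd`) and each step section adds
#' Normal(0, `within_patient_sd`) noise; values are clipped to \[0, 100\].
#'
#' @param group_label character scalar, e.g. "ductal", "medullary", "crc".
#' @param n_patients number of patients in the group.
#' @param mean_percent group mean percent CD8+ cells, in \[0, 100\].
#' @param between_patient_sd SD of latent patient means (percent, >= 0).
#' @param within_patient_sd SD of section-to-section noise (percent, >= 0).
#' @param n_sections step sections cut per block (default 8).
#' @param tissue_loss_rate probability that a section suffers substantial
#'   tissue loss; lost sections keep their expected percent but retain only
#'   30 percent of the cells.
#' @param base_n_cells expected nucleated-cell count per intact section
#'   (Poisson mean).
#' @return an object of class `group_spec`.
#' @export
group_spec <- function(group_label, n_patients, mean_percent,
                       between_patient_sd, within_patient_sd,
                       n_sections = 8L, tissue_loss_rate = 0,
                       base_n_cells = 20000L) {
  stopifnot(is.character(group_label), length(group_label) == 1L)
  if (!is.finite(n_patients) || n_patients < 1L) stop("n_patients must be >= 1")
  if (!is.finite(mean_percent) || mean_percent < 0 || mean_percent > 100)
    stop("mean_percent must be in [0, 100]")
  if (!is.finite(between_patient_sd) || between_patient_sd < 0)
    stop("between_patient_sd must be >= 0")
  if (!is.finite(within_patient_sd) || within_patient_sd < 0)
    stop("within_patient_sd must be >= 0")
  if (!is.finite(n_sections) || n_sections < 1L) stop("n_sections must be >= 1")
  if (!is.finite(tissue_loss_rate) || tissue_loss_rate < 0 || tissue_loss_rate > 1)
    stop("tissue_loss_rate must be in [0, 1]")
  structure(list(group_label = group_label,
                 n_patients = as.integer(n_patients),
                 mean_percent = mean_percent,
                 between_patient_sd = between_patient_sd,
                 within_patient_sd = within_patient_sd,
                 n_sections = as.integer(n_sections),
                 tissue_loss_rate = tissue_loss_rate,
                 base_n_cells = as.integer(base_n_cells)),
            class = "group_spec")
}

#' Default study-like group specification
#'
#' Three groups mirroring a breast/colorectal CD8 IHC cohort: 6 ductal
#' adenocarcinoma (mean 8.8 percent, intrapatient SD 1.2), 6 medullary breast
#' carcinoma (mean 24.0, intrapatient SD 1.7) and 13 colorectal (mean 3.8,
#' intrapatient SD 0.4) patients, 8 step sections each. Between-patient SDs
#' are calibrated, not quoted, to give each group a realistic dynamic range
#' (ductal up to tens of percent, colorectal mostly below 10 percent).
#'
#' @param tissue_loss_rate shared tissue-loss probability (default 0.05).
#' @return list of [group_spec()] objects.
#' @export
default_group_specs <- function(tissue_loss_rate = 0.05) {
  list(
    group_spec("ductal", 6L, 8.8, 8.0, 1.2,
               tissue_loss_rate = tissue_loss_rate),
    group_spec("medullary", 6L, 24.0, 14.0, 1.7,
                tissue_loss_rate = tissue_loss_rate),
    group_spec("crc", 13L, 3.8, 3.0, 0.4,
               tissue_loss_rate = tissue_loss_rate)
  )
}

#' Generate a section-level measurement table
#'
#' For each patient a latent true percent is drawn from
#' Normal(`mean_percent`, `between_patient_sd`); each section observes
#' latent + Normal(0, `within_patient_sd`), clipped to \[0, 100\]. Sections
#' flagged as tissue loss keep the same expected percent but have their cell
#' count multiplied by 0.3.
#'
#' @param groups a [group_spec()] or list of them.
#' @param seed integer seed; identical seeds give byte-identical tables.
#' @return data.frame with columns patient_id, group, section, percent_cd8,
#'   n_cells, tissue_loss. The number of values clipped at either percent
#'   bound is attached as attribute `"n_clipped"`; the seed as `"seed"`.
#' @export
generate_section_measurements <- function(groups, seed) {
  if (inherits(groups, "group_spec")) groups <- list(groups)
  stopifnot(length(groups) >= 1L, all(vapply(groups, inherits, TRUE, "group_spec")))
  rows <- with_seed(as.integer(seed), {
    n_clipped <- 0L
    pieces <- vector("list", length(groups))
    pid_offset <- 0L
    for (g in seq_along(groups)) {
      gs <- groups[[g]]
      np <- gs$n_patients; ns <- gs$n_sections
      latent <- stats::rnorm(np, gs$mean_percent, gs$between_patient_sd)
      raw <- rep(latent, each = ns) +
        stats::rnorm(np * ns, 0, gs$within_patient_sd)
      n_clipped <- n_clipped + sum(raw < 0 | raw > 100)
      pct <- pmin(100, pmax(0, raw))
      loss <- stats::runif(np * ns) < gs$tissue_loss_rate
      ncell <- stats::rpois(np * ns, gs$base_n_cells)
      ncell[loss] <- as.integer(round(ncell[loss] * 0.3))
      pieces[[g]] <- data.frame(
        patient_id = rep(sprintf("P%04d", pid_offset + seq_len(np)), each = ns),
        group = gs$group_label,
        section = rep(seq_len(ns), np),
        percent_cd8 = pct,
        n_cells = ncell,
        tissue_loss = loss,
        stringsAsFactors = FALSE)
      pid_offset <- pid_offset + np
    }
    out <- do.call(rbind, pieces)
    attr(out, "n_clipped") <- n_clipped
    out
  })
  rownames(rows) <- NULL
  attr(rows, "seed") <- as.integer(seed)
  rows
}

#' Specify a synthetic spatial slide
#'
#' @param roi_polygon polygon vertex matrix in micrometres (columns x, y), or
#'   NULL to use a rectangle of `width_um` by `height_um`.
#' @param width_um,height_um rectangle dimensions when `roi_polygon` is NULL.
#' @param cell_density nucleated cells per square millimetre.
#' @param target_percent area-weighted mean percent of CD8+ cells, \[0, 100\].
#' @param pattern `"uniform"` (constant positivity probability) or
#'   `"margin_enriched"` (probability boosted within `margin_width` of the
#'   ROI boundary, rescaled so the area-weighted mean stays `target_percent`).
#' @param margin_width margin band width in micrometres.
#' @param margin_enrichment multiplicative positivity factor in the margin
#'   (>= 1).
#' @return object of class `slide_spec`.
#' @export
slide_spec <- function(roi_polygon = NULL, width_um = 11314, height_um = 10607,
                       cell_density = 2000, target_percent = 10,
                       pattern = c("uniform", "margin_enriched"),
                       margin_width = 500, margin_enrichment = 3) {
  pattern <- match.arg(pattern)
  if (is.null(roi_polygon)) {
    roi_polygon <- cbind(x = c(0, width_um, width_um, 0),
                         y = c(0, 0, height_um, height_um))
  }
  validate_polygon(roi_polygon)
  if (!is.finite(cell_density) || cell_density <= 0) stop("cell_density must be > 0")
  if (!is.finite(target_percent) || target_percent < 0 || target_percent > 100)
    stop("target_percent must be in [0, 100]")
  if (pattern == "margin_enriched") {
    if (!is_convex_polygon(roi_polygon))
      stop("margin_enriched pattern requires a convex ROI polygon")
    if (!is.finite(margin_enrichment) || margin_enrichment < 1)
      stop("margin_enrichment must be >= 1")
    if (!is.finite(margin_width) || margin_width <= 0)
      stop("margin_width must be > 0")
  }
  structure(list(roi_polygon = roi_polygon, cell_density = cell_density,
                 target_percent = target_percent, pattern = pattern,
                 margin_width = margin_width,
                 margin_enrichment = margin_enrichment),
            class = "slide_spec")
}

#' Positivity-probability model of a slide specification
#'
#' Returns the piecewise-constant cell-positivity probability implied by a
#' [slide_spec()]: the probability inside the margin band, the interior
#' probability, and the exact area fraction of the margin band (computed by
#' insetting the convex ROI). The area-weighted mean always equals
#' `target_percent / 100` by construction. When `margin_width` reaches the
#' ROI inradius the whole ROI is margin and the pattern degenerates to
#' uniform.
#'
#' @param spec a [slide_spec()].
#' @return list with elements `p_margin`, `p_interior`, `f_margin` (margin
#'   area fraction), and `roi_area_um2`.
#' @export
slide_marking_model <- function(spec) {
  stopifnot(inherits(spec, "slide_spec"))
  a_roi <- polygon_area(spec$roi_polygon)
  p0 <- spec$target_percent / 100
  if (spec$pattern == "uniform") {
    return(list(p_margin = p0, p_interior = p0, f_margin = 0,
                roi_area_um2 = a_roi))
  }
  inner <- polygon_inset_convex(spec$roi_polygon, spec$margin_width)
  a_inner <- if (nrow(inner) >= 3L) polygon_area(inner) else 0
  f_margin <- 1 - a_inner / a_roi
  if (f_margin >= 1) {           # margin swallows the ROI: uniform fallback
    return(list(p_margin = p0, p_interior = p0, f_margin = 1,
                roi_area_um2 = a_roi))
  }
  e <- spec$margin_enrichment
  base <- p0 / (f_margin * e + (1 - f_margin))
  p_margin <- base * e
  if (p_margin > 1)
    stop("margin positivity probability exceeds 1; lower target_percent or margin_enrichment")
  list(p_margin = p_margin, p_interior = base, f_margin = f_margin,
       roi_area_um2 = a_roi)
}

#' Generate a synthetic spatial slide
#'
#' Cell count is Poisson(`cell_density` x ROI area); positions are uniform on
#' the ROI; each cell is positive with the piecewise probability from
#' [slide_marking_model()], so the area-weighted positivity mean equals
#' `target_percent / 100` exactly for both patterns.
#'
#' @param spec a [slide_spec()].
#' @param seed integer seed.
#' @return list of class `slide` with elements `geometry` (list of
#'   `roi_polygons` and `bounding_box`) and `cells` (data.frame x_um, y_um,
#'   positive).
#' @export
generate_slide <- function(spec, seed) {
  stopifnot(inherits(spec, "slide_spec"))
  model <- slide_marking_model(spec)
  slide <- with_seed(as.integer(seed), {
    n <- stats::rpois(1L, spec$cell_density * model$roi_area_um2 / 1e6)
    pts <- runif_polygon(n, spec$roi_polygon)
    if (spec$pattern == "margin_enriched" && model$f_margin < 1) {
      in_margin <- dist_to_boundary(pts[, 1L], pts[, 2L], spec$roi_polygon) <=
        spec$margin_width
      p <- ifelse(in_margin, model$p_margin, model$p_interior)
    } else {
      p <- rep(model$p_margin, n)
    }
    positive <- stats::runif(n) < p
    bb <- polygon_bbox(spec$roi_polygon)
    list(geometry = list(roi_polygons = list(spec$roi_polygon),
                         bounding_box = bb),
         cells = data.frame(x_um = unname(pts[, 1L]),
                            y_um = unname(pts[, 2L]),
                            positive = positive))
  })
  slide$seed <- as.integer(seed)
  class(slide) <- "slide"
  slide
}
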