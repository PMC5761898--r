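# Region-level cell counting and percent-positive computation.

#' Count cells inside a region
#'
#' Boundary-inclusive point-in-polygon counting: a cell exactly on the region
#' edge counts as inside. For conserved counts across a partition (grid
#' tiles) use the half-open tie rule implemented in [score_cores()].
#'
#' @param cells data.frame with columns x_um, y_um, positive (logical or
#'   0/1).
#' @param region polygon vertex matrix in micrometres.
#' @return named integer vector c(n_total, n_positive).
#' @export
count_cells <- function(cells, region) {
  stopifnot(all(c("x_um", "y_um", "positive") %in% names(cells)))
  validate_polygon(region)
  inside <- point_in_polygon(cells$x_um, cells$y_um, region)
  c(n_total = sum(inside),
    n_positive = sum(inside & as.logical(cells$positive)))
}

#' Percent positive cells
#'
#' @param n_total total cell count (>= 0).
#' @param n_positive positive cell count, 0 <= n_positive <= n_total.
#' @return `100 * n_positive / n_total`, or `NA_real_` when `n_total` is 0
#'   (the caller decides whether to exclude the region).
#' @export
percent_positive <- function(n_total, n_positive) {
  if (any(n_total < 0) || any(n_positive < 0))
    stop("counts must be non-negative")
  if (any(n_positive > n_total))
    stop("n_positive cannot exceed n_total")
  ifelse(n_total > 0, 100 * n_positive / n_total, NA_real_)
}
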