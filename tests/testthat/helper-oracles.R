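# Independent brute-force oracles used to verify the package's geometry,
# ANOVA decomposition and local-regression code paths.

# Ray-casting point-in-polygon with an explicit boundary check (a point on an
# edge counts as inside). Scalar point; independent of pracma.
oracle_point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  # boundary check: point on any segment?
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    ax <- poly[i, 1]; ay <- poly[i, 2]; bx <- poly[j, 1]; by <- poly[j, 2]
    cross <- (bx - ax) * (py - ay) - (by - ay) * (px - ax)
    if (abs(cross) < 1e-9 * max(1, abs(bx - ax), abs(by - ay)) &&
        px >= min(ax, bx) - 1e-12 && px <= max(ax, bx) + 1e-12 &&
        py >= min(ay, by) - 1e-12 && py <= max(ay, by) + 1e-12)
      return(TRUE)
  }
  inside <- FALSE
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    ax <- poly[i, 1]; ay <- poly[i, 2]; bx <- poly[j, 1]; by <- poly[j, 2]
    if ((ay > py) != (by > py)) {
      xint <- ax + (py - ay) / (by - ay) * (bx - ax)
      if (px < xint) inside <- !inside
    }
  }
  inside
}

# Sequential (type-I) sums of squares by explicit least-squares projection:
# RSS differences between nested design matrices solved via the normal
# equations, independent of stats::lm/anova.
oracle_sequential_ss <- function(y, patient, section) {
  rss <- function(X) {
    beta <- qr.solve(crossprod(X), crossprod(X, y))
    sum((y - X %*% beta)^2)
  }
  dummy <- function(f) {
    f <- factor(f)
    if (nlevels(f) < 2L) return(NULL)
    stats::model.matrix(~f)[, -1L, drop = FALSE]
  }
  X0 <- matrix(1, length(y), 1L)
  X1 <- cbind(X0, dummy(patient))
  X2 <- cbind(X1, dummy(section))
  rss0 <- rss(X0); rss1 <- rss(X1); rss2 <- rss(X2)
  list(ss_patient = rss0 - rss1, ss_section = rss1 - rss2,
       ss_residual = rss2, ss_total = rss0)
}

# Direct tricube weighted least-squares solve of a local quadratic fit at x0,
# using the q = floor(n * span) nearest-neighbour bandwidth.
oracle_tricube_fit <- function(x, y, x0, span = 0.75, degree = 2) {
  n <- length(x)
  q <- floor(n * span)
  d <- abs(x - x0)
  lambda <- sort(d)[q]
  w <- pmax(1 - (d / lambda)^3, 0)^3
  X <- stats::poly(x - x0, degree = degree, raw = TRUE)
  X <- cbind(1, X)
  beta <- solve(t(X) %*% (w * X), t(X) %*% (w * y))
  beta[1L]
}

# Small measurement table from a named list of per-patient section values.
make_measurements <- function(values, group = "g") {
  do.call(rbind, lapply(names(values), function(p) {
    v <- values[[p]]
    data.frame(patient_id = p, group = group, section = seq_along(v),
               percent_cd8 = v, n_cells = 1000L, tissue_loss = FALSE,
               stringsAsFactors = FALSE)
  }))
}
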