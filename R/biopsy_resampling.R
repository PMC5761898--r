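# Core-biopsy subsampling: draw 1-5 cores per slide or block without
# replacement, summarize by mean or max, and quantify how well the summary
# tracks the parent mean (within-1-SD rates, out-of-bag differences, loess
# variability curves, ROC across candidate cutoffs).

#' Slide (or block) reference statistics from its cores
#'
#' The set of retained cores on a slide serves as the parent population with
#' known mean and variance against which subsamples are judged.
#'
#' @param core_percents numeric vector of per-core percent CD8 values.
#' @return list of class `slide_reference`: core_mean, core_sd (sample SD,
#'   n - 1 denominator; `NA_real_` for a single core), n_cores.
#' @export
slide_reference <- function(core_percents) {
  if (length(core_percents) < 1L) stop("need >= 1 core")
  if (any(!is.finite(core_percents))) stop("core percents must be finite")
  list(core_mean = mean(core_percents),
       core_sd = if (length(core_percents) >= 2L) stats::sd(core_percents)
       else NA_real_,
       n_cores = length(core_percents))
}

#' Subsample k cores without replacement and summarize
#'
#' Per replicate, `k` distinct cores are drawn; the estimate is the mean or
#' maximum of the drawn percents; the within-1-SD indicator is
#' `|estimate - core_mean| <= core_sd`; the out-of-bag difference is
#' `summary(drawn) - summary(not drawn)`. In restricted mode (the default)
#' the slide must have at least `min_cores` cores — mirroring the restriction
#' of slide-level analysis to slides with >= 15 fragments — and `k` must
#' leave a non-empty out-of-bag set.
#'
#' @param core_percents per-core percent CD8 values of one slide or block.
#' @param k cores drawn per replicate (1-5 in the study design; any
#'   `k < n_cores` accepted).
#' @param summary_stat "mean" or "max".
#' @param n_reps replicates (default 1000).
#' @param seed integer seed.
#' @param min_cores minimum cores required in restricted mode (default 15).
#' @param restricted enforce the `min_cores` floor (default TRUE);
#'   unrestricted mode exists for small enumerable test cases.
#' @return list of class `subsample_summary`: k, summary_stat, n_reps,
#'   reference (the [slide_reference()]), estimates (per-rep), within_1sd_rate,
#'   oob_diffs (per-rep), oob_diff_mean, oob_diff_sd.
#' @export
subsample_cores <- function(core_percents, k, summary_stat = c("mean", "max"),
                            n_reps = 1000L, seed, min_cores = 15L,
                            restricted = TRUE) {
  summary_stat <- match.arg(summary_stat)
  n <- length(core_percents)
  if (k < 1L) stop("k must be >= 1")
  if (k >= n) stop("k must leave a non-empty out-of-bag set (k < n_cores)")
  if (restricted && n < max(k + 1L, min_cores))
    stop(sprintf("restricted mode needs >= %d cores; slide has %d",
                 max(k + 1L, min_cores), n))
  if (n_reps < 1L) stop("n_reps must be >= 1")
  ref <- slide_reference(core_percents)
  sfun <- if (summary_stat == "mean") mean else max
  total <- sum(core_percents)
  res <- with_seed(as.integer(seed), {
    est <- oob <- numeric(n_reps)
    for (r in seq_len(n_reps)) {
      sel <- sample.int(n, k)
      drawn <- core_percents[sel]
      est[r] <- sfun(drawn)
      oob_val <- if (summary_stat == "mean")
        (total - sum(drawn)) / (n - k) else max(core_percents[-sel])
      oob[r] <- est[r] - oob_val
    }
    list(est = est, oob = oob)
  })
  within <- if (is.na(ref$core_sd)) NA_real_ else
    mean(abs(res$est - ref$core_mean) <= ref$core_sd)
  structure(list(k = as.integer(k), summary_stat = summary_stat,
                 n_reps = as.integer(n_reps), reference = ref,
                 estimates = res$est, within_1sd_rate = within,
                 oob_diffs = res$oob, oob_diff_mean = mean(res$oob),
                 oob_diff_sd = stats::sd(res$oob), seed = as.integer(seed)),
            class = "subsample_summary")
}

#' Pool the cores of a block's slides
#'
#' Concatenates all retained cores across the slides of a tumor block;
#' block-level mean and SD are computed over the pooled cores, unweighted by
#' slide. A cell-count-weighted mean is available when per-core cell counts
#' are supplied.
#'
#' @param slides list of numeric vectors (per-slide core percents).
#' @param n_cells optional list of per-core cell counts matching `slides`;
#'   when given, a cell-weighted pooled mean is also reported.
#' @return list of class `block_reference`: pooled (vector of all core
#'   percents), core_mean, core_sd, n_cores, and weighted_mean when
#'   requested.
#' @export
block_pool <- function(slides, n_cells = NULL) {
  if (length(slides) < 1L) stop("empty block")
  pooled <- unlist(slides, use.names = FALSE)
  if (length(pooled) < 1L) stop("block has no retained cores")
  ref <- slide_reference(pooled)
  out <- list(pooled = pooled, core_mean = ref$core_mean,
              core_sd = ref$core_sd, n_cores = ref$n_cores)
  if (!is.null(n_cells)) {
    w <- unlist(n_cells, use.names = FALSE)
    stopifnot(length(w) == length(pooled))
    out$weighted_mean <- sum(pooled * w) / sum(w)
  }
  class(out) <- "block_reference"
  out
}

#' ROC of core-subsample classification across candidate cutoffs
#'
#' Each unit (slide or block) has truth = its core mean, classed high when
#' `truth >= cutoff`. Per replicate and unit, `k` cores are drawn without
#' replacement and the mean/max summary is classed against the same cutoff.
#' Per-replicate sensitivity, specificity and accuracy are computed across
#' units and averaged over replicates (pooled-count versions are also
#' reported). Cutoffs leaving a class empty yield `NA` for the corresponding
#' metric rather than a zero fill.
#'
#' @param units named list of numeric vectors: per-unit core percents.
#' @param ks integer vector of subsample sizes (default 1:5).
#' @param summary_stats character vector from {"mean", "max"}.
#' @param cutoffs percent cutoffs (default c(1, 2, 5, 10)).
#' @param truth_level label recorded in the output ("slide" or "block").
#' @param n_reps replicates (default 1000).
#' @param seed integer seed.
#' @param min_cores,restricted see [subsample_cores()].
#' @return data.frame with one row per cutoff x k x summary_stat:
#'   sensitivity, specificity, accuracy (percent, per-replicate means),
#'   sensitivity_pooled, specificity_pooled, accuracy_pooled, n_units,
#'   n_true_high.
#' @export
roc_over_cutoffs <- function(units, ks = 1:5,
                             summary_stats = c("mean", "max"),
                             cutoffs = c(1, 2, 5, 10),
                             truth_level = c("slide", "block"),
                             n_reps = 1000L, seed, min_cores = 15L,
                             restricted = TRUE) {
  truth_level <- match.arg(truth_level)
  if (length(units) < 1L) stop("empty unit list")
  summary_stats <- match.arg(summary_stats, c("mean", "max"),
                             several.ok = TRUE)
  n_unit <- length(units)
  truths <- vapply(units, mean, numeric(1L))
  if (restricted) {
    short <- vapply(units, length, integer(1L)) < max(max(ks) + 1L, min_cores)
    if (any(short))
      stop(sprintf("%d unit(s) below the %d-core floor in restricted mode",
                   sum(short), max(max(ks) + 1L, min_cores)))
  } else if (any(vapply(units, length, integer(1L)) < max(ks)))
    stop("some unit has fewer cores than max(ks)")

  # one estimate matrix (n_reps x n_unit) per k x summary, shared across
  # cutoffs so every cutoff judges the same draws
  est <- with_seed(as.integer(seed), {
    out <- list()
    for (k in ks) for (ss in summary_stats) {
      sfun <- if (ss == "mean") mean else max
      mat <- matrix(NA_real_, n_reps, n_unit)
      for (u in seq_len(n_unit)) {
        v <- units[[u]]
        for (r in seq_len(n_reps))
          mat[r, u] <- sfun(v[sample.int(length(v), k)])
      }
      out[[paste(k, ss)]] <- mat
    }
    out
  })

  rows <- list()
  for (cutoff in cutoffs) {
    true_high <- truths >= cutoff
    n_hi <- sum(true_high); n_lo <- n_unit - n_hi
    for (k in ks) for (ss in summary_stats) {
      mat <- est[[paste(k, ss)]]
      call_high <- mat >= cutoff
      ok <- sweep(call_high, 2L, true_high, `==`)
      acc <- rowMeans(ok)
      sens <- if (n_hi > 0) rowMeans(call_high[, true_high, drop = FALSE])
      else rep(NA_real_, n_reps)
      spec <- if (n_lo > 0) rowMeans(!call_high[, !true_high, drop = FALSE])
      else rep(NA_real_, n_reps)
      rows[[length(rows) + 1L]] <- data.frame(
        cutoff = cutoff, k = k, summary_stat = ss,
        truth_level = truth_level,
        sensitivity = 100 * mean(sens), specificity = 100 * mean(spec),
        accuracy = 100 * mean(acc),
        sensitivity_pooled = if (n_hi > 0)
          100 * mean(call_high[, true_high, drop = FALSE]) else NA_real_,
        specificity_pooled = if (n_lo > 0)
          100 * mean(!call_high[, !true_high, drop = FALSE]) else NA_real_,
        accuracy_pooled = 100 * mean(ok),
        n_units = n_unit, n_true_high = n_hi,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Loess curve of out-of-bag variability versus mean staining
#'
#' Tricube-weighted local quadratic regression (via [stats::loess()] with
#' exact direct fitting) of a per-unit variability measure on the unit's mean
#' CD8 percent, evaluated on an evenly spaced predictor grid. On the log2
#' scale the predictor becomes `log2(x + 0.1)`; the 0.1 offset keeps
#' zero-percent units finite.
#'
#' @param x per-unit mean CD8 percents.
#' @param y per-unit variability values (e.g. `oob_diff_sd`).
#' @param span loess span in (0, 1] (default 0.75).
#' @param degree local polynomial degree (default 2).
#' @param scale "raw" or "log2" predictor scale.
#' @param n_grid grid points (default 50).
#' @return data.frame with columns grid (predictor scale used), x (original
#'   percent scale) and fit.
#' @export
loess_sd_curve <- function(x, y, span = 0.75, degree = 2,
                           scale = c("raw", "log2"), n_grid = 50L) {
  scale <- match.arg(scale)
  if (!is.finite(span) || span <= 0 || span > 1) stop("span must be in (0, 1]")
  stopifnot(length(x) == length(y))
  xs <- if (scale == "log2") log2(x + 0.1) else x
  if (length(unique(xs)) < max(5L, degree + 2L))
    stop("need at least ", max(5L, degree + 2L), " distinct predictor values")
  fit <- stats::loess(y ~ xs, span = span, degree = degree,
                      family = "gaussian",
                      control = stats::loess.control(surface = "direct"))
  grid <- seq(min(xs), max(xs), length.out = n_grid)
  pred <- stats::predict(fit, newdata = data.frame(xs = grid))
  data.frame(grid = grid,
             x = if (scale == "log2") 2^grid - 0.1 else grid,
             fit = as.numeric(pred))
}
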