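# Section-level resampling: is one (or two) step sections enough to classify
# a tumor block as CD8-high versus CD8-low against a cohort-median cutoff?

#' Per-patient truth values and cohort-median cutoff
#'
#' The mean percent CD8 across a patient's sections is that patient's true
#' value; the cohort median of the true values (midpoint convention for even
#' counts) is the candidate cutoff; a patient is CD8-high when
#' `true_value >= cutoff`.
#'
#' @inheritParams fixed_effects_anova
#' @return list of class `truth_table`: `truth` data.frame (patient_id,
#'   true_value, true_class in {"high","low"}) and `cutoff`.
#' @export
patient_truth_and_cutoff <- function(measurements, exclude_tissue_loss = FALSE) {
  m <- validate_measurements(measurements)
  if (exclude_tissue_loss && "tissue_loss" %in% names(m))
    m <- m[!m$tissue_loss, , drop = FALSE]
  if (nrow(m) == 0L) stop("empty cohort")
  mu <- tapply(m$percent_cd8, m$patient_id, mean)
  cutoff <- stats::median(mu)
  truth <- data.frame(patient_id = names(mu),
                      true_value = as.numeric(mu),
                      true_class = ifelse(mu >= cutoff, "high", "low"),
                      stringsAsFactors = FALSE)
  rownames(truth) <- NULL
  structure(list(truth = truth, cutoff = unname(cutoff)),
            class = "truth_table")
}

#' Resampled agreement of few-section classification with block truth
#'
#' Two schemes, both classifying against the cutoff fixed from the full
#' cohort:
#' \describe{
#'   \item{sections_only}{per replicate, draw `k_sections` sections with
#'     replacement within each of the original patients (technical
#'     reproducibility of the fixed cohort);}
#'   \item{patients_then_sections}{per replicate, draw patients with
#'     replacement, then sections within each drawn patient (variability
#'     expected in a future cohort of the same size).}
#' }
#' The k drawn values are summarized by their mean or maximum, a patient is
#' called high when the summary is >= the cutoff, and per-replicate overall
#' agreement is the fraction of (drawn) patients whose call matches their
#' true class. Sensitivity (among true-high) and specificity (among
#' true-low) are computed per replicate; replicates lacking a class are
#' skipped for that metric and counted.
#'
#' @inheritParams fixed_effects_anova
#' @param k_sections sections drawn per patient per replicate (>= 1).
#' @param summary_stat "mean" or "max" of the drawn sections.
#' @param scheme "sections_only" or "patients_then_sections".
#' @param n_reps replicates (default 1000).
#' @param seed integer seed.
#' @return object of class `agreement_summary`: list with scheme, k_sections,
#'   summary_stat, n_reps, cutoff, agreement_mean, agreement_ci95 (2.5/97.5
#'   percentiles over replicates), sensitivity_mean, specificity_mean,
#'   n_skipped_sensitivity, n_skipped_specificity, and the per-replicate
#'   vectors agreement, sensitivity, specificity.
#' @export
resample_section_classification <- function(measurements, k_sections,
                                            summary_stat = c("mean", "max"),
                                            scheme = c("sections_only",
                                                       "patients_then_sections"),
                                            n_reps = 1000L, seed,
                                            exclude_tissue_loss = FALSE) {
  summary_stat <- match.arg(summary_stat)
  scheme <- match.arg(scheme)
  if (k_sections < 1L) stop("k_sections must be >= 1")
  if (n_reps < 1L) stop("n_reps must be >= 1")
  m <- validate_measurements(measurements)
  if (exclude_tissue_loss && "tissue_loss" %in% names(m))
    m <- m[!m$tissue_loss, , drop = FALSE]
  tt <- patient_truth_and_cutoff(m)
  cutoff <- tt$cutoff
  sections <- split(m$percent_cd8, m$patient_id)
  ids <- tt$truth$patient_id
  sections <- sections[ids]
  true_high <- tt$truth$true_class == "high"
  sfun <- if (summary_stat == "mean") mean else max
  n_pat <- length(ids)

  res <- with_seed(as.integer(seed), {
    agreement <- sens <- spec <- numeric(n_reps)
    for (r in seq_len(n_reps)) {
      pats <- if (scheme == "sections_only") seq_len(n_pat) else
        sample.int(n_pat, n_pat, replace = TRUE)
      est <- vapply(pats, function(i) {
        v <- sections[[i]]
        sfun(v[sample.int(length(v), k_sections, replace = TRUE)])
      }, numeric(1L))
      call_high <- est >= cutoff
      truth_r <- true_high[pats]
      ok <- call_high == truth_r
      agreement[r] <- mean(ok)
      sens[r] <- if (any(truth_r)) mean(call_high[truth_r]) else NA_real_
      spec[r] <- if (any(!truth_r)) mean(!call_high[!truth_r]) else NA_real_
    }
    list(agreement = agreement, sens = sens, spec = spec)
  })
  ci <- stats::quantile(res$agreement, c(0.025, 0.975), names = FALSE)
  structure(list(
    scheme = scheme, k_sections = as.integer(k_sections),
    summary_stat = summary_stat, n_reps = as.integer(n_reps),
    cutoff = cutoff,
    agreement_mean = 100 * mean(res$agreement),
    agreement_ci95 = 100 * ci,
    sensitivity_mean = 100 * mean(res$sens, na.rm = TRUE),
    specificity_mean = 100 * mean(res$spec, na.rm = TRUE),
    n_skipped_sensitivity = sum(is.na(res$sens)),
    n_skipped_specificity = sum(is.na(res$spec)),
    agreement = 100 * res$agreement,
    sensitivity = 100 * res$sens,
    specificity = 100 * res$spec,
    seed = as.integer(seed)),
    class = "agreement_summary")
}

#' @export
print.agreement_summary <- function(x, ...) {
  cat(sprintf(
    "Section resampling (%s, k = %d, %s, %d reps)\n", x$scheme,
    x$k_sections, x$summary_stat, x$n_reps))
  cat(sprintf("  cutoff: %.2f%% CD8+\n", x$cutoff))
  cat(sprintf("  agreement: %.1f%% (95%% CI %.1f-%.1f%%)\n",
              x$agreement_mean, x$agreement_ci95[1L], x$agreement_ci95[2L]))
  cat(sprintf("  sensitivity: %.1f%%  specificity: %.1f%%\n",
              x$sensitivity_mean, x$specificity_mean))
  invisible(x)
}
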