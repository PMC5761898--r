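# Patient-versus-section variance decomposition: sequential two-factor ANOVA
# and a one-way random-intercept model with the intraclass correlation
# coefficient (ICC).

#' Fixed-effects ANOVA of percent CD8 on patient and section
#'
#' Fits the additive model `percent_cd8 ~ patient + section` by least squares
#' with both terms as factors (section levels are the common step depths
#' 1..n) and reports the sequential (type-I) sums of squares with patient
#' entered first. "Percent of variability explained" by a term is
#' `100 * SS_term / SS_total` from that decomposition; the F test for the
#' section term asks whether section-to-section variability matters once
#' patients are accounted for.
#'
#' @param measurements data.frame with columns patient_id, section,
#'   percent_cd8 (e.g. from [generate_section_measurements()]).
#' @param exclude_tissue_loss drop rows flagged tissue_loss before fitting.
#' @return object of class `anova_table`: list with ss_patient, ss_section,
#'   ss_residual, ss_total, df_patient, df_section, df_residual, f_section,
#'   p_section, pct_var_patient, pct_var_section (percents of total SS;
#'   `NA_real_` when total SS is zero).
#' @export
fixed_effects_anova <- function(measurements, exclude_tissue_loss = FALSE) {
  m <- validate_measurements(measurements)
  if (exclude_tissue_loss && "tissue_loss" %in% names(m))
    m <- m[!m$tissue_loss, , drop = FALSE]
  if (length(unique(m$patient_id)) < 2L)
    stop("need >= 2 patients for the patient factor")
  if (max(table(m$patient_id)) < 2L)
    stop("need >= 2 sections for at least one patient")
  m$patient_id <- factor(m$patient_id)
  m$section <- factor(m$section)
  fit <- stats::lm(percent_cd8 ~ patient_id + section, data = m)
  # sequential SS, patient first; degenerate exact fits legitimately occur
  # (e.g. zero within-patient variance), so the perfect-fit warning from
  # anova.lm is muffled
  at <- withCallingHandlers(
    stats::anova(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  ss <- at[["Sum Sq"]]; df <- at[["Df"]]
  ss_total <- sum(ss)
  pct <- if (ss_total > 0) 100 * ss[1:2] / ss_total else c(NA_real_, NA_real_)
  structure(list(
    ss_patient = ss[1L], ss_section = ss[2L], ss_residual = ss[3L],
    ss_total = ss_total,
    df_patient = df[1L], df_section = df[2L], df_residual = df[3L],
    f_section = at[["F value"]][2L], p_section = at[["Pr(>F)"]][2L],
    pct_var_patient = pct[1L], pct_var_section = pct[2L]),
    class = "anova_table")
}

#' One-way random-intercept variance components and ICC
#'
#' Method-of-moments (ANOVA) estimator for the model
#' y_ij = mu + b_i + e_ij with patient effect b_i ~ (0, sigma2_patient) and
#' residual e_ij ~ (0, sigma2_residual):
#' `sigma2_residual = MSW` and `sigma2_patient = (MSB - MSW) / n0`, truncated
#' at zero, where n0 is the group size for balanced data and the standard
#' unbalanced correction `(N - sum(n_i^2) / N) / (a - 1)` otherwise. For
#' balanced one-way designs this coincides with REML. The ICC is
#' `sigma2_patient / (sigma2_patient + sigma2_residual)`.
#'
#' @inheritParams fixed_effects_anova
#' @return object of class `variance_components`: list with sigma2_patient,
#'   sigma2_residual, icc (all >= 0; icc in \[0, 1\], `NA_real_` when total
#'   variance is zero), msb, msw, n0, n_patients, n_obs.
#' @export
random_intercept_icc <- function(measurements, exclude_tissue_loss = FALSE) {
  m <- validate_measurements(measurements)
  if (exclude_tissue_loss && "tissue_loss" %in% names(m))
    m <- m[!m$tissue_loss, , drop = FALSE]
  y <- m$percent_cd8
  g <- factor(m$patient_id)
  a <- nlevels(g)
  if (a < 2L) stop("need >= 2 patients")
  n_i <- as.numeric(table(g))
  N <- length(y)
  ybar_i <- tapply(y, g, mean)
  ybar <- mean(y)
  msb <- sum(n_i * (ybar_i - ybar)^2) / (a - 1)
  msw <- if (N > a) sum((y - ybar_i[g])^2) / (N - a) else 0
  n0 <- if (length(unique(n_i)) == 1L) n_i[1L] else
    (N - sum(n_i^2) / N) / (a - 1)
  s2p <- max(0, (msb - msw) / n0)
  s2r <- msw
  icc <- if (s2p + s2r > 0) s2p / (s2p + s2r) else NA_real_
  structure(list(sigma2_patient = s2p, sigma2_residual = s2r, icc = icc,
                 msb = msb, msw = msw, n0 = unname(n0),
                 n_patients = a, n_obs = N),
            class = "variance_components")
}

# Shared column/range validation for section-measurement tables.
validate_measurements <- function(measurements) {
  req <- c("patient_id", "section", "percent_cd8")
  miss <- setdiff(req, names(measurements))
  if (length(miss))
    stop("measurement table lacks columns: ", paste(miss, collapse = ", "))
  bad <- which(!is.finite(measurements$percent_cd8) |
                 measurements$percent_cd8 < 0 | measurements$percent_cd8 > 100)
  if (length(bad))
    stop("percent_cd8 outside [0, 100] at row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "))
  key <- paste(measurements$patient_id, measurements$section)
  if (anyDuplicated(key))
    stop("duplicate (patient_id, section) at row(s) ",
         paste(utils::head(which(duplicated(key)), 5L), collapse = ", "))
  measurements
}
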