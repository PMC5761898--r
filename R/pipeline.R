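# End-to-end orchestration: synthetic cohort -> variance components ->
# section resampling -> virtual cores -> core resampling -> ROC, with one
# master seed expanded into per-stage seeds.

# Fixed stage order for seed derivation (see derive_stage_seed()).
.stage_names <- c("sections", "slides", "section_resampling",
                  "core_resampling", "roc")

#' Default pipeline configuration
#'
#' Describes a complete demo run: a study-like cohort of 25 patients times 8
#' step sections ([default_group_specs()]), three spatial slides per tumor
#' block (each block's slides share the patient's section-table mean as
#' target percent; every fifth patient gets a margin-enriched CD8 pattern),
#' a 14.14 x 8.49 mm rectangular ROI tiled into 60 cores of 2 square
#' millimetres, and 1000-replicate resampling throughout.
#'
#' @param seed master seed; per-stage seeds are
#'   `derive_stage_seed(seed, i)` for stages (1) section generation,
#'   (2) slide generation, (3) section resampling, (4) core subsampling,
#'   (5) ROC draws.
#' @param out_dir output directory for CSV tables, or NULL to skip writing.
#' @param n_reps resampling replicates for every stochastic stage.
#' @param slides_per_block spatial slides generated per tumor block.
#' @param cell_density nucleated cells per square millimetre on synthetic
#'   slides.
#' @param slide_width_um,slide_height_um rectangular ROI dimensions.
#' @param margin_every every n-th patient's slides use the margin-enriched
#'   spatial pattern (0 disables).
#' @param measurements_path optional path to an existing measurement CSV;
#'   when given, the section-generation stage is skipped and the file is
#'   read instead.
#' @param groups cohort specification, a list of [group_spec()] objects
#'   (default [default_group_specs()]).
#' @return list of class `run_config`.
#' @export
default_run_config <- function(seed = 20170101L, out_dir = NULL,
                               n_reps = 1000L, slides_per_block = 3L,
                               cell_density = 400,
                               slide_width_um = 10 * sqrt(2) * 1000,
                               slide_height_um = 6 * sqrt(2) * 1000,
                               margin_every = 5L,
                               measurements_path = NULL,
                               groups = default_group_specs()) {
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 n_reps = as.integer(n_reps),
                 groups = groups,
                 slides_per_block = as.integer(slides_per_block),
                 cell_density = cell_density,
                 slide_width_um = slide_width_um,
                 slide_height_um = slide_height_um,
                 margin_every = as.integer(margin_every),
                 grid_config = core_grid_config(),
                 ks = 1:5, cutoffs = c(1, 2, 5, 10), min_cores = 15L,
                 measurements_path = measurements_path),
            class = "run_config")
}

#' Run the full sampling-adequacy pipeline
#'
#' Executes, in order: synthetic section generation (or reading an existing
#' table), ANOVA and ICC variance components (with and without tissue-loss
#' sections), section resampling under both schemes, spatial slide
#' generation, core-grid tessellation and scoring, slide- and block-level
#' core subsampling, loess variability curves, and ROC across cutoffs.
#' Identical config and seed give identical outputs. No stage mutates its
#' inputs.
#'
#' @param config a [default_run_config()].
#' @return list of class `report_bundle` with per-stage tables
#'   (`measurements`, `anova`, `variance_components`, `section_agreement`,
#'   `cores`, `slide_subsampling`, `block_subsampling`, `loess_curves`,
#'   `roc`) and `metadata` (master seed, per-stage seeds, warnings).
#' @export
run_pipeline <- function(config = default_run_config()) {
  stopifnot(inherits(config, "run_config"))
  seeds <- vapply(seq_along(.stage_names), function(i)
    derive_stage_seed(config$seed, i), integer(1L))
  names(seeds) <- .stage_names
  warnings <- character(0L)

  ## stage 1: section-level cohort
  measurements <- if (!is.null(config$measurements_path)) {
    if (!file.exists(config$measurements_path))
      stop("stage sections: input file not found: ", config$measurements_path)
    read_measurements(config$measurements_path)
  } else {
    generate_section_measurements(config$groups, seeds[["sections"]])
  }

  ## stage 2: variance components
  av <- fixed_effects_anova(measurements)
  vc <- random_intercept_icc(measurements)
  vc_noloss <- random_intercept_icc(measurements, exclude_tissue_loss = TRUE)
  anova_tab <- data.frame(
    term = c("patient", "section", "residual"),
    ss = c(av$ss_patient, av$ss_section, av$ss_residual),
    df = c(av$df_patient, av$df_section, av$df_residual),
    pct_of_total_ss = c(av$pct_var_patient, av$pct_var_section,
                        100 - av$pct_var_patient - av$pct_var_section),
    f = c(NA, av$f_section, NA), p = c(NA, av$p_section, NA))
  vc_tab <- data.frame(
    analysis = c("all_sections", "tissue_loss_excluded"),
    sigma2_patient = c(vc$sigma2_patient, vc_noloss$sigma2_patient),
    sigma2_residual = c(vc$sigma2_residual, vc_noloss$sigma2_residual),
    icc = c(vc$icc, vc_noloss$icc))

  ## stage 3: section resampling, both schemes, k = 1 and 2
  sec_rows <- list()
  for (scheme in c("sections_only", "patients_then_sections"))
    for (k in 1:2) for (ss in if (k == 2) c("mean", "max") else "mean") {
      ag <- resample_section_classification(
        measurements, k, ss, scheme, n_reps = config$n_reps,
        seed = derive_stage_seed(seeds[["section_resampling"]],
                                 length(sec_rows) + 1L))
      sec_rows[[length(sec_rows) + 1L]] <- data.frame(
        scheme = scheme, k = k, summary_stat = ss, cutoff = ag$cutoff,
        agreement = ag$agreement_mean, agreement_lo = ag$agreement_ci95[1L],
        agreement_hi = ag$agreement_ci95[2L],
        sensitivity = ag$sensitivity_mean, specificity = ag$specificity_mean)
    }
  section_agreement <- do.call(rbind, sec_rows)

  ## stage 4: spatial slides + core grids
  pat_means <- tapply(measurements$percent_cd8, measurements$patient_id, mean)
  pat_ids <- names(pat_means)
  core_rows <- list()
  slide_cores <- list()   # percent vectors keyed by slide id
  block_cores <- list()   # lists of percent vectors keyed by patient id
  slide_counter <- 0L
  for (i in seq_along(pat_ids)) {
    pattern <- if (config$margin_every > 0L && i %% config$margin_every == 0L)
      "margin_enriched" else "uniform"
    for (s in seq_len(config$slides_per_block)) {
      slide_counter <- slide_counter + 1L
      spec <- slide_spec(width_um = config$slide_width_um,
                         height_um = config$slide_height_um,
                         cell_density = config$cell_density,
                         target_percent = min(100, max(0, pat_means[i])),
                         pattern = pattern)
      slide <- generate_slide(spec,
                              derive_stage_seed(seeds[["slides"]],
                                                slide_counter))
      grid <- generate_core_grid(slide$geometry, config$grid_config)
      scored <- withCallingHandlers(
        score_cores(grid, slide$cells, slide$geometry),
        warning = function(w) {
          warnings <<- c(warnings, conditionMessage(w))
          invokeRestart("muffleWarning")
        })
      sid <- sprintf("%s_s%d", pat_ids[i], s)
      core_rows[[slide_counter]] <- cbind(slide_id = sid,
                                          patient_id = pat_ids[i],
                                          as.data.frame(scored))
      slide_cores[[sid]] <- scored$percent_cd8
      block_cores[[pat_ids[i]]] <- c(block_cores[[pat_ids[i]]],
                                     list(scored$percent_cd8))
    }
  }
  cores_tab <- do.call(rbind, core_rows)

  ## stage 5: slide- and block-level subsampling + loess + ROC
  eligible <- names(slide_cores)[vapply(slide_cores, length, integer(1L)) >=
                                   max(max(config$ks) + 1L, config$min_cores)]
  sub_rows <- list()
  sub_seed_i <- 0L
  subsample_unit <- function(unit_id, level, percents) {
    for (k in config$ks) for (ss in c("mean", "max")) {
      sub_seed_i <<- sub_seed_i + 1L
      sub <- subsample_cores(percents, k, ss, n_reps = config$n_reps,
                             seed = derive_stage_seed(
                               seeds[["core_resampling"]], sub_seed_i),
                             min_cores = config$min_cores)
      sub_rows[[length(sub_rows) + 1L]] <<- data.frame(
        unit_id = unit_id, level = level, k = k, summary_stat = ss,
        core_mean = sub$reference$core_mean, core_sd = sub$reference$core_sd,
        n_cores = sub$reference$n_cores,
        within_1sd_rate = sub$within_1sd_rate,
        oob_diff_mean = sub$oob_diff_mean, oob_diff_sd = sub$oob_diff_sd)
    }
  }
  for (sid in eligible) subsample_unit(sid, "slide", slide_cores[[sid]])
  n_slide_rows <- length(sub_rows)
  blocks <- lapply(block_cores, function(b) block_pool(b)$pooled)
  for (bid in names(blocks)) subsample_unit(bid, "block", blocks[[bid]])
  subsampling <- do.call(rbind, sub_rows)
  slide_sub <- subsampling[subsampling$level == "slide", , drop = FALSE]
  block_sub <- subsampling[subsampling$level == "block", , drop = FALSE]

  loess_rows <- list()
  for (level in c("slide", "block")) {
    d <- subsampling[subsampling$level == level & subsampling$k == 1L &
                       subsampling$summary_stat == "mean", , drop = FALSE]
    for (sc in c("raw", "log2")) {
      cv <- loess_sd_curve(d$core_mean, d$oob_diff_sd, scale = sc)
      loess_rows[[length(loess_rows) + 1L]] <-
        cbind(level = level, scale = sc, k = 1L, cv)
    }
  }
  loess_curves <- do.call(rbind, loess_rows)

  roc_slide <- roc_over_cutoffs(slide_cores[eligible], ks = config$ks,
                                cutoffs = config$cutoffs,
                                truth_level = "slide",
                                n_reps = config$n_reps,
                                seed = derive_stage_seed(seeds[["roc"]], 1L),
                                min_cores = config$min_cores)
  roc_block <- roc_over_cutoffs(blocks, ks = config$ks,
                                cutoffs = config$cutoffs,
                                truth_level = "block",
                                n_reps = config$n_reps,
                                seed = derive_stage_seed(seeds[["roc"]], 2L),
                                min_cores = config$min_cores)
  roc <- rbind(roc_slide, roc_block)

  bundle <- structure(list(
    measurements = measurements, anova = anova_tab,
    variance_components = vc_tab, section_agreement = section_agreement,
    cores = cores_tab, slide_subsampling = slide_sub,
    block_subsampling = block_sub, loess_curves = loess_curves, roc = roc,
    metadata = list(master_seed = config$seed, stage_seeds = seeds,
                    n_slides = slide_counter,
                    n_slides_eligible = length(eligible),
                    warnings = warnings,
                    package_version = as.character(
                      utils::packageVersion("cd8sample")))),
    class = "report_bundle")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(tab, name)
      utils::write.csv(tab, file.path(config$out_dir, paste0(name, ".csv")),
                       row.names = FALSE)
    wr(bundle$anova, "anova")
    wr(bundle$variance_components, "variance_components")
    wr(bundle$section_agreement, "section_agreement")
    wr(bundle$cores, "cores")
    wr(bundle$slide_subsampling, "slide_subsampling")
    wr(bundle$block_subsampling, "block_subsampling")
    wr(bundle$loess_curves, "loess_curves")
    wr(bundle$roc, "roc")
    write_measurements(bundle$measurements,
                       file.path(config$out_dir, "measurements.csv"))
    jsonlite::write_json(list(master_seed = config$seed,
                              stage_seeds = as.list(seeds),
                              warnings = warnings),
                         file.path(config$out_dir, "metadata.json"),
                         auto_unbox = TRUE)
  }
  bundle
}
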