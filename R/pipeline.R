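# End-to-end orchestration: simulate (or load) -> annotate -> exclude ->
# serial-dependence model comparison (previous-probe and distractor
# predictors; full data and similarity split) -> RT analysis.

#' Pipeline configuration
#'
#' @param seed Master seed; every stage derives its own substream from it,
#'   so toggling one stage does not perturb another's draws. Mandatory when
#'   simulating.
#' @param design [design_params()] for the simulation stage.
#' @param observers Observer parameters (single [observer_params()] or
#'   list), used when `trials_path` is `NULL`.
#' @param trials_path Optional path to an existing trial table; disables
#'   the simulation stage.
#' @param width_grid Kernel-width grid for the model fits.
#' @param models Model names to compare.
#' @param similarity_threshold Similarity-split threshold in degrees,
#'   in (0, 90).
#' @param run_similarity_split,run_rt_model Stage toggles.
#' @param out_dir Optional directory: intermediate tables and the report
#'   are written there as delimited text / JSON.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = NULL,
                            design = design_params(n_participants = 18L),
                            observers = observer_params(),
                            trials_path = NULL,
                            width_grid = 10:80,
                            models = c("d0", "d1", "d2", "d1xloc", "d2xloc"),
                            similarity_threshold = 45,
                            run_similarity_split = TRUE,
                            run_rt_model = TRUE,
                            out_dir = NULL) {
  if (is.null(trials_path) && is.null(seed))
    stop("pipeline_config(): seed is mandatory when simulating")
  if (similarity_threshold <= 0 || similarity_threshold >= 90)
    stop("pipeline_config(): similarity_threshold must lie in (0, 90)")
  structure(list(seed = seed, design = design, observers = observers,
                 trials_path = trials_path, width_grid = width_grid,
                 models = models, similarity_threshold = similarity_threshold,
                 run_similarity_split = run_similarity_split,
                 run_rt_model = run_rt_model, out_dir = out_dir),
            class = "pipeline_config")
}

# Deterministic substream seed for a named stage (kept below 2^31).
stage_seed <- function(seed, stage) {
  (as.integer(seed) + 1000003 * match(stage, c("simulate"))) %% .Machine$integer.max
}

#' Fit and compare the serial-dependence model family
#'
#' Convenience wrapper: fits every requested model to (delta, error, loc)
#' data and returns the BIC comparison plus the individual fits and the
#' peak biases of the best model.
#'
#' @param data Data frame with `delta`, `error` and `loc` columns.
#' @param models Model names (see [model_spec()]).
#' @param width_grid Candidate widths.
#' @return A list with `comparison` ([compare_models()] table), `fits`, and
#'   `best` (name, fit, peak-bias table of the best model).
#' @export
fit_model_family <- function(data, models = c("d0", "d1", "d2", "d1xloc", "d2xloc"),
                             width_grid = 10:80) {
  need_loc <- any(grepl("xloc", models))
  keep <- is.finite(data$delta) & is.finite(data$error)
  if (need_loc) {
    if (!"loc" %in% names(data))
      stop("interaction models need a 'loc' column (0 = random, 1 = fixed)")
    keep <- keep & is.finite(data$loc)
  }
  d <- data[keep, , drop = FALSE]
  # shared cross-products: every model reuses the same basis sufficient
  # statistics, so the family costs little more than a single fit
  xp <- dog_crossprods(d$delta, d$error, if (need_loc) d$loc else NULL,
                       width_grid)
  fits <- stats::setNames(lapply(models, function(m)
    fit_dog_core(xp, m)), models)
  comparison <- compare_models(fits)
  best_name <- attr(comparison, "best_model")
  list(comparison = comparison, fits = fits,
       best = list(name = best_name, fit = fits[[best_name]],
                   peaks = peak_biases(fits[[best_name]])))
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order and returns a structured run
#' report: per-stage row counts, the exclusion report, BIC comparison
#' tables for the previous-probe and distractor predictors (and for the
#' similarity split of the previous-probe effect on distractor-present
#' trials, including the coefficient z-tests), peak biases of the selected
#' models, and the RT model with the capture-effect summary. Deterministic:
#' the same configuration and seed reproduce the report exactly.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `pipeline_report`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) stop("config must be pipeline_config()")
  if (is.null(config$trials_path)) {
    trials <- simulate_experiment(config$design, config$observers,
                                  seed = stage_seed(config$seed, "simulate"))
  } else {
    trials <- read_trials(config$trials_path)
  }
  annotated <- annotate_trials(trials)
  excl <- exclude_trials(annotated)
  part <- exclude_participants(annotated, excl$report)
  clean <- part$clean

  sd_data <- function(d, predictor) {
    delta <- if (predictor == "prev_probe") d$delta_prev_probe else d$delta_distractor
    data.frame(delta = delta, error = d$adjustment_error,
               loc = as.numeric(d$location_condition == "fixed"))
  }
  prev_probe <- fit_model_family(sd_data(clean, "prev_probe"),
                                 config$models, config$width_grid)
  distractor <- fit_model_family(
    sd_data(clean[clean$distractor_present, , drop = FALSE], "distractor"),
    config$models, config$width_grid)

  similarity <- NULL
  if (config$run_similarity_split) {
    halves <- split_by_similarity(clean, config$similarity_threshold)
    fit_half <- function(h) fit_dog_model(sd_data(h, "prev_probe"), "d2",
                                          config$width_grid)
    fam_half <- function(h) fit_model_family(sd_data(h, "prev_probe"),
                                             config$models, config$width_grid)
    fs <- fit_half(halves$similar); fd <- fit_half(halves$dissimilar)
    similarity <- list(
      n_similar = nrow(halves$similar), n_dissimilar = nrow(halves$dissimilar),
      comparison_similar = fam_half(halves$similar)$comparison,
      comparison_dissimilar = fam_half(halves$dissimilar)$comparison,
      fit_similar = fs, fit_dissimilar = fd,
      z_attractive = compare_coefficients(fs, fd, "dog1"),
      z_repulsive = compare_coefficients(fs, fd, "dog2"))
  }

  rt <- NULL
  if (config$run_rt_model)
    rt <- list(model = fit_rt_model(clean), capture = capture_effect(clean))

  report <- structure(list(
    seed = config$seed,
    n_trials = nrow(trials),
    n_retained = nrow(clean),
    participants_kept = part$kept,
    exclusion = part$report,
    prev_probe = prev_probe,
    distractor = distractor,
    similarity = similarity,
    rt = rt), class = "pipeline_report")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_trials(trials, file.path(config$out_dir, "trials.csv"))
    write_trials(clean, file.path(config$out_dir, "clean.csv"))
    jsonlite::write_json(report_to_json(report),
                         file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

# Plain-list view of a pipeline report for JSON serialization.
report_to_json <- function(report) {
  cmp <- function(x) as.data.frame(unclass(x)[names(x) != "class"])
  fam <- function(f) list(comparison = as.data.frame(f$comparison),
                          best_model = f$best$name, peaks = f$best$peaks)
  out <- list(seed = report$seed, n_trials = report$n_trials,
              n_retained = report$n_retained,
              participants_kept = report$participants_kept,
              exclusion_counts = as.list(report$exclusion$counts),
              prev_probe = fam(report$prev_probe),
              distractor = fam(report$distractor))
  if (!is.null(report$similarity)) {
    s <- report$similarity
    out$similarity <- list(
      n_similar = s$n_similar, n_dissimilar = s$n_dissimilar,
      best_similar = attr(s$comparison_similar, "best_model"),
      best_dissimilar = attr(s$comparison_dissimilar, "best_model"),
      z_attractive = s$z_attractive[c("z", "p")],
      z_repulsive = s$z_repulsive[c("z", "p")])
  }
  if (!is.null(report$rt))
    out$rt <- list(coefficients = report$rt$model$coefficients,
                   ranef_sd = report$rt$model$ranef_sd,
                   method = report$rt$model$method,
                   capture = report$rt$capture$group)
  out
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("Pipeline run (seed %s): %d trials, %d retained, %d participants\n",
              format(x$seed), x$n_trials, x$n_retained,
              length(x$participants_kept)))
  cat("\n-- previous-probe effect --\n"); print(x$prev_probe$comparison)
  print(x$prev_probe$best$peaks, digits = 3)
  cat("\n-- distractor effect --\n"); print(x$distractor$comparison)
  if (!is.null(x$similarity)) {
    cat("\n-- similarity split (previous probe, distractor-present trials) --\n")
    cat(sprintf("  attractive component: z = %.2f, p = %.3g\n",
                x$similarity$z_attractive$z, x$similarity$z_attractive$p))
    cat(sprintf("  repulsive component:  z = %.2f, p = %.3g\n",
                x$similarity$z_repulsive$z, x$similarity$z_repulsive$p))
  }
  if (!is.null(x$rt)) { cat("\n-- RT analysis --\n"); print(x$rt$model) }
  invisible(x)
}
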