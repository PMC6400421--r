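# Trial-table I/O and the end-to-end pipeline runner.
#
# CSV is the single exchange format (trial tables are plain tabular
# behavioral records); derived results are serialized as JSON. Row order is
# semantically load-bearing (temporal order of trials), so reading
# preserves it and validation checks per-subject trial indices.

.REQUIRED_COLS <- c("subject", "trial", "stimulus")

#' Read a trial table from CSV
#'
#' Reads and validates a trial table: required columns present, orientation
#' columns inside `[0, 180)` (orientation experiments), per-subject trial
#' indices strictly increasing. Validation failures name the offending row.
#'
#' @param path CSV file path.
#' @param orientation Validate `stimulus`/`response` as orientations
#'   (degrees in `[0, 180)`); set `FALSE` for size tasks.
#' @return Trial table (data frame), row order preserved.
#' @export
read_trial_table <- function(path, orientation = TRUE) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_trial_table(tab, orientation = orientation)
  tab
}

#' Validate a trial table
#'
#' @param tab Data frame.
#' @param orientation Check orientation ranges?
#' @return `tab`, invisibly; stops with an informative error otherwise.
#' @export
validate_trial_table <- function(tab, orientation = TRUE) {
  miss <- setdiff(.REQUIRED_COLS, names(tab))
  if (length(miss))
    stop("trial table lacks required column(s): ", paste(miss, collapse = ", "))
  if (orientation) {
    for (col in intersect(c("stimulus", "response"), names(tab))) {
      v <- tab[[col]]
      bad <- which(!is.na(v) & (v < 0 | v >= 180))
      if (length(bad))
        stop(sprintf("column '%s' out of [0, 180) at row %d (value %g)",
                     col, bad[1], v[bad[1]]))
    }
  }
  for (s in unique(tab$subject)) {
    tr <- tab$trial[tab$subject == s]
    if (any(diff(tr) <= 0)) {
      i <- which(diff(tr) <= 0)[1]
      stop(sprintf("non-increasing trial index for subject %s (trial %s then %s)",
                   s, tr[i], tr[i + 1]))
    }
  }
  invisible(tab)
}

#' Write a trial table to CSV
#'
#' @param tab Trial table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trial_table <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Run the full synthetic pipeline
#'
#' Executes synth -> preprocess -> fit -> compare (and optionally the
#' calibration sweep) from a single configuration, writing all results and
#' a manifest (effective parameters, seeds, output hashes) to `out_dir`.
#' The configuration may be a YAML file path or a named list with fields:
#' `experiment` (design id), `seed`, optional `n_subjects`/`n_trials`,
#' `truth` (arguments of [ground_truth()]), `fit` (e.g. `predictor`),
#' `compare` (`n` iterations, `engine`), `preprocess` (logical flags).
#' Stage failures abort with the stage name; outputs of completed stages
#' remain on disk.
#'
#' @param config List or YAML path.
#' @param out_dir Output directory (created if needed).
#' @return List of class `pipeline_result` with the trial table, cleaning
#'   report, fits, comparison and the manifest.
#' @export
run_pipeline <- function(config, out_dir = tempfile("serialdep_run_")) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1
  stage <- "synth"
  result <- tryCatch({
    des_args <- c(list(experiment = config$experiment %||% "exp1"),
                  config$design %||% list())
    if (!is.null(config$n_subjects)) des_args$n_subjects <- config$n_subjects
    if (!is.null(config$n_trials)) des_args$n_trials <- config$n_trials
    design <- do.call(experiment_design, des_args)
    tab <- generate_design(design, seed = seed)
    truth <- do.call(ground_truth, config$truth %||% list())
    tab <- generate_behavior(tab, truth, seed = seed + 1)
    write_trial_table(tab, file.path(out_dir, "trials.csv"))

    stage <- "preprocess"
    pp_args <- config$preprocess %||% list()
    pp <- do.call(preprocess_trials, c(list(data = tab), pp_args))
    clean <- pp$data
    write_trial_table(clean, file.path(out_dir, "trials_clean.csv"))
    jsonlite::write_json(
      list(n_removed_rt = pp$report$n_removed_rt,
           n_removed_grubbs = pp$report$n_removed_grubbs,
           fraction_removed_total = pp$report$fraction_removed_total),
      file.path(out_dir, "cleaning_report.json"), auto_unbox = TRUE)

    stage <- "fit"
    if (sum(!is.na(clean$response)) == 0)
      stop("no response trials left to fit")
    predictor <- (config$fit %||% list())$predictor %||% "delta_S"
    fit <- fit_multilevel_dog(clean, predictor)
    jsonlite::write_json(
      fit[c("predictor", "alpha0", "se_alpha0", "z", "p", "w", "rmse",
            "loglik", "aic", "n")],
      file.path(out_dir, "dog_fit.json"), auto_unbox = TRUE, digits = NA)

    stage <- "compare"
    cmp_args <- config$compare %||% list(n = 200)
    cmp <- do.call(rmse_permutation_test,
                   c(list(data = clean, seed = seed + 2), cmp_args))
    jsonlite::write_json(
      cmp[c("rmse_S", "rmse_R", "rmse_diff", "p")],
      file.path(out_dir, "comparison.json"), auto_unbox = TRUE, digits = NA)

    list(trials = tab, clean = clean, report = pp$report, fit = fit,
         comparison = cmp)
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })

  files <- list.files(out_dir, full.names = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("serialdep")),
    seed = seed, config = config,
    outputs = as.list(tools::md5sum(files)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  result$manifest <- manifest
  result$out_dir <- out_dir
  class(result) <- "pipeline_result"
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline run ->", x$out_dir, "\n")
  print(x$fit)
  print(x$comparison)
  invisible(x)
}
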