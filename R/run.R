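# End-to-end pipeline runner behind the command-line interface: prepare ->
# featurize/train -> evaluate, writing every artifact under one run
# directory with the resolved configuration echoed for provenance.

#' Run the full prepare/train/evaluate pipeline
#'
#' Reads a raw activity CSV (or generates a synthetic fixture), cleans it,
#' splits it, trains the hybrid model and writes: `clean.csv` (+ provenance
#' sidecar), `model.rds` (checkpoint bundling parameters, config, vocabulary
#' and normalizer), `history.csv`, `metrics.json` (overall + per-target) and
#' `scatter.csv` (truth, prediction, target id), plus `run_config.json`
#' echoing every resolved setting and seed.
#'
#' @param input path to a raw activity CSV, or a `fixture_spec` to generate
#'   one.
#' @param out_dir run directory (created; must not be an existing non-empty
#'   directory unless `overwrite = TRUE`).
#' @param seed master seed: drives the split and (unless overridden in
#'   `control`) training.
#' @param test_fraction held-out fraction.
#' @param config a [model_config()].
#' @param control a [train_control()]; its `seed` defaults to `seed`.
#' @param overwrite allow writing into an existing directory.
#' @return invisibly, a list with the fitted `ic50net`, metrics and paths.
#' @export
run_pipeline <- function(input, out_dir, seed = 42L, test_fraction = 0.2,
                         config = model_config(), control = NULL,
                         overwrite = FALSE) {
  if (is.null(control)) control <- train_control(seed = seed)
  if (dir.exists(out_dir) && length(dir(out_dir)) && !overwrite) {
    stopf("output directory %s exists and is not empty", out_dir)
  }

  if (inherits(input, "fixture_spec")) {
    raw <- generate_activity_table(input)
    input_desc <- sprintf("synthetic fixture (n_molecules = %d, seed = %d)",
                          input$n_molecules, input$seed)
  } else {
    raw <- read_activity_csv(input)
    input_desc <- normalizePath(input)
  }

  clean <- clean_activities(raw)
  if (nrow(clean$samples) < 10L) stopf("too few clean samples (%d) to train", nrow(clean$samples))
  sp <- split_activities(clean, test_fraction = test_fraction, seed = seed)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_clean_csv(clean, file.path(out_dir, "clean.csv"))

  fit <- ic50net(sp$train, test = sp$test, config = config, control = control)

  save_ic50net(fit, file.path(out_dir, "model.rds"))
  utils::write.csv(fit$history, file.path(out_dir, "history.csv"), row.names = FALSE)
  metrics <- list(
    test = fit$test_metrics,
    train = fit$train_metrics[fit$train_metrics$group == "overall", ]
  )
  jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                       dataframe = "rows", auto_unbox = TRUE, pretty = TRUE, digits = NA)
  utils::write.csv(
    data.frame(truth = fit$test_data$log_ic50, prediction = fit$test_pred,
               target_id = fit$test_data$target_id),
    file.path(out_dir, "scatter.csv"), row.names = FALSE
  )
  jsonlite::write_json(
    list(input = input_desc, seed = seed, test_fraction = test_fraction,
         split_seed = seed, train_seed = control$seed,
         init_seed = 1L,
         model_config = unclass(config), train_control = unclass(control),
         provenance = clean$provenance,
         package_version = as.character(utils::packageVersion("ic50net")),
         timestamp = format(Sys.time(), tz = "UTC")),
    file.path(out_dir, "run_config.json"), auto_unbox = TRUE, pretty = TRUE
  )
  invisible(list(fit = fit, clean = clean, split = sp, out_dir = out_dir))
}
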