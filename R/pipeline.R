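#' Run the full selection pipeline
#'
#' Executes read (or simulate) -> standardize -> screen -> grid search ->
#' fit best -> report, writing every artifact under `config$output_dir`:
#' dataset CSVs (when simulated), the correlation screen (CSV), the MSEP
#' surface (CSV + JSON), the model (JSON), the selection report (JSON) and
#' three PDF plots. A `log.txt` records the seed, package version and every
#' chosen parameter. Identical config and seed produce identical outputs; on
#' failure, partial outputs created by the run are removed.
#'
#' @param config named list or path to a YAML file with entries:
#'   \describe{
#'     \item{data}{either `list(paths = <named list of CSVs>)` (per-block
#'       layout, entry `response` mandatory), `list(wide = <csv>,
#'       block_map = <yaml or list>)`, or `list(synthetic = <spec yaml path>)`
#'       / `list(synthetic = "study_preset")`.}
#'     \item{seed}{integer; drives everything random (simulation).}
#'     \item{screen}{optional: `list(threshold = 0.55)`.}
#'     \item{model}{optional: `list(R_values = ..., L0_values = ...)` for the
#'       grid, or fixed `list(R = ..., L0 = ...)`.}
#'     \item{output_dir}{artifact directory.}
#'     \item{stages}{subset of c("screen", "fit", "report"); default all.}
#'   }
#' @return invisibly, a list with the dataset, screen, cv result, model and
#'   report (those that ran).
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  if (!is.list(config) || is.null(config$output_dir) || is.null(config$data))
    stop_schema("config must be a list (or YAML file) with 'data' and 'output_dir'")

  out_dir <- config$output_dir
  pre_existing <- if (dir.exists(out_dir)) list.files(out_dir, full.names = TRUE) else character(0)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  created <- character(0)
  note <- function(path) { created <<- c(created, path); path }
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  stages <- if (is.null(config$stages)) c("screen", "fit", "report") else config$stages
  log_path <- note(file.path(out_dir, "log.txt"))
  logf <- function(stage, fmt, ...) {
    cat(sprintf("[%s] %s\n", stage, sprintf(fmt, ...)),
        file = log_path, append = TRUE)
  }

  run <- function() {
    cat(sprintf("blockpls %s | R %s | seed %d\n",
                as.character(utils::packageVersion("blockpls")),
                paste(R.version$major, R.version$minor, sep = "."), seed),
        file = log_path)
    result <- list()

    # --- data -------------------------------------------------------------
    dcfg <- config$data
    if (!is.null(dcfg$synthetic)) {
      spec <- if (identical(dcfg$synthetic, "study_preset"))
        study_preset(seed = seed)
      else {
        sp <- read_spec_yaml(dcfg$synthetic)
        sp$seed <- seed
        sp
      }
      gen <- generate_study_data(spec)
      result$data <- gen$data
      result$truth <- gen$truth
      paths <- write_block_dataset(gen$data, file.path(out_dir, "data"))
      created <<- c(created, paths)
      jsonlite::write_json(
        list(active = gen$truth$active,
             signal_responses = gen$truth$signal_responses,
             sign = gen$truth$sign),
        note(file.path(out_dir, "ground_truth.json")),
        auto_unbox = TRUE, digits = I(17), pretty = TRUE)
      logf("data", "simulated: n=%d, blocks=%s", spec$n,
           paste(names(spec$block_sizes), collapse = ","))
    } else if (!is.null(dcfg$wide)) {
      result$data <- read_block_dataset(dcfg$wide, block_map = dcfg$block_map)
      logf("data", "read wide CSV %s", dcfg$wide)
    } else if (!is.null(dcfg$paths)) {
      result$data <- read_block_dataset(unlist(dcfg$paths))
      logf("data", "read %d per-block CSVs", length(dcfg$paths))
    } else stop_schema("config$data needs 'synthetic', 'wide' or 'paths'")

    # --- screen -----------------------------------------------------------
    if ("screen" %in% stages) {
      thr <- if (is.null(config$screen$threshold)) 0.55 else config$screen$threshold
      result$screen <- pearson_screen(result$data, threshold = thr)
      write_screen_csv(result$screen,
                       note(file.path(out_dir, "screen.csv")),
                       note(file.path(out_dir, "screen_matrix.csv")))
      logf("screen", "threshold=%.3g, retained=%d", thr,
           sum(result$screen$table$retained))
    }

    # --- fit --------------------------------------------------------------
    if ("fit" %in% stages) {
      mcfg <- config$model
      if (!is.null(mcfg[["R"]]) && !is.null(mcfg[["L0"]])) {
        best <- list(R = as.integer(mcfg[["R"]]), L0 = as.integer(mcfg[["L0"]]))
        result$cv <- grid_search(result$data, R_values = best$R, L0_values = best$L0)
      } else {
        q <- ncol(result$data$response)
        Rv <- if (is.null(mcfg$R_values)) seq_len(q) else as.integer(mcfg$R_values)
        Lv <- if (is.null(mcfg$L0_values)) seq_len(30) else as.integer(mcfg$L0_values)
        result$cv <- grid_search(result$data, R_values = Rv, L0_values = Lv)
        best <- result$cv$best
      }
      write_cv_result(result$cv,
                      note(file.path(out_dir, "msep_grid.csv")),
                      note(file.path(out_dir, "msep_grid.json")))
      result$model <- fit_ddspls(result$data, R = best$R, L0 = best$L0)
      write_model_json(result$model, note(file.path(out_dir, "model.json")))
      logf("fit", "selected R=%d, L0=%d, lambda=%.6g",
           result$model$R, result$model$L0, result$model$lambda)
      grDevices::pdf(note(file.path(out_dir, "msep_curves.pdf")), width = 9, height = 6)
      plot_msep_curves(result$cv)
      grDevices::dev.off()
      grDevices::pdf(note(file.path(out_dir, "predicted_vs_observed.pdf")),
                     width = 9, height = 6)
      plot_predicted_observed(result$cv)
      grDevices::dev.off()
    }

    # --- report -----------------------------------------------------------
    if ("report" %in% stages && !is.null(result$model)) {
      result$report <- build_selection_report(result$model, result$data, result$cv)
      write_report_json(result$report, note(file.path(out_dir, "report.json")))
      grDevices::pdf(note(file.path(out_dir, "coefficients.pdf")), width = 9, height = 6)
      plot_coefficients(result$report)
      grDevices::dev.off()
      logf("report", "responses with selections: %s",
           paste(unique(result$report$coefficients$response), collapse = ",") )
    }
    result
  }

  tryCatch(invisible(run()), error = function(e) {
    # remove partial outputs created by this run, keep anything pre-existing
    unlink(setdiff(created, pre_existing), recursive = TRUE)
    stop(e)
  })
}
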