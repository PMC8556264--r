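# End-to-end orchestration: ingest -> filter -> quantify -> summarize ->
# (statistics) -> plots -> output bundle. Reruns on identical input and
# config produce byte-identical csv outputs (only the run log carries a
# timestamp).

#' Assemble a run configuration
#'
#' Validates model-specific requirements up front (controls always; a
#' calibrator for the delta-delta-CT and stability models) so configuration
#' errors surface before any processing.
#'
#' @param inputs Character vector of input csv/txt paths.
#' @param model A [model_config()].
#' @param filter A [filter_config()].
#' @param design Optional [design_spec()] to run the statistics stage.
#' @param out_dir Output directory (created if needed).
#' @param target_order,sample_order,error_bar Plot options, see
#'   [plot_summaries()].
#' @param delimiter Passed to [read_results_table()].
#' @param column_overrides Passed to [read_results_table()].
#' @param zip Also bundle the output directory into `results.zip`.
#' @return A `run_config` list.
#' @export
run_config <- function(inputs, model, filter = filter_config(), design = NULL,
                       out_dir = NULL, target_order = NULL, sample_order = NULL,
                       error_bar = "se", delimiter = "auto",
                       column_overrides = NULL, zip = FALSE) {
  stopifnot(inherits(model, "model_config"), inherits(filter, "filter_config"))
  if (!is.null(design)) stopifnot(inherits(design, "design_spec"))
  missing <- inputs[!file.exists(inputs)]
  if (length(missing)) {
    stop(sprintf("input file(s) not found: %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  structure(list(inputs = inputs, model = model, filter = filter,
                 design = design, out_dir = out_dir,
                 target_order = target_order, sample_order = sample_order,
                 error_bar = error_bar, delimiter = delimiter,
                 column_overrides = column_overrides, zip = zip),
            class = "run_config")
}

.log_collector <- function() {
  lines <- character(0)
  list(add = function(msg) lines <<- c(lines, msg),
       get = function() lines)
}

.write_table <- function(df, path, rename = NULL) {
  if (!is.null(rename)) {
    for (nm in names(rename)) names(df)[names(df) == nm] <- rename[[nm]]
  }
  readr::write_csv(df, path)
  path
}

#' Run the full analysis pipeline
#'
#' Executes ingest, replicate filtering, quantification, summarization,
#' optional statistics and plotting, and writes `clean_data.csv`,
#' `summary_data.csv`, statistics tables, png charts and a run log into the
#' output directory. Inputs are never mutated. Warnings raised along the way
#' (skipped wells, preserved groups, removed outliers) are collected into the
#' run log.
#'
#' @param config A [run_config()].
#' @return List with `clean`, `summary`, `stats` (or NULL), `plots`, `files`
#'   (written paths) and `log` (character lines), invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  log <- .log_collector()
  stage <- "ingest"
  capture <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      log$add(sprintf("[%s] warning: %s", stage, conditionMessage(w)))
      invokeRestart("muffleWarning")
    })
  }
  fail <- function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage, conditionMessage(e)),
         call. = FALSE)
  }

  result <- tryCatch({
    tables <- capture(lapply(config$inputs, read_results_table,
                             delimiter = config$delimiter,
                             overrides = config$column_overrides))
    plate <- capture(merge_batches(tables, config$model$model))
    log$add(sprintf("read %d record(s) from %d file(s)", nrow(plate),
                    length(config$inputs)))

    stage <- "filter"
    filtered <- capture(filter_plate(plate, config$filter))
    n_out <- sum(filtered$outlier)
    n_pres <- length(unique(filtered$sample_name[filtered$preserved]))
    log$add(sprintf("flagged %d outlier replicate(s); preserve rule fired for %d group set(s)",
                    n_out, sum(filtered$preserved & !duplicated(
                      paste(filtered$partition, filtered$sample_name, filtered$target_name)))))

    stage <- "quantify"
    clean <- capture(quantify(filtered, config$model, plate = plate))
    summary <- capture(summarize_clean(clean, config$model))

    stage <- "statistics"
    stats_res <- NULL
    grouped <- NULL
    if (!is.null(config$design)) {
      grouped <- capture(assign_groups(summary, config$design))
      stats_res <- list(main = capture(run_main_test(grouped, config$design)),
                        posthoc = capture(posthoc_pairwise(grouped, config$design)))
    }

    stage <- "output"
    files <- character(0)
    plots <- list()
    if (!is.null(config$out_dir)) {
      dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
      value_name <- switch(config$model$model,
                           absolute = "normalized_quantity",
                           relative_dct = "delta_CT",
                           "delta_delta_CT")
      files <- c(files, .write_table(
        clean, file.path(config$out_dir, "clean_data.csv"),
        rename = c(ct = "CT", value = value_name, rq = "RQ", outlier = "Outlier")))
      files <- c(files, .write_table(
        summary, file.path(config$out_dir, "summary_data.csv")))
      if (!is.null(stats_res)) {
        files <- c(files, .write_table(
          stats_res$main, file.path(config$out_dir, "stats_main.csv")))
        files <- c(files, .write_table(
          stats_res$posthoc, file.path(config$out_dir, "stats_posthoc.csv")))
      }
      stage <- "plots"
      plots <- capture(plot_summaries(summary, config$target_order,
                                      config$sample_order, config$error_bar,
                                      out_dir = config$out_dir))
      files <- c(files, attr(plots, "files"))
      if (!is.null(config$design)) {
        sp <- capture(plot_stats_groups(grouped, config$design,
                                        config$error_bar,
                                        out_dir = config$out_dir))
        files <- c(files, attr(sp, "files"))
        plots <- c(plots, sp)
      }

      stage <- "bundle"
      log_path <- file.path(config$out_dir, "run_log.txt")
      writeLines(c(sprintf("run started %s", format(Sys.time())),
                   sprintf("model: %s", config$model$model),
                   log$get()), log_path)
      files <- c(files, log_path)
      if (isTRUE(config$zip)) {
        zf <- file.path(config$out_dir, "results.zip")
        write_zip(zf, files, root = config$out_dir)
        files <- c(files, zf)
      }
    }
    list(clean = clean, summary = summary, stats = stats_res, plots = plots,
         files = files, log = log$get())
  }, error = fail)

  invisible(result)
}

#' Bundle an output directory into a zip archive
#'
#' @param dir Completed run output directory.
#' @param zipfile Archive path (default `results.zip` inside `dir`).
#' @return The archive path, invisibly.
#' @export
bundle_outputs <- function(dir, zipfile = file.path(dir, "results.zip")) {
  files <- list.files(dir, full.names = TRUE, recursive = TRUE)
  files <- files[normalizePath(files) != suppressWarnings(normalizePath(zipfile, mustWork = FALSE))]
  write_zip(zipfile, files, root = dir)
  invisible(zipfile)
}
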