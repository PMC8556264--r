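# Bar-chart output.
#
# Mirrors the chart set of the processing pipeline: one bar chart per target
# (per-sample means with error bars), a combined chart grouped by gene and
# one grouped by sample, and -- when statistics run -- grouped mean charts by
# the design factors (factor 2 mapped to bar colour for two-way designs).
# Bar heights are the summary means exactly; error bars default to SE.

.sanitize_filename <- function(x) gsub("[^A-Za-z0-9._-]+", "_", x)

.apply_order <- function(values, order) {
  obs <- unique(values)
  if (is.null(order)) return(factor(values, levels = obs))
  extra <- setdiff(order, obs)
  if (length(extra)) {
    stop(sprintf("requested order contains unobserved name(s): %s",
                 paste(extra, collapse = ", ")), call. = FALSE)
  }
  factor(values, levels = c(order, setdiff(obs, order)))
}

.bar_chart <- function(df, x, fill = NULL, error_bar = "se", title = NULL) {
  df$.err <- df[[error_bar]]
  dodge <- ggplot2::position_dodge(width = 0.9)
  p <- ggplot2::ggplot(df, ggplot2::aes(
    x = .data[[x]], y = .data$mean,
    fill = if (is.null(fill)) .data[[x]] else .data[[fill]])) +
    ggplot2::geom_col(position = dodge, colour = "grey20", width = 0.8) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$.err, ymax = .data$mean + .data$.err),
      position = dodge, width = 0.25, linewidth = 0.4) +
    ggplot2::labs(x = NULL, y = paste0("mean ± ", toupper(error_bar)),
                  fill = NULL, title = title) +
    ggplot2::theme_classic(base_size = 11) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  if (is.null(fill)) p <- p + ggplot2::guides(fill = "none")
  p
}

.save_pngs <- function(plots, out_dir, width = 6, height = 4) {
  if (is.null(out_dir)) return(character(0))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(out_dir, paste0(names(plots), ".png"))
  for (i in seq_along(plots)) {
    ggplot2::ggsave(paths[i], plots[[i]], width = width, height = height,
                    dpi = 150)
  }
  paths
}

#' Summary bar charts
#'
#' Emits (i) one chart per target of per-sample means with error bars, (ii) a
#' combined chart grouped by gene/target, (iii) a combined chart grouped by
#' sample. Filenames are deterministic functions of the target/sample names.
#'
#' @param summary Summary tibble from [summarize_clean()].
#' @param target_order,sample_order Optional display orders (subsets of the
#'   observed names; unlisted names append in data order).
#' @param error_bar "se" (default) or "sd".
#' @param out_dir Directory to write png files into; NULL returns the plot
#'   objects without writing.
#' @return Named list of ggplot objects (invisible); attribute `files` holds
#'   written paths.
#' @export
plot_summaries <- function(summary, target_order = NULL, sample_order = NULL,
                           error_bar = c("se", "sd"), out_dir = NULL) {
  error_bar <- match.arg(error_bar)
  if (nrow(summary) == 0) {
    warning("empty summary: no plots generated", call. = FALSE)
    return(invisible(list()))
  }
  summary$target_name <- .apply_order(summary$target_name, target_order)
  summary$sample_name <- .apply_order(summary$sample_name, sample_order)

  plots <- list()
  for (t in levels(summary$target_name)) {
    d <- summary[summary$target_name == t, ]
    plots[[paste0("target_", .sanitize_filename(t))]] <-
      .bar_chart(d, "sample_name", error_bar = error_bar, title = t)
  }
  plots[["combined_by_target"]] <-
    .bar_chart(summary, "target_name", fill = "sample_name", error_bar = error_bar)
  plots[["combined_by_sample"]] <-
    .bar_chart(summary, "sample_name", fill = "target_name", error_bar = error_bar)

  files <- .save_pngs(plots, out_dir)
  attr(plots, "files") <- files
  invisible(plots)
}

#' Grouped mean bar charts for the statistics stage
#'
#' Two charts of group means: grouped by target and grouped by the design's
#' first factor. For two-way designs factor 1 spans the x-axis and factor 2
#' maps to bar colours with a legend.
#'
#' @param grouped Output of [assign_groups()].
#' @param design A [design_spec()].
#' @param error_bar "se" (default) or "sd" (of the group's biological
#'   replicates).
#' @param out_dir Directory for png output, or NULL.
#' @return Named list of ggplot objects (invisible); attribute `files`.
#' @export
plot_stats_groups <- function(grouped, design, error_bar = c("se", "sd"),
                              out_dir = NULL) {
  error_bar <- match.arg(error_bar)
  if (!"value" %in% names(grouped)) grouped$value <- grouped$mean
  grp_cols <- c("target_name", "group1", if (!is.null(design$factor2)) "group2")
  means <- grouped |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp_cols))) |>
    dplyr::summarise(
      mean = mean(.data$value),
      sd = if (dplyr::n() > 1) stats::sd(.data$value) else 0,
      se = if (dplyr::n() > 1) stats::sd(.data$value) / sqrt(dplyr::n()) else 0,
      .groups = "drop")
  means$group1 <- factor(means$group1, levels = design$factor1)

  plots <- list()
  if (!is.null(design$factor2) && design$test_family == "two_way") {
    means$group2 <- factor(means$group2, levels = design$factor2)
    for (t in unique(means$target_name)) {
      plots[[paste0("stats_", .sanitize_filename(t), "_by_group")]] <-
        .bar_chart(means[means$target_name == t, ], "group1", fill = "group2",
                   error_bar = error_bar, title = t)
    }
    plots[["stats_by_target"]] <-
      .bar_chart(means, "target_name", fill = "group1", error_bar = error_bar)
  } else {
    plots[["stats_by_target"]] <-
      .bar_chart(means, "target_name", fill = "group1", error_bar = error_bar)
    plots[["stats_by_group"]] <-
      .bar_chart(means, "group1", fill = "target_name", error_bar = error_bar)
  }
  files <- .save_pngs(plots, out_dir)
  attr(plots, "files") <- files
  invisible(plots)
}
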