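# Technical-replicate outlier filtering.
#
# Dual rule: (1) while the replicate group's CT standard deviation exceeds a
# cut-off, drop the replicate furthest from the current group mean, up to a
# budget set by `max_proportion`; (2) a "preserve highly variable" guard keeps
# the whole group when the CT-SD is high but no single replicate is a clear
# outlier (|mean - median| / median below a small ratio), e.g. two of three
# replicates nearly equidistant around the mean.

#' Filtering configuration
#'
#' @param ct_sd_cutoff CT standard-deviation cut-off in cycles above which a
#'   replicate group is considered too variable (default 0.3).
#' @param max_proportion Minimum fraction of replicates that must remain
#'   (default 0.5: outliers are removed until two of three replicates remain).
#' @param preserve_variable Apply the preserve-highly-variable rule
#'   (default TRUE).
#' @param preserve_ratio Threshold on |mean - median| / median below which a
#'   high-SD group is preserved intact (default 0.1).
#' @return A `filter_config` list.
#' @export
filter_config <- function(ct_sd_cutoff = 0.3, max_proportion = 0.5,
                          preserve_variable = TRUE, preserve_ratio = 0.1) {
  stopifnot(ct_sd_cutoff > 0, max_proportion > 0, max_proportion <= 1,
            preserve_ratio > 0, is.logical(preserve_variable))
  structure(list(ct_sd_cutoff = ct_sd_cutoff, max_proportion = max_proportion,
                 preserve_variable = preserve_variable,
                 preserve_ratio = preserve_ratio),
            class = "filter_config")
}

#' CT standard deviation of a replicate group
#'
#' Sample standard deviation (n - 1 denominator); 0 for a single value.
#'
#' @param values Numeric CT values (cycles).
#' @return CT-SD in cycles.
#' @export
ct_sd <- function(values) {
  if (length(values) == 0) stop("ct_sd: empty replicate group", call. = FALSE)
  if (length(values) == 1) return(0)
  stats::sd(values)
}

#' Does the preserve-highly-variable rule fire?
#'
#' TRUE iff the group's CT-SD exceeds the cut-off but |mean - median| /
#' median is below `preserve_ratio` (and the rule is switched on): the group
#' is variable yet has no clear single outlier, so it is kept intact.
#'
#' @param values Numeric CT values, length >= 2.
#' @param config A [filter_config()].
#' @return Logical scalar.
#' @export
is_preserved <- function(values, config = filter_config()) {
  stopifnot(length(values) >= 2)
  if (!config$preserve_variable) return(FALSE)
  med <- stats::median(values)
  if (med == 0) stop("is_preserved: median is 0, ratio undefined", call. = FALSE)
  ct_sd(values) > config$ct_sd_cutoff &&
    abs(mean(values) - med) / med < config$preserve_ratio
}

#' Maximum number of removable replicates
#'
#' `n - ceiling(n * max_proportion)`: with the 0.5 default a triplicate can
#' lose at most one replicate (two of three remain).
#'
#' @param n Replicate count.
#' @param max_proportion Minimum fraction retained.
#' @return Non-negative integer count.
#' @export
max_removable <- function(n, max_proportion = 0.5) {
  stopifnot(n >= 1)
  max(0L, as.integer(n - ceiling(n * max_proportion)))
}

#' Filter one technical-replicate group
#'
#' If the preserve rule fires on the initial set, all replicates are retained.
#' Otherwise, while the retained CT-SD exceeds the cut-off and the removal
#' budget is not exhausted, the replicate furthest from the current retained
#' mean moves to the outlier set (ties broken toward the larger CT). The mean
#' is recomputed after every removal. Duplicates (n = 2) are never split:
#' both members are equidistant from their mean, so any removal would be
#' arbitrary; a high-SD duplicate is reported via a warning.
#'
#' @param ct Numeric CT values of the group's replicates.
#' @param config A [filter_config()].
#' @return List with `retained` and `outliers` (integer indices into `ct`),
#'   `final_ct_sd`, and `preserved` (did the preserve rule fire).
#' @export
filter_replicates <- function(ct, config = filter_config()) {
  stopifnot(length(ct) >= 1, !anyNA(ct))
  n <- length(ct)
  retained <- seq_len(n)
  outliers <- integer(0)

  if (n >= 2 && is_preserved(ct, config)) {
    return(list(retained = retained, outliers = outliers,
                final_ct_sd = ct_sd(ct), preserved = TRUE))
  }

  budget <- max_removable(n, config$max_proportion)
  while (length(retained) > 2 && length(outliers) < budget &&
         ct_sd(ct[retained]) > config$ct_sd_cutoff) {
    dev <- abs(ct[retained] - mean(ct[retained]))
    worst <- retained[dev == max(dev)]
    drop <- worst[which.max(ct[worst])]
    outliers <- c(outliers, drop)
    retained <- setdiff(retained, drop)
  }
  if (length(retained) == 2 && ct_sd(ct[retained]) > config$ct_sd_cutoff) {
    warning(sprintf("duplicate replicates with CT-SD %.3f above cut-off %.3f kept unfiltered",
                    ct_sd(ct[retained]), config$ct_sd_cutoff), call. = FALSE)
  }
  list(retained = retained, outliers = outliers,
       final_ct_sd = ct_sd(ct[retained]), preserved = FALSE)
}

#' Flag replicate outliers across a whole plate table
#'
#' Applies [filter_replicates()] to every sample x target group within each
#' partition, over UNKNOWN-task wells with a non-missing CT. Wells with
#' missing CT are dropped with a warning; NTC and STANDARD wells pass through
#' untouched (they never enter replicate groups).
#'
#' @param plate Tibble from [merge_batches()] (must carry `partition`).
#' @param config A [filter_config()].
#' @return The plate tibble restricted to quantifiable UNKNOWN wells, with
#'   added logical `outlier` and `preserved` columns.
#' @export
filter_plate <- function(plate, config = filter_config()) {
  stopifnot("partition" %in% names(plate))
  unk <- dplyr::filter(plate, .data$task == "UNKNOWN")
  n_missing <- sum(is.na(unk$ct))
  if (n_missing > 0) {
    warning(sprintf("dropping %d well(s) with missing CT from replicate groups",
                    n_missing), call. = FALSE)
    unk <- dplyr::filter(unk, !is.na(.data$ct))
  }
  if (nrow(unk) == 0) {
    warning("no quantifiable wells after excluding NTC/standards and missing CTs",
            call. = FALSE)
    return(dplyr::mutate(unk, outlier = logical(0), preserved = logical(0)))
  }
  unk |>
    dplyr::group_by(.data$partition, .data$sample_name, .data$target_name) |>
    dplyr::group_modify(function(g, key) {
      res <- filter_replicates(g$ct, config)
      g$outlier <- seq_len(nrow(g)) %in% res$outliers
      g$preserved <- res$preserved
      g
    }) |>
    dplyr::ungroup()
}
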