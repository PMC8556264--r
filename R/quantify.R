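# Quantification models.
#
# Four models share one clean-record layout:
#   absolute      -- standard-curve quantities, normalized to the mean
#                    quantity of each endogenous control; value = normalized
#                    quantity ratio.
#   relative_dct  -- dCT_i = ct_i - mean control CT (averaged over controls);
#                    RQ = 2^-dCT.
#   relative_ddct -- ddCT_i = dCT_i - calibrator-sample mean dCT;
#                    RQ = 2^-ddCT.
#   stability     -- the ddCT model on genomic regions; summary RQs are
#                    classified normal / deletion / insertion against a
#                    confidence interval (default 0.7 .. 1.3 around 1).
#
# Control CTs/quantities enter as the mean over that control's retained
# replicates; target values stay per-replicate, and sample-level values are
# means of the per-replicate normalized values.

#' Model configuration
#'
#' @param model One of "absolute", "relative_dct", "relative_ddct",
#'   "stability".
#' @param controls Character vector of endogenous-control target names
#'   (>= 1); for the stability model this is the reference genomic region.
#' @param calibrator Calibrator/reference sample name; required for the
#'   relative_ddct and stability models.
#' @param stability_bounds Lower/upper RQ bounds of the "normal" interval
#'   (default `c(0.7, 1.3)`; bounds are inclusive, i.e. themselves normal).
#' @param quantity_source For the absolute model: "fit_curve" fits a standard
#'   curve per target from STANDARD-task wells; "use_quantity_column" takes
#'   instrument-computed quantities from the Quantity column.
#' @return A `model_config` list.
#' @export
model_config <- function(model = c("absolute", "relative_dct", "relative_ddct", "stability"),
                         controls,
                         calibrator = NULL,
                         stability_bounds = c(0.7, 1.3),
                         quantity_source = c("fit_curve", "use_quantity_column")) {
  model <- match.arg(model)
  quantity_source <- match.arg(quantity_source)
  stopifnot(is.character(controls), length(controls) >= 1)
  if (model %in% c("relative_ddct", "stability") &&
      (is.null(calibrator) || !nzchar(calibrator))) {
    stop(sprintf("model '%s' requires a calibrator sample", model), call. = FALSE)
  }
  stopifnot(length(stability_bounds) == 2, stability_bounds[1] < stability_bounds[2],
            stability_bounds[1] > 0)
  structure(list(model = model, controls = controls, calibrator = calibrator,
                 stability_bounds = stability_bounds,
                 quantity_source = quantity_source),
            class = "model_config")
}

#' Fit a standard curve CT = a log2(quantity) + b
#'
#' Ordinary least squares of CT against log2 input quantity over the serial
#' dilution points. The slope is negative for valid amplification (CT falls
#' as input rises).
#'
#' @param quantity Input quantities (ng), all positive, >= 2 distinct values.
#' @param ct Observed CT values (cycles), same length.
#' @param target_name Target label carried on the fit.
#' @return A `curve_fit` list: `slope_a`, `intercept_b`, `r_squared`,
#'   `n_points`, `target_name`.
#' @export
fit_standard_curve <- function(quantity, ct, target_name = NA_character_) {
  stopifnot(length(quantity) == length(ct))
  if (any(quantity <= 0)) stop("standard quantities must be positive", call. = FALSE)
  if (length(unique(quantity)) < 2) {
    stop("need at least 2 distinct standard quantities to fit a curve", call. = FALSE)
  }
  fit <- stats::lm(ct ~ log2(quantity))
  ss_tot <- sum((ct - mean(ct))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum(stats::resid(fit)^2) / ss_tot
  structure(list(slope_a = unname(stats::coef(fit)[2]),
                 intercept_b = unname(stats::coef(fit)[1]),
                 r_squared = r2, n_points = length(ct),
                 target_name = target_name),
            class = "curve_fit")
}

#' Invert a standard curve: quantity from CT
#'
#' Returns `2^((ct - b) / a)` for curve CT = a log2(quantity) + b.
#'
#' @param ct CT value(s), cycles.
#' @param curve A [fit_standard_curve()] result.
#' @return Estimated quantity in ng.
#' @export
quantity_from_ct <- function(ct, curve) {
  if (curve$slope_a == 0) stop("standard curve slope is 0; cannot invert", call. = FALSE)
  2^((ct - curve$intercept_b) / curve$slope_a)
}

#' Normalize absolute quantities to endogenous controls
#'
#' Each target replicate's quantity is divided by the mean quantity of each
#' control separately; the replicate's normalized value is the mean of those
#' per-control ratios. Sample-level values are means over replicates of these
#' normalized values (mean of normalized replicates, not a normalized mean).
#'
#' @param quantities Per-replicate target quantities (ng).
#' @param control_means Named numeric vector: control target -> mean quantity.
#' @return Per-replicate normalized values.
#' @export
absolute_normalize <- function(quantities, control_means) {
  stopifnot(length(control_means) >= 1, all(control_means > 0))
  vapply(quantities, function(q) mean(q / control_means), numeric(1))
}

#' Per-replicate delta-CT against endogenous controls
#'
#' dCT_i = mean over controls c of (ct_i - mean CT of c); RQ_i = 2^-dCT_i.
#'
#' @param ct Per-replicate target CTs (cycles).
#' @param control_mean_cts Named numeric vector: control -> mean CT over its
#'   retained replicates.
#' @return Tibble with `delta_ct` and `rq`, one row per replicate.
#' @export
delta_ct <- function(ct, control_mean_cts) {
  stopifnot(length(control_mean_cts) >= 1)
  d <- vapply(ct, function(x) mean(x - control_mean_cts), numeric(1))
  tibble::tibble(delta_ct = d, rq = 2^(-d))
}

#' Per-replicate delta-delta-CT against a calibrator sample
#'
#' ddCT_i = dCT_i - calibrator mean dCT; RQ_i = 2^-ddCT_i.
#'
#' @param dct Per-replicate delta-CT values for the test sample.
#' @param calibrator_dct_mean Mean delta-CT of the calibrator sample for the
#'   same target (over its retained replicates).
#' @return Tibble with `delta_delta_ct` and `rq`.
#' @export
delta_delta_ct <- function(dct, calibrator_dct_mean) {
  stopifnot(length(calibrator_dct_mean) == 1, !is.na(calibrator_dct_mean))
  dd <- dct - calibrator_dct_mean
  tibble::tibble(delta_delta_ct = dd, rq = 2^(-dd))
}

#' Classify a genomic-stability RQ
#'
#' Deletion if RQ < lower bound, insertion if RQ > upper bound, else normal
#' (the bounds themselves are normal). A single-copy region in a two-copy
#' background is expected at RQ = 0.5 (e.g. chromosome X in a male sample).
#'
#' @param rq Relative quantity value(s), positive.
#' @param bounds Length-2 numeric, default `c(0.7, 1.3)`.
#' @return Character vector: "deletion", "normal" or "insertion".
#' @export
classify_stability <- function(rq, bounds = c(0.7, 1.3)) {
  stopifnot(all(rq > 0), length(bounds) == 2)
  dplyr::case_when(rq < bounds[1] ~ "deletion",
                   rq > bounds[2] ~ "insertion",
                   TRUE ~ "normal")
}

.control_means <- function(df, controls, valuecol) {
  # per sample: mean retained value of each control target
  df |>
    dplyr::filter(.data$target_name %in% controls, !.data$outlier) |>
    dplyr::group_by(.data$sample_name, .data$target_name) |>
    dplyr::summarise(m = mean(.data[[valuecol]]), .groups = "drop")
}

#' Compute per-replicate clean records for the configured model
#'
#' Takes the filtered plate (from [filter_plate()]) and produces one clean
#' record per technical replicate, outliers included and flagged: `value` is
#' the model-specific normalized quantity (delta-CT, delta-delta-CT, or
#' normalized quantity ratio) and `rq` the relative quantity. Standards
#' needed by the absolute model are taken from the unfiltered plate.
#'
#' @param filtered Output of [filter_plate()].
#' @param config A [model_config()].
#' @param plate The merged plate from [merge_batches()] (needed for
#'   STANDARD-task wells when the absolute model fits its own curves).
#' @return Tibble of clean records; attribute `curves` carries the fitted
#'   standard curves for the absolute model.
#' @export
quantify <- function(filtered, config, plate = NULL) {
  stopifnot(inherits(config, "model_config"))
  switch(config$model,
    absolute = .quantify_absolute(filtered, config, plate),
    relative_dct = .quantify_relative(filtered, config, ddct = FALSE),
    relative_ddct = .quantify_relative(filtered, config, ddct = TRUE),
    stability = .quantify_relative(filtered, config, ddct = TRUE)
  )
}

.quantify_relative <- function(filtered, config, ddct) {
  missing_ctrl <- setdiff(config$controls, unique(filtered$target_name))
  if (length(missing_ctrl)) {
    stop(sprintf("endogenous control(s) not found among targets: %s",
                 paste(missing_ctrl, collapse = ", ")), call. = FALSE)
  }
  if (ddct && !config$calibrator %in% filtered$sample_name) {
    stop(sprintf("calibrator sample '%s' not present in the data",
                 config$calibrator), call. = FALSE)
  }

  clean <- filtered |>
    dplyr::group_by(.data$partition) |>
    dplyr::group_modify(function(part, key) {
      ctrl <- .control_means(part, config$controls, "ct")
      out <- part |>
        dplyr::group_by(.data$sample_name) |>
        dplyr::group_modify(function(s, skey) {
          cm <- ctrl$m[ctrl$sample_name == skey$sample_name]
          names(cm) <- ctrl$target_name[ctrl$sample_name == skey$sample_name]
          cm <- cm[config$controls]
          if (anyNA(cm)) {
            warning(sprintf("sample '%s': control group missing; sample skipped",
                            skey$sample_name), call. = FALSE)
            return(s[0, ])
          }
          dct <- delta_ct(s$ct, cm)
          s$delta_ct <- dct$delta_ct
          s$rq <- dct$rq
          s
        }) |>
        dplyr::ungroup()
      if (!ddct) return(out)

      cal <- out |>
        dplyr::filter(.data$sample_name == config$calibrator, !.data$outlier) |>
        dplyr::group_by(.data$target_name) |>
        dplyr::summarise(cal_dct = mean(.data$delta_ct), .groups = "drop")
      out |>
        dplyr::group_by(.data$target_name) |>
        dplyr::group_modify(function(t, tkey) {
          cd <- cal$cal_dct[cal$target_name == tkey$target_name]
          if (length(cd) == 0) {
            warning(sprintf("target '%s': calibrator sample '%s' has no retained replicates; target skipped",
                            tkey$target_name, config$calibrator), call. = FALSE)
            return(t[0, ])
          }
          dd <- delta_delta_ct(t$delta_ct, cd)
          t$delta_delta_ct <- dd$delta_delta_ct
          t$rq <- dd$rq
          t
        }) |>
        dplyr::ungroup()
    }) |>
    dplyr::ungroup()

  clean$value <- if (ddct) clean$delta_delta_ct else clean$delta_ct
  if (ddct) clean$delta_delta_ct <- NULL
  .order_clean(clean)
}

.order_clean <- function(clean) {
  keep <- intersect(c("source_file", "partition", "well", "sample_name",
                      "target_name", "task", "ct", "quantity", "delta_ct",
                      "value", "rq", "outlier", "preserved", "group"),
                    names(clean))
  clean <- clean[, keep]
  dplyr::arrange(clean, .data$partition, .data$sample_name, .data$target_name,
                 .data$well)
}

.quantify_absolute <- function(filtered, config, plate) {
  if (config$quantity_source == "fit_curve") {
    if (is.null(plate)) stop("absolute model with fit_curve needs the full plate (standards)",
                             call. = FALSE)
    std <- dplyr::filter(plate, .data$task == "STANDARD",
                         !is.na(.data$ct), !is.na(.data$quantity))
    if (nrow(std) == 0) {
      stop("absolute model: no STANDARD wells with both CT and Quantity found",
           call. = FALSE)
    }
    curves <- std |>
      dplyr::group_by(.data$target_name) |>
      dplyr::group_map(function(g, key) {
        fit_standard_curve(g$quantity, g$ct, key$target_name)
      })
    names(curves) <- vapply(curves, `[[`, character(1), "target_name")
    missing_curve <- setdiff(unique(filtered$target_name), names(curves))
    if (length(missing_curve)) {
      stop(sprintf("no standard curve for target(s): %s",
                   paste(missing_curve, collapse = ", ")), call. = FALSE)
    }
    filtered$quantity <- mapply(function(tn, ct) quantity_from_ct(ct, curves[[tn]]),
                                filtered$target_name, filtered$ct)
  } else {
    curves <- list()
    if (anyNA(filtered$quantity)) {
      n_bad <- sum(is.na(filtered$quantity))
      warning(sprintf("dropping %d well(s) without instrument quantity", n_bad),
              call. = FALSE)
      filtered <- dplyr::filter(filtered, !is.na(.data$quantity))
    }
  }
  missing_ctrl <- setdiff(config$controls, unique(filtered$target_name))
  if (length(missing_ctrl)) {
    stop(sprintf("endogenous control(s) not found among targets: %s",
                 paste(missing_ctrl, collapse = ", ")), call. = FALSE)
  }

  ctrl <- .control_means(filtered, config$controls, "quantity")
  clean <- filtered |>
    dplyr::group_by(.data$sample_name) |>
    dplyr::group_modify(function(s, skey) {
      cm <- ctrl$m[ctrl$sample_name == skey$sample_name]
      names(cm) <- ctrl$target_name[ctrl$sample_name == skey$sample_name]
      cm <- cm[config$controls]
      if (anyNA(cm)) {
        warning(sprintf("sample '%s': missing control measurements; sample skipped",
                        skey$sample_name), call. = FALSE)
        return(s[0, ])
      }
      s$value <- absolute_normalize(s$quantity, cm)
      s
    }) |>
    dplyr::ungroup()
  clean$rq <- clean$value
  clean <- .order_clean(clean)
  attr(clean, "curves") <- curves
  clean
}

#' Summarize clean records per sample and target
#'
#' Mean, SD (n - 1 estimator) and SE over the retained (non-outlier)
#' replicates; a single-replicate group gets SD = SE = 0 with a warning. For
#' the stability model the per-sample mean RQ is classified into
#' normal / deletion / insertion.
#'
#' @param clean Tibble from [quantify()].
#' @param config A [model_config()].
#' @return Tibble of summary records (one row per partition x sample x
#'   target): `mean`, `sd`, `se`, `n_retained`, plus `call` for the stability
#'   model. For relative models the summarized value is the RQ; for the
#'   absolute model it is the normalized quantity.
#' @export
summarize_clean <- function(clean, config) {
  stopifnot(nrow(clean) > 0)
  grp_cols <- intersect(c("partition", "source_file", "sample_name",
                          "target_name", "group"), names(clean))
  out <- clean |>
    dplyr::filter(!.data$outlier) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp_cols))) |>
    dplyr::summarise(
      mean = mean(.data$rq),
      sd = if (dplyr::n() > 1) stats::sd(.data$rq) else 0,
      se = if (dplyr::n() > 1) stats::sd(.data$rq) / sqrt(dplyr::n()) else 0,
      n_retained = dplyr::n(),
      .groups = "drop")
  if (any(out$n_retained == 1)) {
    warning(sprintf("%d group(s) summarized from a single retained replicate (SD/SE set to 0)",
                    sum(out$n_retained == 1)), call. = FALSE)
  }
  if (config$model == "stability") {
    out$call <- classify_stability(out$mean, config$stability_bounds)
  }
  dplyr::arrange(out, .data$partition, .data$sample_name, .data$target_name)
}
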