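# Synthetic plate generation.
#
# Emulates a QuantStudio-style results export with known ground truth:
# control CTs sit at a base level (default 20 cycles), target CTs are base +
# true delta-CT, and technical replicates get Gaussian noise on the CT scale
# (the standard qPCR error model). Injected outliers add a fixed CT offset to
# chosen replicates. The generator does not simulate amplification kinetics,
# fluorescence curves or efficiency variation.

.well_labels <- function(n, width = 12) {
  rows <- do.call(paste0, expand.grid(LETTERS, c("", LETTERS)))[seq_len(ceiling(n / width))]
  paste0(rep(rows, each = width), rep(seq_len(width), length(rows)))[seq_len(n)]
}

.with_seed <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(seed, code)
}

.write_plate <- function(df, path) {
  if (!is.null(path)) readr::write_csv(df, path)
  invisible(df)
}

#' Generate a synthetic qPCR results plate
#'
#' @param samples Character vector of sample names.
#' @param targets Character vector of target (gene/region) names.
#' @param controls Subset of `targets` acting as endogenous controls
#'   (their true delta-CT is 0).
#' @param delta_ct Numeric matrix of true delta-CT values in cycles
#'   (rows = samples, cols = targets); control columns are forced to 0.
#'   Default all 0.
#' @param n_replicates Technical replicates per sample x target (default 3).
#' @param noise_sd Gaussian CT noise SD in cycles (default 0: noiseless).
#' @param outliers Optional data frame with columns `sample`, `target`,
#'   `replicate`, `offset` (cycles) describing injected outliers.
#' @param base_ct Base control CT level in cycles (default 20).
#' @param group Optional named character vector sample -> group label; adds a
#'   "Group" column.
#' @param seed Optional integer seed; output is byte-identical given the same
#'   seed.
#' @param path Optional csv path to write the export to.
#' @return Tibble in raw export layout (Well, Sample Name, Target Name, Task,
#'   CT, [Group]).
#' @export
generate_plate <- function(samples, targets, controls = character(0),
                           delta_ct = NULL, n_replicates = 3, noise_sd = 0,
                           outliers = NULL, base_ct = 20, group = NULL,
                           seed = NULL, path = NULL) {
  stopifnot(all(controls %in% targets), noise_sd >= 0, n_replicates >= 1)
  if (is.null(delta_ct)) {
    delta_ct <- matrix(0, length(samples), length(targets),
                       dimnames = list(samples, targets))
  }
  stopifnot(identical(rownames(delta_ct), samples),
            identical(colnames(delta_ct), targets))
  delta_ct[, controls] <- 0

  grid <- expand.grid(replicate = seq_len(n_replicates), target = targets,
                      sample = samples, stringsAsFactors = FALSE)
  grid <- grid[, c("sample", "target", "replicate")]
  true_ct <- base_ct + delta_ct[cbind(grid$sample, grid$target)]
  ct <- .with_seed(seed, true_ct + stats::rnorm(nrow(grid), 0, noise_sd))

  if (!is.null(outliers) && nrow(outliers) > 0) {
    if (any(outliers$replicate > n_replicates)) {
      stop("outlier injection index exceeds replicate count", call. = FALSE)
    }
    for (i in seq_len(nrow(outliers))) {
      hit <- grid$sample == outliers$sample[i] &
        grid$target == outliers$target[i] &
        grid$replicate == outliers$replicate[i]
      ct[hit] <- ct[hit] + outliers$offset[i]
    }
  }

  out <- tibble::tibble(
    Well = .well_labels(nrow(grid)),
    `Sample Name` = grid$sample,
    `Target Name` = grid$target,
    Task = "UNKNOWN",
    CT = sprintf("%.6f", ct)
  )
  if (!is.null(group)) out$Group <- unname(group[grid$sample])
  .write_plate(out, path)
}

#' Generate a plate with a standard-curve serial dilution
#'
#' Adds STANDARD-task wells over a serial dilution (quantities `start_ng /
#' fold^k`, k = 0 .. n_points - 1) whose CTs follow CT = a log2(q) + b plus
#' noise; UNKNOWN wells get CTs from their true quantities through the same
#' curve. The classic design is 8 points of a four-fold dilution from 50 ng
#' (bottom point 50/4^7 ng).
#'
#' @param samples,targets,controls As in [generate_plate()].
#' @param true_quantity Numeric matrix (samples x targets) of true input
#'   quantities in ng; default 1 ng everywhere.
#' @param slope_a,intercept_b Standard-curve parameters (cycles per
#'   log2(ng); cycles). One curve shared by all targets.
#' @param start_ng,fold,n_points Serial-dilution design (defaults 50, 4, 8).
#' @param n_replicates,noise_sd,seed,path As in [generate_plate()].
#' @return Tibble in export layout with a Quantity column on STANDARD wells.
#' @export
generate_standard_plate <- function(samples, targets, controls = character(0),
                                    true_quantity = NULL,
                                    slope_a = -1.5, intercept_b = 30,
                                    start_ng = 50, fold = 4, n_points = 8,
                                    n_replicates = 3, noise_sd = 0,
                                    seed = NULL, path = NULL) {
  stopifnot(fold > 1, n_points >= 1, slope_a != 0)
  if (is.null(true_quantity)) {
    true_quantity <- matrix(1, length(samples), length(targets),
                            dimnames = list(samples, targets))
  }
  std_q <- start_ng / fold^(seq_len(n_points) - 1)

  grid_u <- expand.grid(replicate = seq_len(n_replicates), target = targets,
                        sample = samples, stringsAsFactors = FALSE)
  grid_s <- expand.grid(target = targets, q = std_q, stringsAsFactors = FALSE)

  q_u <- true_quantity[cbind(grid_u$sample, grid_u$target)]
  ct_true <- c(slope_a * log2(q_u) + intercept_b,
               slope_a * log2(grid_s$q) + intercept_b)
  ct <- .with_seed(seed, ct_true + stats::rnorm(length(ct_true), 0, noise_sd))

  out <- tibble::tibble(
    Well = .well_labels(length(ct)),
    `Sample Name` = c(grid_u$sample, paste0("STD_", format(grid_s$q, trim = TRUE))),
    `Target Name` = c(grid_u$target, grid_s$target),
    Task = c(rep("UNKNOWN", nrow(grid_u)), rep("STANDARD", nrow(grid_s))),
    CT = sprintf("%.6f", ct),
    Quantity = c(rep("", nrow(grid_u)), sprintf("%.15g", grid_s$q))
  )
  .write_plate(out, path)
}

#' Generate a genomic-stability (copy-number) scenario
#'
#' Each region's CT is shifted by `-log2(copy / 2)` relative to the reference
#' region and the designated normal reference sample (two copies everywhere),
#' so a single-copy region yields RQ 0.5 (deletion) and a three-copy region
#' RQ 1.5 (insertion) through the stability pipeline. A ground-truth call
#' table is attached as attribute `truth`.
#'
#' @param samples Sample names; must include `reference_sample`.
#' @param regions Genomic region labels; must include `reference_region`.
#' @param copy_number Numeric matrix (samples x regions) of true copy
#'   numbers, all positive; the reference sample must be 2 everywhere and the
#'   reference region 2 in every sample.
#' @param reference_region Region used as endogenous control.
#' @param reference_sample Known-normal calibrator sample (default "Normal").
#' @param n_replicates,noise_sd,base_ct,seed,path As in [generate_plate()].
#' @return Tibble in export layout, with attribute `truth` (sample, region,
#'   expected RQ and call).
#' @export
generate_cnv_scenario <- function(samples, regions, copy_number,
                                  reference_region, reference_sample = "Normal",
                                  n_replicates = 3, noise_sd = 0, base_ct = 25,
                                  seed = NULL, path = NULL) {
  stopifnot(reference_sample %in% samples, reference_region %in% regions,
            identical(rownames(copy_number), samples),
            identical(colnames(copy_number), regions))
  if (any(copy_number <= 0)) stop("copy numbers must be positive", call. = FALSE)
  if (any(copy_number[reference_sample, ] != 2) ||
      any(copy_number[, reference_region] != 2)) {
    stop("reference sample and reference region must carry two copies throughout",
         call. = FALSE)
  }
  delta <- -log2(copy_number / 2)
  out <- generate_plate(samples, regions, controls = reference_region,
                        delta_ct = delta, n_replicates = n_replicates,
                        noise_sd = noise_sd, base_ct = base_ct, seed = seed,
                        path = path)
  rq <- copy_number / 2
  truth <- tibble::tibble(
    sample_name = rep(samples, times = length(regions)),
    target_name = rep(regions, each = length(samples)),
    rq = as.vector(rq),
    call = classify_stability(as.vector(rq))
  )
  attr(out, "truth") <- truth
  invisible(out)
}
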