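# Independent oracles and small fixture builders used across the suite.

# Benjamini-Hochberg step-up, coded directly from the definition:
# adjusted p_(i) = min_{j >= i} p_(j) * m / j, capped at 1, in input order.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  adj <- vapply(seq_len(m), function(i) min(sorted[i:m] * m / (i:m)), numeric(1))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Recursive enumeration of the replicate-removal sequence: preserve gate on
# the initial set, then repeatedly remove the member furthest from the
# current mean (ties to the larger CT), stopping at the SD cut-off, the
# removal budget, or a pair.
filter_oracle <- function(ct, cfg = filter_config()) {
  n <- length(ct)
  if (n >= 2 && cfg$preserve_variable) {
    med <- stats::median(ct)
    if (stats::sd(ct) > cfg$ct_sd_cutoff && abs(mean(ct) - med) / med < cfg$preserve_ratio) {
      return(integer(0))
    }
  }
  budget <- max(0L, as.integer(n - ceiling(n * cfg$max_proportion)))
  recurse <- function(idx, removed) {
    if (length(idx) <= 2 || length(removed) >= budget) return(removed)
    if (stats::sd(ct[idx]) <= cfg$ct_sd_cutoff) return(removed)
    dev <- abs(ct[idx] - mean(ct[idx]))
    cand <- idx[dev == max(dev)]
    pick <- cand[ct[cand] == max(ct[cand])][1]
    recurse(setdiff(idx, pick), c(removed, pick))
  }
  recurse(seq_len(n), integer(0))
}

# Welch two-sample t statistic and two-sided p, from the textbook formulas.
welch_oracle <- function(x, y) {
  vx <- stats::var(x) / length(x)
  vy <- stats::var(y) / length(y)
  tstat <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(statistic = tstat, df = df, p = 2 * stats::pt(-abs(tstat), df))
}

# Write a minimal results export with a metadata preamble.
write_fixture_csv <- function(path, rows,
                              header = "Well,Sample Name,Target Name,Task,CT",
                              preamble = c("# Instrument: synthetic", "# Block: 96-well")) {
  writeLines(c(preamble, header, rows), path)
  path
}

# Internal-format plate rows, bypassing file IO, for unit-level tests.
make_plate <- function(sample, target, ct, task = "UNKNOWN",
                       quantity = NA_real_, partition = "f1",
                       source_file = partition) {
  n <- length(ct)
  tibble::tibble(
    well = paste0("W", seq_len(n)),
    sample_name = rep_len(sample, n), target_name = rep_len(target, n),
    task = rep_len(task, n), ct = ct, quantity = rep_len(quantity, n),
    group = NA_character_, source_file = rep_len(source_file, n),
    partition = rep_len(partition, n))
}
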