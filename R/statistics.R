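# Differential statistics on summary values.
#
# Statistics run on per-sample summary means (biological replicates -- cell
# lines, animals), never on technical replicates. Dispatch:
#   two_group : t-test (paired/unpaired; Welch when unpaired) or
#               Wilcoxon signed-rank / Mann-Whitney
#   one_way   : one-way ANOVA, repeated-measures ANOVA when paired
#               (Kruskal-Wallis / Friedman for the nonparametric switch)
#   two_way   : two-way ANOVA with interaction, type-II sums of squares
# Post-hocs are pairwise t-tests with Benjamini-Hochberg FDR adjustment
# applied per target across its pairs.

#' Statistical design
#'
#' @param test_family One of "two_group", "one_way", "two_way".
#' @param factor1 Character vector of group labels for the first factor.
#' @param factor2 Optional labels for a second factor (required for two_way).
#' @param paired Paired / repeated-measures design (default FALSE).
#' @param parametric Use parametric tests (default TRUE); FALSE switches to
#'   the nonparametric equivalents.
#' @param group_source "parse_sample_names" matches labels as case-insensitive
#'   substrings of sample names; "group_column" matches the plate's grouping
#'   column exactly.
#' @param group_column Name of the grouping column in the summary table when
#'   `group_source = "group_column"` (default "group").
#' @return A `design_spec` list.
#' @export
design_spec <- function(test_family = c("two_group", "one_way", "two_way"),
                        factor1, factor2 = NULL, paired = FALSE,
                        parametric = TRUE,
                        group_source = c("parse_sample_names", "group_column"),
                        group_column = "group") {
  test_family <- match.arg(test_family)
  group_source <- match.arg(group_source)
  stopifnot(is.character(factor1), length(factor1) >= 1, !anyNA(factor1))
  if (test_family == "two_way" && is.null(factor2)) {
    stop("two_way design requires factor2 labels", call. = FALSE)
  }
  if (test_family == "two_group" && length(factor1) != 2) {
    stop("two_group design requires exactly 2 factor1 labels", call. = FALSE)
  }
  structure(list(test_family = test_family, factor1 = factor1,
                 factor2 = factor2, paired = paired, parametric = parametric,
                 group_source = group_source, group_column = group_column),
            class = "design_spec")
}

.rx_escape <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

.match_label <- function(x, labels, what) {
  hits <- lapply(x, function(s) labels[vapply(labels, function(l)
    grepl(.rx_escape(l), s, ignore.case = TRUE), logical(1))])
  n_hit <- lengths(hits)
  if (any(n_hit != 1)) {
    off <- unique(x[n_hit != 1])
    stop(sprintf("%s: sample(s) matching zero or multiple labels of {%s}: %s",
                 what, paste(labels, collapse = ", "),
                 paste(off, collapse = ", ")), call. = FALSE)
  }
  vapply(hits, `[[`, character(1), 1)
}

#' Assign summary records to statistical groups
#'
#' Binds each sample to exactly one label per factor, either by
#' case-insensitive substring match on the sample name or by exact match on
#' the grouping column. A `subject` column (the sample name stripped of its
#' matched labels) supports paired designs.
#'
#' @param summary Summary tibble from [summarize_clean()].
#' @param design A [design_spec()].
#' @return The summary tibble with added `group1` (+ `group2`) and `subject`
#'   columns.
#' @export
assign_groups <- function(summary, design) {
  stopifnot(inherits(design, "design_spec"))
  if (design$group_source == "group_column") {
    col <- design$group_column
    if (!col %in% names(summary) || all(is.na(summary[[col]]))) {
      stop(sprintf("grouping column '%s' not present in the data", col),
           call. = FALSE)
    }
    vals <- as.character(summary[[col]])
    bad <- !vals %in% design$factor1
    if (any(bad)) {
      stop(sprintf("grouping column values outside factor1 labels: %s",
                   paste(unique(vals[bad]), collapse = ", ")), call. = FALSE)
    }
    summary$group1 <- vals
    summary$subject <- summary$sample_name
  } else {
    summary$group1 <- .match_label(summary$sample_name, design$factor1, "factor1")
    subj <- summary$sample_name
    for (l in unique(c(design$factor1, design$factor2))) {
      subj <- gsub(.rx_escape(l), "", subj, ignore.case = TRUE)
    }
    summary$subject <- gsub("^[-_. ]+|[-_. ]+$", "", gsub("[-_. ]{2,}", "-", subj))
  }
  if (!is.null(design$factor2)) {
    summary$group2 <- .match_label(summary$sample_name, design$factor2, "factor2")
  }
  summary
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment: sorted p-values are scaled by m/i, monotonicity is
#' enforced from the largest down, values cap at 1, and the result returns in
#' input order.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same order.
#' @export
fdr_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvalues, method = "BH")
}

# two-group comparison on numeric vectors; the workhorse behind run_main_test
.two_group_test <- function(x, y, paired = FALSE, parametric = TRUE) {
  if (parametric) {
    ht <- stats::t.test(x, y, paired = paired, var.equal = FALSE)
    d <- if (paired) mean(x - y) / stats::sd(x - y)
         else (mean(x) - mean(y)) /
           sqrt((stats::var(x) * (length(x) - 1) + stats::var(y) * (length(y) - 1)) /
                (length(x) + length(y) - 2))
    list(test = if (paired) "paired t-test" else "Welch t-test",
         statistic = unname(ht$statistic), df = unname(ht$parameter),
         p_value = ht$p.value, effect_size = d)
  } else {
    ht <- suppressWarnings(stats::wilcox.test(x, y, paired = paired, exact = FALSE))
    list(test = if (paired) "Wilcoxon signed-rank" else "Mann-Whitney U",
         statistic = unname(ht$statistic), df = NA_real_,
         p_value = ht$p.value, effect_size = NA_real_)
  }
}

.eta_sq <- function(aov_tab, term) {
  ss <- aov_tab[["Sum Sq"]]
  ss[rownames(aov_tab) == term] / sum(ss)
}

.main_test_one_target <- function(g, design) {
  g$group1 <- factor(g$group1, levels = design$factor1)
  fam <- design$test_family
  if (fam == "two_group") {
    xs <- split(g, g$group1)
    if (design$paired) {
      xs <- lapply(xs, function(d) d[order(d$subject), ])
      if (!identical(xs[[1]]$subject, xs[[2]]$subject)) {
        stop("paired design: subjects do not match across the two groups",
             call. = FALSE)
      }
    }
    r <- .two_group_test(xs[[1]]$value, xs[[2]]$value,
                         paired = design$paired, parametric = design$parametric)
    return(tibble::tibble(term = paste(design$factor1, collapse = " vs "),
                          test = r$test, statistic = r$statistic, df = r$df,
                          df2 = NA_real_, p_value = r$p_value,
                          effect_size = r$effect_size))
  }
  if (fam == "one_way") {
    if (!design$parametric) {
      ht <- if (design$paired) {
        stats::friedman.test(value ~ group1 | subject, data = g)
      } else stats::kruskal.test(g$value, g$group1)
      return(tibble::tibble(
        term = "group1", test = if (design$paired) "Friedman" else "Kruskal-Wallis",
        statistic = unname(ht$statistic), df = unname(ht$parameter)[1],
        df2 = NA_real_, p_value = ht$p.value, effect_size = NA_real_))
    }
    if (design$paired) {
      g$subject <- factor(g$subject)
      fit <- stats::aov(value ~ group1 + Error(subject), data = g)
      tab <- summary(fit)[["Error: Within"]][[1]]
      return(tibble::tibble(
        term = "group1", test = "repeated-measures ANOVA",
        statistic = tab["group1", "F value"], df = tab["group1", "Df"],
        df2 = tab["Residuals", "Df"], p_value = tab["group1", "Pr(>F)"],
        effect_size = tab["group1", "Sum Sq"] / sum(tab[, "Sum Sq"])))
    }
    fit <- stats::aov(value ~ group1, data = g)
    tab <- summary(fit)[[1]]
    return(tibble::tibble(
      term = "group1", test = "one-way ANOVA",
      statistic = tab[1, "F value"],
      df = tab[1, "Df"], df2 = tab[nrow(tab), "Df"],
      p_value = tab[1, "Pr(>F)"],
      effect_size = tab[1, "Sum Sq"] / sum(tab[, "Sum Sq"])))
  }
  # two_way: type-II sums of squares (robust to unbalanced designs)
  g$group2 <- factor(g$group2, levels = design$factor2)
  fit <- stats::lm(value ~ group1 * group2, data = g)
  tab <- car::Anova(fit, type = 2)
  terms <- setdiff(rownames(tab), "Residuals")
  tibble::tibble(
    term = terms, test = "two-way ANOVA (type II)",
    statistic = tab[terms, "F value"], df = tab[terms, "Df"],
    df2 = tab["Residuals", "Df"], p_value = tab[terms, "Pr(>F)"],
    effect_size = tab[terms, "Sum Sq"] / sum(tab[, "Sum Sq"]))
}

#' Run the main differential test per target
#'
#' @param grouped Output of [assign_groups()] (summary records with group
#'   columns); the tested value is the `value` column if present, else `mean`.
#' @param design A [design_spec()].
#' @return Main-test tibble: one row per target (per model term for two-way
#'   ANOVA) with test name, statistic, degrees of freedom, p-value and effect
#'   size (Cohen's d / eta squared).
#' @export
run_main_test <- function(grouped, design) {
  if (!"value" %in% names(grouped)) grouped$value <- grouped$mean
  if (length(unique(grouped$group1)) < 2) {
    stop("fewer than 2 groups after assignment", call. = FALSE)
  }
  small <- grouped |>
    dplyr::count(.data$target_name, .data$group1) |>
    dplyr::filter(.data$n < 2)
  if (nrow(small) > 0 && design$parametric) {
    warning(sprintf("group(s) with n < 2 biological replicates: %s",
                    paste(unique(small$group1), collapse = ", ")), call. = FALSE)
  }
  grouped |>
    dplyr::group_by(.data$target_name) |>
    dplyr::group_modify(function(g, key) .main_test_one_target(g, design)) |>
    dplyr::ungroup()
}

#' Pairwise post-hoc t-tests with FDR correction
#'
#' All pairwise comparisons (paired where the design says so) with
#' Benjamini-Hochberg adjustment applied per target across its pairs. For
#' two-way designs the second factor is compared within each level of the
#' first (e.g. treatment vs control within each brain region). Both
#' unadjusted and adjusted p-values are reported; pairs with fewer than two
#' observations per side are flagged untestable.
#'
#' @param grouped Output of [assign_groups()].
#' @param design A [design_spec()].
#' @return Post-hoc tibble: target, group_a, group_b, statistic,
#'   p_unadjusted, p_fdr_adjusted, untestable.
#' @export
posthoc_pairwise <- function(grouped, design) {
  if (!"value" %in% names(grouped)) grouped$value <- grouped$mean

  pair_rows <- function(g) {
    if (is.null(design$factor2) || design$test_family != "two_way") {
      cells <- split(g, g$group1)
      pairs <- utils::combn(design$factor1, 2, simplify = FALSE)
      labeller <- function(p) p
    } else {
      g$cell <- paste(g$group1, g$group2, sep = ":")
      cells <- split(g, g$cell)
      pairs <- unlist(lapply(design$factor1, function(f1)
        lapply(utils::combn(design$factor2, 2, simplify = FALSE),
               function(p2) paste(f1, p2, sep = ":"))), recursive = FALSE)
      labeller <- function(p) p
    }
    rows <- lapply(pairs, function(p) {
      a <- cells[[p[1]]]; b <- cells[[p[2]]]
      if (is.null(a) || is.null(b) || nrow(a) < 2 || nrow(b) < 2) {
        return(tibble::tibble(group_a = p[1], group_b = p[2],
                              statistic = NA_real_, p_unadjusted = NA_real_,
                              untestable = TRUE))
      }
      if (design$paired) {
        a <- a[order(a$subject), ]; b <- b[order(b$subject), ]
        if (!identical(a$subject, b$subject)) {
          return(tibble::tibble(group_a = p[1], group_b = p[2],
                                statistic = NA_real_, p_unadjusted = NA_real_,
                                untestable = TRUE))
        }
      }
      r <- .two_group_test(a$value, b$value, paired = design$paired,
                           parametric = design$parametric)
      tibble::tibble(group_a = p[1], group_b = p[2], statistic = r$statistic,
                     p_unadjusted = r$p_value, untestable = FALSE)
    })
    out <- dplyr::bind_rows(rows)
    ok <- !out$untestable
    out$p_fdr_adjusted <- NA_real_
    out$p_fdr_adjusted[ok] <- fdr_adjust(out$p_unadjusted[ok])
    out
  }

  grouped |>
    dplyr::group_by(.data$target_name) |>
    dplyr::group_modify(function(g, key) pair_rows(g)) |>
    dplyr::ungroup()
}

#' Run the full statistics stage
#'
#' Convenience wrapper: [assign_groups()], [run_main_test()] and
#' [posthoc_pairwise()] in one call.
#'
#' @param summary Summary tibble from [summarize_clean()].
#' @param design A [design_spec()].
#' @return List with `main` and `posthoc` tibbles.
#' @export
run_stats <- function(summary, design) {
  grouped <- assign_groups(summary, design)
  list(main = run_main_test(grouped, design),
       posthoc = posthoc_pairwise(grouped, design))
}
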