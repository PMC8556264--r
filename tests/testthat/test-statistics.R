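make_summary <- function(samples, values, target = "GENE", group = NA_character_) {
  tibble::tibble(partition = "f1", source_file = "f1", sample_name = samples,
                 target_name = target, group = group, mean = values,
                 sd = 0, se = 0, n_retained = 3L)
}

test_that("groups are assigned by sample-name substring or grouping column", {
  s <- make_summary(c("AIW002-D0", "AIW002-D7", "NCRM1-D0", "NCRM1-D7"), 1:4)
  d <- design_spec("two_group", factor1 = c("D0", "D7"))
  g <- assign_groups(s, d)
  expect_equal(g$group1, c("D0", "D7", "D0", "D7"))
  expect_equal(g$subject, c("AIW002", "AIW002", "NCRM1", "NCRM1"))

  expect_error(assign_groups(s, design_spec("two_group", factor1 = c("D0", "X7"))),
               "zero or multiple")

  s2 <- make_summary(c("m1", "m2", "m3", "m4"), 1:4,
                     group = c("ctrl", "ctrl", "cocaine", "cocaine"))
  d2 <- design_spec("two_group", factor1 = c("ctrl", "cocaine"),
                    group_source = "group_column")
  g2 <- assign_groups(s2, d2)
  expect_equal(g2$group1, s2$group)
})

test_that("two-group t-test matches the closed-form Welch oracle", {
  withr::with_seed(5, {
    x <- rnorm(6, 10); y <- rnorm(6, 10.5)
  })
  s <- make_summary(c(paste0("A", 1:6, "-G1"), paste0("B", 1:6, "-G2")), c(x, y))
  d <- design_spec("two_group", factor1 = c("G1", "G2"))
  res <- run_main_test(assign_groups(s, d), d)
  orc <- welch_oracle(x, y)
  expect_equal(res$statistic, orc$statistic, tolerance = 1e-10)
  expect_equal(res$df, orc$df, tolerance = 1e-10)
  expect_equal(res$p_value, orc$p, tolerance = 1e-10)
})

test_that("perfect separation reports a tiny p-value rather than crashing", {
  s <- make_summary(c("a1-G1", "a2-G1", "a3-G1", "b1-G2", "b2-G2", "b3-G2"),
                    c(1, 1, 1 + 1e-9, 2, 2, 2 + 1e-9))
  d <- design_spec("two_group", factor1 = c("G1", "G2"))
  res <- run_main_test(assign_groups(s, d), d)
  expect_lt(res$p_value, 1e-6)
})

test_that("test dispatch covers parametric and nonparametric families", {
  withr::with_seed(9, {
    subj <- rep(paste0("L", 1:6), times = 3)
    stage <- rep(c("iPSC", "NPC", "DA4W"), each = 6)
    val <- rnorm(18, mean = rep(c(1, 2, 3), each = 6), sd = 0.3)
  })
  s <- make_summary(paste0(subj, "-", stage), val)

  d1 <- design_spec("one_way", factor1 = c("iPSC", "NPC", "DA4W"))
  r1 <- run_main_test(assign_groups(s, d1), d1)
  expect_equal(r1$test, "one-way ANOVA")
  expect_lt(r1$p_value, 0.01)
  # cross-check F against stats::oneway.test with equal variances
  ow <- stats::oneway.test(val ~ stage, var.equal = TRUE)
  expect_equal(r1$statistic, unname(ow$statistic), tolerance = 1e-10)

  d2 <- design_spec("one_way", factor1 = c("iPSC", "NPC", "DA4W"), paired = TRUE)
  r2 <- run_main_test(assign_groups(s, d2), d2)
  expect_equal(r2$test, "repeated-measures ANOVA")
  expect_true(r2$p_value < 0.01)

  d3 <- design_spec("one_way", factor1 = c("iPSC", "NPC", "DA4W"),
                    parametric = FALSE)
  r3 <- run_main_test(assign_groups(s, d3), d3)
  kw <- stats::kruskal.test(val, factor(stage))
  expect_equal(r3$statistic, unname(kw$statistic), tolerance = 1e-10)

  d4 <- design_spec("two_group", factor1 = c("iPSC", "NPC"), parametric = FALSE)
  sub <- s[grepl("iPSC|NPC", s$sample_name), ]
  r4 <- run_main_test(assign_groups(sub, d4), d4)
  expect_equal(r4$test, "Mann-Whitney U")
})

test_that("two-way ANOVA uses type-II sums of squares on unbalanced designs", {
  withr::with_seed(13, {
    region <- rep(c("STN", "GP", "SN"), times = c(5, 4, 5))
    region <- c(region, rep(c("STN", "GP", "SN"), times = c(5, 5, 4)))
    treat <- rep(c("ctrl", "cocaine"), times = c(14, 14))
    val <- rnorm(28, mean = ifelse(region == "GP" & treat == "cocaine", 2, 1), sd = 0.4)
  })
  s <- make_summary(paste0("m", seq_along(val), "-", region, "-", treat), val)
  d <- design_spec("two_way", factor1 = c("STN", "GP", "SN"),
                   factor2 = c("ctrl", "cocaine"))
  res <- run_main_test(assign_groups(s, d), d)
  expect_setequal(res$term, c("group1", "group2", "group1:group2"))
  # oracle: car on the same lm
  g <- assign_groups(s, d)
  fit <- stats::lm(mean ~ factor(group1, c("STN", "GP", "SN")) *
                     factor(group2, c("ctrl", "cocaine")), data = g)
  tab <- car::Anova(fit, type = 2)
  expect_equal(sort(res$p_value), sort(tab[["Pr(>F)"]][1:3]), tolerance = 1e-10)
})

test_that("post-hoc tables enumerate pairs with per-target BH adjustment", {
  withr::with_seed(17, {
    subj <- rep(paste0("L", 1:6), times = 4)
    stage <- rep(c("iPSC", "NPC", "DA4W", "DA6W"), each = 6)
    val <- rnorm(24, rep(c(1, 1.5, 3, 3.2), each = 6), 0.3)
  })
  s <- make_summary(paste0(subj, "-", stage), val)
  d <- design_spec("one_way", factor1 = c("iPSC", "NPC", "DA4W", "DA6W"))
  ph <- posthoc_pairwise(assign_groups(s, d), d)
  expect_equal(nrow(ph), choose(4, 2))  # 6 pairwise rows per gene
  expect_true(all(ph$p_fdr_adjusted >= ph$p_unadjusted - 1e-15))
  expect_equal(ph$p_fdr_adjusted, bh_oracle(ph$p_unadjusted))

  # 2 groups: post-hoc equals the main test, adjusted = unadjusted
  d2 <- design_spec("two_group", factor1 = c("iPSC", "NPC"))
  sub <- s[grepl("iPSC|NPC", s$sample_name), ]
  g2 <- assign_groups(sub, d2)
  ph2 <- posthoc_pairwise(g2, d2)
  expect_equal(nrow(ph2), 1)
  expect_equal(ph2$p_fdr_adjusted, ph2$p_unadjusted)
  expect_equal(ph2$p_unadjusted, run_main_test(g2, d2)$p_value)
})

test_that("fdr_adjust performs Benjamini-Hochberg step-up", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(fdr_adjust(0.5), 0.5)
  expect_equal(fdr_adjust(c(1, 1)), c(1, 1))
  expect_error(fdr_adjust(c(0.5, 1.2)), "0, 1")
  withr::with_seed(19, {
    for (i in 1:50) {
      p <- runif(sample(1:30, 1))
      expect_equal(fdr_adjust(p), bh_oracle(p))
    }
  })
})

test_that("renaming groups consistently leaves p-values unchanged", {
  withr::with_seed(23, {
    val <- rnorm(12, rep(c(1, 2), each = 6), 0.5)
  })
  s1 <- make_summary(paste0("s", 1:12, "-", rep(c("alpha", "beta"), each = 6)), val)
  s2 <- make_summary(paste0("s", 1:12, "-", rep(c("gamma", "delta"), each = 6)), val)
  d1 <- design_spec("two_group", factor1 = c("alpha", "beta"))
  d2 <- design_spec("two_group", factor1 = c("gamma", "delta"))
  expect_equal(run_main_test(assign_groups(s1, d1), d1)$p_value,
               run_main_test(assign_groups(s2, d2), d2)$p_value, tolerance = 1e-12)
})

test_that("a one-cycle expression shift is detected in nearly all simulations", {
  # RQ 0.5 vs 1.0, CT noise sd 0.1, n = 6 biological replicates per group
  withr::with_seed(29, {
    hits <- vapply(1:200, function(i) {
      a <- 2^-rnorm(6, 0, 0.1)   # RQ around 1
      b <- 2^-rnorm(6, 1, 0.1)   # RQ around 0.5
      qpcrflow:::.two_group_test(a, b)$p_value < 0.05
    }, logical(1))
  })
  expect_gt(mean(hits), 0.95)
})
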