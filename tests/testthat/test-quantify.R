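test_that("standard curves fit CT = a log2(q) + b exactly on exact lines", {
  fit <- fit_standard_curve(c(1, 4, 16), c(30, 28, 26), "GENE")
  expect_equal(fit$slope_a, -1)
  expect_equal(fit$intercept_b, 30)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$n_points, 3L)

  expect_error(fit_standard_curve(c(1, 1), c(30, 30)), "distinct")
  expect_error(fit_standard_curve(c(-1, 4), c(30, 28)), "positive")
})

test_that("curve inversion returns 2^((ct - b) / a)", {
  fit <- fit_standard_curve(c(1, 4, 16), c(30, 28, 26))
  expect_equal(quantity_from_ct(28, fit), 4)
  expect_equal(quantity_from_ct(30, fit), 1)  # ct = b -> 1 ng
  fit2 <- list(slope_a = -2, intercept_b = 30)
  expect_equal(quantity_from_ct(20, fit2), 32)
  expect_error(quantity_from_ct(20, list(slope_a = 0, intercept_b = 30)), "slope")
})

test_that("noiseless CTs refit to the generating curve parameters", {
  a <- -1.44; b <- 31.7
  q <- 50 / 4^(0:7)
  fit <- fit_standard_curve(q, a * log2(q) + b)
  expect_equal(fit$slope_a, a, tolerance = 1e-9)
  expect_equal(fit$intercept_b, b, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
})

test_that("absolute normalization averages per-control ratios per replicate", {
  v <- absolute_normalize(c(4, 4, 4), c(ACTB = 2, GAPDH = 8))
  expect_equal(v, rep((4 / 2 + 4 / 8) / 2, 3))  # 1.25 each
  expect_equal(absolute_normalize(7, c(C = 7)), 1)
  # mean of normalized replicates, not normalized mean
  v2 <- absolute_normalize(c(2, 4), c(C = 2))
  expect_equal(v2, c(1, 2))
  expect_equal(mean(v2), 1.5)
})

test_that("delta-CT and RQ follow the mean-over-controls formula", {
  d <- delta_ct(25, c(ACTB = 20))
  expect_equal(d$delta_ct, 5)
  expect_equal(d$rq, 2^-5)
  expect_equal(delta_ct(20, c(ACTB = 20))$rq, 1)
  d2 <- delta_ct(25, c(ACTB = 20, GAPDH = 22))
  expect_equal(d2$delta_ct, 4)  # mean of deltas 5 and 3
  expect_equal(d2$rq, 0.0625)
})

test_that("delta-delta-CT subtracts the calibrator mean delta-CT", {
  dd <- delta_delta_ct(5, 3)
  expect_equal(dd$delta_delta_ct, 2)
  expect_equal(dd$rq, 0.25)
  expect_equal(delta_delta_ct(3, 5)$rq, 4)
  expect_equal(delta_delta_ct(3, 3)$rq, 1)  # calibrator against itself
})

test_that("stability calls partition RQ space with inclusive bounds", {
  expect_equal(classify_stability(0.5), "deletion")   # one X copy in a male
  expect_equal(classify_stability(1.0), "normal")
  expect_equal(classify_stability(1.4), "insertion")
  expect_equal(classify_stability(c(0.7, 1.3)), c("normal", "normal"))
  withr::with_seed(3, {
    rq <- runif(500, 0.01, 3)
    calls <- classify_stability(rq)
    expect_true(all(calls %in% c("deletion", "normal", "insertion")))
    expect_equal(calls == "deletion", rq < 0.7)
    expect_equal(calls == "insertion", rq > 1.3)
  })
})

test_that("summaries use retained replicates only, with n-1 SD and SE", {
  clean <- tibble::tibble(
    partition = "f1", source_file = "f1", sample_name = "S1",
    target_name = "G", group = NA_character_,
    rq = c(1, 2, 9), outlier = c(FALSE, FALSE, TRUE))
  s <- summarize_clean(clean, model_config("relative_dct", controls = "C"))
  expect_equal(s$mean, 1.5)
  expect_equal(s$sd, sd(c(1, 2)), tolerance = 1e-10)
  expect_equal(s$se, s$sd / sqrt(2))
  expect_equal(s$n_retained, 2L)

  clean$outlier <- c(FALSE, TRUE, TRUE)
  expect_warning(s1 <- summarize_clean(clean, model_config("relative_dct", controls = "C")),
                 "single retained")
  expect_equal(s1$sd, 0)
  expect_equal(s1$se, 0)
})

test_that("relative quantification is invariant to per-sample CT shifts", {
  withr::with_seed(21, {
    base <- rbind(
      make_plate("Cal", "ACTB", rnorm(3, 20, 0.05)),
      make_plate("Cal", "GENE", rnorm(3, 24, 0.05)),
      make_plate("S", "ACTB", rnorm(3, 20, 0.05)),
      make_plate("S", "GENE", rnorm(3, 23, 0.05)))
  })
  shifted <- base
  shifted$ct[shifted$sample_name == "S"] <- shifted$ct[shifted$sample_name == "S"] + 2.5

  cfg <- model_config("relative_ddct", controls = "ACTB", calibrator = "Cal")
  run <- function(p) {
    f <- filter_plate(p, filter_config())
    summarize_clean(quantify(f, cfg), cfg)
  }
  expect_equal(run(base)$mean, run(shifted)$mean, tolerance = 1e-12)
})

test_that("ddct RQ equals dct RQ rescaled by the calibrator (constant-calibrator data)", {
  # exact only when the calibrator's replicate dCTs are constant per target:
  # sample RQs aggregate arithmetically, so a noisy calibrator's mean RQ is
  # not the reciprocal of 2^(mean dCT)
  plate <- rbind(
    make_plate("Cal", "ACTB", c(20, 20, 20)),
    make_plate("Cal", "GENE", c(23, 23, 23)),
    make_plate("S", "ACTB", c(20.02, 19.98, 20.00)),
    make_plate("S", "GENE", c(21.95, 22.00, 22.05)))
  f <- filter_plate(plate, filter_config())
  cfg_d <- model_config("relative_dct", controls = "ACTB")
  cfg_dd <- model_config("relative_ddct", controls = "ACTB", calibrator = "Cal")
  s_d <- summarize_clean(quantify(f, cfg_d), cfg_d)
  s_dd <- summarize_clean(quantify(f, cfg_dd), cfg_dd)
  pick <- function(s, smp) s$mean[s$sample_name == smp & s$target_name == "GENE"]
  expect_equal(pick(s_dd, "S"), pick(s_d, "S") / pick(s_d, "Cal"),
               tolerance = 1e-12)
})

test_that("a true one-cycle shift recovers RQ 0.5 exactly without noise", {
  plate <- rbind(
    make_plate("Cal", "ACTB", rep(20, 3)),
    make_plate("Cal", "GENE", rep(23, 3)),
    make_plate("S", "ACTB", rep(20, 3)),
    make_plate("S", "GENE", rep(24, 3)))
  cfg <- model_config("relative_ddct", controls = "ACTB", calibrator = "Cal")
  s <- summarize_clean(quantify(filter_plate(plate, filter_config()), cfg), cfg)
  expect_identical(s$mean[s$sample_name == "S" & s$target_name == "GENE"], 0.5)
})

test_that("absolute model pools files and applies controls across them", {
  # gene and control in separate files, instrument quantities supplied
  gene <- make_plate("S1", "GENE", c(25, 25, 25), quantity = 6,
                     partition = "pooled", source_file = "gene.csv")
  ctrl <- make_plate("S1", "ACTB", c(20, 20, 20), quantity = 3,
                     partition = "pooled", source_file = "actb.csv")
  plate <- rbind(gene, ctrl)
  cfg <- model_config("absolute", controls = "ACTB",
                      quantity_source = "use_quantity_column")
  clean <- quantify(filter_plate(plate, filter_config()), cfg, plate = plate)
  expect_equal(clean$value[clean$target_name == "GENE"], rep(2, 3))
  s <- summarize_clean(clean, cfg)
  expect_equal(s$mean[s$target_name == "GENE"], 2)
})

test_that("missing calibrator or controls raise clear errors", {
  plate <- make_plate("S", "GENE", c(20, 20, 20))
  f <- filter_plate(plate, filter_config())
  expect_error(quantify(f, model_config("relative_dct", controls = "ACTB")),
               "control")
  expect_error(
    quantify(rbind(f, filter_plate(make_plate("S", "ACTB", rep(19, 3)), filter_config())),
             model_config("relative_ddct", controls = "ACTB", calibrator = "Missing")),
    "calibrator")
  expect_error(model_config("relative_ddct", controls = "ACTB"), "calibrator")
})
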