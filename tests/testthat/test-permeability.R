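# Threshold classification, descriptor evaluation and test statistics.

test_that("the threshold rule puts the boundary value with the permeant class", {
  expect_identical(classify_permeability(1.0), "permeant")
  expect_identical(classify_permeability(0.999), "impermeant")
  expect_identical(classify_permeability(-0.01), "impermeant")
  expect_identical(classify_permeability(c(2, NA)), c("permeant", NA))
  expect_error(classify_permeability(NaN), "NaN")
  # threshold is configurable, rule direction is not
  expect_identical(classify_permeability(1.5, classifier_config(2)),
                   "impermeant")
})

test_that("descriptor evaluation reproduces a hand-enumerated toy case", {
  values <- c(2, 0, 0, 2)
  labels <- c("permeant", "permeant", "impermeant", "impermeant")
  ev <- evaluate_descriptor(values, labels)
  expect_equal(ev$accuracy, 0.5)
  expect_equal(unname(ev$confusion), c(1L, 1L, 1L, 1L))  # TP FN TN FP
  expect_equal(ev$frac_permeant_ge_threshold, 0.5)
  expect_equal(ev$frac_impermeant_lt_threshold, 0.5)
})

test_that("a perfectly separated panel scores accuracy 1 with no misses", {
  ev <- evaluate_descriptor(c(3, 2, 5, 0, -1), c(rep("permeant", 3),
                                                 rep("impermeant", 2)))
  expect_equal(ev$accuracy, 1)
  expect_equal(unname(ev$confusion["FN"]), 0L)
  expect_equal(ev$pct_permeant_ge_threshold, 100)
})

test_that("missing descriptor values are excluded and counted", {
  values <- c(2, NA, 0.5, NA, 3)
  labels <- c("permeant", "permeant", "impermeant", "impermeant", "permeant")
  ev <- evaluate_descriptor(values, labels)
  expect_equal(ev$missing, 2L)
  expect_equal(ev$n_permeant, 2L)
  expect_equal(ev$n_impermeant, 1L)
  expect_error(evaluate_descriptor(c(1, 2), c("permeant", "permeant")),
               "both classes")
  expect_error(evaluate_descriptor(1, c("permeant", "impermeant")),
               "equal length")
})

test_that("accuracy decomposition and per-class fractions hold exactly", {
  set.seed(23)
  for (i in 1:10) {
    n <- sample(20:100, 1)
    values <- rnorm(n, 1, 2)
    labels <- sample(c("permeant", "impermeant"), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    ev <- evaluate_descriptor(values, labels)
    cf <- ev$confusion
    expect_equal(ev$accuracy, (cf["TP"] + cf["TN"]) / sum(cf),
                 ignore_attr = TRUE)
    expect_equal(sum(cf), ev$n_permeant + ev$n_impermeant,
                 ignore_attr = TRUE)
    expect_equal(ev$frac_permeant_ge_threshold, cf[["TP"]] / ev$n_permeant)
  }
})

test_that("raising the threshold moves both per-class fractions monotonically", {
  set.seed(41)
  values <- rnorm(300, 1, 2)
  labels <- sample(c("permeant", "impermeant"), 300, replace = TRUE)
  thresholds <- seq(-2, 4, by = 0.5)
  evs <- lapply(thresholds, function(th) {
    evaluate_descriptor(values, labels, classifier_config(th))
  })
  frac_perm <- vapply(evs, `[[`, numeric(1), "frac_permeant_ge_threshold")
  frac_imp <- vapply(evs, `[[`, numeric(1), "frac_impermeant_lt_threshold")
  expect_true(all(diff(frac_perm) <= 1e-12))
  expect_true(all(diff(frac_imp) >= -1e-12))
})

test_that("the Welch test matches the closed-form textbook computation", {
  a <- c(1, 2, 3, 4)
  b <- c(2, 4, 6, 8)
  got <- welch_ttest(a, b)
  # independent closed-form Welch/Satterthwaite computation
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  t_exp <- (mean(a) - mean(b)) / sqrt(va + vb)
  df_exp <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  p_exp <- 2 * pt(-abs(t_exp), df_exp)
  expect_equal(got$t_statistic, t_exp, tolerance = 1e-10)
  expect_equal(got$df, df_exp, tolerance = 1e-10)
  expect_equal(got$p_value, p_exp, tolerance = 1e-10)
})

test_that("identical or equal-mean samples give t = 0, p = 1", {
  r1 <- welch_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r1$t_statistic, 0)
  expect_equal(r1$p_value, 1)
  r2 <- welch_ttest(c(0, 0, 1, 1), c(0, 0, 1, 1))
  expect_equal(r2$t_statistic, 0)
  expect_equal(r2$p_value, 1)
  expect_error(welch_ttest(1, c(1, 2)), "at least 2")
})

test_that("swapping the Welch samples negates t and preserves p", {
  set.seed(13)
  a <- rnorm(20, 1)
  b <- rnorm(15, 2, 2)
  f <- welch_ttest(a, b)
  r <- welch_ttest(b, a)
  expect_equal(f$t_statistic, -r$t_statistic)
  expect_equal(f$p_value, r$p_value)
})

test_that("regression metrics match their definitions", {
  y <- c(0, 1, 2)
  expect_equal(regression_metrics(y, y), list(r_squared = 1, mse = 0))
  const <- regression_metrics(y, rep(mean(y), 3))
  expect_equal(const$r_squared, 0)
  worked <- regression_metrics(y, c(0, 1, 3))
  expect_equal(worked$mse, 1 / 3)
  expect_equal(worked$r_squared, 0.5)
  expect_error(regression_metrics(c(1, 1), c(1, 2)), "zero variance")
})

test_that("descriptor ranking is by accuracy, ties alphabetical", {
  mk <- function(name, values, labels) {
    evaluate_descriptor(values, labels, descriptor_name = name)
  }
  labels <- c(rep("permeant", 50), rep("impermeant", 50))
  good <- c(rnorm(50, 4), rnorm(50, -2))       # high accuracy
  bad <- c(rnorm(50, 1), rnorm(50, 0.8))       # poor separation
  set.seed(3)
  evs <- list(mk("miLogP", bad, labels), mk("DeepFl", good, labels))
  ranked <- rank_descriptors(evs)
  expect_identical(names(ranked)[1], "DeepFl")
  # single evaluation ranks as itself
  expect_identical(names(rank_descriptors(evs[1])), "miLogP")
  # exact tie -> alphabetical
  same <- c(rnorm(50, 4), rnorm(50, -2))
  tie <- list(mk("Y", same, labels), mk("X", same, labels))
  expect_identical(names(rank_descriptors(tie)), c("X", "Y"))
  expect_error(rank_descriptors(list()), "at least one")
})

test_that("boxplot numbers are ordered and bound the non-outlier range", {
  set.seed(9)
  x <- c(rnorm(100), 8, -7)
  bs <- boxplot_summary(x)
  expect_true(bs["lower_whisker"] <= bs["q1"])
  expect_true(bs["q1"] <= bs["median"] && bs["median"] <= bs["q3"])
  expect_true(bs["q3"] <= bs["upper_whisker"])
  expect_equal(unname(bs["median"]), median(x))
  expect_gte(unname(bs["n_outliers"]), 2)
})
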