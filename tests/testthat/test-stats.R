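test_that("pooled t test matches hand computation and handles the null case", {
  r <- independent_t_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$t, -3 / sqrt(2 / 3), tolerance = 1e-9)  # -3.674
  expect_equal(r$df, 4)

  same <- independent_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  expect_error(independent_t_test(1, c(1, 2)), "at least 2")
})

test_that("t statistic flips sign under group swap and resists affine maps", {
  set.seed(1)
  x <- rnorm(15); y <- rnorm(20, 1)
  a <- independent_t_test(x, y)
  b <- independent_t_test(y, x)
  expect_equal(a$t, -b$t)
  for (rep in 1:5) {
    s <- runif(1, 0.5, 3); m <- rnorm(1)
    z <- independent_t_test(s * x + m, s * y + m)
    expect_equal(z$t, a$t, tolerance = 1e-9)
    expect_equal(z$p, a$p, tolerance = 1e-9)
  }
  # Welch variant available by flag
  w <- independent_t_test(x, y, var_equal = FALSE)
  expect_identical(w$method, "welch")
})

test_that("Kruskal-Wallis omnibus matches direct rank computation", {
  same <- kruskal_wallis_pairwise(list(a = c(1, 2, 3), b = c(1, 2, 3),
                                       c = c(1, 2, 3)))
  expect_equal(same$h, 0)

  r <- kruskal_wallis_pairwise(list(a = c(1, 2, 3), b = c(4, 5, 6),
                                    c = c(7, 8, 9)))
  expect_equal(r$h, 7.2, tolerance = 1e-9)

  expect_error(kruskal_wallis_pairwise(list(a = 1:3)), "at least 2")
  expect_error(kruskal_wallis_pairwise(list(a = 1:3, b = numeric(0))),
               "non-empty")
})

test_that("fully separated groups give significant pairwise comparisons", {
  set.seed(2)
  g <- list(a = rnorm(20, 0, 0.5), b = rnorm(20, 5, 0.5),
            c = rnorm(20, 10, 0.5))
  r <- kruskal_wallis_pairwise(g)
  expect_true(all(r$pairwise$p < 0.05))
  expect_true(all(r$pairwise$p_pair < 0.05))
  # Bonferroni never decreases a p value
  rb <- kruskal_wallis_pairwise(g, p_adjust = "bonferroni")
  expect_true(all(rb$pairwise$p >= r$pairwise$p))
})

test_that("the logistic probability formula evaluates exactly as written", {
  expect_equal(predict_probability(c(a = 0, b = 0, c = 0, d = 0), 1, 1, 1),
               0.5)
  expect_equal(
    predict_probability(c(a = 4.733, b = 1.580, c = 1.290, d = 0.698),
                        1, 1, 1),
    1 / (1 + exp(4.733 - 1.580 - 1.290 - 0.698)), tolerance = 1e-12)
  expect_equal(round(predict_probability(
    c(a = 4.733, b = 1.580, c = 1.290, d = 0.698), 1, 1, 1), 3), 0.238)
  # limit: with positive slope the probability tends to 1
  expect_equal(predict_probability(c(a = 4.733, b = 1.580), 1e8, 0, 0), 1)
})

test_that("logistic fitting recovers known coefficients from simulated data", {
  # one seeded instance; the replicate-averaged bias property is tested
  # separately at larger n
  set.seed(19)
  n <- 2000
  truth <- c(a = 2.0, b = 1.2, c = 0.8, d = 0.5)
  df <- data.frame(cho_cr = rlnorm(n, 0, 0.5), cho_naa = rlnorm(n, 0, 0.5),
                   ll_cr = rlnorm(n, 0, 0.5))
  p <- predict_probability(truth, df$cho_cr, df$cho_naa, df$ll_cr)
  df$outcome <- rbinom(n, 1, p)
  m <- fit_logistic_ratios(df)
  expect_true(m$converged)
  expect_true(all(abs(coef(m) - truth) < 0.1))
})

test_that("degenerate or separated outcomes are rejected, small n warns", {
  df <- data.frame(cho_cr = runif(20), cho_naa = runif(20),
                   ll_cr = runif(20), outcome = 1)
  expect_error(fit_logistic_ratios(df), "degenerate")

  set.seed(8)
  sep <- data.frame(cho_cr = c(runif(10, 0, 1), runif(10, 10, 11)),
                    cho_naa = runif(20), ll_cr = runif(20),
                    outcome = rep(c(0, 1), each = 10))
  expect_error(fit_logistic_ratios(sep), "separation")

  small <- data.frame(cho_cr = c(0.1, 2.0, 0.3, 0.2, 2.2, 2.3),
                      cho_naa = c(1, 2, 1, 2, 1, 2),
                      ll_cr = c(2, 1, 2, 1, 2, 1),
                      outcome = c(0, 0, 1, 0, 1, 1))
  expect_warning(try(fit_logistic_ratios(small), silent = TRUE), "fragile")
})

test_that("rows missing LL drop out only when LL is a predictor", {
  rec <- generate_cohort(cohort_spec(missing_ll_fraction = 0.3, seed = 4))
  tum <- rec[rec$area == "tumoral", ]
  m3 <- fit_logistic_ratios(tum)
  m2 <- fit_logistic_ratios(tum, predictors = c("cho_cr", "cho_naa"))
  expect_equal(m2$n, nrow(tum))
  expect_lt(m3$n, nrow(tum))
  expect_named(coef(m2), c("a", "b", "c"))
})

test_that("predicted-probability mean equals outcome prevalence", {
  for (seed in 1:5) {
    rec <- generate_cohort(cohort_spec(seed = seed))
    tum <- rec[rec$area == "tumoral", ]
    m <- fit_logistic_ratios(tum)
    expect_equal(mean(predict(m, tum)), mean(tum$grade_group == "HGG"),
                 tolerance = 1e-6)
  }
})

test_that("ROC handles separation, null scores and a hand-counted example", {
  sep <- roc_analysis(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))
  expect_equal(sep$auc, 1.0)
  expect_equal(sep$sens_at_cutoff, 100)
  expect_equal(sep$spec_at_cutoff, 100)

  ex <- roc_analysis(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
  expect_equal(ex$auc, 0.75)

  set.seed(5)
  null <- roc_analysis(runif(10000), rbinom(10000, 1, 0.5))
  expect_lt(abs(null$auc - 0.5), 0.02)

  expect_error(roc_analysis(runif(5), rep(1, 5)), "both classes")
})

test_that("trapezoidal AUC equals the normalized Mann-Whitney U with ties", {
  set.seed(6)
  for (rep in 1:50) {
    n1 <- sample(5:40, 1); n0 <- sample(5:40, 1)
    scores <- c(round(rnorm(n1, 0.5), 1), round(rnorm(n0), 1))  # many ties
    labels <- rep(c(1, 0), c(n1, n0))
    auc <- roc_analysis(scores, labels)$auc
    pos <- scores[labels == 1]; neg <- scores[labels == 0]
    u <- sum(vapply(pos, function(p)
      sum(p > neg) + 0.5 * sum(p == neg), numeric(1)))
    expect_equal(auc, u / (n1 * n0), tolerance = 1e-10)
  }
})

test_that("ROC agrees with an independent reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(7)
  scores <- rnorm(200)
  labels <- rbinom(200, 1, plogis(scores))
  ours <- roc_analysis(scores, labels)
  ref <- pROC::roc(labels, scores, quiet = TRUE)
  expect_equal(ours$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-10)
})

test_that("Youden ties break toward the lower threshold", {
  # two thresholds attain J: symmetric configuration
  r <- roc_analysis(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_equal(r$best_cutoff, 2.5)
  r2 <- roc_analysis(c(1, 3, 2, 4), c(0, 1, 0, 1))  # J tied at 0.5 twice
  js <- with(r2$curve, sensitivity + specificity - 100)
  ties <- r2$curve$threshold[js == max(js)]
  expect_equal(r2$best_cutoff, min(ties))
})

test_that("cohort summaries report mean, n-1 SD and per-cell n", {
  df <- case_records(data.frame(
    case_id = c("a", "b", "c", "d"),
    who_grade = c("II", "II", "II", "IV"),
    area = "tumoral",
    cho_naa = c(1, 2, 3, 5), cho_cr = c(1, 1, 1, 2),
    ll_cr = c(NA, 2, 4, NA)))
  s <- summarize_cohort(df, by = "grade_group")
  lgg_cho_naa <- s[s$group == "LGG" & s$ratio == "cho_naa", ]
  expect_equal(lgg_cho_naa$mean, 2)
  expect_equal(lgg_cho_naa$sd, 1)
  expect_equal(lgg_cho_naa$n, 3)
  lgg_ll <- s[s$group == "LGG" & s$ratio == "ll_cr", ]
  expect_equal(lgg_ll$n, 2)
  expect_equal(lgg_ll$mean, 3)
  # single observation: mean is the value, SD missing
  hgg_cho_naa <- s[s$group == "HGG" & s$ratio == "cho_naa", ]
  expect_equal(hgg_cho_naa$mean, 5)
  expect_true(is.na(hgg_cho_naa$sd))
})
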