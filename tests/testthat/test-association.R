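test_that("log10 transform hits exactly the five skewed outcomes", {
  panel <- tibble::tibble(
    homa_ir = c(1, 10), triglycerides = c(70, 100), total_chol = c(100, 200),
    hdl = c(50, 50), ldl = c(100, 100), mean_bp = c(85, 90),
    risk_z = c(-0.2, 0.2)
  )
  tr <- transform_outcomes(panel)
  expect_equal(tr$homa_ir, c(0, 1))
  expect_equal(tr$triglycerides[1], log10(70))
  expect_equal(round(tr$triglycerides[1], 4), 1.8451)
  # mean BP and the composite score stay on their original scales
  expect_equal(tr$mean_bp, panel$mean_bp)
  expect_equal(tr$risk_z, panel$risk_z)
})

test_that("non-positive values are excluded from the transformed outcome", {
  panel <- tibble::tibble(homa_ir = c(2, 0, -1), triglycerides = c(70, 80, 90))
  tr <- transform_outcomes(panel)
  expect_true(all(is.na(tr$homa_ir[2:3])))
  expect_equal(attr(tr, "n_nonpositive"), 2L)
})

test_that("simple regression: exact fits and the Pearson-r identity", {
  x <- 1:10
  # summary.lm() flags the deliberately perfect fit; that is the point here
  r <- suppressWarnings(simple_regression(x, 2 * x + 1))
  expect_equal(r$beta_std, 1)
  expect_equal(r$adj_r2, 1)

  withr::with_seed(13, {
    for (i in 1:10) {
      n <- sample(10:60, 1)
      x <- rnorm(n)
      y <- rnorm(n, 0.3 * x)
      fit <- simple_regression(x, y)
      expect_equal(fit$beta_std, cor(x, y))
      expect_equal(fit$adj_r2,
                   1 - (1 - cor(x, y)^2) * (n - 1) / (n - 2))
    }
  })
  expect_error(simple_regression(1:2, 2:3), class = "chronomeal_input_error")
  expect_error(simple_regression(rep(1, 10), rnorm(10)),
               class = "chronomeal_degenerate_error")
})

test_that("a planted zero correlation is recovered near zero", {
  withr::with_seed(17, {
    x <- rnorm(4000); y <- rnorm(4000)
    expect_lt(abs(simple_regression(x, y)$beta_std), 0.05)
  })
})

test_that("multiple regression reduces to simple with constant covariates", {
  withr::with_seed(19, {
    x <- rnorm(40); y <- rnorm(40, 0.5 * x)
    covs <- data.frame(a = rep(1, 40), b = rep(2, 40))
    m <- multiple_regression(y, x, covs)
    s <- simple_regression(x, y)
    expect_equal(m$beta_std, s$beta_std)
    expect_equal(m$p, s$p)
    expect_equal(m$adjusted_for, "")
  })
})

test_that("multiple regression recovers a planted partial effect", {
  withr::with_seed(23, {
    n <- 5000
    z <- rnorm(n)                      # confounder
    x <- 0.6 * z + rnorm(n, sd = 0.8)  # exposure contaminated by z
    y <- 0.3 * x + 0.5 * z + rnorm(n)
    m <- multiple_regression(y, x, data.frame(z = z))
    expect_equal(m$beta_std * sd(y) / sd(x), 0.3, tolerance = 0.05)
    # the unadjusted slope is confounded upward
    expect_gt(simple_regression(x, y)$beta_std, m$beta_std)
  })
})

test_that("rank-deficient designs error naming the collinear column", {
  withr::with_seed(29, {
    x <- rnorm(30); y <- rnorm(30)
    covs <- data.frame(c1 = x)     # exact duplicate of the exposure
    expect_error(multiple_regression(y, x, covs),
                 class = "chronomeal_collinearity_error", regexp = "c1")
  })
})

test_that("Welch t test matches its closed form and a permutation oracle", {
  same <- welch_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  expect_lt(welch_t_test(c(1, 2, 3), c(11, 12, 13))$p, 0.01)

  withr::with_seed(31, {
    a <- rnorm(12, 0); b <- rnorm(12, 1.2)
    w <- welch_t_test(a, b)
    pooled <- c(a, b)
    perm <- replicate(4000, {
      idx <- sample(24, 12)
      abs(mean(pooled[idx]) - mean(pooled[-idx]))
    })
    p_perm <- mean(perm >= abs(mean(a) - mean(b)))
    expect_lt(abs(w$p - p_perm), 0.02)
  })
  expect_error(welch_t_test(1, c(1, 2)), class = "chronomeal_input_error")
})

test_that("one-way ANOVA equals the squared pooled t for two groups", {
  withr::with_seed(37, {
    for (i in 1:10) {
      a <- rnorm(sample(5:20, 1)); b <- rnorm(sample(5:20, 1), 0.5)
      res <- sex_comparison_anova(c(a, b), rep(c("m", "w"), c(length(a), length(b))))
      t_pooled <- t.test(a, b, var.equal = TRUE)
      expect_equal(res$f, unname(t_pooled$statistic)^2)
      expect_equal(res$p, t_pooled$p.value)
    }
  })
  eq <- sex_comparison_anova(c(1, 2, 3, 1, 2, 3), rep(c("m", "w"), each = 3))
  expect_equal(eq$f, 0)
  sep <- sex_comparison_anova(c(0, 0, 0, 1, 1, 1), rep(c("m", "w"), each = 3))
  expect_lt(sep$p, 0.001)
  expect_error(sex_comparison_anova(1:5, rep("m", 5)),
               class = "chronomeal_input_error")
})

test_that("step-up adjustments reproduce hand-enumerated values", {
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  expect_equal(adjust_pvalues(0.03), 0.03)
  expect_equal(adjust_pvalues(c(0.001, rep(1, 9)))[1], 0.01)
  # Hochberg: step-up with (m - rank + 1) multipliers
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03, 0.04), "hochberg"),
               c(0.04, 0.04, 0.04, 0.04))
  expect_equal(adjust_pvalues(c(0.005, 0.9), "hochberg"), c(0.01, 0.9))
  expect_error(adjust_pvalues(c(0.5, 1.2)), class = "chronomeal_input_error")
})

test_that("adjusted p-values are monotone, bounded and idempotent", {
  withr::with_seed(41, {
    for (method in c("benjamini_hochberg", "hochberg")) {
      p <- runif(25)
      adj <- adjust_pvalues(p, method)
      expect_true(all(adj >= p))
      expect_true(all(adj <= 1))
      # non-decreasing in the sorted-p order
      expect_true(all(diff(adj[order(p)]) >= -1e-12))
      # re-adjusting never lowers a value, and genuinely fixed inputs
      # (constant vectors) pass through unchanged
      expect_true(all(adjust_pvalues(adj, method) >= adj - 1e-12))
      expect_equal(adjust_pvalues(rep(0.2, 6), method), rep(0.2, 6))
    }
  })
})

test_that("association table runs the grid with per-stratum families", {
  withr::with_seed(43, {
    n <- 60
    data <- tibble::tibble(
      sex = rep(c("man", "woman"), each = n / 2),
      eating_window = rnorm(n, 12, 1.5),
      msp_to_first = rnorm(n, 4.9, 1.4),
      homa_ir = rnorm(n, 0.2, 0.2),
      risk_z = rnorm(n),
      med_diet_score = rnorm(n, 8, 2),
      light_pa_min = rnorm(n, 120, 30),
      midsleep_week = rnorm(n, 5, 1),
      sleep_duration_week = rnorm(n, 7.8, 1),
      bmi = rnorm(n, 25, 4)
    )
    tab <- association_table(data, c("eating_window", "msp_to_first"),
                             c("homa_ir", "risk_z"), adjusted = TRUE)
    expect_setequal(unique(tab$stratum), c("all", "man", "woman"))
    expect_true(all(tab$p_adj >= tab$p))
    # sex is a covariate only in the pooled stratum
    adj_rows <- tab[tab$adjusted_for != "", ]
    expect_true(all(grepl("sex", adj_rows$adjusted_for[adj_rows$stratum == "all"])))
    expect_false(any(grepl("sex", adj_rows$adjusted_for[adj_rows$stratum != "all"])))
    # midsleep-anchored exposures are adjusted for sleep duration instead of
    # midsleep point
    m2f <- adj_rows[adj_rows$exposure == "msp_to_first", ]
    expect_true(all(grepl("sleep_duration_week", m2f$adjusted_for)))
    expect_false(any(grepl("midsleep_week", m2f$adjusted_for)))
    ew <- adj_rows[adj_rows$exposure == "eating_window", ]
    expect_true(all(grepl("midsleep_week", ew$adjusted_for)))

    wide <- association_wide(tab)
    expect_equal(nrow(wide), 4) # 2 exposures x 2 outcomes
    expect_true(all(c("beta_std_man", "p_woman", "n_all") %in% names(wide)))
  })
})
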