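test_that("mixed ANOVA matches stats::aov on balanced data", {
  set.seed(10)
  n <- 12
  tb <- tibble::tibble(
    id = sprintf("P%02d", 1:(2 * n)),
    group = rep(c("MDD", "control"), each = n),
    ext_prop_csp = rnorm(2 * n, 1, 0.3) + rep(c(0, 0.3), each = n),
    ext_prop_csm = rnorm(2 * n, 0.8, 0.3)
  )
  a <- mixed_anova_2x2(tb, "extinction")
  long <- tidyr::pivot_longer(tb, dplyr::starts_with("ext"),
                              names_to = "cs", values_to = "y")
  fit <- summary(stats::aov(y ~ group * cs + Error(id / cs), data = long))
  between <- fit[["Error: id"]][[1]]
  within <- fit[["Error: id:cs"]][[1]]
  expect_equal(a$f[a$effect == "group"], between["group", "F value"],
               tolerance = 1e-10)
  expect_equal(a$f[a$effect == "cs_type"], within["cs", "F value"],
               tolerance = 1e-10)
  expect_equal(a$f[a$effect == "cs_type:group"], within["group:cs", "F value"],
               tolerance = 1e-10)
  expect_equal(a$ss, c(between["group", "Sum Sq"], within["cs", "Sum Sq"],
                       within["group:cs", "Sum Sq"]),
               tolerance = 1e-10)
  expect_equal(a$df_den, rep(2 * n - 2L, 3))
})

test_that("mixed ANOVA agrees with an independent contrast oracle on random unbalanced data", {
  set.seed(20)
  for (k in 1:100) {
    n1 <- sample(3:12, 1)
    n2 <- sample(3:12, 1)
    tb <- tibble::tibble(
      group = c(rep("MDD", n1), rep("control", n2)),
      acq_prop_csp = rnorm(n1 + n2, 1.2, 0.4),
      acq_prop_csm = rnorm(n1 + n2, 0.9, 0.4)
    )
    a <- mixed_anova_2x2(tb, "acquisition")
    want <- oracle_mixed_anova(tb$group, tb$acq_prop_csp, tb$acq_prop_csm)
    expect_equal(a$f[a$effect == "group"], unname(want["group"]), tolerance = 1e-9)
    expect_equal(a$f[a$effect == "cs_type"], unname(want["cs_type"]), tolerance = 1e-9)
    expect_equal(a$f[a$effect == "cs_type:group"], unname(want["interaction"]),
                 tolerance = 1e-9)
    # effect-size identity eta_p^2 = F / (F + df_den)
    expect_equal(a$eta_p_sq, a$f / (a$f + a$df_den), tolerance = 1e-12)
    expect_true(all(a$eta_p_sq >= 0 & a$eta_p_sq <= 1))
  }
})

test_that("single-group within F equals the squared paired t", {
  set.seed(30)
  tb <- tibble::tibble(group = "MDD",
                       ext_prop_csp = rnorm(15, 1, 0.3),
                       ext_prop_csm = rnorm(15, 0.8, 0.3))
  a <- mixed_anova_2x2(tb, "extinction")
  tt <- paired_t(tb$ext_prop_csp, tb$ext_prop_csm)
  expect_equal(a$f, tt$t^2, tolerance = 1e-12)
  expect_equal(a$df_den, tt$df)
  expect_equal(a$p, tt$p, tolerance = 1e-12)
})

test_that("a null within-effect gives F = 0 with nonzero between spread", {
  tb <- tibble::tibble(group = rep(c("MDD", "control"), each = 5),
                       acq_prop_csp = c(1:5, 2:6) / 2,
                       acq_prop_csm = c(1:5, 2:6) / 2)
  a <- mixed_anova_2x2(tb, "acquisition")
  expect_equal(a$ss[a$effect == "cs_type"], 0)
  expect_equal(a$f[a$effect == "cs_type"], 0)
})

test_that("listwise deletion drops incomplete participants with a count", {
  tb <- tibble::tibble(group = rep(c("MDD", "control"), each = 5),
                       acq_prop_csp = c(NA, rnorm(9)),
                       acq_prop_csm = rnorm(10))
  a <- mixed_anova_2x2(tb, "acquisition")
  expect_equal(attr(a, "n"), 9)
  expect_equal(attr(a, "n_dropped"), 1)
})

test_that("t statistics match brute-force formulas and swap symmetry", {
  set.seed(40)
  for (k in 1:100) {
    x <- rnorm(sample(3:20, 1), 1, 2)
    y <- rnorm(sample(3:20, 1), 0, 2)
    got <- independent_t(x, y)
    expect_equal(got$t, oracle_pooled_t(x, y), tolerance = 1e-12)
    expect_equal(got$df, length(x) + length(y) - 2)
    swapped <- independent_t(y, x)
    expect_equal(swapped$t, -got$t, tolerance = 1e-12)
    expect_equal(swapped$p, got$p, tolerance = 1e-12)
  }
  # summary-input route equals the raw-data route
  x <- rnorm(14, 5, 2); y <- rnorm(11, 4, 1.5)
  a <- independent_t(x, y)
  b <- independent_t_summary(mean(x), sd(x), 14, mean(y), sd(y), 11)
  expect_equal(a$t, b$t, tolerance = 1e-12)
  w1 <- independent_t(x, y, var_equal = FALSE)
  w2 <- independent_t_summary(mean(x), sd(x), 14, mean(y), sd(y), 11,
                              var_equal = FALSE)
  expect_equal(w1$t, w2$t, tolerance = 1e-12)
  expect_equal(w1$df, w2$df, tolerance = 1e-9)
})

test_that("paired t matches its formula and errors on zero variance", {
  set.seed(41)
  x <- rnorm(12); y <- rnorm(12)
  got <- paired_t(x, y)
  d <- x - y
  expect_equal(got$t, mean(d) / (sd(d) / sqrt(12)), tolerance = 1e-12)
  expect_equal(got$df, 11)
  expect_error(paired_t(x, x), class = "startlekit_stats_error")
})

test_that("Pearson r matches its formula on random and exact inputs", {
  set.seed(42)
  for (k in 1:100) {
    n <- sample(4:30, 1)
    x <- rnorm(n); y <- rnorm(n)
    got <- pearson_r(x, y)
    expect_equal(got$r, oracle_r(x, y), tolerance = 1e-12)
    expect_equal(got$df, n - 2)
  }
  x <- rnorm(10)
  expect_equal(pearson_r(x, 2 * x + 1)$r, 1.0)
  expect_equal(pearson_r(x, -x)$r, -1.0)
  expect_error(pearson_r(x, rep(1, 10)), class = "startlekit_stats_error")
})

test_that("chi-square matches sum((O-E)^2/E) and handles edge tables", {
  set.seed(43)
  for (k in 1:100) {
    m <- matrix(sample(1:40, 4, replace = TRUE), 2)
    got <- chi_square_2x2(m)
    expect_equal(got$chisq, oracle_chisq(m), tolerance = 1e-12)
    expect_equal(got$df, 1)
  }
  expect_equal(chi_square_2x2(matrix(c(10, 20, 10, 20), 2))$chisq, 0)
  expect_error(chi_square_2x2(matrix(c(0, 0, 5, 5), 2, byrow = TRUE)),
               class = "startlekit_stats_error")
})

test_that("awareness classification follows the three-level rule", {
  expect_equal(classify_awareness(TRUE, TRUE), "fully_aware")
  expect_equal(classify_awareness(TRUE, FALSE), "partially_aware")
  expect_equal(classify_awareness(FALSE, TRUE), "partially_aware")
  expect_equal(classify_awareness(FALSE, FALSE), "unaware")
  expect_equal(classify_awareness(c(TRUE, FALSE), c(TRUE, FALSE)),
               c("fully_aware", "unaware"))
})

test_that("tidy and glance methods expose the ANOVA as tibbles", {
  sc <- simulate_cohort_scores(cohort_design(seed = 2))
  a <- mixed_anova_2x2(sc, "extinction")
  td <- generics::tidy(a)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("effect", "f", "p", "eta_p_sq") %in% names(td)))
  gl <- generics::glance(a)
  expect_equal(gl$n, attr(a, "n"))
  expect_equal(gl$p_interaction, a$p[a$effect == "cs_type:group"])
})
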