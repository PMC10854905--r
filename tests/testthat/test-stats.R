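test_that("normality/variance gate decides sensibly on known distributions", {
  set.seed(101)
  x <- rnorm(500); y <- rnorm(500)
  g <- normality_and_variance_gate(x, y)
  expect_equal(g$policy, "parametric")
  expect_true(g$equal_variance)

  xs <- rlnorm(200, 0, 1); ys <- rlnorm(200, 0, 1)
  gs <- normality_and_variance_gate(xs, ys)
  expect_equal(gs$policy, "nonparametric")

  expect_error(normality_and_variance_gate(rep(1, 10), rnorm(10)),
               "degenerate variance")
  expect_error(normality_and_variance_gate(1:2, rnorm(10)), "at least 3")
})

test_that("two-group dispatch and closed-form values", {
  # identical pairs: statistic 0, p 1
  r <- two_group_continuous(c(1, 2, 3, 4), c(1, 2, 3, 4), paired = TRUE)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)

  # hand-computed pooled t: x=(1,2,3), y=(2,3,4) -> sp2 = 1, t = -1.2247
  gate <- structure(list(policy = "parametric", equal_variance = TRUE,
                         trail = "forced"), class = "test_gate")
  r2 <- two_group_continuous(c(1, 2, 3), c(2, 3, 4), gate = gate)
  expect_equal(unname(round(r2$statistic, 4)), -1.2247)
  expect_match(r2$test, "pooled")

  # nonparametric gate dispatches to Mann-Whitney
  gate_np <- structure(list(policy = "nonparametric", equal_variance = TRUE,
                            trail = "forced"), class = "test_gate")
  r3 <- suppressWarnings(
    two_group_continuous(c(1, 2, 3, 10), c(2, 3, 4, 11), gate = gate_np))
  expect_match(r3$test, "Mann-Whitney")
})

test_that("Mann-Whitney is invariant under strictly monotone transforms", {
  set.seed(5)
  gate_np <- structure(list(policy = "nonparametric", equal_variance = TRUE,
                            trail = "forced"), class = "test_gate")
  for (i in 1:20) {
    x <- rnorm(25); y <- rnorm(30, 0.4)
    r1 <- two_group_continuous(x, y, gate = gate_np)
    f <- function(v) exp(3 * v) + v^3  # strictly increasing
    r2 <- two_group_continuous(f(x), f(y), gate = gate_np)
    expect_equal(r1$statistic, r2$statistic)
    expect_equal(r1$p_value, r2$p_value)
  }
})

test_that("chi-square matches its closed form on random tables", {
  r <- chi_square_2x2(18, 16, 16, 9)
  expect_equal(unname(round(r$statistic, 3)), 0.722)
  expect_equal(unname(round(r$p_value, 3)), 0.396)
  expect_equal(chi_square_2x2(10, 10, 10, 10)$statistic, 0)
  expect_equal(suppressWarnings(chi_square_2x2(3, 1, 1, 3)$statistic), 2)
  expect_error(chi_square_2x2(0, 0, 5, 5), "degenerate table")

  set.seed(33)
  for (i in 1:1000) {
    t <- rpois(4, sample(3:40, 1)) + 1  # positive margins guaranteed
    a <- t[1]; b <- t[2]; cc <- t[3]; d <- t[4]
    n <- a + b + cc + d
    closed <- n * (a * d - b * cc)^2 /
      ((a + b) * (cc + d) * (a + cc) * (b + d))
    # small random tables trigger the expected-count approximation notice
    expect_equal(suppressWarnings(chi_square_2x2(a, b, cc, d)$statistic),
                 closed, tolerance = 1e-12)
  }
})

test_that("one-way ANOVA: hand table, identical groups, t^2 = F", {
  r <- anova_oneway(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)

  # oracle ANOVA table: groups (1,2),(3,4),(5,6): SSB=16 (df 2, MS 8),
  # SSW=1.5 (df 3, MS 0.5) -> F = 16
  r2 <- anova_oneway(list(c(1, 2), c(3, 4), c(5, 6)))
  expect_equal(r2$statistic, 16)

  expect_error(anova_oneway(list(c(1, 1), c(2, 2))), "zero within-group")

  # pooled t^2 equals the 2-group F
  set.seed(9)
  gate <- structure(list(policy = "parametric", equal_variance = TRUE,
                         trail = ""), class = "test_gate")
  for (i in 1:25) {
    x <- rnorm(12); y <- rnorm(15, 0.5)
    t <- two_group_continuous(x, y, gate = gate)$statistic
    f <- anova_oneway(list(x, y))$statistic
    expect_equal(t^2, f, tolerance = 1e-9)
  }
})

test_that("logistic regression: null, parameter recovery, degeneracies", {
  set.seed(77)
  n <- 4000
  x <- rnorm(n)
  y0 <- rbinom(n, 1, 0.4)  # independent of x
  m0 <- logistic_regression(y0, data.frame(x = x))
  expect_gt(m0$terms$or, 0.9)
  expect_lt(m0$terms$or, 1.1)

  # true OR 2.0
  y1 <- rbinom(n, 1, plogis(-0.3 + log(2) * x))
  m1 <- logistic_regression(y1, data.frame(x = x))
  expect_gt(m1$terms$or, 1.8)
  expect_lt(m1$terms$or, 2.2)
  expect_true(m1$terms$ci_low <= 2 && 2 <= m1$terms$ci_high)
  expect_true(m1$terms$ci_low <= m1$terms$or &&
                m1$terms$or <= m1$terms$ci_high)

  expect_error(logistic_regression(rep(1, 50), data.frame(x = rnorm(50))),
               "degenerate outcome")
  # perfect separation is named
  xs <- c(rnorm(30, -5), rnorm(30, 5))
  ys <- rep(c(0, 1), each = 30)
  expect_error(suppressWarnings(
    logistic_regression(ys, data.frame(sep = xs))), "separation.*sep")

  # listwise deletion is counted
  xm <- rnorm(100); xm[1:7] <- NA
  ym <- rbinom(100, 1, 0.5)
  mm <- logistic_regression(ym, data.frame(x = xm))
  expect_equal(mm$n_dropped, 7)
})

test_that("report: structure enforcement and null cohort behaviour", {
  co <- generate_cohort(cohort_spec(n_subjects = c(BRVO = 30L, CRVO = 30L),
                                    seed = 21))
  broken <- co[-1, ]  # drops one eye of subject 1
  expect_error(build_comparison_report(broken), "exactly one affected")

  expect_error(build_comparison_report(co[, setdiff(names(co), "avr")]),
               "missing required column.*avr")

  rep <- build_comparison_report(co)
  expect_s3_class(rep, "comparison_report")
  expect_equal(nrow(rep$per_eye), length(fundusgeom:::.eye_var_names))
  expect_true(all(rep$per_eye$paired_BRVO_p >= 0 &
                    rep$per_eye$paired_BRVO_p <= 1))
})

test_that("null cohorts rarely reach significance", {
  # global null: effects off -> expected false-positive rate ~ alpha per test
  ps <- c()
  for (seed in 1:5) {
    co <- generate_cohort(cohort_spec(n_subjects = c(BRVO = 40L, CRVO = 40L),
                                      effects = FALSE, seed = seed))
    rep <- build_comparison_report(co)
    ps <- c(ps, rep$per_eye$between_aff_p, rep$per_eye$between_con_p)
  }
  expect_lt(mean(ps < 0.05), 0.12)  # ~0.05 expected, generous margin
})
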