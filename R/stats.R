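# Case-control statistical workflow: normality/variance gating, paired and
# independent two-sample tests, chi-square, one-way ANOVA, and
# multivariable logistic regression with adjusted odds ratios.

#' Normality and variance-homogeneity gate
#'
#' Decides between parametric and nonparametric two-sample testing at
#' alpha = 0.05.  Normality: Shapiro-Wilk when a group has n < 50,
#' Lilliefors-corrected Kolmogorov-Smirnov otherwise.  Variance
#' homogeneity: Levene's test (centered at the mean, the SPSS convention).
#'
#' @param x,y numeric vectors, n >= 3 each.
#' @param alpha gate level (default 0.05).
#' @return list of class `test_gate`: `policy`
#'   ("parametric"/"nonparametric"), `equal_variance` (logical),
#'   `p_normality` (per group), `p_levene`, `trail` (character log of the
#'   decisions).
#' @export
normality_and_variance_gate <- function(x, y, alpha = 0.05) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  check_that(length(x) >= 3 && length(y) >= 3, "x, y",
             "need at least 3 observations per group")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("degenerate variance: a group is constant", call. = FALSE)
  }
  p_norm <- vapply(list(x, y), function(v) {
    if (length(v) < 50) stats::shapiro.test(v)$p.value
    else nortest::lillie.test(v)$p.value
  }, numeric(1))
  which_norm <- ifelse(lengths(list(x, y)) < 50, "shapiro", "ks-lilliefors")
  dat <- data.frame(v = c(x, y),
                    g = factor(rep(c("x", "y"), c(length(x), length(y)))))
  p_lev <- car::leveneTest(v ~ g, data = dat, center = mean)[1, "Pr(>F)"]
  policy <- if (all(p_norm > alpha)) "parametric" else "nonparametric"
  structure(list(
    policy = policy,
    equal_variance = p_lev > alpha,
    p_normality = p_norm, p_levene = p_lev,
    trail = c(sprintf("normality[%s]: p=%.3g, %.3g", paste(which_norm, collapse = "/"),
                      p_norm[1], p_norm[2]),
              sprintf("levene: p=%.3g", p_lev),
              sprintf("policy: %s, %s variance", policy,
                      if (p_lev > alpha) "equal" else "unequal"))
  ), class = "test_gate")
}

new_stat_result <- function(test, statistic, p, n, trail = character(0)) {
  structure(list(test = test, statistic = unname(statistic),
                 p_value = unname(p), n = n, trail = trail),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (n = %s)\n", x$test,
              x$statistic, x$p_value, paste(x$n, collapse = "/")))
  invisible(x)
}

#' Gated two-group comparison of a continuous variable
#'
#' Dispatches on the gate and pairing: Student's pooled t (parametric,
#' equal variances), Welch t (parametric, unequal), Mann-Whitney U
#' (independent nonparametric), paired t, or Wilcoxon signed-rank (paired
#' nonparametric).  Two-sided throughout.
#'
#' @param x,y numeric vectors; equal length when `paired`.
#' @param paired logical.
#' @param gate optional [normality_and_variance_gate()] result; computed
#'   from the data when NULL (for paired data the gate runs on the
#'   differences against a symmetry check).
#' @return `stat_result`.
#' @export
two_group_continuous <- function(x, y, paired = FALSE, gate = NULL) {
  if (paired) {
    check_that(length(x) == length(y), "x, y",
               "paired comparison needs equal lengths")
    d <- x - y
    d <- d[!is.na(d)]
    if (all(d == 0)) {
      return(new_stat_result("paired t-test", 0, 1, length(d),
                             "identical pairs: t = 0, p = 1"))
    }
    if (is.null(gate)) {
      p_norm <- stats::shapiro.test(d)$p.value
      policy <- if (p_norm > 0.05) "parametric" else "nonparametric"
      trail <- sprintf("shapiro on differences: p=%.3g -> %s", p_norm, policy)
    } else {
      policy <- gate$policy; trail <- gate$trail
    }
    if (policy == "parametric") {
      tt <- stats::t.test(x, y, paired = TRUE)
      new_stat_result("paired t-test", tt$statistic, tt$p.value, length(d), trail)
    } else {
      wt <- stats::wilcox.test(x, y, paired = TRUE, exact = length(d) <= 20,
                               correct = FALSE)
      new_stat_result("Wilcoxon signed-rank test", wt$statistic, wt$p.value,
                      length(d), trail)
    }
  } else {
    if (is.null(gate)) gate <- normality_and_variance_gate(x, y)
    n <- c(sum(!is.na(x)), sum(!is.na(y)))
    if (gate$policy == "parametric") {
      tt <- stats::t.test(x, y, var.equal = gate$equal_variance)
      nm <- if (gate$equal_variance) "independent t-test (pooled)" else
        "independent t-test (Welch)"
      new_stat_result(nm, tt$statistic, tt$p.value, n, gate$trail)
    } else {
      exact <- max(n) <= 20
      wt <- stats::wilcox.test(x, y, exact = exact, correct = FALSE)
      new_stat_result("Mann-Whitney U test", wt$statistic, wt$p.value, n,
                      gate$trail)
    }
  }
}

#' Pearson chi-square test on a 2x2 table
#'
#' Uncorrected Pearson chi-square (no Yates continuity correction), df = 1.
#'
#' @param a,b,c,d cell counts, row-wise: (a b / c d).
#' @return `stat_result`.
#' @examples
#' chi_square_2x2(18, 16, 16, 9)  # chi-square 0.722, p 0.396
#' @export
chi_square_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  check_that(all(cells >= 0) && all(cells == round(cells)), "cells",
             "must be nonnegative integers")
  m <- matrix(cells, 2, 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("degenerate table: a margin is zero", call. = FALSE)
  }
  ct <- stats::chisq.test(m, correct = FALSE)
  new_stat_result("chi-square test", ct$statistic, ct$p.value, sum(m))
}

#' One-way analysis of variance
#'
#' @param groups list of numeric vectors (>= 2 groups, each n >= 2).
#' @return `stat_result` with the F statistic; degrees of freedom in
#'   `$n` as c(df_between, df_within).
#' @export
anova_oneway <- function(groups) {
  check_that(is.list(groups) && length(groups) >= 2, "groups",
             "need at least two groups")
  check_that(all(lengths(groups) >= 2), "groups", "each group needs n >= 2")
  v <- unlist(groups)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (all(vapply(groups, stats::sd, numeric(1)) == 0)) {
    if (stats::sd(v) == 0) {
      return(new_stat_result("one-way ANOVA", 0, 1, lengths(groups),
                             "all values identical"))
    }
    stop("zero within-group variance in every group", call. = FALSE)
  }
  fit <- stats::aov(v ~ g)
  s <- summary(fit)[[1]]
  new_stat_result("one-way ANOVA", s[1, "F value"], s[1, "Pr(>F)"],
                  c(s[1, "Df"], s[2, "Df"]))
}

#' Multivariable logistic regression with adjusted odds ratios
#'
#' Maximum-likelihood fit (IRLS via `glm`, binomial logit); Wald 95%
#' confidence intervals; odds ratios exp(coefficient).  With the control
#' condition as reference, OR > 1 flags a risk factor.
#'
#' @param outcome binary vector (0/1, logical, or 2-level factor).
#' @param covariates data.frame of numeric covariates of interest.
#' @param adjust_for optional data.frame of adjustment covariates.
#' @return object of class `logistic_result`: data.frame `terms` (term,
#'   or, ci_low, ci_high, p), `n_used`, `n_dropped` (listwise deletion),
#'   `adjusted_for`.
#' @export
logistic_regression <- function(outcome, covariates, adjust_for = NULL) {
  if (is.factor(outcome)) outcome <- as.integer(outcome) - 1L
  outcome <- as.numeric(outcome)
  check_that(all(outcome %in% c(0, 1), na.rm = TRUE), "outcome",
             "must be binary 0/1")
  dat <- cbind(data.frame(.y = outcome), covariates)
  adj_names <- character(0)
  if (!is.null(adjust_for)) {
    adj_names <- names(adjust_for)
    dat <- cbind(dat, adjust_for)
  }
  cc <- stats::complete.cases(dat)
  n_dropped <- sum(!cc)
  dat <- dat[cc, , drop = FALSE]
  if (length(unique(dat$.y)) < 2) {
    stop("degenerate outcome: only one class present", call. = FALSE)
  }
  fit <- suppressWarnings(
    stats::glm(.y ~ ., data = dat, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)))
  co <- summary(fit)$coefficients
  big <- rownames(co)[abs(co[, "Estimate"]) > 15 & rownames(co) != "(Intercept)"]
  if (length(big) || fit$deviance < 1e-6) {
    # name the covariates that separate the outcome on their own
    culprits <- big
    for (nm in setdiff(names(dat), ".y")) {
      x0 <- dat[[nm]][dat$.y == 0]; x1 <- dat[[nm]][dat$.y == 1]
      if (is.numeric(dat[[nm]]) &&
            (max(x0) < min(x1) || max(x1) < min(x0))) {
        culprits <- c(culprits, nm)
      }
    }
    if (!length(culprits)) culprits <- "a linear combination of covariates"
    stop("perfect (or quasi-perfect) separation on covariate(s): ",
         paste(unique(culprits), collapse = ", "), call. = FALSE)
  }
  if (!fit$converged) {
    stop("logistic model did not converge after ", fit$iter, " iterations",
         call. = FALSE)
  }
  idx <- rownames(co) != "(Intercept)"
  terms <- data.frame(
    term = rownames(co)[idx],
    or = exp(co[idx, "Estimate"]),
    ci_low = exp(co[idx, "Estimate"] - 1.96 * co[idx, "Std. Error"]),
    ci_high = exp(co[idx, "Estimate"] + 1.96 * co[idx, "Std. Error"]),
    p = co[idx, "Pr(>|z|)"],
    row.names = NULL
  )
  structure(list(terms = terms, n_used = nrow(dat), n_dropped = n_dropped,
                 adjusted_for = adj_names, fit = fit),
            class = "logistic_result")
}

#' @export
print.logistic_result <- function(x, ...) {
  cat(sprintf("logistic model, n = %d (%d dropped)%s\n", x$n_used, x$n_dropped,
              if (length(x$adjusted_for))
                paste0(", adjusted for ", paste(x$adjusted_for, collapse = ", "))
              else ""))
  t <- x$terms
  for (i in seq_len(nrow(t))) {
    cat(sprintf("  %-24s OR %6.3f (95%% CI %.3f-%.3f), p = %.4g\n",
                t$term[i], t$or[i], t$ci_low[i], t$ci_high[i], t$p[i]))
  }
  invisible(x)
}
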