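#' Simple linear regression with R-squared and F-test p-value
#'
#' Ordinary least squares of `y` on `x`, as used to relate mean depolarization
#' or success rate to the temporal-average intensity. The p-value is the
#' F-test of the slope (equivalently the two-sided t-test).
#'
#' @param x,y Numeric vectors of equal length, `n >= 2`, `var(x) > 0`.
#' @return A list of class `regression_result`: `slope`, `intercept`,
#'   `r_squared`, `p_value` (`NA` when `n < 3`), `n`.
#' @examples
#' linear_regression(0:2, c(0, 2, 1))
#' @export
linear_regression <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  n <- length(x)
  if (n < 2L) stop("need at least 2 observations", call. = FALSE)
  if (stats::var(x) == 0) stop("degenerate design: x is constant", call. = FALSE)
  if (stats::var(y) == 0) {
    # flat response: zero slope explains nothing
    return(structure(list(slope = 0, intercept = y[1], r_squared = 0,
                          p_value = NA_real_, n = n),
                     class = "regression_result"))
  }
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  p <- if (n >= 3) {
    f <- sm$fstatistic
    if (is.null(f)) NA_real_ else unname(stats::pf(f[1], f[2], f[3], lower.tail = FALSE))
  } else NA_real_
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = sm$r.squared,
                 p_value = p,
                 n = n),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("<regression> slope %.4g, intercept %.4g, R^2 = %.3f, p = %.3g, n = %d\n",
              x$slope, x$intercept, x$r_squared, x$p_value, x$n))
  invisible(x)
}

#' Kruskal-Wallis rank test across groups
#'
#' Rank-based one-way comparison (tie-corrected H statistic, chi-square
#' approximation with k - 1 degrees of freedom), the test used for all
#' distributional comparisons of spike features and per-DC responses.
#'
#' @param groups A list of numeric vectors (>= 2 groups, each non-empty).
#' @return A list of class `group_test_result`: `statistic`, `p_value`, `dof`,
#'   `group_sizes`, `test_name`. Degenerate input (all pooled values
#'   identical) returns H = 0, p = 1.
#' @examples
#' kruskal_wallis(list(c(1, 2, 3), c(101, 102, 103)))
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("need a list of >= 2 groups", call. = FALSE)
  }
  if (any(!vapply(groups, length, integer(1)))) {
    stop("all groups must be non-empty", call. = FALSE)
  }
  pooled <- unlist(groups, use.names = FALSE)
  sizes <- vapply(groups, length, integer(1))
  if (length(unique(pooled)) == 1L) {
    return(structure(list(statistic = 0, p_value = 1,
                          dof = length(groups) - 1L,
                          group_sizes = sizes,
                          test_name = "Kruskal-Wallis"),
                     class = "group_test_result"))
  }
  g <- factor(rep(seq_along(groups), times = sizes))
  kt <- stats::kruskal.test(pooled, g)
  structure(list(statistic = unname(kt$statistic),
                 p_value = kt$p.value,
                 dof = unname(kt$parameter),
                 group_sizes = sizes,
                 test_name = "Kruskal-Wallis"),
            class = "group_test_result")
}

#' @export
print.group_test_result <- function(x, ...) {
  cat(sprintf("<%s> H = %.4g, dof = %d, p = %.3g (n = %s)\n",
              x$test_name, x$statistic, x$dof, x$p_value,
              paste(x$group_sizes, collapse = "/")))
  invisible(x)
}

#' Two-way factorial ANOVA (Type II sums of squares)
#'
#' Factorial decomposition of `values` over two crossed factors (e.g. duty
#' cycle and pressure) with main-effect and interaction F tests. Type II sums
#' of squares are used so that unbalanced cell counts (trace counts differ
#' across settings) do not contaminate the main effects.
#'
#' @param values Numeric response vector.
#' @param factor_a,factor_b Factor labels, same length as `values`; >= 2
#'   levels each. Every A x B cell must be observed; the interaction test
#'   requires > 0 residual degrees of freedom.
#' @return A list of class `two_way_anova_result` with per-term `F` and `p`
#'   (`factor_a`, `factor_b`, `interaction`), the term names and
#'   `residual_dof`.
#' @export
two_way_anova <- function(values, factor_a, factor_b) {
  if (length(values) != length(factor_a) || length(values) != length(factor_b)) {
    stop("values and factors must have equal length", call. = FALSE)
  }
  a <- factor(factor_a)
  b <- factor(factor_b)
  if (nlevels(a) < 2L || nlevels(b) < 2L) {
    stop("each factor needs >= 2 levels", call. = FALSE)
  }
  tab <- table(a, b)
  if (any(tab == 0L)) {
    empty <- which(tab == 0L, arr.ind = TRUE)[1, ]
    stop(sprintf("unbalanced design: empty cell (%s = %s, %s = %s)",
                 "factor_a", levels(a)[empty[1]],
                 "factor_b", levels(b)[empty[2]]), call. = FALSE)
  }
  fit <- stats::lm(values ~ a * b)
  an <- car::Anova(fit, type = 2)
  terms <- rownames(an)
  get_row <- function(nm) {
    i <- match(nm, terms)
    c(F = an[i, "F value"], p = an[i, "Pr(>F)"])
  }
  structure(list(factor_a = get_row("a"),
                 factor_b = get_row("b"),
                 interaction = get_row("a:b"),
                 residual_dof = an["Residuals", "Df"],
                 term_names = c("factor_a", "factor_b", "interaction")),
            class = "two_way_anova_result")
}

#' @export
print.two_way_anova_result <- function(x, ...) {
  cat("<two-way ANOVA, Type II SS>\n")
  for (nm in x$term_names) {
    cat(sprintf("  %-11s F = %.4g, p = %.3g\n", nm, x[[nm]]["F"], x[[nm]]["p"]))
  }
  cat(sprintf("  residual dof = %d\n", x$residual_dof))
  invisible(x)
}

#' Pairwise Kruskal-Wallis comparisons
#'
#' Post-hoc pairwise comparisons between groups, each a two-group
#' Kruskal-Wallis test. No multiple-testing correction is applied (raw
#' p-values are reported throughout the package).
#'
#' @param groups Named list of numeric vectors.
#' @return data.frame with columns `group1`, `group2`, `statistic`, `p_value`.
#' @export
pairwise_kruskal <- function(groups) {
  nm <- names(groups)
  if (is.null(nm)) nm <- paste0("g", seq_along(groups))
  pairs <- utils::combn(seq_along(groups), 2)
  rows <- apply(pairs, 2, function(ij) {
    kt <- kruskal_wallis(groups[ij])
    data.frame(group1 = nm[ij[1]], group2 = nm[ij[2]],
               statistic = kt$statistic, p_value = kt$p_value)
  })
  do.call(rbind, rows)
}
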