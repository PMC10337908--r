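#' Benjamini-Hochberg step-up adjustment
#'
#' Classic step-up false-discovery-rate adjustment: sort ascending, scale
#' `p_(i) * m / i`, enforce monotonicity from the largest rank down, cap at
#' 1, and return in the input order. Output never falls below the input,
#' preserves order, and is idempotent.
#'
#' @param p_values Numeric vector of p-values in [0, 1].
#' @return Adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p_values) {
  p <- as.numeric(p_values)
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p)
  scaled <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(scaled)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

as_group_list <- function(groups, values = NULL) {
  if (is.data.frame(groups)) {
    if (!all(c("group", "value") %in% names(groups))) {
      stop("data frame input needs columns 'group' and 'value'")
    }
    return(split(groups$value, groups$group))
  }
  if (is.list(groups)) return(groups)
  if (!is.null(values)) return(split(values, groups))
  stop("groups must be a list of numeric vectors or a data frame (group, value)")
}

group_moments <- function(g) {
  n <- vapply(g, length, numeric(1))
  if (any(n < 2)) stop("each group needs at least 2 values")
  s2 <- vapply(g, var, numeric(1))
  if (any(s2 == 0)) stop("zero-variance group: Welch-type tests are undefined")
  list(n = n, m = vapply(g, mean, numeric(1)), s2 = s2)
}

#' Welch's heteroscedastic one-way ANOVA
#'
#' Welch's F* statistic with Satterthwaite-type denominator degrees of
#' freedom; does not assume equal group variances.
#'
#' @param groups List of numeric vectors, or a data frame with columns
#'   `group` and `value`.
#' @return List of class `welch_anova`: `statistic` (F*), `df1`, `df2`,
#'   `p_value`, `n` (per-group sizes).
#' @export
welch_anova <- function(groups) {
  g <- as_group_list(groups)
  k <- length(g)
  if (k < 2) stop("need at least 2 groups")
  mo <- group_moments(g)
  w <- mo$n / mo$s2
  W <- sum(w)
  xbar <- sum(w * mo$m) / W
  A <- sum(w * (mo$m - xbar)^2) / (k - 1)
  lambda <- sum((1 - w / W)^2 / (mo$n - 1))
  B <- 1 + (2 * (k - 2) / (k^2 - 1)) * lambda
  f_star <- A / B
  df2 <- (k^2 - 1) / (3 * lambda)
  structure(list(statistic = f_star, df1 = k - 1, df2 = df2,
                 p_value = pf(f_star, k - 1, df2, lower.tail = FALSE),
                 n = mo$n),
            class = "welch_anova")
}

#' @export
print.welch_anova <- function(x, ...) {
  cat(sprintf("Welch ANOVA: F* = %.4g, df = (%g, %.2f), p = %.4g\n",
              x$statistic, x$df1, x$df2, x$p_value))
  invisible(x)
}

#' Games-Howell post hoc pairwise comparisons
#'
#' All pairwise comparisons after a Welch-type ANOVA: each pair uses its
#' own standard error `sqrt(s_i^2/n_i + s_j^2/n_j)`, Welch-Satterthwaite
#' degrees of freedom, and the studentized-range distribution with the full
#' number of groups (two-sided, familywise at `conf_level`).
#'
#' @inheritParams welch_anova
#' @param conf_level Confidence level for the simultaneous intervals.
#' @return Data frame: `group1`, `group2`, `difference` (mean1 - mean2),
#'   `se`, `df`, `q`, `p_value`, `ci_lo`, `ci_hi`.
#' @export
games_howell <- function(groups, conf_level = 0.95) {
  g <- as_group_list(groups)
  k <- length(g)
  if (k < 2) stop("need at least 2 groups")
  labels <- names(g)
  if (is.null(labels)) labels <- as.character(seq_len(k))
  mo <- group_moments(g)
  pairs <- utils::combn(k, 2)
  out <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(c_) {
    i <- pairs[1, c_]
    j <- pairs[2, c_]
    vi <- mo$s2[i] / mo$n[i]
    vj <- mo$s2[j] / mo$n[j]
    se <- sqrt(vi + vj)
    df <- (vi + vj)^2 / (vi^2 / (mo$n[i] - 1) + vj^2 / (mo$n[j] - 1))
    diff <- mo$m[i] - mo$m[j]
    q <- abs(diff) / (se / sqrt(2))
    p <- ptukey(q, nmeans = k, df = df, lower.tail = FALSE)
    crit <- qtukey(conf_level, nmeans = k, df = df) * se / sqrt(2)
    data.frame(group1 = labels[i], group2 = labels[j], difference = diff,
               se = se, df = df, q = q, p_value = p,
               ci_lo = diff - crit, ci_hi = diff + crit,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Dispatch to the standard tests used for group comparisons
#'
#' Thin, uniform interface over the base-R implementations:
#' `"mann-whitney"` (two-sample Wilcoxon rank-sum), `"anova"` (one-way),
#' `"pairwise-t"` (two-sided pairwise t tests, Benjamini-Hochberg
#' adjusted), `"two-way-anova"` (with interaction), `"welch-t"`
#' (two-sample Welch t test).
#'
#' @param test Test name (see above).
#' @param data Data frame. For one-way tests: columns `group`, `value`;
#'   for `"two-way-anova"`: columns `a`, `b`, `value`.
#' @param ... Passed to the underlying test.
#' @return List with `test`, `statistic`, `p_value`, `n`, and `detail`
#'   (the underlying fit/htest object, or the pairwise p-value matrix).
#' @export
standard_tests <- function(test = c("mann-whitney", "anova", "pairwise-t",
                                    "two-way-anova", "welch-t"),
                           data, ...) {
  test <- match.arg(test)
  n <- nrow(data)
  if (test == "two-way-anova") {
    if (!all(c("a", "b", "value") %in% names(data))) {
      stop("two-way ANOVA needs columns a, b, value")
    }
    fit <- aov(value ~ a * b, data = transform(data, a = factor(a), b = factor(b)))
    tab <- anova(fit)
    return(list(test = test, statistic = tab[["F value"]][seq_len(3)],
                p_value = tab[["Pr(>F)"]][seq_len(3)], n = n, detail = tab))
  }
  if (!all(c("group", "value") %in% names(data))) {
    stop("need columns group, value")
  }
  g <- split(data$value, data$group)
  if (any(vapply(g, length, numeric(1)) < 2)) {
    stop("each group needs at least 2 values")
  }
  switch(test,
    "mann-whitney" = {
      if (length(g) != 2) stop("Mann-Whitney needs exactly 2 groups")
      ht <- wilcox.test(g[[1]], g[[2]], ...)
      list(test = test, statistic = unname(ht$statistic),
           p_value = ht$p.value, n = n, detail = ht)
    },
    "welch-t" = {
      if (length(g) != 2) stop("Welch t test needs exactly 2 groups")
      ht <- t.test(g[[1]], g[[2]], ...)
      list(test = test, statistic = unname(ht$statistic),
           p_value = ht$p.value, n = n, detail = ht)
    },
    "anova" = {
      fit <- aov(value ~ factor(group), data = data)
      tab <- anova(fit)
      list(test = test, statistic = tab[["F value"]][1],
           p_value = tab[["Pr(>F)"]][1], n = n, detail = tab)
    },
    "pairwise-t" = {
      pt <- pairwise.t.test(data$value, data$group, p.adjust.method = "BH",
                            pool.sd = FALSE, ...)
      list(test = test, statistic = NA_real_, p_value = pt$p.value,
           n = n, detail = pt)
    }
  )
}

#' Power of a two-sample t test
#'
#' Exact power from the noncentral t distribution for a two-sided
#' two-sample t test with equal group sizes and a standardized effect size
#' (Cohen's d).
#'
#' @param effect_size Cohen's d (>= 0).
#' @param n_per_group Observations per group (>= 2).
#' @param alpha Two-sided significance level.
#' @return Power in [alpha, 1).
#' @export
power_two_groups <- function(effect_size, n_per_group, alpha = 0.05) {
  if (effect_size < 0) stop("effect size must be >= 0")
  if (n_per_group < 2) stop("need n >= 2 per group")
  df <- 2 * n_per_group - 2
  ncp <- effect_size * sqrt(n_per_group / 2)
  tc <- qt(1 - alpha / 2, df)
  pt(-tc, df, ncp) + pt(tc, df, ncp, lower.tail = FALSE)
}
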