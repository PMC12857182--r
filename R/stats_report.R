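#' One-way analysis of variance
#'
#' Classical decomposition into between-group and within-group sums of
#' squares; the omnibus test preceding Tukey's HSD post hoc comparisons.
#'
#' @param values Numeric response vector.
#' @param group Factor (or coercible) of group labels, same length.
#' @return A list: `F`, `df_between`, `df_within`, `p`, plus `ss_between`,
#'   `ss_within` and the group `means`.
#' @export
one_way_anova <- function(values, group) {
  group <- factor(group)
  if (nlevels(group) < 2L) ect_error("need >= 2 groups", "ect_invalid_input")
  if (anyNA(values) || any(!is.finite(values))) {
    ect_error("values must be finite", "ect_invalid_input")
  }
  n <- length(values)
  df_b <- nlevels(group) - 1L
  df_w <- n - nlevels(group)
  if (df_w < 1L) ect_error("insufficient residual degrees of freedom", "ect_invalid_input")
  means <- tapply(values, group, mean)
  counts <- tapply(values, group, length)
  grand <- mean(values)
  ss_b <- sum(counts * (means - grand)^2)
  ss_w <- sum((values - means[group])^2)
  if (ss_w == 0) {
    f <- if (ss_b == 0) 0 else Inf
  } else {
    f <- (ss_b / df_b) / (ss_w / df_w)
  }
  list(
    F = f, df_between = df_b, df_within = df_w,
    p = stats::pf(f, df_b, df_w, lower.tail = FALSE),
    ss_between = ss_b, ss_within = ss_w, means = means, counts = counts
  )
}

#' Tukey's honestly significant difference post hoc test
#'
#' All pairwise group comparisons with familywise control via the studentized
#' range distribution; used after a significant one-way ANOVA.
#'
#' @param values,group As in [one_way_anova()].
#' @param alpha Familywise significance level for the `reject` flag.
#' @return A data frame with one row per pair: `group1`, `group2`,
#'   `mean_diff` (group2 - group1), `p_adj`, `reject`.
#' @export
tukey_hsd <- function(values, group, alpha = 0.05) {
  group <- factor(group)
  av <- one_way_anova(values, group)
  k <- nlevels(group)
  mse <- av$ss_within / av$df_within
  levs <- levels(group)
  pairs <- utils::combn(k, 2)
  out <- data.frame(
    group1 = levs[pairs[1, ]], group2 = levs[pairs[2, ]],
    mean_diff = NA_real_, p_adj = NA_real_, reject = NA
  )
  for (j in seq_len(ncol(pairs))) {
    i1 <- pairs[1, j]
    i2 <- pairs[2, j]
    diff <- av$means[i2] - av$means[i1]
    se <- sqrt(mse / 2 * (1 / av$counts[i1] + 1 / av$counts[i2]))
    if (se == 0) {
      p <- if (diff == 0) 1 else 0
    } else {
      q <- abs(diff) / se
      p <- stats::ptukey(q, nmeans = k, df = av$df_within, lower.tail = FALSE)
    }
    out$mean_diff[j] <- diff
    out$p_adj[j] <- p
    out$reject[j] <- p < alpha
  }
  out
}

#' Two-way analysis of variance with type-II sums of squares
#'
#' Fits `value ~ A * B` and reports type-II sums of squares for both main
#' effects and the interaction (equal to the classical sequential
#' decomposition for balanced designs). Every design cell must be nonempty.
#'
#' @param values Numeric response.
#' @param factor_a,factor_b Factors (or coercible), same length as `values`.
#' @return A data frame with rows `A`, `B`, `A:B`, `Residuals` and columns
#'   `term`, `ss`, `df`, `F`, `p`.
#' @export
two_way_anova <- function(values, factor_a, factor_b) {
  a <- factor(factor_a)
  b <- factor(factor_b)
  if (nlevels(a) < 2L || nlevels(b) < 2L) {
    ect_error("both factors need >= 2 levels", "ect_invalid_input")
  }
  cells <- table(a, b)
  if (any(cells == 0L)) {
    bad <- which(cells == 0L, arr.ind = TRUE)[1, ]
    ect_error(sprintf(
      "empty design cell: %s x %s",
      rownames(cells)[bad[1]], colnames(cells)[bad[2]]
    ), "ect_invalid_input")
  }
  rss <- function(formula) sum(stats::lm(formula, data = data.frame(
    y = values, a = a, b = b
  ))$residuals^2)
  rss_full <- rss(y ~ a * b)
  rss_add <- rss(y ~ a + b)
  rss_a <- rss(y ~ a)
  rss_b <- rss(y ~ b)
  n <- length(values)
  df_a <- nlevels(a) - 1L
  df_b <- nlevels(b) - 1L
  df_ab <- df_a * df_b
  df_res <- n - nlevels(a) * nlevels(b)
  if (df_res < 1L) ect_error("insufficient residual degrees of freedom", "ect_invalid_input")
  ss <- c(A = rss_b - rss_add, B = rss_a - rss_add, `A:B` = rss_add - rss_full)
  df <- c(df_a, df_b, df_ab)
  mse <- rss_full / df_res
  f <- (ss / df) / mse
  p <- stats::pf(f, df, df_res, lower.tail = FALSE)
  data.frame(
    term = c(names(ss), "Residuals"),
    ss = c(unname(ss), rss_full),
    df = c(df, df_res),
    F = c(unname(f), NA),
    p = c(unname(p), NA)
  )
}

#' Chi-squared test of independence on a contingency table
#'
#' Pearson statistic against independence expectations; Yates continuity
#' correction applied to 2x2 tables by default.
#'
#' @param counts Matrix of nonnegative integer counts (>= 2 rows and
#'   columns).
#' @param yates Apply the continuity correction to 2x2 tables.
#' @return A list: `statistic`, `df`, `p`.
#' @export
chi_squared_contingency <- function(counts, yates = TRUE) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2L || ncol(counts) < 2L || sum(counts) <= 0) {
    ect_error("need a table of >= 2 rows and columns with positive total",
      "ect_invalid_input")
  }
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    ect_error("zero marginal in contingency table", "ect_invalid_input")
  }
  res <- suppressWarnings(stats::chisq.test(counts, correct = yates))
  list(
    statistic = unname(res$statistic), df = unname(res$parameter),
    p = unname(res$p.value)
  )
}

#' Simple linear regression with Pearson correlation
#'
#' @param x,y Numeric vectors, `length >= 3`, `x` not constant.
#' @return A list: `slope`, `intercept`, `r`, `p` (two-sided, for the slope).
#' @export
linear_fit <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    ect_error("need >= 3 paired points", "ect_invalid_input")
  }
  if (stats::var(x) == 0) ect_error("x is constant", "ect_invalid_input")
  fit <- stats::lm(y ~ x)
  # exactly colinear input trips summary.lm's "essentially perfect fit"
  # warning; the p value degenerates to 0 there, which is what we report
  sm <- suppressWarnings(summary(fit))
  slope <- unname(stats::coef(fit)[2])
  r <- if (stats::var(y) == 0) 0 else stats::cor(x, y)
  p <- if (stats::var(y) == 0) 1 else unname(sm$coefficients[2, 4])
  list(
    slope = slope, intercept = unname(stats::coef(fit)[1]),
    r = r, p = p
  )
}

#' Bonferroni-corrected two-sample Student's t tests
#'
#' Two-tailed pooled-variance t test per treatment/control pair, with the
#' Bonferroni adjustment `p_adj = min(1, m * p)` over `m` planned
#' comparisons (the screen used m = 44).
#'
#' @param comparisons A list of `list(treatment =, control =)` numeric
#'   vectors (each of length >= 2).
#' @param m Total number of comparisons for the correction; must be at least
#'   `length(comparisons)`.
#' @return A data frame: `comparison`, `t`, `p_raw`, `p_adj`.
#' @export
t_test_bonferroni <- function(comparisons, m = length(comparisons)) {
  if (m < length(comparisons)) {
    ect_error("m must be >= number of comparisons", "ect_invalid_input")
  }
  out <- data.frame(
    comparison = seq_along(comparisons),
    t = NA_real_, p_raw = NA_real_, p_adj = NA_real_
  )
  for (i in seq_along(comparisons)) {
    tr <- comparisons[[i]]$treatment
    ct <- comparisons[[i]]$control
    if (length(tr) < 2L || length(ct) < 2L) {
      ect_error("each group needs >= 2 values", "ect_invalid_input")
    }
    if (stats::var(tr) == 0 && stats::var(ct) == 0) {
      t <- if (mean(tr) == mean(ct)) 0 else Inf * sign(mean(tr) - mean(ct))
      p <- if (mean(tr) == mean(ct)) 1 else 0
    } else {
      res <- stats::t.test(tr, ct, var.equal = TRUE)
      t <- unname(res$statistic)
      p <- res$p.value
    }
    out$t[i] <- t
    out$p_raw[i] <- p
    out$p_adj[i] <- min(1, m * p)
  }
  out
}

#' Weighted clone mean
#'
#' Weighted average of per-clone values, e.g. per-clone untethering
#' percentages weighted by the number of cells measured per clone.
#'
#' @param values Numeric vector.
#' @param weights Positive weights, same length.
#' @return `sum(w * v) / sum(w)`.
#' @export
weighted_clone_mean <- function(values, weights) {
  if (length(values) == 0L || length(values) != length(weights)) {
    ect_error("values and weights must be nonempty and equal length",
      "ect_invalid_input")
  }
  if (any(weights <= 0)) ect_error("weights must be > 0", "ect_invalid_input")
  sum(weights * values) / sum(weights)
}

#' Relative quantification by the 2^-ddCt method
#'
#' Per sample, `dCt = ct_target - ct_reference`; `ddCt` subtracts the mean
#' `dCt` of the control group; the fold change is `2^-ddCt` (target copy
#' number normalized to the reference locus and the control condition).
#'
#' @param records Data frame with columns `sample`, `group`, `ct_target`,
#'   `ct_reference`.
#' @param control_group Label of the control (e.g. vehicle) group.
#' @return `records` with added columns `dct`, `ddct`, `fold_change`.
#' @export
delta_delta_ct <- function(records, control_group = "control") {
  need <- c("sample", "group", "ct_target", "ct_reference")
  if (!all(need %in% names(records))) {
    ect_error(sprintf("records must have columns %s", paste(need, collapse = ", ")),
      "ect_invalid_input")
  }
  if (!control_group %in% records$group) {
    ect_error(sprintf("control group '%s' missing", control_group), "ect_invalid_input")
  }
  dct <- records$ct_target - records$ct_reference
  ddct <- dct - mean(dct[records$group == control_group])
  records$dct <- dct
  records$ddct <- ddct
  records$fold_change <- 2^(-ddct)
  records
}
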