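#' Normality-gated paired comparison
#'
#' Two-sided paired comparison of one measure across two conditions, gated
#' on normality of the per-experiment differences: Shapiro-Wilk at `alpha`
#' chooses between a paired t-test (normal differences) and a Wilcoxon
#' signed-rank test.
#'
#' @param a,b Equal-length numeric vectors paired by experiment.
#' @param alpha Significance level for the normality gate (default 0.05).
#' @param labels Condition labels, length 2.
#' @return One-row tibble: `condition_a`, `condition_b`, `test_name`,
#'   `statistic`, `p`, `n`, `normality_p`, `mean_diff`.
#' @export
normality_gated_paired_test <- function(a, b, alpha = 0.05,
                                        labels = c("a", "b")) {
  if (length(a) != length(b)) rlang::abort("paired samples differ in length")
  ok <- stats::complete.cases(a, b)
  a <- a[ok]
  b <- b[ok]
  if (length(a) < 3) rlang::abort("need >= 3 pairs")
  d <- a - b
  if (stats::sd(d) == 0) {
    rlang::abort("degenerate: zero-variance paired differences")
  }
  norm_p <- tryCatch(stats::shapiro.test(d)$p.value, error = function(e) 0)
  if (norm_p >= alpha) {
    ht <- stats::t.test(a, b, paired = TRUE)
    name <- "paired t"
  } else {
    ht <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE))
    name <- "Wilcoxon signed-rank"
  }
  tibble::tibble(
    condition_a = labels[1], condition_b = labels[2],
    test_name = name, statistic = unname(ht$statistic),
    p = ht$p.value, n = length(a), normality_p = norm_p,
    mean_diff = mean(d)
  )
}

#' One-way repeated-measures ANOVA with Tukey HSD
#'
#' Within-subjects one-way ANOVA (subject = experiment) on a complete
#' long-format table, followed by Tukey honestly-significant-difference
#' pairwise comparisons of condition means using the within-subjects error
#' term and the studentized-range distribution. No sphericity correction is
#' applied by default (matching the conventional uncorrected df such as
#' F(2,10) for 3 conditions x 6 subjects); Greenhouse-Geisser adjustment of
#' the omnibus p is available via `gg_correction = TRUE`.
#'
#' @param data Long data frame with one row per subject x condition.
#' @param value,condition,subject Column names (defaults `"value"`,
#'   `"condition"`, `"subject"`).
#' @param gg_correction Apply Greenhouse-Geisser epsilon to the omnibus df
#'   (default `FALSE`).
#' @return Object of class `"rm_anova"`: `f`, `df1`, `df2`, `p`, `epsilon`
#'   (GG epsilon, reported regardless), `pairwise` tibble (`contrast`,
#'   `diff`, `q`, `p_tukey`), plus the condition means.
#' @export
rm_anova_tukey <- function(data, value = "value", condition = "condition",
                           subject = "subject", gg_correction = FALSE) {
  stopifnot(all(c(value, condition, subject) %in% names(data)))
  d <- tibble::tibble(
    value = data[[value]],
    condition = factor(data[[condition]]),
    subject = factor(data[[subject]])
  )
  if (anyNA(d$value)) rlang::abort("missing cells; no imputation is done")
  tab <- table(d$subject, d$condition)
  if (any(tab != 1)) {
    rlang::abort("need exactly one value per subject x condition (complete table)")
  }
  k <- nlevels(d$condition)
  n <- nlevels(d$subject)
  if (k < 2 || n < 3) rlang::abort("need >= 2 conditions and >= 3 subjects")
  aov_fit <- stats::aov(value ~ condition + subject, data = d)
  s <- summary(aov_fit)[[1]]
  ms_cond <- s["condition", "Mean Sq"]
  ms_err <- s["Residuals", "Mean Sq"]
  df1 <- s["condition", "Df"]
  df2 <- s["Residuals", "Df"]
  # guard against floating-point dust when columns are identical
  tol <- 1e-12 * (mean(d$value^2) + 1)
  f <- if (ms_cond <= tol) 0 else if (ms_err <= tol) Inf else
    ms_cond / ms_err

  # Greenhouse-Geisser epsilon from the covariance of the subject x
  # condition matrix
  wide <- matrix(d$value[order(d$subject, d$condition)], nrow = n,
                 byrow = TRUE)
  S <- stats::cov(wide)
  eps <- tryCatch({
    m <- k
    num <- (m * mean(diag(S)) - mean(S))^2
    den <- (m - 1) * (sum(S^2) - 2 * m * sum(rowMeans(S)^2) +
                        m^2 * mean(S)^2)
    if (den <= 0) 1 else min(1, max(1 / (m - 1), num / den))
  }, error = function(e) 1)
  p <- if (gg_correction) {
    stats::pf(f, eps * df1, eps * df2, lower.tail = FALSE)
  } else {
    stats::pf(f, df1, df2, lower.tail = FALSE)
  }
  if (f == 0) p <- 1

  means <- tapply(d$value, d$condition, mean)
  combs <- utils::combn(levels(d$condition), 2)
  pairwise <- purrr::map(seq_len(ncol(combs)), function(j) {
    a <- combs[1, j]
    b <- combs[2, j]
    diff <- means[[a]] - means[[b]]
    if (ms_err <= tol) {
      q <- if (abs(diff) <= tol) 0 else Inf
    } else {
      q <- abs(diff) / sqrt(ms_err / n)
    }
    tibble::tibble(
      contrast = paste(a, "-", b),
      diff = diff,
      q = q,
      p_tukey = if (q == 0) 1 else if (is.infinite(q)) 0 else
        stats::ptukey(q, nmeans = k, df = df2, lower.tail = FALSE)
    )
  }) |> purrr::list_rbind()

  structure(
    list(f = f, df1 = df1, df2 = df2, p = p, epsilon = eps,
         gg_correction = gg_correction,
         means = tibble::tibble(condition = names(means),
                                mean = as.numeric(means)),
         pairwise = pairwise, n_subjects = n),
    class = "rm_anova"
  )
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("<rm_anova> F(%d,%d) = %.4g, p = %.4g%s\n", x$df1, x$df2, x$f,
              x$p, if (x$gg_correction)
                sprintf(" (GG eps = %.3f)", x$epsilon) else ""))
  print(x$pairwise)
  invisible(x)
}

#' Pearson correlation with t-approximation p-value
#'
#' @param x,y Equal-length numeric vectors (n >= 3, both with positive
#'   variance).
#' @return One-row tibble: `r`, `df` (n - 2), `p` (two-sided), `n`.
#' @export
pearson_corr <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 3) rlang::abort("need >= 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    rlang::abort("zero variance in x or y")
  }
  ht <- stats::cor.test(x, y, method = "pearson")
  tibble::tibble(
    r = unname(ht$estimate),
    df = unname(ht$parameter),
    p = ht$p.value,
    n = length(x)
  )
}

#' Two-sample comparison of Q10s across experiment groups
#'
#' Welch two-sample t-test by default (pooled variance behind a flag), for
#' comparisons between independent groups of experiments.
#'
#' @param a,b Numeric vectors (independent groups).
#' @param pooled Use the pooled-variance t-test instead of Welch
#'   (default `FALSE`).
#' @return One-row tibble: `test_name`, `statistic`, `df`, `p`, `n_a`,
#'   `n_b`.
#' @export
two_sample_test <- function(a, b, pooled = FALSE) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) rlang::abort("need >= 2 per group")
  ht <- stats::t.test(a, b, var.equal = pooled)
  tibble::tibble(
    test_name = if (pooled) "pooled two-sample t" else "Welch two-sample t",
    statistic = unname(ht$statistic),
    df = unname(ht$parameter),
    p = ht$p.value,
    n_a = length(a), n_b = length(b)
  )
}
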