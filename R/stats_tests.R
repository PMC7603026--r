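# Inferential procedures used on the assay readouts: paired t-test,
# one-way ANOVA with Tukey HSD post-test, and balanced two-way ANOVA with
# Tukey HSD. Thin, validated wrappers around the standard R machinery
# (stats::t.test, stats::aov, stats::TukeyHSD) that return a uniform
# result structure. All tests are two-sided.

test_result <- function(statistic, df, p_value, method,
                        pairwise = NULL, effects = NULL) {
  structure(list(statistic = statistic, df = df, p_value = p_value,
                 method = method, pairwise = pairwise, effects = effects),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat("<test_result>", x$method, "\n")
  cat(sprintf("  statistic = %.4g, df = %s, p = %.4g\n",
              x$statistic, paste(signif(x$df, 6), collapse = ", "), x$p_value))
  if (!is.null(x$pairwise)) {
    cat("  pairwise (Tukey HSD):\n")
    print(x$pairwise, row.names = FALSE)
  }
  invisible(x)
}

#' Paired t-test
#'
#' Two-sided paired t-test on matched samples: `t = mean(d) / (sd(d)/sqrt(n))`
#' with `n - 1` degrees of freedom, `d = x - y`. The pairing key (which
#' observations are matched) is the caller's responsibility: `x[i]` pairs
#' with `y[i]`.
#'
#' @param x,y equal-length numeric vectors of paired measurements.
#' @return a `test_result`.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) stop("paired samples must have equal length")
  if (length(x) < 2) stop("need at least 2 pairs")
  d <- x - y
  # matches the near-constant guard of t.test to give a clearer error
  if (stats::sd(d) <= 10 * .Machine$double.eps * max(abs(mean(d)), 1e-300))
    stop("zero variance of paired differences; t statistic undefined")
  ht <- tryCatch(stats::t.test(x, y, paired = TRUE), error = function(e)
    stop("zero variance of paired differences; t statistic undefined"))
  test_result(unname(ht$statistic), unname(ht$parameter), ht$p.value,
              "paired t-test (two-sided)")
}

#' One-way ANOVA with Tukey HSD post-test
#'
#' @param values numeric response vector, or a named list of numeric group
#'   vectors (in which case `group` is ignored).
#' @param group factor/character of group membership, parallel to `values`.
#' @param conf_level family-wise confidence level for Tukey intervals.
#' @return a `test_result` with the F statistic, `(k - 1, N - k)` degrees of
#'   freedom, the omnibus p-value, and a `pairwise` data.frame of Tukey HSD
#'   comparisons (`comparison`, `diff`, `lwr`, `upr`, `p_adj`).
#' @export
oneway_anova_tukey <- function(values, group = NULL, conf_level = 0.95) {
  if (is.list(values) && !is.data.frame(values)) {
    if (is.null(names(values))) names(values) <- paste0("g", seq_along(values))
    group <- rep(names(values), lengths(values))
    values <- unlist(values, use.names = FALSE)
  }
  if (is.null(group)) stop("'group' is required")
  group <- factor(group)
  if (nlevels(group) < 2) stop("need at least 2 groups")
  if (any(table(group) < 2)) stop("every group needs n >= 2")
  df <- data.frame(y = as.numeric(values), g = group)
  fit <- stats::aov(y ~ g, data = df)
  tab <- summary(fit)[[1]]
  Fst <- tab["g", "F value"]
  p <- tab["g", "Pr(>F)"]
  # a numerically-zero between-group sum of squares is no effect: F = 0, p = 1
  if (zero_ss(tab["g", "Sum Sq"], df$y)) { Fst <- 0; p <- 1 }
  tk <- tukey_table(fit, "g", conf_level)
  test_result(unname(Fst), c(df1 = tab["g", "Df"], df2 = tab["Residuals", "Df"]),
              unname(p), "one-way ANOVA + Tukey HSD", pairwise = tk)
}

#' Balanced two-way ANOVA with Tukey HSD post-test
#'
#' Fits `y ~ A * B` on a complete, balanced crossed design (every cell of
#' the design has the same n >= 2); unbalanced designs are rejected so the
#' sums-of-squares decomposition is unambiguous. Reports main-effect and
#' interaction F tests and Tukey HSD on the factor of interest. A factor
#' with a single level degrades gracefully to the one-way analysis on the
#' other factor.
#'
#' @param values numeric response vector.
#' @param factor_a,factor_b crossed design factors, parallel to `values`.
#' @param tukey_on which factor the Tukey comparisons are for: `"a"`
#'   (default) or `"b"`.
#' @param conf_level family-wise confidence level for Tukey intervals.
#' @return a `test_result`; `effects` is a data.frame of F tests for A, B
#'   and A:B, and `statistic`/`df`/`p_value` refer to the `tukey_on` factor's
#'   main effect.
#' @export
twoway_anova_tukey <- function(values, factor_a, factor_b, tukey_on = c("a", "b"),
                               conf_level = 0.95) {
  tukey_on <- match.arg(tukey_on)
  A <- factor(factor_a); B <- factor(factor_b)
  y <- as.numeric(values)
  stopifnot(length(A) == length(y), length(B) == length(y))
  if (nlevels(A) == 1 && nlevels(B) == 1) stop("both factors have a single level")
  if (nlevels(B) == 1) return(oneway_anova_tukey(y, A, conf_level))
  if (nlevels(A) == 1) return(oneway_anova_tukey(y, B, conf_level))
  cells <- table(A, B)
  if (any(cells == 0)) stop("design is not complete (empty factor cell)")
  if (length(unique(as.vector(cells))) != 1)
    stop("design is unbalanced; this analysis requires equal cell sizes")
  if (any(cells < 2)) stop("every design cell needs n >= 2")
  df <- data.frame(y = y, A = A, B = B)
  fit <- stats::aov(y ~ A * B, data = df)
  tab <- summary(fit)[[1]]
  rn <- trimws(rownames(tab))
  eff <- data.frame(
    term = rn[rn != "Residuals"],
    df = tab[rn != "Residuals", "Df"],
    F = tab[rn != "Residuals", "F value"],
    p = tab[rn != "Residuals", "Pr(>F)"]
  )
  null_eff <- vapply(tab[rn != "Residuals", "Sum Sq"], zero_ss, TRUE, y = y)
  eff$F[null_eff] <- 0
  eff$p[null_eff] <- 1
  rownames(eff) <- NULL
  which_f <- if (tukey_on == "a") "A" else "B"
  tk <- tukey_table(fit, which_f, conf_level)
  i <- match(which_f, eff$term)
  test_result(eff$F[i], c(df1 = eff$df[i], df2 = tab["Residuals", "Df"]),
              eff$p[i], "two-way ANOVA + Tukey HSD",
              pairwise = tk, effects = eff)
}

# a sum of squares that is zero up to floating-point noise, judged against
# the squared scale of the response itself
zero_ss <- function(ss, y) {
  ss <= 1e-20 * max(sum(y^2), 1)
}

tukey_table <- function(fit, which, conf_level) {
  tk <- stats::TukeyHSD(fit, which = which, conf.level = conf_level)[[which]]
  data.frame(comparison = rownames(tk),
             diff = tk[, "diff"], lwr = tk[, "lwr"], upr = tk[, "upr"],
             p_adj = tk[, "p adj"], row.names = NULL)
}
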