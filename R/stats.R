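## Repeated-measures statistics applied to the pipeline outputs: one- and
## two-way repeated-measures ANOVA (subject-blocked error terms, no
## sphericity correction by default), paired and one-sample t-tests with
## Cohen's d, and Pearson correlation. Partial eta-squared is reported for
## ANOVA effects. All tests are two-tailed unless stated otherwise.

stat_result <- function(statistic, df, p_value, effect_size, method,
                        tails = "two") {
  structure(list(statistic = unname(statistic), df = unname(df),
                 p_value = unname(p_value), effect_size = unname(effect_size),
                 method = method, tails = tails),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  dfs <- paste(signif(x$df, 4), collapse = ", ")
  cat(sprintf("%s: statistic = %.4g, df = (%s), p = %.4g, effect size = %.4g (%s-tailed)\n",
              x$method, x$statistic, dfs, x$p_value, x$effect_size, x$tails))
  invisible(x)
}

eta_p2 <- function(e) {
  tot <- e$ss_effect + e$ss_error
  if (!is.finite(tot) || tot <= 0) 0 else e$ss_effect / tot
}

## pull one effect's row out of a summary.aovlist; an effect whose sum of
## squares is numerically zero at the data's scale (tol) reports F = 0
aov_effect <- function(fit, effect, tol = 0) {
  s <- summary(fit)
  for (stratum in s) {
    tab <- stratum[[1]]
    row <- trimws(rownames(tab)) == effect
    res <- trimws(rownames(tab)) == "Residuals"
    if (any(row) && any(res)) {
      out <- list(F = tab[row, "F value"],
                  df = c(tab[row, "Df"], tab[res, "Df"]),
                  p = tab[row, "Pr(>F)"],
                  ss_effect = tab[row, "Sum Sq"],
                  ss_error = tab[res, "Sum Sq"])
      if (!is.finite(out$F) || out$ss_effect <= tol) {
        out$F <- 0; out$p <- 1; out$ss_effect <- 0
      }
      return(out)
    }
  }
  stop("effect not found in ANOVA strata: ", effect)
}

ss_tolerance <- function(values) {
  1e-20 * (1 + mean(values)^2) * length(values)
}

#' One-way repeated-measures ANOVA
#'
#' F-test for a within-subject factor on a complete balanced
#' subject x level table, using the subject-blocked error term
#' (df = (k-1, (k-1)(n-1))). Effect size is partial eta-squared,
#' SS_effect / (SS_effect + SS_error). No sphericity correction is applied.
#'
#' @param values Numeric matrix, subjects in rows, factor levels in columns
#'   (>= 2 of each); no missing cells.
#' @return A `stat_result`.
#' @export
rm_anova_oneway <- function(values) {
  values <- as.matrix(values)
  if (anyNA(values)) stop("missing cells: repeated-measures ANOVA needs a complete table")
  n <- nrow(values); k <- ncol(values)
  if (n < 2 || k < 2) stop("need at least 2 subjects and 2 levels")
  df <- data.frame(y = as.vector(values),
                   subject = factor(rep(seq_len(n), k)),
                   level = factor(rep(seq_len(k), each = n)))
  fit <- stats::aov(y ~ level + Error(subject / level), data = df)
  eff <- aov_effect(fit, "level", ss_tolerance(values))
  stat_result(eff$F, eff$df, eff$p, eta_p2(eff),
              "one-way repeated-measures ANOVA")
}

#' Two-way repeated-measures ANOVA
#'
#' F-tests for both within-subject main effects and their interaction on a
#' complete balanced subject x A x B array, each against its conventional
#' within-subject error term. Partial eta-squared per effect.
#'
#' @param values 3-d numeric array: subjects x levels of A x levels of B.
#' @return Named list of `stat_result`s: `A`, `B`, `interaction`.
#' @export
rm_anova_twoway <- function(values) {
  if (length(dim(values)) != 3) stop("values must be subjects x A x B")
  if (anyNA(values)) stop("missing cells: repeated-measures ANOVA needs a complete table")
  n <- dim(values)[1]; a <- dim(values)[2]; b <- dim(values)[3]
  if (n < 2 || a < 2 || b < 2) stop("need >= 2 subjects and 2 levels per factor")
  df <- data.frame(
    y = as.vector(values),
    subject = factor(rep(seq_len(n), a * b)),
    A = factor(rep(rep(seq_len(a), each = n), b)),
    B = factor(rep(seq_len(b), each = n * a))
  )
  fit <- stats::aov(y ~ A * B + Error(subject / (A * B)), data = df)
  out <- lapply(c(A = "A", B = "B", interaction = "A:B"), function(e) {
    eff <- aov_effect(fit, e, ss_tolerance(values))
    stat_result(eff$F, eff$df, eff$p, eta_p2(eff),
                sprintf("two-way repeated-measures ANOVA (%s)", e))
  })
  out
}

#' Paired and one-sample t-tests with Cohen's d
#'
#' @param x Numeric sample.
#' @param y Second paired sample (paired mode) or the reference value
#'   (one-sample mode; default 0).
#' @param mode `"paired"` or `"one_sample"`.
#' @param tails `"two"`, or `"greater"`/`"less"` for one-tailed tests.
#' @return A `stat_result` (Cohen's d = mean difference / SD of
#'   differences).
#' @export
t_tests <- function(x, y = 0, mode = c("paired", "one_sample"),
                    tails = c("two", "greater", "less")) {
  mode <- match.arg(mode)
  tails <- match.arg(tails)
  alt <- if (tails == "two") "two.sided" else tails
  d <- if (mode == "paired") {
    if (length(x) != length(y)) stop("paired samples must have equal length")
    x - y
  } else {
    x - y[1]
  }
  if (length(d) < 2) stop("need at least 2 observations")
  if (stats::sd(d) == 0) {
    if (mean(d) != 0) stop("zero variance: t-test undefined")
    # identical paired samples: no difference, no evidence
    return(stat_result(0, length(d) - 1, 1, 0,
                       if (mode == "paired") "paired t-test"
                       else "one-sample t-test", tails))
  }
  ht <- stats::t.test(d, mu = 0, alternative = alt)
  stat_result(ht$statistic, ht$parameter, ht$p.value,
              mean(d) / stats::sd(d),
              if (mode == "paired") "paired t-test" else "one-sample t-test",
              tails)
}

#' Pearson correlation
#'
#' Product-moment correlation with its t-based p-value.
#'
#' @param x,y Equal-length samples (>= 3), both non-constant.
#' @param tails `"two"`, `"greater"` or `"less"`.
#' @return A `stat_result` (effect size = r).
#' @export
pearson_r <- function(x, y, tails = c("two", "greater", "less")) {
  tails <- match.arg(tails)
  if (length(x) != length(y)) stop("samples must have equal length")
  if (length(x) < 3) stop("need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input: correlation undefined")
  alt <- if (tails == "two") "two.sided" else tails
  ht <- stats::cor.test(x, y, method = "pearson", alternative = alt)
  stat_result(ht$statistic, ht$parameter, ht$p.value, unname(ht$estimate),
              "Pearson correlation", tails)
}
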