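## Group descriptive statistics and delegated hypothesis tests. The tests
## themselves are off-the-shelf routines; what the package contributes is the
## measures feeding them, so computation is delegated to stats::t.test,
## wilcox.test and aov/TukeyHSD and only packaged into a tidy report.

#' Compare a measure between groups
#'
#' Descriptive statistics (mean +/- SEM, n) per group plus a delegated
#' hypothesis test: Student's t (paired or unpaired), Mann-Whitney/Wilcoxon,
#' or one-way ANOVA with Tukey post hoc.
#'
#' @param data data frame with the measure and a grouping column.
#' @param measure,group column names (strings) of the measure and the group.
#' @param design one of `"t_test"`, `"paired_t_test"`, `"wilcoxon"`,
#'   `"anova_tukey"`.
#' @return object of class `group_report`: list with `summary` tibble
#'   (`group`, `n`, `mean`, `sem`), `test` tibble (`statistic`, `df`,
#'   `p_value`, `method`), `posthoc` tibble (Tukey contrasts; ANOVA only),
#'   `design`.
#' @export
compare_groups <- function(data, measure, group,
                           design = c("t_test", "paired_t_test", "wilcoxon",
                                      "anova_tukey")) {
  design <- match.arg(design)
  x <- data[[measure]]; g <- factor(data[[group]])
  if (is.null(x) || is.null(data[[group]])) {
    abort("`measure` and `group` must name columns of `data`.")
  }
  ng <- nlevels(g)
  if (ng < 2) abort("Need at least two groups.")
  tab <- table(g)
  if (any(tab < 2)) {
    abort(sprintf("Every group needs n >= 2 (got %s).",
                  paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
  }
  summary <- tibble(group = levels(g),
                    n = as.integer(tab),
                    mean = as.numeric(tapply(x, g, mean)),
                    sem = as.numeric(tapply(x, g, sd) / sqrt(tab)))
  posthoc <- NULL
  if (design %in% c("t_test", "paired_t_test", "wilcoxon") && ng != 2) {
    abort(sprintf("`%s` requires exactly two groups.", design))
  }
  if (design == "t_test" || design == "paired_t_test") {
    ht <- t.test(x ~ g, paired = design == "paired_t_test")
    test <- tibble(statistic = unname(ht$statistic),
                   df = unname(ht$parameter), p_value = ht$p.value,
                   method = ht$method)
  } else if (design == "wilcoxon") {
    ht <- wilcox.test(x ~ g, exact = FALSE)
    test <- tibble(statistic = unname(ht$statistic), df = NA_real_,
                   p_value = ht$p.value, method = ht$method)
  } else {
    fit <- aov(x ~ g)
    a <- summary(fit)[[1]]
    test <- tibble(statistic = a[["F value"]][1],
                   df = a[["Df"]][1], p_value = a[["Pr(>F)"]][1],
                   method = "One-way ANOVA")
    tk <- TukeyHSD(fit)$g
    posthoc <- tibble(contrast = rownames(tk),
                      diff = tk[, "diff"], p_adj = tk[, "p adj"])
  }
  structure(list(summary = summary, test = test, posthoc = posthoc,
                 design = design),
            class = "group_report")
}

#' @export
print.group_report <- function(x, ...) {
  cat(sprintf("<group_report> %s\n", x$test$method[1]))
  print(x$summary)
  cat(sprintf("statistic = %.4g, p = %.4g\n", x$test$statistic, x$test$p_value))
  if (!is.null(x$posthoc)) print(x$posthoc)
  invisible(x)
}
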