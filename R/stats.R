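#' Flag outliers beyond two standard deviations from the mean
#'
#' Single-pass screen: values with `|x - mean(x)| > 2 * sd(x)` (mean and
#' sample SD computed on all values) are flagged. A constant vector has SD 0
#' and yields no removals.
#'
#' @param x Numeric values (at least 3).
#' @return List with `keep` (logical mask), `flagged` (indices removed),
#'   `mean`, `sd`.
#' @export
outlier_filter <- function(x) {
  if (length(x) < 3) stop("need at least 3 values")
  m <- mean(x)
  s <- stats::sd(x)
  keep <- if (s == 0) rep(TRUE, length(x)) else abs(x - m) <= 2 * s
  list(keep = keep, flagged = which(!keep), mean = m, sd = s)
}

#' Step-down Sidak (Holm-Sidak) p-value adjustment
#'
#' Raw p values sorted ascending receive `1 - (1 - p_(i))^(m - i + 1)`,
#' enforced monotone by a running maximum; adjusted values are returned in
#' the original order. Adjusted p values are monotone in the raw values and
#' never smaller than them.
#'
#' @param p Raw p values.
#' @return Adjusted p values.
#' @export
holm_sidak_adjust <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- 1 - (1 - p[o])^(m - seq_len(m) + 1)
  adj <- pmin(1, cummax(adj))
  out <- numeric(m)
  out[o] <- adj
  out
}

# Long-format input checks shared by the ANOVA fits.
check_long <- function(data, cols) {
  miss <- setdiff(cols, names(data))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (anyNA(data[cols])) stop("missing values in the design columns")
  invisible(data)
}

#' One-way repeated-measures ANOVA with Tukey post hoc
#'
#' Within-subject F test: `F = MS_level / MS_(level x subject)` with
#' `df = (k - 1), (k - 1)(n - 1)`, fitted via `aov` with an
#' `Error(subject)` stratum on a complete balanced table. No sphericity
#' correction is applied (the degrees of freedom are reported uncorrected).
#' Pairwise level comparisons use the studentized range (Tukey) with the
#' within-subject error mean square.
#'
#' @param data Long data.frame.
#' @param value,subject,level Column names.
#' @return Object of class `rm_anova`: `table` (effect, df1, df2, F, p) and
#'   `posthoc` (pairwise Tukey-adjusted comparisons).
#' @export
rm_anova_1way <- function(data, value = "value", subject = "subject",
                          level = "level") {
  check_long(data, c(value, subject, level))
  d <- data.frame(y = data[[value]],
                  subject = factor(data[[subject]]),
                  level = factor(data[[level]],
                                 levels = unique(data[[level]])))
  tab <- table(d$subject, d$level)
  if (any(tab != 1)) stop("design must be complete with one value per cell")
  fit <- stats::aov(y ~ level + Error(subject), data = d)
  s <- summary(fit)
  within <- s[["Error: Within"]][[1]]
  rownames(within) <- trimws(rownames(within))
  f_val <- within["level", "F value"]
  df1 <- within["level", "Df"]
  df2 <- within["Residuals", "Df"]
  p <- within["level", "Pr(>F)"]
  ms_err <- within["Residuals", "Mean Sq"]

  k <- nlevels(d$level)
  n <- nlevels(d$subject)
  means <- tapply(d$y, d$level, mean)
  cmb <- utils::combn(levels(d$level), 2)
  diffs <- means[cmb[2, ]] - means[cmb[1, ]]
  se <- sqrt(ms_err / n)
  padj <- stats::ptukey(abs(diffs) / se, k, df2, lower.tail = FALSE)
  posthoc <- data.frame(comparison = paste(cmb[2, ], "-", cmb[1, ]),
                        diff = as.numeric(diffs),
                        p_adj = as.numeric(padj))

  structure(list(table = data.frame(effect = "level", df1 = df1, df2 = df2,
                                    F = f_val, p = p),
                 posthoc = posthoc, method = "one-way RM ANOVA + Tukey",
                 sphericity_correction = "none"),
            class = "rm_anova")
}

#' Mixed-design (two-way repeated-measures) ANOVA with Holm-Sidak post hoc
#'
#' Between-subjects factor `group` (e.g. control vs CIS), within-subjects
#' factor `level` (trial blocks or timepoints). Error terms: subjects within
#' group for the group effect; level x subjects-within-group for the level
#' and interaction effects. No sphericity correction. The post hoc table
#' compares the two groups at each level (two-sample t tests on the cell
#' data), with Holm-Sidak adjusted p values.
#'
#' @param data Long data.frame.
#' @param value,subject,group,level Column names.
#' @return Object of class `rm_anova` with a three-row `table` (group,
#'   level, interaction).
#' @export
rm_anova_mixed <- function(data, value = "value", subject = "subject",
                           group = "group", level = "level") {
  check_long(data, c(value, subject, group, level))
  d <- data.frame(y = data[[value]],
                  subject = factor(data[[subject]]),
                  group = factor(data[[group]]),
                  level = factor(data[[level]],
                                 levels = unique(data[[level]])))
  if (any(table(d$subject, d$level) != 1)) {
    stop("design must be complete with one value per subject x level cell")
  }
  if (any(table(unique(d[c("subject", "group")])$group) < 2)) {
    stop("each group needs at least two subjects")
  }
  fit <- stats::aov(y ~ group * level + Error(subject), data = d)
  s <- summary(fit)
  btw <- s[["Error: subject"]][[1]]
  wth <- s[["Error: Within"]][[1]]
  rownames(btw) <- trimws(rownames(btw))
  rownames(wth) <- trimws(rownames(wth))
  tab <- data.frame(
    effect = c("group", "level", "group:level"),
    df1 = c(btw["group", "Df"], wth["level", "Df"], wth["group:level", "Df"]),
    df2 = c(btw["Residuals", "Df"], wth["Residuals", "Df"],
            wth["Residuals", "Df"]),
    F = c(btw["group", "F value"], wth["level", "F value"],
          wth["group:level", "F value"]),
    p = c(btw["group", "Pr(>F)"], wth["level", "Pr(>F)"],
          wth["group:level", "Pr(>F)"]))

  lv <- levels(d$level)
  gr <- levels(d$group)
  raw <- vapply(lv, function(l) {
    a <- d$y[d$level == l & d$group == gr[1]]
    b <- d$y[d$level == l & d$group == gr[2]]
    stats::t.test(a, b, var.equal = TRUE)$p.value
  }, numeric(1))
  posthoc <- data.frame(level = lv,
                        diff = vapply(lv, function(l) {
                          mean(d$y[d$level == l & d$group == gr[2]]) -
                            mean(d$y[d$level == l & d$group == gr[1]])
                        }, numeric(1)),
                        p_raw = raw,
                        p_adj = holm_sidak_adjust(raw))
  rownames(posthoc) <- NULL

  structure(list(table = tab, posthoc = posthoc,
                 method = "mixed two-way RM ANOVA + Holm-Sidak",
                 sphericity_correction = "none"),
            class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, ...) {
  cat("<rm_anova>", x$method, "\n")
  tb <- x$table
  for (i in seq_len(nrow(tb))) {
    cat(sprintf("  %-12s F(%d,%d) = %.2f, p = %.4g\n", tb$effect[i],
                tb$df1[i], tb$df2[i], tb$F[i], tb$p[i]))
  }
  cat("  (no sphericity correction)\n")
  invisible(x)
}

#' Test lead/lag values against chance
#'
#' Verbatim mode (`"two_sample"`): unpaired Student's t test between the
#' per-animal lead/lags and chance-derived lags, as described for these
#' data. A documented alternative (`"one_sample"`, default off) tests the
#' lead/lags against zero directly.
#'
#' @param lags Per-animal lead/lag values (seconds).
#' @param chance Chance-derived lags (required for `"two_sample"`).
#' @param mode `"two_sample"` or `"one_sample"`.
#' @return `htest` object from [stats::t.test()].
#' @export
lag_vs_chance <- function(lags, chance = NULL,
                          mode = c("two_sample", "one_sample")) {
  mode <- match.arg(mode)
  if (length(lags) < 2) stop("need at least two lag values")
  if (mode == "two_sample") {
    if (is.null(chance) || length(chance) < 2) {
      stop("two_sample mode needs at least two chance values")
    }
    if (stats::sd(lags) == 0 && stats::sd(chance) == 0) {
      if (mean(lags) == mean(chance)) {
        return(structure(list(statistic = c(t = 0), p.value = 1,
                              method = "degenerate two-sample t",
                              estimate = c(mean(lags), mean(chance))),
                         class = "htest"))
      }
      stop("zero variance in both samples")
    }
    stats::t.test(lags, chance, var.equal = TRUE)
  } else {
    stats::t.test(lags, mu = 0)
  }
}
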