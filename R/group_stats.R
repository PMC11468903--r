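#' Grouped replicate values for between-area / between-time comparisons
#'
#' A minimal container pairing group labels with replicate measurements
#' (fluxes or metabolic rates in shared units). At least two groups are
#' required, each with at least two values so a within-group variance
#' exists.
#'
#' @param groups Named list, label -> numeric vector of replicate values.
#' @return An object of class `group_table`.
#' @export
group_table <- function(groups) {
  if (!is.list(groups) || is.null(names(groups)) || length(groups) < 2L)
    stop("group_table: need a named list of >= 2 groups", call. = FALSE)
  if (any(vapply(groups, length, 1L) < 2L))
    stop("group_table: every group needs >= 2 values", call. = FALSE)
  groups <- lapply(groups, as.numeric)
  if (any(vapply(groups, function(v) any(!is.finite(v)), TRUE)))
    stop("group_table: values must be finite", call. = FALSE)
  structure(list(groups = groups), class = "group_table")
}

#' Normality check with optional log transform
#'
#' Shapiro--Wilk test of the pooled values; if normality is rejected at
#' `alpha` and all values are strictly positive, a natural-log transform
#' is applied and the test repeated. The transform actually applied is
#' part of the result so downstream ANOVA can be run on the same scale.
#' With nonpositive values present the log transform is unavailable and
#' the data are left untransformed with a warning.
#'
#' @param values Numeric vector, length >= 3, not all equal.
#' @param alpha Rejection level for the Shapiro--Wilk test.
#' @return List with `statistic`, `p_value`, `transform_applied`
#'   (`"none"` or `"log"`), and `values` on the chosen scale.
#' @export
normality_check <- function(values, alpha = 0.05) {
  values <- values[is.finite(values)]
  if (length(values) < 3L)
    stop("normality_check: need >= 3 finite values", call. = FALSE)
  if (stats::sd(values) == 0)
    stop("normality_check: values are constant", call. = FALSE)
  sw <- stats::shapiro.test(values)
  if (sw$p.value >= alpha)
    return(list(statistic = unname(sw$statistic), p_value = sw$p.value,
                transform_applied = "none", values = values))
  if (any(values <= 0)) {
    warning("normality rejected but nonpositive values preclude a log ",
            "transform; data left untransformed", call. = FALSE)
    return(list(statistic = unname(sw$statistic), p_value = sw$p.value,
                transform_applied = "none", values = values))
  }
  lv <- log(values)
  sw2 <- stats::shapiro.test(lv)
  list(statistic = unname(sw2$statistic), p_value = sw2$p.value,
       transform_applied = "log", values = lv)
}

#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA via the sums-of-squares
#' decomposition: F = MS_between / MS_within with k - 1 and N - k degrees
#' of freedom, p from the F distribution. Tukey HSD pairwise comparisons
#' are attached via [posthoc_pairwise()].
#'
#' @param table A [group_table()].
#' @param posthoc Attach Tukey HSD pairwise comparisons?
#' @return An object of class `anova_result`: `f_statistic`,
#'   `df_between`, `df_within`, `p_value`, `ms_within`, group summaries,
#'   and (optionally) a `pairwise` data.frame.
#' @export
one_way_anova <- function(table, posthoc = TRUE) {
  stopifnot(inherits(table, "group_table"))
  g <- table$groups
  k <- length(g)
  n_i <- vapply(g, length, 1L)
  N <- sum(n_i)
  means <- vapply(g, mean, 1)
  grand <- sum(unlist(g)) / N
  ssb <- sum(n_i * (means - grand)^2)
  ssw <- sum(vapply(g, function(v) sum((v - mean(v))^2), 1))
  df_b <- k - 1L
  df_w <- N - k
  if (ssw == 0)
    stop("one_way_anova: zero within-group variance, F undefined",
         call. = FALSE)
  msb <- ssb / df_b
  msw <- ssw / df_w
  f <- msb / msw
  p <- stats::pf(f, df_b, df_w, lower.tail = FALSE)
  res <- structure(list(f_statistic = f, df_between = df_b,
                        df_within = df_w, p_value = p,
                        ss_between = ssb, ss_within = ssw, ms_within = msw,
                        group_means = means, group_n = n_i,
                        pairwise = NULL),
                   class = "anova_result")
  if (posthoc) res$pairwise <- posthoc_pairwise(table, res)
  res
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$df_between, x$df_within, x$f_statistic, x$p_value))
  if (!is.null(x$pairwise)) {
    cat("Tukey HSD pairwise comparisons:\n")
    print(x$pairwise, row.names = FALSE)
  }
  invisible(x)
}

#' Tukey HSD all-pairs comparisons after one-way ANOVA
#'
#' Honestly-significant-difference test for every pair of groups: the
#' studentized-range statistic
#' \eqn{q = |\bar y_i - \bar y_j| / \sqrt{(MS_W/2)(1/n_i + 1/n_j)}}
#' referred to the studentized range distribution with k groups and
#' N - k error degrees of freedom (the Tukey--Kramer form for unequal
#' group sizes, identical to `stats::TukeyHSD`).
#'
#' @param table A [group_table()].
#' @param anova Optionally a precomputed `anova_result` for the same
#'   table (avoids refitting).
#' @return data.frame with columns `group1`, `group2`, `mean_diff`,
#'   `p_adjusted`.
#' @export
posthoc_pairwise <- function(table, anova = NULL) {
  stopifnot(inherits(table, "group_table"))
  if (is.null(anova)) anova <- one_way_anova(table, posthoc = FALSE)
  g <- table$groups
  labs <- names(g)
  k <- length(g)
  pairs <- utils::combn(k, 2L)
  out <- data.frame(group1 = labs[pairs[1L, ]], group2 = labs[pairs[2L, ]],
                    mean_diff = NA_real_, p_adjusted = NA_real_,
                    stringsAsFactors = FALSE)
  for (j in seq_len(ncol(pairs))) {
    i1 <- pairs[1L, j]; i2 <- pairs[2L, j]
    d <- anova$group_means[i2] - anova$group_means[i1]
    se <- sqrt(anova$ms_within / 2 *
                 (1 / anova$group_n[i1] + 1 / anova$group_n[i2]))
    q <- abs(d) / se
    out$mean_diff[j] <- unname(d)
    out$p_adjusted[j] <- stats::ptukey(q, k, anova$df_within,
                                       lower.tail = FALSE)
  }
  out
}

#' Grouped ANOVA over a tidy results table
#'
#' Pipeline helper: takes a tidy data.frame (e.g. from
#' [deployment_fluxes()] or [study_metabolism()]), groups one metric
#' column by one label column, runs the normality check (with optional
#' log transform), one-way ANOVA and Tukey HSD, and returns a tidy
#' summary. Rows with missing metric values (e.g. non-detects) are
#' excluded, never zero-imputed.
#'
#' @param df data.frame of per-chamber results.
#' @param metric Name of the numeric column to compare.
#' @param grouping Name of the label column to group by.
#' @param alpha Level for the normality screen.
#' @return List with `normality`, `anova`, and a tidy `summary`
#'   data.frame (metric, grouping, transform, F, dfs, p, pairwise rows).
#' @export
compare_groups <- function(df, metric, grouping, alpha = 0.05) {
  vals <- df[[metric]]
  labs <- df[[grouping]]
  keep <- is.finite(vals)
  vals <- vals[keep]; labs <- labs[keep]
  norm <- normality_check(vals, alpha)
  if (norm$transform_applied == "log") vals <- log(vals)
  tab <- group_table(split(vals, labs))
  an <- one_way_anova(tab)
  summary <- data.frame(metric = metric, grouping = grouping,
                        transform = norm$transform_applied,
                        f = an$f_statistic, df_between = an$df_between,
                        df_within = an$df_within, p = an$p_value,
                        stringsAsFactors = FALSE)
  list(normality = norm, anova = an, summary = summary,
       pairwise = an$pairwise)
}
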