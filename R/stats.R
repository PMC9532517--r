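#' Group-comparison report
#'
#' Light S3 container for the statistical battery: per-group estimates
#' (mean, SEM, n), the test name, statistic, degrees of freedom, p-value and
#' any adjusted pairwise comparisons. Significance is judged at
#' `alpha = 0.05`.
#'
#' @param test test name.
#' @param statistic test statistic.
#' @param p.value p-value.
#' @param estimates data.frame with columns `group`, `mean`, `sem`, `n`.
#' @param df degrees of freedom (scalar or vector), if applicable.
#' @param comparisons data.frame of pairwise comparisons, if applicable.
#' @param extra list of method-specific payloads.
#' @param flags character vector of caveats (e.g. degenerate input).
#' @return a `stat_report`.
#' @export
stat_report <- function(test, statistic, p.value, estimates = NULL,
                        df = NULL, comparisons = NULL, extra = list(),
                        flags = character(0)) {
  if (!is.na(p.value) && (p.value < 0 || p.value > 1))
    nq_data_error("p-value outside [0, 1]")
  structure(list(test = test, statistic = statistic, df = df,
                 p.value = p.value, estimates = estimates,
                 comparisons = comparisons, alpha = 0.05, extra = extra,
                 flags = flags),
            class = "stat_report")
}

#' @export
print.stat_report <- function(x, ...) {
  cat("<stat_report> ", x$test, "\n", sep = "")
  if (!is.null(x$estimates)) {
    print(x$estimates, row.names = FALSE)
  }
  cat("  statistic = ", signif(x$statistic, 5),
      if (!is.null(x$df)) paste0(", df = ",
                                 paste(signif(x$df, 5), collapse = ", ")),
      ", p = ", format.pval(x$p.value, digits = 4), "\n", sep = "")
  if (!is.null(x$comparisons)) {
    cat("  comparisons:\n")
    print(x$comparisons, row.names = FALSE)
  }
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

group_estimates <- function(groups) {
  data.frame(group = names(groups),
             mean = vapply(groups, mean, numeric(1)),
             sem = vapply(groups, function(g) sd(g) / sqrt(length(g)),
                          numeric(1)),
             n = vapply(groups, length, integer(1)),
             row.names = NULL)
}

name_groups <- function(groups, prefix = "group") {
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    names(groups) <- paste0(prefix, seq_along(groups))
  groups
}

#' Densitometry normalization against a loading control
#'
#' Each sample's normalized value is `target_intensity / loading_intensity`
#' (the loading control, e.g. Tuj1 or GAPDH); fold change is the normalized
#' value divided by the mean normalized value of the control group, so the
#' control group's mean fold change is 1 by construction.
#'
#' @param table data.frame with columns `sample_id`, `group`,
#'   `target_intensity`, `loading_intensity`.
#' @param control_group name of the reference group.
#' @return the table with added columns `normalized` and `fold_change`.
#' @export
normalize_bands <- function(table, control_group) {
  need <- c("sample_id", "group", "target_intensity", "loading_intensity")
  if (!all(need %in% names(table)))
    nq_data_error("band table lacks required columns")
  if (any(table$loading_intensity <= 0))
    nq_data_error("loading intensities must be > 0")
  if (any(table$target_intensity <= 0))
    nq_data_error("target intensities must be > 0")
  if (!control_group %in% table$group)
    nq_data_error(paste0("control group not present: ", control_group))
  table$normalized <- table$target_intensity / table$loading_intensity
  ctl <- mean(table$normalized[table$group == control_group])
  table$fold_change <- table$normalized / ctl
  table
}

#' Welch's unpaired two-tailed t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom
#' and a two-tailed p-value. Zero-variance degenerate input is flagged
#' rather than erroring (t = 0, p = 1 when the groups are identical in
#' mean).
#'
#' @param group_a,group_b numeric vectors (n >= 2 each).
#' @return a [stat_report()].
#' @export
welch_t <- function(group_a, group_b) {
  if (length(group_a) < 2L || length(group_b) < 2L)
    nq_data_error("each group needs n >= 2")
  groups <- name_groups(list(a = group_a, b = group_b))
  est <- group_estimates(groups)
  if (var(group_a) == 0 && var(group_b) == 0) {
    same <- mean(group_a) == mean(group_b)
    return(stat_report("Welch two-sample t-test",
                       statistic = if (same) 0 else Inf,
                       p.value = if (same) 1 else 0,
                       estimates = est, df = NA_real_,
                       flags = "degenerate: zero variance in both groups"))
  }
  tt <- t.test(group_a, group_b, var.equal = FALSE)
  stat_report("Welch two-sample t-test", statistic = unname(tt$statistic),
              p.value = tt$p.value, estimates = est,
              df = unname(tt$parameter))
}

# CDF of the studentized maximum modulus: max of r independent |N(0,1)|
# studentized by a common chi(df)/sqrt(df). Numerical integration over the
# scale variable.
psmm <- function(q, r, df) {
  if (q <= 0) return(0)
  if (!is.finite(df)) return((2 * pnorm(q) - 1)^r)
  f <- function(s) (2 * pnorm(q * s) - 1)^r *
    dchisq(s^2 * df, df) * 2 * s * df
  integrate(f, 0, Inf, rel.tol = 1e-9)$value
}

#' One-way ANOVA with Dunnett's T3 comparisons against a control
#'
#' One-way ANOVA F-test across all groups, followed by Dunnett's T3
#' multiple-comparison procedure for unequal variances: each non-control
#' group is compared with the control by a Welch-type t statistic with
#' Welch-Satterthwaite degrees of freedom, and adjusted p-values are taken
#' from the studentized maximum modulus distribution (evaluated by numerical
#' integration) with the number of comparisons as its extent parameter.
#'
#' @param groups list of >= 3 numeric vectors (n >= 2 each), optionally
#'   named.
#' @param control_index index of the control group (default 1).
#' @return a [stat_report()] whose `comparisons` hold the per-comparison
#'   Welch t, df, unadjusted and T3-adjusted p.
#' @export
anova_dunnett_t3 <- function(groups, control_index = 1L) {
  if (length(groups) < 3L)
    nq_data_error("Dunnett T3 requires at least 3 groups")
  if (any(lengths(groups) < 2L)) nq_data_error("each group needs n >= 2")
  groups <- name_groups(groups)
  values <- unlist(groups, use.names = FALSE)
  fac <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  fit <- aov(values ~ fac)
  atab <- anova(fit)
  ctl <- groups[[control_index]]
  others <- setdiff(seq_along(groups), control_index)
  r <- length(others)
  comp <- do.call(rbind, lapply(others, function(i) {
    g <- groups[[i]]
    se2 <- var(ctl) / length(ctl) + var(g) / length(g)
    tstat <- (mean(g) - mean(ctl)) / sqrt(se2)
    dfw <- se2^2 / ((var(ctl) / length(ctl))^2 / (length(ctl) - 1) +
                    (var(g) / length(g))^2 / (length(g) - 1))
    p_unadj <- 2 * pt(-abs(tstat), dfw)
    p_adj <- 1 - psmm(abs(tstat), r, dfw)
    data.frame(comparison = paste(names(groups)[i], "vs",
                                  names(groups)[control_index]),
               estimate = mean(g) - mean(ctl), t = tstat, df = dfw,
               p.unadjusted = p_unadj,
               p.adjusted = min(1, max(p_adj, p_unadj)))
  }))
  stat_report("one-way ANOVA with Dunnett's T3 comparisons",
              statistic = atab$`F value`[1], p.value = atab$`Pr(>F)`[1],
              estimates = group_estimates(groups),
              df = c(atab$Df[1], atab$Df[2]), comparisons = comp)
}

#' One-way ANOVA with Tukey's HSD all-pairs comparisons
#'
#' @param groups list of >= 3 numeric vectors, optionally named.
#' @return a [stat_report()] with Tukey-adjusted pairwise p-values from the
#'   studentized range distribution.
#' @export
anova_tukey <- function(groups) {
  if (length(groups) < 3L)
    nq_data_error("Tukey HSD requires at least 3 groups (use a t-test for 2)")
  groups <- name_groups(groups)
  values <- unlist(groups, use.names = FALSE)
  fac <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  fit <- aov(values ~ fac)
  atab <- anova(fit)
  tuk <- TukeyHSD(fit)$fac
  comp <- data.frame(comparison = rownames(tuk),
                     estimate = tuk[, "diff"],
                     p.adjusted = tuk[, "p adj"], row.names = NULL)
  stat_report("one-way ANOVA with Tukey's HSD",
              statistic = atab$`F value`[1], p.value = atab$`Pr(>F)`[1],
              estimates = group_estimates(groups),
              df = c(atab$Df[1], atab$Df[2]), comparisons = comp)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Exact maximal ECDF gap D with the asymptotic p-value, as used for
#' Sholl-profile distribution comparisons.
#'
#' @param sample_a,sample_b numeric vectors.
#' @return a [stat_report()].
#' @export
ks_two_sample <- function(sample_a, sample_b) {
  if (!length(sample_a) || !length(sample_b))
    nq_data_error("samples must be non-empty")
  ks <- suppressWarnings(ks.test(sample_a, sample_b, exact = FALSE))
  D <- if (length(sample_a) == length(sample_b) &&
           all(sort(sample_a) == sort(sample_b))) 0 else unname(ks$statistic)
  stat_report("two-sample Kolmogorov-Smirnov", statistic = D,
              p.value = if (D == 0) 1 else unname(ks$p.value),
              estimates = group_estimates(
                name_groups(list(a = sample_a, b = sample_b))))
}

#' Percent change between two groups with propagated SEM
#'
#' `100 * (mean_b - mean_a) / mean_a`, with the SEM obtained by first-order
#' error propagation of the two group SEMs.
#'
#' @param group_a reference (control) values.
#' @param group_b comparison values.
#' @return list with `percent` and `sem`.
#' @export
percent_change <- function(group_a, group_b) {
  ma <- mean(group_a); mb <- mean(group_b)
  sa <- sd(group_a) / sqrt(length(group_a))
  sb <- sd(group_b) / sqrt(length(group_b))
  pct <- 100 * (mb - ma) / ma
  sem <- 100 * sqrt((sb / ma)^2 + (mb * sa / ma^2)^2)
  list(percent = pct, sem = sem)
}
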