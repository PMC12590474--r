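#' Screen-design detection probability
#'
#' Probability that a line with phenotype penetrance `p` shows the phenotype
#' in at least one of `n` flies tested: `1 - (1 - p)^n`. With 80% penetrance
#' and 3 flies this is 0.992 -- the chance that none shows tremor is 0.2^3.
#'
#' @param p Penetrance in \[0, 1\] (vectorised).
#' @param n Number of flies per line (positive integer, vectorised).
#' @return Detection probability, same length as `p`/`n`.
#' @examples
#' detection_probability(0.8, 3)  # 0.992
#' @export
detection_probability <- function(p, n) {
  if (any(p < 0 | p > 1)) abort("`p` must be in [0, 1].")
  if (any(n < 1) || any(n != round(n))) abort("`n` must be a positive integer.")
  1 - (1 - p)^n
}

#' Penetrance with exact binomial confidence interval
#'
#' Point estimate `k/n` of the fraction of flies expressing the phenotype,
#' with an exact Clopper-Pearson interval (beta-quantile form).
#'
#' @param k Number of phenotype-positive flies (vectorised).
#' @param n Number of flies tested.
#' @param conf_level Confidence level (default 0.95).
#' @return A tibble: `k`, `n`, `penetrance`, `ci_lo`, `ci_hi`.
#' @examples
#' estimate_penetrance(6, 10)
#' @export
estimate_penetrance <- function(k, n, conf_level = 0.95) {
  if (any(n < 1)) abort("`n` must be >= 1.")
  if (any(k < 0) || any(k > n)) abort("`k` must satisfy 0 <= k <= n.")
  a <- (1 - conf_level) / 2
  tibble(
    k = k, n = n, penetrance = k / n,
    ci_lo = ifelse(k == 0, 0, qbeta(a, k, n - k + 1)),
    ci_hi = ifelse(k == n, 1, qbeta(1 - a, k + 1, n - k))
  )
}

#' Background phenotype rate
#'
#' The proportion `k/n`, with the percentage label rounded half-up to one
#' decimal as reported in screen summaries (2/167 -> "1.2%").
#'
#' @param k,n Counts; `n` must be positive.
#' @return A tibble: `k`, `n`, `rate`, `percent` (numeric, one decimal),
#'   `label`.
#' @examples
#' background_rate(2, 167)
#' @export
background_rate <- function(k, n) {
  if (any(n <= 0)) abort("`n` must be positive.")
  if (any(k < 0) || any(k > n)) abort("`k` must satisfy 0 <= k <= n.")
  pct <- round_half_up(100 * k / n, 1)
  tibble(k = k, n = n, rate = k / n, percent = pct,
         label = sprintf("%.1f%%", pct))
}

#' Cohen's d effect size
#'
#' Standardised mean difference `(mean(a) - mean(b)) / s_pooled`, with the
#' pooled standard deviation using n-1 weighting.
#'
#' @param a,b Numeric samples with at least 2 values each.
#' @return A single number; positive when `a` has the larger mean.
#' @examples
#' cohens_d(c(1, 2, 3), c(3, 4, 5))  # -2
#' @export
cohens_d <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2)
    abort("Each sample needs at least 2 values.")
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  if (sp2 <= 0) abort("Pooled SD is zero; effect size undefined.")
  (mean(a) - mean(b)) / sqrt(sp2)
}

#' Correlation between climbing ability and tremor rate
#'
#' Tests whether poorer climbers tremor more: correlation between
#' `climbing_score_cm` and `tremor_rate_per_s` across flies, Pearson by
#' default (Spearman via `method`), with a two-sided p-value.
#'
#' @param summaries A per-fly summary tibble (from [summarize_fly()]) with
#'   columns `climbing_score_cm` and `tremor_rate_per_s`.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return A one-row tibble: `r`, `p_value`, `n`, `method`.
#' @export
climbing_tremor_correlation <- function(summaries,
                                        method = c("pearson", "spearman")) {
  method <- match.arg(method)
  ok <- stats::complete.cases(summaries$climbing_score_cm,
                              summaries$tremor_rate_per_s)
  x <- summaries$climbing_score_cm[ok]
  y <- summaries$tremor_rate_per_s[ok]
  if (length(x) < 3) abort("Need at least 3 flies with both measurements.")
  if (sd(x) == 0 || sd(y) == 0)
    abort("Zero variance in climbing score or tremor rate.")
  ct <- suppressWarnings(cor.test(x, y, method = method,
                                  alternative = "two.sided", exact = FALSE))
  tibble(r = unname(ct$estimate), p_value = ct$p.value, n = length(x),
         method = method)
}

#' Select the poorest climbers
#'
#' The selection rule for which flies of a line get recorded: the `k` flies
#' with the lowest climbing scores, ties broken deterministically by
#' lexicographic `fly_id`.
#'
#' @param scores A tibble with columns `fly_id` and `climbing_score_cm`.
#' @param k Number of flies to select (default 3).
#' @return The selected rows of `scores`, in selection order.
#' @export
select_poorest_climbers <- function(scores, k = 3) {
  if (!all(c("fly_id", "climbing_score_cm") %in% names(scores)))
    abort("`scores` needs columns `fly_id` and `climbing_score_cm`.")
  if (nrow(scores) < k)
    abort(sprintf("Need at least %d flies; got %d.", k, nrow(scores)))
  ord <- order(scores$climbing_score_cm, scores$fly_id)
  as_tibble(scores)[ord[seq_len(k)], , drop = FALSE]
}

#' Nonparametric group comparison
#'
#' Two groups: Mann-Whitney U (normal approximation, tie-corrected,
#' two-sided). More than two groups: Kruskal-Wallis omnibus followed by Dunn's
#' rank-based pairwise post-hoc comparisons (vs the control group when given,
#' otherwise all pairs) with multiplicity adjustment. A parametric route
#' (one-way ANOVA + pairwise t vs control) is available behind
#' `parametric = TRUE`.
#'
#' @param df A data frame with one observation per row.
#' @param value,group Column names (strings or bare names via `{{ }}`) of the
#'   response and the grouping factor.
#' @param control Optional control group label; pairwise comparisons are then
#'   restricted to each group vs control.
#' @param adjust Multiplicity adjustment for the pairwise p-values (a
#'   `p.adjust` method; default `"bonferroni"`, the classical Dunn
#'   correction).
#' @param parametric Use ANOVA + t tests instead of rank tests.
#' @return An object of class `group_comparison`; see [tidy()] and
#'   [glance()] methods.
#' @export
compare_groups <- function(df, value, group, control = NULL,
                           adjust = "bonferroni", parametric = FALSE) {
  v <- rlang::eval_tidy(rlang::enquo(value), df)
  g <- rlang::eval_tidy(rlang::enquo(group), df)
  if (is.character(v) && length(v) == 1 && v %in% names(df)) v <- df[[v]]
  if (is.character(g) && length(g) == 1 && g %in% names(df)) g <- df[[g]]
  ok <- !is.na(v) & !is.na(g)
  v <- v[ok]; g <- as.character(g)[ok]
  tab <- table(g)
  if (length(tab) < 2) abort("Need at least 2 nonempty groups.")
  if (any(tab == 0)) abort("Empty group.")
  if (!is.null(control) && !control %in% names(tab))
    abort(sprintf("Control group '%s' not present.", control))

  if (length(unique(v)) == 1) {
    # degenerate: no variation anywhere -> no evidence of any difference
    gs <- names(tab)
    pairs <- if (!is.null(control)) {
      lapply(setdiff(gs, control), function(a) c(a, control))
    } else utils::combn(gs, 2, simplify = FALSE)
    omnibus <- tibble(method = "degenerate (constant response)",
                      statistic = 0, df = NA_real_, p_value = 1)
    pairwise <- purrr::map_dfr(pairs, function(pr)
      tibble(group1 = pr[1], group2 = pr[2], statistic = 0,
             p_value = 1, p_adjusted = 1))
  } else if (length(tab) == 2) {
    gs <- names(tab)
    wt <- suppressWarnings(wilcox.test(v[g == gs[1]], v[g == gs[2]],
                                       exact = FALSE, correct = TRUE))
    omnibus <- tibble(method = "Mann-Whitney U", statistic = unname(wt$statistic),
                      df = NA_real_, p_value = wt$p.value)
    pairwise <- tibble(group1 = gs[1], group2 = gs[2],
                       statistic = unname(wt$statistic),
                       p_value = wt$p.value, p_adjusted = wt$p.value)
  } else if (parametric) {
    fit <- stats::aov(v ~ factor(g))
    an <- summary(fit)[[1]]
    omnibus <- tibble(method = "one-way ANOVA", statistic = an$`F value`[1],
                      df = an$Df[1], p_value = an$`Pr(>F)`[1])
    pairwise <- pairwise_t_vs(v, g, control, adjust)
  } else {
    kw <- kruskal.test(v, factor(g))
    omnibus <- tibble(method = "Kruskal-Wallis", statistic = unname(kw$statistic),
                      df = unname(kw$parameter), p_value = kw$p.value)
    pairwise <- dunn_test(v, g, control = control, adjust = adjust)
  }
  structure(list(omnibus = omnibus, pairwise = pairwise,
                 control = control, n = as.integer(tab), groups = names(tab)),
            class = "group_comparison")
}

# Dunn's rank-based post-hoc z tests with tie correction.
dunn_test <- function(v, g, control = NULL, adjust = "bonferroni") {
  r <- rank(v)
  N <- length(v)
  ties <- table(r)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  s2 <- N * (N + 1) / 12 - tie_corr
  means <- tapply(r, g, mean)
  ns <- tapply(r, g, length)
  gs <- names(means)
  pairs <- if (!is.null(control)) {
    lapply(setdiff(gs, control), function(a) c(a, control))
  } else {
    utils::combn(gs, 2, simplify = FALSE)
  }
  res <- purrr::map_dfr(pairs, function(pr) {
    z <- (means[[pr[1]]] - means[[pr[2]]]) /
      sqrt(s2 * (1 / ns[[pr[1]]] + 1 / ns[[pr[2]]]))
    tibble(group1 = pr[1], group2 = pr[2], statistic = z,
           p_value = 2 * pnorm(-abs(z)))
  })
  res$p_adjusted <- stats::p.adjust(res$p_value, method = adjust)
  res
}

pairwise_t_vs <- function(v, g, control, adjust) {
  gs <- unique(g)
  pairs <- if (!is.null(control)) {
    lapply(setdiff(gs, control), function(a) c(a, control))
  } else {
    utils::combn(gs, 2, simplify = FALSE)
  }
  res <- purrr::map_dfr(pairs, function(pr) {
    tt <- stats::t.test(v[g == pr[1]], v[g == pr[2]])
    tibble(group1 = pr[1], group2 = pr[2], statistic = unname(tt$statistic),
           p_value = tt$p.value)
  })
  res$p_adjusted <- stats::p.adjust(res$p_value, method = adjust)
  res
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: statistic %.4g, p = %.4g\n",
              x$omnibus$method, x$omnibus$statistic, x$omnibus$p_value))
  print(x$pairwise)
  invisible(x)
}

#' @rdname compare_groups
#' @param x A `group_comparison` object.
#' @param ... Unused.
#' @export
tidy.group_comparison <- function(x, ...) x$pairwise

#' @rdname compare_groups
#' @export
glance.group_comparison <- function(x, ...) x$omnibus

#' Line-level screen summary
#'
#' Collapses per-fly tremor summaries to one row per genotype: sample size,
#' tremor-positive count, penetrance with exact Clopper-Pearson interval, mean
#' tremor rate, and a p-value vs the control line (Mann-Whitney on per-fly
#' tremor rates for a single test line; Kruskal-Wallis + Dunn vs control when
#' several lines are screened together). Lines with adjusted p below `alpha`
#' and penetrance above the control's are flagged as hits.
#'
#' @param fly_summaries Row-bound output of [summarize_fly()] (needs columns
#'   `genotype`, `tremor_positive`, `tremor_rate_per_s`).
#' @param control Control genotype label (required).
#' @param alpha Hit-calling significance level (default 0.05).
#' @param adjust Multiplicity adjustment for the pairwise tests.
#' @return A tibble of class `line_result`, one row per genotype.
#' @export
summarize_screen <- function(fly_summaries, control, alpha = 0.05,
                             adjust = "bonferroni") {
  need <- c("genotype", "tremor_positive", "tremor_rate_per_s")
  if (!all(need %in% names(fly_summaries)))
    abort("`fly_summaries` must contain per-fly tremor summaries.")
  if (missing(control) || !control %in% fly_summaries$genotype)
    abort("`control` must name a genotype present in the data.")

  lines <- fly_summaries |>
    dplyr::group_by(.data$genotype) |>
    dplyr::summarise(
      n = dplyr::n(),
      k = sum(.data$tremor_positive),
      mean_tremor_rate = mean(.data$tremor_rate_per_s),
      .groups = "drop"
    )
  ci <- estimate_penetrance(lines$k, lines$n)
  lines$penetrance <- ci$penetrance
  lines$ci_lo <- ci$ci_lo
  lines$ci_hi <- ci$ci_hi

  cmp <- compare_groups(fly_summaries, "tremor_rate_per_s", "genotype",
                        control = control, adjust = adjust)
  pw <- tidy(cmp)
  pmap <- stats::setNames(pw$p_adjusted,
                          ifelse(pw$group1 == control, pw$group2, pw$group1))
  lines$p_vs_control <- unname(pmap[lines$genotype])
  ctrl_pen <- lines$penetrance[lines$genotype == control]
  lines$hit <- !is.na(lines$p_vs_control) & lines$p_vs_control < alpha &
    lines$penetrance > ctrl_pen
  lines$is_control <- lines$genotype == control
  class(lines) <- c("line_result", class(lines))
  lines
}
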