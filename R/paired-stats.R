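## Paired pre/post statistics: Shapiro-Wilk-gated paired t or Wilcoxon
## signed-rank tests, mean differences with t-based 95% CIs, and
## publication-style comparison tables. Differences are defined pre - post,
## so a decrease after treatment is a positive difference.

#' Normality gate for paired differences
#'
#' Routes a vector of paired differences to the parametric (paired t) or
#' nonparametric (Wilcoxon signed-rank) branch using the Shapiro-Wilk test:
#' p >= alpha selects the parametric branch. A constant vector is degenerate
#' and routed nonparametric with normality p = 0.
#'
#' @param diffs numeric vector of paired differences, length >= 3.
#' @param alpha gate level (default 0.05).
#' @return list with `route` (`"parametric"`/`"nonparametric"`) and
#'   `normality_p`.
#' @export
normalityGate <- function(diffs, alpha = 0.05) {
  diffs <- diffs[!is.na(diffs)]
  if (length(diffs) < 3L) stop("need at least 3 paired differences")
  if (diff(range(diffs)) == 0)
    return(list(route = "nonparametric", normality_p = 0))
  p <- stats::shapiro.test(diffs)$p.value
  list(route = if (p >= alpha) "parametric" else "nonparametric",
       normality_p = p)
}

#' Mean difference with t-based confidence interval
#'
#' mean +/- t_{1-alpha/2, n-1} * SD / sqrt(n). For a constant vector the
#' interval collapses to the point.
#'
#' @param diffs numeric vector, length >= 2.
#' @param level confidence level (default 0.95).
#' @return list with `mean`, `ci_low`, `ci_high`.
#' @export
meanDifferenceCI <- function(diffs, level = 0.95) {
  diffs <- diffs[!is.na(diffs)]
  n <- length(diffs)
  if (n < 2L) stop("need at least 2 values for a confidence interval")
  m <- mean(diffs)
  s <- stats::sd(diffs)
  half <- stats::qt(1 - (1 - level) / 2, df = n - 1L) * s / sqrt(n)
  list(mean = m, ci_low = m - half, ci_high = m + half)
}

## Exact null distribution of the signed-rank statistic over doubled
## midranks (so tied midranks of the form k/2 stay integral), by dynamic
## programming: f[w+1] = number of sign assignments with doubled W+ = w.
.signedRankExactP <- function(W, ranks) {
  r2 <- as.integer(round(2 * ranks))
  total <- sum(r2)
  f <- numeric(total + 1L)
  f[1L] <- 1
  for (r in r2) {
    g <- f
    g[(r + 1L):(total + 1L)] <- g[(r + 1L):(total + 1L)] + f[1L:(total - r + 1L)]
    f <- g
  }
  w2 <- round(2 * W)
  mu2 <- total / 2
  extreme <- abs(seq(0L, total) - mu2) >= abs(w2 - mu2) - 1e-9
  sum(f[extreme]) / 2^length(r2)
}

#' Wilcoxon signed-rank test for paired differences
#'
#' Zero differences are dropped (Wilcoxon's rule), absolute values are
#' midranked in the presence of ties, and the two-sided p-value is exact
#' (full null distribution by dynamic programming) for up to `exactMax`
#' non-zero differences, and a normal approximation with continuity
#' correction and midrank variance above that. The exact two-sided p is the
#' null probability of a signed-rank statistic at least as far from its mean
#' as observed.
#'
#' @param diffs numeric vector of paired differences.
#' @param exactMax largest number of non-zero differences for which the
#'   exact distribution is used (default 25).
#' @return list with `statistic` (W+, sum of positive ranks), `p_value`,
#'   `n_nonzero`, `method` (`"exact"`/`"normal_approx"`/`"degenerate"`).
#' @export
wilcoxonSignedRank <- function(diffs, exactMax = 25L) {
  d <- diffs[!is.na(diffs)]
  d <- d[d != 0]
  m <- length(d)
  if (m == 0L)
    return(list(statistic = 0, p_value = 1, n_nonzero = 0L,
                method = "degenerate"))
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  mu <- sum(r) / 2
  if (m <= exactMax) {
    p <- .signedRankExactP(W, r)
    method <- "exact"
  } else {
    sigma <- sqrt(sum(r^2) / 4)
    z <- (abs(W - mu) - 0.5) / sigma
    p <- 2 * stats::pnorm(-max(z, 0))
    method <- "normal_approx"
  }
  list(statistic = W, p_value = min(p, 1), n_nonzero = m, method = method)
}

#' Summarise a variable as the tables do
#'
#' Parametric style: mean and SD; nonparametric style: median with
#' interquartile range (linear-interpolation quantiles). A single value has
#' SD reported as 0 with a degenerate flag.
#'
#' @param values numeric vector, length >= 1.
#' @param style `"parametric"` or `"nonparametric"`.
#' @return list with `center`, `spread_low`, `spread_high` (for parametric
#'   style these are mean -/+ SD carriers: `sd` is also returned),
#'   `style` and `degenerate`.
#' @export
summarizeVariable <- function(values, style = c("parametric", "nonparametric")) {
  style <- match.arg(style)
  values <- values[!is.na(values)]
  if (!length(values)) stop("no values to summarise")
  degenerate <- length(values) == 1L
  if (style == "parametric") {
    s <- if (degenerate) 0 else stats::sd(values)
    list(center = mean(values), sd = s, spread_low = mean(values) - s,
         spread_high = mean(values) + s, style = style, degenerate = degenerate)
  } else {
    q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    list(center = q[2L], sd = NA_real_, spread_low = q[1L],
         spread_high = q[3L], style = style, degenerate = degenerate)
  }
}

#' Difference of two summary means
#'
#' Convenience for worked-example arithmetic on published summary tables:
#' the mean of paired differences equals the difference of the pre and post
#' means.
#'
#' @param meanPre,meanPost summary means.
#' @return meanPre - meanPost.
#' @export
summaryDifference <- function(meanPre, meanPost) meanPre - meanPost

#' Normality-gated paired comparison of one variable
#'
#' Computes differences pre - post, routes them through [normalityGate()],
#' and tests whether they are centred on zero with a paired t-test
#' (parametric branch) or the Wilcoxon signed-rank test (nonparametric
#' branch). The mean difference with its t-based 95% CI is always reported,
#' even alongside a Wilcoxon p (nonparametric results carry a style flag and
#' median/IQR summaries).
#'
#' @param pre,post paired numeric vectors (same subjects, same order).
#' @param variable variable name for the output row.
#' @param alpha gate and significance level (default 0.05).
#' @param level confidence level for the mean-difference CI.
#' @param force `NULL` for gated routing, or `"parametric"`/`"nonparametric"`
#'   to force a branch.
#' @param exactMax passed to [wilcoxonSignedRank()].
#' @return one-row data.frame: variable, n, pre/post summaries (mean, sd,
#'   median, q1, q3), summary_style, normality_p, test_used,
#'   mean_difference, ci_low, ci_high, p_value, significant.
#' @examples
#' pairedTest(c(4.2, 3.9, 4.8, 4.4), c(3.6, 3.8, 4.1, 3.9), variable = "LVEDVi")
#' @export
pairedTest <- function(pre, post, variable = "variable", alpha = 0.05,
                       level = 0.95, force = NULL, exactMax = 25L) {
  if (length(pre) != length(post)) stop("pre and post must have equal length")
  keep <- !(is.na(pre) | is.na(post))
  pre <- pre[keep]; post <- post[keep]
  n <- length(pre)
  if (n < 3L) stop("need at least 3 complete pairs")
  d <- pre - post

  if (is.null(force)) {
    gate <- normalityGate(d, alpha = alpha)
  } else {
    force <- match.arg(force, c("parametric", "nonparametric"))
    gate <- list(route = force,
                 normality_p = if (diff(range(d)) == 0) 0
                               else stats::shapiro.test(d)$p.value)
  }

  ci <- meanDifferenceCI(d, level = level)
  if (diff(range(d)) == 0 && d[1L] == 0) {
    ## identical pre/post: differences all zero, p defined as 1
    p <- 1
    test <- if (gate$route == "parametric") "paired_t" else "wilcoxon"
  } else if (gate$route == "parametric") {
    tstat <- mean(d) / (stats::sd(d) / sqrt(n))
    p <- 2 * stats::pt(-abs(tstat), df = n - 1L)
    test <- "paired_t"
  } else {
    p <- wilcoxonSignedRank(d, exactMax = exactMax)$p_value
    test <- "wilcoxon"
  }

  style <- if (test == "wilcoxon") "nonparametric" else "parametric"
  qs <- function(x) stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  qpre <- qs(pre); qpost <- qs(post)
  data.frame(variable = variable, n = n,
             pre_mean = mean(pre), pre_sd = stats::sd(pre),
             pre_median = qpre[2L], pre_q1 = qpre[1L], pre_q3 = qpre[3L],
             post_mean = mean(post), post_sd = stats::sd(post),
             post_median = qpost[2L], post_q1 = qpost[1L], post_q3 = qpost[3L],
             summary_style = style, normality_p = gate$normality_p,
             test_used = test, mean_difference = ci$mean,
             ci_low = ci$ci_low, ci_high = ci$ci_high, p_value = p,
             significant = p < alpha, stringsAsFactors = FALSE)
}

#' Paired comparison table over many variables
#'
#' Runs [pairedTest()] for every variable (and, for per-phase variables,
#' every phase) of a long-format measurement table. Subjects missing either
#' visit for a variable are dropped for that variable, with the dropped
#' count recorded. No multiplicity adjustment is applied (each variable is
#' tested at `alpha` on its own), matching common practice in small paired
#' cohort studies; interpret families of tests accordingly.
#'
#' @param data long-format data.frame with columns `subject_id`, `visit`
#'   (`"pre"`/`"post"`), `variable`, `value` and optionally `phase`.
#' @param variables variables to test (default: all present).
#' @param phases phases to include for phase-resolved variables (default:
#'   all present).
#' @param alpha significance level (default 0.05).
#' @param ... passed to [pairedTest()].
#' @return data.frame with one row per variable (x phase), the
#'   [pairedTest()] columns plus `phase` and `n_dropped`.
#' @export
comparisonTable <- function(data, variables = NULL, phases = NULL,
                            alpha = 0.05, ...) {
  stopifnot(all(c("subject_id", "visit", "variable", "value") %in% names(data)))
  if (!"phase" %in% names(data)) data$phase <- NA_character_
  if (is.null(variables)) variables <- unique(data$variable)
  out <- list()
  for (v in variables) {
    dv <- data[data$variable == v, , drop = FALSE]
    if (!nrow(dv)) next
    phs <- unique(dv$phase)
    if (!is.null(phases) && !all(is.na(phs)))
      phs <- phs[is.na(phs) | phs %in% phases]
    for (ph in phs) {
      dp <- if (is.na(ph)) dv[is.na(dv$phase), , drop = FALSE]
            else dv[!is.na(dv$phase) & dv$phase == ph, , drop = FALSE]
      if (!nrow(dp)) next
      wide <- merge(dp[dp$visit == "pre", c("subject_id", "value")],
                    dp[dp$visit == "post", c("subject_id", "value")],
                    by = "subject_id", suffixes = c("_pre", "_post"))
      complete <- stats::complete.cases(wide[, c("value_pre", "value_post")])
      nDropped <- length(unique(dp$subject_id)) - sum(complete)
      if (nDropped > 0)
        message(sprintf("%s%s: dropped %d subject(s) with incomplete pairs",
                        v, if (is.na(ph)) "" else paste0(" @", ph), nDropped))
      wide <- wide[complete, , drop = FALSE]
      if (nrow(wide) < 3L) next
      row <- pairedTest(wide$value_pre, wide$value_post, variable = v,
                        alpha = alpha, ...)
      row$phase <- ph
      row$n_dropped <- nDropped
      out[[length(out) + 1L]] <- row
    }
  }
  if (!length(out))
    return(data.frame(variable = character(), phase = character()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Render a comparison table in publication style
#'
#' Formats a [comparisonTable()] result with mean +/- SD (or median, IQR for
#' nonparametric rows), the mean difference with its 95% CI, and p-values,
#' rounded to `digits` decimal places.
#'
#' @param tbl output of [comparisonTable()].
#' @param digits rounding for summaries and differences (default 2).
#' @return data.frame of formatted character columns: Variable, Phase, Pre,
#'   Post, MeanDiff, CI95, P, Test, Flag.
#' @export
formatComparisonTable <- function(tbl, digits = 2) {
  fm <- function(x) formatC(round(x, digits), format = "f", digits = digits)
  fp <- function(p) ifelse(p < 0.001, "<.001", sub("^0", "", sprintf("%.3g", p)))
  summ <- function(center, sd, med, q1, q3, style)
    ifelse(style == "nonparametric",
           sprintf("%s, %s - %s", fm(med), fm(q1), fm(q3)),
           sprintf("%s ± %s", fm(center), fm(sd)))
  data.frame(
    Variable = tbl$variable,
    Phase = ifelse(is.na(tbl$phase), "", tbl$phase),
    Pre = summ(tbl$pre_mean, tbl$pre_sd, tbl$pre_median, tbl$pre_q1,
               tbl$pre_q3, tbl$summary_style),
    Post = summ(tbl$post_mean, tbl$post_sd, tbl$post_median, tbl$post_q1,
                tbl$post_q3, tbl$summary_style),
    MeanDiff = fm(tbl$mean_difference),
    CI95 = sprintf("%s, %s", fm(tbl$ci_low), fm(tbl$ci_high)),
    P = fp(tbl$p_value),
    Test = tbl$test_used,
    Flag = ifelse(tbl$significant, "*", ""),
    stringsAsFactors = FALSE)
}
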