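check_pairs <- function(criterion, test, min_n = 2) {
  stopifnot(is.numeric(criterion), is.numeric(test))
  if (length(criterion) != length(test)) {
    abort("criterion and test must have the same length")
  }
  if (length(criterion) < min_n) {
    abort(paste0("need at least ", min_n, " pairs"))
  }
  invisible(TRUE)
}

#' Pearson correlation between paired method estimates
#'
#' @param criterion,test Paired numeric vectors (one value per
#'   participant).
#' @return List with `r` and two-sided `p` (t transform, n - 2 df).
#' @export
pearson_r <- function(criterion, test) {
  check_pairs(criterion, test, min_n = 3)
  if (sd(criterion) == 0 || sd(test) == 0) {
    abort("correlation undefined: zero variance")
  }
  ct <- cor.test(criterion, test, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Mean difference (criterion minus test) and its standard error
#'
#' @inheritParams pearson_r
#' @return List with `mean_diff` and `se_diff` (SD of differences / sqrt n).
#' @export
mean_difference <- function(criterion, test) {
  check_pairs(criterion, test)
  d <- criterion - test
  list(mean_diff = mean(d), se_diff = sd(d) / sqrt(length(d)))
}

#' Mean absolute percent error
#'
#' Participant-level MAPE: the mean over pairs of
#' `|criterion - test| / criterion * 100`. Pairs with a zero criterion
#' value are dropped with a warning.
#'
#' @inheritParams pearson_r
#' @return Percent error (scalar).
#' @export
mape <- function(criterion, test) {
  check_pairs(criterion, test, min_n = 1)
  keep <- criterion != 0
  if (!any(keep)) abort("MAPE undefined: all criterion values are zero")
  if (!all(keep)) warn("dropping pairs with zero criterion value")
  mean(abs(criterion[keep] - test[keep]) / criterion[keep]) * 100
}

#' Bland-Altman agreement analysis
#'
#' Differences are criterion minus test; bias is their mean and the 95%
#' limits of agreement are bias +/- 1.96 sample standard deviations.
#'
#' @inheritParams pearson_r
#' @return List with `bias`, `loa_low`, `loa_high` and a `points` tibble
#'   (`mean`, `diff`) for plotting.
#' @export
bland_altman <- function(criterion, test) {
  check_pairs(criterion, test)
  d <- criterion - test
  s <- sd(d)
  list(bias = mean(d), loa_low = mean(d) - 1.96 * s,
       loa_high = mean(d) + 1.96 * s,
       points = tibble::tibble(mean = (criterion + test) / 2, diff = d))
}

#' t-based confidence interval of a sample mean
#'
#' @param values Numeric vector (n >= 2).
#' @param level Confidence level (default 0.90).
#' @return Named numeric `c(low, high)`.
#' @export
ci_mean <- function(values, level = 0.90) {
  stopifnot(length(values) >= 2, level > 0, level < 1)
  n <- length(values)
  half <- qt(1 - (1 - level) / 2, n - 1) * sd(values) / sqrt(n)
  c(low = mean(values) - half, high = mean(values) + half)
}

#' 90% confidence interval of a sample mean
#'
#' @param values Numeric vector (n >= 2).
#' @return Named numeric `c(low, high)`.
#' @export
ci90_mean <- function(values) ci_mean(values, level = 0.90)

#' Minimum equivalence zone containing a confidence interval
#'
#' The equivalence zone (EZ) at `p` percent is the interval
#' `criterion mean * (1 +/- p/100)`. The minimum EZ is the smallest
#' multiple of `granularity` (percentage points, ceiling) such that the
#' test method's confidence interval lies entirely inside the zone:
#' `ceiling` of `100 * max(crit_mean - ci_low, ci_high - crit_mean) /
#' crit_mean`, floored at zero.
#'
#' @param crit_mean Criterion-method mean (> 0).
#' @param ci_low,ci_high Confidence-interval bounds of the test-method
#'   mean (`ci_low <= ci_high`).
#' @param granularity EZ step in percentage points.
#' @return List with `ez_pct`, `ez_low`, `ez_high`.
#' @export
#' @examples
#' minimum_equivalence_zone(237.1, 198.18, 275.7)$ez_pct # 16.5
minimum_equivalence_zone <- function(crit_mean, ci_low, ci_high,
                                     granularity = 0.1) {
  if (!is.numeric(crit_mean) || crit_mean <= 0) {
    abort("crit_mean must be positive")
  }
  stopifnot(ci_low <= ci_high, granularity > 0)
  ratio <- 100 * max(crit_mean - ci_low, ci_high - crit_mean, 0) / crit_mean
  ez <- ceiling(ratio / granularity - 1e-9) * granularity
  ez <- max(0, ez)
  list(ez_pct = ez,
       ez_low = crit_mean * (1 - ez / 100),
       ez_high = crit_mean * (1 + ez / 100))
}

#' Is a confidence interval contained in an equivalence zone?
#'
#' @inheritParams minimum_equivalence_zone
#' @param ez_pct Equivalence zone half-width in percent of the criterion
#'   mean.
#' @return `TRUE` iff `[ci_low, ci_high]` lies inside
#'   `crit_mean * (1 +/- ez_pct/100)`.
#' @export
equivalence_at <- function(crit_mean, ci_low, ci_high, ez_pct) {
  if (!is.numeric(crit_mean) || crit_mean <= 0) {
    abort("crit_mean must be positive")
  }
  stopifnot(ci_low <= ci_high)
  eps <- 1e-9 * max(1, abs(crit_mean))
  ci_low >= crit_mean * (1 - ez_pct / 100) - eps &&
    ci_high <= crit_mean * (1 + ez_pct / 100) + eps
}

agreement_row <- function(criterion, test, ci_level = 0.90,
                          granularity = 0.1) {
  n <- length(criterion)
  safe <- function(expr) tryCatch(expr, error = function(e) NULL)
  pr <- safe(pearson_r(criterion, test))
  md <- safe(mean_difference(criterion, test))
  mp <- safe(mape(criterion, test))
  ba <- safe(bland_altman(criterion, test))
  ci <- safe(ci_mean(test, level = ci_level))
  cm <- mean(criterion)
  ez <- if (!is.null(ci) && cm > 0) {
    minimum_equivalence_zone(cm, ci["low"], ci["high"], granularity)
  }
  na_if_null <- function(x) if (is.null(x)) NA_real_ else x
  tibble::tibble(
    n = n, crit_mean = cm, test_mean = mean(test),
    r = na_if_null(pr$r), r_pvalue = na_if_null(pr$p),
    mean_diff = na_if_null(md$mean_diff), se_diff = na_if_null(md$se_diff),
    mape = na_if_null(mp),
    ba_bias = na_if_null(ba$bias), ba_loa_low = na_if_null(ba$loa_low),
    ba_loa_high = na_if_null(ba$loa_high),
    ci_low = na_if_null(unname(ci["low"])),
    ci_high = na_if_null(unname(ci["high"])),
    ez_pct = na_if_null(ez$ez_pct), ez_low = na_if_null(ez$ez_low),
    ez_high = na_if_null(ez$ez_high)
  )
}

#' Paired-method validation suite
#'
#' Computes the full agreement battery — Pearson r, mean difference with
#' SE, MAPE, Bland-Altman bias and 95% limits of agreement, the
#' `ci_level` confidence interval of the test-method mean, and the minimum
#' equivalence zone around the criterion mean — for each group of paired
#' per-participant estimates. Cells needing more participants than
#' provided are `NA`.
#'
#' @param pairs Tibble with numeric columns `criterion` and `test`, one
#'   row per participant, plus optional grouping columns (e.g. `class`,
#'   `comparison`).
#' @param by Character vector of grouping columns (default: every column
#'   other than `criterion`, `test`, `participant`).
#' @param ci_level Confidence level of the test-method interval.
#' @param granularity Equivalence-zone step (percentage points).
#' @return A `wpa_agreement` object; `tidy()` returns one row per group.
#' @export
validate_methods <- function(pairs, by = NULL, ci_level = 0.90,
                             granularity = 0.1) {
  stopifnot(all(c("criterion", "test") %in% names(pairs)))
  if (is.null(by)) {
    by <- setdiff(names(pairs), c("criterion", "test", "participant"))
  }
  results <- if (length(by)) {
    dplyr::group_by(pairs, dplyr::across(dplyr::all_of(by))) |>
      dplyr::group_modify(function(df, key) {
        agreement_row(df$criterion, df$test, ci_level, granularity)
      }) |>
      dplyr::ungroup()
  } else {
    agreement_row(pairs$criterion, pairs$test, ci_level, granularity)
  }
  structure(list(results = results, pairs = pairs, by = by,
                 ci_level = ci_level, granularity = granularity),
            class = "wpa_agreement")
}

#' @export
print.wpa_agreement <- function(x, ...) {
  cat("Method-agreement suite (", x$ci_level * 100, "% CI, EZ step ",
      x$granularity, " pp)\n", sep = "")
  print(x$results, ...)
  invisible(x)
}

#' Tidy a method-agreement fit
#' @param x A `wpa_agreement`.
#' @param ... Unused.
#' @return Tibble with one row per comparison group.
#' @method tidy wpa_agreement
#' @export
tidy.wpa_agreement <- function(x, ...) x$results

#' One-row summary of a method-agreement fit
#' @param x A `wpa_agreement`.
#' @param ... Unused.
#' @return One-row tibble.
#' @method glance wpa_agreement
#' @export
glance.wpa_agreement <- function(x, ...) {
  tibble::tibble(
    n_groups = nrow(x$results), n_pairs = nrow(x$pairs),
    ci_level = x$ci_level, median_r = stats::median(x$results$r),
    max_mape = max(x$results$mape)
  )
}

#' Bland-Altman plot of a method-agreement fit
#'
#' One panel per comparison group: paired means on the x axis, criterion
#' minus test differences on the y axis, with the bias and 95% limits of
#' agreement as horizontal lines.
#'
#' @param object A `wpa_agreement`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot wpa_agreement
#' @export
autoplot.wpa_agreement <- function(object, ...) {
  by <- object$by
  pts <- object$pairs |>
    dplyr::mutate(mean = (.data$criterion + .data$test) / 2,
                  diff = .data$criterion - .data$test)
  lines <- object$results |>
    tidyr::pivot_longer(c("ba_bias", "ba_loa_low", "ba_loa_high"),
                        names_to = "line", values_to = "y")
  p <- ggplot2::ggplot(pts, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_hline(
      data = lines,
      ggplot2::aes(yintercept = .data$y,
                   linetype = .data$line == "ba_bias")
    ) +
    ggplot2::guides(linetype = "none") +
    ggplot2::labs(x = "Mean of methods (min)",
                  y = "Criterion - test (min)") +
    ggplot2::theme_minimal()
  if (length(by)) {
    p <- p + ggplot2::facet_wrap(by, scales = "free")
  }
  p
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
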