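#' Quality-filter an EVI series
#'
#' Per composite date, keeps the observations of the best quality rank
#' present (high > median > poor) and averages them; poor observations
#' survive only on dates with nothing better.
#'
#' @param series an `EviSeries` (possibly with several observations per
#'   date, e.g. merged orbits).
#' @return an `EviSeries` with one value per date and the retained rank in
#'   `$qa`.
#' @export
filter_by_qa <- function(series) {
  if (!length(series$values)) stop("empty series", call. = FALSE)
  rank <- match(series$qa, QA_LEVELS)
  if (anyNA(rank)) stop("qa ranks must be high/median/poor", call. = FALSE)
  key <- as.numeric(series$dates)
  best <- tapply(rank, key, min)
  keep <- rank == best[as.character(key)]
  v <- tapply(series$values[keep], key[keep], mean)
  d <- as.Date(as.numeric(names(v)), origin = "1970-01-01")
  evi_series(d, as.numeric(v), QA_LEVELS[best[as.character(as.numeric(d))]],
             series$location_id)
}

# Gaussian log-likelihood of a segment at its own MLEs (variance floored).
seg_loglik <- function(n, varhat) {
  varhat <- max(varhat, 1e-12)
  -n / 2 * (log(2 * pi * varhat) + 1)
}

#' Detect the single most likely change point in mean and variance
#'
#' At-most-one-change Gaussian likelihood-ratio scan: for each admissible
#' split after index tau the two segments get their own mean and variance
#' MLEs, and the statistic is twice the log-likelihood gain over the
#' unsplit series. The change is significant when the maximal statistic
#' exceeds the penalty (default MBIC-style `(p + 1) log n` with `p = 3`
#' extra parameters: second mean, second variance, the location itself).
#'
#' @param series an `EviSeries` (or plain numeric vector).
#' @param min_seg minimum observations per segment (default 4).
#' @param penalty numeric penalty, or `"mbic"` for the default rule.
#' @return a `ChangePointResult`: `tau` (index of the last pre-change
#'   observation, `NA` when not significant), `prior_mean`, `current_mean`,
#'   `prior_var`, `current_var`, `test_statistic`, `significant`.
#' @export
detect_changepoint <- function(series, min_seg = 4L, penalty = "mbic") {
  x <- if (inherits(series, "EviSeries")) series$values else as.numeric(series)
  n <- length(x)
  if (n < 2L * min_seg)
    stop("series shorter than 2 * min_seg", call. = FALSE)
  pen <- if (identical(penalty, "mbic")) 4 * log(n) else as.numeric(penalty)
  # cumulative sums give all segment MLEs in O(n)
  cs <- cumsum(x); cs2 <- cumsum(x^2)
  taus <- seq(min_seg, n - min_seg)
  n1 <- taus; n2 <- n - taus
  m1 <- cs[taus] / n1
  m2 <- (cs[n] - cs[taus]) / n2
  v1 <- pmax(cs2[taus] / n1 - m1^2, 1e-12)
  v2 <- pmax((cs2[n] - cs2[taus]) / n2 - m2^2, 1e-12)
  if (any(c(v1, v2) <= 1e-12))
    warning("zero segment variance floored at 1e-12")
  v0 <- max(cs2[n] / n - (cs[n] / n)^2, 1e-12)
  ll0 <- seg_loglik(n, v0)
  stat <- 2 * (-n1 / 2 * (log(2 * pi * v1) + 1) +
               -n2 / 2 * (log(2 * pi * v2) + 1) - ll0)
  k <- which.max(stat)
  sig <- stat[k] > pen
  if (sig) {
    tau <- taus[k]
    res <- list(tau = tau,
                prior_mean = mean(x[1:tau]), current_mean = mean(x[(tau + 1):n]),
                prior_var = v1[k], current_var = v2[k],
                test_statistic = stat[k], significant = TRUE)
  } else {
    res <- list(tau = NA_integer_,
                prior_mean = mean(x), current_mean = mean(x),
                prior_var = v0, current_var = v0,
                test_statistic = stat[k], significant = FALSE)
  }
  res$penalty <- pen
  if (inherits(series, "EviSeries")) {
    res$location_id <- series$location_id
    res$tau_date <- if (sig) series$dates[res$tau] else as.Date(NA)
  }
  structure(res, class = "ChangePointResult")
}

#' @export
print.ChangePointResult <- function(x, ...) {
  cat(sprintf("<ChangePoint: tau=%s stat=%.2f (pen %.2f) %s; mean %.3f -> %.3f>\n",
              ifelse(is.na(x$tau), "none", x$tau), x$test_statistic,
              x$penalty, ifelse(x$significant, "significant", "n.s."),
              x$prior_mean, x$current_mean))
  invisible(x)
}

# 16-day period of the year, 1..23 (the last period absorbs the year tail).
period_of_year <- function(dates) {
  doy <- as.integer(format(dates, "%j"))
  pmin(doy %/% 16L + 1L, 23L)
}

#' Post-change EVI phenology (23 per-period medians)
#'
#' Groups the observations after the change point (the "current" segment;
#' the whole series when no change was found) by 16-day period of the
#' year and takes the multi-year median per period.
#'
#' @param series an `EviSeries`.
#' @param cp its `ChangePointResult` (optional; default detects none and
#'   uses the whole series).
#' @return a `Phenology`: numeric vector of 23 medians (NA where a period
#'   has no post-change data), with `location_id` and `n_missing`
#'   attributes.
#' @export
phenology <- function(series, cp = NULL) {
  idx <- seq_along(series$values)
  if (!is.null(cp) && cp$significant) idx <- idx[idx > cp$tau]
  per <- period_of_year(series$dates[idx])
  v <- rep(NA_real_, 23L)
  med <- tapply(series$values[idx], per, median)
  v[as.integer(names(med))] <- med
  structure(v, class = "Phenology", location_id = series$location_id,
            n_missing = sum(is.na(v)))
}

#' Summarize degradation across labeled locations
#'
#' A location counts as "reduced" when its change point is significant
#' and the current mean is below the prior mean. Reports the overall
#' percentage reduced and the Pearson chi-square of the reduced-by-
#' category contingency table (df = number of categories - 1).
#'
#' @param results list of `ChangePointResult`s, one per location.
#' @param labels ordinal suitability labels, same length and order.
#' @return list: `reduced` (logical), `pct_reduced`, `table` (2 x 4),
#'   `chisq`, `df`, `p_value` (NA when the table is degenerate).
#' @export
summarize_degradation <- function(results, labels) {
  if (length(results) != length(labels))
    stop("results and labels lengths differ", call. = FALSE)
  red <- vapply(results, function(r)
    isTRUE(r$significant) && r$current_mean < r$prior_mean, TRUE)
  labels <- factor(labels, levels = SUITABILITY_LEVELS)
  tab <- table(reduced = factor(red, levels = c(FALSE, TRUE)), labels)
  chi <- tryCatch(suppressWarnings(chisq.test(tab, correct = FALSE)),
                  error = function(e) NULL)
  degenerate <- is.null(chi) || !is.finite(chi$statistic)
  list(reduced = red,
       pct_reduced = 100 * mean(red),
       table = tab,
       chisq = if (degenerate) NA_real_ else unname(chi$statistic),
       df = length(SUITABILITY_LEVELS) - 1L,
       p_value = if (degenerate) NA_real_ else chi$p.value)
}
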