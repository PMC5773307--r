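lattice <- composite_dates("2001-01-01", "2002-12-31")

test_that("filter_by_qa keeps the best rank per date and averages it", {
  d <- rep(lattice[1:2], each = 2)
  s <- evi_series(d, c(0.5, 0.9, 0.3, 0.7),
                  c("high", "poor", "poor", "poor"), "loc1")
  f <- filter_by_qa(s)
  # date 1: the high obs alone; date 2: only poor exists, mean retained
  expect_equal(f$values, c(0.5, 0.5))
  expect_equal(f$qa, c("high", "poor"))

  allhigh <- evi_series(lattice[1:10], seq(0.1, 1, length.out = 10),
                        rep("high", 10), "loc2")
  expect_equal(filter_by_qa(allhigh)$values, allhigh$values)

  two <- evi_series(rep(lattice[1], 2), c(0.2, 0.4), c("median", "median"), 1)
  expect_equal(filter_by_qa(two)$values, 0.3)

  expect_error(filter_by_qa(evi_series(as.Date(character()), numeric(),
                                       character(), 1)), "empty")
})

test_that("detect_changepoint equals the brute-force scan", {
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(30:300, 1)
    x <- rnorm(n, 0.5, 0.05)
    if (rep %% 2 == 0) {
      tau <- sample(seq(10, n - 10), 1)
      x[(tau + 1):n] <- x[(tau + 1):n] - 0.2
    }
    cp <- detect_changepoint(x, min_seg = 4L, penalty = -Inf)
    orc <- oracle_changepoint(x, min_seg = 4L)
    expect_equal(cp$tau, orc$tau)
    expect_equal(cp$test_statistic, orc$stat, tolerance = 1e-9)
  }
})

test_that("change-point results are internally consistent and shift-invariant", {
  set.seed(32)
  x <- c(rnorm(100, 0.6, 0.02), rnorm(100, 0.4, 0.04))
  cp <- detect_changepoint(x)
  expect_true(cp$significant)
  expect_equal(cp$prior_mean, mean(x[1:cp$tau]))
  expect_equal(cp$current_mean, mean(x[(cp$tau + 1):200]))

  cp2 <- detect_changepoint(x + 5)
  expect_equal(cp2$tau, cp$tau)
  expect_equal(cp2$test_statistic, cp$test_statistic, tolerance = 1e-9)

  expect_error(detect_changepoint(rnorm(6), min_seg = 4L), "min_seg")

  # no change found: prior equals current, whole-series stats
  flat <- rnorm(100, 0.5, 0.01)
  cpf <- detect_changepoint(flat, penalty = 1e6)
  expect_false(cpf$significant)
  expect_equal(cpf$prior_mean, cpf$current_mean)
  expect_equal(cpf$prior_mean, mean(flat))
})

test_that("phenology takes post-change per-period medians", {
  # constant series: all 23 periods at 0.4
  dts <- composite_dates("2010-01-01", "2012-12-31")
  s <- evi_series(dts, rep(0.4, length(dts)), rep("high", length(dts)), 1)
  ph <- phenology(s)
  expect_equal(as.numeric(ph), rep(0.4, 23))

  # hand-built 2-year series: median of the two year's values per period
  two <- composite_dates("2001-01-01", "2002-12-31")
  v <- c(seq(0.1, 0.54, by = 0.02), seq(0.3, 0.74, by = 0.02))  # 23 + 23
  s2 <- evi_series(two, v, rep("high", 46), 2)
  ph2 <- phenology(s2)
  expect_equal(as.numeric(ph2), (v[1:23] + v[24:46]) / 2)

  # observation order within periods does not matter
  shuf <- sample(46)
  s3 <- evi_series(two[shuf], v[shuf], rep("high", 46), 3)
  expect_equal(as.numeric(phenology(s3)), as.numeric(ph2))

  # post-change restriction + missing-period marking
  ph4 <- phenology(s2, structure(list(tau = 40L, significant = TRUE),
                                 class = "ChangePointResult"))
  expect_equal(attr(ph4, "n_missing"), sum(is.na(ph4)))
  expect_gt(attr(ph4, "n_missing"), 0L)
  expect_equal(as.numeric(ph4)[18:23], v[41:46])
})

test_that("summarize_degradation flags reductions and runs the chi-square", {
  mk <- function(sig, prior, cur)
    structure(list(significant = sig, prior_mean = prior, current_mean = cur),
              class = "ChangePointResult")
  labs <- factor(rep(c("poor", "acceptable", "good", "excellent"), each = 3),
                 levels = levels_suitability <- c("poor", "acceptable",
                                                  "good", "excellent"),
                 ordered = TRUE)
  res <- c(lapply(1:9, function(i) mk(TRUE, 0.6, 0.4)),
           lapply(1:3, function(i) mk(FALSE, 0.5, 0.5)))
  s <- summarize_degradation(res, labs)
  expect_equal(s$pct_reduced, 75)
  expect_equal(s$df, 3L)
  expect_equal(sum(s$table), 12)

  one <- summarize_degradation(list(mk(TRUE, 0.6, 0.3)),
                               factor("good", levels = levels_suitability))
  expect_equal(one$pct_reduced, 100)

  none <- summarize_degradation(lapply(1:4, function(i) mk(FALSE, 0.5, 0.5)),
                                labs[c(1, 4, 7, 10)])
  expect_equal(none$pct_reduced, 0)
  expect_true(is.na(none$chisq))

  expect_error(summarize_degradation(res, labs[1:3]), "lengths differ")
})

test_that("chi-square p-values are uniform when drops ignore category", {
  # category-independent degradation: the reduced x category table should
  # show no association; KS on the p-values over simulated cohorts
  set.seed(33)
  mk <- function(red)
    structure(list(significant = red, prior_mean = 0.6,
                   current_mean = if (red) 0.4 else 0.6),
              class = "ChangePointResult")
  pvals <- replicate(200, {
    labs <- sample(c("poor", "acceptable", "good", "excellent"), 80,
                   replace = TRUE)
    red <- runif(80) < 0.6
    summarize_degradation(lapply(red, mk), labs)$p_value
  })
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})
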