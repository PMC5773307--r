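make_layer <- function(v, nr = 20, nc = 20) grid_layer(matrix(v, nr, nc), 1000)

test_that("cluster_covariates groups by |r| and keeps TREE and AI", {
  set.seed(1)
  n <- 400
  a <- rnorm(n)
  dup <- a * 2 + 5           # r = 1 with a
  b <- rnorm(n)              # independent
  layers <- list(TREE = make_layer(a), DUP = make_layer(dup),
                 AI = make_layer(b))
  cl <- cluster_covariates(layers, threshold = 0.6)
  expect_length(cl$clusters, 2L)
  expect_setequal(cl$representatives, c("TREE", "AI"))

  # eight layers engineered into 3 blocks with within-block r ~ 0.9
  base <- replicate(3, rnorm(n))
  mk <- function(k) 0.95 * base[, k] + sqrt(1 - 0.95^2) * rnorm(n)
  eight <- list(TREE = make_layer(mk(1)), AI = make_layer(mk(2)),
                BIO02 = make_layer(mk(3)), BIO03 = make_layer(mk(1)),
                BIO07 = make_layer(mk(2)), BIO10 = make_layer(mk(3)),
                BIO17 = make_layer(mk(1)), BIO19 = make_layer(mk(2)))
  cl8 <- cluster_covariates(eight, threshold = 0.6)
  expect_length(cl8$clusters, 3L)

  expect_error(cluster_covariates(list(TREE = make_layer(a),
                                       K = make_layer(1))),
               "constant")
})

test_that("transform_and_standardize centers, scales and fixes skew", {
  set.seed(2)
  ln <- make_layer(exp(rnorm(400)))
  flat <- make_layer(rnorm(400, 10))
  st <- transform_and_standardize(list(A = ln, B = flat), skewed_names = "A")
  for (nm in c("A", "B")) {
    expect_equal(mean(st$layers[[nm]]$values), 0, tolerance = 1e-8)
    expect_equal(sd(st$layers[[nm]]$values), 1, tolerance = 1e-8)
  }
  skewness <- function(v) mean((v - mean(v))^3) / sd(v)^3
  expect_lt(abs(skewness(sqrt(ln$values))), abs(skewness(ln$values)))

  expect_error(transform_and_standardize(list(A = make_layer(0))), "variance")
  expect_error(transform_and_standardize(list(A = make_layer(rnorm(400)))
                                         , skewed_names = "A"),
               "negative")
})

test_that("partition_records splits by round(frac * n)", {
  pres <- data.frame(id = 1:88, x = runif(88), y = runif(88), year = 2000)
  sp <- partition_records(pres, 0.75, 5L, seed = 1)
  expect_length(sp, 5L)
  for (s in sp) {
    expect_equal(nrow(s$calibration), 66L)
    expect_equal(nrow(s$validation), 22L)
    expect_setequal(c(s$calibration$id, s$validation$id), pres$id)
  }
  tiny <- partition_records(pres[1:4, ], 0.75, 1L, seed = 1)[[1]]
  expect_equal(nrow(tiny$calibration), 3L)

  s1 <- partition_records(pres, 0.75, 1L, seed = 1)[[1]]$calibration$id
  s2 <- partition_records(pres, 0.75, 1L, seed = 2)[[1]]$calibration$id
  expect_false(identical(s1, s2))
  expect_error(partition_records(pres, 1.2), "frac")
})

test_that("fit_maxlike maximizes the presence-only likelihood", {
  land <- tiny_landscape(seed = 21, shape = c(40L, 40L))
  stack <- tiny_stack(land)
  pres <- simulate_presences(land, 300L, seed = 5, replace = TRUE)
  fit <- fit_maxlike(pres, stack, c("TREE", "AI"))
  expect_true(fit$converged)

  # the optimum beats beta = 0
  d <- keyhabitat:::maxlike_design(pres, stack, c("TREE", "AI"))
  expect_gte(fit$loglik,
             keyhabitat:::maxlike_loglik(rep(0, 3), d$X, d$pres_rows))

  # AICc invariant
  K <- length(fit$beta); n <- nrow(pres)
  expect_equal(fit$aicc,
               -2 * fit$loglik + 2 * K + 2 * K * (K + 1) / (n - K - 1))

  # shifting a covariate by a constant only moves the intercept
  stack2 <- covariate_stack(
    list(TREE = grid_layer(stack$layers$TREE$values + 3,
                           stack$layers$TREE$cell_size),
         AI = stack$layers$AI),
    stack$transforms, stack$center, stack$scale, NULL)
  fit2 <- fit_maxlike(pres, stack2, c("TREE", "AI"))
  expect_equal(unname(fit2$beta[-1]), unname(fit$beta[-1]), tolerance = 1e-4)
  expect_equal(unname(fit2$beta[1] + 3 * fit2$beta["TREE"]),
               unname(fit$beta[1]), tolerance = 1e-4)
})

test_that("slope error shrinks with sample size; AICc ignores scaling", {
  land <- tiny_landscape(seed = 25, shape = c(40L, 40L))
  stack <- tiny_stack(land)
  truth <- land$truth_beta[c("TREE", "AI")]
  mae <- vapply(c(200L, 1000L, 5000L), function(n) {
    errs <- vapply(1:25, function(r) {
      pres <- simulate_presences(land, n, seed = 5000 + 31 * n + r,
                                 replace = TRUE)
      fit <- fit_maxlike(pres, stack, c("TREE", "AI"))
      mean(abs(fit$beta[c("TREE", "AI")] - truth))
    }, 0)
    mean(errs)
  }, 0)
  expect_lt(mae[2], mae[1])
  expect_lt(mae[3], mae[1])

  # affine rescaling of the covariates leaves loglik and AICc unchanged
  pres <- simulate_presences(land, 200L, seed = 99, replace = TRUE)
  raw <- covariate_stack(land$layers[c("TREE", "AI")])
  fit_raw <- fit_maxlike(pres, raw, c("TREE", "AI"))
  fit_std <- fit_maxlike(pres, stack, c("TREE", "AI"))
  expect_equal(fit_raw$loglik, fit_std$loglik, tolerance = 1e-6)
  expect_equal(fit_raw$aicc, fit_std$aicc, tolerance = 1e-6)
})

test_that("complete separation is flagged, not thrown", {
  land <- tiny_landscape(seed = 22)
  pres <- simulate_presences(land, 40L, seed = 6)
  # indicator layer exactly 1 on presence cells: likelihood is unbounded
  sep <- matrix(0, 30, 30); sep[pres$cell] <- 1
  layers <- c(land$layers[c("TREE", "AI")],
              list(SEP = grid_layer(sep, 1000)))
  stack <- transform_and_standardize(layers)
  fit <- fit_maxlike(pres, stack, c("TREE", "AI", "SEP"))
  expect_false(fit$converged)
})

test_that("select_best_model counts converged AICc wins with small-model ties", {
  mk <- function(formula, rep, aicc, conv) {
    f <- list(formula = formula, aicc = aicc, converged = conv,
              replicate_id = rep)
    class(f) <- "MaxLikeFit"
    f
  }
  # Table-1 pattern: rich formulas never converge, small one always does
  fits <- c(
    lapply(1:5, function(r) mk(c("TREE", "AI", "BIO02"), r, 630 + r, FALSE)),
    lapply(1:5, function(r) mk(c("BIO02", "BIO03"), r, 633 + r, FALSE)),
    lapply(1:5, function(r) mk(c("TREE", "AI"), r, 690 + r, TRUE)))
  best <- select_best_model(fits)
  expect_equal(best$formula, c("TREE", "AI"))
  expect_equal(unname(best$wins[["TREE+AI"]]), 5L)

  # equal win counts: fewer covariates wins
  tied <- c(lapply(1:2, function(r) mk(c("A", "B"), r, c(10, 20)[r], TRUE)),
            lapply(1:2, function(r) mk("A", r, c(20, 10)[r], TRUE)))
  expect_equal(select_best_model(tied)$formula, "A")

  one <- list(mk("A", 1, 5, TRUE))
  expect_equal(select_best_model(one)$formula, "A")
  none <- lapply(1:2, function(r) mk(c("A", letters[r]), r, 1, FALSE))
  expect_error(select_best_model(none), "converged")
})

test_that("evaluate_fit equals the exhaustive threshold-search oracle", {
  land <- tiny_landscape(seed = 23)
  mask <- delineate_study_area(land$layers, target_cell = land$coarse_cell)
  stack <- tiny_stack(land, mask)
  pres <- simulate_presences(land, 60L, seed = 7, mask = mask)
  fit <- fit_maxlike(pres, stack, c("TREE", "AI"))
  pseudo <- sample_pseudoabsences(mask, 60L, seed = 8)

  m <- evaluate_fit(fit, pres[41:60, ], pseudo, stack)
  p1 <- keyhabitat:::predict_at_points(fit, stack, pres[41:60, ])
  p0 <- keyhabitat:::predict_at_points(fit, stack, pseudo)
  orc <- oracle_threshold_search(c(p1, p0),
                                 c(rep(1, length(p1)), rep(0, length(p0))))
  expect_equal(m$max_kappa, orc$max_kappa, tolerance = 1e-12)
  expect_equal(m$maxsss_value, orc$max_sss, tolerance = 1e-12)
  expect_equal(m$auc, oracle_auc(p1, p0), tolerance = 1e-12)

  expect_error(evaluate_fit(fit, pres[0, ], pseudo, stack), "empty")
})

test_that("evaluate_fit handles degenerate and separated predictions", {
  fit <- structure(list(formula = "X", beta = c(0, 0), replicate_id = 1L),
                   class = "MaxLikeFit")
  # constant covariate surface -> identical predictions for both classes
  stack <- covariate_stack(list(X = make_layer(0.5, 10, 10)))
  pts1 <- data.frame(x = c(500, 1500, 2500), y = rep(500, 3))
  pts0 <- data.frame(x = c(3500, 4500, 5500), y = rep(500, 3))
  m <- evaluate_fit(fit, pts1, pts0, stack)
  expect_equal(m$auc, 0.5)
  expect_equal(m$cor, 0)
  expect_equal(m$max_kappa, 0)

  # perfectly separated: monotone covariate, presences on the high side
  fit2 <- structure(list(formula = "X", beta = c(0, 1), replicate_id = 1L),
                    class = "MaxLikeFit")
  # column-constant gradient: value = column index (increases with x)
  grad <- covariate_stack(list(X = grid_layer(matrix(rep(1:10, each = 10),
                                                     10, 10), 1000)))
  hi <- data.frame(x = rep(9500, 3), y = c(500, 1500, 2500))
  lo <- data.frame(x = rep(500, 3), y = c(500, 1500, 2500))
  m2 <- evaluate_fit(fit2, hi, lo, grad)
  expect_equal(m2$auc, 1)
  expect_equal(m2$max_kappa, 1)
})

test_that("threshold selection averages the chosen kappa-argmax statistics", {
  mk <- function(id, t) structure(list(auc = 0.7, cor = 0.3, max_kappa = 0.5,
                                       kappa_argmax_threshold = t,
                                       maxsss_value = 1.5, replicate_id = id),
                                  class = "EvalMetrics")
  metrics <- list(mk(1L, 0.786), mk(2L, 0.692), mk(3L, 0.544),
                  mk(4L, 0.139), mk(5L, 0.751))
  expect_equal(select_threshold(metrics, c(1L, 2L, 5L))$t_psi, 0.743)
  expect_equal(select_threshold(metrics, 2L)$t_psi, 0.692)
  same <- list(mk(1L, 0.4), mk(2L, 0.4))
  expect_equal(select_threshold(same, 1:2)$t_psi, 0.4)
  expect_error(select_threshold(metrics, integer()), "empty")
})

test_that("rank_replicates orders by AUC then cor then maxSSS", {
  mk <- function(id, auc, cr, sss)
    structure(list(auc = auc, cor = cr, maxsss_value = sss,
                   max_kappa = 0, kappa_argmax_threshold = 0,
                   replicate_id = id), class = "EvalMetrics")
  m <- list(mk(1L, 0.77, 0.37, 1.5), mk(2L, 0.73, 0.35, 1.4),
            mk(3L, 0.73, 0.33, 1.2), mk(4L, 0.66, 0.21, 1.1),
            mk(5L, 0.73, 0.35, 1.5))
  expect_equal(rank_replicates(m), c(1L, 5L, 2L, 3L, 4L))
})

test_that("predict_psi_surface matches the in-likelihood psi exactly", {
  land <- tiny_landscape(seed = 24)
  mask <- delineate_study_area(land$layers, target_cell = land$coarse_cell)
  stack <- tiny_stack(land, mask)
  pres <- simulate_presences(land, 50L, seed = 9, mask = mask)
  fit <- fit_maxlike(pres, stack, c("TREE", "AI"))

  surf <- predict_psi_surface(fit, stack)
  d <- keyhabitat:::maxlike_design(pres, stack, c("TREE", "AI"))
  psi_lik <- stats::plogis(drop(d$X %*% fit$beta))
  sel <- as.vector(mask$values == 1)
  expect_equal(as.vector(surf$values)[sel], psi_lik, tolerance = 1e-10)

  # beta = 0 gives a uniform 0.5 surface
  fit0 <- fit; fit0$beta[] <- 0
  expect_true(all(predict_psi_surface(fit0, stack)$values == 0.5))

  # monotone in a positive-slope covariate
  fitp <- fit; fitp$beta[] <- c(0, 1, 0)
  s1 <- predict_psi_surface(fitp, stack)$values
  bumped <- stack
  bumped$layers$TREE$values <- bumped$layers$TREE$values + 1
  s2 <- predict_psi_surface(fitp, bumped)$values
  expect_true(all(s2 >= s1))

  expect_error(predict_psi_surface(fit, covariate_stack(stack$layers["TREE"])),
               "missing covariate")
})
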