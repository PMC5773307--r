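# Independent brute-force oracles used to freeze expected values.
# These stay deliberately naive (plain loops, stats::var) so they share no
# code path with the implementations they check.

# Exhaustive threshold search for Cohen's kappa and sens+spec over a dense
# threshold grid (every predicted value and midpoint, plus the extremes).
oracle_threshold_search <- function(p, y) {
  u <- sort(unique(p))
  grid <- sort(unique(c(u, u[-length(u)] + diff(u) / 2, min(u) - 1, max(u) + 1)))
  best_kappa <- -Inf; best_kappa_t <- NA
  best_sss <- -Inf; best_sss_t <- NA
  for (t in grid) {
    pred <- as.integer(p >= t)
    tp <- sum(pred == 1 & y == 1); fp <- sum(pred == 1 & y == 0)
    fn <- sum(pred == 0 & y == 1); tn <- sum(pred == 0 & y == 0)
    n <- tp + fp + fn + tn
    po <- (tp + tn) / n
    pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
    kap <- if (pe == 1) 0 else (po - pe) / (1 - pe)
    sss <- tp / (tp + fn) + tn / (tn + fp)
    if (kap > best_kappa) { best_kappa <- kap; best_kappa_t <- t }
    if (sss > best_sss) { best_sss <- sss; best_sss_t <- t }
  }
  list(max_kappa = best_kappa, kappa_t = best_kappa_t,
       max_sss = best_sss, sss_t = best_sss_t)
}

# Rank-based AUC by direct pair counting.
oracle_auc <- function(p1, p0) {
  tot <- 0
  for (a in p1) for (b in p0)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(p1) * length(p0))
}

# Brute-force single change-point scan: Gaussian mean+variance likelihood
# ratio computed from scratch at every admissible tau.
oracle_changepoint <- function(x, min_seg = 4L) {
  n <- length(x)
  ll <- function(seg) {
    v <- max(mean((seg - mean(seg))^2), 1e-12)
    -length(seg) / 2 * (log(2 * pi * v) + 1)
  }
  ll0 <- ll(x)
  taus <- seq(min_seg, n - min_seg)
  stat <- vapply(taus, function(tau)
    2 * (ll(x[1:tau]) + ll(x[(tau + 1):n]) - ll0), 0)
  list(tau = taus[which.max(stat)], stat = max(stat))
}

# Small landscape for fast tests.
tiny_landscape <- function(seed = 42L, shape = c(30L, 30L), refine = 2L) {
  generate_landscape(seed = seed, coarse_shape = shape, refine_factor = refine)
}

# Unmasked standardized stack on the coarse grid of a landscape.
tiny_stack <- function(land, mask = NULL) {
  transform_and_standardize(land$layers[c("TREE", "AI")], character(), mask)
}

# Synthetic phenologies with class-dependent mean level; `sep` controls
# how far apart the class means sit relative to the noise.
make_phenologies <- function(n_per_class = 50, sep = 0.15, noise = 0.02,
                             seed = 41) {
  withr::with_seed(seed, {
    lab <- rep(c("poor", "acceptable", "good", "excellent"),
               each = n_per_class)
    base <- 0.2 + sep * (match(lab, c("poor", "acceptable", "good",
                                      "excellent")) - 1)
    season <- sin(2 * pi * (0:22) / 23)
    x <- t(vapply(seq_along(lab), function(i)
      base[i] + 0.05 * season + rnorm(23, 0, noise), numeric(23)))
    list(x = x, labels = factor(lab, levels = c("poor", "acceptable", "good",
                                                "excellent"), ordered = TRUE))
  })
}
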