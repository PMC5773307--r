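#' @importFrom stats dnorm median optim rbinom rnorm runif sd setNames
#'   quantile cor hclust cutree as.dist chisq.test
NULL

SUITABILITY_LEVELS <- c("poor", "acceptable", "good", "excellent")
QA_LEVELS <- c("high", "median", "poor")

# Evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's stream afterwards.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Separable Gaussian-kernel smoothing of a matrix; sigma in cell units.
# Kernel is truncated at 3*sigma and renormalized; edges use renormalized
# partial kernels (no wrap-around).
gaussian_smooth <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  half <- max(1L, ceiling(3 * sigma))
  k <- dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  smooth_1d <- function(m) {
    n <- nrow(m)
    padded <- rbind(matrix(0, half, ncol(m)), m, matrix(0, half, ncol(m)))
    wts <- rbind(matrix(0, half, 1), matrix(1, n, 1), matrix(0, half, 1))
    out <- matrix(0, n, ncol(m)); norm <- matrix(0, n, 1)
    for (d in seq_along(k)) {
      idx <- seq_len(n) + (d - 1L)
      out <- out + k[d] * padded[idx, , drop = FALSE]
      norm <- norm + k[d] * wts[idx, , drop = FALSE]
    }
    out / as.vector(norm)
  }
  t(smooth_1d(t(smooth_1d(mat))))
}

rescale_to <- function(mat, range, skew = 1) {
  rng <- range(mat)
  if (diff(rng) == 0) return(matrix(mean(range), nrow(mat), ncol(mat)))
  u <- (mat - rng[1]) / diff(rng)
  range[1] + u^skew * diff(range)
}

#' Default layer specifications for the synthetic landscape
#'
#' Each spec gives the layer's value `range`, its `smoothness` (Gaussian
#' kernel sigma in fine-grid cells; larger = stronger spatial
#' autocorrelation), and optionally a `parent` layer plus correlation
#' weight `cor` so climate-style layers share spatial structure with
#' elevation. Ranges follow typical northern-Venezuela magnitudes:
#' elevation 0--4382 m, tree cover 0--84 %, aridity index 1847--26349.
#' The `skew` exponent (> 1 = right-skewed) reflects that elevation,
#' aridity and dry-season precipitation fields concentrate mass at low
#' values — which both makes the default suitability bands cover a
#' realistic share of the landscape and motivates the square-root
#' transform downstream.
#'
#' @return named list of layer specs.
#' @export
default_layer_specs <- function() {
  list(
    ELEV  = list(range = c(0, 4382),     smoothness = 8, skew = 2.5),
    TREE  = list(range = c(0, 84),       smoothness = 5),
    AI    = list(range = c(1847, 26349), smoothness = 8, skew = 2.5),
    BIO02 = list(range = c(5, 16),       smoothness = 8, parent = "ELEV", cor = 0.7),
    BIO03 = list(range = c(60, 95),      smoothness = 8, parent = "ELEV", cor = 0.6),
    BIO07 = list(range = c(8, 25),       smoothness = 8, parent = "BIO02", cor = 0.8),
    BIO10 = list(range = c(10, 29),      smoothness = 8, parent = "ELEV", cor = -0.8),
    BIO17 = list(range = c(0, 300),      smoothness = 6, parent = "AI", cor = 0.7, skew = 2),
    BIO19 = list(range = c(0, 400),      smoothness = 6, parent = "AI", cor = 0.6, skew = 2)
  )
}

#' Generate a synthetic two-resolution landscape
#'
#' Builds spatially autocorrelated covariate fields (Gaussian-smoothed
#' white noise, rescaled into each layer's range) on a fine grid, and
#' derives the coarse grid by nearest-neighbour aggregation so the two
#' resolutions are mutually consistent. The landscape carries the true
#' coefficient vector of the occurrence-generating model
#' `psi = logistic(b0 + b' x)` over standardized coarse-grid covariates,
#' so parameter recovery is checkable downstream.
#'
#' @param seed integer; the generator is a pure function of it.
#' @param coarse_shape c(nrow, ncol) of the coarse (1 km analog) grid.
#' @param refine_factor fine cells per coarse cell edge (>= 2; 4 gives the
#'   250 m analog).
#' @param layer_specs per-layer spec list, see [default_layer_specs()];
#'   must include ELEV, TREE and AI.
#' @param coarse_cell coarse cell edge, meters.
#' @param truth_beta named numeric: intercept plus one slope per truth
#'   covariate (on the standardized scale).
#' @return object of class `Landscape`: `layers` (coarse), `fine_layers`,
#'   `truth_beta`, `truth_covariates`, `seed`.
#' @export
generate_landscape <- function(seed = 1L,
                               coarse_shape = c(50L, 50L),
                               refine_factor = 4L,
                               layer_specs = default_layer_specs(),
                               coarse_cell = 1000,
                               truth_beta = c(intercept = -1, TREE = 1.2, AI = 0.8)) {
  stopifnot(refine_factor >= 2L, length(coarse_shape) == 2L)
  needed <- c("ELEV", "TREE", "AI")
  if (!all(needed %in% names(layer_specs)))
    stop("layer_specs must include ELEV, TREE and AI", call. = FALSE)
  for (nm in names(layer_specs)) {
    sp <- layer_specs[[nm]]
    if (!all(c("range", "smoothness") %in% names(sp)))
      stop("bad spec for layer ", nm, ": need range and smoothness", call. = FALSE)
    if (!is.null(sp$parent) && !sp$parent %in% names(layer_specs))
      stop("unknown parent layer in spec for ", nm, call. = FALSE)
  }
  fine_cell <- coarse_cell / refine_factor
  nr <- coarse_shape[1] * refine_factor
  nc <- coarse_shape[2] * refine_factor
  fields <- list()
  with_seed(seed, {
    for (nm in names(layer_specs)) {
      sp <- layer_specs[[nm]]
      f <- gaussian_smooth(matrix(rnorm(nr * nc), nr, nc), sp$smoothness)
      f <- (f - mean(f)) / sd(f)
      if (!is.null(sp$parent)) {
        p <- fields[[sp$parent]]
        p <- (p - mean(p)) / sd(p)
        f <- sp$cor * p + sqrt(1 - sp$cor^2) * f
      }
      fields[[nm]] <- f
    }
  })
  fine_layers <- lapply(names(layer_specs), function(nm)
    grid_layer(rescale_to(fields[[nm]], layer_specs[[nm]]$range,
                          layer_specs[[nm]]$skew %||% 1), fine_cell))
  names(fine_layers) <- names(layer_specs)
  layers <- lapply(fine_layers, resample_nearest, target_cell = coarse_cell)
  truth_cov <- setdiff(names(truth_beta), "intercept")
  if (!all(truth_cov %in% names(layers)))
    stop("truth_beta names must match layers", call. = FALSE)
  structure(list(layers = layers, fine_layers = fine_layers,
                 truth_beta = truth_beta, truth_covariates = truth_cov,
                 coarse_cell = coarse_cell, fine_cell = fine_cell,
                 seed = seed),
            class = "Landscape")
}

#' @export
print.Landscape <- function(x, ...) {
  cat(sprintf("<Landscape: %s; coarse %dx%d @ %gm, fine @ %gm, seed %d>\n",
              paste(names(x$layers), collapse = ", "),
              nrow(x$layers[[1]]$values), ncol(x$layers[[1]]$values),
              x$coarse_cell, x$fine_cell, x$seed))
  invisible(x)
}

# True occurrence probability on every coarse cell (vector, column-major).
# When a study-area mask is given, covariates are standardized over mask
# cells (matching the fitted model's standardization) and psi is 0 outside.
true_psi <- function(landscape, mask = NULL) {
  sel <- if (is.null(mask)) rep(TRUE, length(landscape$layers[[1]]$values))
         else as.vector(mask$values == 1)
  b <- landscape$truth_beta
  eta <- rep(b[["intercept"]], length(sel))
  for (nm in landscape$truth_covariates) {
    v <- as.vector(landscape$layers[[nm]]$values)
    eta <- eta + b[[nm]] * (v - mean(v[sel])) / sd(v[sel])
  }
  psi <- stats::plogis(eta)
  psi[!sel] <- 0
  psi
}

#' Simulate presence-only records
#'
#' Draws `n` coarse-grid cells with probability proportional to the true
#' occurrence surface `psi` (sampling without replacement by default, one
#' record per cell, matching the likelihood's one-record-per-cell use) and
#' places each record at the cell center.
#'
#' @param landscape a `Landscape`.
#' @param n number of presence records.
#' @param seed integer.
#' @param replace sample cells with replacement.
#' @param mask optional study-area `BinaryMask`; records are then drawn
#'   from mask cells only (the survey analog: all compiled records lie in
#'   the study area) and the truth model is standardized over mask cells.
#' @param years range from which record years are drawn uniformly.
#' @return a `PresenceSet`: data.frame (id, x, y, year, cell) with the
#'   source landscape's grid geometry in attributes.
#' @export
simulate_presences <- function(landscape, n, seed = 1L, replace = FALSE,
                               mask = NULL, years = c(1960, 2013)) {
  psi <- true_psi(landscape, mask)
  pos <- which(psi > 0)
  if (!replace && n > length(pos))
    stop("n exceeds the number of cells with positive occurrence probability",
         call. = FALSE)
  ref <- landscape$layers[[1L]]
  ctr <- cell_centers(ref)
  nrw <- nrow(ref$values)
  with_seed(seed, {
    cells <- sample(pos, n, replace = replace, prob = psi[pos])
    yr <- sample(seq(years[1], years[2]), n, replace = TRUE)
  })
  i <- (cells - 1L) %% nrw + 1L   # row (y)
  j <- (cells - 1L) %/% nrw + 1L  # col (x)
  out <- data.frame(id = seq_len(n), x = ctr$x[j], y = ctr$y[i],
                    year = yr, cell = cells)
  class(out) <- c("PresenceSet", "data.frame")
  attr(out, "cell_size") <- ref$cell_size
  attr(out, "origin") <- ref$origin
  out
}

# Crisp ordinal suitability from local elevation and tree cover, following
# field descriptions: excellent = mid elevation, well-forested mosaic;
# poor = low/transformed or extreme sites.
label_from_covariates <- function(elev, tree) {
  lab <- rep("acceptable", length(elev))
  lab[elev < 250 | elev > 1200 | tree < 15] <- "poor"
  good <- elev >= 400 & elev <= 1000 & tree >= 25
  lab[good] <- "good"
  exc <- elev >= 500 & elev <= 800 & tree >= 40
  lab[exc] <- "excellent"
  factor(lab, levels = SUITABILITY_LEVELS, ordered = TRUE)
}

#' Simulate a ground-truth evaluation design
#'
#' Draws `n_points` anchor points uniformly inside the study-area mask,
#' expands each into `stops` collinear evaluation locations `spacing`
#' meters apart along a random bearing, discards `n_discard` locations
#' uniformly at random (a stand-in for inaccessible/insecure sites), and
#' assigns each survivor an ordinal suitability label by thresholding the
#' local fine-grid elevation and tree cover, plus `label_noise` one-step
#' label noise.
#'
#' @param landscape a `Landscape`.
#' @param n_points anchors (default 90).
#' @param stops locations per anchor (default 3).
#' @param spacing distance between stops, meters (default 500).
#' @param n_discard locations removed (default 79; must be < n_points*stops).
#' @param mask study-area `BinaryMask` on the coarse grid; default derives
#'   it from the landscape with [delineate_study_area()] defaults.
#' @param label_noise probability a label moves one ordinal step.
#' @param seed integer.
#' @return a `GroundTruthDesign`: `locations` data.frame (location_id, x, y,
#'   anchor, label) plus the design parameters.
#' @export
simulate_ground_truth <- function(landscape, n_points = 90L, stops = 3L,
                                  spacing = 500, n_discard = 79L,
                                  mask = NULL, label_noise = 0.1, seed = 1L) {
  if (n_discard >= n_points * stops)
    stop("n_discard must be smaller than n_points * stops", call. = FALSE)
  if (is.null(mask)) mask <- delineate_study_area(landscape$layers,
                                                  target_cell = landscape$coarse_cell)
  cells <- which(mask$values == 1)
  if (!length(cells)) stop("study-area mask is empty", call. = FALSE)
  nrw <- nrow(mask$values); cs <- mask$cell_size
  elev_f <- landscape$fine_layers$ELEV
  tree_f <- landscape$fine_layers$TREE
  fcs <- elev_f$cell_size
  fnr <- nrow(elev_f$values); fnc <- ncol(elev_f$values)
  with_seed(seed, {
    anchor_cells <- sample(cells, n_points, replace = TRUE)
    i <- (anchor_cells - 1L) %% nrw + 1L
    j <- (anchor_cells - 1L) %/% nrw + 1L
    ax <- mask$origin[1] + (j - 1L + runif(n_points)) * cs
    ay <- mask$origin[2] + (i - 1L + runif(n_points)) * cs
    bearing <- runif(n_points, 0, 2 * pi)
    step <- rep(seq_len(stops) - 1L, times = n_points)
    px <- rep(ax, each = stops) + step * spacing * cos(rep(bearing, each = stops))
    py <- rep(ay, each = stops) + step * spacing * sin(rep(bearing, each = stops))
    # clamp inside the fine grid extent
    px <- pmin(pmax(px, elev_f$origin[1]), elev_f$origin[1] + fnc * fcs - fcs / 2)
    py <- pmin(pmax(py, elev_f$origin[2]), elev_f$origin[2] + fnr * fcs - fcs / 2)
    keep <- sort(sample(seq_along(px), length(px) - n_discard))
    fj <- pmin(floor((px - elev_f$origin[1]) / fcs) + 1L, fnc)
    fi <- pmin(floor((py - elev_f$origin[2]) / fcs) + 1L, fnr)
    lab <- label_from_covariates(elev_f$values[cbind(fi, fj)],
                                 tree_f$values[cbind(fi, fj)])
    flip <- runif(length(lab)) < label_noise
    dir <- sample(c(-1L, 1L), length(lab), replace = TRUE)
    ilab <- as.integer(lab)
    ilab[flip] <- pmin(pmax(ilab[flip] + dir[flip], 1L), 4L)
    lab <- factor(SUITABILITY_LEVELS[ilab], levels = SUITABILITY_LEVELS,
                  ordered = TRUE)
  })
  loc <- data.frame(location_id = seq_along(keep), x = px[keep], y = py[keep],
                    anchor = rep(seq_len(n_points), each = stops)[keep],
                    label = lab[keep])
  structure(list(points = cbind(x = ax, y = ay), stops_per_point = stops,
                 stop_spacing = spacing, discarded = n_discard,
                 locations = loc, seed = seed),
            class = "GroundTruthDesign")
}

#' @export
print.GroundTruthDesign <- function(x, ...) {
  cat(sprintf("<GroundTruthDesign: %d anchors x %d stops - %d discarded = %d locations>\n",
              nrow(x$points), x$stops_per_point, x$discarded, nrow(x$locations)))
  print(table(x$locations$label))
  invisible(x)
}

#' 16-day composite date lattice
#'
#' Dates with day-of-year in 1, 17, 33, ... (23 composites per year),
#' restricted to `[start, end]`.
#'
#' @param start,end `Date` or parseable strings.
#' @return vector of `Date`s.
#' @export
composite_dates <- function(start = "2000-02-18", end = "2015-06-30") {
  start <- as.Date(start); end <- as.Date(end)
  years <- seq(as.integer(format(start, "%Y")), as.integer(format(end, "%Y")))
  d <- as.Date(unlist(lapply(years, function(y)
    as.Date(sprintf("%d-01-01", y)) + 16L * (0:22))), origin = "1970-01-01")
  d[d >= start & d <= end]
}

#' One location's EVI series
#' @param dates `Date` vector on the 16-day lattice, strictly increasing.
#' @param values EVI in [0, 1].
#' @param qa quality ranks, in `c("high", "median", "poor")`.
#' @param location_id scalar id.
#' @return object of class `EviSeries`.
#' @export
evi_series <- function(dates, values, qa, location_id = NA) {
  stopifnot(length(dates) == length(values), length(values) == length(qa),
            all(qa %in% QA_LEVELS))
  if (is.unsorted(as.numeric(dates))) {
    o <- order(dates); dates <- dates[o]; values <- values[o]; qa <- qa[o]
  }
  if (any(values < 0 | values > 1, na.rm = TRUE))
    stop("EVI values must lie in [0, 1]", call. = FALSE)
  structure(list(dates = as.Date(dates, origin = "1970-01-01"),
                 values = as.numeric(values),
                 qa = as.character(qa), location_id = location_id),
            class = "EviSeries")
}

#' @export
print.EviSeries <- function(x, ...) {
  cat(sprintf("<EviSeries %s: %d obs, %s .. %s, mean %.3f>\n",
              as.character(x$location_id), length(x$values),
              format(min(x$dates)), format(max(x$dates)), mean(x$values)))
  invisible(x)
}

#' Simulate EVI time series for a ground-truth design
#'
#' Each location's series is a category-dependent baseline plus an annual
#' sinusoid, a step drop in mean (and an inflation of the noise variance)
#' after its change date, and Gaussian noise, clipped to [0, 1]. QA ranks
#' are i.i.d. multinomial with the stated high/median/poor proportions. A
#' fraction `prop_changed` of locations receives a change point at all;
#' change dates are uniform over `change_years`.
#'
#' @param design a `GroundTruthDesign`.
#' @param start,end series date range (16-day lattice).
#' @param baselines named mean EVI per category; defaults keep optimal
#'   categories above 0.4 even after the default drop.
#' @param degradation named mean drop per category after the change point.
#' @param prop_changed fraction of locations with a change point.
#' @param change_years calendar-year window for change dates.
#' @param amplitude seasonal sinusoid amplitude.
#' @param noise_sd pre-change Gaussian noise sd; post-change sd is
#'   `noise_sd * var_inflation`.
#' @param var_inflation post-change sd multiplier (variance shift).
#' @param qa_probs multinomial probabilities for high/median/poor QA.
#' @param seed integer.
#' @return list of `EviSeries`, one per location, with the true change
#'   date (or `NA`) in attribute `"change_dates"`.
#' @export
simulate_evi <- function(design,
                         start = "2000-02-18", end = "2015-06-30",
                         baselines = c(poor = 0.35, acceptable = 0.45,
                                       good = 0.55, excellent = 0.62),
                         degradation = c(poor = 0.10, acceptable = 0.10,
                                         good = 0.10, excellent = 0.10),
                         prop_changed = 0.85,
                         change_years = c(2004, 2012),
                         amplitude = 0.05, noise_sd = 0.02,
                         var_inflation = 1.5,
                         qa_probs = c(0.37, 0.47, 0.16),
                         seed = 1L) {
  if (abs(sum(qa_probs) - 1) > 1e-8)
    stop("qa_probs must sum to 1", call. = FALSE)
  if (any(baselines[names(degradation)] - degradation < 0))
    warning("baseline minus drop below 0; values will clip at 0")
  dates <- composite_dates(start, end)
  doy <- as.integer(format(dates, "%j"))
  season <- sin(2 * pi * (doy - 49) / 365)
  loc <- design$locations
  n <- nrow(loc)
  with_seed(seed, {
    changed <- runif(n) < prop_changed
    cp_date <- as.Date(sprintf("%d-01-01", change_years[1])) +
      round(runif(n) * as.numeric(as.Date(sprintf("%d-12-31", change_years[2])) -
                                  as.Date(sprintf("%d-01-01", change_years[1]))))
    cp_date[!changed] <- NA
    out <- vector("list", n)
    for (k in seq_len(n)) {
      cat_k <- as.character(loc$label[k])
      base <- baselines[[cat_k]]
      drop <- if (changed[k]) degradation[[cat_k]] else 0
      post <- !is.na(cp_date[k]) & dates > cp_date[k]
      sdv <- ifelse(post, noise_sd * var_inflation, noise_sd)
      v <- base - drop * post + amplitude * season + rnorm(length(dates), 0, sdv)
      v <- pmin(pmax(v, 0), 1)
      qa <- sample(QA_LEVELS, length(dates), replace = TRUE, prob = qa_probs)
      out[[k]] <- evi_series(dates, v, qa, loc$location_id[k])
    }
  })
  attr(out, "change_dates") <- cp_date
  attr(out, "changed") <- changed
  out
}
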