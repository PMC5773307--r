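# Bagged CART ensemble for the ordinal suitability classifier.
#
# No tree package is assumed: trees are grown in-package (Gini impurity,
# per-split random feature subset, grown to purity). Trees are stored as
# flat node tables so raster-scale prediction stays vectorized.

# Best Gini split of one feature; returns c(score, threshold) or NULL.
best_split_feature <- function(xf, y, K) {
  ord <- order(xf)
  xs <- xf[ord]; ys <- y[ord]
  n <- length(ys)
  cuts <- which(xs[-n] < xs[-1L])
  if (!length(cuts)) return(NULL)
  C <- vapply(seq_len(K), function(k) cumsum(ys == k), numeric(n))
  nl <- cuts
  CL <- C[cuts, , drop = FALSE]
  CR <- matrix(C[n, ], length(cuts), K, byrow = TRUE) - CL
  gl <- 1 - rowSums((CL / nl)^2)
  gr <- 1 - rowSums((CR / (n - nl))^2)
  score <- (nl * gl + (n - nl) * gr) / n
  b <- which.min(score)
  c(score = score[b], threshold = (xs[cuts[b]] + xs[cuts[b] + 1L]) / 2)
}

# Grow one classification tree; returns a matrix with one row per node:
# feature (0 = leaf), threshold, left, right, class.
grow_tree <- function(x, y, K, mtry, min_node = 1L) {
  p <- ncol(x)
  nodes <- matrix(0, 0L, 5L,
                  dimnames = list(NULL, c("feature", "threshold", "left",
                                          "right", "class")))
  new_node <- function() {
    nodes <<- rbind(nodes, c(0, 0, 0, 0, 0))
    nrow(nodes)
  }
  build <- function(idx) {
    id <- new_node()
    ys <- y[idx]
    tab <- tabulate(ys, K)
    maj <- which.max(tab)
    pure <- tab[maj] == length(idx)
    if (pure || length(idx) <= min_node) {
      nodes[id, "class"] <<- maj
      return(id)
    }
    feats <- if (mtry >= p) seq_len(p) else sample.int(p, mtry)
    best <- NULL; best_f <- 0L
    for (f in feats) {
      sp <- best_split_feature(x[idx, f], ys, K)
      if (!is.null(sp) && (is.null(best) || sp["score"] < best["score"])) {
        best <- sp; best_f <- f
      }
    }
    if (is.null(best)) {
      nodes[id, "class"] <<- maj
      return(id)
    }
    go_left <- x[idx, best_f] <= best["threshold"]
    l <- build(idx[go_left])
    r <- build(idx[!go_left])
    nodes[id, ] <<- c(best_f, best["threshold"], l, r, 0)
    id
  }
  build(seq_len(nrow(x)))
  nodes
}

# Vectorized per-tree prediction: class index per row of newx.
predict_tree <- function(nodes, newx) {
  cur <- rep(1L, nrow(newx))
  repeat {
    feat <- nodes[cur, "feature"]
    live <- feat > 0
    if (!any(live)) break
    i <- which(live)
    f <- feat[i]
    goes_left <- newx[cbind(i, f)] <= nodes[cur[i], "threshold"]
    cur[i] <- ifelse(goes_left, nodes[cur[i], "left"], nodes[cur[i], "right"])
  }
  as.integer(nodes[cur, "class"])
}

#' Fit the ordinal suitability forest
#'
#' Bagged classification trees mapping the 23-value EVI phenology to the
#' four ordered suitability categories. Each tree is grown on a bootstrap
#' sample (n draws with replacement, so about 63.2% unique records in-bag
#' and 36.8% out-of-bag) with `mtry` randomly chosen predictors per split,
#' to purity. Out-of-bag votes are accumulated per training record and
#' summarized as an ordered confusion matrix. Ordinality enters through
#' [weighted_oob()] and [votes_to_index()], not the split criterion, as in
#' the original analysis. The field-scale default is 50,000 trees; demo
#' and test profiles use a few hundred.
#'
#' @param phenologies numeric matrix, rows = locations, 23 columns (rows
#'   with NA are dropped with a warning).
#' @param labels ordinal labels in `poor < acceptable < good < excellent`.
#' @param n_trees number of trees.
#' @param mtry predictors tried per split (default 5).
#' @param min_node minimum records per leaf.
#' @param seed integer; votes are deterministic given it.
#' @return an `OrdinalForestModel`: `trees`, `levels`, `oob_votes` (n x 4
#'   proportions), `oob_confusion` (4 x 4 counts, true x predicted),
#'   `params`.
#' @export
fit_forest <- function(phenologies, labels, n_trees = 500L, mtry = 5L,
                       min_node = 1L, seed = 1L) {
  x <- as.matrix(phenologies)
  labels <- factor(labels, levels = SUITABILITY_LEVELS, ordered = TRUE)
  ok <- stats::complete.cases(x) & !is.na(labels)
  if (!all(ok)) {
    warning(sum(!ok), " record(s) with missing values dropped")
    x <- x[ok, , drop = FALSE]; labels <- labels[ok]
  }
  n <- nrow(x)
  if (n < 20L) stop("need at least 20 complete records", call. = FALSE)
  if (length(unique(labels)) < 2L)
    stop("labels must cover at least two classes", call. = FALSE)
  if (all(apply(x, 2L, function(v) length(unique(v))) == 1L))
    stop("all predictors are constant", call. = FALSE)
  y <- as.integer(labels)
  K <- length(SUITABILITY_LEVELS)
  trees <- vector("list", n_trees)
  oob_counts <- matrix(0L, n, K)
  with_seed(seed, {
    for (t in seq_len(n_trees)) {
      bag <- sample.int(n, n, replace = TRUE)
      oob <- setdiff(seq_len(n), bag)
      trees[[t]] <- grow_tree(x[bag, , drop = FALSE], y[bag], K, mtry, min_node)
      if (length(oob)) {
        pr <- predict_tree(trees[[t]], x[oob, , drop = FALSE])
        oob_counts[cbind(oob, pr)] <- oob_counts[cbind(oob, pr)] + 1L
      }
    }
  })
  tot <- rowSums(oob_counts)
  votes <- oob_counts / pmax(tot, 1L)
  pred <- max.col(votes, ties.method = "first")
  seen <- tot > 0
  confusion <- table(factor(SUITABILITY_LEVELS[y[seen]], levels = SUITABILITY_LEVELS),
                     factor(SUITABILITY_LEVELS[pred[seen]], levels = SUITABILITY_LEVELS))
  structure(list(trees = trees, levels = SUITABILITY_LEVELS,
                 oob_votes = votes, oob_confusion = unclass(confusion),
                 params = list(n_trees = n_trees, mtry = mtry,
                               min_node = min_node, seed = seed, n = n)),
            class = "OrdinalForestModel")
}

#' @export
print.OrdinalForestModel <- function(x, ...) {
  w <- weighted_oob(x$oob_confusion)
  cat(sprintf("<OrdinalForest: %d trees, mtry %d, n %d; OOB error %.1f%% raw, %.1f%% weighted>\n",
              x$params$n_trees, x$params$mtry, x$params$n,
              100 * w$raw_error, 100 * w$weighted_error))
  invisible(x)
}

#' Ordered-weight correction of an OOB confusion matrix
#'
#' The raw OOB error treats a miss between contiguous ordinal categories
#' the same as a four-level miss. The weighted error down-weights near
#' misses with a symmetric penalty matrix (default linear, `|i-j| / 3`:
#' 0 on the diagonal, 1 at the extreme corners).
#'
#' @param counts 4x4 confusion counts (true x predicted, ordered).
#' @param penalty `"linear"` or a 4x4 penalty matrix (diagonal 0,
#'   symmetric, nondecreasing away from the diagonal).
#' @return a `WeightedConfusion`: `counts`, `weights`, `raw_error`,
#'   `weighted_error`.
#' @export
weighted_oob <- function(counts, penalty = "linear") {
  counts <- as.matrix(counts)
  K <- nrow(counts)
  stopifnot(ncol(counts) == K, all(counts >= 0))
  total <- sum(counts)
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  w <- if (is.matrix(penalty)) penalty else
    abs(outer(seq_len(K), seq_len(K), `-`)) / (K - 1)
  stopifnot(all(dim(w) == K), all(diag(w) == 0), isTRUE(all.equal(w, t(w))))
  structure(list(counts = counts, weights = w,
                 raw_error = sum(counts[row(counts) != col(counts)]) / total,
                 weighted_error = sum(w * counts) / total),
            class = "WeightedConfusion")
}

#' Collapse class votes into a continuous suitability index
#'
#' Weighted average of single-step category weights (0 for poor up to 3
#' for excellent) under the per-cell vote proportions; the index lives in
#' [0, 3].
#'
#' @param votes matrix (rows = cells) or vector of 4 nonnegative vote
#'   proportions summing to 1 (tolerance 1e-6).
#' @param weights category weights, default `c(0, 1, 2, 3)`.
#' @return numeric index per row.
#' @export
votes_to_index <- function(votes, weights = c(0, 1, 2, 3)) {
  v <- if (is.matrix(votes)) votes else matrix(votes, nrow = 1L)
  stopifnot(ncol(v) == length(weights))
  if (any(v < 0, na.rm = TRUE))
    stop("negative vote share", call. = FALSE)
  s <- rowSums(v)
  bad <- is.finite(s) & abs(s - 1) > 1e-6
  if (any(bad)) stop("vote vector(s) not summing to 1", call. = FALSE)
  drop(v %*% weights)
}

#' Predict class votes for new phenologies
#'
#' @param model an `OrdinalForestModel`.
#' @param newx matrix with 23 columns; NA rows give NA votes.
#' @return list: `votes` (n x 4 proportions), `class` (ordered factor,
#'   modal category, first level on ties), `index` (weighted vote index).
#' @export
predict_forest <- function(model, newx) {
  newx <- as.matrix(newx)
  K <- length(model$levels)
  ok <- stats::complete.cases(newx)
  counts <- matrix(0L, nrow(newx), K)
  if (any(ok)) {
    xo <- newx[ok, , drop = FALSE]
    io <- which(ok)
    for (tr in model$trees) {
      pr <- predict_tree(tr, xo)
      counts[cbind(io, pr)] <- counts[cbind(io, pr)] + 1L
    }
  }
  votes <- counts / length(model$trees)
  votes[!ok, ] <- NA
  cls <- rep(NA_integer_, nrow(newx))
  cls[ok] <- max.col(votes[ok, , drop = FALSE], ties.method = "first")
  list(votes = votes,
       class = factor(model$levels[cls], levels = model$levels, ordered = TRUE),
       index = votes_to_index(votes))
}

#' Predict the suitability category and index surfaces
#'
#' Runs the forest on a 23-layer EVI phenology stack (one layer per
#' 16-day period) and returns the modal-category surface and the
#' vote-weighted suitability index surface. Cells with any missing layer
#' value are nodata in both outputs.
#'
#' @param model an `OrdinalForestModel`.
#' @param evi_layers list of exactly 23 `GridLayer`s on one geometry.
#' @return list: `category` (`GridLayer` of 1..4), `index` (`GridLayer` in
#'   [0, 3]).
#' @export
predict_suitability <- function(model, evi_layers) {
  if (length(evi_layers) != 23L)
    stop("need exactly 23 EVI layers", call. = FALSE)
  ref <- stop_if_geometry_mismatch(evi_layers)
  newx <- vapply(evi_layers, function(l) as.vector(l$values),
                 numeric(length(ref$values)))
  pr <- predict_forest(model, newx)
  shape <- function(v) grid_layer(matrix(v, nrow(ref$values), ncol(ref$values)),
                                  ref$cell_size, ref$origin, ref$nodata)
  list(category = shape(as.integer(pr$class)), index = shape(pr$index))
}
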