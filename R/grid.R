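#' Single-band planar raster layer
#'
#' `grid_layer()` is the package's raster container: a numeric matrix plus a
#' planar grid geometry. Rows index the y axis (row 1 nearest the origin),
#' columns the x axis. Cells are half-open: cell (i, j) covers
#' `[origin + (j-1)*cell, origin + j*cell)` in x and likewise in y, so a
#' point on a shared edge belongs to the higher-index cell.
#'
#' @param values numeric matrix (nrow = y cells, ncol = x cells). `NA` is
#'   stored as the nodata sentinel on write; in memory nodata is `NA`.
#' @param cell_size cell edge length in ground units (meters).
#' @param origin numeric length-2, (x, y) of the grid's lower-left corner.
#' @param nodata sentinel used in on-disk representations.
#' @return object of class `GridLayer`.
#' @export
grid_layer <- function(values, cell_size, origin = c(0, 0), nodata = -9999) {
  values <- as.matrix(values)
  stopifnot(is.numeric(values), length(cell_size) == 1L, cell_size > 0,
            length(origin) == 2L)
  structure(list(values = values, cell_size = as.numeric(cell_size),
                 origin = as.numeric(origin), nodata = as.numeric(nodata)),
            class = "GridLayer")
}

#' @export
print.GridLayer <- function(x, ...) {
  cat(sprintf("<GridLayer %d x %d, cell %g m, origin (%g, %g), %d nodata>\n",
              nrow(x$values), ncol(x$values), x$cell_size,
              x$origin[1], x$origin[2], sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.GridLayer <- function(x) dim(x$values)

same_geometry <- function(a, b, tol = 1e-9) {
  identical(dim(a$values), dim(b$values)) &&
    abs(a$cell_size - b$cell_size) < tol &&
    all(abs(a$origin - b$origin) < tol)
}

stop_if_geometry_mismatch <- function(layers) {
  ref <- layers[[1L]]
  ok <- vapply(layers, same_geometry, logical(1L), b = ref)
  if (!all(ok)) stop("grid geometry mismatch between layers", call. = FALSE)
  invisible(ref)
}

#' Cell-center coordinates of a layer
#' @param layer a `GridLayer`.
#' @return list with numeric vectors `x` (length ncol) and `y` (length nrow).
#' @export
cell_centers <- function(layer) {
  list(x = layer$origin[1] + (seq_len(ncol(layer$values)) - 0.5) * layer$cell_size,
       y = layer$origin[2] + (seq_len(nrow(layer$values)) - 0.5) * layer$cell_size)
}

#' Nearest-neighbour resampling by cell centers
#'
#' Each output cell takes the value of the input cell that contains the
#' output cell's center, with half-open cell membership so a center on an
#' exact cell edge resolves to the higher row/column index. Works both as
#' aggregation (target a multiple of the input cell) and disaggregation
#' (target a divisor); nodata propagates.
#'
#' @param layer a `GridLayer`.
#' @param target_cell output cell size; must be an integer multiple or
#'   divisor of `layer$cell_size` (non-commensurate sizes error).
#' @return a `GridLayer` on the target resolution covering the same extent.
#' @export
resample_nearest <- function(layer, target_cell) {
  stopifnot(target_cell > 0)
  r <- target_cell / layer$cell_size
  agg <- r >= 1
  f <- if (agg) r else 1 / r
  if (abs(f - round(f)) > 1e-9)
    stop("target_cell must be an integer multiple or divisor of cell_size",
         call. = FALSE)
  ext_x <- ncol(layer$values) * layer$cell_size
  ext_y <- nrow(layer$values) * layer$cell_size
  n_out_x <- floor(ext_x / target_cell + 1e-9)
  n_out_y <- floor(ext_y / target_cell + 1e-9)
  cx <- layer$origin[1] + (seq_len(n_out_x) - 0.5) * target_cell
  cy <- layer$origin[2] + (seq_len(n_out_y) - 0.5) * target_cell
  # half-open [x, x+w): floor() sends an exact edge to the higher index
  jx <- pmin(floor((cx - layer$origin[1]) / layer$cell_size) + 1L, ncol(layer$values))
  iy <- pmin(floor((cy - layer$origin[2]) / layer$cell_size) + 1L, nrow(layer$values))
  grid_layer(layer$values[iy, jx, drop = FALSE], target_cell, layer$origin,
             layer$nodata)
}

#' Binary suitability mask
#'
#' @param values 0/1 matrix.
#' @param cell_size,origin grid geometry (see [grid_layer()]).
#' @return object of class `BinaryMask` (also a `GridLayer`); `area_km2(m)`
#'   gives count-of-ones times cell area.
#' @export
binary_mask <- function(values, cell_size, origin = c(0, 0)) {
  values <- as.matrix(values)
  if (!all(values %in% c(0, 1))) stop("mask values must be 0 or 1", call. = FALSE)
  g <- grid_layer(values, cell_size, origin)
  class(g) <- c("BinaryMask", class(g))
  g
}

#' Total area of the 1-cells of a mask, in square kilometers
#' @param mask a `BinaryMask`.
#' @export
area_km2 <- function(mask) {
  sum(mask$values == 1) * (mask$cell_size / 1000)^2
}

#' Binarize a layer by a closed value interval
#'
#' Cells with `lo <= value <= hi` become 1, everything else (including
#' nodata) becomes 0. Both bounds are inclusive; pass `-Inf`/`Inf` for
#' one-sided intervals.
#'
#' @param layer a `GridLayer`.
#' @param lo,hi interval bounds, `lo <= hi`.
#' @return a `BinaryMask` on the layer's geometry.
#' @export
binarize <- function(layer, lo, hi) {
  if (lo > hi) stop("lo must not exceed hi", call. = FALSE)
  v <- layer$values
  m <- ifelse(!is.na(v) & v >= lo & v <= hi, 1, 0)
  binary_mask(m, layer$cell_size, layer$origin)
}

#' Intersect binary masks cellwise
#'
#' @param masks list of `BinaryMask` objects on one grid geometry.
#' @return the cellwise product as a `BinaryMask`.
#' @export
intersect_masks <- function(masks) {
  if (inherits(masks, "BinaryMask")) masks <- list(masks)
  stopifnot(length(masks) >= 1L)
  stop_if_geometry_mismatch(masks)
  v <- Reduce(`*`, lapply(masks, `[[`, "values"))
  binary_mask(v, masks[[1L]]$cell_size, masks[[1L]]$origin)
}

#' Delineate a study area from environmental layers
#'
#' Resamples each named layer to `target_cell` by nearest neighbour,
#' binarizes it by its closed suitability interval, and intersects the
#' masks. The default bounds are elevation 200--1500 m, tree cover
#' 10--100 %, and aridity index 2000--6500.
#'
#' @param layers named list of `GridLayer`s; must contain every name in
#'   `bounds`.
#' @param bounds named list of length-2 numeric intervals.
#' @param target_cell common resolution for the overlay (default 1000 m).
#' @return a `BinaryMask` of the study area.
#' @export
delineate_study_area <- function(layers,
                                 bounds = list(ELEV = c(200, 1500),
                                               TREE = c(10, 100),
                                               AI = c(2000, 6500)),
                                 target_cell = 1000) {
  missing_nm <- setdiff(names(bounds), names(layers))
  if (length(missing_nm))
    stop("missing layer(s): ", paste(missing_nm, collapse = ", "), call. = FALSE)
  masks <- lapply(names(bounds), function(nm) {
    lyr <- resample_nearest(layers[[nm]], target_cell)
    binarize(lyr, bounds[[nm]][1], bounds[[nm]][2])
  })
  intersect_masks(masks)
}

#' Read / write ESRI ASCII grids
#'
#' Plain-text single-band raster exchange format (`ncols/nrows/xllcorner/
#' yllcorner/cellsize/NODATA_value` header then rows top-to-bottom).
#'
#' @param layer a `GridLayer`.
#' @param path file path.
#' @return `read_ascii_grid` returns a `GridLayer`; `write_ascii_grid`
#'   returns `path` invisibly.
#' @export
write_ascii_grid <- function(layer, path) {
  v <- layer$values
  v[is.na(v)] <- layer$nodata
  hdr <- sprintf(paste0("ncols %d\nnrows %d\nxllcorner %.10g\nyllcorner %.10g\n",
                        "cellsize %.10g\nNODATA_value %.10g"),
                 ncol(v), nrow(v), layer$origin[1], layer$origin[2],
                 layer$cell_size, layer$nodata)
  # ASCII grid rows run top to bottom; internal row 1 is the bottom row
  body <- apply(v[rev(seq_len(nrow(v))), , drop = FALSE], 1L,
                paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(tolower(lines[1:6]), "\\s+")
  kv <- stats::setNames(vapply(hdr, function(h) as.numeric(h[2]), 0),
                        vapply(hdr, `[[`, "", 1L))
  vals <- do.call(rbind, lapply(lines[-(1:6)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1L]])))
  vals <- vals[rev(seq_len(nrow(vals))), , drop = FALSE]
  vals[vals == kv[["nodata_value"]]] <- NA
  grid_layer(vals, kv[["cellsize"]], c(kv[["xllcorner"]], kv[["yllcorner"]]),
             kv[["nodata_value"]])
}
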