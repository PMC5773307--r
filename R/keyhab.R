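#' Overlap index of historic occurrence and current suitability
#'
#' Cellwise product of the occurrence probability surface (in [0, 1]) and
#' the suitability index surface (in [0, 3]); nodata in either input
#' propagates.
#'
#' @param psi `GridLayer` of occurrence probabilities.
#' @param index `GridLayer` suitability index.
#' @return a `GridLayer` in [0, 3].
#' @export
overlap_index <- function(psi, index) {
  if (!same_geometry(psi, index))
    stop("grid geometry mismatch", call. = FALSE)
  grid_layer(psi$values * index$values, psi$cell_size, psi$origin, psi$nodata)
}

#' Delineate key habitats
#'
#' A cell is key habitat when its historic occurrence probability exceeds
#' the selected threshold and its current suitability category is in the
#' included set (`"excellent"` for the strict definition, `c("good",
#' "excellent")` for the expanded one).
#'
#' @param psi `GridLayer` of occurrence probabilities.
#' @param categories `GridLayer` of category codes 1..4 (poor..excellent).
#' @param t_psi occurrence threshold (strict inequality, psi > t_psi).
#' @param included category names to accept.
#' @return a `BinaryMask`.
#' @export
delineate_key <- function(psi, categories, t_psi,
                          included = "excellent") {
  if (!length(included)) stop("empty included set", call. = FALSE)
  if (!all(included %in% SUITABILITY_LEVELS))
    stop("unknown category name", call. = FALSE)
  if (!same_geometry(psi, categories))
    stop("grid geometry mismatch", call. = FALSE)
  codes <- match(included, SUITABILITY_LEVELS)
  v <- ifelse(!is.na(psi$values) & psi$values > t_psi &
                !is.na(categories$values) & categories$values %in% codes, 1, 0)
  binary_mask(v, psi$cell_size, psi$origin)
}

# Round half away from zero (the convention the reported integers use;
# base round() is banker's).
round_half_up <- function(x, digits = 0) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

#' AOO decline and IUCN A2 category
#'
#' Decline is `(1 - aoo_now / aoo_hist) * 100` (floored at 0 when the
#' current area exceeds the historic one). Threat category follows the A2
#' thresholds, closed at the lower bound: >= 80% Critically Endangered,
#' >= 50% Endangered, >= 30% Vulnerable, else below-threshold.
#'
#' @param aoo_now current Area of Occupancy, km^2.
#' @param aoo_hist historic area, km^2 (> 0).
#' @return list: `decline_pct` (raw), `decline_pct_rounded` (half-up
#'   integer), `iucn_category`.
#' @export
decline_and_category <- function(aoo_now, aoo_hist) {
  if (aoo_hist <= 0) stop("historic area must be positive", call. = FALSE)
  decline <- max(0, (1 - aoo_now / aoo_hist) * 100)
  category <- if (decline >= 80) "Critically Endangered"
              else if (decline >= 50) "Endangered"
              else if (decline >= 30) "Vulnerable"
              else "Below-threshold"
  list(decline_pct = decline,
       decline_pct_rounded = round_half_up(decline),
       iucn_category = category)
}

#' Protected share of a habitat mask
#'
#' @param mask habitat `BinaryMask` (nonzero area).
#' @param protected protected-area `BinaryMask`, same geometry.
#' @return list: `km2` of the intersection, `pct` of the mask area
#'   (raw), `pct_rounded` (half-up integer).
#' @export
protected_overlap <- function(mask, protected) {
  if (!same_geometry(mask, protected))
    stop("grid geometry mismatch", call. = FALSE)
  denom <- area_km2(mask)
  if (denom == 0) stop("mask has zero area", call. = FALSE)
  inter <- area_km2(intersect_masks(list(mask, protected)))
  list(km2 = inter, pct = 100 * inter / denom,
       pct_rounded = round_half_up(100 * inter / denom))
}

#' Assemble the key-habitat report
#'
#' Delineates the strict (excellent-only) and expanded (good + excellent)
#' key-habitat masks, the historic mask (psi > t_psi), the overlap-index
#' surface, the AOO declines with their IUCN A2 categories, and the
#' protected share of the historic area when a protected mask is given.
#'
#' @param psi fine-grid `GridLayer` of historic occurrence probability.
#' @param categories fine-grid `GridLayer` of category codes 1..4.
#' @param index fine-grid `GridLayer` suitability index.
#' @param t_psi occurrence threshold.
#' @param protected optional protected-area `BinaryMask`.
#' @return a `KeyHabitatReport` list (areas in km^2, raw and rounded
#'   percentages, category strings, masks, overlap surface).
#' @export
key_habitat_report <- function(psi, categories, index, t_psi,
                               protected = NULL) {
  key <- delineate_key(psi, categories, t_psi, "excellent")
  expanded <- delineate_key(psi, categories, t_psi, c("good", "excellent"))
  historic <- binarize(psi, t_psi + .Machine$double.eps, Inf)
  ov <- overlap_index(psi, index)
  aoo_key <- area_km2(key)
  aoo_exp <- area_km2(expanded)
  hist_km2 <- area_km2(historic)
  strict <- decline_and_category(aoo_key, hist_km2)
  broad <- decline_and_category(aoo_exp, hist_km2)
  prot <- if (!is.null(protected)) protected_overlap(historic, protected)
  structure(list(t_psi = t_psi,
                 aoo_key_km2 = aoo_key, aoo_expanded_km2 = aoo_exp,
                 historic_km2 = hist_km2,
                 decline_strict = strict, decline_expanded = broad,
                 protected = prot,
                 masks = list(key = key, expanded = expanded,
                              historic = historic),
                 overlap = ov),
            class = "KeyHabitatReport")
}

#' @export
print.KeyHabitatReport <- function(x, ...) {
  cat(sprintf("<KeyHabitatReport: t_psi %.3f>\n", x$t_psi))
  cat(sprintf("  historic (psi > t): %.0f km2\n", x$historic_km2))
  cat(sprintf("  key habitat (excellent): %.0f km2 -> decline %.1f%% (%s)\n",
              x$aoo_key_km2, x$decline_strict$decline_pct,
              x$decline_strict$iucn_category))
  cat(sprintf("  expanded (good+excellent): %.0f km2 -> decline %.1f%% (%s)\n",
              x$aoo_expanded_km2, x$decline_expanded$decline_pct,
              x$decline_expanded$iucn_category))
  if (!is.null(x$protected))
    cat(sprintf("  protected: %.0f km2 (%d%%)\n", x$protected$km2,
                as.integer(x$protected$pct_rounded)))
  invisible(x)
}
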