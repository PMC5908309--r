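#' Segmentation parameters
#'
#' @param smooth_sigma Gaussian pre-smoothing sigma in pixels applied to the
#'   DAPI raster before thresholding.
#' @param watershed_tolerance Minimum height (in distance-map pixels) a
#'   local maximum must have relative to its neighbourhood to seed a
#'   separate nucleus in the watershed split of touching nuclei.
#' @param otsu_levels Number of histogram levels for the automatic global
#'   threshold.
#' @return List of class `segmentation_params`.
#' @export
segmentation_params <- function(smooth_sigma = 1, watershed_tolerance = 2,
                                otsu_levels = 256L) {
  stopifnot(smooth_sigma >= 0, watershed_tolerance >= 0, otsu_levels >= 2)
  structure(list(smooth_sigma = smooth_sigma,
                 watershed_tolerance = watershed_tolerance,
                 otsu_levels = as.integer(otsu_levels)),
            class = "segmentation_params")
}

#' Construct a nucleus label map from a label raster
#'
#' Builds the per-nucleus bookkeeping (areas in square microns, centroids
#' in pixel coordinates) from an integer label raster, e.g. one produced by
#' [segment_nuclei()] or rendered synthetically.
#'
#' @param labels 2-D integer raster; 0 is background, each positive value
#'   one nucleus.
#' @param microns_per_pixel Positive linear calibration.
#' @return Object of class `nucleus_label_map`.
#' @export
nucleus_label_map <- function(labels, microns_per_pixel) {
  storage.mode(labels) <- "integer"
  ids <- sort(unique(labels[labels > 0L]))
  px_area <- microns_per_pixel^2
  if (length(ids)) {
    counts <- tabulate(labels, nbins = max(ids))[ids]
    idx <- which(labels > 0L, arr.ind = TRUE)
    lab <- labels[labels > 0L]
    cr <- rowsum(as.numeric(idx[, 1]), lab)[, 1] / counts[match(
      sort(unique(lab)), ids)]
    cc <- rowsum(as.numeric(idx[, 2]), lab)[, 1] / counts[match(
      sort(unique(lab)), ids)]
    centroids <- cbind(row = cr, col = cc)
    rownames(centroids) <- as.character(ids)
    areas <- counts * px_area
    names(areas) <- as.character(ids)
  } else {
    centroids <- matrix(numeric(0), 0, 2,
                        dimnames = list(NULL, c("row", "col")))
    areas <- numeric(0)
  }
  structure(list(labels = labels, areas_um2 = areas, centroids = centroids,
                 microns_per_pixel = microns_per_pixel,
                 n = length(ids)),
            class = "nucleus_label_map")
}

#' @export
print.nucleus_label_map <- function(x, ...) {
  cat(sprintf("<nucleus_label_map> %d nuclei on a %d x %d raster (%.4g um/px)\n",
              x$n, nrow(x$labels), ncol(x$labels), x$microns_per_pixel))
  invisible(x)
}

#' Segment nuclei from a DAPI raster
#'
#' Deterministic nuclear segmentation: Gaussian smoothing, automatic global
#' (Otsu) intensity threshold, hole filling, then a distance-transform
#' watershed to split touching nuclei, and 8-connected labelling. A blank
#' raster yields zero nuclei rather than an error.
#'
#' @param dapi 2-D nonnegative raster (integer intensities).
#' @param microns_per_pixel Positive linear calibration.
#' @param params A [segmentation_params()].
#' @return A `nucleus_label_map`: label raster (0 = background), per-label
#'   areas in square microns, and centroids in pixel coordinates.
#' @export
segment_nuclei <- function(dapi, microns_per_pixel,
                           params = segmentation_params()) {
  stopifnot(is.matrix(dapi), microns_per_pixel > 0)
  if (anyNA(dapi) || any(dapi < 0)) stop("DAPI raster must be nonnegative")
  x <- dapi / max(dapi, 1)
  if (max(dapi) == min(dapi))  # flat image: nothing to threshold
    return(nucleus_label_map(matrix(0L, nrow(dapi), ncol(dapi)),
                                 microns_per_pixel))
  if (params$smooth_sigma > 0)
    x <- EBImage::imageData(EBImage::gblur(x, sigma = params$smooth_sigma))
  thr <- EBImage::otsu(EBImage::Image(x), range = c(0, 1),
                       levels = params$otsu_levels)
  mask <- EBImage::fillHull(x > thr)
  mask <- EBImage::imageData(mask) * 1L
  if (!any(mask > 0))
    return(nucleus_label_map(matrix(0L, nrow(dapi), ncol(dapi)),
                                 microns_per_pixel))
  dm <- EBImage::distmap(mask)
  ws <- EBImage::watershed(dm, tolerance = params$watershed_tolerance,
                           ext = 1)
  labels <- EBImage::imageData(ws)
  storage.mode(labels) <- "integer"
  nucleus_label_map(labels, microns_per_pixel)
}

#' Filter segmented nuclei by area
#'
#' Removes nuclei whose area lies outside the retention window (by default
#' the 50-200 square-micron range used for tissue nuclei), discarding
#' improperly segmented objects. Pixels of removed nuclei become background;
#' no pixels are reassigned.
#'
#' @param nmap A `nucleus_label_map`.
#' @param min_area_um2,max_area_um2 Retention window in square microns;
#'   nuclei with `min <= area <= max` are kept.
#' @return A filtered `nucleus_label_map` (original label ids retained).
#' @export
filter_nuclei_by_area <- function(nmap, min_area_um2 = 50,
                                  max_area_um2 = 200) {
  stopifnot(inherits(nmap, "nucleus_label_map"))
  if (min_area_um2 >= max_area_um2)
    stop("inverted bounds: min_area_um2 must be < max_area_um2")
  keep <- nmap$areas_um2 >= min_area_um2 & nmap$areas_um2 <= max_area_um2
  drop_ids <- as.integer(names(nmap$areas_um2)[!keep])
  labels <- nmap$labels
  if (length(drop_ids)) labels[labels %in% drop_ids] <- 0L
  out <- nucleus_label_map(labels, nmap$microns_per_pixel)
  out
}

# Exact nearest-nucleus distance/label maps out to max_width_um.
# Internal wrapper around the compiled routine; distances returned as exact
# integer squared pixel distances.
nearest_nucleus_maps <- function(nmap, max_width_um) {
  r_px <- max_width_um / nmap$microns_per_pixel
  cpp_nearest_nucleus(nmap$labels, r_px)
}

#' Automatically select a ring width for a specimen
#'
#' Chooses the perinuclear ring (simulated cytoplasm) width on a
#' specimen-by-specimen basis: the widest width in `widths_um` for which the
#' median per-cell fraction of ring pixels contested by a neighbouring
#' nucleus stays below `max_contested_frac`. Wide rings maximise cytoplasmic
#' sampling; the contested-pixel bound limits cross-cell contamination in
#' crowded fields, so the selected width shrinks as nuclei crowd together.
#'
#' @param nmap A `nucleus_label_map` with at least one nucleus.
#' @param widths_um Candidate widths in microns (must lie in `[1, 5]`).
#' @param max_contested_frac Upper bound on the median per-cell contested
#'   fraction (default 0.2).
#' @return A single width in microns from `widths_um`.
#' @export
auto_select_ring_width <- function(nmap, widths_um = 1:5,
                                   max_contested_frac = 0.2) {
  stopifnot(inherits(nmap, "nucleus_label_map"))
  if (nmap$n == 0L) stop("cannot select a ring width on an empty label map")
  widths_um <- sort(widths_um)
  if (any(widths_um < 1) || any(widths_um > 5))
    stop("candidate ring widths must lie within [1, 5] microns")
  nn <- nearest_nucleus_maps(nmap, max(widths_um))
  ids <- as.integer(names(nmap$areas_um2))
  sel <- nn$best_label > 0L
  lab <- nn$best_label[sel]
  bd2 <- nn$best_d2[sel]
  sd2 <- nn$second_d2[sel]
  best <- min(widths_um)
  for (w in widths_um) {
    w2 <- (w / nmap$microns_per_pixel)^2
    inring <- bd2 <= w2
    if (!any(inring)) next
    tot <- tabulate(lab[inring], nbins = max(ids))[ids]
    con <- tabulate(lab[inring & sd2 <= w2], nbins = max(ids))[ids]
    frac <- ifelse(tot > 0, con / tot, NA_real_)
    if (isTRUE(median(frac, na.rm = TRUE) < max_contested_frac)) best <- w
  }
  best
}

#' Build exclusive cytoplasmic ring masks
#'
#' Constructs, for each nucleus, the set of background pixels whose
#' (centre-to-centre Euclidean) distance to that nucleus is at most
#' `ring_width_um` and for which that nucleus is the nearest one. Rings are
#' therefore pairwise disjoint and never overlap any nucleus; pixels within
#' reach of two nuclei are assigned to the closer one (ties to the lower
#' label).
#'
#' @param nmap A `nucleus_label_map`.
#' @param ring_width_um Ring width in microns, within `[1, 5]`.
#' @return Object of class `cell_rings`: the nucleus label raster, a ring
#'   label raster, a per-cell data frame (`label`, `nuclear_area_um2`,
#'   `ring_px`, `ring_area_um2`), the width and the calibration.
#' @export
make_cytoplasm_rings <- function(nmap, ring_width_um) {
  stopifnot(inherits(nmap, "nucleus_label_map"))
  if (ring_width_um < 1 || ring_width_um > 5)
    stop("ring_width_um must lie within [1, 5] microns")
  nn <- nearest_nucleus_maps(nmap, ring_width_um)
  w2 <- (ring_width_um / nmap$microns_per_pixel)^2
  ring <- matrix(0L, nrow(nmap$labels), ncol(nmap$labels))
  sel <- nn$best_label > 0L & nn$best_d2 <= w2
  ring[sel] <- nn$best_label[sel]
  ids <- as.integer(names(nmap$areas_um2))
  ring_px <- if (length(ids)) tabulate(ring, nbins = max(ids))[ids]
             else integer(0)
  cells <- data.frame(label = ids,
                      nuclear_area_um2 = unname(nmap$areas_um2),
                      ring_px = ring_px,
                      ring_area_um2 = ring_px * nmap$microns_per_pixel^2)
  structure(list(nucleus_labels = nmap$labels, ring_labels = ring,
                 cells = cells, ring_width_um = ring_width_um,
                 microns_per_pixel = nmap$microns_per_pixel),
            class = "cell_rings")
}

#' @export
print.cell_rings <- function(x, ...) {
  cat(sprintf("<cell_rings> %d cells, %.3g um rings (%.4g um/px)\n",
              nrow(x$cells), x$ring_width_um, x$microns_per_pixel))
  invisible(x)
}
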