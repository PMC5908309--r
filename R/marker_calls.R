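#' Intensity threshold specification
#'
#' Thresholds can be given as an absolute intensity (native integer scale)
#' or resolved automatically from the field background as
#' `median + k * MAD` of pixels outside all nuclei and rings.
#'
#' @param method `"absolute"` or `"mad"`.
#' @param value Absolute threshold (required for `"absolute"`).
#' @param k MAD multiplier for the automatic rule (default 6).
#' @return List of class `threshold_spec`.
#' @export
threshold_spec <- function(method = c("absolute", "mad"), value = NULL,
                           k = 6) {
  method <- match.arg(method)
  if (method == "absolute") {
    if (is.null(value) || !is.finite(value) || value < 0)
      stop("an absolute threshold_spec requires a nonnegative value")
  } else if (!is.finite(k) || k <= 0) {
    stop("mad threshold_spec requires k > 0")
  }
  structure(list(method = method, value = value, k = k),
            class = "threshold_spec")
}

#' Resolve a threshold specification against a raster
#'
#' @param spec A [threshold_spec()] or a single nonnegative number.
#' @param raster Intensity raster the threshold will be applied to.
#' @param rings A `cell_rings` object; the automatic rule estimates the
#'   background from pixels outside all nuclei and all rings.
#' @return A single nonnegative threshold.
#' @export
resolve_threshold <- function(spec, raster, rings = NULL) {
  if (is.numeric(spec) && length(spec) == 1L) return(as.numeric(spec))
  stopifnot(inherits(spec, "threshold_spec"))
  if (spec$method == "absolute") return(as.numeric(spec$value))
  if (is.null(rings)) stop("mad threshold resolution requires ring masks")
  bgpx <- raster[rings$nucleus_labels == 0L & rings$ring_labels == 0L]
  if (!length(bgpx)) stop("no background pixels available to estimate a threshold")
  median(bgpx) + spec$k * stats::mad(bgpx)
}

#' Spot-detection parameters for CC3 puncta
#'
#' Defaults follow the blebbing assay definition: a characteristic spot
#' size of 0.9 square microns with spots outside the 0.2-5 square-micron
#' window filtered out, and a cell called CC3(bleb)-positive when it holds
#' at least 2 puncta.
#'
#' @param expected_spot_area_um2 Characteristic punctum area (square
#'   microns); sets the band-pass scale when `bandpass = TRUE`.
#' @param min_spot_area_um2,max_spot_area_um2 Retained spot-area window.
#' @param spot_intensity_threshold A [threshold_spec()] or absolute value.
#' @param min_puncta_per_cell Minimum puncta for a CC3(bleb)+ call.
#' @param bandpass If `TRUE`, apply a difference-of-Gaussians band-pass
#'   (scaled to the expected spot area) before thresholding; the default
#'   thresholds the raw raster directly.
#' @return List of class `spot_params`.
#' @export
spot_params <- function(expected_spot_area_um2 = 0.9,
                        min_spot_area_um2 = 0.2, max_spot_area_um2 = 5,
                        spot_intensity_threshold = threshold_spec("mad"),
                        min_puncta_per_cell = 2L, bandpass = FALSE) {
  if (!(min_spot_area_um2 < expected_spot_area_um2 &&
        expected_spot_area_um2 < max_spot_area_um2))
    stop("spot areas must satisfy min < expected < max")
  if (min_puncta_per_cell < 1) stop("min_puncta_per_cell must be >= 1")
  structure(list(expected_spot_area_um2 = expected_spot_area_um2,
                 min_spot_area_um2 = min_spot_area_um2,
                 max_spot_area_um2 = max_spot_area_um2,
                 spot_intensity_threshold = spot_intensity_threshold,
                 min_puncta_per_cell = as.integer(min_puncta_per_cell),
                 bandpass = isTRUE(bandpass)),
            class = "spot_params")
}

#' Classify cells by diffuse cytoplasmic CC3 intensity
#'
#' A cell is cytoplasmic-CC3-positive when the mean CC3 intensity over its
#' ring mask exceeds the threshold (strict `>`). Cells with an empty ring
#' mask are flagged unevaluable and carry `NA` calls so they can be
#' excluded from denominators with an auditable count.
#'
#' @param rings A `cell_rings` object.
#' @param cc3 CC3 intensity raster (same shape as the masks).
#' @param threshold Nonnegative intensity threshold (or [threshold_spec()]).
#' @return Data frame: `cell_label`, `cyto_cc3_mean`, `cyto_cc3_pos`,
#'   `evaluable` (one row per cell).
#' @export
classify_cytoplasmic_cc3 <- function(rings, cc3, threshold) {
  stopifnot(inherits(rings, "cell_rings"),
            identical(dim(cc3), dim(rings$ring_labels)))
  thr <- resolve_threshold(threshold, cc3, rings)
  ids <- rings$cells$label
  sel <- rings$ring_labels > 0L
  sums <- rep(0, max(ids, 1L))
  if (any(sel)) {
    s <- rowsum(as.numeric(cc3[sel]), rings$ring_labels[sel])
    sums[as.integer(rownames(s))] <- s[, 1]
  }
  npx <- rings$cells$ring_px
  means <- ifelse(npx > 0, sums[ids] / npx, NA_real_)
  data.frame(cell_label = ids, cyto_cc3_mean = means,
             cyto_cc3_pos = ifelse(npx > 0, means > thr, NA),
             evaluable = npx > 0)
}

#' Detect CC3 puncta within cytoplasmic ring masks
#'
#' Spot detection used as the membrane-blebbing proxy: threshold the CC3
#' raster (optionally after a band-pass tuned to the expected spot area),
#' restrict to the union of ring masks, label 8-connected components, and
#' retain components whose area lies within the configured window. Each
#' punctum is assigned to the cell whose ring contains its centroid (with a
#' majority-overlap fallback for spots whose centroid pixel falls on
#' another ring after rounding).
#'
#' @param rings A `cell_rings` object.
#' @param cc3 CC3 intensity raster.
#' @param params A [spot_params()].
#' @return Data frame of puncta: `cell_label`, `centroid_row`,
#'   `centroid_col`, `area_um2`, `mean_intensity`. Zero rows when no spots
#'   survive the filters.
#' @export
detect_cc3_puncta <- function(rings, cc3, params = spot_params()) {
  stopifnot(inherits(rings, "cell_rings"), inherits(params, "spot_params"),
            identical(dim(cc3), dim(rings$ring_labels)))
  thr <- resolve_threshold(params$spot_intensity_threshold, cc3, rings)
  img <- cc3
  if (params$bandpass) {
    # difference of Gaussians with the centre scale matched to the expected
    # spot radius; response is maximal for spots near that size
    r_px <- sqrt(params$expected_spot_area_um2 / pi) / rings$microns_per_pixel
    s1 <- max(r_px / sqrt(2), 0.5)
    img <- EBImage::imageData(EBImage::gblur(cc3, sigma = s1)) -
      EBImage::imageData(EBImage::gblur(cc3, sigma = 2 * s1))
  }
  mask <- (img > thr) & (rings$ring_labels > 0L)
  empty <- data.frame(cell_label = integer(0), centroid_row = numeric(0),
                      centroid_col = numeric(0), area_um2 = numeric(0),
                      mean_intensity = numeric(0))
  if (!any(mask)) return(empty)
  lab <- cpp_label8(mask * 1L)
  px_area <- rings$microns_per_pixel^2
  npx <- tabulate(lab)
  areas <- npx * px_area
  keep <- which(areas >= params$min_spot_area_um2 &
                areas <= params$max_spot_area_um2)
  if (!length(keep)) return(empty)
  idx <- which(lab > 0L, arr.ind = TRUE)
  sl <- lab[lab > 0L]
  inkeep <- sl %in% keep
  idx <- idx[inkeep, , drop = FALSE]
  sl <- sl[inkeep]
  cr <- rowsum(as.numeric(idx[, 1]), sl)[, 1]
  cc <- rowsum(as.numeric(idx[, 2]), sl)[, 1]
  ii <- rowsum(as.numeric(cc3[idx]), sl)[, 1]
  ord <- sort(unique(sl))
  n <- npx[ord]
  centroid_row <- cr / n
  centroid_col <- cc / n
  mean_int <- ii / n
  # ownership: ring label at the rounded centroid, falling back to the
  # majority ring label over the spot's own pixels
  own <- rings$ring_labels[cbind(pmin(pmax(round(centroid_row), 1), nrow(cc3)),
                                 pmin(pmax(round(centroid_col), 1), ncol(cc3)))]
  if (any(own == 0L)) {
    for (m in which(own == 0L)) {
      rl <- rings$ring_labels[idx[sl == ord[m], , drop = FALSE]]
      rl <- rl[rl > 0L]
      own[m] <- as.integer(names(which.max(table(rl))))
    }
  }
  data.frame(cell_label = as.integer(own), centroid_row = centroid_row,
             centroid_col = centroid_col, area_um2 = n * px_area,
             mean_intensity = mean_int)
}

#' Count puncta per cell
#'
#' @param puncta Data frame from [detect_cc3_puncta()].
#' @param rings A `cell_rings` object (defines the full cell set).
#' @return Named integer vector, one entry per cell (zeros included).
#' @export
count_puncta <- function(puncta, rings) {
  ids <- rings$cells$label
  counts <- integer(length(ids))
  names(counts) <- as.character(ids)
  if (nrow(puncta)) {
    t <- table(factor(puncta$cell_label, levels = ids))
    counts[] <- as.integer(t)
  }
  counts
}

#' Classify CC3 blebbing from puncta counts
#'
#' A cell is CC3(bleb)-positive when it contains at least `min_puncta`
#' puncta (default 2).
#'
#' @param puncta_counts Named nonnegative integer vector (cell label ->
#'   punctum count).
#' @param min_puncta Minimum count for positivity.
#' @return Named logical vector aligned with `puncta_counts`.
#' @export
classify_cc3_bleb <- function(puncta_counts, min_puncta = 2L) {
  if (any(puncta_counts < 0)) stop("puncta counts must be nonnegative")
  if (min_puncta < 1) stop("min_puncta must be >= 1")
  puncta_counts >= min_puncta
}

#' Automatic gamma-H2AX positivity threshold
#'
#' Deterministic two-class split of per-nucleus mean intensities: the
#' within-class variance-minimising cut over all sorted split points (an
#' Otsu-style rule on the means). When the between-class separation is too
#' small relative to the pooled within-class spread -- i.e. the sample looks
#' unimodal background rather than background plus a positive population --
#' the rule falls back to a conservative threshold at the sample maximum so
#' that no cell is called positive.
#'
#' @param nuclear_means Numeric vector of per-nucleus mean intensities
#'   (length >= 2).
#' @param min_separation Minimum ratio of between-class separation to
#'   pooled within-class standard deviation for the split to be accepted
#'   (default 4; an Otsu cut of a pure Gaussian background yields a ratio
#'   near 2.6, well below it).
#' @return A single threshold; positives are values strictly above it.
#' @export
auto_threshold_gh2ax <- function(nuclear_means, min_separation = 4) {
  if (length(nuclear_means) < 2L)
    stop("at least 2 nuclear means are required")
  if (anyNA(nuclear_means) || any(nuclear_means < 0))
    stop("nuclear means must be nonnegative and non-missing")
  v <- sort(nuclear_means)
  n <- length(v)
  cs <- cumsum(v); css <- cumsum(v^2)
  i <- seq_len(n - 1L)
  ss1 <- css[i] - cs[i]^2 / i
  ss2 <- (css[n] - css[i]) - (cs[n] - cs[i])^2 / (n - i)
  tot <- ss1 + ss2
  cut <- which.min(tot)  # ties: earliest split, deterministic
  m1 <- cs[cut] / cut
  m2 <- (cs[n] - cs[cut]) / (n - cut)
  pooled <- sqrt(tot[cut] / n)
  if (pooled == 0) pooled <- .Machine$double.eps
  if ((m2 - m1) / pooled < min_separation) return(max(v))
  (v[cut] + v[cut + 1L]) / 2
}

#' Classify nuclear gamma-H2AX positivity
#'
#' A cell is gamma-H2AX-positive when the mean intensity over its nucleus
#' pixels exceeds the threshold (strict `>`).
#'
#' @param nmap A `nucleus_label_map`.
#' @param gh2ax gamma-H2AX intensity raster.
#' @param threshold Nonnegative intensity threshold.
#' @return Data frame: `cell_label`, `gh2ax_mean`, `gh2ax_pos`.
#' @export
classify_gh2ax <- function(nmap, gh2ax, threshold) {
  stopifnot(inherits(nmap, "nucleus_label_map"),
            identical(dim(gh2ax), dim(nmap$labels)))
  if (nmap$n == 0L) stop("no nuclei to classify")
  ids <- as.integer(names(nmap$areas_um2))
  sel <- nmap$labels > 0L
  s <- rowsum(as.numeric(gh2ax[sel]), nmap$labels[sel])
  npx <- tabulate(nmap$labels, nbins = max(ids))[ids]
  means <- s[match(as.character(ids), rownames(s)), 1] / npx
  data.frame(cell_label = ids, gh2ax_mean = unname(means),
             gh2ax_pos = unname(means) > threshold)
}

#' Combine marker calls into colocalization calls
#'
#' A cell is gamma-H2AX/CC3(bleb) colocalization-positive exactly when it is
#' both gamma-H2AX-positive and CC3(bleb)-positive. Gating order is
#' immaterial: classifying blebbing on all cells and intersecting with the
#' gamma-H2AX-positive set equals detecting blebbing within
#' gamma-H2AX-positive cells only.
#'
#' @param calls Data frame with logical columns `gh2ax_pos` and
#'   `cc3_bleb_pos`.
#' @return `calls` with a `coloc_pos` column set.
#' @export
classify_colocalization <- function(calls) {
  stopifnot(all(c("gh2ax_pos", "cc3_bleb_pos") %in% names(calls)))
  calls$coloc_pos <- calls$gh2ax_pos & calls$cc3_bleb_pos
  calls
}

#' Full per-cell marker calls for one field
#'
#' Convenience wrapper producing the complete per-cell call table for one
#' field: cytoplasmic CC3, CC3(bleb) from puncta counts, nuclear
#' gamma-H2AX (with automatic thresholding by default), and colocalization.
#'
#' @param rings A `cell_rings` object.
#' @param cc3,gh2ax Intensity rasters.
#' @param params A [spot_params()].
#' @param cyto_threshold Threshold for diffuse cytoplasmic CC3.
#' @param gh2ax_threshold Threshold for nuclear gamma-H2AX, or `NULL` to
#'   apply [auto_threshold_gh2ax()] to the per-nucleus means.
#' @param nmap The `nucleus_label_map` the rings were built from.
#' @return Per-cell data frame with means, counts and boolean calls.
#' @export
call_cells <- function(rings, nmap, cc3, gh2ax, params = spot_params(),
                       cyto_threshold = threshold_spec("mad"),
                       gh2ax_threshold = NULL) {
  cyto <- classify_cytoplasmic_cc3(rings, cc3, cyto_threshold)
  puncta <- detect_cc3_puncta(rings, cc3, params)
  counts <- count_puncta(puncta, rings)
  bleb <- classify_cc3_bleb(counts, params$min_puncta_per_cell)
  gh <- classify_gh2ax(nmap, gh2ax,
                       if (is.null(gh2ax_threshold))
                         auto_threshold_gh2ax(
                           classify_gh2ax(nmap, gh2ax, 0)$gh2ax_mean)
                       else gh2ax_threshold)
  calls <- data.frame(cell_label = rings$cells$label,
                      nuclear_area_um2 = rings$cells$nuclear_area_um2,
                      ring_area_um2 = rings$cells$ring_area_um2,
                      evaluable = cyto$evaluable,
                      cyto_cc3_mean = cyto$cyto_cc3_mean,
                      cyto_cc3_pos = cyto$cyto_cc3_pos,
                      puncta_count = unname(counts),
                      cc3_bleb_pos = unname(bleb),
                      gh2ax_mean = gh$gh2ax_mean[match(rings$cells$label,
                                                       gh$cell_label)],
                      gh2ax_pos = gh$gh2ax_pos[match(rings$cells$label,
                                                     gh$cell_label)])
  classify_colocalization(calls)
}
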