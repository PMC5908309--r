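#' Configuration for a synthetic immunofluorescence field
#'
#' Defines one simulated three-channel field (DAPI / CC3 / GH2AX) with
#' exact per-cell ground truth. Nuclei are non-overlapping ellipses with
#' areas spanning the 50-200 square-micron retention window; a configurable
#' fraction carries pan-nuclear gamma-H2AX signal, diffuse perinuclear CC3,
#' and/or perinuclear CC3 puncta (the blebbing phenotype), with the
#' colocalized fraction contained in both marker-positive sets by
#' construction. Decoy spots with areas outside the punctum filter window
#' are added as distractors, and additive Gaussian noise is applied to all
#' channels before 16-bit clipping.
#'
#' Class counts are exact (`round(frac * n_cells)`), not binomial draws,
#' so ground-truth percentages are sharp.
#'
#' @param n_cells Number of nuclei to place.
#' @param field_px Field size in pixels, `c(rows, cols)`.
#' @param microns_per_pixel Linear calibration (default 0.4 um/px).
#' @param nucleus_area_range_um2 Uniform sampling range for nuclear areas.
#' @param frac_gh2ax,frac_bleb,frac_coloc,frac_diffuse_cc3 True positive
#'   fractions; `frac_coloc <= min(frac_gh2ax, frac_bleb)` and
#'   `frac_gh2ax + frac_bleb - frac_coloc <= 1` are required.
#' @param puncta_per_apoptotic_cell Integer range `c(min, max)` of puncta
#'   per blebbing-positive cell.
#' @param punctum_area_um2_range Uniform range of true punctum areas
#'   (square microns), inside the 0.2-5 filter window.
#' @param decoy_spot_areas_um2 Areas of distractor spots rendered outside
#'   the filter window (default 0.1 and 6.0).
#' @param decoy_fraction Fraction of cells receiving one decoy of each
#'   configured area.
#' @param signal_to_background Ratio of marker signal amplitude to the
#'   background level.
#' @param noise_sd Standard deviation of the additive Gaussian noise.
#' @param background_level Mean background intensity (16-bit scale).
#' @param seed Integer RNG seed; fields are bit-reproducible per seed.
#' @return List of class `synthetic_config`.
#' @export
synthetic_config <- function(n_cells, field_px = c(1000L, 1000L),
                             microns_per_pixel = 0.4,
                             nucleus_area_range_um2 = c(50, 200),
                             frac_gh2ax = 0, frac_bleb = 0, frac_coloc = 0,
                             frac_diffuse_cc3 = 0,
                             puncta_per_apoptotic_cell = c(2L, 8L),
                             punctum_area_um2_range = c(0.4, 3),
                             decoy_spot_areas_um2 = c(0.1, 6),
                             decoy_fraction = 0.2,
                             signal_to_background = 20, noise_sd = 50,
                             background_level = 500, seed = 1L) {
  fr <- c(frac_gh2ax, frac_bleb, frac_coloc, frac_diffuse_cc3,
          decoy_fraction)
  if (any(!is.finite(fr)) || any(fr < 0) || any(fr > 1))
    stop("all fractions must lie in [0, 1]")
  if (frac_coloc > min(frac_gh2ax, frac_bleb) + 1e-12)
    stop("inconsistent fractions: frac_coloc must not exceed min(frac_gh2ax, frac_bleb)")
  if (frac_gh2ax + frac_bleb - frac_coloc > 1 + 1e-12)
    stop("inconsistent fractions: gh2ax+ and bleb+ sets cannot fit in the cell population")
  if (n_cells < 1) stop("n_cells must be positive")
  if (diff(nucleus_area_range_um2) <= 0 ||
      any(nucleus_area_range_um2 <= 0))
    stop("nucleus_area_range_um2 must be an increasing positive pair")
  if (diff(punctum_area_um2_range) < 0)
    stop("punctum_area_um2_range must be nondecreasing")
  if (puncta_per_apoptotic_cell[1] < 1 ||
      diff(puncta_per_apoptotic_cell) < 0)
    stop("puncta_per_apoptotic_cell must be an increasing range of positive counts")
  if (signal_to_background <= 0 || noise_sd < 0 || background_level < 0 ||
      microns_per_pixel <= 0)
    stop("invalid signal, noise, background or calibration setting")
  structure(list(
    n_cells = as.integer(n_cells), field_px = as.integer(field_px),
    microns_per_pixel = microns_per_pixel,
    nucleus_area_range_um2 = nucleus_area_range_um2,
    frac_gh2ax = frac_gh2ax, frac_bleb = frac_bleb,
    frac_coloc = frac_coloc, frac_diffuse_cc3 = frac_diffuse_cc3,
    puncta_per_apoptotic_cell = as.integer(puncta_per_apoptotic_cell),
    punctum_area_um2_range = punctum_area_um2_range,
    decoy_spot_areas_um2 = decoy_spot_areas_um2,
    decoy_fraction = decoy_fraction,
    signal_to_background = signal_to_background, noise_sd = noise_sd,
    background_level = background_level, seed = as.integer(seed)),
    class = "synthetic_config")
}

# geometry constants of the placement model
ASPECT_RANGE <- c(1, 1.3)      # nuclear ellipse aspect ratio
MIN_BORDER_GAP_UM <- 3         # guaranteed nucleus border separation
DIFFUSE_BAND_UM <- 5           # extent of diffuse perinuclear CC3
PUNCTA_BAND_UM <- c(0.8, 2.2)  # punctum centre distance from the border
MAX_SPOT_EXTENT_UM <- 4.6      # spot pixels stay within this border distance

# spot "blob": the n nearest pixels to a centre pixel, deterministic
# tie-break by (d2, dcol, drow)
blob_offsets <- function(max_npx) {
  r <- ceiling(sqrt(max_npx / pi)) + 3L
  g <- expand.grid(di = -r:r, dj = -r:r)
  g$d2 <- g$di^2 + g$dj^2
  g <- g[order(g$d2, g$dj, g$di), ]
  g
}

#' Generate one synthetic field with ground truth
#'
#' Nuclei are placed on a jittered grid whose pitch guarantees
#' non-overlapping ellipses with a minimum border gap; an error is raised
#' when the requested cell count cannot be placed at that density. Diffuse
#' CC3 and puncta are rendered only on pixels whose nearest nucleus is the
#' owning cell, so neighbouring cells' cytoplasmic measurements are not
#' contaminated. Puncta (and decoys) are uniform-intensity pixel blobs of
#' exactly known area, mutually separated so that connected-component
#' counts match the truth.
#'
#' @param cfg A [synthetic_config()].
#' @param field_id Identifier for the generated field.
#' @param group_label Optional group label attached to the field.
#' @return List with elements `field` (a [calibrated_field()]) and `truth`
#'   (per-cell truth table, true puncta, and the true nucleus label
#'   raster).
#' @export
generate_field <- function(cfg, field_id = sprintf("synthetic_s%d", cfg$seed),
                           group_label = NULL) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  mpp <- cfg$microns_per_pixel
  nr <- cfg$field_px[1]; nc <- cfg$field_px[2]
  n <- cfg$n_cells

  ## --- placement grid ---------------------------------------------------
  a_max_um <- sqrt(cfg$nucleus_area_range_um2[2] / pi * ASPECT_RANGE[2])
  pitch_um <- 2 * a_max_um + MIN_BORDER_GAP_UM
  gr <- floor(nr * mpp / pitch_um); gc <- floor(nc * mpp / pitch_um)
  if (n > gr * gc)
    stop(sprintf(
      "unplaceable density: %d nuclei requested but at most %d fit a %d x %d px field without overlap",
      n, gr * gc, nr, nc))
  slots <- sample.int(gr * gc, n)
  srow <- (slots - 1L) %% gr; scol <- (slots - 1L) %/% gr
  off_r <- (nr * mpp - gr * pitch_um) / 2
  off_c <- (nc * mpp - gc * pitch_um) / 2

  areas_um2 <- runif(n, cfg$nucleus_area_range_um2[1],
                     cfg$nucleus_area_range_um2[2])
  rho <- runif(n, ASPECT_RANGE[1], ASPECT_RANGE[2])
  theta <- runif(n, 0, pi)
  b_um <- sqrt(areas_um2 / (pi * rho))
  a_um <- rho * b_um
  jmax <- pmax(a_max_um - a_um, 0)
  cen_r_um <- off_r + (srow + 0.5) * pitch_um + runif(n, -1, 1) * jmax
  cen_c_um <- off_c + (scol + 0.5) * pitch_um + runif(n, -1, 1) * jmax
  cen_r <- cen_r_um / mpp; cen_c <- cen_c_um / mpp  # continuous px coords

  ## --- rasterize ellipses ----------------------------------------------
  labels <- matrix(0L, nr, nc)
  a_px <- a_um / mpp; b_px <- b_um / mpp
  for (i in seq_len(n)) {
    ext <- ceiling(a_px[i]) + 1L
    rr <- max(1L, floor(cen_r[i]) - ext):min(nr, ceiling(cen_r[i]) + ext)
    cc <- max(1L, floor(cen_c[i]) - ext):min(nc, ceiling(cen_c[i]) + ext)
    dx <- rr - cen_r[i]
    dy <- cc - cen_c[i]
    u <- outer(dx, dy, function(x, y) x * cos(theta[i]) + y * sin(theta[i]))
    v <- outer(dx, dy, function(x, y) -x * sin(theta[i]) + y * cos(theta[i]))
    inside <- (u / a_px[i])^2 + (v / b_px[i])^2 <= 1
    sub <- labels[rr, cc]
    sub[inside] <- i
    labels[rr, cc] <- sub
  }
  npx_nuc <- tabulate(labels, nbins = n)
  if (any(npx_nuc == 0L)) stop("degenerate nucleus rasterized to zero pixels")

  ## --- class assignment (exact counts, coloc contained in both) --------
  n_coloc <- round(cfg$frac_coloc * n)
  n_gh <- max(round(cfg$frac_gh2ax * n), n_coloc)
  n_bleb <- max(round(cfg$frac_bleb * n), n_coloc)
  if (n_gh + n_bleb - n_coloc > n)
    stop("inconsistent fractions at this cell count")
  perm <- sample.int(n)
  coloc_set <- perm[seq_len(n_coloc)]
  gh_set <- perm[seq_len(n_gh)]  # includes coloc set
  bleb_set <- c(coloc_set,
                perm[n_gh + seq_len(n_bleb - n_coloc)])
  diffuse_set <- sample.int(n, round(cfg$frac_diffuse_cc3 * n))
  is_gh <- seq_len(n) %in% gh_set
  is_bleb <- seq_len(n) %in% bleb_set
  is_coloc <- seq_len(n) %in% coloc_set
  is_diffuse <- seq_len(n) %in% diffuse_set

  ## --- nearest-nucleus geometry -----------------------------------------
  nn <- cpp_nearest_nucleus(labels, DIFFUSE_BAND_UM / mpp)
  bl <- nn$best_label; bd2 <- nn$best_d2

  bg <- cfg$background_level
  sig <- bg * cfg$signal_to_background
  amp <- min(3 * sig, 60000 - bg)  # punctum amplitude above the diffuse level

  dapi <- matrix(bg, nr, nc)
  gh2ax <- matrix(bg, nr, nc)
  cc3 <- matrix(bg, nr, nc)
  dapi[labels > 0L] <- bg + sig
  gh2ax[labels %in% gh_set] <- bg + sig
  if (length(diffuse_set)) {
    sel <- bl > 0L & bd2 <= (DIFFUSE_BAND_UM / mpp)^2 & (bl %in% diffuse_set)
    cc3[sel] <- cc3[sel] + sig
  }

  ## --- puncta and decoys -------------------------------------------------
  band2 <- (PUNCTA_BAND_UM / mpp)^2
  ext2 <- (MAX_SPOT_EXTENT_UM / mpp)^2
  cand <- which(bl > 0L & bd2 >= band2[1] & bd2 <= band2[2])
  cand_by_cell <- split(cand, bl[cand])
  max_npx <- max(ceiling(c(cfg$punctum_area_um2_range[2],
                           cfg$decoy_spot_areas_um2) / mpp^2)) + 2L
  offs <- blob_offsets(max_npx)
  forbidden <- matrix(FALSE, nr, nc)

  place_blob <- function(cell, target_area_um2, min_px) {
    cands <- cand_by_cell[[as.character(cell)]]
    if (is.null(cands) || !length(cands)) return(NULL)
    npx <- max(min_px, round(target_area_um2 / mpp^2))
    for (try in seq_len(60L)) {
      ctr <- cands[sample.int(length(cands), 1L)]
      r0 <- (ctr - 1L) %% nr + 1L; c0 <- (ctr - 1L) %/% nr + 1L
      rb <- r0 + offs$di[seq_len(npx)]
      cb <- c0 + offs$dj[seq_len(npx)]
      if (any(rb < 1L | rb > nr | cb < 1L | cb > nc)) next
      pix <- rb + (cb - 1L) * nr
      if (any(bl[pix] != cell) || any(bd2[pix] > ext2)) next
      if (any(forbidden[pix])) next
      # stamp a 1-px dilated halo so distinct blobs never become 8-adjacent
      hr <- rep(rb, each = 9L) + rep(c(-1L, 0L, 1L), times = 3L)
      hc <- rep(cb, each = 9L) + rep(c(-1L, 0L, 1L), each = 3L)
      ok <- hr >= 1L & hr <= nr & hc >= 1L & hc <= nc
      forbidden[unique(hr[ok] + (hc[ok] - 1L) * nr)] <<- TRUE
      return(list(pix = pix, row = r0, col = c0, npx = npx))
    }
    NULL
  }

  puncta_truth <- list()
  n_puncta <- integer(n)
  pr <- cfg$puncta_per_apoptotic_cell
  for (cell in which(is_bleb)) {
    k <- pr[1] + sample.int(pr[2] - pr[1] + 1L, 1L) - 1L
    for (p in seq_len(k)) {
      A <- runif(1, cfg$punctum_area_um2_range[1],
                 cfg$punctum_area_um2_range[2])
      blob <- place_blob(cell, A, min_px = 2L)
      if (is.null(blob))
        stop("unplaceable density: could not position ", k,
             " separated puncta around cell ", cell)
      cc3[blob$pix] <- cc3[blob$pix] + amp
      n_puncta[cell] <- n_puncta[cell] + 1L
      puncta_truth[[length(puncta_truth) + 1L]] <-
        data.frame(cell_label = cell, row = blob$row, col = blob$col,
                   area_um2 = blob$npx * mpp^2)
    }
  }
  if (length(cfg$decoy_spot_areas_um2) && cfg$decoy_fraction > 0) {
    decoy_cells <- sample.int(n, round(cfg$decoy_fraction * n))
    for (cell in decoy_cells) {
      for (A in cfg$decoy_spot_areas_um2) {
        blob <- place_blob(cell, A, min_px = 1L)
        if (!is.null(blob)) cc3[blob$pix] <- cc3[blob$pix] + amp
      }
    }
  }

  ## --- noise, clipping, assembly ----------------------------------------
  clip16 <- function(x) {
    if (cfg$noise_sd > 0) x <- x + rnorm(length(x), 0, cfg$noise_sd)
    m <- matrix(as.integer(round(pmin(pmax(x, 0), 65535))), nr, nc)
    m
  }
  field <- calibrated_field(
    list(DAPI = clip16(dapi), CC3 = clip16(cc3), GH2AX = clip16(gh2ax)),
    microns_per_pixel = mpp, field_id = field_id, bit_depth = 16L,
    source = "synthetic", group_label = group_label)

  truth <- structure(list(
    cells = data.frame(
      label = seq_len(n), center_row = cen_r, center_col = cen_c,
      area_um2 = npx_nuc * mpp^2, gh2ax_pos = is_gh, bleb_pos = is_bleb,
      coloc_pos = is_coloc, diffuse_pos = is_diffuse,
      n_puncta = n_puncta),
    puncta = if (length(puncta_truth)) do.call(rbind, puncta_truth)
             else data.frame(cell_label = integer(0), row = integer(0),
                             col = integer(0), area_um2 = numeric(0)),
    nucleus_labels = labels, config = cfg), class = "field_truth")

  list(field = field, truth = truth)
}

#' Generate a multi-group synthetic study
#'
#' Generates `fields_per_group` fields for each treatment group, mirroring
#' the per-specimen design of the assay (at least six fields analysed per
#' specimen). Per-field seeds are derived deterministically from the master
#' seed, so a study is bit-reproducible.
#'
#' @param groups Named list of [synthetic_config()] objects; names are the
#'   group labels.
#' @param fields_per_group Number of fields per group (>= 1).
#' @param master_seed Integer master seed.
#' @return List of `list(field=, truth=)` pairs, one per generated field.
#' @export
generate_study <- function(groups, fields_per_group = 6L, master_seed = 1L) {
  stopifnot(fields_per_group >= 1, length(groups) >= 1,
            !is.null(names(groups)), all(nzchar(names(groups))))
  set.seed(master_seed)
  seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                             length(groups) * fields_per_group),
                  nrow = length(groups))
  out <- list()
  for (g in seq_along(groups)) {
    label <- names(groups)[g]
    for (i in seq_len(fields_per_group)) {
      cfg <- groups[[g]]
      cfg$seed <- seeds[g, i]
      out[[length(out) + 1L]] <- generate_field(
        cfg, field_id = sprintf("%s_f%02d", label, i), group_label = label)
    }
  }
  out
}
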