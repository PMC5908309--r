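#' Canonical channel names
#'
#' Every analysed field carries exactly these three channels after channel
#' mapping: the DAPI nuclear counterstain, the cleaved caspase-3 immunostain
#' ("CC3"), and the gamma-H2AX immunostain ("GH2AX").
#' @export
CANONICAL_CHANNELS <- c("DAPI", "CC3", "GH2AX")

#' Construct a channel map
#'
#' Maps plane indices of a multi-plane image file onto the canonical channel
#' names. The mapping must be injective and must cover all three canonical
#' channels.
#'
#' @param DAPI,CC3,GH2AX 1-based plane index of each channel in the file.
#' @return A named integer vector of class `channel_map`.
#' @examples
#' channel_map(DAPI = 1, CC3 = 2, GH2AX = 3)
#' @export
channel_map <- function(DAPI = 1, CC3 = 2, GH2AX = 3) {
  m <- c(DAPI = as.integer(DAPI), CC3 = as.integer(CC3),
         GH2AX = as.integer(GH2AX))
  if (anyNA(m) || any(m < 1))
    stop("channel map indices must be positive integers")
  if (anyDuplicated(m))
    stop("channel map is not injective: two channels share a plane index")
  class(m) <- "channel_map"
  m
}

#' Construct a calibrated multichannel field
#'
#' A `calibrated_field` is the unit of analysis: one image field with named
#' integer channel rasters and a micron calibration. All rasters must share
#' one shape and the channels must be exactly `"DAPI"`, `"CC3"`, `"GH2AX"`.
#'
#' @param channels Named list of 2-D nonnegative integer matrices.
#' @param microns_per_pixel Positive linear calibration (micrometres per
#'   pixel edge); pixel area is `microns_per_pixel^2` square microns.
#' @param field_id Identifier for the field.
#' @param bit_depth Nominal bit depth of the rasters (default 16).
#' @param source Provenance string (file path or `"synthetic"`).
#' @param group_label Optional treatment-group / time-point label.
#' @return Object of class `calibrated_field`.
#' @export
calibrated_field <- function(channels, microns_per_pixel, field_id = "field",
                             bit_depth = 16L, source = "synthetic",
                             group_label = NULL) {
  if (!is.list(channels) || !setequal(names(channels), CANONICAL_CHANNELS))
    stop("channels must be a named list with exactly DAPI, CC3 and GH2AX")
  channels <- channels[CANONICAL_CHANNELS]
  dims <- lapply(channels, dim)
  if (any(vapply(dims, length, 1L) != 2L))
    stop("each channel must be a 2-D matrix")
  if (!all(vapply(dims, identical, TRUE, y = dims[[1]])))
    stop("all channel rasters must share one shape")
  for (nm in CANONICAL_CHANNELS) {
    ch <- channels[[nm]]
    if (anyNA(ch) || any(ch < 0))
      stop("channel ", nm, " contains NA or negative intensities")
    if (!is.integer(ch)) storage.mode(channels[[nm]]) <- "integer"
  }
  if (!is.numeric(microns_per_pixel) || length(microns_per_pixel) != 1L ||
      !is.finite(microns_per_pixel) || microns_per_pixel <= 0)
    stop("microns_per_pixel must be a single positive number")
  structure(list(field_id = as.character(field_id), channels = channels,
                 bit_depth = as.integer(bit_depth),
                 microns_per_pixel = microns_per_pixel,
                 source = as.character(source), group_label = group_label),
            class = "calibrated_field")
}

#' @export
print.calibrated_field <- function(x, ...) {
  d <- dim(x$channels$DAPI)
  cat(sprintf(
    "<calibrated_field> %s: %d x %d px, %.4g um/px, %d-bit, group=%s\n",
    x$field_id, d[1], d[2], x$microns_per_pixel, x$bit_depth,
    if (is.null(x$group_label)) "<none>" else x$group_label))
  invisible(x)
}

#' Field dimensions in pixels
#' @param field A [calibrated_field()].
#' @return Integer vector `c(rows, cols)`.
#' @export
field_dim <- function(field) dim(field$channels$DAPI)

#' Read a multichannel field from a TIFF file
#'
#' Reads a multi-plane grayscale TIFF (or OME-TIFF saved as plain planes)
#' and maps planes onto the canonical channel names. Integer intensities are
#' preserved bit-exactly.
#'
#' @param path Path to the TIFF file.
#' @param map A [channel_map()] giving the plane index of each channel.
#' @param microns_per_pixel Linear calibration in microns per pixel edge.
#' @param field_id Field identifier; defaults to the file name.
#' @param group_label Optional group label to attach.
#' @return A [calibrated_field()].
#' @seealso [write_field()] for the inverse operation.
#' @export
read_field <- function(path, map = channel_map(), microns_per_pixel,
                       field_id = basename(path), group_label = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (!inherits(map, "channel_map")) map <- do.call(channel_map, as.list(map))
  planes <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(planes)) planes <- list(planes)
  if (max(map) > length(planes))
    stop("channel index out of range: map references plane ", max(map),
         " but file has ", length(planes), " plane(s)")
  channels <- lapply(seq_along(map), function(i) {
    m <- planes[[map[[i]]]]
    if (length(dim(m)) == 3L) m <- m[, , 1]  # tolerate grey stored as RGB
    storage.mode(m) <- "integer"
    m
  })
  names(channels) <- names(map)
  calibrated_field(channels, microns_per_pixel, field_id = field_id,
                   source = path, group_label = group_label)
}

#' Write a field to a 16-bit multi-plane TIFF
#'
#' Planes are written in canonical order (DAPI, CC3, GH2AX), so reading the
#' file back with the default [channel_map()] reproduces all pixel values
#' exactly.
#'
#' @param field A [calibrated_field()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_field <- function(field, path) {
  stopifnot(inherits(field, "calibrated_field"))
  scale <- 2^field$bit_depth - 1
  planes <- lapply(field$channels, function(ch) {
    if (any(ch > scale)) stop("intensity exceeds the declared bit depth")
    ch / scale
  })
  tiff::writeTIFF(planes, path, bits.per.sample = field$bit_depth,
                  compression = "none", reduce = FALSE)
  invisible(path)
}

#' Extract a fixed-size tile from a field
#'
#' Extracts a rectangular tile, the analysis unit used when pulling fields
#' out of whole-tissue scans (conventionally 1,000 x 1,000 pixels). The tile
#' must lie fully inside the field; out-of-bounds requests raise an error
#' rather than clipping silently.
#'
#' @param field A [calibrated_field()].
#' @param origin Integer pair `c(row, col)`, 1-based position of the tile's
#'   top-left pixel.
#' @param size_px Integer pair `c(rows, cols)`; default `c(1000, 1000)`.
#' @return A [calibrated_field()] with inherited calibration and group
#'   label.
#' @export
extract_tile <- function(field, origin = c(1L, 1L),
                         size_px = c(1000L, 1000L)) {
  stopifnot(inherits(field, "calibrated_field"))
  origin <- as.integer(origin); size_px <- as.integer(size_px)
  if (length(origin) != 2L || length(size_px) != 2L || any(size_px < 1L))
    stop("origin and size_px must be integer pairs with positive sizes")
  d <- field_dim(field)
  end <- origin + size_px - 1L
  if (any(origin < 1L) || any(end > d))
    stop(sprintf(
      "tile out of bounds: rows %d..%d, cols %d..%d requested from a %d x %d field",
      origin[1], end[1], origin[2], end[2], d[1], d[2]))
  channels <- lapply(field$channels,
                     function(ch) ch[origin[1]:end[1], origin[2]:end[2],
                                     drop = FALSE])
  calibrated_field(channels, field$microns_per_pixel,
                   field_id = sprintf("%s_tile_r%d_c%d", field$field_id,
                                      origin[1], origin[2]),
                   bit_depth = field$bit_depth, source = field$source,
                   group_label = field$group_label)
}

# Columns of the per-cell table, in stable output order.
CELL_TABLE_COLUMNS <- c(
  "field_id", "cell_label", "nuclear_area_um2", "ring_area_um2",
  "evaluable", "cyto_cc3_mean", "cyto_cc3_pos", "puncta_count",
  "cc3_bleb_pos", "gh2ax_mean", "gh2ax_pos", "coloc_pos")

#' Write a per-cell table to CSV
#'
#' Writes the per-cell call table with a stable column order and full
#' double precision, so that [read_cell_table()] reproduces the table
#' exactly (numeric columns round-trip bit-exactly via 17-significant-digit
#' formatting).
#'
#' @param table Data frame with the columns listed in
#'   `blebquant:::CELL_TABLE_COLUMNS`; `(field_id, cell_label)` must be
#'   unique and areas positive.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(table, path) {
  miss <- setdiff(CELL_TABLE_COLUMNS, names(table))
  if (length(miss)) stop("cell table is missing columns: ",
                         paste(miss, collapse = ", "))
  table <- table[, CELL_TABLE_COLUMNS, drop = FALSE]
  if (nrow(table)) {
    if (anyDuplicated(table[, c("field_id", "cell_label")]))
      stop("(field_id, cell_label) pairs must be unique")
    if (any(!is.finite(table$nuclear_area_um2)) ||
        any(table$nuclear_area_um2 <= 0))
      stop("nuclear areas must be positive")
  }
  out <- table
  for (nm in names(out)) {
    if (is.double(out[[nm]])) out[[nm]] <- sprintf("%.17g", out[[nm]])
  }
  write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a per-cell table written by [write_cell_table()]
#' @param path CSV path.
#' @return Data frame with typed columns.
#' @export
read_cell_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  for (nm in c("nuclear_area_um2", "ring_area_um2", "cyto_cc3_mean",
               "gh2ax_mean"))
    tab[[nm]] <- as.numeric(tab[[nm]])
  for (nm in c("cell_label", "puncta_count"))
    tab[[nm]] <- as.integer(tab[[nm]])
  for (nm in c("evaluable", "cyto_cc3_pos", "cc3_bleb_pos", "gh2ax_pos",
               "coloc_pos"))
    tab[[nm]] <- as.logical(tab[[nm]])
  tab
}
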