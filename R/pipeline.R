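#' Read a run configuration from YAML
#'
#' A run configuration drives the whole assay: either a manifest of TIFF
#' fields with group labels, or a synthetic study specification; plus the
#' channel map, calibration, segmentation settings, ring-width policy,
#' spot parameters, thresholds, and the group contrasts to test.
#'
#' @param path Path to a YAML configuration file.
#' @return List of class `run_config`.
#' @seealso [validate_config()], [run_assay()]; a packaged example lives at
#'   `system.file("extdata", "study_demo.yaml", package = "blebquant")`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  as_run_config(yaml::read_yaml(path))
}

#' Coerce a list to a run configuration (filling defaults)
#' @param cfg A named list with the fields described in [read_run_config()].
#' @return List of class `run_config`.
#' @export
as_run_config <- function(cfg) {
  defaults <- list(
    channel_map = list(DAPI = 1L, CC3 = 2L, GH2AX = 3L),
    microns_per_pixel = 0.4622,
    calibration_unit = "linear",
    segmentation = list(min_area_um2 = 50, max_area_um2 = 200,
                        smooth_sigma = 1, watershed_tolerance = 2),
    ring_width_um = "auto",
    spot = list(expected_spot_area_um2 = 0.9, min_spot_area_um2 = 0.2,
                max_spot_area_um2 = 5, min_puncta_per_cell = 2L),
    thresholds = list(cyto_cc3 = list(method = "mad", k = 6),
                      spot = list(method = "mad", k = 6),
                      gh2ax = list(method = "auto")),
    comparisons = list(),
    seed = 1L)
  # merge: nested parameter blocks merge by name; everything else (incl.
  # unnamed lists such as comparisons or manifest entries) replaces wholesale
  merged <- defaults
  for (nm in names(cfg)) {
    if (nm %in% c("segmentation", "spot", "thresholds", "channel_map") &&
        is.list(cfg[[nm]]))
      merged[[nm]] <- utils::modifyList(defaults[[nm]], cfg[[nm]])
    else merged[[nm]] <- cfg[[nm]]
  }
  cfg <- merged
  # the printed scan resolution of the reference instrument is ambiguous
  # between pixel area and linear pitch; both interpretations are supported
  if (identical(cfg$calibration_unit, "area"))
    cfg$microns_per_pixel <- sqrt(cfg$microns_per_pixel)
  class(cfg) <- "run_config"
  cfg
}

#' Validate a run configuration
#'
#' @param cfg A `run_config` (or plain list).
#' @return Character vector of violations; empty when the configuration is
#'   valid. Each message names the offending field.
#' @export
validate_config <- function(cfg) {
  if (!inherits(cfg, "run_config")) cfg <- as_run_config(cfg)
  v <- character(0)
  has_manifest <- !is.null(cfg$manifest)
  has_synth <- !is.null(cfg$synthetic)
  if (has_manifest == has_synth)
    v <- c(v, "exactly one of 'manifest' or 'synthetic' must be present")
  sp <- cfg$spot
  if (!(sp$min_spot_area_um2 < sp$expected_spot_area_um2 &&
        sp$expected_spot_area_um2 < sp$max_spot_area_um2))
    v <- c(v, "spot: areas must satisfy min_spot_area_um2 < expected_spot_area_um2 < max_spot_area_um2")
  if (!is.null(sp$min_puncta_per_cell) && sp$min_puncta_per_cell < 1)
    v <- c(v, "spot: min_puncta_per_cell must be >= 1")
  w <- cfg$ring_width_um
  if (!identical(w, "auto") && (!is.numeric(w) || w < 1 || w > 5))
    v <- c(v, "ring_width_um: must be 'auto' or a width within the [1, 5] micron bound")
  sg <- cfg$segmentation
  if (sg$min_area_um2 >= sg$max_area_um2)
    v <- c(v, "segmentation: min_area_um2 must be < max_area_um2")
  if (!is.numeric(cfg$microns_per_pixel) || cfg$microns_per_pixel <= 0)
    v <- c(v, "microns_per_pixel: must be positive")
  cm <- unlist(cfg$channel_map)
  if (!setequal(names(cm), CANONICAL_CHANNELS) || anyDuplicated(cm))
    v <- c(v, "channel_map: must map DAPI, CC3 and GH2AX to distinct plane indices")
  if (has_manifest) {
    for (entry in cfg$manifest) {
      if (is.null(entry$path) || !file.exists(entry$path))
        v <- c(v, paste0("manifest: missing input file ",
                         if (is.null(entry$path)) "<unset>" else entry$path))
      if (is.null(entry$group)) v <- c(v, "manifest: entry lacks a group label")
    }
  }
  if (has_synth) {
    syn <- cfg$synthetic
    if (is.null(syn$groups) || !length(syn$groups))
      v <- c(v, "synthetic: at least one group is required")
    if (!is.null(syn$fields_per_group) && syn$fields_per_group < 1)
      v <- c(v, "synthetic: fields_per_group must be >= 1")
    for (g in syn$groups) {
      chk <- tryCatch({
        do.call(synthetic_config,
                c(list(n_cells = g$n_cells %||% syn$base$n_cells %||% 100L),
                  syn_cfg_args(syn$base, g)))
        NULL
      }, error = function(e) conditionMessage(e))
      if (!is.null(chk)) v <- c(v, paste0("synthetic group '",
                                          g$label %||% "?", "': ", chk))
    }
  }
  for (cmp in cfg$comparisons) {
    if (is.null(cmp$group_a) || is.null(cmp$group_b) || is.null(cmp$metric))
      v <- c(v, "comparisons: each contrast needs group_a, group_b and metric")
    else if (!cmp$metric %in% c("pct_cyto_cc3", "pct_bleb", "pct_gh2ax",
                                "pct_coloc", "pct_gh2ax_of_which_bleb"))
      v <- c(v, paste0("comparisons: unknown metric ", cmp$metric))
  }
  v
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# merge base + per-group synthetic settings into synthetic_config arguments
syn_cfg_args <- function(base, group) {
  args <- utils::modifyList(base %||% list(), group)
  args$label <- NULL
  args$n_cells <- NULL
  known <- names(formals(synthetic_config))
  args[intersect(names(args), known)]
}

#' Analyse one calibrated field
#'
#' Runs the full single-field workflow: nuclear segmentation from DAPI,
#' area filtering, ring-width selection (automatic by default), exclusive
#' ring masks, marker classification (cytoplasmic CC3, CC3 blebbing via
#' puncta, nuclear gamma-H2AX, colocalization) and the per-field summary.
#'
#' @param field A [calibrated_field()].
#' @param cfg A `run_config` supplying parameters (a default config is
#'   used when omitted).
#' @return List: `calls` (per-cell table), `summary` (one-row
#'   [summarize_field()] output), `qc` (retained/excluded counts, selected
#'   ring width, resolved thresholds), or `NULL` with a warning when no
#'   nuclei survive filtering.
#' @export
analyze_field <- function(field, cfg = as_run_config(list())) {
  if (!inherits(cfg, "run_config")) cfg <- as_run_config(cfg)
  sg <- cfg$segmentation
  nmap <- segment_nuclei(field$channels$DAPI, field$microns_per_pixel,
                         segmentation_params(
                           smooth_sigma = sg$smooth_sigma %||% 1,
                           watershed_tolerance = sg$watershed_tolerance %||% 2))
  n_raw <- nmap$n
  nmap <- filter_nuclei_by_area(nmap, sg$min_area_um2, sg$max_area_um2)
  if (nmap$n == 0L) {
    warning("field ", field$field_id,
            " excluded: no nuclei within the area window")
    return(NULL)
  }
  w <- if (identical(cfg$ring_width_um, "auto"))
    auto_select_ring_width(nmap) else cfg$ring_width_um
  rings <- make_cytoplasm_rings(nmap, w)

  to_spec <- function(t) {
    if (identical(t$method, "absolute")) threshold_spec("absolute", value = t$value)
    else threshold_spec("mad", k = t$k %||% 6)
  }
  params <- spot_params(
    expected_spot_area_um2 = cfg$spot$expected_spot_area_um2,
    min_spot_area_um2 = cfg$spot$min_spot_area_um2,
    max_spot_area_um2 = cfg$spot$max_spot_area_um2,
    spot_intensity_threshold = to_spec(cfg$thresholds$spot),
    min_puncta_per_cell = cfg$spot$min_puncta_per_cell,
    bandpass = isTRUE(cfg$spot$bandpass))
  gh_thr <- if (identical(cfg$thresholds$gh2ax$method, "absolute"))
    cfg$thresholds$gh2ax$value else NULL

  calls <- call_cells(rings, nmap, field$channels$CC3, field$channels$GH2AX,
                      params = params,
                      cyto_threshold = to_spec(cfg$thresholds$cyto_cc3),
                      gh2ax_threshold = gh_thr)
  calls <- cbind(field_id = field$field_id, calls)
  summary <- summarize_field(calls, field$field_id,
                             field$group_label %||% NA_character_)
  list(calls = calls, summary = summary,
       qc = list(field_id = field$field_id, n_nuclei_raw = n_raw,
                 n_area_filtered = n_raw - nmap$n,
                 n_empty_ring = sum(!calls$evaluable),
                 ring_width_um = w))
}

#' Run the full assay from a configuration
#'
#' Orchestrates the end-to-end workflow (read or generate fields, segment,
#' build rings, call markers, summarise, compare groups) and writes the run
#' artifacts: `cells.csv` (per-cell calls), `field_summaries.csv`,
#' `comparisons.json`, `provenance.json` (config hash, seed, package
#' version) and `run_log.txt`. All outputs are deterministic for a fixed
#' configuration and seed.
#'
#' @param cfg A `run_config`, a plain list, or a path to a YAML file.
#' @param output_dir Output directory (created if needed); `NULL` analyses
#'   in memory without writing files.
#' @param seed Optional override of the configuration seed.
#' @return Invisibly, a list with `cells`, `summaries`, `comparisons`,
#'   `qc`, and `output_dir`.
#' @export
run_assay <- function(cfg, output_dir = NULL, seed = NULL) {
  if (is.character(cfg) && length(cfg) == 1L) cfg <- read_run_config(cfg)
  if (!inherits(cfg, "run_config")) cfg <- as_run_config(cfg)
  violations <- validate_config(cfg)
  if (length(violations))
    stop("invalid configuration:\n  - ",
         paste(violations, collapse = "\n  - "))
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  log_lines <- character(0)
  say <- function(...) log_lines <<- c(log_lines, sprintf(...))

  if (!is.null(cfg$synthetic)) {
    syn <- cfg$synthetic
    groups <- list()
    for (g in syn$groups) {
      args <- syn_cfg_args(syn$base, g)
      args$n_cells <- g$n_cells %||% syn$base$n_cells
      groups[[g$label]] <- do.call(synthetic_config, args)
    }
    say("generating synthetic study: %d group(s) x %d field(s), master seed %d",
        length(groups), syn$fields_per_group %||% 6L, cfg$seed)
    pairs <- generate_study(groups, syn$fields_per_group %||% 6L,
                            master_seed = cfg$seed)
    fields <- lapply(pairs, `[[`, "field")
  } else {
    cm <- unlist(cfg$channel_map)
    fields <- lapply(cfg$manifest, function(entry) {
      read_field(entry$path, map = channel_map(DAPI = cm[["DAPI"]],
                                               CC3 = cm[["CC3"]],
                                               GH2AX = cm[["GH2AX"]]),
                 microns_per_pixel = cfg$microns_per_pixel,
                 group_label = entry$group)
    })
    say("manifest: %d field(s) read", length(fields))
  }

  all_calls <- list(); all_sum <- list(); all_qc <- list()
  for (f in fields) {
    res <- analyze_field(f, cfg)
    if (is.null(res)) {
      say("field %s excluded from statistics: no retained nuclei",
          f$field_id)
      next
    }
    say("field %s: %d cells retained (%d raw, %d area-filtered, %d empty-ring), ring width %g um",
        f$field_id, res$summary$n_cells, res$qc$n_nuclei_raw,
        res$qc$n_area_filtered, res$qc$n_empty_ring, res$qc$ring_width_um)
    all_calls[[length(all_calls) + 1L]] <- res$calls
    all_sum[[length(all_sum) + 1L]] <- res$summary
    all_qc[[length(all_qc) + 1L]] <- res$qc
  }
  if (!length(all_sum)) stop("no field produced analysable cells")
  cells <- do.call(rbind, all_calls)
  summaries <- do.call(rbind, all_sum)
  comparisons <- if (length(cfg$comparisons))
    compare_groups(summaries, cfg$comparisons) else NULL

  result <- list(cells = cells, summaries = summaries,
                 comparisons = comparisons, qc = all_qc,
                 output_dir = output_dir)
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write_cell_table(cells, file.path(output_dir, "cells.csv"))
    sums_out <- summaries
    for (nm in names(sums_out))
      if (is.double(sums_out[[nm]]))
        sums_out[[nm]] <- sprintf("%.17g", sums_out[[nm]])
    write.csv(sums_out, file.path(output_dir, "field_summaries.csv"),
              row.names = FALSE)
    if (!is.null(comparisons))
      jsonlite::write_json(comparisons,
                           file.path(output_dir, "comparisons.json"),
                           dataframe = "rows", digits = NA, pretty = TRUE)
    cfg_plain <- unclass(cfg)
    cfg_json <- jsonlite::toJSON(cfg_plain, auto_unbox = TRUE, digits = NA)
    tf <- tempfile(); writeLines(cfg_json, tf)
    provenance <- list(config_md5 = unname(tools::md5sum(tf)),
                       seed = cfg$seed,
                       package = "blebquant",
                       version = as.character(packageVersion("blebquant")))
    unlink(tf)
    jsonlite::write_json(provenance,
                         file.path(output_dir, "provenance.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    writeLines(log_lines, file.path(output_dir, "run_log.txt"))
  }
  invisible(result)
}
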