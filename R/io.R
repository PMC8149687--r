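## File I/O: multi-page TIFF stacks, CSV contours / ellipses / ROIs / traces,
## JSON tracks / transforms / reports, YAML run configs, provenance records.

#' Read a multi-page TIFF stack
#'
#' Pages become frames in order (first page = frame 1); intensities are
#' returned as floating-point values in the stored range.
#'
#' @param path path to a single-channel multi-page TIFF.
#' @return numeric array (height x width x frames).
#' @export
readStack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (any(vapply(pages, function(p) length(dim(p)) > 2, logical(1))))
    stop("unsupported format: multi-channel or RGB TIFF")
  array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
}

#' Write a stack as multi-page 16-bit TIFF
#'
#' Values are clamped to [0, 65535] and rounded; the round trip through
#' \code{\link{readStack}} is lossless for integer-valued 16-bit data.
#'
#' @param stack numeric array (height x width x frames) or list of matrices.
#' @param path output path.
#' @export
writeStack <- function(stack, path) {
  stack <- asStack(stack)
  pages <- lapply(seq_len(dim(stack)[3]), function(t)
    pmin(pmax(round(stack[, , t]), 0), 65535) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read initialization ellipses
#'
#' CSV with columns cell_id, cx, cy, a, b, angle_deg (0-based pixel
#' coordinates; angle in degrees).
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
readEllipses <- function(path) {
  d <- read.csv(path)
  need <- c("cell_id", "cx", "cy", "a", "b")
  if (!all(need %in% names(d)))
    stop("ellipse file must have columns ", paste(need, collapse = ", "))
  if (!"angle_deg" %in% names(d)) d$angle_deg <- 0
  d
}

#' Write / read per-frame contour nodes as CSV
#'
#' Long format with columns frame, cell_id, layer ("cyt" or "nuc"),
#' node_index, x, y in 0-based pixel coordinates.
#'
#' @param tracks list of \linkS4class{CellTrack}.
#' @param path CSV path.
#' @export
writeContoursCSV <- function(tracks, path) {
  rows <- list()
  for (tr in tracks) {
    for (t in seq_along(tr@contours)) {
      cell <- tr@contours[[t]]
      layers <- if (is(cell, "DoubleContour"))
        list(cyt = cell@cytoplasm, nuc = cell@nucleus) else list(cyt = cell)
      for (ln in names(layers)) {
        g <- contourGeometry(layers[[ln]])
        rows[[length(rows) + 1]] <- data.frame(
          frame = t, cell_id = tr@cellId, layer = ln,
          node_index = seq_along(g$px) - 1L, x = g$px, y = g$py)
      }
    }
  }
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeContoursCSV
#' @export
readContoursCSV <- function(path) read.csv(path)

#' Write / read ROI polygons as CSV
#'
#' Columns roi_id, vertex_index, x, y (0-based pixels).
#'
#' @param rois list of ROIs (list(roi_id, vertices)).
#' @param path CSV path.
#' @export
writeROIsCSV <- function(rois, path) {
  rows <- lapply(rois, function(r)
    data.frame(roi_id = r$roi_id, vertex_index = seq_len(nrow(r$vertices)) - 1L,
               x = r$vertices[, 1], y = r$vertices[, 2]))
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeROIsCSV
#' @export
readROIsCSV <- function(path) {
  d <- read.csv(path)
  lapply(split(d, d$roi_id), function(g)
    list(roi_id = g$roi_id[1],
         vertices = cbind(g$x[order(g$vertex_index)],
                          g$y[order(g$vertex_index)])))
}

#' Serialize frame transforms to JSON
#'
#' @param transforms list of \linkS4class{FrameTransform}.
#' @param path JSON path.
#' @export
writeTransformsJSON <- function(transforms, path) {
  jsonlite::write_json(lapply(transforms, function(tf)
    list(model = tf@model, frames = tf@frames, rms = tf@rms,
         params = unclass(tf@params))), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

.runConfigKeys <- list(
  top = c("input", "mode", "energy", "descent", "scene", "output", "seed",
          "verbosity", "n_nodes"),
  energy = c("rho", "w_kappa", "w_area", "w_area_stab", "w_comp", "d_thresh",
             "area_min", "area_max", "margin_dc", "rho_guard", "smooth_sigma"),
  descent = c("initial_step", "step_up", "step_down", "max_iterations",
              "tolerance", "outer_sweeps"))

#' Read and validate a YAML run configuration
#'
#' Top-level keys: input, mode ("one_layer"/"double"), energy, descent,
#' scene, output, seed, verbosity, n_nodes.  The \code{energy:} and
#' \code{descent:} sections use the snake_case field names of
#' \code{\link{energyConfig}} and \code{\link{descentConfig}}.  Unknown keys
#' are rejected by name.
#'
#' @param path YAML path.
#' @return list with elements \code{raw}, \code{energy}
#'   (\code{\link{energyConfig}}), \code{descent}
#'   (\code{\link{descentConfig}}), plus the remaining top-level fields.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  bad <- setdiff(names(cfg), .runConfigKeys$top)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  toCamel <- function(x) gsub("_(\\w)", "\\U\\1", x, perl = TRUE)
  build <- function(section, keys, fn) {
    s <- cfg[[section]]
    if (is.null(s)) return(fn())
    bad <- setdiff(names(s), keys)
    if (length(bad))
      stop("unknown config key(s) in '", section, "': ",
           paste(bad, collapse = ", "))
    do.call(fn, setNames(s, toCamel(names(s))))
  }
  energy <- build("energy", .runConfigKeys$energy, energyConfig)
  descent <- build("descent", .runConfigKeys$descent, descentConfig)
  if (!is.null(cfg$mode) && !cfg$mode %in% c("one_layer", "double"))
    stop("config field 'mode' must be 'one_layer' or 'double'")
  c(list(raw = cfg, energy = energy, descent = descent),
    cfg[setdiff(names(cfg), c("energy", "descent"))])
}

#' Write a provenance record
#'
#' JSON sidecar with the tool version, seed, timestamp and an MD5 hash of the
#' run configuration, so identical config + seed can be verified to have
#' produced an output.
#'
#' @param outDir output directory.
#' @param configPath path of the config actually used (or NULL).
#' @param seed integer seed.
#' @export
writeProvenance <- function(outDir, configPath = NULL, seed = NA) {
  rec <- list(tool = "beastrack",
              version = as.character(packageVersion("beastrack")),
              seed = seed,
              config_md5 = if (!is.null(configPath))
                unname(tools::md5sum(configPath)) else NA,
              written = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(rec, file.path(outDir, "provenance.json"),
                       auto_unbox = TRUE)
  invisible(rec)
}
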