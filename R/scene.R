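#' Segmented scene
#'
#' A calibrated collection of membrane traces from one electron-microscopy
#' cross-section: closed MOM contours (one per mitochondrion) plus zero or
#' more ER membrane profiles, with scene-level metadata.
#'
#' @param traces list of [membrane_trace()] objects.
#' @param pixel_size_nm positive number; nm per pixel of the source image
#'   (default 1, matching 1 nm/px EM acquisition).  Trace coordinates are
#'   always stored in nm; the calibration is kept for provenance and
#'   rasterization.
#' @param scene_id,cell_id,group free-text metadata carried into output
#'   tables (`group` is the experimental condition, e.g. WT / KO).
#' @return An object of class `segmented_scene`.
#' @export
segmented_scene <- function(traces, pixel_size_nm = 1,
                            scene_id = "scene", cell_id = "", group = "") {
  if (is_membrane_trace(traces)) traces <- list(traces)
  if (!is.list(traces) || !all(vapply(traces, is_membrane_trace, logical(1))))
    stop("traces must be a list of membrane_trace objects")
  if (!is.numeric(pixel_size_nm) || length(pixel_size_nm) != 1L ||
      !is.finite(pixel_size_nm) || pixel_size_nm <= 0)
    stop("pixel_size_nm must be a positive number")
  open_mom <- vapply(traces, function(tr) tr$role == "MOM" && !tr$closed,
                     logical(1))
  if (any(open_mom))
    stop("MOM traces must be closed contours: ",
         paste(vapply(traces[open_mom], `[[`, "", "object_id"),
               collapse = ", "))
  structure(list(scene_id = as.character(scene_id),
                 cell_id = as.character(cell_id),
                 group = as.character(group),
                 pixel_size_nm = pixel_size_nm,
                 traces = traces),
            class = "segmented_scene")
}

#' @export
print.segmented_scene <- function(x, ...) {
  roles <- vapply(x$traces, `[[`, "", "role")
  cat(sprintf(
    "<segmented_scene '%s'> group='%s' cell='%s' %.3g nm/px, %d MOM + %d ER traces\n",
    x$scene_id, x$group, x$cell_id, x$pixel_size_nm,
    sum(roles == "MOM"), sum(roles == "ER")))
  invisible(x)
}

scene_traces <- function(scene, role) {
  scene$traces[vapply(scene$traces, `[[`, "", "role") == role]
}

.polyline_cols <- c("scene_id", "object_id", "role", "vertex_index",
                    "x", "y", "closed")

#' Read membrane traces from a polyline table
#'
#' Reads a CSV of manually traced membranes with columns `scene_id`,
#' `object_id`, `role` (MOM/ER), `vertex_index`, `x`, `y`, `closed` and an
#' optional `units` column (`"nm"` or `"px"`; pixel coordinates are
#' multiplied by `pixel_size_nm`).  Without a `units` column, `units`
#' applies to the whole file.
#'
#' @param path CSV file path.
#' @param pixel_size_nm calibration in nm per pixel.
#' @param units default coordinate units when the file has no `units`
#'   column: `"nm"` (default) or `"px"`.
#' @param cell_id,group scene metadata (not stored in the table).
#' @return A [segmented_scene()] if the file contains a single `scene_id`,
#'   otherwise a named list of scenes.
#' @export
read_polyline_table <- function(path, pixel_size_nm = 1, units = c("nm", "px"),
                                cell_id = "", group = "") {
  units <- match.arg(units)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.polyline_cols, names(df))
  if (length(missing_cols))
    stop("polyline table '", path, "' is missing columns: ",
         paste(missing_cols, collapse = ", "))
  if (!"units" %in% names(df)) df$units <- units
  bad_units <- setdiff(unique(df$units), c("nm", "px"))
  if (length(bad_units))
    stop("unknown units in polyline table: ", paste(bad_units, collapse = ", "))
  scenes <- lapply(split(df, df$scene_id), function(sd) {
    traces <- lapply(split(sd, sd$object_id), function(od) {
      od <- od[order(od$vertex_index), , drop = FALSE]
      role <- unique(od$role)
      if (length(role) != 1L || !role %in% c("MOM", "ER"))
        stop("object '", od$object_id[1L], "': unknown or inconsistent role '",
             paste(role, collapse = "/"), "'")
      xy <- cbind(od$x, od$y)
      if (!is.numeric(xy) || !all(is.finite(xy)))
        stop("object '", od$object_id[1L], "': non-finite coordinates")
      scale <- ifelse(od$units == "px", pixel_size_nm, 1)
      xy <- xy * scale
      closed <- unique(as.logical(od$closed))
      if (length(closed) != 1L || is.na(closed))
        stop("object '", od$object_id[1L], "': inconsistent 'closed' flag")
      membrane_trace(xy, role = role, closed = closed,
                     object_id = od$object_id[1L])
    })
    segmented_scene(unname(traces), pixel_size_nm = pixel_size_nm,
                    scene_id = sd$scene_id[1L], cell_id = cell_id,
                    group = group)
  })
  if (length(scenes) == 1L) scenes[[1L]] else scenes
}

#' Write a segmented scene to a polyline table
#'
#' Inverse of [read_polyline_table()]; coordinates are written in nm.
#'
#' @param scene a [segmented_scene()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_polyline_table <- function(scene, path) {
  stopifnot(inherits(scene, "segmented_scene"))
  rows <- lapply(scene$traces, function(tr) {
    data.frame(scene_id = scene$scene_id, object_id = tr$object_id,
               role = tr$role, vertex_index = seq_len(nrow(tr$vertices)),
               x = tr$vertices[, 1L], y = tr$vertices[, 2L],
               closed = tr$closed, units = "nm")
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
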