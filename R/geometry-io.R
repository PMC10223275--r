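# Geometry config I/O: the pixel->internal-coordinate map is fully
# determined by (rows, cols, ankle_pixel, axis_pixel, cell_size, side), so
# only those are serialized.

#' Write a foot geometry to a YAML config file
#' @param geometry a `foot_geometry`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_geometry <- function(geometry, path) {
  stopifnot(inherits(geometry, "foot_geometry"))
  yaml::write_yaml(list(side = geometry$side,
                        rows = geometry$rows, cols = geometry$cols,
                        ankle_pixel = as.numeric(geometry$ankle_pixel),
                        axis_pixel = as.numeric(geometry$axis_pixel),
                        cell_size = geometry$cell_size), path)
  invisible(path)
}

#' Read a foot geometry from a YAML config file
#' @param path config path.
#' @return a `foot_geometry`.
#' @export
read_geometry <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path),
                               call. = FALSE)
  o <- yaml::read_yaml(path)
  need <- c("side", "rows", "cols", "ankle_pixel", "axis_pixel", "cell_size")
  miss <- setdiff(need, names(o))
  if (length(miss))
    stop(sprintf("geometry config missing field(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  build_geometry(o$rows, o$cols, unlist(o$ankle_pixel),
                 unlist(o$axis_pixel), o$cell_size, o$side)
}
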