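# Gridded scalar fields (topography in nm, stiffness in kPa).

#' Construct a scalar map
#'
#' A `scalar_map` holds a gridded scalar field with its physical pixel size.
#' Rows index the slow scan axis (y), columns the fast axis (x); by
#' convention the anteroposterior (AP) axis of the egg chamber is aligned
#' with the fast axis.
#'
#' @param values numeric matrix (rows = y, columns = x, fast axis).
#' @param pixel_size physical pixel size in micrometres.
#' @param units `"nm"` (topography) or `"kPa"` (stiffness).
#' @param mask logical matrix of valid pixels; defaults to all finite values.
#' @return object of class `scalar_map`.
#' @export
scalar_map <- function(values, pixel_size, units = c("kPa", "nm"),
                       mask = NULL) {
  units <- match.arg(units)
  stopifnot(is.matrix(values), is.numeric(pixel_size), pixel_size > 0)
  if (is.null(mask)) mask <- is.finite(values)
  stopifnot(identical(dim(mask), dim(values)))
  structure(
    list(values = values, pixel_size = pixel_size, units = units,
         mask = mask, fast_axis = "x"),
    class = "scalar_map"
  )
}

#' @export
print.scalar_map <- function(x, ...) {
  v <- x$values[x$mask]
  cat(sprintf("<scalar_map> %d x %d px, %.3g um/px, units %s\n",
              nrow(x$values), ncol(x$values), x$pixel_size, x$units))
  cat(sprintf("  valid %d/%d, median %.4g, range [%.4g, %.4g]\n",
              sum(x$mask), length(x$mask), stats::median(v), min(v), max(v)))
  invisible(x)
}

#' @export
dim.scalar_map <- function(x) dim(x$values)

#' Map side length in micrometres (along x)
#' @param map a [scalar_map].
#' @return numeric scalar.
#' @export
map_size <- function(map) ncol(map$values) * map$pixel_size

#' @keywords internal
check_congruent <- function(a, b) {
  if (!identical(dim(a$values), dim(b$values)) ||
      abs(a$pixel_size - b$pixel_size) > 1e-9) {
    stop("maps are not congruent (dimensions or pixel size differ)")
  }
  invisible(TRUE)
}
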