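#' Categorized colour pattern raster
#'
#' A `colour_pattern` is the atomic phenotype object: a 2-D raster of
#' integer class codes (0 = background, then one code per declared colour
#' class in order), together with the ordered class table and the space the
#' raster lives in (`"native"` for as-photographed images, `"model"` for
#' rasters aligned into the common model frame).
#'
#' @param grid integer matrix of class codes.
#' @param classes ordered character vector of class names; the first entry
#'   must be `"background"`.
#' @param space `"native"` or `"model"`.
#' @return An object of class `colour_pattern`.
#' @export
colour_pattern <- function(grid, classes = cpm_classes(), space = "native") {
  stopifnot(is.matrix(grid))
  storage.mode(grid) <- "integer"
  if (classes[1] != "background")
    stop("first class must be 'background'")
  if (anyDuplicated(classes))
    stop("class names must be unique")
  bad <- grid < 0L | grid >= length(classes)
  if (any(bad, na.rm = TRUE) || anyNA(grid))
    stop("grid holds codes outside the declared class table")
  space <- match.arg(space, c("native", "model"))
  structure(list(grid = grid, classes = classes, space = space),
            class = "colour_pattern")
}

#' @export
print.colour_pattern <- function(x, ...) {
  tab <- tabulate(x$grid + 1L, nbins = length(x$classes))
  cat(sprintf("<colour_pattern> %dx%d (%s space)\n",
              nrow(x$grid), ncol(x$grid), x$space))
  cat(paste(sprintf("  %s: %d px", x$classes, tab), collapse = "\n"), "\n")
  invisible(x)
}

#' @export
dim.colour_pattern <- function(x) dim(x$grid)

#' @export
`==.colour_pattern` <- function(e1, e2) {
  identical(e1$classes, e2$classes) && identical(e1$grid, e2$grid)
}

#' Wing mask of a pattern
#'
#' Logical matrix: `TRUE` where the pattern is non-background.
#' @param pattern a [colour_pattern].
#' @return logical matrix.
#' @export
wing_mask <- function(pattern) pattern$grid > 0L

# code for a class name (0-based), with validation
class_code <- function(classes, name) {
  i <- match(name, classes)
  if (anyNA(i)) stop("unknown colour class: ", paste(name[is.na(i)], collapse = ", "))
  i - 1L
}
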