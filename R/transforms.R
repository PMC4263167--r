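#' Similarity transforms between wing images
#'
#' A similarity transform maps native (specimen) coordinates into model
#' coordinates as `model = s * R(theta) * native + t`, with coordinates
#' taken relative to the image centre `((dim - 1) / 2)`, x along columns,
#' y along rows (row-major, 0-based, origin top-left; positive `theta`
#' rotates x towards y).  `tx`, `ty` are in pixels, `theta` in degrees,
#' `s` a strictly positive isotropic scale.
#'
#' @param tx,ty translation in pixels.
#' @param theta rotation in degrees.
#' @param s isotropic scale factor (> 0).
#' @return A `similarity_transform` object.
#' @export
similarity_transform <- function(tx = 0, ty = 0, theta = 0, s = 1) {
  stopifnot(is.finite(tx), is.finite(ty), is.finite(theta), is.finite(s))
  if (s <= 0) stop("scale must be > 0")
  structure(list(tx = tx, ty = ty, theta = theta, s = s),
            class = "similarity_transform")
}

#' @export
print.similarity_transform <- function(x, ...) {
  cat(sprintf("<similarity_transform> t=(%.3f, %.3f) px, theta=%.3f deg, s=%.4f\n",
              x$tx, x$ty, x$theta, x$s))
  invisible(x)
}

#' Compose two similarity transforms
#'
#' `tf_compose(b, a)` returns the transform applying `a` first, then `b`.
#' @param b,a similarity transforms.
#' @return the composed `similarity_transform`.
#' @export
tf_compose <- function(b, a) {
  th <- b$theta * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  t2 <- b$s * R %*% c(a$tx, a$ty) + c(b$tx, b$ty)
  similarity_transform(t2[1], t2[2], a$theta + b$theta, a$s * b$s)
}

#' Invert a similarity transform
#' @param tf a similarity transform.
#' @return the inverse `similarity_transform`.
#' @export
tf_invert <- function(tf) {
  th <- -tf$theta * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  t2 <- -(R %*% c(tf$tx, tf$ty)) / tf$s
  similarity_transform(t2[1], t2[2], -tf$theta, 1 / tf$s)
}

#' Apply a similarity transform to a pattern raster
#'
#' Resamples the pattern onto an output grid by nearest-neighbour lookup
#' (class labels are categorical, so no blending).  Output pixels whose
#' source falls outside the input raster are set to background.
#'
#' @param pattern a [colour_pattern].
#' @param tf the `similarity_transform` mapping the pattern into the output
#'   frame.
#' @param dim_out output dimensions `c(rows, cols)`; default same as input.
#' @param space space label for the result.
#' @param vote supersampling factor for area-majority resampling: each
#'   output pixel takes the modal class over `vote^2` subpixel samples
#'   (ties to the class declared earlier).  `vote = 1` is plain
#'   nearest-neighbour; higher values reduce boundary re-quantization
#'   jitter when rasters are resampled repeatedly.
#' @return a [colour_pattern] in the output frame.  The attribute
#'   `"in_bounds"` holds the logical matrix of pixels whose source was
#'   inside the input raster (used for model support counting).
#' @export
tf_apply <- function(pattern, tf, dim_out = dim(pattern$grid), space = "model",
                     vote = 1) {
  g <- cpm_resample_vote(pattern$grid, tf$tx, tf$ty, tf$theta * pi / 180, tf$s,
                         dim_out[1], dim_out[2], -1L,
                         length(pattern$classes), as.integer(vote))
  inb <- g >= 0L
  g[!inb] <- 0L
  out <- colour_pattern(g, pattern$classes, space)
  attr(out, "in_bounds") <- inb
  out
}
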