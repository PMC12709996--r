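## Image preparation: clearest-frame selection from video, head cropping,
## and quality filtering of small crops. Images are numeric matrices
## (grayscale, H x W) or H x W x 3 arrays with values in [0, 1].

#' Convert an RGB array to luminance
#'
#' Rec. 601 weights (0.299 R + 0.587 G + 0.114 B). Grayscale input is
#' returned unchanged.
#'
#' @param image Numeric matrix or H x W x 3 array.
#' @return Numeric matrix.
#' @export
rgb_to_luminance <- function(image) {
  if (is.matrix(image)) return(image)
  abort_if(length(dim(image)) != 3 || dim(image)[3] < 3,
           "expected a matrix or an H x W x 3 array")
  0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
}

#' Sharpness score by Laplacian variance
#'
#' Variance of the response of the 4-neighbour Laplacian kernel
#' `[[0,1,0],[1,-4,1],[0,1,0]]` over the valid interior of the image
#' (no padding). Higher means sharper. Colour images are converted to
#' luminance first.
#'
#' @param image Numeric matrix (or RGB array) at least 3 x 3.
#' @return Non-negative scalar score.
#' @export
laplacian_variance <- function(image) {
  g <- rgb_to_luminance(image)
  h <- nrow(g); w <- ncol(g)
  abort_if(h < 3 || w < 3, "image smaller than the 3x3 Laplacian kernel (",
           h, "x", w, ")")
  core <- g[2:(h - 1), 2:(w - 1), drop = FALSE]
  lap <- g[1:(h - 2), 2:(w - 1), drop = FALSE] +
         g[3:h,       2:(w - 1), drop = FALSE] +
         g[2:(h - 1), 1:(w - 2), drop = FALSE] +
         g[2:(h - 1), 3:w,       drop = FALSE] - 4 * core
  stats::var(as.vector(lap))
}

#' Select the clearest frame per second of video
#'
#' Frames are grouped into whole-or-partial seconds by
#' `floor(index / fps)`; within each group the frame with the highest
#' [laplacian_variance()] is kept (earliest frame wins ties). Output
#' preserves temporal order.
#'
#' @param frames List of image matrices/arrays, in temporal order.
#' @param fps Frames per second, `>= 1`.
#' @return List of selected frames with attribute `selected_indices`.
#' @export
select_clearest_per_second <- function(frames, fps = 30) {
  abort_if(length(frames) == 0, "empty frame set")
  abort_if(!is_scalar_number(fps) || fps < 1, "fps must be a number >= 1")
  group <- floor((seq_along(frames) - 1) / fps)
  scores <- vapply(frames, laplacian_variance, numeric(1))
  keep <- vapply(split(seq_along(frames), group),
                 function(idx) idx[which.max(scores[idx])],
                 integer(1))
  keep <- unname(sort(keep))
  out <- frames[keep]
  attr(out, "selected_indices") <- keep
  out
}

#' Crop a head region from an image
#'
#' Pixel-exact extraction of the half-open box `[x0, x1) x [y0, y1)`
#' (0-based, x = column, y = row).
#'
#' @param image Image matrix or array.
#' @param box Numeric vector or list with `x0, y0, x1, y1`.
#' @return The cropped image, with attributes `width` and `height`.
#' @export
crop_head <- function(image, box) {
  b <- as.list(box)
  x0 <- b$x0; y0 <- b$y0; x1 <- b$x1; y1 <- b$y1
  h <- dim(image)[1]; w <- dim(image)[2]
  abort_if(is.null(x0) || is.null(y0) || is.null(x1) || is.null(y1),
           "box must provide x0, y0, x1, y1")
  abort_if(x1 <= x0 || y1 <= y0, "degenerate crop box (x0=", x0, ", y0=", y0,
           ", x1=", x1, ", y1=", y1, ")")
  abort_if(x0 < 0 || y0 < 0 || x1 > w || y1 > h,
           "crop box (", x0, ",", y0, ",", x1, ",", y1,
           ") outside image bounds ", w, "x", h)
  rows <- (y0 + 1):y1
  cols <- (x0 + 1):x1
  out <- if (is.matrix(image)) image[rows, cols, drop = FALSE]
         else image[rows, cols, , drop = FALSE]
  attr(out, "width") <- x1 - x0
  attr(out, "height") <- y1 - y0
  out
}

#' Remove crops smaller than a minimum size
#'
#' Keeps crops whose width and height are both at least the minima
#' (a crop exactly at the threshold survives; the rule removes images
#' *smaller than* `min_w x min_h`). Order is preserved.
#'
#' @param crops List of cropped images.
#' @param min_w,min_h Minimum width and height in pixels; defaults 20 and 50.
#' @return Surviving crops, with attribute `n_removed`.
#' @export
filter_small_crops <- function(crops, min_w = 20, min_h = 50) {
  if (length(crops) == 0) {
    out <- crops
    attr(out, "n_removed") <- 0L
    return(out)
  }
  ok <- vapply(crops, function(cr) {
    w <- attr(cr, "width") %||% dim(cr)[2]
    h <- attr(cr, "height") %||% dim(cr)[1]
    w >= min_w && h >= min_h
  }, logical(1))
  out <- crops[ok]
  attr(out, "n_removed") <- sum(!ok)
  if (sum(!ok) > 0) {
    message(sum(!ok), " crop(s) below ", min_w, "x", min_h, " removed")
  }
  out
}

#' Bilinear image resize
#'
#' Resamples a grayscale matrix (or each channel of an RGB array) to the
#' target size with bilinear interpolation; used to bring crops to the
#' backbone's input resolution.
#'
#' @param image Image matrix or H x W x 3 array.
#' @param height,width Target size in pixels.
#' @return Resized image of the requested size.
#' @export
resize_image <- function(image, height, width = height) {
  abort_if(height < 1 || width < 1, "target size must be >= 1")
  one <- function(m) {
    h <- nrow(m); w <- ncol(m)
    if (h == height && w == width) return(m)
    yy <- if (height == 1) rep((h + 1) / 2, 1) else seq(1, h, length.out = height)
    xx <- if (width == 1) rep((w + 1) / 2, 1) else seq(1, w, length.out = width)
    y0 <- pmin(floor(yy), h - 1); x0 <- pmin(floor(xx), w - 1)
    fy <- yy - y0; fx <- xx - x0
    a <- m[y0, x0, drop = FALSE]; b <- m[y0 + 1, x0, drop = FALSE]
    c_ <- m[y0, x0 + 1, drop = FALSE]; d <- m[y0 + 1, x0 + 1, drop = FALSE]
    wy <- matrix(fy, height, width); wx <- matrix(fx, height, width, byrow = TRUE)
    a * (1 - wy) * (1 - wx) + b * wy * (1 - wx) + c_ * (1 - wy) * wx + d * wy * wx
  }
  if (is.matrix(image)) return(one(image))
  out <- array(0, c(height, width, dim(image)[3]))
  for (k in seq_len(dim(image)[3])) out[, , k] <- one(image[, , k])
  out
}
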