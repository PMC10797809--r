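#' RGB image container
#'
#' A height x width x 3 integer array of 8-bit channel intensities
#' (0-255) with a recorded channel order. Channel permutations and
#' mirrors are pure reindexing operations on this container and are
#' bitwise-lossless; resizing and rotation interpolate.
#'
#' @param pixels Numeric array `h x w x 3`, values in \[0, 255\] (values in
#'   \[0, 1\] as produced by PNG readers are accepted and rescaled).
#' @param channel_order `"RGB"`, `"RBG"` or `"BGR"`.
#' @return An `rgb_img` object.
#' @export
rgb_image <- function(pixels, channel_order = "RGB") {
  if (!is.array(pixels) || length(dim(pixels)) != 3 || dim(pixels)[3] != 3) {
    abort("pixels must be a height x width x 3 array.",
          class = "evidfuse_image_error")
  }
  if (any(dim(pixels)[1:2] == 0)) {
    abort("Image has a zero dimension.", class = "evidfuse_image_error")
  }
  if (!all(is.finite(pixels))) {
    abort("Image contains non-finite values.", class = "evidfuse_image_error")
  }
  mx <- max(pixels)
  if (min(pixels) < 0 || mx > 255) {
    abort("Channel intensities must lie in [0, 255].",
          class = "evidfuse_image_error")
  }
  if (mx <= 1 && !is.integer(pixels)) pixels <- pixels * 255
  storage <- array(as.integer(round(pixels)), dim = dim(pixels))
  channel_order <- match.arg(channel_order, c("RGB", "RBG", "BGR"))
  structure(storage, channel_order = channel_order,
            class = c("rgb_img", "array"))
}

#' @export
print.rgb_img <- function(x, ...) {
  d <- dim(x)
  cat("<rgb_img> ", d[1], " x ", d[2], " x 3, channel order ",
      attr(x, "channel_order"), "\n", sep = "")
  invisible(x)
}

reclass_img <- function(pixels, template, channel_order = NULL) {
  structure(array(as.integer(pixels), dim = dim(pixels)),
            channel_order = channel_order %||% attr(template, "channel_order"),
            class = c("rgb_img", "array"))
}

# rgb_img (h x w x 3, 0-255) <-> EBImage Image (w x h x 3, 0-1)
to_ebimage <- function(img) {
  EBImage::Image(aperm(unclass(img), c(2, 1, 3)) / 255, colormode = "Color")
}

from_ebimage <- function(e, template) {
  px <- pmin(pmax(aperm(EBImage::imageData(e), c(2, 1, 3)), 0), 1)
  reclass_img(round(px * 255), template)
}

#' Resize an image to a square target
#'
#' Direct rescale of both axes to `size x size` (no cropping; aspect ratio
#' is not preserved), by bilinear interpolation. Squaring fundus images to
#' a fixed side keeps network input small while retaining the optic-disc
#' region where pathology concentrates.
#'
#' @param img An [rgb_image()].
#' @param size Target side length in pixels (default 512).
#' @return An `rgb_img` of dimension `size x size x 3`.
#' @export
img_resize <- function(img, size = 512) {
  img <- as_rgb_image(img)
  if (size < 1) abort("size must be positive.", class = "evidfuse_image_error")
  from_ebimage(EBImage::resize(to_ebimage(img), w = size, h = size), img)
}

#' Channel permutation, mirroring and rotation
#'
#' `img_permute()` reorders the colour planes (RGB -> RBG swaps green and
#' blue; RGB -> BGR reverses). Permutation changes the brightness and
#' contrast of the rendered image but not its structure: each per-plane
#' histogram is preserved exactly and the operation is bitwise-invertible.
#' `img_mirror()` reverses one axis (`"horizontal"` flips left-right,
#' `"vertical"` flips top-bottom), also bitwise-invertible.
#' `img_rotate()` rotates about the image centre by `angle` degrees
#' (drawn uniformly from \[-180, 180) via the session RNG when `NULL`),
#' bilinear, keeping the original dimensions and filling exposed corners
#' with black; rotation interpolates and is not invertible.
#'
#' @param img An [rgb_image()].
#' @param order Target channel order, `"RBG"` or `"BGR"`.
#' @return An `rgb_img`.
#' @export
img_permute <- function(img, order = c("RBG", "BGR")) {
  img <- as_rgb_image(img)
  order <- rlang::arg_match(order)
  perm <- switch(order, RBG = c(1, 3, 2), BGR = c(3, 2, 1))
  reclass_img(unclass(img)[, , perm, drop = FALSE], img, channel_order = order)
}

#' @rdname img_permute
#' @param axis `"horizontal"` (left-right) or `"vertical"` (top-bottom).
#' @export
img_mirror <- function(img, axis = c("horizontal", "vertical")) {
  img <- as_rgb_image(img)
  axis <- rlang::arg_match(axis)
  px <- unclass(img)
  px <- switch(axis,
               horizontal = px[, rev(seq_len(dim(px)[2])), , drop = FALSE],
               vertical = px[rev(seq_len(dim(px)[1])), , , drop = FALSE])
  reclass_img(px, img)
}

#' @rdname img_permute
#' @param angle Rotation angle in degrees; `NULL` draws uniformly from
#'   \[-180, 180). Seed the session RNG for reproducibility.
#' @export
img_rotate <- function(img, angle = NULL) {
  img <- as_rgb_image(img)
  if (is.null(angle)) angle <- runif(1, -180, 180)
  d <- dim(img)
  e <- EBImage::rotate(to_ebimage(img), angle, bg.col = "black",
                       output.dim = c(d[2], d[1]))
  from_ebimage(e, img)
}

as_rgb_image <- function(img) {
  if (inherits(img, "rgb_img")) img else rgb_image(img)
}

#' Sixfold augmentation of one image
#'
#' Expands one image into six: the original plus five label-preserving
#' transforms -- a random rotation, a horizontal mirror, a vertical
#' mirror, and the RBG and BGR channel permutations. This is the
#' composition under which a dataset grows exactly sixfold (e.g. 5258
#' images become 31,548). Deterministic when the session RNG is seeded
#' (only the rotation draws randomness).
#'
#' @param img An [rgb_image()].
#' @return A named list of six `rgb_img`s:
#'   `original`, `rotated`, `mirror_h`, `mirror_v`, `rbg`, `bgr`.
#' @examples
#' set.seed(1)
#' length(augment_sixfold(gen_image(16, 16, seed = 1)))
#' @export
augment_sixfold <- function(img) {
  img <- as_rgb_image(img)
  list(original = img,
       rotated = img_rotate(img),
       mirror_h = img_mirror(img, "horizontal"),
       mirror_v = img_mirror(img, "vertical"),
       rbg = img_permute(img, "RBG"),
       bgr = img_permute(img, "BGR"))
}

#' Output count of sixfold augmentation
#'
#' Bookkeeping for dataset expansion: `n` input images yield `6 * n`
#' augmented images.
#'
#' @param n_images Number of input images.
#' @return Integer count of augmented outputs.
#' @examples
#' augmented_count(5258)  # 31548
#' @export
augmented_count <- function(n_images) {
  stopifnot(n_images >= 0)
  6L * as.integer(n_images)
}

#' Read / write images
#'
#' PNG via the png package; JPEG via the jpeg package when installed.
#' Alpha channels are dropped on read.
#'
#' @param path File path; format chosen by extension (`.png`, `.jpg`,
#'   `.jpeg`).
#' @return `read_image()`: an `rgb_img`. `write_image()` returns `path`
#'   invisibly (always writes PNG content for `.png`, JPEG otherwise).
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  px <- if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("jpg", "jpeg")) {
    if (!requireNamespace("jpeg", quietly = TRUE)) {
      abort("Reading JPEG requires the 'jpeg' package.",
            class = "evidfuse_image_error")
    }
    jpeg::readJPEG(path)
  } else {
    abort(paste0("Unsupported image extension: .", ext),
          class = "evidfuse_image_error")
  }
  if (length(dim(px)) == 2) px <- array(rep(px, 3), c(dim(px), 3))
  if (dim(px)[3] == 4) px <- px[, , 1:3, drop = FALSE]
  rgb_image(px * 255)
}

#' @rdname read_image
#' @param img An `rgb_img`.
#' @export
write_image <- function(img, path) {
  img <- as_rgb_image(img)
  px <- unclass(img) / 255
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(px, path)
  } else if (ext %in% c("jpg", "jpeg")) {
    if (!requireNamespace("jpeg", quietly = TRUE)) {
      abort("Writing JPEG requires the 'jpeg' package.",
            class = "evidfuse_image_error")
    }
    jpeg::writeJPEG(px, path, quality = 0.95)
  } else {
    abort(paste0("Unsupported image extension: .", ext),
          class = "evidfuse_image_error")
  }
  invisible(path)
}
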