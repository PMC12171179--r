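## Image input/output and geometric region masks.
##
## Images are handled throughout the package as numeric arrays of shape
## H x W x 3 (rows = image rows), channel order RGB, values on the 0-255
## scale. Decoding and resizing go through EBImage, which supports both PNG
## and JPEG; EBImage stores rasters transposed (width first), so readers and
## writers transpose explicitly.

#' Read an RGB image into an H x W x 3 array
#'
#' @param path PNG or JPEG file.
#' @param size optional `c(H, W)` target size; when given, the decoded image
#'   is resized with bilinear interpolation.
#' @return numeric array `H x W x 3`, values in 0-255.
#' @export
read_image <- function(path, size = NULL) {
  assert_that(file.exists(path), "image file not found: ", path)
  img <- tryCatch(EBImage::readImage(path),
                  error = function(e) stop_cadfuse("cannot decode image ", path, ": ",
                                                   conditionMessage(e)))
  a <- as.array(img)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3L), c(dim(a), 3L))
  if (dim(a)[3] == 4L) a <- a[, , 1:3, drop = FALSE]  # drop alpha
  if (!is.null(size)) {
    assert_that(length(size) == 2L && all(size >= 2), "invalid image size")
    a <- as.array(EBImage::resize(EBImage::Image(a, colormode = "Color"),
                                  w = size[2], h = size[1], filter = "bilinear"))
  }
  ## EBImage axis order is (x = column, y = row, channel)
  out <- aperm(a, c(2, 1, 3)) * 255
  out[out < 0] <- 0; out[out > 255] <- 255
  out
}

#' Write an H x W x 3 array (0-255) as a PNG file
#'
#' @param img numeric array `H x W x 3`, values 0-255.
#' @param path output path.
#' @export
write_image <- function(img, path) {
  assert_that(length(dim(img)) == 3L && dim(img)[3] == 3L, "expected H x W x 3 array")
  x <- img / 255
  x[x < 0] <- 0; x[x > 1] <- 1
  png::writePNG(x, path)
  invisible(path)
}

## bilinear resize of a single-channel matrix (used for CAM upsampling)
bilinear_resize <- function(m, H, W) {
  h0 <- nrow(m); w0 <- ncol(m)
  if (h0 == H && w0 == W) return(m)
  ## map output pixel centres into input coordinates
  ry <- (seq_len(H) - 0.5) * h0 / H + 0.5
  rx <- (seq_len(W) - 0.5) * w0 / W + 0.5
  y0 <- pmin(pmax(floor(ry), 1), h0); y1 <- pmin(y0 + 1, h0)
  x0 <- pmin(pmax(floor(rx), 1), w0); x1 <- pmin(x0 + 1, w0)
  fy <- pmin(pmax(ry - y0, 0), 1);    fx <- pmin(pmax(rx - x0, 0), 1)
  a <- m[y0, x0, drop = FALSE]; b <- m[y0, x1, drop = FALSE]
  c_ <- m[y1, x0, drop = FALSE]; d <- m[y1, x1, drop = FALSE]
  top <- a * outer(rep(1, H), 1 - fx) + b * outer(rep(1, H), fx)
  bot <- c_ * outer(rep(1, H), 1 - fx) + d * outer(rep(1, H), fx)
  top * outer(1 - fy, rep(1, W)) + bot * outer(fy, rep(1, W))
}

ellipse_mask <- function(H, W, cy, cx, ry, rx) {
  yy <- matrix(seq_len(H), H, W)
  xx <- matrix(seq_len(W), H, W, byrow = TRUE)
  ((yy - cy) / ry)^2 + ((xx - cx) / rx)^2 <= 1
}

#' Tongue and tongue-coating region masks
#'
#' Fixed geometric masks, relative to image size: the tongue body is a large
#' ellipse in the lower-central part of the frame and the coating region is a
#' smaller central-upper ellipse on the tongue surface. The same masks are
#' used by the synthetic generator to plant class signal and by the image
#' summary-feature extractor.
#'
#' @param H,W image height and width in pixels.
#' @return list of logical `H x W` matrices `tongue` and `coating`.
#' @export
tongue_region_masks <- function(H, W) {
  tongue  <- ellipse_mask(H, W, cy = 0.58 * H, cx = 0.50 * W,
                          ry = 0.36 * H, rx = 0.30 * W)
  coating <- ellipse_mask(H, W, cy = 0.46 * H, cx = 0.50 * W,
                          ry = 0.17 * H, rx = 0.18 * W)
  list(tongue = tongue, coating = coating & tongue)
}

#' Facial region masks (forehead, nose, cheeks)
#'
#' Fixed geometric masks for the facial regions carrying class signal in the
#' synthetic cohort and summarised by the image feature extractor: the
#' frontal (forehead), nasal and left/right zygomatic (cheek) regions of an
#' idealised face centred in the frame.
#'
#' @param H,W image height and width in pixels.
#' @return list of logical `H x W` matrices `face`, `forehead`, `nose`,
#'   `cheek_left`, `cheek_right`.
#' @export
face_region_masks <- function(H, W) {
  face <- ellipse_mask(H, W, cy = 0.52 * H, cx = 0.50 * W,
                       ry = 0.42 * H, rx = 0.32 * W)
  forehead <- ellipse_mask(H, W, cy = 0.28 * H, cx = 0.50 * W,
                           ry = 0.12 * H, rx = 0.22 * W) & face
  nose <- ellipse_mask(H, W, cy = 0.55 * H, cx = 0.50 * W,
                       ry = 0.14 * H, rx = 0.07 * W) & face
  cheek_left <- ellipse_mask(H, W, cy = 0.58 * H, cx = 0.32 * W,
                             ry = 0.10 * H, rx = 0.09 * W) & face
  cheek_right <- ellipse_mask(H, W, cy = 0.58 * H, cx = 0.68 * W,
                              ry = 0.10 * H, rx = 0.09 * W) & face
  list(face = face, forehead = forehead, nose = nose,
       cheek_left = cheek_left, cheek_right = cheek_right)
}

## mean hue (degrees, 0-360) of masked pixels of an H x W x 3 image (0-255);
## circular mean so hue wrap-around is handled
mask_mean_hue <- function(img, mask) {
  px <- rbind(img[, , 1][mask], img[, , 2][mask], img[, , 3][mask])
  hsv <- grDevices::rgb2hsv(px, maxColorValue = 255)
  ang <- hsv[1, ] * 2 * pi
  (atan2(mean(sin(ang)), mean(cos(ang))) %% (2 * pi)) * 180 / pi
}

mask_mean_intensity <- function(img, mask) {
  mean((img[, , 1][mask] + img[, , 2][mask] + img[, , 3][mask]) / 3)
}
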