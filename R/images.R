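## Low-level image utilities shared by every stage.
##
## Images are plain numeric matrices, [row = y, col = x], holding 16-bit
## grayscale counts (0..65535).  Pixel coordinates reported to callers are
## 0-based, (x, y), with (0, 0) the centre of the top-left pixel; conversion
## to R's 1-based matrix indices happens only at indexing sites.

#' Validate a grayscale image matrix
#'
#' @param img object to check.
#' @param what name used in error messages.
#' @return the image, invisibly.
#' @keywords internal
check_image <- function(img, what = "image") {
  if (!is.matrix(img) || !is.numeric(img)) {
    stop(sprintf("%s must be a numeric matrix", what), call. = FALSE)
  }
  if (anyNA(img)) stop(sprintf("%s contains NA pixels", what), call. = FALSE)
  invisible(img)
}

#' Clamp pixel values to the 16-bit range
#' @param img numeric matrix.
#' @return matrix with values in [0, 65535].
#' @keywords internal
clamp16 <- function(img) {
  img[img < 0] <- 0
  img[img > 65535] <- 65535
  img
}

## replicate-pad by one pixel on every side
pad1 <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(0, nr + 2L, nc + 2L)
  out[2:(nr + 1L), 2:(nc + 1L)] <- img
  out[1L, ] <- out[2L, ]; out[nr + 2L, ] <- out[nr + 1L, ]
  out[, 1L] <- out[, 2L]; out[, nc + 2L] <- out[, nc + 1L]
  out
}

## the nine 1-pixel shifts of a padded image, as a list of matrices
shift9 <- function(img) {
  p <- pad1(img)
  nr <- nrow(img); nc <- ncol(img)
  lapply(seq_len(9L) - 1L, function(k) {
    dr <- k %% 3L; dc <- k %/% 3L
    p[(1L + dr):(nr + dr), (1L + dc):(nc + dc)]
  })
}

#' 3x3 median filter
#'
#' Vectorised Paeth median-of-nine sorting network with edge replication;
#' exact on integer counts (no rescaling round-trip).
#'
#' @param img numeric matrix.
#' @return filtered matrix, same shape.
#' @export
median3x3 <- function(img) {
  check_image(img)
  if (length(img) == 1L) return(img)
  p <- shift9(img)
  swap <- function(i, j) {
    lo <- pmin(p[[i]], p[[j]]); hi <- pmax(p[[i]], p[[j]])
    p[[i]] <<- lo; p[[j]] <<- hi
  }
  ## 19-exchange median-of-9 sorting network (indices 1-based)
  swap(2, 3); swap(5, 6); swap(8, 9)
  swap(1, 2); swap(4, 5); swap(7, 8)
  swap(2, 3); swap(5, 6); swap(8, 9)
  swap(1, 4); swap(6, 9); swap(5, 8)
  swap(4, 7); swap(2, 5); swap(3, 6)
  swap(5, 8); swap(5, 3); swap(7, 5)
  swap(5, 3)
  p[[5]]
}

#' 3x3 Laplacian filter
#'
#' Kernel 4*centre - N - S - E - W with replicated edges; exact integer
#' arithmetic (no FFT).
#'
#' @param img numeric matrix.
#' @return response matrix, same shape (can be negative).
#' @export
laplacian3x3 <- function(img) {
  check_image(img)
  nr <- nrow(img); nc <- ncol(img)
  p <- pad1(img)
  4 * img -
    p[1:nr, 2:(nc + 1L)] - p[3:(nr + 2L), 2:(nc + 1L)] -
    p[2:(nr + 1L), 1:nc] - p[2:(nr + 1L), 3:(nc + 2L)]
}

#' Gaussian blur via the frequency domain
#'
#' Exact (periodised) Gaussian convolution: multiply the image spectrum by
#' the Gaussian transfer function exp(-2 pi^2 sigma^2 f^2).  Appropriate for
#' fields whose borders are close to background, as all images here are.
#'
#' @param img numeric matrix.
#' @param sigma standard deviation in pixels; 0 returns the input.
#' @return blurred matrix, same shape.
#' @export
gaussian_blur <- function(img, sigma) {
  check_image(img)
  stopifnot(is.numeric(sigma), length(sigma) == 1L, sigma >= 0)
  if (sigma == 0) return(img)
  nr <- nrow(img); nc <- ncol(img)
  fy <- c(0:(nr %/% 2), -((nr - nr %/% 2 - 1L):1)) / nr
  if (nr == 1L) fy <- 0
  fx <- c(0:(nc %/% 2), -((nc - nc %/% 2 - 1L):1)) / nc
  if (nc == 1L) fx <- 0
  g <- exp(-2 * pi^2 * sigma^2 * outer(fy^2, fx^2, `+`))
  out <- Re(stats::fft(stats::fft(img) * g, inverse = TRUE)) / (nr * nc)
  out
}

#' Rolling-ball style background subtraction
#'
#' Estimates the background as the grayscale morphological opening with a
#' disc structuring element (the flat-disc analogue of ImageJ's rolling
#' ball), subtracts it and clamps at zero.
#'
#' @param img numeric matrix of counts.
#' @param radius disc radius in pixels (default 50).
#' @return list with `image` (background-subtracted, >= 0) and `background`.
#' @details For large radii the opening is computed on a downscaled copy
#'   (as ImageJ's rolling ball does) and smoothly upsampled; the estimate
#'   is clamped below the original image so the subtraction never clips
#'   genuine signal structure.
#' @export
subtract_background <- function(img, radius = 50) {
  check_image(img)
  stopifnot(radius >= 1)
  shrink <- max(1L, as.integer(radius) %/% 12L)
  if (shrink > 1L && all(dim(img) >= 4L * shrink)) {
    small <- EBImage::resize(img / 65535, w = nrow(img) %/% shrink,
                             h = ncol(img) %/% shrink)
    r <- max(1L, as.integer(round(radius / shrink)))
    brush <- EBImage::makeBrush(2L * r + 1L, shape = "disc")
    op <- EBImage::opening(small, brush)
    bg <- as.matrix(EBImage::resize(op, w = nrow(img), h = ncol(img))) * 65535
    bg <- pmin(bg, img)
  } else {
    brush <- EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
    bg <- EBImage::opening(img / 65535, brush) * 65535
  }
  out <- img - bg
  out[out < 0] <- 0
  list(image = out, background = bg)
}

#' Population variance of pixel intensities
#'
#' Divides by N (not N-1): the image is the whole population, matching the
#' variance statistics used by the QC thresholds.
#'
#' @param img numeric matrix.
#' @return scalar variance.
#' @export
img_variance <- function(img) {
  check_image(img)
  v <- as.numeric(img)
  mean((v - mean(v))^2)
}
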