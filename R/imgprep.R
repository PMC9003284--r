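# Image preprocessing: grayscale conversion, median filtering, normalization.
# Images are plain numeric matrices (rows = y, cols = x); RGB inputs are
# height x width x 3 arrays. Working gray images live on the [0,1] scale.

#' Validate a raster image
#'
#' Checks the minimal contract every image entering the pipeline must meet:
#' at least 3x3 (the descriptor needs a full 3x3 neighborhood), all samples
#' finite and non-negative.
#'
#' @param img numeric matrix (grayscale) or height x width x 3 array (RGB).
#' @return `img`, invisibly.
#' @keywords internal
check_raster <- function(img) {
  if (is.null(dim(img)) || !(length(dim(img)) %in% c(2L, 3L)))
    stop("image must be a matrix or a height x width x 3 array", call. = FALSE)
  if (length(dim(img)) == 3L && dim(img)[3] != 3L)
    stop("multi-channel images must have exactly 3 channels", call. = FALSE)
  if (dim(img)[1] < 3L || dim(img)[2] < 3L)
    stop("image too small: need at least 3x3 pixels", call. = FALSE)
  if (!all(is.finite(img)))
    stop("image contains non-finite samples", call. = FALSE)
  if (any(img < 0))
    stop("image contains negative samples", call. = FALSE)
  invisible(img)
}

#' Convert an image to grayscale on the [0,1] scale
#'
#' RGB inputs are collapsed with the ITU-R BT.601 luminance weights
#' (0.299, 0.587, 0.114). Integer-scaled inputs (maximum above 1) are
#' rescaled by the nominal bit depth: /255 for 8-bit-range data, /65535
#' above that. Already-gray [0,1] input passes through unchanged.
#'
#' @param img numeric matrix or height x width x 3 array.
#' @return numeric matrix with values in [0,1].
#' @examples
#' rgb <- array(0.4, dim = c(4, 4, 3))
#' all(to_grayscale(rgb) == 0.4)
#' @export
to_grayscale <- function(img) {
  check_raster(img)
  g <- if (length(dim(img)) == 3L) {
    0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  } else {
    img
  }
  mx <- max(g)
  if (mx > 1) g <- g / (if (mx <= 255) 255 else 65535)
  g
}

#' Median-filter a gray image
#'
#' Each output pixel is the median of its `window` x `window` neighborhood;
#' borders are handled by edge replication, so no values outside the input's
#' value set are ever produced.
#'
#' @param img numeric matrix.
#' @param window odd integer window side, >= 3.
#' @return filtered matrix, same shape.
#' @export
median_filter <- function(img, window = 3L) {
  check_raster(img)
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L)
    stop("`window` must be an odd integer >= 3", call. = FALSE)
  h <- (window - 1L) %/% 2L
  p <- pad_replicate(img, h)
  nr <- nrow(img); nc <- ncol(img)
  k <- window * window
  stack <- matrix(0, nrow = nr * nc, ncol = k)
  j <- 0L
  for (dr in -h:h) for (dc in -h:h) {
    j <- j + 1L
    stack[, j] <- p[(h + 1L + dr):(h + nr + dr), (h + 1L + dc):(h + nc + dc)]
  }
  mid <- (k + 1L) %/% 2L
  out <- apply(stack, 1L, function(v) sort.int(v, partial = mid)[mid])
  matrix(out, nr, nc)
}

#' Min-max normalize a gray image to [0,1]
#'
#' Affine rescale `(x - min) / (max - min)`, producing the dynamic-threshold
#' matrix gamma that both the descriptor and the PCNN consume. A constant
#' image (max == min) has no defined rescale; it is mapped to all zeros with
#' a warning so degenerate inputs still flow through the pipeline.
#'
#' @param img numeric matrix.
#' @return matrix with values in [0,1].
#' @export
normalize_gray <- function(img) {
  check_raster(img)
  lo <- min(img); hi <- max(img)
  if (hi == lo) {
    warning("constant image: normalization undefined, returning all zeros",
            call. = FALSE)
    return(array(0, dim(img)))
  }
  (img - lo) / (hi - lo)
}

#' Pad a matrix by edge replication
#' @keywords internal
pad_replicate <- function(m, h) {
  ri <- c(rep(1L, h), seq_len(nrow(m)), rep(nrow(m), h))
  ci <- c(rep(1L, h), seq_len(ncol(m)), rep(ncol(m), h))
  m[ri, ci, drop = FALSE]
}

#' Shift a matrix by (dr, dc) with edge replication
#' @keywords internal
shift_replicate <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) + dr, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) + dc, 1L), nc)
  m[ri, ci, drop = FALSE]
}

#' Shift a matrix by (dr, dc), filling vacated cells with `fill`
#' @keywords internal
shift_fill <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  sr <- seq_len(nr) + dr
  sc <- seq_len(nc) + dc
  ok_r <- sr >= 1L & sr <= nr
  ok_c <- sc >= 1L & sc <= nc
  out[ok_r, ok_c] <- m[sr[ok_r], sc[ok_c], drop = FALSE]
  out
}

#' Windowed box mean with border clipping
#'
#' Mean of each `window` x `window` neighborhood, with windows clipped at the
#' image border (counts follow the clipped window). Computed via an integral
#' image, O(1) per pixel.
#'
#' @keywords internal
box_mean <- function(m, window) {
  h <- (window - 1L) %/% 2L
  nr <- nrow(m); nc <- ncol(m)
  # summed-area table with a zero top row / left column
  S <- matrix(0, nr + 1L, nc + 1L)
  S[-1L, -1L] <- apply(apply(m, 2L, cumsum), 1L, cumsum) |> t()
  r1 <- pmax(seq_len(nr) - h, 1L); r2 <- pmin(seq_len(nr) + h, nr)
  c1 <- pmax(seq_len(nc) - h, 1L); c2 <- pmin(seq_len(nc) + h, nc)
  sums <- S[r2 + 1L, c2 + 1L, drop = FALSE] - S[r1, c2 + 1L, drop = FALSE] -
    S[r2 + 1L, c1, drop = FALSE] + S[r1, c1, drop = FALSE]
  counts <- outer(r2 - r1 + 1L, c2 - c1 + 1L)
  sums / counts
}

#' Separable Gaussian blur with replicated borders
#'
#' @param img numeric matrix.
#' @param sigma Gaussian standard deviation in pixels; 0 returns the input.
#' @return blurred matrix.
#' @export
gaussian_blur <- function(img, sigma) {
  if (sigma < 0) stop("`sigma` must be >= 0", call. = FALSE)
  if (sigma == 0) return(img)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  out <- matrix(0, nrow(img), ncol(img))
  for (i in seq_along(k)) out <- out + k[i] * shift_replicate(img, -r + i - 1L, 0L)
  out2 <- matrix(0, nrow(img), ncol(img))
  for (i in seq_along(k)) out2 <- out2 + k[i] * shift_replicate(out, 0L, -r + i - 1L)
  out2
}
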