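# Local binary / ternary pattern descriptor, uniform-pattern labeling,
# sliding-window sharpness map, and the blur mask.
#
# LTP assigns each neighbor a ternary value from the difference d to the
# center: +1 if d >= t, 0 if |d| < t, -1 if d <= -t (the boundary d = -t is
# assigned -1, symmetric with the inclusive upper boundary). The ternary
# code splits into two binary codes: "upper" keeps the +1s, "lower" keeps
# the -1s. Codes with at most two circular 0<->1 transitions are "uniform"
# and labeled by their number of set bits; all other codes pool into a
# single non-uniform label NUP = P + 1.

#' Descriptor configuration
#'
#' @param neighbors number of sampling points P on the ring (default 8).
#' @param radius sampling radius R in pixels (default 1). With the default
#'   `P = 8, R = 1` the sampling ring is the 8 surrounding grid pixels
#'   (axis-aligned unit ring); other settings sample the circle with
#'   bilinear interpolation.
#' @param t ternary threshold on the [0,1] gray scale; must be > 0.
#'   Default 0.02 (about 5 gray levels of an 8-bit image).
#' @param window odd side of the sliding sharpness window. Default 33 for
#'   desk-scale images; use 111 to approximate the full-scale 110x110
#'   setting on large photographs.
#' @param sharp_bins uniform labels counted as sharp evidence. Default
#'   `c(6, 7, 8, 9)`: the high-transition-count bins plus the non-uniform
#'   bin (NUP = P + 1 = 9), which dominate in-focus texture.
#' @return object of class `descriptor_config`.
#' @export
descriptor_config <- function(neighbors = 8L, radius = 1, t = 0.02,
                              window = 33L, sharp_bins = c(6L, 7L, 8L, 9L)) {
  neighbors <- as.integer(neighbors)
  if (neighbors <= 0L) stop("`neighbors` must be positive", call. = FALSE)
  if (radius <= 0) stop("`radius` must be positive", call. = FALSE)
  if (t <= 0) stop("ternary threshold `t` must be > 0", call. = FALSE)
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L)
    stop("`window` must be an odd integer >= 3", call. = FALSE)
  if (!all(sharp_bins %in% 0:(neighbors + 1L)))
    stop("`sharp_bins` must be labels in 0..P or NUP = P + 1", call. = FALSE)
  structure(list(neighbors = neighbors, radius = radius, t = t,
                 window = window, sharp_bins = as.integer(sharp_bins)),
            class = "descriptor_config")
}

# Sampling offsets (drow, dcol) for neighbor n = 0..P-1, counterclockwise
# from east. Rows point down, so counterclockwise means drow = -R sin(a).
ring_offsets <- function(P, R) {
  if (P == 8L && R == 1) {
    # unit grid ring: the 8 adjacent pixels
    list(dr = c(0, -1, -1, -1, 0, 1, 1, 1), dc = c(1, 1, 0, -1, -1, -1, 0, 1))
  } else {
    a <- 2 * pi * (seq_len(P) - 1L) / P
    dr <- -R * sin(a); dc <- R * cos(a)
    dr[abs(dr) < 1e-9] <- 0; dc[abs(dc) < 1e-9] <- 0
    list(dr = dr, dc = dc)
  }
}

# Sample the image at fractional offsets (dr, dc) from every pixel, with
# edge replication; bilinear interpolation for non-integer offsets.
sample_offset <- function(img, dr, dc) {
  if (dr == round(dr) && dc == round(dc))
    return(shift_replicate(img, as.integer(round(dr)), as.integer(round(dc))))
  r0 <- floor(dr); c0 <- floor(dc)
  fr <- dr - r0; fc <- dc - c0
  (1 - fr) * (1 - fc) * shift_replicate(img, r0, c0) +
    (1 - fr) * fc       * shift_replicate(img, r0, c0 + 1) +
    fr       * (1 - fc) * shift_replicate(img, r0 + 1, c0) +
    fr       * fc       * shift_replicate(img, r0 + 1, c0 + 1)
}

#' Per-pixel local binary pattern codes
#'
#' Bit n is set when neighbor n is >= the center pixel (a zero difference
#' counts as set); bit n carries weight 2^n.
#'
#' @param img numeric matrix in [0,1].
#' @param cfg a [descriptor_config()].
#' @return integer-valued matrix of codes in `[0, 2^P - 1]`.
#' @export
lbp_map <- function(img, cfg = descriptor_config()) {
  off <- ring_offsets(cfg$neighbors, cfg$radius)
  code <- matrix(0, nrow(img), ncol(img))
  for (n in seq_len(cfg$neighbors)) {
    d <- sample_offset(img, off$dr[n], off$dc[n]) - img
    code <- code + 2^(n - 1L) * (d >= 0)
  }
  code
}

#' Per-pixel local ternary pattern codes (upper and lower)
#'
#' @inheritParams lbp_map
#' @return list with matrices `upper` and `lower`; at every pixel the two
#'   codes are bitwise disjoint.
#' @export
ltp_map <- function(img, cfg = descriptor_config()) {
  off <- ring_offsets(cfg$neighbors, cfg$radius)
  up <- matrix(0, nrow(img), ncol(img))
  lo <- matrix(0, nrow(img), ncol(img))
  for (n in seq_len(cfg$neighbors)) {
    d <- sample_offset(img, off$dr[n], off$dc[n]) - img
    up <- up + 2^(n - 1L) * (d >= cfg$t)
    lo <- lo + 2^(n - 1L) * (d <= -cfg$t)
  }
  list(upper = up, lower = lo)
}

#' LBP code of a single neighborhood
#'
#' Convenience scalar form: `nbhd` is a square matrix whose center pixel is
#' the code's center.
#'
#' @param nbhd square numeric matrix of odd side.
#' @param cfg a [descriptor_config()].
#' @return single integer code.
#' @export
lbp_code <- function(nbhd, cfg = descriptor_config()) {
  ctr <- (dim(nbhd) + 1L) %/% 2L
  m <- lbp_map(nbhd, cfg)
  m[ctr[1], ctr[2]]
}

#' LTP codes of a single neighborhood
#'
#' @inheritParams lbp_code
#' @return list with scalars `upper` and `lower`.
#' @export
ltp_code <- function(nbhd, cfg = descriptor_config()) {
  ctr <- (dim(nbhd) + 1L) %/% 2L
  m <- ltp_map(nbhd, cfg)
  list(upper = m$upper[ctr[1], ctr[2]], lower = m$lower[ctr[1], ctr[2]])
}

#' Uniform rotation-invariant label of a binary code
#'
#' A code whose circular bit sequence has at most two 0<->1 transitions is
#' uniform and labeled by its count of ones (0..P); every other code gets
#' the pooled non-uniform label NUP = P + 1. Vectorized over `code`.
#'
#' @param code integer code(s) in `[0, 2^P - 1]`.
#' @param P number of bits.
#' @return integer label(s) in `{0..P, P + 1}`.
#' @export
uniform_label <- function(code, P = 8L) {
  P <- as.integer(P)
  if (any(code < 0 | code >= 2^P)) stop("code out of range", call. = FALSE)
  lut <- uniform_lut(P)
  shp <- dim(code)
  out <- lut[as.integer(code) + 1L]
  if (!is.null(shp)) dim(out) <- shp
  out
}

# label lookup table for all 2^P codes (cached per P)
uniform_lut <- local({
  cache <- list()
  function(P) {
    key <- as.character(P)
    if (!is.null(cache[[key]])) return(cache[[key]])
    codes <- 0:(2^P - 1)
    bits <- matrix(0L, length(codes), P)
    for (n in seq_len(P)) bits[, n] <- bitwAnd(codes, 2^(n - 1L)) > 0
    trans <- rowSums(bits != bits[, c(2:P, 1L), drop = FALSE])
    ones <- rowSums(bits)
    lut <- ifelse(trans <= 2L, ones, P + 1L)
    cache[[key]] <<- as.integer(lut)
    cache[[key]]
  }
})

#' Sliding-window LTP sharpness map
#'
#' For each pixel, the fraction of pixels in its window whose uniform LTP
#' label is sharp-indicative (`cfg$sharp_bins`), computed separately on the
#' upper and lower code maps and averaged (the upper/lower fusion). Smooth,
#' defocused regions produce near-zero codes (label 0) and score ~0;
#' focused texture produces high-count and non-uniform labels and scores
#' near 1.
#'
#' @param img normalized gray matrix (see [normalize_gray()]).
#' @param cfg a [descriptor_config()].
#' @return object of class `sharpness_map`: the score matrix in [0,1] with
#'   attribute `window`.
#' @export
sharpness_map <- function(img, cfg = descriptor_config()) {
  check_raster(img)
  w <- cfg$window
  if (w > min(dim(img))) {
    warning("sharpness window larger than image; clipping to image extent",
            call. = FALSE)
    w <- min(dim(img)); if (w %% 2L == 0L) w <- w - 1L
  }
  codes <- ltp_map(img, cfg)
  lab_up <- uniform_label(codes$upper, cfg$neighbors)
  lab_lo <- uniform_label(codes$lower, cfg$neighbors)
  ind_up <- matrix(as.numeric(lab_up %in% cfg$sharp_bins), nrow(img))
  ind_lo <- matrix(as.numeric(lab_lo %in% cfg$sharp_bins), nrow(img))
  s <- (box_mean(ind_up, w) + box_mean(ind_lo, w)) / 2
  structure(s, window = w, class = c("sharpness_map", "matrix", "array"))
}

#' Zero out blur-classified pixels
#'
#' Classifies each pixel sharp where its sharpness score reaches `TdLTP`
#' and replaces blur-classified pixels by zero intensity; the result feeds
#' the PCNN, which then groups the surviving in-focus evidence.
#'
#' @param img gray matrix.
#' @param s sharpness map from [sharpness_map()], same shape as `img`.
#' @param TdLTP threshold in [0,1]; `NULL` (default) uses the adaptive
#'   threshold [adaptive_threshold()] = twice the map mean. The adaptive
#'   rule presumes a *partially* blurred image (a mixed sharpness
#'   population): a homogeneous map always falls below twice its own mean,
#'   so when adaptive thresholding finds no appreciable clearly-blurred
#'   population (under 5% of pixels below a quarter of the threshold,
#'   i.e. below half the map mean) the image is
#'   taken as uniformly in focus and passed through unmasked, with a
#'   warning.
#' @return object of class `blur_masked` with fields `pixels` (gray matrix,
#'   zero where blurred) and `sharp_mask` (logical).
#' @export
blur_mask <- function(img, s, TdLTP = NULL) {
  if (!all(dim(img) == dim(s)))
    stop("sharpness map shape differs from image shape", call. = FALSE)
  if (is.null(TdLTP)) {
    TdLTP <- adaptive_threshold(s)
    if (mean(unclass(s) < TdLTP / 4) < 0.05) {
      warning("no appreciable blurred population under the adaptive ",
              "threshold: treating the image as uniformly in focus",
              call. = FALSE)
      TdLTP <- 0
    }
  }
  sharp <- unclass(s) >= TdLTP
  structure(list(pixels = img * sharp, sharp_mask = sharp,
                 TdLTP = TdLTP),
            class = "blur_masked")
}
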