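# Seeded synthetic fixtures: partially blurred images with ground-truth
# masks. The texture model is band-limited noise (white noise lightly
# smoothed), so sharpness statistics are controlled and reproducible; the
# ground truth follows the generating geometry (sharp = TRUE/white), with a
# thin transition band at the blur boundary accepted as part of the world
# being emulated (real low-depth-of-field images have no hard boundary
# either).

#' Fixture specification
#'
#' @param shape `c(height, width)`, each >= 32.
#' @param foreground geometry: `"disk"`, `"ring"`, `"blob"` (elongated
#'   rotated ellipse).
#' @param contrast peak-to-peak texture contrast of the pattern around
#'   mid-gray (default 0.3).
#' @param blur_sigma Gaussian sigma applied outside the foreground
#'   (default 3).
#' @param noise_sigma additive sensor-noise sd (default 0.005, about the
#'   quantization scale of 8-bit data).
#' @param seed integer RNG seed; same spec + seed gives identical pixels.
#' @return object of class `fixture_spec`.
#' @export
fixture_spec <- function(shape = c(256L, 256L), foreground = "disk",
                         contrast = 0.3, blur_sigma = 3, noise_sigma = 0.005,
                         seed = 1L) {
  if (length(shape) != 2L || any(shape < 32L))
    stop("`shape` must be two dimensions >= 32", call. = FALSE)
  if (blur_sigma < 0) stop("`blur_sigma` must be >= 0", call. = FALSE)
  structure(list(shape = as.integer(shape), foreground = foreground,
                 contrast = contrast, blur_sigma = blur_sigma,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "fixture_spec")
}

# smoothed white-noise texture around mid-gray, peak contrast `contrast`
texture_field <- function(h, w, contrast, smooth = 0.7) {
  z <- matrix(stats::rnorm(h * w), h, w)
  z <- gaussian_blur(z, smooth)
  z <- z / stats::sd(z)
  pmin(pmax(0.5 + (contrast / 2) * z, 0), 1)
}

# foreground geometry masks
geometry_mask <- function(kind, h, w) {
  r <- row(matrix(0, h, w)); c <- col(matrix(0, h, w))
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  s <- min(h, w)
  switch(kind,
    disk = (r - cy)^2 + (c - cx)^2 <= (0.25 * s)^2,
    ring = {
      d2 <- (r - cy)^2 + (c - cx)^2
      d2 <= (0.3 * s)^2 & d2 >= (0.18 * s)^2
    },
    blob = {
      th <- pi / 6
      u <- (r - cy) * cos(th) + (c - cx) * sin(th)
      v <- -(r - cy) * sin(th) + (c - cx) * cos(th)
      (u / (0.12 * s))^2 + (v / (0.28 * s))^2 <= 1
    },
    stop("unknown foreground geometry '", kind, "'", call. = FALSE))
}

#' Generate a partially blurred image with ground truth
#'
#' Renders texture over the full frame, Gaussian-blurs the complement of
#' the foreground geometry, adds sensor noise, and returns the image with
#' its generating mask (sharp = `TRUE`).
#'
#' @param spec a [fixture_spec()] (or arguments forwarded to it).
#' @param ... forwarded to [fixture_spec()] when `spec` is missing.
#' @return list with `image` (gray matrix in [0,1]), `mask` (logical),
#'   and `spec`.
#' @export
make_partial_blur <- function(spec = fixture_spec(...), ...) {
  h <- spec$shape[1]; w <- spec$shape[2]
  mask <- geometry_mask(spec$foreground, h, w)
  frac <- mean(mask)
  if (frac == 0 || frac == 1)
    stop("foreground must contain both classes", call. = FALSE)
  withr::with_seed(spec$seed, {
    tex <- texture_field(h, w, spec$contrast)
    img <- ifelse(mask, tex, gaussian_blur(tex, spec$blur_sigma))
    if (spec$noise_sigma > 0)
      img <- img + matrix(stats::rnorm(h * w, sd = spec$noise_sigma), h, w)
    img <- pmin(pmax(img, 0), 1)
  })
  list(image = img, mask = mask, spec = spec)
}

#' Microscopy-like fixtures
#'
#' `"seed_ring"`: an annulus of sharp texture (a round plant seed imaged in
#' a thin focal plane shows its rim in focus) with blurred interior and
#' exterior. `"paramecium"`: one elongated textured blob in focus over a
#' background of blurred distractor blobs.
#'
#' @param kind `"seed_ring"` or `"paramecium"`.
#' @param spec a [fixture_spec()]; its `foreground` field is ignored.
#' @return list with `image`, `mask`, `spec`.
#' @export
make_microscopy_like <- function(kind = c("seed_ring", "paramecium"),
                                 spec = fixture_spec()) {
  kind <- match.arg(kind)
  h <- spec$shape[1]; w <- spec$shape[2]
  mask <- geometry_mask(if (kind == "seed_ring") "ring" else "blob", h, w)
  withr::with_seed(spec$seed, {
    tex <- texture_field(h, w, spec$contrast)
    if (kind == "paramecium") {
      # blurred distractor blobs: low-frequency blotches in the background
      blobs <- gaussian_blur(matrix(stats::rnorm(h * w), h, w), 6)
      blobs <- 0.15 * blobs / stats::sd(blobs)
      bg <- pmin(pmax(gaussian_blur(tex, spec$blur_sigma) + blobs, 0), 1)
    } else {
      bg <- gaussian_blur(tex, spec$blur_sigma)
    }
    img <- ifelse(mask, tex, bg)
    if (spec$noise_sigma > 0)
      img <- img + matrix(stats::rnorm(h * w, sd = spec$noise_sigma), h, w)
    img <- pmin(pmax(img, 0), 1)
  })
  list(image = img, mask = mask, spec = spec)
}
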