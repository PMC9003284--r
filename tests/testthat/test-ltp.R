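# neighborhood builder: places the 8 ring values counterclockwise from east
# (E, NE, N, NW, W, SW, S, SE) around a 3x3 center
nbhd8 <- function(center, ring) {
  m <- matrix(center, 3, 3)
  m[2, 3] <- ring[1]; m[1, 3] <- ring[2]; m[1, 2] <- ring[3]
  m[1, 1] <- ring[4]; m[2, 1] <- ring[5]; m[3, 1] <- ring[6]
  m[3, 2] <- ring[7]; m[3, 3] <- ring[8]
  m
}

test_that("lbp_code follows the sign convention and shift invariance", {
  cfg <- descriptor_config()
  expect_equal(lbp_code(matrix(0.5, 3, 3), cfg), 255)

  alt <- nbhd8(0.5, rep(c(0.6, 0.4), 4))  # bits 10101010, n = 0 least significant
  expect_equal(lbp_code(alt, cfg), 85)

  set.seed(2)
  for (i in 1:10) {
    ring <- runif(8); ctr <- runif(1); c0 <- runif(1, -0.2, 0.2)
    m <- nbhd8(ctr, ring)
    expect_equal(lbp_code(m, cfg), lbp_code(m + c0, cfg))
  }
})

test_that("ltp_code splits the ternary pattern into disjoint halves", {
  cfg <- descriptor_config(t = 0.05)
  got <- ltp_code(nbhd8(0.50, c(0.53, 0.49, 0.12, 0.90, 0.51, 0.48, 0.47, 0.55)),
                  cfg)
  expect_equal(got$upper, 2^3 + 2^7)  # ternary (0,0,-1,1,0,0,0,1)
  expect_equal(got$lower, 2^2)

  flat <- ltp_code(matrix(0.42, 3, 3), cfg)
  expect_equal(flat$upper, 0)
  expect_equal(flat$lower, 0)

  # the boundary d = t is inclusive for the upper half, d = -t for the
  # lower; dyadic values keep the comparison exact in floating point
  cfgx <- descriptor_config(t = 0.0625)
  b <- ltp_code(nbhd8(0.5, c(0.5625, 0.4375, rep(0.5, 6))), cfgx)
  expect_equal(b$upper, 1)
  expect_equal(b$lower, 2)
})

test_that("LTP maps satisfy disjointness, illumination invariance, and duality", {
  cfg <- descriptor_config(t = 0.03)
  set.seed(4)
  for (i in 1:5) {
    img <- matrix(runif(100), 10, 10)
    cm <- ltp_map(img, cfg)
    expect_true(all(bitwAnd(cm$upper, cm$lower) == 0))
    shifted <- ltp_map(img + 0.2, cfg)
    expect_equal(shifted$upper, cm$upper)
    expect_equal(shifted$lower, cm$lower)
    neg <- ltp_map(1 - img, cfg)  # runif makes |d| == t a null event
    expect_equal(neg$upper, cm$lower)
    expect_equal(neg$lower, cm$upper)
  }
})

test_that("upper LTP converges to strict-positive LBP as t -> 0+", {
  set.seed(9)
  img <- matrix(runif(64), 8, 8)
  up <- ltp_map(img, descriptor_config(t = 1e-12))$upper
  # LBP restricted to strictly positive differences
  cfg <- descriptor_config()
  strict <- matrix(0, 8, 8)
  off <- focusfield:::ring_offsets(8L, 1)
  for (n in 1:8) {
    d <- focusfield:::sample_offset(img, off$dr[n], off$dc[n]) - img
    strict <- strict + 2^(n - 1) * (d > 0)
  }
  expect_equal(up, strict)
})

test_that("uniform_label implements riu2 binning", {
  expect_equal(uniform_label(0, 8), 0L)
  expect_equal(uniform_label(255, 8), 8L)
  expect_equal(uniform_label(7, 8), 3L)   # 00000111: two circular transitions
  expect_equal(uniform_label(strtoi("10101010", base = 2), 8), 9L)

  labs <- uniform_label(0:255, 8)
  expect_equal(labs, vapply(0:255, oracle_uniform_label, integer(1), P = 8L))
  expect_equal(sum(labs <= 8), 58L)  # the uniform-pattern census
  expect_equal(as.integer(table(labs)[as.character(0:8)]),
               c(1L, 8L, 8L, 8L, 8L, 8L, 8L, 8L, 1L))
})

test_that("sharpness_map scores flat regions zero and decays under blur", {
  cfg <- descriptor_config(window = 5)
  s <- sharpness_map(matrix(0.6, 9, 9), cfg)
  expect_true(all(s == 0))

  set.seed(21)
  img <- matrix(runif(64 * 64), 64, 64)
  cfg15 <- descriptor_config(t = 0.02, window = 15)
  ms <- vapply(c(0, 1, 2, 3), function(sg) {
    mean(sharpness_map(if (sg > 0) gaussian_blur(img, sg) else img, cfg15))
  }, numeric(1))
  expect_true(all(diff(ms) <= 0))        # non-increasing in sigma
  expect_gt(ms[1], ms[4])                # and strictly overall
  expect_true(all(s >= 0 & s <= 1))
})

test_that("sharpness_map counts sharp-bin fractions as stated", {
  # windows holding half label-8 and half label-0 patterns score 0.5:
  # verified against a direct recount from the label maps
  set.seed(33)
  img <- matrix(runif(144), 12, 12)
  cfg <- descriptor_config(t = 0.05, window = 5)
  s <- sharpness_map(img, cfg)
  cm <- ltp_map(img, cfg)
  iu <- matrix(uniform_label(cm$upper, 8) %in% cfg$sharp_bins, 12, 12)
  il <- matrix(uniform_label(cm$lower, 8) %in% cfg$sharp_bins, 12, 12)
  expect_equal(unclass(s),
               (oracle_box_mean(iu * 1, 5) + oracle_box_mean(il * 1, 5)) / 2,
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_warning(sharpness_map(matrix(runif(9), 3, 3),
                               descriptor_config(window = 7)), "clipping")
})

test_that("blur_mask zeroes blur-classified pixels", {
  img <- matrix(runif(9), 3, 3)
  s <- structure(matrix(c(0.2, 0.8, 0.2, 0.8, 0.2, 0.8, 0.2, 0.8, 0.2), 3, 3),
                 class = c("sharpness_map", "matrix", "array"))
  bm <- blur_mask(img, s, TdLTP = 0.5)
  expect_equal(bm$sharp_mask, unclass(s) >= 0.5, ignore_attr = TRUE)
  expect_true(all(bm$pixels[!bm$sharp_mask] == 0))
  expect_equal(bm$pixels[bm$sharp_mask], img[bm$sharp_mask])

  bm0 <- blur_mask(img, s, TdLTP = 0)
  expect_equal(bm0$pixels, img)
  bm1 <- blur_mask(img, s, TdLTP = 1.1)
  expect_true(all(bm1$pixels == 0))

  expect_error(blur_mask(matrix(1, 4, 4), s), "shape")
})
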