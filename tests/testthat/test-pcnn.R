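test_that("band_stats orders tercile spreads on a three-band image", {
  # flat | medium texture | fine high-contrast checkerboard, equal areas
  set.seed(6)
  h <- 12; w <- 36
  img <- matrix(0.5, h, w)
  img[, 13:24] <- 0.5 + 0.1 * matrix(sample(c(-1, 1), h * 12, TRUE), h)
  img[, 25:36] <- 0.5 + 0.3 * ((row(img[, 25:36]) + col(img[, 25:36])) %% 2 * 2 - 1)
  st <- band_stats(img)
  expect_equal(st$M_LF, 0.5, tolerance = 0.05)
  expect_equal(st$M_MF, 0.5, tolerance = 0.05)
  expect_equal(st$M_HF, 0.5, tolerance = 0.05)
  expect_lt(st$sigma_LF, st$sigma_MF)
  expect_lt(st$sigma_MF, st$sigma_HF)
})

test_that("constant images trigger the degenerate-statistics error", {
  img <- matrix(0.5, 8, 8)
  st <- band_stats(img)
  expect_equal(st$sigma_LF, 0)
  expect_error(estimate_params(img, st), "degenerate")
})

test_that("estimate_params matches the closed forms", {
  # independent straight-line evaluation of the adaptive formulas
  st <- structure(list(M_LF = 0.5, M_MF = 0.6, M_HF = 0.8,
                       sigma_LF = 0.1, sigma_MF = 0.1, sigma_HF = 0.1),
                  class = "band_stats")
  set.seed(8)
  img <- matrix(runif(100), 10, 10)
  p <- estimate_params(img, st)
  F_E <- log((0.5 + 0.1) / (0.5 - 0.1))
  C <- min(8, log((0.8 + 0.1) / (0.8 - 0.1)) / F_E)
  expect_equal(p$F_E, F_E, tolerance = 1e-12)
  expect_equal(p$C, C, tolerance = 1e-12)
  expect_equal(p$delta, 3 * 0.1 / (C * (0.5 - 0.1)), tolerance = 1e-12)
  expect_equal(p$theta_E, img)  # per-pixel initialization
  expect_gte(mean(img >= p$Td_min), 0.94)
  expect_equal(p$W_con, matrix(c(0.5, 1, 0.5, 1, 0, 1, 0.5, 1, 0.5), 3, 3))

  st_bad <- st; st_bad$sigma_LF <- 0.6
  expect_error(estimate_params(img, st_bad), "degenerate")
  st_c0 <- st; st_c0$sigma_HF <- 0
  expect_error(estimate_params(img, st_c0), "C = 0")
})

test_that("identical neurons synchronize and fired neurons stay refractory", {
  u <- matrix(0.8, 6, 6)
  p <- make_params(theta_E = u, F_E = 0.4)
  st <- pcnn_init(u, p)
  st <- pcnn_step(st, p)
  expect_true(all(st$Y == 1))
  expect_true(all(st$f == 1L))
  for (i in 1:5) st <- pcnn_step(st, p)
  expect_true(all(st$Y == 0))          # one-time firing
  expect_true(all(st$f == 1L))
})

test_that("max-initialization orders firing by intensity", {
  img <- cbind(matrix(0.9, 4, 2), matrix(0.2, 4, 2))
  # per-pixel init: both blocks satisfy U >= E at n = 1
  p1 <- make_params(theta_E = img, F_E = 0.4)
  s1 <- pcnn_step(pcnn_init(img, p1), p1)
  expect_true(all(s1$f == 1L))
  # global-max init: bright block fires strictly first
  p2 <- make_params(theta_E = matrix(0.9, 4, 4), F_E = 0.4)
  st <- pcnn_init(img, p2)
  repeat { st <- pcnn_step(st, p2); if (all(st$f > 0)) break }
  expect_true(all(st$f[, 1:2] == 1L))
  expect_true(all(st$f[, 3:4] > 1L))
})

test_that("threshold decay matches the closed form in the no-fire limit", {
  img <- matrix(0, 5, 5)
  p <- make_params(theta_E = matrix(1, 5, 5), F_E = 0.3, Td_min = 1e-9)
  st <- pcnn_init(img, p)
  for (k in 1:20) {
    st <- pcnn_step(st, p)
    expect_equal(st$E, matrix(exp(-0.3 * k), 5, 5), tolerance = 1e-12)
  }
})

test_that("every neuron fires exactly once and waves partition the image", {
  set.seed(14)
  img <- matrix(runif(24 * 24, 0.05, 1), 24, 24)
  p <- estimate_params(img)
  st <- pcnn_init(img, p)
  fired_total <- matrix(0, 24, 24)
  repeat {
    st <- pcnn_step(st, p)
    fired_total <- fired_total + st$Y
    if (all(st$f > 0)) break
    if (st$n > p$max_iters) stop("no termination")
  }
  expect_true(all(fired_total == 1))   # sum over n of Y(n) is 1 per pixel
  expect_true(all(st$f >= 1))
})

test_that("pcnn_run labels disjoint synchronous squares separately", {
  img <- matrix(0.1, 12, 12)
  img[2:5, 2:5] <- 0.9
  img[8:11, 8:11] <- 0.9
  p <- make_params(theta_E = matrix(0.9, 12, 12), F_E = 0.4, max_iters = 500L)
  run <- pcnn_run(img, p)
  f <- run$edge$fired_iter
  expect_true(all(f[2:5, 2:5] == 1L))
  expect_true(all(f[8:11, 8:11] == 1L))
  expect_true(all(f[f > 0 & img == 0.1] > 1L))
  l1 <- run$edge$labels[3, 3]; l2 <- run$edge$labels[9, 9]
  expect_true(l1 != l2)
  expect_true(all(run$edge$labels[2:5, 2:5] == l1))
  # wave-1 set is exactly the bright region
  expect_equal(unname(f == 1L), img == 0.9)
  expect_true(all(run$state$f > 0))
})

test_that("pcnn_run raises a partial-result error carrying state", {
  img <- matrix(0.1, 6, 6); img[2:3, 2:3] <- 0.9
  p <- make_params(theta_E = matrix(0.9, 6, 6), F_E = 0.4, max_iters = 1L)
  err <- tryCatch(pcnn_run(img, p), error = identity)
  expect_s3_class(err, "focusfield_partial_result")
  expect_s3_class(err$state, "pcnn_state")
  expect_true(any(err$state$f == 0L))
})

test_that("label_components agrees with a BFS flood-fill oracle", {
  set.seed(17)
  for (i in 1:25) {
    nr <- sample(2:8, 1); nc <- sample(2:8, 1)
    mask <- matrix(runif(nr * nc) < 0.45, nr, nc)
    for (conn in c(8L, 4L)) {
      got <- label_components(mask, conn)
      want <- oracle_label(mask, conn)
      expect_true(same_partition(got, want))
      expect_equal(max(got), max(want))
    }
  }
  expect_equal(label_components(matrix(FALSE, 3, 3)), matrix(0L, 3, 3))
})

test_that("binarize_and_clean fills driven-seed rings and handles empties", {
  empty <- structure(list(M_edge = matrix(0, 8, 8),
                          driven_seed = matrix(FALSE, 8, 8),
                          fired_iter = matrix(1L, 8, 8)),
                     class = "edge_map")
  expect_true(all(!binarize_and_clean(empty)))

  # a ring of driven first-wave pixels becomes a filled disk
  rr <- sqrt((row(matrix(0, 15, 15)) - 8)^2 + (col(matrix(0, 15, 15)) - 8)^2)
  ring <- rr >= 3 & rr <= 5
  e <- structure(list(M_edge = ring * 1, driven_seed = ring,
                      fired_iter = ring * 1L),
                 class = "edge_map")
  mask <- binarize_and_clean(e)
  expect_true(all(mask[rr <= 5]))          # interior hole filled
  expect_true(all(!mask[rr > 6.5]))        # exterior untouched
  # Td = 0 on a strictly positive edge map marks every pixel as edge
  pos <- structure(list(M_edge = matrix(0.2, 4, 4),
                        driven_seed = matrix(TRUE, 4, 4),
                        fired_iter = matrix(1L, 4, 4)),
                   class = "edge_map")
  expect_true(all(attr(binarize_and_clean(pos, Td = 0), "edges")))
})

test_that("hole filling and closing behave on simple shapes", {
  m <- matrix(FALSE, 7, 7); m[2:6, 2:6] <- TRUE; m[4, 4] <- FALSE
  expect_true(all(fill_holes(m)[2:6, 2:6]))
  notch <- matrix(FALSE, 7, 7); notch[3:5, 2:6] <- TRUE; notch[4, 4] <- FALSE
  expect_true(close_mask(notch)[4, 4])
})
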