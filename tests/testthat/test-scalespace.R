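test_that("scale list is geometric and spans the requested range", {
  sl <- scale_list(0.5, 64, layers_per_octave = 4)
  r <- sl$t[-1] / sl$t[-length(sl$t)]
  expect_lt(max(abs(r - sl$ratio)), 1e-12 * sl$ratio)
  expect_equal(sl$t[1], 0.5)
  expect_gte(max(sl$t), 64)
})

test_that("constant images are fixed points of smoothing", {
  img <- height_image(matrix(3.7, 16, 16), 1)
  for (fam in c("discrete", "sampled")) {
    ss <- build_scale_space(img, t_max = 8, kernel = fam)
    expect_lt(max(abs(ss$layers - 3.7)), 1e-12)
  }
})

test_that("impulse response equals the dense-convolution oracle", {
  M <- matrix(0, 21, 21); M[11, 11] <- 1
  for (t in c(1, 3)) {
    k <- discrete_gaussian_kernel(t, tol = 1e-10)
    expect_equal(smooth_image(M, t, tol = 1e-10), dense_conv2(M, k),
                 tolerance = 1e-12)
  }
})

test_that("Gaussian bump smoothing follows the closed-form semigroup", {
  # bump of scale t0 smoothed at t is a bump of scale t0 + t with centre
  # amplitude A * t0 / (t0 + t)
  t0 <- 6; A <- 2
  g <- gaussian_blob_image(c(64, 64), 1,
                           data.frame(x = 32, y = 32, A = A, t0 = t0))
  for (t in c(2, 8)) {
    L <- smooth_image(g$image$heights, t)
    # discrete kernel vs continuous closed form agree to ~1%
    expect_equal(L[32, 32], A * t0 / (t0 + t), tolerance = 0.02)
    # off-centre value at r = 4 px
    expect_equal(L[32, 36], A * t0 / (t0 + t) * exp(-16 / (2 * (t0 + t))),
                 tolerance = 0.02)
  }
})

test_that("two-stage smoothing equals one-stage at the summed scale", {
  set.seed(1)
  M <- smooth_image(matrix(rnorm(48 * 48), 48, 48), 1)
  one <- smooth_image(M, 6, tol = 1e-12)
  two <- smooth_image(smooth_image(M, 2, tol = 1e-12), 4, tol = 1e-12)
  interior <- 12:36
  rng <- diff(range(M))
  expect_lt(max(abs(one[interior, interior] - two[interior, interior])),
            1e-9 * rng)
})

test_that("layer sums are conserved and total variation decreases", {
  set.seed(2)
  img <- height_image(matrix(rnorm(32 * 32), 32, 32), 1)
  ss <- build_scale_space(img, t_max = 16)
  sums <- apply(ss$layers, 3, sum)
  expect_lt(max(abs(sums - sum(img$heights))),
            1e-9 * abs(sum(img$heights)) + 1e-9)
  tv <- apply(ss$layers, 3, function(L) {
    sum(abs(diff(L))) + sum(abs(t(diff(t(L)))))
  })
  expect_true(all(diff(tv) <= 1e-12))
})

test_that("detector volumes annihilate planes and are rotation-equivariant", {
  plane <- outer(seq_len(48), seq_len(48), function(i, j) 0.3 * i - 0.1 * j + 2)
  vol <- detector_volumes(build_scale_space(height_image(plane, 1), t_max = 4))
  # interior strictly beyond the truncated kernel support: border padding
  # has exactly zero influence there, so second differences annihilate the
  # plane to rounding error
  w <- attr(discrete_gaussian_kernel(4), "half_width")
  interior <- (w + 3):(48 - w - 2)
  rng2 <- diff(range(plane))^2
  expect_lt(max(abs(vol$detH[interior, interior, ])), 1e-9 * rng2)
  expect_lt(max(abs(vol$lap[interior, interior, ])), 1e-9 * rng2)

  set.seed(3)
  M <- smooth_image(matrix(rnorm(24 * 24), 24, 24), 1)
  v1 <- detector_volumes(build_scale_space(height_image(M, 1), t_max = 4))
  rotM <- t(M)[ncol(M):1, ]   # 90 degree rotation
  v2 <- detector_volumes(build_scale_space(height_image(rotM, 1), t_max = 4))
  for (k in seq_along(v1$scales)) {
    back <- t(v2$detH[, , k][nrow(rotM):1, ])
    expect_lt(max(abs(v1$detH[, , k] - back)), 1e-12 * max(abs(v1$detH)))
  }
})

test_that("affine offsets and tilts leave the detectors unchanged", {
  fx <- bump_fixture()
  base <- fx$vol
  rng2 <- diff(range(fx$gen$image$heights))^2
  # compare only layers whose truncated kernel support stays clear of the
  # border for an interior window of the 96 px frame
  ks <- which(vapply(fx$vol$scales, function(t) {
    attr(discrete_gaussian_kernel(t), "half_width") <= 28
  }, logical(1)))
  interior <- 33:64
  for (kind in c("offset", "tilt")) {
    pert <- detector_volumes(build_scale_space(perturb(fx$gen$image, kind, 2),
                                               t_max = 64))
    expect_lt(max(abs(base$detH[interior, interior, ks] -
                        pert$detH[interior, interior, ks])), 1e-9 * rng2)
    expect_lt(max(abs(base$lap[interior, interior, ks] -
                        pert$lap[interior, interior, ks])), 1e-9 * rng2)
  }
})

test_that("detH at a bump centre follows the closed form with argmax at t0", {
  # for h = A exp(-r^2/(2 t0)): detH(t) = A^2 t0^2 t^2 / (t0 + t)^4
  fx <- bump_fixture()
  t <- fx$vol$scales
  obs <- fx$vol$detH[48, 48, ]
  pred <- 9 * 64 * t^2 / (8 + t)^4
  mid <- t >= 2 & t <= 32
  expect_lt(max(abs(obs[mid] - pred[mid]) / pred[mid]), 0.03)
  expect_equal(t[which.max(obs)], 8, tolerance = 1e-9)
  # bright bump: Laplacian negative at the centre
  expect_true(all(fx$vol$lap[48, 48, ] < 0))
})

test_that("Gaussian curvature: zero on planes, sign matches detH, radial sign", {
  plane <- outer(seq_len(24), seq_len(24), function(i, j) 0.2 * i + 0.4 * j)
  expect_lt(max(abs(gaussian_curvature(derivative_fields(plane)))), 1e-12)

  set.seed(4)
  L <- smooth_image(matrix(rnorm(32 * 32), 32, 32), 2)
  f <- derivative_fields(L)
  K <- gaussian_curvature(f)
  deth <- f$Lxx * f$Lyy - f$Lxy^2
  expect_identical(sign(K), sign(deth))

  # radial Gaussian of scale s: K > 0 for r < sqrt(s), < 0 beyond
  s <- 9
  r2 <- outer((1:41) - 21, (1:41) - 21, function(a, b) a^2 + b^2)
  K <- gaussian_curvature(derivative_fields(exp(-r2 / (2 * s))))
  r <- sqrt(r2)
  expect_true(all(K[r < sqrt(s) - 0.8] > 0))
  expect_true(all(K[r > sqrt(s) + 0.8 & r < 15] < 0))
})

test_that("t_max beyond the image is clamped with a warning", {
  img <- height_image(matrix(rnorm(64), 8, 8), 1)
  expect_warning(ss <- build_scale_space(img, t_max = 100),
                 "clamped")
  expect_lte(max(ss$scales) / ss$ratio, 64)
})
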