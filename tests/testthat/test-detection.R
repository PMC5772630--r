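test_that("a single spiked voxel is the only seed", {
  A <- array(0, c(7, 7, 3)); A[4, 5, 2] <- 2
  s <- find_scale_space_maxima(fake_volume(A), exclude_border = FALSE)
  expect_equal(nrow(s), 1L)
  expect_equal(unlist(s[1, c("k", "i", "j")]), c(k = 2, i = 4, j = 5))
  expect_equal(s$strength, 2)
})

test_that("maxima detection matches the brute-force 26-neighbour oracle", {
  set.seed(10)
  for (rep in 1:20) {
    A <- array(rnorm(9 * 9 * 5), c(9, 9, 5))
    got <- find_scale_space_maxima(fake_volume(A), exclude_border = FALSE)
    want <- brute_force_maxima(A)
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$k, want$k)
    expect_equal(got$i, want$i)
    expect_equal(got$j, want$j)
    expect_equal(got$strength, want$strength)
  }
})

test_that("plateaus (exact ties) yield no seed", {
  A <- array(0, c(5, 5, 3)); A[3, 3, 2] <- 1; A[3, 4, 2] <- 1
  s <- find_scale_space_maxima(fake_volume(A), exclude_border = FALSE)
  expect_equal(nrow(s), 0L)
})

test_that("raising min_strength culls monotonically without moving seeds", {
  set.seed(11)
  A <- array(abs(rnorm(11 * 11 * 4)), c(11, 11, 4))
  v <- fake_volume(A)
  s0 <- find_scale_space_maxima(v, 0, exclude_border = FALSE)
  for (ms in c(0.5, 1, 2)) {
    s1 <- find_scale_space_maxima(v, ms, exclude_border = FALSE)
    expect_true(all(s1$strength > ms))
    key0 <- paste(s0$k, s0$i, s0$j)
    key1 <- paste(s1$k, s1$i, s1$j)
    expect_true(all(key1 %in% key0))
  }
})

test_that("one planted bump gives one seed at its centre and scale", {
  fx <- bump_fixture()
  s <- find_scale_space_maxima(fx$vol)
  expect_equal(nrow(s), 1L)
  expect_equal(c(s$i, s$j), c(48, 48))
  # selected scale within one geometric step of t0 = 8
  expect_lt(abs(log(s$t_px2 / 8)), log(fx$vol$ratio) + 1e-9)
})

test_that("sign classification: bright bumps, dark craters, detH blind to sign", {
  fx <- bump_fixture()
  s <- classify_sign(find_scale_space_maxima(fx$vol), fx$vol)
  expect_equal(s$sign, "bright")
  neg <- height_image(-fx$gen$image$heights, 1)
  voln <- detector_volumes(build_scale_space(neg, t_max = 64))
  sn <- classify_sign(find_scale_space_maxima(voln), voln)
  expect_equal(sn$sign, "dark")
  # detH maxima appear at the same place for both signs
  expect_equal(c(sn$i, sn$j, sn$k), c(s$i, s$j, s$k))
  expect_equal(sn$strength, s$strength, tolerance = 1e-12)
})

test_that("Taylor refinement recovers an analytic quadratic vertex exactly", {
  d <- c(9, 9, 5)
  v0 <- c(5.3, 4.8, 3.1)   # vertex at offset (0.3, -0.2, 0.1) from (5,5,3)
  M <- diag(c(0.8, 1.2, 0.5))
  M[1, 2] <- M[2, 1] <- 0.1
  A <- array(0, d)
  for (i in 1:9) for (j in 1:9) for (k in 1:5) {
    u <- c(i, j, k) - v0
    A[i, j, k] <- 10 - drop(t(u) %*% M %*% u)
  }
  rc <- refine_center_subpixel(fake_volume(A), list(k = 3L, i = 5L, j = 5L))
  expect_true(rc$converged)
  expect_equal(rc$off_i, 0.3, tolerance = 1e-10)
  expect_equal(rc$off_j, -0.2, tolerance = 1e-10)
  expect_equal(rc$off_k, 0.1, tolerance = 1e-10)
})

test_that("refinement is centred for an on-pixel bump and degrades gracefully", {
  fx <- bump_fixture()
  s <- find_scale_space_maxima(fx$vol)
  rc <- refine_center_subpixel(fx$vol, as.list(s[1, ]))
  expect_true(rc$converged)
  expect_lt(abs(rc$off_i), 1e-6)
  expect_lt(abs(rc$off_j), 1e-6)
  expect_lte(abs(rc$off_k), 0.5)
  # seed on the volume edge cannot be refined
  rc2 <- refine_center_subpixel(fx$vol, list(k = 1L, i = s$i, j = s$j))
  expect_false(rc2$converged)
  expect_equal(rc2$row, s$i)
})

test_that("subpixel centres planted off-grid are recovered within 0.15 px", {
  offs <- c(0.37, -0.24, 0.11, -0.41, 0.29, -0.18, 0.43, -0.07)
  errs <- vapply(1:8, function(q) {
    x0 <- 40 + offs[q]; y0 <- 40 + offs[(q %% 8) + 1]
    g <- gaussian_blob_image(c(80, 80), 1,
                             data.frame(x = x0, y = y0, A = 3, t0 = 8))
    img <- perturb(g$image, "gaussian_noise", 0.3, seed = 500 + q)  # SNR 10
    vol <- detector_volumes(build_scale_space(img, t_max = 32))
    s <- find_scale_space_maxima(vol)
    rc <- refine_center_subpixel(vol, as.list(s[1, ]))
    sqrt((rc$col - x0)^2 + (rc$row - y0)^2)
  }, numeric(1))
  expect_lt(stats::median(errs), 0.15)
})

test_that("whole-pixel translations shift seeds equally", {
  mk <- function(dx, dy) {
    gaussian_blob_image(c(96, 96), 1,
                        data.frame(x = c(34, 62) + dx, y = c(30, 60) + dy,
                                   A = 3, t0 = c(4, 8)))$image
  }
  s0 <- find_scale_space_maxima(detector_volumes(build_scale_space(mk(0, 0), t_max = 32)),
                                min_strength = 0.01)
  s1 <- find_scale_space_maxima(detector_volumes(build_scale_space(mk(5, 3), t_max = 32)),
                                min_strength = 0.01)
  expect_equal(nrow(s0), 2L)
  expect_equal(s1$i, s0$i + 3L)
  expect_equal(s1$j, s0$j + 5L)
  expect_equal(s1$k, s0$k)
})

test_that("signatures: bump scale, flat background, nested two-scale structure", {
  fx <- bump_fixture()
  sig <- scale_space_signature(fx$vol, 48, 48)
  expect_equal(sum(sig$is_max), 1L)
  expect_lt(abs(log(sig$t_px2[sig$is_max] / 8)), log(fx$vol$ratio) + 1e-9)
  expect_true(all(diff(sig$effective_scale) > 0))
  # flat corner far from the bump: negligible response at all scales
  sig0 <- scale_space_signature(fx$vol, 12, 12)
  expect_lt(max(abs(sig0$response)), 1e-6 * max(sig$response))
  # small strong bump on a much larger one: two signature maxima
  g2 <- gaussian_blob_image(
    c(160, 160), 1,
    data.frame(x = 80, y = 80, A = c(2.5, 3), t0 = c(1.5, 50)),
    allow_overlap = TRUE)
  v2 <- detector_volumes(build_scale_space(g2$image, t_max = 400))
  s2 <- scale_space_signature(v2, 80, 80)
  expect_gte(sum(s2$is_max), 2L)
})
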