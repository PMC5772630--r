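test_that("single positive pixel: unit-square region and 4-vertex contour", {
  A <- array(-1, c(9, 9, 3)); A[5, 5, 2] <- 1
  v <- fake_volume(A)
  reg <- extract_region(v, list(k = 2L, i = 5L, j = 5L))
  expect_equal(length(reg$pixels), 1L)
  ct <- trace_contour(reg, v, subpixel_factor = 1)
  expect_length(ct, 1L)
  V <- ct[[1]]$vertices
  expect_true(ct[[1]]$closed)
  expect_equal(nrow(V), 5L)           # 4 vertices plus closure
  expect_equal(abs(hessianblob:::polygon_area_signed(V[, "x"], V[, "y"])), 1)
  expect_equal(hessianblob:::polygon_perimeter(V[, "x"], V[, "y"]), 4)
})

test_that("3x3 block at 2 nm pixels measures 36 nm^2 and 24 nm", {
  A <- array(-1, c(11, 11, 3)); A[5:7, 5:7, 2] <- 1
  v <- fake_volume(A, pixel_size = 2)
  reg <- extract_region(v, list(k = 2L, i = 6L, j = 6L))
  expect_equal(length(reg$pixels), 9L)
  blob <- list(region = reg,
               contours = trace_contour(reg, v, subpixel_factor = 1))
  m <- measure_blob(v$image, blob)
  expect_equal(m$area, 36)
  expect_equal(m$perimeter, 24)
})

test_that("degenerate single-pixel region measures one pixel", {
  A <- array(-1, c(9, 9, 1)); A[4, 4, 1] <- 1
  v <- fake_volume(A, pixel_size = 2)
  reg <- extract_region(v, list(k = 1L, i = 4L, j = 4L))
  blob <- list(region = reg,
               contours = trace_contour(reg, v, subpixel_factor = 1))
  m <- measure_blob(v$image, blob)
  expect_equal(m$area, 4)
  expect_equal(m$perimeter, 8)
})

test_that("an inconsistent seed (detH <= 0) errors", {
  A <- array(-1, c(9, 9, 1))
  expect_error(extract_region(fake_volume(A), list(k = 1L, i = 4L, j = 4L)),
               "inconsistent seed")
})

test_that("a planted bump's region is a disk of radius sqrt(2 t)", {
  fx <- bump_fixture()
  s <- find_scale_space_maxima(fx$vol)
  reg <- extract_region(fx$vol, as.list(s[1, ]))
  r_eq <- sqrt(length(reg$pixels) / pi)
  expect_lt(abs(r_eq - sqrt(2 * s$t_px2)) / sqrt(2 * s$t_px2), 0.10)
  # well-separated bumps give disjoint regions (saddle between is negative)
  g2 <- gaussian_blob_image(c(96, 96), 1,
                            data.frame(x = c(32, 64), y = 48, A = 3, t0 = 8))
  v2 <- detector_volumes(build_scale_space(g2$image, t_max = 32))
  s2 <- find_scale_space_maxima(v2, min_strength = 0.01)
  expect_equal(nrow(s2), 2L)
  r1 <- extract_region(v2, as.list(s2[1, ]))
  r2 <- extract_region(v2, as.list(s2[2, ]))
  expect_length(intersect(r1$pixels, r2$pixels), 0L)
})

test_that("factor-20 subpixel contour matches the analytic circle", {
  fx <- bump_fixture()
  s <- find_scale_space_maxima(fx$vol)
  reg <- extract_region(fx$vol, as.list(s[1, ]))
  perims <- sapply(c(bilinear = "bilinear", bicubic = "bicubic"), function(ip) {
    ct <- trace_contour(reg, fx$vol, subpixel_factor = 20, interp = ip)
    expect_true(ct[[1]]$closed)
    V <- ct[[1]]$vertices
    # vertex spacing bounded by the refined cell diagonal
    steps <- sqrt(diff(V[, "x"])^2 + diff(V[, "y"])^2)
    expect_lte(max(steps), sqrt(2) / 20 + 1e-9)
    # contour encloses the seed
    expect_true(hessianblob:::point_in_polygon(47, 47, V[, "x"], V[, "y"]))
    hessianblob:::polygon_perimeter(V[, "x"], V[, "y"])
  })
  circle <- 2 * pi * sqrt(2 * 8)
  expect_lt(abs(perims["bilinear"] - circle) / circle, 0.02)
  expect_lt(abs(perims["bicubic"] - circle) / circle, 0.02)
  # bicubic interpolation hugs the analytic circle more closely
  expect_lt(abs(perims["bicubic"] - circle), abs(perims["bilinear"] - circle))
})

test_that("factor-1 polygon area equals the pixel count exactly", {
  fx <- bump_fixture()
  s <- find_scale_space_maxima(fx$vol)
  reg <- extract_region(fx$vol, as.list(s[1, ]))
  ct <- trace_contour(reg, fx$vol, subpixel_factor = 1)
  V <- ct[[1]]$vertices
  expect_equal(abs(hessianblob:::polygon_area_signed(V[, "x"], V[, "y"])),
               length(reg$pixels))
})

test_that("region area grows monotonically with evaluation scale", {
  fx <- bump_fixture()
  ks <- which(fx$vol$scales >= 4 & fx$vol$scales <= 16)  # t0/2 .. 2 t0
  areas <- vapply(ks, function(k) {
    length(extract_region(fx$vol, list(k = k, i = 48L, j = 48L))$pixels)
  }, numeric(1))
  expect_true(all(diff(areas) >= 0))
})

test_that("interior holes are traced and subtracted from the area", {
  A <- array(-1, c(13, 13, 1))
  A[4:10, 4:10, 1] <- 1
  A[7, 7, 1] <- -2            # one-pixel hole
  v <- fake_volume(A)
  reg <- extract_region(v, list(k = 1L, i = 4L, j = 4L))
  expect_equal(length(reg$pixels), 48L)
  ct <- trace_contour(reg, v, subpixel_factor = 1)
  rings <- vapply(ct, function(x) x$ring, character(1))
  expect_equal(sort(rings), c("hole", "outer"))
  m <- measure_blob(v$image, list(region = reg, contours = ct))
  expect_equal(m$area, 48)
})
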