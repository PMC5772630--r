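# Independent oracles and small fixture builders used across the suite.

# Brute-force 26-neighbour scan: strict maxima of a 3D array with value > 0
# and > min_strength; top/bottom scale layers use available neighbours only.
brute_force_maxima <- function(A, min_strength = 0) {
  d <- dim(A)
  out <- NULL
  for (k in seq_len(d[3])) for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    v <- A[i, j, k]
    if (v <= max(min_strength, 0)) next
    ok <- TRUE
    for (dk in -1:1) for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0 && dk == 0) next
      ii <- i + di; jj <- j + dj; kk <- k + dk
      if (ii < 1 || ii > d[1] || jj < 1 || jj > d[2] ||
          kk < 1 || kk > d[3]) next
      if (v <= A[ii, jj, kk]) { ok <- FALSE; break }
    }
    if (ok) out <- rbind(out, c(k = k, i = i, j = j, strength = v))
  }
  if (is.null(out)) {
    return(data.frame(k = integer(), i = integer(), j = integer(),
                      strength = numeric()))
  }
  out <- as.data.frame(out)
  out[order(-out$strength, out$k, out$i, out$j), ]
}

# Exhaustive intra-class-variance scan over all histogram bin cuts of
# log10(strengths); same binning/threshold convention as the implementation
# but the opposite (direct minimization) route.
otsu_scan_oracle <- function(strengths, bins = 256) {
  x <- log10(strengths)
  brk <- seq(min(x), max(x), length.out = bins + 1)
  h <- tabulate(pmin(findInterval(x, brk, rightmost.closed = TRUE), bins),
                nbins = bins)
  mid <- (brk[-1] + brk[-(bins + 1)]) / 2
  best <- Inf; best_cut <- NA
  for (cut in 1:(bins - 1)) {
    lo <- 1:cut; hi <- (cut + 1):bins
    w1 <- sum(h[lo]); w2 <- sum(h[hi])
    if (w1 == 0 || w2 == 0) next
    m1 <- sum(h[lo] * mid[lo]) / w1
    m2 <- sum(h[hi] * mid[hi]) / w2
    v1 <- sum(h[lo] * (mid[lo] - m1)^2)
    v2 <- sum(h[hi] * (mid[hi] - m2)^2)
    if (v1 + v2 < best) { best <- v1 + v2; best_cut <- cut }
  }
  10^brk[best_cut + 1]
}

# Dense direct 2D convolution with reflect padding (oracle for separable
# smoothing).
dense_conv2 <- function(M, k) {
  w <- (length(k) - 1L) / 2L
  K2 <- outer(k, k)
  n <- nrow(M); m <- ncol(M)
  ridx <- hessianblob:::reflect_index(n, w)
  cidx <- hessianblob:::reflect_index(m, w)
  P <- M[ridx, cidx]
  out <- matrix(0, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    out[i, j] <- sum(K2 * P[i:(i + 2 * w), j:(j + 2 * w)])
  }
  out
}

# Minimal detector_volume for unit tests that construct detH directly.
fake_volume <- function(detH, lap = NULL, scales = NULL, ratio = 2,
                        pixel_size = 1) {
  d <- dim(detH)
  if (is.null(lap)) lap <- array(-1, d)
  if (is.null(scales)) scales <- 2^(seq_len(d[3]) - 1)
  img <- height_image(matrix(0, d[1], d[2]), pixel_size)
  structure(
    list(detH = detH, lap = lap, scales = scales, ratio = ratio,
         border_band = rep(0L, d[3]), image = img),
    class = "detector_volume"
  )
}

# One planted bump plus its detector volume, cached (several files probe
# the same stated layout).
.fixture_cache <- new.env(parent = emptyenv())

bump_fixture <- function() {
  if (!is.null(.fixture_cache$bump)) return(.fixture_cache$bump)
  g <- gaussian_blob_image(c(96, 96), 1,
                           data.frame(x = 48, y = 48, A = 3, t0 = 8))
  vol <- detector_volumes(build_scale_space(g$image, t_max = 64))
  .fixture_cache$bump <- list(gen = g, vol = vol)
  .fixture_cache$bump
}
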