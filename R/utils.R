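# Internal numerical helpers shared across modules.

# Half-sample symmetric (reflect) index vector for positions 1-w .. n+w.
# Reflection preserves constants and, with a symmetric normalized kernel,
# conserves the image sum exactly.
reflect_index <- function(n, w) {
  i <- (1 - w):(n + w)
  j <- (i - 1) %% (2 * n)
  ifelse(j < n, j + 1, 2 * n - j)
}

# Banded convolution operator: n x (n + 2w) matrix applying kernel k
# (length 2w + 1) to a reflect-padded signal.
band_matrix <- function(n, w, k) {
  A <- matrix(0, n, n + 2 * w)
  for (d in 0:(2 * w)) A[cbind(seq_len(n), seq_len(n) + d)] <- k[d + 1]
  A
}

# Separable convolution with reflect padding (rows then columns).
conv_separable <- function(M, k) {
  w <- attr(k, "half_width")
  if (is.null(w)) w <- (length(k) - 1L) / 2L
  if (w == 0) return(M * k[1])
  n <- nrow(M); m <- ncol(M)
  P <- M[reflect_index(n, w), , drop = FALSE]
  Q <- band_matrix(n, w, k) %*% P
  P2 <- Q[, reflect_index(m, w), drop = FALSE]
  P2 %*% t(band_matrix(m, w, k))
}

# Central differences on the full grid, one-sided at the borders.
# Column direction = x, row direction = y.
diff_col <- function(M) {
  m <- ncol(M)
  D <- matrix(0, nrow(M), m)
  D[, 2:(m - 1)] <- (M[, 3:m] - M[, 1:(m - 2)]) / 2
  D[, 1] <- M[, 2] - M[, 1]
  D[, m] <- M[, m] - M[, m - 1]
  D
}

diff_row <- function(M) {
  n <- nrow(M)
  D <- matrix(0, n, ncol(M))
  D[2:(n - 1), ] <- (M[3:n, ] - M[1:(n - 2), ]) / 2
  D[1, ] <- M[2, ] - M[1, ]
  D[n, ] <- M[n, ] - M[n - 1, ]
  D
}

diff2_col <- function(M) {
  m <- ncol(M)
  D <- matrix(0, nrow(M), m)
  D[, 2:(m - 1)] <- M[, 3:m] - 2 * M[, 2:(m - 1)] + M[, 1:(m - 2)]
  D[, 1] <- M[, 1] - 2 * M[, 2] + M[, 3]
  D[, m] <- M[, m] - 2 * M[, m - 1] + M[, m - 2]
  D
}

diff2_row <- function(M) {
  n <- nrow(M)
  D <- matrix(0, n, ncol(M))
  D[2:(n - 1), ] <- M[3:n, ] - 2 * M[2:(n - 1), ] + M[1:(n - 2), ]
  D[1, ] <- M[1, ] - 2 * M[2, ] + M[3, ]
  D[n, ] <- M[n, ] - 2 * M[n - 1, ] + M[n - 2, ]
  D
}

# Shifted view of a 3D array, filling with `fill` outside; out[i,j,k] =
# A[i+dr, j+dc, k+dk].
shift3 <- function(A, dr, dc, dk, fill = -Inf) {
  d <- dim(A)
  out <- array(fill, d)
  src_r <- max(1, 1 + dr):min(d[1], d[1] + dr)
  src_c <- max(1, 1 + dc):min(d[2], d[2] + dc)
  src_k <- max(1, 1 + dk):min(d[3], d[3] + dk)
  out[src_r - dr, src_c - dc, src_k - dk] <- A[src_r, src_c, src_k, drop = FALSE]
  out
}

# Even-odd ray-crossing point-in-polygon test; px, py scalars, polygon open
# or closed (duplicate last vertex tolerated).
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  if (vx[1] == vx[n] && vy[1] == vy[n]) {
    vx <- vx[-n]; vy <- vy[-n]; n <- n - 1L
  }
  j <- c(n, seq_len(n - 1L))
  crosses <- ((vy > py) != (vy[j] > py)) &
    (px < (vx[j] - vx) * (py - vy) / (vy[j] - vy) + vx)
  sum(crosses) %% 2L == 1L
}

# Shoelace signed area of a polygon given open or closed vertex lists.
polygon_area_signed <- function(vx, vy) {
  n <- length(vx)
  if (n < 3) return(0)
  if (vx[1] == vx[n] && vy[1] == vy[n]) {
    vx <- vx[-n]; vy <- vy[-n]; n <- n - 1L
  }
  j <- c(2:n, 1L)
  sum(vx * vy[j] - vx[j] * vy) / 2
}

polygon_perimeter <- function(vx, vy) {
  n <- length(vx)
  if (n < 2) return(0)
  if (vx[1] != vx[n] || vy[1] != vy[n]) {
    vx <- c(vx, vx[1]); vy <- c(vy, vy[1]); n <- n + 1L
  }
  sum(sqrt(diff(vx)^2 + diff(vy)^2))
}

# 1D interpolation operator from grid 1..n onto positions `pos` (within
# [1, n]); rows are interpolation weights. method "bilinear" is piecewise
# linear; "bicubic" is Catmull-Rom cubic convolution with clamped ends.
interp_matrix_1d <- function(n, pos, method = c("bilinear", "bicubic")) {
  method <- match.arg(method)
  B <- matrix(0, length(pos), n)
  i0 <- pmin(pmax(floor(pos), 1L), n - 1L)
  f <- pos - i0
  if (method == "bilinear") {
    B[cbind(seq_along(pos), i0)] <- 1 - f
    B[cbind(seq_along(pos), i0 + 1L)] <- B[cbind(seq_along(pos), i0 + 1L)] + f
  } else {
    # Catmull-Rom weights for samples i0-1, i0, i0+1, i0+2 (clamped)
    w0 <- ((-0.5 * f + 1) * f - 0.5) * f
    w1 <- ((1.5 * f - 2.5) * f) * f + 1
    w2 <- ((-1.5 * f + 2) * f + 0.5) * f
    w3 <- ((0.5 * f - 0.5) * f) * f
    idx <- cbind(pmax(i0 - 1L, 1L), i0, i0 + 1L, pmin(i0 + 2L, n))
    W <- cbind(w0, w1, w2, w3)
    for (s in 1:4) {
      ij <- cbind(seq_along(pos), idx[, s])
      B[ij] <- B[ij] + W[, s]
    }
  }
  B
}

# Bilinear sample of matrix M at fractional (row, col) positions.
bilinear_sample <- function(M, r, c) {
  n <- nrow(M); m <- ncol(M)
  r <- pmin(pmax(r, 1), n); c <- pmin(pmax(c, 1), m)
  r0 <- pmin(pmax(floor(r), 1L), n - 1L)
  c0 <- pmin(pmax(floor(c), 1L), m - 1L)
  fr <- r - r0; fc <- c - c0
  M[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    M[cbind(r0 + 1L, c0)] * fr * (1 - fc) +
    M[cbind(r0, c0 + 1L)] * (1 - fr) * fc +
    M[cbind(r0 + 1L, c0 + 1L)] * fr * fc
}

# Vectorized-frontier BFS flood fill over a logical mask, 8-connectivity.
# Returns linear indices of the connected component containing seed_idx.
# O(component area) with one vectorized step per frontier layer.
flood_fill8 <- function(mask, seed_idx) {
  n <- nrow(mask); m <- ncol(mask)
  visited <- matrix(FALSE, n, m)
  visited[seed_idx] <- TRUE
  frontier <- seed_idx
  acc <- seed_idx
  while (length(frontier) > 0) {
    r <- ((frontier - 1L) %% n) + 1L
    c <- ((frontier - 1L) %/% n) + 1L
    nb_r <- c(r - 1L, r - 1L, r - 1L, r, r, r + 1L, r + 1L, r + 1L)
    nb_c <- c(c - 1L, c, c + 1L, c - 1L, c + 1L, c - 1L, c, c + 1L)
    ok <- nb_r >= 1L & nb_r <= n & nb_c >= 1L & nb_c <= m
    nb <- (nb_c[ok] - 1L) * n + nb_r[ok]
    nb <- unique(nb[mask[nb] & !visited[nb]])
    visited[nb] <- TRUE
    acc <- c(acc, nb)
    frontier <- nb
  }
  acc
}

# 8-connected dilation of a logical matrix by one pixel.
dilate8 <- function(M) {
  n <- nrow(M); m <- ncol(M)
  pad <- matrix(FALSE, n + 2, m + 2)
  pad[2:(n + 1), 2:(m + 1)] <- M
  out <- matrix(FALSE, n, m)
  for (dr in -1:1) for (dc in -1:1) {
    out <- out | pad[(2 + dr):(n + 1 + dr), (2 + dc):(m + 1 + dc)]
  }
  out
}

# Label 8-connected components of a logical mask; returns integer matrix
# (0 = background). Iterative flood fill; suitable for the modest component
# counts seen in detector masks.
label_components8 <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  remaining <- mask
  nlab <- 0L
  while (any(remaining)) {
    nlab <- nlab + 1L
    seed_idx <- which(remaining)[1]
    comp <- matrix(FALSE, nrow(mask), ncol(mask))
    comp[seed_idx] <- TRUE
    repeat {
      grown <- dilate8(comp) & remaining
      if (sum(grown) == sum(comp)) break
      comp <- grown
    }
    lab[comp] <- nlab
    remaining <- remaining & !comp
  }
  lab
}
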