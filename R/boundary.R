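#' Extract the positive-curvature support region of a blob
#'
#' The spatial extent of a blob at its selected scale is the 8-connected
#' component of strictly positive determinant-of-Hessian (equivalently,
#' positive Gaussian curvature) containing the seed pixel, found by flood
#' fill at the seed's scale layer.
#'
#' @param vol A `detector_volume`.
#' @param seed One-row seed (`k`, `i`, `j`) with `detH > 0` at the seed.
#' @return An object of class `blob_region`: list with `k`, `t_px2`,
#'   `pixels` (linear indices into the layer), `dims`, `seed`,
#'   `connectivity` (8), `touches_border_band`.
#' @export
extract_region <- function(vol, seed) {
  stopifnot(inherits(vol, "detector_volume"))
  Z <- vol$detH[, , seed$k]
  d <- dim(Z)
  if (Z[seed$i, seed$j] <= 0) {
    stop("inconsistent seed: detH <= 0 at seed pixel", call. = FALSE)
  }
  # strictly positive up to a relative floating-point guard: structureless
  # directions (e.g. pure scan-line offsets) give detH that is exactly zero
  # analytically but rounds to +/- machine dust, which must not connect
  tol_pos <- 1e-12 * max(abs(Z))
  pix <- sort(flood_fill8(Z > tol_pos, (seed$j - 1L) * d[1] + seed$i))
  rows <- ((pix - 1L) %% d[1]) + 1L
  cols <- ((pix - 1L) %/% d[1]) + 1L
  band <- vol$border_band[seed$k]
  structure(
    list(k = seed$k, t_px2 = vol$scales[seed$k],
         pixels = pix, dims = d,
         seed = c(i = seed$i, j = seed$j),
         connectivity = 8L,
         touches_border_band = any(rows <= band | rows > d[1] - band |
                                     cols <= band | cols > d[2] - band)),
    class = "blob_region"
  )
}

region_rows <- function(region) ((region$pixels - 1L) %% region$dims[1]) + 1L
region_cols <- function(region) ((region$pixels - 1L) %/% region$dims[1]) + 1L

# Pixel-edge boundary polygons of a pixel set: loops of pixel-corner
# vertices with the outer ring and any hole rings. Vertices in (row, col)
# half-integer coordinates. At pinch corners (diagonal connections) the
# continuation that keeps a single loop is preferred.
pixel_edge_polygons <- function(rows, cols) {
  n_px <- length(rows)
  keyf <- function(r2, c2) r2 * 1e6 + c2   # half-unit integer coords
  inset <- new.env(hash = TRUE, size = 4 * n_px)
  for (q in seq_len(n_px)) {
    assign(as.character(keyf(2 * rows[q], 2 * cols[q])), TRUE, envir = inset)
  }
  inreg <- function(r, c) {
    exists(as.character(keyf(2 * r, 2 * c)), envir = inset)
  }
  # directed boundary edges, clockwise around each pixel in (col, row-down)
  from <- to <- numeric(0)
  fr_r <- fr_c <- to_r <- to_c <- numeric(0)
  add_edge <- function(r1, c1, r2, c2) {
    fr_r <<- c(fr_r, r1); fr_c <<- c(fr_c, c1)
    to_r <<- c(to_r, r2); to_c <<- c(to_c, c2)
  }
  for (q in seq_len(n_px)) {
    r <- rows[q]; c <- cols[q]
    if (!inreg(r - 1, c)) add_edge(r - 0.5, c - 0.5, r - 0.5, c + 0.5)
    if (!inreg(r, c + 1)) add_edge(r - 0.5, c + 0.5, r + 0.5, c + 0.5)
    if (!inreg(r + 1, c)) add_edge(r + 0.5, c + 0.5, r + 0.5, c - 0.5)
    if (!inreg(r, c - 1)) add_edge(r + 0.5, c - 0.5, r - 0.5, c - 0.5)
  }
  ne <- length(fr_r)
  fkey <- fr_r * 2e6 + fr_c * 2
  used <- rep(FALSE, ne)
  loops <- list()
  for (start in seq_len(ne)) {
    if (used[start]) next
    path_r <- fr_r[start]; path_c <- fr_c[start]
    cur <- start
    repeat {
      used[cur] <- TRUE
      path_r <- c(path_r, to_r[cur]); path_c <- c(path_c, to_c[cur])
      if (to_r[cur] == fr_r[start] && to_c[cur] == fr_c[start]) break
      nxt <- which(!used & fkey == to_r[cur] * 2e6 + to_c[cur] * 2)
      if (length(nxt) == 0) break   # should not happen: edges pair up
      if (length(nxt) > 1) {
        # pinch vertex between diagonally touching pixels: continue onto
        # the other pixel so the component keeps a single outer loop
        din <- c(to_r[cur] - fr_r[cur], to_c[cur] - fr_c[cur])
        turn <- vapply(nxt, function(e) {
          dout <- c(to_r[e] - fr_r[e], to_c[e] - fr_c[e])
          din[2] * dout[1] - din[1] * dout[2]
        }, numeric(1))
        nxt <- nxt[which.min(turn)]
      }
      cur <- nxt
    }
    loops[[length(loops) + 1L]] <- cbind(row = path_r, col = path_c)
  }
  # drop collinear midpoints so a straight run is a single edge
  loops <- lapply(loops, function(P) {
    n <- nrow(P)
    if (n <= 4) return(P)
    open <- P[-n, , drop = FALSE]
    m <- nrow(open)
    prev <- open[c(m, 1:(m - 1)), , drop = FALSE]
    nxt <- open[c(2:m, 1), , drop = FALSE]
    keep <- !((nxt[, 1] - prev[, 1]) * (open[, 2] - prev[, 2]) ==
                (open[, 1] - prev[, 1]) * (nxt[, 2] - prev[, 2]))
    open <- open[keep, , drop = FALSE]
    rbind(open, open[1, , drop = FALSE])
  })
  loops
}

#' Trace the closed boundary contour(s) of a blob region
#'
#' At `subpixel_factor = 1` the pixel-resolution boundary is returned: the
#' polygon of pixel edges around the region (and around any interior
#' holes). At factors above 1 the detector layer is interpolated on a grid
#' refined by the factor (bilinear or Catmull-Rom bicubic) and the zero
#' level set enclosing the seed's component is traced as closed polygon(s),
#' outer contour first, holes after.
#'
#' @param region A `blob_region` from [extract_region()].
#' @param vol The `detector_volume` the region came from.
#' @param subpixel_factor Integer >= 1; grid refinement factor.
#' @param interp Interpolation for refined grids: `"bilinear"` or
#'   `"bicubic"`.
#' @return List of contours; each an object of class `hb_contour`: list with
#'   `vertices` (matrix with columns `x`, `y`, physical units; first vertex
#'   repeated last), `ring` (`"outer"` or `"hole"`), `closed`, `valid`
#'   (`FALSE` when the region touches the untrusted border band),
#'   `subpixel_factor`, `interp`.
#' @export
trace_contour <- function(region, vol, subpixel_factor = 1,
                          interp = c("bilinear", "bicubic")) {
  interp <- match.arg(interp)
  stopifnot(inherits(region, "blob_region"),
            inherits(vol, "detector_volume"),
            subpixel_factor >= 1, length(region$pixels) > 0)
  subpixel_factor <- as.integer(subpixel_factor)
  px <- vol$image$pixel_size
  valid <- !region$touches_border_band
  rows <- region_rows(region); cols <- region_cols(region)

  wrap <- function(P_rowcol, ring) {
    closed <- nrow(P_rowcol) >= 4 &&
      P_rowcol[1, 1] == P_rowcol[nrow(P_rowcol), 1] &&
      P_rowcol[1, 2] == P_rowcol[nrow(P_rowcol), 2]
    structure(
      list(vertices = cbind(x = (P_rowcol[, 2] - 1) * px,
                            y = (P_rowcol[, 1] - 1) * px),
           ring = ring, closed = closed, valid = valid && closed,
           subpixel_factor = subpixel_factor, interp = interp),
      class = "hb_contour"
    )
  }

  if (subpixel_factor == 1L) {
    loops <- pixel_edge_polygons(rows, cols)
    # orientation sign distinguishes outer ring(s) (positive, by the edge
    # direction convention) from hole rings (negative)
    sa <- vapply(loops, function(P) {
      polygon_area_signed(P[, 2], P[, 1])
    }, numeric(1))
    ord <- order(sa <= 0, -abs(sa))
    out <- lapply(ord, function(q) {
      wrap(loops[[q]], if (sa[q] > 0) "outer" else "hole")
    })
    return(out)
  }

  Z <- vol$detH[, , region$k]
  d <- dim(Z)
  margin <- 3L
  r0 <- max(1L, min(rows) - margin); r1 <- min(d[1], max(rows) + margin)
  c0 <- max(1L, min(cols) - margin); c1 <- min(d[2], max(cols) + margin)
  Zc <- Z[r0:r1, c0:c1]
  # mask pixels beyond a 2-pixel guard ring around the region to a small
  # negative value so only this component's zero-crossing is traced; the
  # ring itself keeps true detector values
  mask <- matrix(FALSE, nrow(Zc), ncol(Zc))
  mask[cbind(rows - r0 + 1L, cols - c0 + 1L)] <- TRUE
  guard <- dilate8(dilate8(mask))
  floor_val <- -1e-6 * max(abs(Zc), .Machine$double.xmin)
  Zc[!guard] <- pmin(Zc[!guard], floor_val)

  s <- subpixel_factor
  rp <- seq(1, nrow(Zc), by = 1 / s)
  cp <- seq(1, ncol(Zc), by = 1 / s)
  Zu <- interp_matrix_1d(nrow(Zc), rp, interp) %*% Zc %*%
    t(interp_matrix_1d(ncol(Zc), cp, interp))
  cl <- grDevices::contourLines(x = rp + (r0 - 1), y = cp + (c0 - 1),
                                z = Zu, levels = 0)
  if (length(cl) == 0) {
    # degenerate: fall back to the pixel-edge polygon
    return(trace_contour(region, vol, 1L, interp))
  }
  polys <- lapply(cl, function(co) {
    P <- cbind(row = co$x, col = co$y)
    closes <- sqrt((P[1, 1] - P[nrow(P), 1])^2 +
                     (P[1, 2] - P[nrow(P), 2])^2) < 2 / s
    if (closes && (P[1, 1] != P[nrow(P), 1] || P[1, 2] != P[nrow(P), 2])) {
      P <- rbind(P, P[1, , drop = FALSE])
    }
    list(P = P, closed = closes)
  })
  seed_r <- region$seed["i"]; seed_c <- region$seed["j"]
  contains_seed <- vapply(polys, function(p) {
    p$closed && point_in_polygon(seed_r, seed_c, p$P[, 1], p$P[, 2])
  }, logical(1))
  if (!any(contains_seed)) {
    return(trace_contour(region, vol, 1L, interp))
  }
  areas <- vapply(polys, function(p) {
    abs(polygon_area_signed(p$P[, 2], p$P[, 1]))
  }, numeric(1))
  outer_i <- which(contains_seed)[which.max(areas[contains_seed])]
  outer_P <- polys[[outer_i]]$P
  out <- list(wrap(outer_P, "outer"))
  for (q in setdiff(seq_along(polys), outer_i)) {
    p <- polys[[q]]
    if (p$closed &&
        point_in_polygon(p$P[1, 1], p$P[1, 2], outer_P[, 1], outer_P[, 2]) &&
        !point_in_polygon(seed_r, seed_c, p$P[, 1], p$P[, 2])) {
      out[[length(out) + 1L]] <- wrap(p$P, "hole")
    }
  }
  out
}
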