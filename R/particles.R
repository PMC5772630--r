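#' Resolve overlapping blobs by blob strength
#'
#' When two blobs overlap in the image plane only the one with the stronger
#' detector response at its centre is kept. The rule is applied greedily in
#' descending strength (ties broken by scale, row, column indices): a blob
#' is accepted iff its pixel-resolution region shares no pixel with any
#' already-accepted blob's region.
#'
#' @param blobs List of blob records, each with `seed` (list with
#'   `strength`, `k`, `i`, `j`) and `region` (a `blob_region`).
#' @return The accepted sublist, in descending strength order.
#' @export
resolve_overlaps <- function(blobs) {
  if (length(blobs) == 0) return(blobs)
  strength <- vapply(blobs, function(b) b$seed$strength, numeric(1))
  kk <- vapply(blobs, function(b) b$seed$k, numeric(1))
  ii <- vapply(blobs, function(b) b$seed$i, numeric(1))
  jj <- vapply(blobs, function(b) b$seed$j, numeric(1))
  ord <- order(-strength, kk, ii, jj)
  dims <- blobs[[ord[1]]]$region$dims
  occupied <- logical(prod(dims))
  keep <- logical(length(blobs))
  for (q in ord) {
    p <- blobs[[q]]$region$pixels
    if (!any(occupied[p])) {
      occupied[p] <- TRUE
      keep[q] <- TRUE
    }
  }
  blobs[ord[keep[ord]]]
}

#' Filter blobs by minimum scale
#'
#' Keeps blobs whose selected scale `t` is at least `t0` (pixel^2). A pure
#' filter: surviving blobs are returned untouched, so regions, contours and
#' centres are bit-identical to the unfiltered run.
#'
#' @param blobs List of blob records with a `t_px2` element.
#' @param t0 Minimum scale in pixel^2 (>= 0); 0 keeps everything.
#' @return Filtered list.
#' @export
filter_min_scale <- function(blobs, t0) {
  stopifnot(t0 >= 0)
  Filter(function(b) b$t_px2 >= t0, blobs)
}

#' Filter blobs by minimum strength
#'
#' Keeps blobs whose strength (detector value at the scale-space maximum) is
#' at least `s_min`. With `s_min = 0` every blob survives — the
#' zero-parameter limit of the algorithm. A pure filter: survivors are
#' unaltered.
#'
#' @param blobs List of blob records with `seed$strength`.
#' @param s_min Minimum strength (>= 0).
#' @return Filtered list.
#' @export
filter_min_strength <- function(blobs, s_min) {
  stopifnot(s_min >= 0)
  Filter(function(b) b$seed$strength >= s_min, blobs)
}

#' Automatic strength threshold by Otsu's method
#'
#' Blob strengths span many decades, so the threshold is computed on
#' `log10(strength)`: a 256-bin histogram is scanned for the cut maximizing
#' the between-class variance (equivalently minimizing the intra-class
#' variance), and the chosen bin boundary is mapped back to the linear
#' scale. Separates "significant" from "insignificant" blobs without a
#' user-set parameter.
#'
#' @param strengths Numeric vector of positive blob strengths (>= 2 values).
#' @param bins Number of histogram bins (default 256).
#' @return Threshold on the linear strength scale.
#' @export
otsu_strength_threshold <- function(strengths, bins = 256) {
  stopifnot(length(strengths) >= 2, all(strengths > 0))
  x <- log10(strengths)
  if (diff(range(x)) == 0) {
    warning("degenerate strength distribution: all values equal")
    return(strengths[1])
  }
  brk <- seq(min(x), max(x), length.out = bins + 1)
  h <- tabulate(pmin(findInterval(x, brk, rightmost.closed = TRUE), bins),
                nbins = bins)
  mid <- (brk[-1] + brk[-(bins + 1)]) / 2
  w1 <- cumsum(h)
  w2 <- sum(h) - w1
  m1 <- cumsum(h * mid) / pmax(w1, 1)
  m2 <- (sum(h * mid) - cumsum(h * mid)) / pmax(w2, 1)
  between <- w1 * w2 * (m1 - m2)^2
  between[w1 == 0 | w2 == 0] <- -Inf
  cut <- which.max(between)          # classes: bins <= cut vs > cut
  10^brk[cut + 1]
}

#' Automatic strength threshold by 2-means clustering
#'
#' Alternative automatic threshold: k-means with k = 2 on `log10(strength)`,
#' initialized at the sample extremes for determinism; the threshold is the
#' midpoint between the two cluster boundaries, mapped back to linear scale.
#'
#' @inheritParams otsu_strength_threshold
#' @return Threshold on the linear strength scale.
#' @export
kmeans_strength_threshold <- function(strengths) {
  stopifnot(length(strengths) >= 2, all(strengths > 0))
  x <- log10(strengths)
  if (diff(range(x)) == 0) {
    warning("degenerate strength distribution: all values equal")
    return(strengths[1])
  }
  km <- stats::kmeans(x, centers = matrix(range(x), ncol = 1))
  lo <- which.min(km$centers)
  10^((max(x[km$cluster == lo]) + min(x[km$cluster != lo])) / 2)
}

#' Measure particle properties from region and contour
#'
#' Computes the measurement set from the polygon approximation of the
#' boundary: projected area (shoelace area of the outer polygon minus any
#' hole polygons), perimeter (outer polygon length), maximum raw height
#' inside the region, and relative height above a provisional baseline (the
#' mean raw height sampled along the outer contour — an explicit stand-in
#' while true background estimation under particles is unavailable). The
#' provisional volume integrates (height - baseline) over the region.
#'
#' @param img The source [height_image].
#' @param blob Blob record with `region` (`blob_region`) and `contours`
#'   (list from [trace_contour()], outer first).
#' @return One-row tibble: `area`, `perimeter`, `max_height`,
#'   `relative_height`, `equivalent_radius`, `volume_provisional`,
#'   `n_pixels`, `valid`.
#' @export
measure_blob <- function(img, blob) {
  stopifnot(inherits(img, "height_image"))
  px <- img$pixel_size
  contours <- blob$contours
  outer <- contours[[1]]
  valid <- isTRUE(outer$closed) && isTRUE(outer$valid)
  V <- outer$vertices
  area <- abs(polygon_area_signed(V[, "x"], V[, "y"]))
  for (ct in contours[-1]) {
    if (identical(ct$ring, "hole")) {
      area <- area - abs(polygon_area_signed(ct$vertices[, "x"],
                                             ct$vertices[, "y"]))
    }
  }
  perimeter <- polygon_perimeter(V[, "x"], V[, "y"])
  rows <- region_rows(blob$region); cols <- region_cols(blob$region)
  h_in <- img$heights[cbind(rows, cols)]
  max_height <- max(h_in)
  baseline <- mean(bilinear_sample(img$heights,
                                   V[, "y"] / px + 1, V[, "x"] / px + 1))
  tibble::tibble(
    area = area,
    perimeter = perimeter,
    max_height = max_height,
    relative_height = max_height - baseline,
    equivalent_radius = sqrt(area / pi),
    volume_provisional = sum(h_in - baseline) * px^2,
    n_pixels = length(rows),
    valid = valid
  )
}
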