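#' Find scale-space maxima of the determinant-of-Hessian detector
#'
#' Candidate blob centres are voxels of the detector volume strictly greater
#' than all 26 neighbours in the 3 x 3 x 3 scale-space neighbourhood (top and
#' bottom scale layers are compared against their available neighbours
#' only). Exact plateau ties yield no seed. Maxima must be strictly
#' positive and exceed `min_strength`; seeds inside the per-scale untrusted
#' border band are discarded when `exclude_border` is `TRUE`.
#'
#' @param vol A `detector_volume` from [detector_volumes()].
#' @param min_strength Minimum detector value for a seed (>= 0).
#' @param exclude_border Drop seeds within `ceiling(3 sqrt(t))` pixels of the
#'   image edge (default `TRUE`).
#' @return A tibble of seeds sorted by descending strength (ties broken by
#'   scale, row, column): columns `k`, `i`, `j` (scale/row/col indices),
#'   `strength`, `t_px2`.
#' @export
find_scale_space_maxima <- function(vol, min_strength = 0,
                                    exclude_border = TRUE) {
  stopifnot(inherits(vol, "detector_volume"), min_strength >= 0)
  A <- vol$detH
  d <- dim(A)
  if (any(d == 0)) {
    return(tibble::tibble(k = integer(), i = integer(), j = integer(),
                          strength = numeric(), t_px2 = numeric()))
  }
  # positive up to a relative floating-point guard, consistent with region
  # extraction (see extract_region): machine dust around detH = 0 is not a
  # blob response
  is_max <- A > max(min_strength, 1e-12 * max(abs(A)), 0)
  for (dr in -1:1) for (dc in -1:1) for (dk in -1:1) {
    if (dr == 0 && dc == 0 && dk == 0) next
    if (!any(is_max)) break
    is_max <- is_max & (A > shift3(A, dr, dc, dk, fill = -Inf))
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    return(tibble::tibble(k = integer(), i = integer(), j = integer(),
                          strength = numeric(), t_px2 = numeric()))
  }
  k <- idx[, 3]; i <- idx[, 1]; j <- idx[, 2]
  if (exclude_border) {
    band <- vol$border_band[k]
    keep <- i > band & i <= d[1] - band & j > band & j <= d[2] - band
    k <- k[keep]; i <- i[keep]; j <- j[keep]
  }
  strength <- A[cbind(i, j, k)]
  ord <- order(-strength, k, i, j)
  tibble::tibble(k = as.integer(k[ord]), i = as.integer(i[ord]),
                 j = as.integer(j[ord]), strength = strength[ord],
                 t_px2 = vol$scales[k[ord]])
}

#' Classify blob sign from the normalized Laplacian
#'
#' The determinant of the Hessian is maximal at both bright and dark blobs;
#' the sign is recovered from the Laplacian at the seed voxel: negative for
#' bright blobs (protrusions), positive for dark blobs (depressions). An
#' exactly zero Laplacian is degenerate and classified bright with a
#' warning.
#'
#' @param seeds Tibble of seeds (columns `k`, `i`, `j`), as returned by
#'   [find_scale_space_maxima()].
#' @param vol The `detector_volume` the seeds came from.
#' @return `seeds` with a `sign` column (`"bright"` or `"dark"`).
#' @export
classify_sign <- function(seeds, vol) {
  stopifnot(inherits(vol, "detector_volume"))
  if (nrow(seeds) == 0) {
    return(dplyr::mutate(seeds, sign = character()))
  }
  lap <- vol$lap[cbind(seeds$i, seeds$j, seeds$k)]
  if (any(lap == 0)) {
    warning("degenerate seed(s) with zero Laplacian classified as bright")
  }
  dplyr::mutate(seeds, sign = ifelse(lap > 0, "dark", "bright"))
}

#' Refine a blob centre to subpixel precision
#'
#' Fits the local second-order Taylor model of the detector around the seed
#' voxel and solves `offset = -H^{ -1} grad` for the interpolated extremum,
#' in (row, col, scale-index) units. If any offset component exceeds 0.5 the
#' estimate is re-seeded at the adjacent voxel and repeated, up to
#' `max_iter` times. The refined scale is interpolated geometrically (in
#' log t), matching the geometric scale sampling.
#'
#' @param vol A `detector_volume`.
#' @param seed A one-row seed (list or tibble row with `k`, `i`, `j`).
#' @param max_iter Maximum re-seeding iterations (default 5).
#' @return One-row tibble: subpixel `x`, `y` (physical units), `row`, `col`
#'   (pixel units), `t_px2`, `t_phys`, offsets `off_i`, `off_j`, `off_k`,
#'   and `converged`. Seeds lacking a full 26-neighbourhood or with a
#'   singular local Hessian are returned unrefined with `converged = FALSE`.
#' @export
refine_center_subpixel <- function(vol, seed, max_iter = 5) {
  stopifnot(inherits(vol, "detector_volume"))
  A <- vol$detH
  d <- dim(A)
  px <- vol$image$pixel_size
  k <- seed$k; i <- seed$i; j <- seed$j
  off <- c(0, 0, 0)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    if (i < 2 || i > d[1] - 1 || j < 2 || j > d[2] - 1 ||
        k < 2 || k > d[3] - 1) {
      off <- c(0, 0, 0); converged <- FALSE; break
    }
    g <- c((A[i + 1, j, k] - A[i - 1, j, k]) / 2,
           (A[i, j + 1, k] - A[i, j - 1, k]) / 2,
           (A[i, j, k + 1] - A[i, j, k - 1]) / 2)
    H <- matrix(0, 3, 3)
    H[1, 1] <- A[i + 1, j, k] - 2 * A[i, j, k] + A[i - 1, j, k]
    H[2, 2] <- A[i, j + 1, k] - 2 * A[i, j, k] + A[i, j - 1, k]
    H[3, 3] <- A[i, j, k + 1] - 2 * A[i, j, k] + A[i, j, k - 1]
    H[1, 2] <- H[2, 1] <- (A[i + 1, j + 1, k] - A[i + 1, j - 1, k] -
                             A[i - 1, j + 1, k] + A[i - 1, j - 1, k]) / 4
    H[1, 3] <- H[3, 1] <- (A[i + 1, j, k + 1] - A[i + 1, j, k - 1] -
                             A[i - 1, j, k + 1] + A[i - 1, j, k - 1]) / 4
    H[2, 3] <- H[3, 2] <- (A[i, j + 1, k + 1] - A[i, j + 1, k - 1] -
                             A[i, j - 1, k + 1] + A[i, j - 1, k - 1]) / 4
    sol <- tryCatch(solve(H, -g), error = function(e) NULL)
    if (is.null(sol) || any(!is.finite(sol))) {
      off <- c(0, 0, 0); converged <- FALSE; break
    }
    if (all(abs(sol) <= 0.5)) {
      off <- sol; converged <- TRUE; break
    }
    # move to the adjacent voxel indicated by the overflow and retry
    step <- round(pmin(pmax(sol, -1), 1))
    i <- as.integer(i + step[1]); j <- as.integer(j + step[2])
    k <- as.integer(k + step[3])
    if (iter == max_iter) { off <- c(0, 0, 0); converged <- FALSE }
  }
  row_sub <- i + off[1]
  col_sub <- j + off[2]
  log_ratio <- log(vol$ratio)
  t_hat <- exp(log(vol$scales[k]) + off[3] * log_ratio)
  tibble::tibble(
    x = (col_sub - 1) * px, y = (row_sub - 1) * px,
    row = row_sub, col = col_sub,
    t_px2 = t_hat, t_phys = t_hat * px^2,
    off_i = off[1], off_j = off[2], off_k = off[3],
    converged = converged
  )
}

#' Scale-space signature at a fixed point
#'
#' The detector response `detH(x0, y0; t)` at one pixel across all scales,
#' reported against the effective scale `log2(1 + t)`. Local maxima of the
#' signature are candidate natural scales of the structure at that point;
#' several maxima indicate nested substructure (blobs within blobs).
#'
#' @param vol A `detector_volume`.
#' @param i,j Pixel row and column indices of the probed point.
#' @return A tibble of class `hb_signature`: columns `t_px2`, `t_phys`,
#'   `effective_scale`, `response`, `is_max` (strict interior local maxima
#'   of the response).
#' @export
scale_space_signature <- function(vol, i, j) {
  stopifnot(inherits(vol, "detector_volume"))
  r <- vol$detH[i, j, ]
  n <- length(r)
  is_max <- rep(FALSE, n)
  if (n >= 3) {
    is_max[2:(n - 1)] <- r[2:(n - 1)] > r[1:(n - 2)] &
      r[2:(n - 1)] > r[3:n]
  }
  px <- vol$image$pixel_size
  out <- tibble::tibble(
    t_px2 = vol$scales,
    t_phys = vol$scales * px^2,
    effective_scale = log2(1 + vol$scales),
    response = r,
    is_max = is_max
  )
  class(out) <- c("hb_signature", class(out))
  attr(out, "point") <- c(i = i, j = j)
  out
}
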