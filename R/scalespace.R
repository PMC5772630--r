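#' Geometric scale list
#'
#' Scales `t` (pixel^2) sampled in geometric steps from `t_min` upward with
#' ratio `2^(1/layers_per_octave)`, continuing until `t_max` is reached or
#' exceeded, so that the requested range is fully covered.
#'
#' @param t_min,t_max Scale bounds in pixel^2, `0 < t_min < t_max`.
#' @param layers_per_octave Number of layers per doubling of `t` (>= 1).
#' @return A list with `t` (strictly increasing scales) and `ratio`.
#' @export
scale_list <- function(t_min, t_max, layers_per_octave = 4) {
  stopifnot(t_min > 0, t_max > t_min, layers_per_octave >= 1)
  ratio <- 2^(1 / layers_per_octave)
  n <- ceiling(log(t_max / t_min) / log(ratio)) + 1L
  t <- t_min * ratio^(0:(n - 1L))
  list(t = t, ratio = ratio)
}

#' Smooth an image at one scale
#'
#' Separable discrete Gaussian smoothing with reflect (half-sample
#' symmetric) border padding, which preserves constants and the total image
#' sum exactly.
#'
#' @param M Numeric matrix.
#' @param t Scale in pixel^2 (>= 0).
#' @param kernel Kernel family, see [discrete_gaussian_kernel()].
#' @param tol Kernel truncation tolerance.
#' @return Smoothed matrix of the same dimensions.
#' @export
smooth_image <- function(M, t, kernel = c("discrete", "sampled"),
                         tol = 1e-8) {
  kernel <- match.arg(kernel)
  conv_separable(M, discrete_gaussian_kernel(t, tol = tol, family = kernel))
}

#' Build the discrete scale-space representation
#'
#' Stacks progressively smoothed copies `L(x, y; t)` of a height image over
#' a geometric scale list. Each layer is smoothed directly from the source
#' image at its scale `t` (pixel^2).
#'
#' Scales below the pixel spacing carry no information and scales approaching
#' the image size leave nothing to detect, hence the default bounds
#' `t_min = 0.5` px^2 and `t_max = (min(nrow, ncol)/8)^2` px^2.
#'
#' @param img A [height_image] with dimensions at least 8 x 8.
#' @param t_min,t_max Scale bounds in pixel^2. `t_max` greater than the
#'   squared minimum image dimension is clamped with a warning.
#' @param layers_per_octave Scale sampling density (default 4).
#' @param kernel Kernel family (see [discrete_gaussian_kernel()]).
#' @param tol Kernel truncation tolerance.
#' @return An object of class `scale_space`: list with `layers` (array
#'   rows x cols x n_scales), `scales` (pixel^2), `ratio`, `image`,
#'   `kernel`, `border_band` (per-scale untrusted edge width, pixels).
#' @export
build_scale_space <- function(img, t_min = 0.5, t_max = NULL,
                              layers_per_octave = 4,
                              kernel = c("discrete", "sampled"),
                              tol = 1e-8) {
  kernel <- match.arg(kernel)
  stopifnot(inherits(img, "height_image"))
  d <- dim(img$heights)
  if (min(d) < 8) stop("image must be at least 8 x 8 pixels", call. = FALSE)
  if (!all(is.finite(img$heights))) {
    stop("non-finite pixels in input image", call. = FALSE)
  }
  if (is.null(t_max)) t_max <- (min(d) / 8)^2
  lim <- min(d)^2
  if (t_max > lim) {
    warning("t_max exceeds squared minimum image dimension; clamped")
    t_max <- lim
  }
  sl <- scale_list(t_min, t_max, layers_per_octave)
  layers <- array(NA_real_, c(d[1], d[2], length(sl$t)))
  for (k in seq_along(sl$t)) {
    layers[, , k] <- smooth_image(img$heights, sl$t[k], kernel = kernel,
                                  tol = tol)
  }
  structure(
    list(layers = layers, scales = sl$t, ratio = sl$ratio, image = img,
         kernel = kernel, tol = tol,
         border_band = pmax(1L, as.integer(ceiling(3 * sqrt(sl$t))))),
    class = "scale_space"
  )
}

#' @export
print.scale_space <- function(x, ...) {
  cat(sprintf("<scale_space> %d x %d px, %d scales t = %.3g..%.3g px^2 (ratio %.4g)\n",
              dim(x$layers)[1], dim(x$layers)[2], length(x$scales),
              min(x$scales), max(x$scales), x$ratio))
  invisible(x)
}

#' Finite-difference derivative fields of one scale layer
#'
#' First and second spatial derivatives of a smoothed layer, in pixel units,
#' by 3-point central differences (one-sided at the image border). The
#' column direction is x, the row direction is y; the mixed derivative is
#' computed symmetrically (the row and column operators commute).
#'
#' @param L Numeric matrix (one scale-space layer).
#' @return List with matrices `Lx`, `Ly`, `Lxx`, `Lyy`, `Lxy`.
#' @export
derivative_fields <- function(L) {
  list(
    Lx = diff_col(L),
    Ly = diff_row(L),
    Lxx = diff2_col(L),
    Lyy = diff2_row(L),
    Lxy = diff_row(diff_col(L))
  )
}

#' Scale-normalized blob-detector volumes
#'
#' Evaluates the two scale-normalized differential blob detectors over the
#' whole scale-space stack: the determinant of the Hessian
#' `detH = t^2 (Lxx Lyy - Lxy^2)`, maximal at blob centres of either sign,
#' and the Laplacian `lap = t (Lxx + Lyy)`, whose sign separates bright
#' blobs (negative) from dark blobs (positive). The normalization exponent
#' is fixed at 1 (plain `t` and `t^2` factors).
#'
#' @param ss A `scale_space` from [build_scale_space()].
#' @return An object of class `detector_volume`: list with 3D arrays `detH`
#'   and `lap`, plus `scales`, `ratio`, `border_band`, `image`.
#' @export
detector_volumes <- function(ss) {
  stopifnot(inherits(ss, "scale_space"))
  d <- dim(ss$layers)
  detH <- array(NA_real_, d)
  lap <- array(NA_real_, d)
  for (k in seq_len(d[3])) {
    f <- derivative_fields(ss$layers[, , k])
    t_k <- ss$scales[k]
    detH[, , k] <- t_k^2 * (f$Lxx * f$Lyy - f$Lxy^2)
    lap[, , k] <- t_k * (f$Lxx + f$Lyy)
  }
  structure(
    list(detH = detH, lap = lap, scales = ss$scales, ratio = ss$ratio,
         border_band = ss$border_band, image = ss$image),
    class = "detector_volume"
  )
}

#' @export
print.detector_volume <- function(x, ...) {
  cat(sprintf("<detector_volume> %d x %d px, %d scales, max detH %.4g\n",
              dim(x$detH)[1], dim(x$detH)[2], length(x$scales),
              max(x$detH)))
  invisible(x)
}

#' Gaussian curvature of a scale layer
#'
#' `K = (Lxx Lyy - Lxy^2) / (1 + Lx^2 + Ly^2)^2`, the product of principal
#' curvatures of the layer viewed as a surface. The denominator is strictly
#' positive, so `K` shares its sign with the determinant of the Hessian:
#' positive on convex blob interiors, negative on saddle-like background.
#' Boundary extraction therefore works on the detector sign directly; this
#' function is the explicit diagnostic.
#'
#' @param fields Derivative fields of one layer, from [derivative_fields()].
#' @return Numeric matrix `K`.
#' @export
gaussian_curvature <- function(fields) {
  (fields$Lxx * fields$Lyy - fields$Lxy^2) /
    (1 + fields$Lx^2 + fields$Ly^2)^2
}
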