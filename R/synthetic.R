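#' Generate a synthetic AFM-like image of Gaussian bumps
#'
#' Ground-truth image for validation: a sum of isotropic Gaussian bumps
#' `A * exp(-r^2 / (2 t0))` evaluated at pixel centres, on a zero (or
#' constant) background. Such a bump is exactly the profile whose
#' determinant-of-Hessian scale selection and boundary radius have closed
#' forms, which the test-suite oracles rely on.
#'
#' @param shape `c(rows, cols)` in pixels.
#' @param pixel_size Lateral pixel spacing in physical units (default 1).
#' @param blobs Data frame with one row per bump: columns `x`, `y`
#'   (subpixel centre in pixel coordinates: `x` = column, `y` = row,
#'   1-based), `A` (amplitude, height units) and `t0` (squared size scale in
#'   pixel^2).
#' @param background Constant background height (default 0).
#' @param allow_overlap Permit bumps closer than `4 sqrt(2 max(t0))`
#'   (default `FALSE`, which errors on crowded layouts).
#' @param check Enforce the layout margins (centres at least `3 sqrt(2 t0)`
#'   pixels from the border). Default `TRUE`.
#' @param unit Unit label.
#' @return List with `image` (a [height_image]) and `truth` (tibble: `id`,
#'   `x`, `y`, `A`, `t0_px2`, `sign`).
#' @export
gaussian_blob_image <- function(shape, pixel_size = 1, blobs,
                                background = 0, allow_overlap = FALSE,
                                check = TRUE, unit = "nm") {
  blobs <- tibble::as_tibble(blobs)
  n <- shape[1]; m <- shape[2]
  if (nrow(blobs) > 0) {
    stopifnot(all(blobs$t0 > 0), all(blobs$A != 0),
              all(blobs$x >= 1 & blobs$x <= m),
              all(blobs$y >= 1 & blobs$y <= n))
    if (check) {
      marg <- 3 * sqrt(2 * blobs$t0)
      if (any(blobs$x - 1 < marg | m - blobs$x < marg |
              blobs$y - 1 < marg | n - blobs$y < marg)) {
        stop("blob centre closer than 3*sqrt(2*t0) px to the image border",
             call. = FALSE)
      }
      if (nrow(blobs) > 1 && !allow_overlap) {
        dmin <- 4 * sqrt(2 * max(blobs$t0))
        dd <- as.matrix(stats::dist(cbind(blobs$x, blobs$y)))
        diag(dd) <- Inf
        if (any(dd < dmin)) {
          stop("blobs closer than 4*sqrt(2*max(t0)) px; pass ",
               "`allow_overlap = TRUE` if intended", call. = FALSE)
        }
      }
    }
  }
  H <- matrix(background, n, m)
  R <- matrix(seq_len(n), n, m)
  C <- matrix(seq_len(m), n, m, byrow = TRUE)
  for (q in seq_len(nrow(blobs))) {
    H <- H + blobs$A[q] *
      exp(-((R - blobs$y[q])^2 + (C - blobs$x[q])^2) / (2 * blobs$t0[q]))
  }
  truth <- tibble::tibble(
    id = seq_len(nrow(blobs)),
    x = blobs$x, y = blobs$y, A = blobs$A, t0_px2 = blobs$t0,
    sign = ifelse(blobs$A > 0, "bright", "dark")
  )
  list(image = height_image(H, pixel_size, unit = unit), truth = truth)
}

#' Generate a hexagonal trimer lattice image
#'
#' Emulates a 2D crystal of trimeric membrane proteins (the
#' bacteriorhodopsin purple-membrane geometry): trimer centroids on a
#' hexagonal lattice, each carrying three Gaussian monomer bumps at
#' `trimer_spacing` from the centroid. Used to exercise nested-scale
#' behaviour: fine scales isolate monomers, coarser scales the trimer as a
#' whole.
#'
#' Defaults follow the physical system at 0.5 nm pixels: lattice constant
#' 6.2 nm (12.4 px), monomer-to-centroid distance 1.5 nm (3 px), monomer
#' radius 1 nm, i.e. size scale t0 = 0.5 nm^2 (2 px^2), amplitude 0.8 nm.
#'
#' @param shape `c(rows, cols)` in pixels.
#' @param pixel_size Pixel spacing (default 0.5, nm).
#' @param monomer_t0 Monomer Gaussian scale in pixel^2 (default 2).
#' @param trimer_spacing Monomer-to-centroid distance in pixels (default 3).
#' @param lattice_constant Trimer-centroid spacing in pixels (default 12.4).
#' @param A Monomer amplitude in height units (default 0.8).
#' @param unit Unit label.
#' @return List with `image` ([height_image]) and `truth` (tibble with
#'   `level` = `"monomer"` or `"trimer"`, `x`, `y`, `A`, `t0_px2`).
#' @export
trimer_lattice_image <- function(shape, pixel_size = 0.5, monomer_t0 = 2,
                                 trimer_spacing = 3,
                                 lattice_constant = 12.4, A = 0.8,
                                 unit = "nm") {
  stopifnot(monomer_t0 > 0, trimer_spacing > 0, lattice_constant > 0)
  n <- shape[1]; m <- shape[2]
  marg <- trimer_spacing + 3 * sqrt(2 * monomer_t0)
  a1 <- c(lattice_constant, 0)                       # (x, y) basis
  a2 <- c(lattice_constant / 2, lattice_constant * sqrt(3) / 2)
  imax <- ceiling(m / lattice_constant) + 2
  jmax <- ceiling(n / (lattice_constant * sqrt(3) / 2)) + 2
  cent <- NULL
  for (v in -jmax:jmax) for (u in -imax:imax) {
    p <- c(1 + marg, 1 + marg) + u * a1 + v * a2
    if (p[1] >= 1 + marg && p[1] <= m - marg &&
        p[2] >= 1 + marg && p[2] <= n - marg) {
      cent <- rbind(cent, p)
    }
  }
  if (is.null(cent)) {
    warning("lattice overflow: no trimer fits in the requested shape")
    return(list(
      image = height_image(matrix(0, n, m), pixel_size, unit = unit),
      truth = tibble::tibble(level = character(), x = numeric(),
                             y = numeric(), A = numeric(),
                             t0_px2 = numeric())
    ))
  }
  ang <- pi / 2 + c(0, 2, 4) * pi / 3
  mon_x <- as.vector(outer(cent[, 1], trimer_spacing * cos(ang), `+`))
  mon_y <- as.vector(outer(cent[, 2], trimer_spacing * sin(ang), `+`))
  H <- matrix(0, n, m)
  R <- matrix(seq_len(n), n, m)
  C <- matrix(seq_len(m), n, m, byrow = TRUE)
  for (q in seq_along(mon_x)) {
    H <- H + A * exp(-((R - mon_y[q])^2 + (C - mon_x[q])^2) /
                       (2 * monomer_t0))
  }
  truth <- dplyr::bind_rows(
    tibble::tibble(level = "monomer", x = mon_x, y = mon_y, A = A,
                   t0_px2 = monomer_t0),
    tibble::tibble(level = "trimer", x = cent[, 1], y = cent[, 2],
                   A = NA_real_, t0_px2 = NA_real_)
  )
  list(image = height_image(H, pixel_size, unit = unit), truth = truth)
}

#' Apply an AFM-style perturbation to a height image
#'
#' The defect battery used to probe detection stability, mirroring common
#' imaging artifacts:
#' * `offset` — constant addition of `magnitude` to every pixel;
#' * `fault` — constant addition above a horizontal fault line
#'   (`line_row`, default mid-height);
#' * `tilt` — plane rising from 0 at the top-left corner to `magnitude` at
#'   the bottom-right corner;
#' * `parabolic` — per-scanline parabola, zero at both line ends and
#'   peaking at `magnitude` mid-line (scanner bowing);
#' * `scanline_noise` — per-line offsets drawn from N(0, magnitude^2);
#' * `gaussian_noise` — i.i.d. per-pixel noise N(0, magnitude^2).
#'
#' Stochastic kinds are reproducible under `seed`.
#'
#' @param img A [height_image].
#' @param kind Perturbation kind (see above).
#' @param magnitude Non-negative amplitude (height units for all kinds;
#'   standard deviation for the noise kinds).
#' @param seed Optional RNG seed for the stochastic kinds.
#' @param line_row Fault-line row (only for `kind = "fault"`).
#' @return The perturbed [height_image].
#' @export
perturb <- function(img, kind = c("offset", "fault", "tilt", "parabolic",
                                  "scanline_noise", "gaussian_noise"),
                    magnitude, seed = NULL, line_row = NULL) {
  kind <- match.arg(kind)
  stopifnot(inherits(img, "height_image"), magnitude >= 0)
  H <- img$heights
  n <- nrow(H); m <- ncol(H)
  if (!is.null(seed)) set.seed(seed)
  H <- switch(
    kind,
    offset = H + magnitude,
    fault = {
      lr <- if (is.null(line_row)) floor(n / 2) else line_row
      H[seq_len(min(lr, n)), ] <- H[seq_len(min(lr, n)), ] + magnitude
      H
    },
    tilt = {
      plane <- (outer(seq_len(n) - 1, seq_len(m) - 1, `+`)) /
        ((n - 1) + (m - 1)) * magnitude
      H + plane
    },
    parabolic = {
      u <- (seq_len(m) - 1) / (m - 1)
      H + matrix(magnitude * 4 * u * (1 - u), n, m, byrow = TRUE)
    },
    scanline_noise = H + stats::rnorm(n, 0, magnitude),
    gaussian_noise = H + matrix(stats::rnorm(n * m, 0, magnitude), n, m)
  )
  height_image(H, img$pixel_size, unit = img$unit)
}
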