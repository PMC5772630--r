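#' Discrete Gaussian smoothing kernel
#'
#' One-dimensional separable smoothing kernel at scale `t` (pixel^2). The
#' default family is the discrete analogue of the Gaussian,
#' `T(n; t) = exp(-t) I_n(t)` with `I_n` the modified Bessel function of
#' integer order, which satisfies the semigroup property exactly on the
#' integer grid and is the canonical kernel of discrete scale-space theory.
#' A sampled-and-renormalized continuous Gaussian is available as an
#' alternative.
#'
#' The kernel is truncated at the smallest half-width whose discarded tail
#' mass is below `tol`, then renormalized to sum exactly to 1.
#'
#' @param t Scale in pixel^2, `t >= 0`. `t = 0` returns the identity kernel.
#' @param tol Relative truncation tolerance in (0, 1); default `1e-8`.
#' @param family `"discrete"` (Bessel analogue, default) or `"sampled"`.
#' @return Numeric vector of odd length `2w + 1`, symmetric, non-negative,
#'   summing to 1, with attribute `half_width = w`.
#' @examples
#' k <- discrete_gaussian_kernel(2)
#' sum(k)  # 1
#' @export
discrete_gaussian_kernel <- function(t, tol = 1e-8,
                                     family = c("discrete", "sampled")) {
  family <- match.arg(family)
  if (!is.finite(t) || t < 0) stop("invalid scale: t must be >= 0",
                                   call. = FALSE)
  if (tol <= 0 || tol >= 1) stop("tol must be in (0, 1)", call. = FALSE)
  if (t == 0) return(structure(1, half_width = 0L))

  if (family == "discrete") {
    # grow half-width until the retained mass exceeds 1 - tol
    w <- max(1L, as.integer(ceiling(3 * sqrt(t))))
    repeat {
      half <- besselI(t, 0:w, expon.scaled = TRUE)
      mass <- half[1] + 2 * sum(half[-1])
      if (1 - mass < tol || w > 40 + 20 * sqrt(t)) break
      w <- w + max(1L, as.integer(ceiling(0.2 * sqrt(t))))
    }
    # shrink to the smallest half-width still within tol
    cum <- half[1] + 2 * cumsum(c(0, half[-1]))
    w_min <- which(1 - cum < tol)[1] - 1L
    if (!is.na(w_min) && w_min < w) {
      w <- max(1L, w_min)
      half <- half[seq_len(w + 1L)]
    }
    k <- c(rev(half[-1]), half)
  } else {
    w <- max(1L, as.integer(ceiling(sqrt(2 * t * log(1 / tol)))))
    n <- -w:w
    k <- exp(-n^2 / (2 * t))
  }
  k <- k / sum(k)
  structure(k, half_width = as.integer((length(k) - 1L) / 2L))
}
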