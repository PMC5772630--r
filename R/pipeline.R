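#' Detect particles in a height image (full Hessian blob pipeline)
#'
#' Runs the complete workflow: scale-space construction, detector volumes,
#' scale-space maxima, sign classification, positive-curvature region
#' extraction, overlap resolution by strength, strength/scale culling,
#' subpixel centre refinement, boundary tracing, and measurement.
#'
#' Culling is pure filtering: it never recomputes or deforms surviving
#' blobs. With `min_strength = 0` the algorithm has no significant free
#' parameter.
#'
#' @param img A [height_image].
#' @param t_min,t_max,layers_per_octave,kernel,tol Scale-space controls, see
#'   [build_scale_space()].
#' @param min_strength Either a number (>= 0), `"auto-otsu"` (default) or
#'   `"auto-kmeans"`. Automatic thresholds are computed from the strengths
#'   of the non-overlapping blobs.
#' @param min_scale Minimum selected scale in pixel^2 (default 0).
#' @param signs Which blob signs to report: `"bright"` (default, AFM
#'   protrusions), `"dark"`, or `"both"`.
#' @param subpixel_factor Contour refinement factor (default 1: pixel
#'   resolution).
#' @param interp Contour interpolation (`"bilinear"` or `"bicubic"`).
#' @param max_iter Subpixel-refinement iteration cap (default 5).
#' @param keep_volume Keep the detector volume in the result (default
#'   `FALSE`; it is large).
#' @return An object of class `hb_result`: list with tibbles `particles`
#'   and `contours`, the blob list `blobs`, `threshold` (resolved strength
#'   threshold), `counts` (audit log of blob counts through each stage),
#'   `config` (fully resolved parameters), `image`, and optionally
#'   `volume`.
#' @export
detect_particles <- function(img,
                             t_min = 0.5, t_max = NULL,
                             layers_per_octave = 4,
                             kernel = c("discrete", "sampled"),
                             tol = 1e-8,
                             min_strength = "auto-otsu",
                             min_scale = 0,
                             signs = c("bright", "dark", "both"),
                             subpixel_factor = 1,
                             interp = c("bilinear", "bicubic"),
                             max_iter = 5,
                             keep_volume = FALSE) {
  kernel <- match.arg(kernel)
  signs <- match.arg(signs)
  interp <- match.arg(interp)
  stopifnot(inherits(img, "height_image"))

  ss <- build_scale_space(img, t_min = t_min, t_max = t_max,
                          layers_per_octave = layers_per_octave,
                          kernel = kernel, tol = tol)
  vol <- detector_volumes(ss)
  rm(ss)

  seeds <- find_scale_space_maxima(vol, min_strength = 0)
  counts <- list(n_maxima = nrow(seeds))
  seeds <- classify_sign(seeds, vol)
  if (signs != "both") seeds <- dplyr::filter(seeds, .data$sign == signs)
  counts$n_after_sign <- nrow(seeds)

  # extract support regions, sharing the flood fill between seeds that sit
  # in the same connected component of a layer
  sd <- as.data.frame(seeds)
  d <- dim(vol$detH)
  compmap <- vector("list", d[3])
  comp_pixels <- list()
  blobs <- vector("list", nrow(sd))
  for (q in seq_len(nrow(sd))) {
    seed <- as.list(sd[q, ])
    k <- seed$k
    if (is.null(compmap[[k]])) compmap[[k]] <- matrix(0L, d[1], d[2])
    lin <- (seed$j - 1L) * d[1] + seed$i
    cid <- compmap[[k]][lin]
    if (cid == 0L) {
      region <- extract_region(vol, seed)
      comp_pixels[[length(comp_pixels) + 1L]] <- region
      compmap[[k]][region$pixels] <- length(comp_pixels)
    } else {
      region <- comp_pixels[[cid]]
      region$seed <- c(i = seed$i, j = seed$j)
    }
    blobs[[q]] <- list(seed = seed, t_px2 = seed$t_px2, sign = seed$sign,
                       region = region)
  }
  rm(compmap, comp_pixels)
  blobs <- resolve_overlaps(blobs)
  counts$n_after_overlap <- length(blobs)

  strengths <- vapply(blobs, function(b) b$seed$strength, numeric(1))
  threshold <- if (identical(min_strength, "auto-otsu")) {
    if (length(strengths) >= 2) otsu_strength_threshold(strengths) else 0
  } else if (identical(min_strength, "auto-kmeans")) {
    if (length(strengths) >= 2) kmeans_strength_threshold(strengths) else 0
  } else {
    stopifnot(is.numeric(min_strength), min_strength >= 0)
    min_strength
  }
  blobs <- filter_min_strength(blobs, threshold)
  counts$n_after_strength <- length(blobs)
  blobs <- filter_min_scale(blobs, min_scale)
  counts$n_after_scale <- length(blobs)

  for (q in seq_along(blobs)) {
    blobs[[q]]$center <- refine_center_subpixel(vol, blobs[[q]]$seed,
                                                max_iter = max_iter)
    blobs[[q]]$contours <- trace_contour(blobs[[q]]$region, vol,
                                         subpixel_factor = subpixel_factor,
                                         interp = interp)
    blobs[[q]]$measurements <- measure_blob(img, blobs[[q]])
    blobs[[q]]$id <- q
  }

  px <- img$pixel_size
  particles <- if (length(blobs) == 0) {
    tibble::tibble(
      id = integer(), x = numeric(), y = numeric(), row = numeric(),
      col = numeric(), t_px2 = numeric(), t_phys = numeric(),
      strength = numeric(), sign = character(), area = numeric(),
      perimeter = numeric(), max_height = numeric(),
      relative_height = numeric(), equivalent_radius = numeric(),
      volume_provisional = numeric(), n_pixels = integer(),
      converged = logical(), valid = logical()
    )
  } else {
    dplyr::bind_rows(lapply(blobs, function(b) {
      tibble::tibble(
        id = b$id,
        x = b$center$x, y = b$center$y,
        row = b$center$row, col = b$center$col,
        t_px2 = b$center$t_px2, t_phys = b$center$t_phys,
        strength = b$seed$strength, sign = b$sign,
        area = b$measurements$area,
        perimeter = b$measurements$perimeter,
        max_height = b$measurements$max_height,
        relative_height = b$measurements$relative_height,
        equivalent_radius = b$measurements$equivalent_radius,
        volume_provisional = b$measurements$volume_provisional,
        n_pixels = as.integer(b$measurements$n_pixels),
        converged = b$center$converged,
        valid = b$measurements$valid
      )
    }))
  }

  contours <- if (length(blobs) == 0) {
    tibble::tibble(blob_id = integer(), ring_id = integer(),
                   ring = character(), vertex_idx = integer(),
                   x_phys = numeric(), y_phys = numeric())
  } else {
    dplyr::bind_rows(lapply(blobs, function(b) {
      dplyr::bind_rows(lapply(seq_along(b$contours), function(r) {
        V <- b$contours[[r]]$vertices
        tibble::tibble(blob_id = b$id, ring_id = r,
                       ring = b$contours[[r]]$ring,
                       vertex_idx = seq_len(nrow(V)),
                       x_phys = V[, "x"], y_phys = V[, "y"])
      }))
    }))
  }

  config <- list(
    pixel_size = px, unit = img$unit,
    t_min = t_min,
    t_max = if (is.null(t_max)) (min(dim(img$heights)) / 8)^2 else t_max,
    layers_per_octave = layers_per_octave, kernel = kernel, tol = tol,
    min_strength = if (is.character(min_strength)) min_strength
                   else as.numeric(min_strength),
    resolved_threshold = threshold,
    min_scale = min_scale, signs = signs,
    subpixel_factor = subpixel_factor, interp = interp,
    max_iter = max_iter,
    coordinate_convention = paste(
      "row-major, origin at top-left pixel centre,",
      "x = (col-1)*pixel_size, y = (row-1)*pixel_size")
  )

  structure(
    list(particles = particles, contours = contours, blobs = blobs,
         threshold = threshold, counts = counts, config = config,
         image = img, scales = vol$scales,
         volume = if (keep_volume) vol else NULL),
    class = "hb_result"
  )
}

#' @export
print.hb_result <- function(x, ...) {
  cat(sprintf(
    "<hb_result> %d particle(s) [%s] from %d scale-space maxima\n",
    nrow(x$particles), x$config$signs, x$counts$n_maxima))
  cat(sprintf("  strength threshold: %.4g (%s)\n", x$threshold,
              if (is.character(x$config$min_strength))
                x$config$min_strength else "manual"))
  if (nrow(x$particles) > 0) print(x$particles, n = 10)
  invisible(x)
}

#' Count positive-curvature bright regions at one scale
#'
#' Diagnostic for nested-scale structure: the number of 8-connected
#' components of positive determinant of the Hessian that are bright
#' (negative Laplacian somewhere in the component) at the scale layer
#' nearest `t_px2`. On a trimer lattice, fine scales isolate monomer
#' regions and coarse scales merge each trimer into one.
#'
#' @param vol A `detector_volume`.
#' @param t_px2 Requested scale (pixel^2); the nearest layer is used.
#' @param exclude_border Ignore components overlapping the untrusted border
#'   band (default `TRUE`).
#' @return Integer count of bright positive regions.
#' @export
count_curvature_regions <- function(vol, t_px2, exclude_border = TRUE) {
  stopifnot(inherits(vol, "detector_volume"))
  k <- which.min(abs(log(vol$scales) - log(t_px2)))
  Z <- vol$detH[, , k]
  mask <- Z > 1e-12 * max(abs(Z)) & vol$lap[, , k] < 0
  if (exclude_border) {
    band <- vol$border_band[k]
    d <- dim(mask)
    keep <- matrix(FALSE, d[1], d[2])
    keep[(band + 1):(d[1] - band), (band + 1):(d[2] - band)] <- TRUE
    mask <- mask & keep
  }
  max(label_components8(mask))
}

#' Write run artifacts to disk
#'
#' Writes the particle table and contour table as CSV, the label mask as a
#' whitespace-delimited integer text matrix, the resolved configuration as
#' JSON, and a short audit log (scale list and blob counts before/after each
#' culling stage). All file headers record the coordinate convention.
#'
#' @param result An `hb_result` from [detect_particles()].
#' @param prefix Output path prefix; files are written as
#'   `<prefix>_particles.csv`, `<prefix>_contours.csv`, `<prefix>_mask.txt`,
#'   `<prefix>_config.json`, `<prefix>_log.txt`.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_run_artifacts <- function(result, prefix) {
  stopifnot(inherits(result, "hb_result"))
  paths <- c(particles = paste0(prefix, "_particles.csv"),
             contours = paste0(prefix, "_contours.csv"),
             mask = paste0(prefix, "_mask.txt"),
             config = paste0(prefix, "_config.json"),
             log = paste0(prefix, "_log.txt"))
  hdr <- paste0("# ", result$config$coordinate_convention)
  writeLines(c(hdr, paste(names(result$particles), collapse = ",")),
             paths["particles"])
  utils::write.table(result$particles, paths["particles"], sep = ",",
                     row.names = FALSE, col.names = FALSE, append = TRUE,
                     quote = FALSE)
  writeLines(c(hdr, "blob_id,ring_id,ring,vertex_idx,x_phys,y_phys"),
             paths["contours"])
  utils::write.table(
    result$contours[, c("blob_id", "ring_id", "ring", "vertex_idx",
                        "x_phys", "y_phys")],
    paths["contours"], sep = ",", row.names = FALSE, col.names = FALSE,
    append = TRUE, quote = FALSE)
  d <- dim(result$image$heights)
  mask <- matrix(0L, d[1], d[2])
  for (b in result$blobs) mask[b$region$pixels] <- b$id
  utils::write.table(mask, paths["mask"], row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(result$config, paths["config"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  writeLines(c(
    hdr,
    sprintf("scales_px2: %s", paste(signif(result$scales, 8),
                                    collapse = " ")),
    sprintf("n_maxima: %d", result$counts$n_maxima),
    sprintf("n_after_sign: %d", result$counts$n_after_sign),
    sprintf("n_after_overlap: %d", result$counts$n_after_overlap),
    sprintf("strength_threshold: %.17g", result$threshold),
    sprintf("n_after_strength: %d", result$counts$n_after_strength),
    sprintf("n_after_scale: %d", result$counts$n_after_scale)
  ), paths["log"])
  invisible(paths)
}
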