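#' Construct an AFM height map
#'
#' @param heights numeric matrix of heights in nm (finite values).
#' @param pixel_size lateral sampling in nm per pixel (> 0).
#' @param metadata optional named list of scan metadata.
#' @return object of class `afm_heightmap`.
#' @examples
#' afm_heightmap(matrix(0, 16, 16), pixel_size = 2)
#' @export
afm_heightmap <- function(heights, pixel_size, metadata = list()) {
  if (!is.matrix(heights) || !is.numeric(heights)) abort("`heights` must be a numeric matrix.")
  if (any(!is.finite(heights))) abort("`heights` must be finite.")
  check_number(pixel_size, "pixel_size", 0, strict = TRUE)
  structure(list(heights = heights, pixel_size = pixel_size, metadata = metadata),
            class = "afm_heightmap")
}

#' @export
print.afm_heightmap <- function(x, ...) {
  cat(sprintf("<afm_heightmap> %d x %d px, %.3g nm/px (%.3g x %.3g nm), z range [%.3g, %.3g] nm\n",
              nrow(x$heights), ncol(x$heights), x$pixel_size,
              nrow(x$heights) * x$pixel_size, ncol(x$heights) * x$pixel_size,
              min(x$heights), max(x$heights)))
  invisible(x)
}

#' Row-wise polynomial background flattening
#'
#' Standard AFM line-flattening: per scan row, a polynomial of the given
#' order is fitted to background pixels only — those below a robust
#' `median + 2 * MAD` mask computed on the whole image — and subtracted.
#' Masking keeps particles from biasing the background estimate.
#'
#' @param map an [afm_heightmap()].
#' @param order polynomial order per row (0 = offset, 1 = tilt, ...).
#' @return a flattened [afm_heightmap()].
#' @examples
#' m <- afm_heightmap(outer(1:32, 1:32, function(i, j) 0.01 * j), 1)
#' max(abs(afm_flatten(m)$heights)) < 1e-9
#' @export
afm_flatten <- function(map, order = 1) {
  stopifnot(inherits(map, "afm_heightmap"))
  order <- check_count(order, "order", 0L)
  h <- map$heights
  cutoff <- median(h) + 2 * mad(h)
  mask <- h <= cutoff                     # TRUE = background
  if (!any(mask)) abort("all pixels masked as features; cannot estimate background.")
  xs <- seq_len(ncol(h))
  for (i in seq_len(nrow(h))) {
    bg <- mask[i, ]
    if (sum(bg) < order + 1) bg <- rep(TRUE, ncol(h))  # too few background px
    if (order == 0) {
      h[i, ] <- h[i, ] - mean(h[i, bg])
    } else {
      X <- outer(xs / length(xs), 0:order, `^`)     # scaled Vandermonde
      fit <- stats::lm.fit(X[bg, , drop = FALSE], h[i, bg])
      h[i, ] <- h[i, ] - drop(X %*% fit$coefficients)
    }
  }
  afm_heightmap(h, map$pixel_size, map$metadata)
}

# 8-connected component labeling: EBImage::bwlabel is 4-connected, so labels
# touching diagonally are merged with a union-find pass
label_components <- function(mask) {
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  lab <- EBImage::imageData(lab)
  nlab <- max(lab)
  if (nlab < 2) return(lab)
  parent <- seq_len(nlab)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union_ <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj) }
  nr <- nrow(lab); nc <- ncol(lab)
  # diagonal neighbour pairs (down-right and down-left shifts)
  a <- lab[-nr, -nc]; b <- lab[-1, -1]
  ij <- which(a > 0 & b > 0 & a != b)
  if (length(ij)) invisible(mapply(union_, a[ij], b[ij]))
  a <- lab[-nr, -1]; b <- lab[-1, -nc]
  ij <- which(a > 0 & b > 0 & a != b)
  if (length(ij)) invisible(mapply(union_, a[ij], b[ij]))
  roots <- vapply(seq_len(nlab), find, integer(1))
  relab <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

#' Detect particles in a flattened AFM height map
#'
#' Hysteresis segmentation: 8-connected regions are delineated at a low
#' boundary threshold near the background noise level, but only regions
#' whose maximum height exceeds the detection threshold are kept — so pure
#' background roughness never yields particles, while real particles are
#' delineated down to near their true footprint (a detection-level mask
#' would clip a cap of height h to `sqrt(1 - thr/h)` of its axes).
#' Regions smaller than `min_area_px` and regions touching the image border
#' (censored ellipses) are discarded.
#'
#' @param map a (flattened) [afm_heightmap()].
#' @param threshold detection threshold in nm (default 0.5 — the height
#'   below which protein-free control scans show no objects).
#' @param boundary_threshold delineation threshold in nm; default
#'   `3 * mad(heights)`, a robust estimate of 3 background sd.
#' @param min_area_px minimum region area in pixels (default 4).
#' @return object of class `afm_detection`: `labels` (integer matrix, 0 =
#'   background), `n_particles`, `regions` tibble (`id`, `area_px`,
#'   `max_height`), plus the thresholds used.
#' @examples
#' sim <- simulate_afm(3, seed = 2)
#' detect_particles(sim$map)$n_particles
#' @export
detect_particles <- function(map, threshold = 0.5, boundary_threshold = NULL,
                             min_area_px = 4) {
  stopifnot(inherits(map, "afm_heightmap"))
  check_number(threshold, "threshold", 0, strict = TRUE)
  h <- map$heights
  boundary_threshold <- boundary_threshold %||% (3 * mad(h))
  boundary_threshold <- min(boundary_threshold, threshold)
  lab <- label_components(h > boundary_threshold)
  nlab <- max(lab)
  keep <- integer(0)
  regions <- tibble(id = integer(), area_px = integer(), max_height = numeric())
  if (nlab > 0) {
    idx <- which(lab > 0)
    ids <- lab[idx]
    area <- tabulate(ids, nlab)
    maxh <- vapply(split(h[idx], ids), max, numeric(1))
    # border contact per label
    nr <- nrow(h); nc <- ncol(h)
    border_ids <- unique(c(lab[1, ], lab[nr, ], lab[, 1], lab[, nc]))
    on_border <- seq_len(nlab) %in% border_ids
    keep <- which(maxh > threshold & area >= min_area_px & !on_border)
    regions <- tibble(id = seq_along(keep),
                      area_px = area[keep],
                      max_height = unname(maxh[keep]))
    relab <- integer(nlab)
    relab[keep] <- seq_along(keep)
    lab[lab > 0] <- relab[lab[lab > 0]]
  }
  structure(list(labels = lab, n_particles = length(keep), regions = regions,
                 threshold = threshold, boundary_threshold = boundary_threshold,
                 min_area_px = min_area_px, map = map),
            class = "afm_detection")
}

#' @export
print.afm_detection <- function(x, ...) {
  cat(sprintf("<afm_detection> %d particle(s); detect > %.3g nm, delineate > %.3g nm, min area %d px\n",
              x$n_particles, x$threshold, x$boundary_threshold, x$min_area_px))
  invisible(x)
}

#' Per-particle equivalent-ellipse morphometry
#'
#' For each detected region, computes the equivalent ellipse from the second
#' central moments of the binary mask: the semi-axes are `2 * sqrt(lambda)`
#' for the two eigenvalues of the pixel covariance matrix (exact for an
#' ideal filled ellipse), scaled to nm. Reported per particle:
#' semi-major `a1`, semi-minor `a2`, `ratio = a1/a2`, square-root area from
#' the mask (`s_mask`) and from the fitted ellipse (`s_ellipse =
#' sqrt(pi a1 a2)`), height `z` (region maximum), centroid (px) and
#' orientation (rad). One-pixel-wide regions get an `a2` floor of half a
#' pixel and a degeneracy flag.
#'
#' @param detection an [detect_particles()] result.
#' @return a tibble with one row per particle.
#' @examples
#' sim <- simulate_afm(3, seed = 2)
#' measure_particles(detect_particles(sim$map))
#' @export
measure_particles <- function(detection) {
  stopifnot(inherits(detection, "afm_detection"))
  lab <- detection$labels
  h <- detection$map$heights
  px <- detection$map$pixel_size
  n <- detection$n_particles
  if (n == 0L) {
    return(tibble(id = integer(), a1 = numeric(), a2 = numeric(),
                  ratio = numeric(), s_mask = numeric(), s_ellipse = numeric(),
                  z = numeric(), x_px = numeric(), y_px = numeric(),
                  theta = numeric(), area_px = integer(), degenerate = logical()))
  }
  idx <- which(lab > 0)
  ids <- lab[idx]
  rows <- (idx - 1) %% nrow(lab) + 1
  cols <- (idx - 1) %/% nrow(lab) + 1
  hv <- h[idx]
  purrr::map_dfr(seq_len(n), function(k) {
    sel <- ids == k
    x <- rows[sel]; y <- cols[sel]
    area <- sum(sel)
    mx <- mean(x); my <- mean(y)
    # second central moments with the 1/12 pixel-variance correction
    cxx <- mean((x - mx)^2) + 1 / 12
    cyy <- mean((y - my)^2) + 1 / 12
    cxy <- mean((x - mx) * (y - my))
    ev <- eigen(matrix(c(cxx, cxy, cxy, cyy), 2), symmetric = TRUE)
    a1 <- 2 * sqrt(max(ev$values[1], 0)) * px
    a2 <- 2 * sqrt(max(ev$values[2], 0)) * px
    degenerate <- a2 < px / 2
    a2 <- max(a2, px / 2)
    theta <- atan2(ev$vectors[2, 1], ev$vectors[1, 1]) %% pi
    tibble(id = k, a1 = a1, a2 = a2, ratio = a1 / a2,
           s_mask = sqrt(area) * px, s_ellipse = sqrt(pi * a1 * a2),
           z = max(hv[sel]), x_px = mx, y_px = my, theta = theta,
           area_px = area, degenerate = degenerate)
  })
}

#' Default semi-major-axis class windows
#'
#' The four particle classes used to stratify the morphometry, defined on
#' the semi-major axis `a1` (nm). Classes I and II intentionally overlap on
#' 17-20 nm; particles falling in the overlap belong to both.
#'
#' @return tibble with `range`, `a1_min`, `a1_max`.
#' @export
afm_ranges <- function() {
  afm_particle_classes()[c("range", "a1_min", "a1_max")]
}

#' Assign particles to semi-major-axis classes
#'
#' A particle joins **every** class whose `a1` window contains it, so
#' overlap membership is preserved and flagged rather than resolved by an
#' arbitrary cut. Particles outside all windows land in an `"unbinned"`
#' class.
#'
#' @param particles tibble from [measure_particles()] (needs column `a1`).
#' @param ranges tibble with `range`, `a1_min`, `a1_max` (default
#'   [afm_ranges()]).
#' @return the particle tibble in long form, one row per (particle, class),
#'   with columns `range` and `multi_range` added.
#' @examples
#' segment_ranges(tibble::tibble(a1 = c(18, 50, 70)))
#' @export
segment_ranges <- function(particles, ranges = afm_ranges()) {
  stopifnot(is.data.frame(particles), "a1" %in% names(particles))
  stopifnot(all(c("range", "a1_min", "a1_max") %in% names(ranges)))
  p <- as_tibble(particles)
  p$.row <- seq_len(nrow(p))
  hits <- purrr::map_dfr(seq_len(nrow(ranges)), function(i) {
    sel <- p$a1 >= ranges$a1_min[i] & p$a1 <= ranges$a1_max[i]
    if (!any(sel)) return(tibble())
    dplyr::mutate(p[sel, ], range = ranges$range[i])
  })
  n_mem <- table(factor(hits$.row, levels = p$.row))
  unbinned <- p[n_mem[as.character(p$.row)] == 0, ]
  if (nrow(unbinned)) unbinned$range <- "unbinned"
  out <- dplyr::bind_rows(hits, unbinned)
  out$multi_range <- as.integer(n_mem[as.character(out$.row)]) > 1L
  out$.row <- NULL
  as_tibble(out)
}

#' Per-class Gaussian statistics of particle parameters
#'
#' For each class with at least `min_count` particles, fits a Gaussian to
#' each morphometric parameter. The reported mean/sd are the
#' maximum-likelihood (sample) estimates; a least-squares Gaussian fit to
#' the histogram is run alongside as a diagnostic (`hist_mean`, `hist_sd`,
#' `NA` when it fails). Classes with fewer particles are skipped with a
#' warning; near-constant parameters are flagged degenerate.
#'
#' @param segmented output of [segment_ranges()].
#' @param params character vector of parameter columns to summarize.
#' @param min_count minimum particles per class (default 20).
#' @return a `range_stats` tibble: `range`, `param`, `n`, `mean`, `sd`,
#'   `hist_mean`, `hist_sd`, `degenerate`.
#' @export
fit_range_gaussians <- function(segmented,
                                params = c("a1", "a2", "ratio", "s_mask", "z"),
                                min_count = 20) {
  stopifnot(is.data.frame(segmented), "range" %in% names(segmented))
  params <- intersect(params, names(segmented))
  out <- segmented |>
    dplyr::filter(.data$range != "unbinned") |>
    tidyr::pivot_longer(dplyr::all_of(params), names_to = "param", values_to = "value") |>
    dplyr::group_by(.data$range, .data$param) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$value),
      sd = sd(.data$value),
      .groups = "drop"
    )
  small <- unique(out$range[out$n < min_count])
  if (length(small)) {
    warn(sprintf("class(es) %s have fewer than %d particles; skipped.",
                 paste(small, collapse = ", "), min_count))
    out <- out[!(out$range %in% small), ]
  }
  out$degenerate <- out$sd < 1e-9 * pmax(abs(out$mean), 1)
  # histogram-curve diagnostic fit
  hist_fit <- function(rg, pm) {
    v <- segmented[segmented$range == rg, pm, drop = TRUE]
    hh <- graphics::hist(v, breaks = "FD", plot = FALSE)
    df <- data.frame(x = hh$mids, y = hh$counts)
    fit <- tryCatch(
      stats::nls(y ~ A * exp(-(x - mu)^2 / (2 * s^2)), data = df,
                 start = list(A = max(df$y), mu = mean(v), s = sd(v))),
      error = function(e) NULL
    )
    if (is.null(fit)) c(NA_real_, NA_real_) else abs(coef(fit)[c("mu", "s")])
  }
  hm <- purrr::map2(out$range, out$param, hist_fit)
  out$hist_mean <- purrr::map_dbl(hm, 1)
  out$hist_sd <- purrr::map_dbl(hm, 2)
  class(out) <- c("range_stats", class(out))
  out
}

#' Full AFM morphometry pipeline
#'
#' Convenience wrapper: flatten, detect, measure, segment and summarize in
#' one call.
#'
#' @param map an [afm_heightmap()].
#' @param flatten run [afm_flatten()] first? (default TRUE)
#' @param threshold,boundary_threshold,min_area_px see [detect_particles()].
#' @param ranges see [segment_ranges()].
#' @param min_count see [fit_range_gaussians()].
#' @return list with `particles` (measured tibble), `segmented` (long form)
#'   and `stats` (per-class Gaussian summary).
#' @examples
#' \donttest{
#' sim <- simulate_afm(50, seed = 3)
#' res <- afm_morphometry(sim$map)
#' res$stats
#' }
#' @export
afm_morphometry <- function(map, flatten = TRUE, threshold = 0.5,
                            boundary_threshold = NULL, min_area_px = 4,
                            ranges = afm_ranges(), min_count = 20) {
  if (flatten) map <- afm_flatten(map)
  det <- detect_particles(map, threshold = threshold,
                          boundary_threshold = boundary_threshold,
                          min_area_px = min_area_px)
  particles <- measure_particles(det)
  segmented <- segment_ranges(particles, ranges)
  stats <- if (nrow(segmented)) {
    suppressWarnings(fit_range_gaussians(segmented, min_count = min_count))
  } else {
    tibble()
  }
  list(particles = particles, segmented = segmented, stats = stats,
       detection = det)
}
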