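#' Spheroid fluorescence image
#'
#' A 2-D grayscale intensity grid with its physical pixel size, as produced by
#' confocal imaging of a dye-loaded spheroid (glucose-analog or hypoxia
#' channel).
#'
#' @param pixels Numeric matrix of non-negative intensities, at least 64 x 64.
#' @param pixel_size Pixel edge length in µm (square pixels).
#' @param channel Channel label, e.g. `"glucose"` or `"hypoxia"`.
#' @return An object of class `spheroid_image`.
#' @export
spheroid_image <- function(pixels, pixel_size, channel = "glucose") {
  stopifnot(is.matrix(pixels), is.numeric(pixels))
  if (nrow(pixels) < 64L || ncol(pixels) < 64L) {
    stop("image must be at least 64 x 64 pixels", call. = FALSE)
  }
  if (any(!is.finite(pixels)) || any(pixels < 0)) {
    stop("pixel intensities must be finite and non-negative", call. = FALSE)
  }
  if (!is.numeric(pixel_size) || pixel_size <= 0) {
    stop("'pixel_size' must be positive (µm)", call. = FALSE)
  }
  structure(list(pixels = pixels, pixel_size = as.numeric(pixel_size),
                 channel = as.character(channel)),
            class = "spheroid_image")
}

#' @export
print.spheroid_image <- function(x, ...) {
  cat(sprintf("<spheroid_image> %d x %d px, %.3g µm/px, channel = %s\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size, x$channel))
  invisible(x)
}

# Distances (µm) from each pixel center to a point given in µm coordinates;
# pixel (i, j) has its center at ((i - 0.5) ps, (j - 0.5) ps).
pixel_distances <- function(dim, pixel_size, center) {
  xs <- (seq_len(dim[1]) - 0.5) * pixel_size
  ys <- (seq_len(dim[2]) - 0.5) * pixel_size
  sqrt(outer((xs - center[1])^2, (ys - center[2])^2, `+`))
}

#' Generate a synthetic spheroid fluorescence image
#'
#' Emulates the radial structure seen in dye-loaded spheroids: a bright
#' Gaussian ridge at the proliferation rim and a separate Gaussian core term
#' (dim for a glucose-starved necrotic core, bright for a hypoxia probe
#' accumulating centrally), inside a disk of the given radius, zero outside,
#' with additive Gaussian noise clipped at zero. The radial truth is
#' \deqn{i(r) = A_{rim} e^{-(r - r_{rim})^2 / (2 w^2)} +
#'       A_{core} e^{-r^2 / (2 c^2)}.}
#'
#' @param radius_um Spheroid radius in µm; must exceed `rim_width_um`.
#' @param rim_peak_um Radius of the rim intensity ridge in µm.
#' @param rim_amplitude,core_amplitude Amplitudes of the rim and core terms.
#' @param noise_sd Standard deviation of additive Gaussian noise.
#' @param pixel_size Pixel size in µm.
#' @param seed Optional integer seed (bit-reproducible noise).
#' @param rim_width_um Gaussian width `w` of the rim ridge.
#' @param core_width_um Gaussian width `c` of the core term.
#' @param size_px Optional image edge length in pixels; defaults to the
#'   smallest even size with a 10% margin around the spheroid, at least 64.
#' @param channel Channel label.
#' @return A [spheroid_image()] centered in the frame.
#' @examples
#' img <- generate_spheroid_image(radius_um = 200, rim_peak_um = 150,
#'                                noise_sd = 0, pixel_size = 2, seed = 1)
#' @export
generate_spheroid_image <- function(radius_um = 200, rim_peak_um = 150,
                                    rim_amplitude = 1, core_amplitude = 0.2,
                                    noise_sd = 0.05, pixel_size = 2,
                                    seed = NULL, rim_width_um = 25,
                                    core_width_um = 50, size_px = NULL,
                                    channel = "glucose") {
  if (radius_um <= rim_width_um) {
    stop("'radius_um' must exceed 'rim_width_um'", call. = FALSE)
  }
  if (pixel_size <= 0) stop("'pixel_size' must be positive", call. = FALSE)
  if (is.null(size_px)) {
    size_px <- max(64L, 2L * ceiling(1.1 * radius_um / pixel_size))
  }
  if (size_px * pixel_size < 2 * radius_um) {
    stop("spheroid geometry exceeds the image bounds", call. = FALSE)
  }
  center <- rep(size_px * pixel_size / 2, 2)
  r <- pixel_distances(c(size_px, size_px), pixel_size, center)
  img <- rim_amplitude * exp(-(r - rim_peak_um)^2 / (2 * rim_width_um^2)) +
    core_amplitude * exp(-r^2 / (2 * core_width_um^2))
  img[r > radius_um] <- 0
  if (noise_sd > 0) {
    noise <- with_seed(seed,
                       matrix(stats::rnorm(size_px^2, 0, noise_sd),
                              size_px, size_px))
    img <- img + noise
  }
  img <- pmax(img, 0)
  out <- spheroid_image(img, pixel_size, channel)
  attr(out, "truth") <- list(radius_um = radius_um, rim_peak_um = rim_peak_um,
                             rim_amplitude = rim_amplitude,
                             core_amplitude = core_amplitude,
                             rim_width_um = rim_width_um,
                             core_width_um = core_width_um, seed = seed)
  out
}

#' Intensity-weighted spheroid center
#'
#' Centroid of the above-threshold pixels (Otsu threshold on the normalized
#' image), in µm coordinates. This is the default center used by
#' [radial_profile()].
#'
#' @param image A [spheroid_image()].
#' @return Length-2 numeric, center `(x, y)` in µm.
#' @export
spheroid_center <- function(image) {
  stopifnot(inherits(image, "spheroid_image"))
  px <- image$pixels
  rng <- range(px)
  if (rng[2] <= rng[1]) {
    return(rep(dim(px)[1] * image$pixel_size / 2, 2))
  }
  norm <- (px - rng[1]) / (rng[2] - rng[1])
  thr <- EBImage::otsu(norm, range = c(0, 1))
  mask <- norm > thr
  w <- px * mask
  if (sum(w) == 0) { mask[] <- TRUE; w <- px }
  xs <- (seq_len(nrow(px)) - 0.5) * image$pixel_size
  ys <- (seq_len(ncol(px)) - 0.5) * image$pixel_size
  c(sum(rowSums(w) * xs), sum(colSums(w) * ys)) / sum(w)
}

#' Radial intensity profile of a spheroid image
#'
#' Annulus-averaged intensity versus distance from the spheroid center:
#' pixels are assigned to half-open annuli `[r, r + dr)` by the distance of
#' their centers (in µm) from the intensity-weighted centroid (or a manual
#' center override), and each annulus reports its mean intensity, standard
#' error of the mean, and pixel count. Empty annuli are dropped.
#'
#' @param image A [spheroid_image()].
#' @param annulus_width_um Annulus width in µm, at least one pixel.
#' @param center Optional manual center `(x, y)` in µm.
#' @param max_radius_um Outermost radius profiled; defaults to half the image
#'   width.
#' @return An object of class `radial_profile`: data.frame-like list with
#'   `radii` (annulus mid-radii, µm), `mean_intensity`, `sem`, `n_pixels`.
#' @export
radial_profile <- function(image, annulus_width_um = 10, center = NULL,
                           max_radius_um = NULL) {
  stopifnot(inherits(image, "spheroid_image"))
  if (annulus_width_um < image$pixel_size) {
    stop("'annulus_width_um' must be at least one pixel", call. = FALSE)
  }
  if (is.null(center)) center <- spheroid_center(image)
  if (is.null(max_radius_um)) {
    max_radius_um <- dim(image$pixels)[1] * image$pixel_size / 2
  }
  r <- pixel_distances(dim(image$pixels), image$pixel_size, center)
  breaks <- seq(0, max_radius_um + annulus_width_um, by = annulus_width_um)
  idx <- findInterval(r, breaks, left.open = FALSE)  # half-open [lo, hi)
  keep <- idx >= 1L & idx < length(breaks) & r < max_radius_um
  idx <- idx[keep]
  vals <- image$pixels[keep]
  n <- tabulate(idx, nbins = length(breaks) - 1L)
  nonempty <- which(n > 0L)
  if (length(nonempty) < length(breaks) - 1L) {
    message(sprintf("radial_profile: dropping %d empty annuli",
                    length(breaks) - 1L - length(nonempty)))
  }
  sums <- vapply(nonempty, function(k) sum(vals[idx == k]), numeric(1))
  m <- sums / n[nonempty]
  s <- vapply(nonempty, function(k) stats::sd(vals[idx == k]), numeric(1))
  sem <- s / sqrt(n[nonempty])
  structure(list(radii = (breaks[nonempty] + breaks[nonempty + 1L]) / 2,
                 mean_intensity = m, sem = sem, n_pixels = n[nonempty],
                 annulus_width_um = annulus_width_um, center = center),
            class = "radial_profile")
}

#' @export
print.radial_profile <- function(x, ...) {
  cat(sprintf("<radial_profile> %d annuli of %g µm, radii %g–%g µm\n",
              length(x$radii), x$annulus_width_um, min(x$radii), max(x$radii)))
  invisible(x)
}

#' @export
as.data.frame.radial_profile <- function(x, ...) {
  data.frame(radius_um = x$radii, mean_intensity = x$mean_intensity,
             sem = x$sem, n_pixels = x$n_pixels)
}

#' Core and rim region statistics of a radial profile
#'
#' Pixel-count-weighted mean intensity over the necrotic-core region
#' (distances in `[50, 100)` µm from the center by default) and the
#' proliferation-rim region (`[100, 200)` µm). The half-open bounds make the
#' two regions disjoint: an annulus belongs to exactly one region. If the
#' profile does not reach the outer rim bound, statistics are computed over
#' the available range and flagged `partial`.
#'
#' @param profile A [radial_profile()].
#' @param core_um,rim_um Length-2 half-open region bounds `[lo, hi)` in µm.
#' @return An object of class `region_stats`: list with `core_mean`,
#'   `rim_mean`, region bounds and a `partial` flag.
#' @export
region_stats <- function(profile, core_um = c(50, 100),
                         rim_um = c(100, 200)) {
  stopifnot(inherits(profile, "radial_profile"))
  partial <- max(profile$radii) < rim_um[2]
  if (partial) {
    warning(sprintf("profile reaches only %g µm; region statistics cover the available range",
                    max(profile$radii)), call. = FALSE)
  }
  region_mean <- function(bounds) {
    sel <- profile$radii >= bounds[1] & profile$radii < bounds[2]
    if (!any(sel)) return(NA_real_)
    sum(profile$mean_intensity[sel] * profile$n_pixels[sel]) /
      sum(profile$n_pixels[sel])
  }
  structure(list(core_mean = region_mean(core_um),
                 rim_mean = region_mean(rim_um),
                 core_um = core_um, rim_um = rim_um, partial = partial),
            class = "region_stats")
}

#' @export
print.region_stats <- function(x, ...) {
  cat(sprintf("<region_stats> core [%g, %g) µm: %.4g; rim [%g, %g) µm: %.4g%s\n",
              x$core_um[1], x$core_um[2], x$core_mean,
              x$rim_um[1], x$rim_um[2], x$rim_mean,
              if (x$partial) " (partial coverage)" else ""))
  invisible(x)
}

#' Two-group comparison of a spheroid region
#'
#' Welch two-sample t-test on per-spheroid region means (core or rim) between
#' two groups of spheroids. Degenerate input where every spheroid in both
#' groups has the identical value short-circuits to `p = 1` when the means
#' are equal.
#'
#' @param group_a,group_b Lists of [region_stats()] (>= 2 spheroids each).
#' @param region `"rim"` or `"core"`.
#' @return List with `difference` (mean a minus mean b), `t`, `p`, `region`
#'   and the per-group values.
#' @export
compare_regions <- function(group_a, group_b, region = c("rim", "core")) {
  region <- match.arg(region)
  pick <- function(g) {
    vapply(g, function(s) {
      stopifnot(inherits(s, "region_stats"))
      if (region == "rim") s$rim_mean else s$core_mean
    }, numeric(1))
  }
  a <- pick(group_a)
  b <- pick(group_b)
  if (length(a) < 2L || length(b) < 2L) {
    stop("need at least 2 spheroids per group", call. = FALSE)
  }
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    return(list(difference = mean(a) - mean(b),
                t = if (mean(a) == mean(b)) 0 else Inf,
                p = if (mean(a) == mean(b)) 1 else 0,
                region = region, values_a = a, values_b = b))
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  list(difference = unname(mean(a) - mean(b)), t = unname(tt$statistic),
       p = tt$p.value, region = region, values_a = a, values_b = b)
}
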