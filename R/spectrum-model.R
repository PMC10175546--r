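#' Decay component of a PALS spectrum
#'
#' One annihilation channel of a positron annihilation lifetime spectrum:
#' a label, a mean lifetime and an intensity (the fraction of all recorded
#' coincidence events arising from this channel).
#'
#' The canonical four-component decomposition of a sodium-22 spheroid
#' measurement uses the labels \code{"p-Ps"} (para-positronium),
#' \code{"source"} (annihilation in the Kapton-wrapped source foil),
#' \code{"free"} (direct electron-positron annihilation) and \code{"o-Ps"}
#' (ortho-positronium, the biomarker channel).
#'
#' @param label Short character label for the channel.
#' @param lifetime Mean lifetime in ns, strictly positive.
#' @param intensity Fraction of events in `[0, 1]`.
#' @return An object of class `decay_component`.
#' @examples
#' decay_component("o-Ps", lifetime = 1.876, intensity = 0.165)
#' @export
decay_component <- function(label, lifetime, intensity) {
  stopifnot(is.character(label), length(label) == 1L)
  if (!is.numeric(lifetime) || length(lifetime) != 1L || !is.finite(lifetime) ||
      lifetime <= 0) {
    stop("'lifetime' must be a single positive number (ns)", call. = FALSE)
  }
  if (!is.numeric(intensity) || length(intensity) != 1L ||
      !is.finite(intensity) || intensity < 0 || intensity > 1) {
    stop("'intensity' must be a single number in [0, 1]", call. = FALSE)
  }
  structure(list(label = label, lifetime = as.numeric(lifetime),
                 intensity = as.numeric(intensity)),
            class = "decay_component")
}

#' @export
print.decay_component <- function(x, ...) {
  cat(sprintf("<decay_component> %-8s tau = %.4g ns  I = %.4g\n",
              x$label, x$lifetime, x$intensity))
  invisible(x)
}

#' Gaussian timing resolution of the spectrometer
#'
#' The timing-jitter kernel convolved with every exponential decay channel.
#' A single Gaussian parameterized by its full width at half maximum is the
#' default; a weighted mixture of shifted Gaussians is supported for
#' spectrometers whose response is not well described by one Gaussian.
#'
#' @param fwhm Full width(s) at half maximum in ns, all positive.
#' @param weight Mixture weights, non-negative, summing to 1.
#' @param shift Per-term time shifts in ns (relative to the model time zero).
#' @return An object of class `resolution_function` with elements `fwhm`,
#'   `weight`, `shift` and the derived `sigma` (`fwhm / (2 sqrt(2 log 2))`).
#' @examples
#' resolution_function(fwhm = 0.25)
#' @export
resolution_function <- function(fwhm = 0.25, weight = NULL, shift = NULL) {
  if (!is.numeric(fwhm) || length(fwhm) < 1L || any(!is.finite(fwhm)) ||
      any(fwhm <= 0)) {
    stop("all 'fwhm' values must be positive (ns)", call. = FALSE)
  }
  n <- length(fwhm)
  if (is.null(weight)) weight <- rep(1 / n, n)
  if (is.null(shift)) shift <- rep(0, n)
  stopifnot(length(weight) == n, length(shift) == n)
  if (any(weight < 0)) stop("resolution weights must be non-negative",
                            call. = FALSE)
  if (abs(sum(weight) - 1) > 1e-9) {
    stop("resolution weights must sum to 1 (within 1e-9)", call. = FALSE)
  }
  structure(list(fwhm = as.numeric(fwhm), weight = as.numeric(weight),
                 shift = as.numeric(shift),
                 sigma = as.numeric(fwhm) / (2 * sqrt(2 * log(2)))),
            class = "resolution_function")
}

#' @export
print.resolution_function <- function(x, ...) {
  cat("<resolution_function>\n")
  for (i in seq_along(x$fwhm)) {
    cat(sprintf("  FWHM = %.4g ns (sigma = %.4g), weight = %.3g, shift = %.3g ns\n",
                x$fwhm[i], x$sigma[i], x$weight[i], x$shift[i]))
  }
  invisible(x)
}

#' Generative model of a PALS lifetime spectrum
#'
#' The full forward model of a coincidence lifetime measurement: a list of
#' exponential decay components convolved with the detector resolution, plus a
#' flat background of accidental coincidences spread uniformly over the
#' acquisition window. Component intensities and the background fraction must
#' partition the unit event mass.
#'
#' @param components List of [decay_component()] objects.
#' @param t0 Time-zero offset in ns (position of the prompt peak).
#' @param resolution A [resolution_function()].
#' @param background_fraction Fraction of events uniform over `window`,
#'   in `[0, 1)`.
#' @param window Length-2 numeric, acquisition window `(t_min, t_max)` in ns,
#'   with `t_min < t0 < t_max`.
#' @param n_events Total number of coincidence events (positive).
#' @return An object of class `spectrum_model`.
#' @examples
#' m <- spectrum_model(
#'   components = list(
#'     decay_component("p-Ps",   0.125, 0.055),
#'     decay_component("source", 0.374, 0.100),
#'     decay_component("free",   0.395, 0.675),
#'     decay_component("o-Ps",   1.876, 0.165)),
#'   background_fraction = 0.005)
#' m
#' @export
spectrum_model <- function(components, t0 = 0,
                           resolution = resolution_function(),
                           background_fraction = 0,
                           window = c(-2, 25),
                           n_events = 1e6) {
  stopifnot(is.list(components), length(components) >= 1L)
  ok <- vapply(components, inherits, logical(1), "decay_component")
  if (!all(ok)) stop("'components' must be a list of decay_component objects",
                     call. = FALSE)
  if (!inherits(resolution, "resolution_function")) {
    stop("'resolution' must be a resolution_function", call. = FALSE)
  }
  if (background_fraction < 0 || background_fraction >= 1) {
    stop("'background_fraction' must be in [0, 1)", call. = FALSE)
  }
  stopifnot(length(window) == 2L, window[1] < window[2])
  if (!(window[1] < t0 && t0 < window[2])) {
    stop("time zero 't0' must lie strictly inside the window", call. = FALSE)
  }
  if (n_events < 1) stop("'n_events' must be >= 1", call. = FALSE)
  isum <- sum(vapply(components, `[[`, numeric(1), "intensity")) +
    background_fraction
  if (abs(isum - 1) > 1e-9) {
    stop(sprintf(paste0("component intensities plus background must sum to 1 ",
                        "(got %.12g)"), isum), call. = FALSE)
  }
  structure(list(components = components, t0 = as.numeric(t0),
                 resolution = resolution,
                 background_fraction = as.numeric(background_fraction),
                 window = as.numeric(window),
                 n_events = as.numeric(n_events)),
            class = "spectrum_model")
}

#' @export
print.spectrum_model <- function(x, ...) {
  cat("<spectrum_model>\n")
  for (cc in x$components) {
    cat(sprintf("  %-8s tau = %.4g ns  I = %.4g\n",
                cc$label, cc$lifetime, cc$intensity))
  }
  cat(sprintf("  background = %.4g, t0 = %.4g ns, window = (%g, %g) ns\n",
              x$background_fraction, x$t0, x$window[1], x$window[2]))
  cat(sprintf("  resolution FWHM = %s ns, n_events = %g\n",
              paste(signif(x$resolution$fwhm, 4), collapse = "/"),
              x$n_events))
  invisible(x)
}

component_labels <- function(model) {
  vapply(model$components, `[[`, character(1), "label")
}

component_lifetimes <- function(model) {
  vapply(model$components, `[[`, numeric(1), "lifetime")
}

component_intensities <- function(model) {
  vapply(model$components, `[[`, numeric(1), "intensity")
}

#' Binned coincidence lifetime spectrum
#'
#' @param bin_edges Strictly increasing bin edges in ns (length B + 1); bins
#'   must be uniform in width (within 1e-12 relative).
#' @param counts Length-B vector of non-negative integer counts.
#' @param metadata Named list of free-text provenance (seed, truth, source
#'   file, ...).
#' @return An object of class `lifetime_histogram`.
#' @seealso [bin_events()], [read_histogram()]
#' @export
lifetime_histogram <- function(bin_edges, counts, metadata = list()) {
  bin_edges <- as.numeric(bin_edges)
  if (length(bin_edges) < 2L || any(diff(bin_edges) <= 0)) {
    stop("'bin_edges' must be strictly increasing", call. = FALSE)
  }
  w <- diff(bin_edges)
  if (max(w) - min(w) > 1e-12 * max(abs(bin_edges))) {
    stop("bin widths must be uniform", call. = FALSE)
  }
  if (length(counts) != length(bin_edges) - 1L) {
    stop("'counts' must have length(bin_edges) - 1 entries", call. = FALSE)
  }
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(abs(counts - round(counts)) > 1e-9)) {
    stop("'counts' must be non-negative integers", call. = FALSE)
  }
  structure(list(bin_edges = bin_edges, counts = as.numeric(round(counts)),
                 metadata = metadata),
            class = "lifetime_histogram")
}

#' @export
print.lifetime_histogram <- function(x, ...) {
  b <- length(x$counts)
  cat(sprintf("<lifetime_histogram> %d bins on (%g, %g) ns, %g counts\n",
              b, x$bin_edges[1], x$bin_edges[b + 1], sum(x$counts)))
  if (length(x$metadata)) {
    cat("  metadata:", paste(names(x$metadata), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Bin centers of a lifetime histogram
#' @param hist A [lifetime_histogram()].
#' @return Numeric vector of bin mid-times in ns.
#' @export
bin_centers <- function(hist) {
  e <- hist$bin_edges
  (e[-1] + e[-length(e)]) / 2
}

#' Default uniform bin edges for a time window
#' @param window Length-2 window `(t_min, t_max)` in ns.
#' @param width Bin width in ns (default 0.025 ns).
#' @return Numeric vector of edges covering the window.
#' @export
default_bin_edges <- function(window = c(-2, 25), width = 0.025) {
  stopifnot(length(window) == 2L, window[1] < window[2], width > 0)
  n <- round((window[2] - window[1]) / width)
  window[1] + width * (0:n)
}

#' Exponentially modified Gaussian density
#'
#' Density of a one-sided exponential decay with mean lifetime `lifetime`,
#' starting at `t0`, convolved with a centered Gaussian of standard deviation
#' `sigma` — the per-component shape of a PALS spectrum. The evaluation is
#' overflow-safe for `sigma/lifetime` ratios of at least 10 (the complementary
#' error function is taken in log space), and `sigma = 0` returns the pure
#' one-sided exponential.
#'
#' @param t Times in ns (vectorized).
#' @param lifetime Mean lifetime in ns, positive.
#' @param t0 Time-zero offset in ns.
#' @param sigma Gaussian resolution standard deviation in ns, non-negative.
#' @return Density values in 1/ns.
#' @examples
#' emg_density(0.5, lifetime = 1.876, t0 = 0, sigma = 0.106)
#' @export
emg_density <- function(t, lifetime, t0 = 0, sigma = 0) {
  if (!is.numeric(lifetime) || lifetime <= 0) {
    stop("'lifetime' must be positive", call. = FALSE)
  }
  if (!is.numeric(sigma) || sigma < 0) {
    stop("'sigma' must be non-negative", call. = FALSE)
  }
  u <- t - t0
  if (sigma == 0) {
    return(ifelse(u < 0, 0, exp(-u / lifetime) / lifetime))
  }
  # log f = -log(2 tau) + sigma^2/(2 tau^2) - u/tau + log erfc(z),
  # z = (sigma/tau - u/sigma)/sqrt(2); log erfc via the stable Gaussian
  # upper-tail log-probability, so the two large exponents cancel in log space.
  z <- (sigma / lifetime - u / sigma) / sqrt(2)
  log_erfc <- log(2) + stats::pnorm(z * sqrt(2), lower.tail = FALSE,
                                    log.p = TRUE)
  exp(-log(2 * lifetime) + sigma^2 / (2 * lifetime^2) - u / lifetime +
        log_erfc)
}

#' Exponentially modified Gaussian cumulative distribution
#'
#' Cumulative probability of the [emg_density()] shape; used for exact
#' (bin-width independent) per-bin expectations.
#'
#' @inheritParams emg_density
#' @return Cumulative probabilities in `[0, 1]`.
#' @export
emg_cdf <- function(t, lifetime, t0 = 0, sigma = 0) {
  if (!is.numeric(lifetime) || lifetime <= 0) {
    stop("'lifetime' must be positive", call. = FALSE)
  }
  if (!is.numeric(sigma) || sigma < 0) {
    stop("'sigma' must be non-negative", call. = FALSE)
  }
  u <- t - t0
  if (sigma == 0) {
    return(ifelse(u < 0, 0, 1 - exp(-u / lifetime)))
  }
  v <- u / sigma
  # F(t) = Phi(v) - exp(sigma^2/(2 tau^2) - u/tau) Phi(v - sigma/tau),
  # with the second term assembled in log space for stability.
  tail_log <- stats::pnorm(v - sigma / lifetime, log.p = TRUE)
  second <- exp(sigma^2 / (2 * lifetime^2) - u / lifetime + tail_log)
  out <- stats::pnorm(v) - second
  pmin(pmax(out, 0), 1)
}

# Probability mass of one decay component between consecutive edges, summed
# over the (possibly multi-Gaussian) resolution terms.
component_bin_mass <- function(edges, lifetime, t0, resolution) {
  mass <- 0
  for (j in seq_along(resolution$sigma)) {
    cdf <- emg_cdf(edges, lifetime, t0 + resolution$shift[j],
                   resolution$sigma[j])
    mass <- mass + resolution$weight[j] * diff(cdf)
  }
  mass
}

#' Expected counts per histogram bin under a spectrum model
#'
#' Exact per-bin expectations from CDF differences (not midpoint density times
#' width), plus the uniform-background contribution proportional to each bin's
#' overlap with the acquisition window.
#'
#' @param model A [spectrum_model()].
#' @param hist_edges Strictly increasing bin edges in ns.
#' @return Numeric vector of expected counts, one per bin.
#' @examples
#' m <- spectrum_model(list(decay_component("free", 0.4, 0.9)),
#'                     background_fraction = 0.1, n_events = 1000)
#' sum(expected_counts(m, default_bin_edges()))
#' @export
expected_counts <- function(model, hist_edges) {
  stopifnot(inherits(model, "spectrum_model"))
  hist_edges <- as.numeric(hist_edges)
  if (length(hist_edges) < 2L || any(diff(hist_edges) <= 0)) {
    stop("'hist_edges' must be strictly increasing", call. = FALSE)
  }
  probs <- numeric(length(hist_edges) - 1L)
  for (cc in model$components) {
    probs <- probs + cc$intensity *
      component_bin_mass(hist_edges, cc$lifetime, model$t0, model$resolution)
  }
  if (model$background_fraction > 0) {
    lo <- pmax(hist_edges[-length(hist_edges)], model$window[1])
    hi <- pmin(hist_edges[-1], model$window[2])
    overlap <- pmax(hi - lo, 0)
    probs <- probs + model$background_fraction * overlap /
      (model$window[2] - model$window[1])
  }
  model$n_events * probs
}
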