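#' Published o-Ps decomposition of the melanoma spheroid conditions
#'
#' Ortho-positronium mean lifetime (ns) and production intensity (fraction of
#' events) for the four measured conditions: two melanoma cell lines of
#' different malignancy (WM266-4, metastatic; WM115, primary tumor) on days 4
#' and 8 after spheroid seeding. Parenthesized one-sigma uncertainties are in
#' `tau_sd` / `intensity_sd`.
#'
#' @format A data.frame with columns `cell_line`, `day`, `tau`, `tau_sd`,
#'   `intensity`, `intensity_sd`.
#' @export
spheroid_conditions <- data.frame(
  cell_line    = c("WM266-4", "WM266-4", "WM115", "WM115"),
  day          = c(4L, 8L, 4L, 8L),
  tau          = c(1.876, 1.861, 1.909, 1.875),
  tau_sd       = c(0.005, 0.006, 0.006, 0.006),
  intensity    = c(0.165, 0.170, 0.180, 0.150),
  intensity_sd = c(0.006, 0.002, 0.008, 0.002),
  stringsAsFactors = FALSE
)

#' Ground-truth spectrum model for a measured spheroid condition
#'
#' Builds the four-component generative model whose o-Ps lifetime and
#' intensity are the published values for the requested cell line and culture
#' day. The three short-lived components are fixed at their fitted lifetimes
#' (p-Ps 0.125 ns, Kapton source 0.374 ns, free annihilation 0.395 ns). The
#' short-component intensities are not published, so defaults encode standard
#' PALS practice: para-positronium forms at one third of the o-Ps rate (the
#' 1:3 singlet:triplet formation ratio), the foil-wrapped source contributes a
#' typical 10% of events, a 0.5% flat background models accidental
#' coincidences, and free annihilation absorbs the remainder.
#'
#' @param cell_line `"WM266-4"` or `"WM115"`.
#' @param day Culture day, 4 or 8.
#' @param source_intensity Intensity of the Kapton source component.
#' @param background_fraction Flat accidental-coincidence fraction.
#' @param resolution Detector [resolution_function()].
#' @param window Acquisition window in ns.
#' @param n_events Total coincidence events (default one million, the per-
#'   measurement event budget of the spheroid experiment).
#' @return A [spectrum_model()] carrying the condition truth.
#' @examples
#' make_condition_truth("WM266-4", 4)
#' @export
make_condition_truth <- function(cell_line = c("WM266-4", "WM115"),
                              day = c(4, 8),
                              source_intensity = 0.10,
                              background_fraction = 0.005,
                              resolution = resolution_function(),
                              window = c(-2, 25),
                              n_events = 1e6) {
  cell_line <- match.arg(cell_line)
  day <- as.integer(day[1])
  row <- spheroid_conditions[spheroid_conditions$cell_line == cell_line &
                             spheroid_conditions$day == day, ]
  if (nrow(row) != 1L) {
    stop(sprintf("unknown condition: %s day %d", cell_line, day),
         call. = FALSE)
  }
  i_ops <- row$intensity
  i_pps <- i_ops / 3
  i_free <- 1 - background_fraction - source_intensity - i_ops - i_pps
  if (i_free <= 0) {
    stop("short-component intensities leave no mass for free annihilation",
         call. = FALSE)
  }
  model <- spectrum_model(
    components = list(
      decay_component("p-Ps",   0.125, i_pps),
      decay_component("source", 0.374, source_intensity),
      decay_component("free",   0.395, i_free),
      decay_component("o-Ps",   row$tau, i_ops)),
    t0 = 0,
    resolution = resolution,
    background_fraction = background_fraction,
    window = window,
    n_events = n_events)
  attr(model, "condition") <- sprintf("%s:day%d", cell_line, day)
  model
}

#' Source-only calibration model
#'
#' Model of a calibration run with an empty sample chamber: only the Kapton
#' source component and background are present. Fitting such a spectrum pins
#' the source intensity used as a fixed constraint in sample fits.
#'
#' @inheritParams make_condition_truth
#' @return A [spectrum_model()] with a single `"source"` component.
#' @export
make_calibration_model <- function(background_fraction = 0.005,
                                   resolution = resolution_function(),
                                   window = c(-2, 25),
                                   n_events = 1e6) {
  spectrum_model(
    components = list(
      decay_component("source", 0.374, 1 - background_fraction)),
    resolution = resolution,
    background_fraction = background_fraction,
    window = window,
    n_events = n_events)
}

# Restore the caller's RNG stream after seeded simulation.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Draw event-level annihilation times from a spectrum model
#'
#' Monte-Carlo generator of coincidence lifetimes: each event first draws its
#' channel from the categorical law given by the component intensities and the
#' background fraction; decay channels return
#' `t0 + Exponential(lifetime) + Gaussian(0, sigma)` (resolution smearing,
#' mixture-resolved for multi-Gaussian responses) and the background channel
#' returns a uniform draw over the acquisition window. Events falling outside
#' the window are kept — truncation is applied at binning — so intensities
#' stay interpretable as true formation fractions.
#'
#' @param model A [spectrum_model()]; intensities plus background must sum
#'   to 1.
#' @param n_events Number of events (default `model$n_events`).
#' @param seed Optional integer seed; identical seeds give identical draws,
#'   and the caller's RNG state is left untouched.
#' @return Numeric vector of `n_events` annihilation times in ns.
#' @examples
#' t <- sample_events(make_condition_truth("WM115", 4), n_events = 1000, seed = 1)
#' length(t)
#' @export
sample_events <- function(model, n_events = model$n_events, seed = NULL) {
  stopifnot(inherits(model, "spectrum_model"))
  n_events <- as.integer(n_events)
  if (n_events < 1L) stop("'n_events' must be >= 1", call. = FALSE)
  intens <- component_intensities(model)
  p <- c(intens, model$background_fraction)
  if (abs(sum(p) - 1) > 1e-9) {
    stop("component intensities plus background must sum to 1", call. = FALSE)
  }
  with_seed(seed, {
    k <- length(intens)
    channel <- sample.int(k + 1L, n_events, replace = TRUE, prob = p)
    times <- numeric(n_events)
    res <- model$resolution
    for (i in seq_len(k)) {
      idx <- which(channel == i)
      if (!length(idx)) next
      jitter <- if (length(res$sigma) == 1L) {
        stats::rnorm(length(idx), res$shift, res$sigma)
      } else {
        j <- sample.int(length(res$sigma), length(idx), replace = TRUE,
                        prob = res$weight)
        stats::rnorm(length(idx), res$shift[j], res$sigma[j])
      }
      times[idx] <- model$t0 +
        stats::rexp(length(idx), rate = 1 / model$components[[i]]$lifetime) +
        jitter
    }
    idx <- which(channel == k + 1L)
    if (length(idx)) {
      times[idx] <- stats::runif(length(idx), model$window[1], model$window[2])
    }
    times
  })
}

#' Bin event times into a lifetime histogram
#'
#' Half-open bins `[e_b, e_{b+1})`; events outside `[e_1, e_{B+1})` are
#' dropped.
#'
#' @param times Numeric event times in ns.
#' @param edges Strictly increasing bin edges.
#' @param metadata Named list recorded in the histogram (seed, truth, ...).
#' @return A [lifetime_histogram()].
#' @examples
#' bin_events(c(0.5, 1.5, 2.5), 0:3)$counts
#' @export
bin_events <- function(times, edges, metadata = list()) {
  edges <- as.numeric(edges)
  if (length(edges) < 2L || any(diff(edges) <= 0)) {
    stop("'edges' must be strictly increasing", call. = FALSE)
  }
  b <- length(edges) - 1L
  if (length(times)) {
    idx <- findInterval(times, edges, left.open = FALSE)
    idx <- idx[times < edges[b + 1L] & idx >= 1L]
    counts <- tabulate(idx, nbins = b)
  } else {
    counts <- integer(b)
  }
  lifetime_histogram(edges, counts, metadata = metadata)
}

#' Simulate a binned lifetime spectrum with known ground truth
#'
#' Convenience wrapper: [sample_events()] followed by [bin_events()] on the
#' default 0.025-ns grid over the model window, with the seed and the
#' generating truth recorded in the histogram metadata.
#'
#' @param model A [spectrum_model()] (the ground truth).
#' @param n_events Number of events (default `model$n_events`).
#' @param seed Optional integer seed.
#' @param bin_width Bin width in ns.
#' @return A [lifetime_histogram()] whose `metadata$truth` holds the model.
#' @examples
#' h <- simulate_spectrum(make_condition_truth("WM266-4", 4), n_events = 5000,
#'                        seed = 7)
#' sum(h$counts)
#' @export
simulate_spectrum <- function(model, n_events = model$n_events, seed = NULL,
                              bin_width = 0.025) {
  times <- sample_events(model, n_events = n_events, seed = seed)
  edges <- default_bin_edges(model$window, bin_width)
  meta <- list(seed = seed, n_events = n_events, rng = "Mersenne-Twister",
               truth = model)
  cond <- attr(model, "condition")
  if (!is.null(cond)) meta$condition <- cond
  bin_events(times, edges, metadata = meta)
}
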