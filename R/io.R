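#' Write a lifetime histogram as two-column ASCII
#'
#' The common PALS instrument-export dialect: '#'-prefixed `key = value`
#' metadata header lines, then one row per bin with the bin center (ns) and
#' the integer count, tab-separated. Only scalar metadata entries are
#' serialized (a `truth` model, if present, is summarized by its condition
#' label).
#'
#' @param hist A [lifetime_histogram()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_histogram <- function(hist, path) {
  stopifnot(inherits(hist, "lifetime_histogram"))
  meta <- hist$metadata
  if (!is.null(meta$truth)) {
    cond <- attr(meta$truth, "condition")
    meta$truth <- NULL
    if (!is.null(cond) && is.null(meta$condition)) meta$condition <- cond
  }
  keep <- vapply(meta, function(v) is.atomic(v) && length(v) == 1L,
                 logical(1))
  lines <- c(
    sprintf("# %s = %s", names(meta)[keep],
            vapply(meta[keep], function(v) format(v, digits = 17),
                   character(1))),
    sprintf("%.6f\t%d", bin_centers(hist), as.integer(hist$counts)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a two-column ASCII lifetime histogram
#'
#' Parses the dialect written by [write_histogram()]: bin centers must be
#' uniformly spaced (the bin edges are reconstructed from the inferred
#' width), counts must be non-negative integers. Violations are reported with
#' the first offending row number.
#'
#' @param path Input file path.
#' @return A [lifetime_histogram()] with the header metadata attached.
#' @export
read_histogram <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  is_meta <- startsWith(lines, "#")
  meta <- list()
  for (ln in lines[is_meta]) {
    m <- regmatches(ln, regexec("^#\\s*([^=]+?)\\s*=\\s*(.*)$", ln))[[1]]
    if (length(m) == 3L) {
      val <- m[3]
      num <- suppressWarnings(as.numeric(val))
      meta[[m[2]]] <- if (!is.na(num)) num else val
    }
  }
  body <- which(!is_meta & nzchar(trimws(lines)))
  if (!length(body)) stop("no data rows in ", path, call. = FALSE)
  parts <- strsplit(trimws(lines[body]), "[\t ]+")
  bad <- which(lengths(parts) != 2L)
  if (length(bad)) {
    stop(sprintf("row %d: expected two columns", body[bad[1]]), call. = FALSE)
  }
  tab <- matrix(suppressWarnings(as.numeric(unlist(parts))), ncol = 2,
                byrow = TRUE)
  if (anyNA(tab)) {
    stop(sprintf("row %d: non-numeric entry",
                 body[which(rowSums(is.na(tab)) > 0)[1]]), call. = FALSE)
  }
  centers <- tab[, 1]
  counts <- tab[, 2]
  w <- diff(centers)
  if (length(w)) {
    off <- which(abs(w - w[1]) > 1e-6 * max(abs(centers)))
    if (length(off)) {
      stop(sprintf("row %d: bin centers are not uniformly spaced",
                   body[off[1] + 1L]), call. = FALSE)
    }
  }
  bad <- which(counts < 0 | abs(counts - round(counts)) > 1e-9)
  if (length(bad)) {
    stop(sprintf("row %d: counts must be non-negative integers (got %s)",
                 body[bad[1]], format(counts[bad[1]])), call. = FALSE)
  }
  width <- if (length(w)) stats::median(w) else 1
  edges <- c(centers - width / 2, centers[length(centers)] + width / 2)
  lifetime_histogram(edges, counts, metadata = meta)
}

#' Serialize a fit result to JSON
#'
#' Structured report of a spectrum decomposition: estimates, one-sigma
#' uncertainties, the free-parameter covariance (row-major with labels), fit
#' statistics, degrees of freedom, the convergence flag, the input
#' histogram's metadata verbatim, and provenance (package version, timestamp,
#' optional input path / config hash / seed).
#'
#' @param result A `pals_fit` (see [fit_spectrum()]).
#' @param path Output JSON path.
#' @param input_path,config_hash,seed Optional provenance fields.
#' @return `path`, invisibly.
#' @export
write_result <- function(result, path, input_path = NULL, config_hash = NULL,
                         seed = NULL) {
  stopifnot(inherits(result, "pals_fit"))
  meta <- result$metadata
  meta$truth <- NULL
  payload <- list(
    estimates = as.list(result$estimates),
    uncertainties = as.list(result$uncertainties),
    covariance = list(labels = rownames(result$covariance),
                      values = as.numeric(t(result$covariance))),
    statistic = as.list(result$statistic),
    ndf = result$ndf,
    converged = result$converged,
    n_events_fit = result$n_events_fit,
    metadata = meta,
    provenance = list(
      package = "palspheroid",
      version = as.character(utils::packageVersion("palspheroid")),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      input_path = input_path, config_hash = config_hash, seed = seed))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a fit-result JSON report
#'
#' @param path Path written by [write_result()].
#' @return List with numeric `estimates`, `uncertainties`, the reshaped
#'   `covariance` matrix, `statistic`, `ndf`, `converged`, `metadata` and
#'   `provenance`.
#' @export
read_result <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  k <- length(x$covariance$labels)
  cov <- matrix(x$covariance$values, k, k, byrow = TRUE,
                dimnames = list(x$covariance$labels, x$covariance$labels))
  list(estimates = unlist(x$estimates),
       uncertainties = unlist(x$uncertainties),
       covariance = cov, statistic = unlist(x$statistic), ndf = x$ndf,
       converged = x$converged, n_events_fit = x$n_events_fit,
       metadata = x$metadata, provenance = x$provenance)
}

# ---- run configuration --------------------------------------------------

#' Serialize a spectrum model and run settings to a YAML run config
#'
#' @param model A [spectrum_model()].
#' @param path Output YAML path.
#' @param constraints Optional [fit_constraints()] block.
#' @param simulation Optional list (e.g. `n_events`, `seed`).
#' @return `path`, invisibly.
#' @export
write_run_config <- function(model, path, constraints = NULL,
                             simulation = NULL) {
  stopifnot(inherits(model, "spectrum_model"))
  cfg <- list(model = list(
    components = lapply(model$components, function(cc) {
      list(label = cc$label, lifetime = cc$lifetime,
           intensity = cc$intensity)
    }),
    t0 = model$t0,
    resolution = list(fwhm = model$resolution$fwhm,
                      weight = model$resolution$weight,
                      shift = model$resolution$shift),
    background_fraction = model$background_fraction,
    window = model$window,
    n_events = model$n_events))
  if (!is.null(constraints)) {
    cfg$constraints <- list(
      fixed_lifetimes = as.list(constraints$fixed_lifetimes),
      fixed_intensities = as.list(constraints$fixed_intensities),
      fit_t0 = constraints$fit_t0,
      fit_resolution = constraints$fit_resolution,
      lifetime_bounds = constraints$lifetime_bounds)
  }
  if (!is.null(simulation)) cfg$simulation <- simulation
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}

#' Read a YAML run config
#'
#' Inverse of [write_run_config()]; `read_run_config(write_run_config(m, p))`
#' reproduces the model exactly.
#'
#' @param path YAML path.
#' @return List with `model` (a [spectrum_model()]), and, when present,
#'   `constraints` (a [fit_constraints()]) and `simulation` (a list).
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  m <- cfg$model
  model <- spectrum_model(
    components = lapply(m$components, function(cc) {
      decay_component(cc$label, cc$lifetime, cc$intensity)
    }),
    t0 = m$t0,
    resolution = resolution_function(fwhm = unlist(m$resolution$fwhm),
                                     weight = unlist(m$resolution$weight),
                                     shift = unlist(m$resolution$shift)),
    background_fraction = m$background_fraction,
    window = unlist(m$window),
    n_events = m$n_events)
  out <- list(model = model)
  if (!is.null(cfg$constraints)) {
    cs <- cfg$constraints
    out$constraints <- fit_constraints(
      fixed_lifetimes = unlist(cs$fixed_lifetimes),
      fixed_intensities = unlist(cs$fixed_intensities),
      fit_t0 = cs$fit_t0, fit_resolution = cs$fit_resolution,
      lifetime_bounds = unlist(cs$lifetime_bounds))
  }
  if (!is.null(cfg$simulation)) out$simulation <- cfg$simulation
  out
}

#' Read a growth series CSV
#'
#' Columns: `time_days` plus at least one of `diameter_um`, `volume_um3`,
#' `cell_count`.
#'
#' @param path CSV path.
#' @return A [growth_series()].
#' @export
read_growth_csv <- function(path) {
  growth_series(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Read a grayscale spheroid image (PNG or TIFF)
#'
#' Multi-channel images are averaged to grayscale. The pixel size is not
#' stored in these formats and must be supplied.
#'
#' @param path Image path ending in `.png`, `.tif` or `.tiff`.
#' @param pixel_size Pixel size in µm.
#' @param channel Channel label.
#' @return A [spheroid_image()].
#' @export
read_spheroid_image <- function(path, pixel_size, channel = "glucose") {
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
                png = png::readPNG(path),
                tif = ,
                tiff = tiff::readTIFF(path),
                stop("unsupported image format: .", ext, call. = FALSE))
  if (length(dim(arr)) == 3L) arr <- apply(arr, c(1, 2), mean)
  spheroid_image(arr, pixel_size, channel)
}
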