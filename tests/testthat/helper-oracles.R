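# Independent oracles used across test files.

# Brute-force numeric convolution of a one-sided exponential with a centered
# Gaussian, by adaptive quadrature; independent of the closed-form EMG code.
conv_density_oracle <- function(t, lifetime, t0, sigma) {
  vapply(t, function(tt) {
    stats::integrate(function(s) {
      stats::dexp(s, rate = 1 / lifetime) *
        stats::dnorm(tt - t0 - s, mean = 0, sd = sigma)
    }, lower = 0, upper = Inf, rel.tol = 1e-12, abs.tol = 0)$value
  }, numeric(1))
}

# Half-normal CDF (the law of |Z| for standard normal Z).
phalfnorm <- function(q) ifelse(q < 0, 0, 2 * stats::pnorm(q) - 1)

# Unbinned EM fit of a two-component exponential mixture (lifetime
# parameterization); an independent route to the binned Poisson MLE.
em_two_exponentials <- function(times, tau_init = c(0.5, 2), max_iter = 500) {
  tau <- tau_init
  w <- c(0.5, 0.5)
  times <- times[times > 0]
  for (it in seq_len(max_iter)) {
    d1 <- w[1] * stats::dexp(times, 1 / tau[1])
    d2 <- w[2] * stats::dexp(times, 1 / tau[2])
    r1 <- d1 / (d1 + d2)
    tau_new <- c(sum(r1 * times) / sum(r1),
                 sum((1 - r1) * times) / sum(1 - r1))
    w_new <- c(mean(r1), 1 - mean(r1))
    if (max(abs(tau_new - tau)) < 1e-10) {
      tau <- tau_new; w <- w_new
      break
    }
    tau <- tau_new; w <- w_new
  }
  list(tau = tau, weight = w)
}

# Memoized replicate ensemble of fitted WM266-4 day-4 spectra, shared by the
# recovery, uncertainty-scale and calibration checks.
.replicate_cache <- new.env(parent = emptyenv())

wm2664_day4_replicates <- function(n = 20, n_events = 1e6) {
  key <- sprintf("wm2664_%d_%g", n, n_events)
  if (!is.null(.replicate_cache[[key]])) return(.replicate_cache[[key]])
  truth <- make_condition_truth("WM266-4", 4)
  out <- data.frame(tau = numeric(n), tau_sd = numeric(n),
                    intensity = numeric(n), intensity_sd = numeric(n),
                    converged = logical(n))
  for (i in seq_len(n)) {
    f <- fit_spectrum(simulate_spectrum(truth, n_events = n_events, seed = i))
    out$tau[i] <- f$estimates["tau.o-Ps"]
    out$tau_sd[i] <- f$uncertainties["tau.o-Ps"]
    out$intensity[i] <- f$estimates["I.o-Ps"]
    out$intensity_sd[i] <- f$uncertainties["I.o-Ps"]
    out$converged[i] <- f$converged
  }
  .replicate_cache[[key]] <- out
  out
}
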