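# Constraint set for single-free-component toys: nothing fixed but a zero
# background, time zero held at the init model's value.
toy_constraints <- function() {
  fit_constraints(fixed_lifetimes = NULL,
                  fixed_intensities = c(background = 0),
                  fit_t0 = FALSE)
}

toy_model <- function(tau = 2, sigma = 0.01, window = c(-0.5, 40),
                      n_events = 1e5) {
  spectrum_model(list(decay_component("exp", tau, 1)),
                 resolution = resolution_function(sigma * 2 *
                                                    sqrt(2 * log(2))),
                 t0 = 0, background_fraction = 0, window = window,
                 n_events = n_events)
}

test_that("single-exponential lifetime is recovered at Cramer-Rao precision", {
  truth <- toy_model(tau = 2, sigma = 0.01, n_events = 1e5)
  h <- simulate_spectrum(truth, seed = 101, bin_width = 0.05)
  init <- toy_model(tau = 2.4, sigma = 0.01, n_events = 1e5)
  f <- fit_spectrum(h, init = init, constraints = toy_constraints())
  expect_true(f$converged)
  expect_lt(abs(f$estimates["tau.exp"] - 2), 3 * 2 / sqrt(1e5))
  # curvature uncertainty should be near the tau/sqrt(n) bound
  expect_equal(unname(f$uncertainties["tau.exp"]), 2 / sqrt(1e5),
               tolerance = 0.1)
})

test_that("refitting the Asimov histogram returns the truth", {
  # a large event budget keeps integer rounding of the expectations from
  # perturbing the noise-free optimum
  truth <- make_condition_truth("WM266-4", 4, n_events = 1e7)
  edges <- default_bin_edges()
  mu <- expected_counts(truth, edges)
  h <- lifetime_histogram(edges, round(mu))
  f <- fit_spectrum(h)
  expect_true(f$converged)
  expect_equal(unname(f$estimates["tau.o-Ps"]), 1.876, tolerance = 1e-3)
  expect_equal(unname(f$estimates["I.o-Ps"]), 0.165, tolerance = 1e-3)
  expect_equal(unname(f$estimates["t0"]), 0, tolerance = 1e-3)
  expect_lt(goodness_of_fit(f), 0.01)
})

test_that("a simulated published condition is recovered within 3 sigma", {
  truth <- make_condition_truth("WM266-4", 4)
  f <- fit_spectrum(simulate_spectrum(truth, seed = 1))
  expect_true(f$converged)
  expect_lt(abs(f$estimates["tau.o-Ps"] - 1.876),
            3 * f$uncertainties["tau.o-Ps"])
  expect_lt(abs(f$estimates["I.o-Ps"] - 0.165),
            3 * f$uncertainties["I.o-Ps"])
})

test_that("fit results satisfy their structural invariants", {
  truth <- make_condition_truth("WM115", 8)
  f <- fit_spectrum(simulate_spectrum(truth, n_events = 2e5, seed = 5))
  expect_true(all(f$uncertainties >= 0))
  cv <- f$covariance
  expect_equal(cv, t(cv), tolerance = 1e-12)
  ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8 * max(abs(ev)))
  labs <- sub("^I\\.", "", grep("^I\\.", names(f$estimates), value = TRUE))
  isum <- sum(f$estimates[paste0("I.", labs)]) + f$estimates[["background"]]
  expect_equal(isum, 1, tolerance = 1e-6)
  expect_equal(f$ndf, length(default_bin_edges()) - 1L - length(f$par))
})

test_that("goodness of fit is calibrated and detects misspecification", {
  truth <- make_condition_truth("WM266-4", 4)
  h <- simulate_spectrum(truth, seed = 2)
  f <- fit_spectrum(h)
  expect_gt(goodness_of_fit(f), 0.8)
  expect_lt(goodness_of_fit(f), 1.2)
  # drop the o-Ps component: the long tail is unexplained
  init3 <- spectrum_model(
    list(decay_component("p-Ps", 0.125, 0.06),
         decay_component("source", 0.374, 0.10),
         decay_component("free", 0.395, 0.835)),
    t0 = 0, background_fraction = 0.005, window = truth$window,
    n_events = sum(h$counts))
  f3 <- fit_spectrum(h, init = init3)
  expect_gt(goodness_of_fit(f3), 2)
  bad <- f
  bad$ndf <- 0
  expect_error(goodness_of_fit(bad), "degrees of freedom")
})

test_that("fit errors on empty histograms and inconsistent initialization", {
  edges <- default_bin_edges()
  expect_error(fit_spectrum(lifetime_histogram(edges,
                                               rep(0, length(edges) - 1L))),
               "all-zero")
  truth <- make_condition_truth("WM266-4", 4)
  h <- simulate_spectrum(truth, n_events = 1e4, seed = 3)
  bad_init <- spectrum_model(
    list(decay_component("p-Ps", 0.2, 0.055),
         decay_component("source", 0.374, 0.1),
         decay_component("free", 0.395, 0.675),
         decay_component("o-Ps", 1.8, 0.165)),
    t0 = 0, background_fraction = 0.005, window = truth$window)
  expect_error(fit_spectrum(h, init = bad_init), "contradicts")
})

test_that("fitted o-Ps lifetime is invariant to bin width", {
  truth <- make_condition_truth("WM115", 4)
  ta <- sample_events(truth, n_events = 5e5, seed = 9)
  f1 <- fit_spectrum(bin_events(ta, default_bin_edges(truth$window, 0.025)))
  f2 <- fit_spectrum(bin_events(ta, default_bin_edges(truth$window, 0.0125)))
  expect_lt(abs(f1$estimates["tau.o-Ps"] - f2$estimates["tau.o-Ps"]),
            f1$uncertainties["tau.o-Ps"])
})

test_that("binned MLE agrees with an unbinned EM mixture oracle", {
  m <- spectrum_model(list(decay_component("short", 0.4, 0.6),
                           decay_component("long", 1.9, 0.4)),
                      resolution = resolution_function(1e-9), t0 = 0,
                      background_fraction = 0, window = c(-0.5, 30))
  times <- sample_events(m, n_events = 1e5, seed = 17)
  h <- bin_events(times, default_bin_edges(c(-0.5, 30), 0.025))
  init <- spectrum_model(list(decay_component("short", 0.5, 0.5),
                              decay_component("long", 1.6, 0.5)),
                         resolution = resolution_function(1e-9), t0 = 0,
                         background_fraction = 0, window = c(-0.5, 30))
  f <- fit_spectrum(h, init = init, constraints = toy_constraints())
  em <- em_two_exponentials(times, tau_init = c(0.5, 1.6))
  expect_lt(abs(f$estimates["tau.short"] - min(em$tau)),
            2 * f$uncertainties["tau.short"] + 1e-4)
  expect_lt(abs(f$estimates["tau.long"] - max(em$tau)),
            2 * f$uncertainties["tau.long"] + 1e-4)
})

test_that("increasing the true o-Ps lifetime increases the fitted one", {
  f_lo <- fit_spectrum(simulate_spectrum(make_condition_truth("WM266-4", 8),
                                         n_events = 5e5, seed = 23))
  f_hi <- fit_spectrum(simulate_spectrum(make_condition_truth("WM115", 4),
                                         n_events = 5e5, seed = 23))
  expect_gt(f_hi$estimates["tau.o-Ps"], f_lo$estimates["tau.o-Ps"])
})

test_that("profile intervals match curvature in the quadratic limit and
           shrink like 1/sqrt(n)", {
  truth <- toy_model(tau = 2, sigma = 0.01, window = c(-0.5, 20),
                     n_events = 1e5)
  init <- toy_model(tau = 2.2, sigma = 0.01, window = c(-0.5, 20),
                    n_events = 1e5)
  h1 <- simulate_spectrum(truth, seed = 41, bin_width = 0.05)
  f1 <- fit_spectrum(h1, init = init, constraints = toy_constraints())
  pr1 <- profile_uncertainty(h1, f1, "tau.exp")
  hw1 <- attr(pr1, "half_width")
  expect_gt(pr1["upper"], f1$estimates["tau.exp"])
  expect_lt(pr1["lower"], f1$estimates["tau.exp"])
  expect_equal(hw1, unname(f1$uncertainties["tau.exp"]), tolerance = 0.05)
  truth2 <- toy_model(tau = 2, sigma = 0.01, window = c(-0.5, 20),
                      n_events = 4e5)
  h2 <- simulate_spectrum(truth2, seed = 41, bin_width = 0.05)
  f2 <- fit_spectrum(h2, init = init, constraints = toy_constraints())
  pr2 <- profile_uncertainty(h2, f2, "tau.exp")
  ratio <- hw1 / attr(pr2, "half_width")  # quadrupling n halves the width
  expect_gt(ratio, 1.6)
  expect_lt(ratio, 2.4)
  expect_error(profile_uncertainty(h1, f1, "background"), "not a free")
  f_bad <- f1
  f_bad$converged <- FALSE
  expect_error(profile_uncertainty(h1, f_bad, "tau.exp"), "converged")
})
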