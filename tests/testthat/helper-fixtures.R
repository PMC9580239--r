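# Shared fixtures: generator truths and small scenarios used across tests.

default_truth <- function() calibration_params(2, 5, 8, lambda = -1.5, sigma = 1)

# a compact multi-site layout with a wide size range
fixture_sites <- function(n_sites = 6) {
  tibble::tibble(
    site = paste0("site", seq_len(n_sites)),
    region = "synthetic",
    size_ha = exp(seq(log(0.5), log(100), length.out = n_sites)),
    date_calBC = seq(6000, 2000, length.out = n_sites),
    rain_min_mm = 400, rain_max_mm = 600
  )
}

fixture_arch <- function(gamma = -0.5, n_per_site = 10, seed = 42,
                         sigma_u = 0.5, n_sites = 6, ...) {
  generate_arch(scenario_spec(fixture_sites(n_sites), calib = default_truth(),
                              gamma = gamma, sigma_u = sigma_u,
                              n_per_site = n_per_site, seed = seed, ...))
}

# fast MCMC settings for unit tests
fast_config <- function(...) {
  defaults <- list(warmup = 300, draws = 600, n_completed = 300,
                   stage2_iter = 15)
  do.call(manure_config, utils::modifyList(defaults, list(...)))
}

expect_prob_vector <- function(p) {
  expect_true(all(p >= 0))
  expect_equal(sum(p), 1, tolerance = 1e-9)
}
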