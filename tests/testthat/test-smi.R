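test_that("with deterministic levels the cut and joint posteriors coincide", {
  # near-zero measurement noise: imputation is a point mass, so no feedback
  # is possible and the two-stage (cut) and one-stage (full) samplers target
  # the same Bayesian proportional-odds posterior on the fixed levels
  truth <- calibration_params(2, 5, 8, lambda = -1.5, sigma = 0.02)
  arch <- generate_arch(scenario_spec(fixture_sites(4), calib = truth,
                                      gamma = -0.8, sigma_u = 0.3,
                                      n_per_site = 10, seed = 31))
  # the one-stage sampler keeps every 5th kept draw so both sets of gamma
  # draws are close to independent before the two-sample comparison
  cfg <- fast_config(n_completed = 500, warmup = 600, draws = 2500)
  cut <- sample_cut_posterior(arch, truth, cfg, seed = 1)
  full <- suppressWarnings(sample_full_posterior(arch, truth, cfg, seed = 2))
  ks <- suppressWarnings(ks.test(cut$draws$gamma, full$draws$gamma))
  expect_gt(ks$p.value, 0.01)
  # imputed levels are pinned to the truth
  P <- as.matrix(cut$level_probs[, 2:4])
  expect_equal(P[cbind(seq_len(nrow(P)), attr(arch, "truth")$level)],
               rep(1, nrow(P)), tolerance = 1e-6)
})

test_that("without level signal the cut posterior of gamma stays near its prior", {
  # d15n carries (almost) no information about levels: all level lines
  # essentially coincide, so imputed levels are uniform noise and the
  # analysis stage should learn (almost) nothing about gamma
  flat <- calibration_params(4.999, 5.0, 5.001, lambda = 0, sigma = 1)
  arch <- generate_arch(scenario_spec(fixture_sites(4), calib = flat,
                                      gamma = -2, sigma_u = 0.2,
                                      n_per_site = 15, seed = 41))
  cfg <- fast_config(n_completed = 400)
  cut <- sample_cut_posterior(arch, flat, cfg, seed = 3)
  P <- as.matrix(cut$level_probs[, 2:4])
  expect_true(all(abs(P - 1 / 3) < 0.1))
  expect_lt(abs(mean(cut$draws$gamma)), 0.5)
  # far wider than any data-informed posterior, reflecting the prior scale
  expect_gt(sd(cut$draws$gamma), 0.5)
})

test_that("posterior means are stable across independent seeds", {
  arch <- fixture_arch(gamma = -0.5, n_per_site = 15, seed = 51, n_sites = 5)
  cfg <- fast_config(n_completed = 400)
  f1 <- sample_smi_posterior(arch, default_truth(), cfg, eta = 0.5, seed = 11)
  f2 <- sample_smi_posterior(arch, default_truth(), cfg, eta = 0.5, seed = 222)
  se <- sqrt(var(f1$draws$gamma) / 300 + var(f2$draws$gamma) / 300)
  expect_lt(abs(mean(f1$draws$gamma) - mean(f2$draws$gamma)), 5 * se + 0.05)
})

test_that("bayes_factor follows posterior sign proportions", {
  expect_equal(bayes_factor(c(rep(-1, 500), rep(1, 500)))$bf, 1)
  expect_equal(bayes_factor(c(rep(-1, 840), rep(1, 160)))$bf, 5.25)
  b_neg <- bayes_factor(c(rep(-1, 200), rep(1, 1000)), "negative")
  b_pos <- bayes_factor(c(rep(-1, 200), rep(1, 1000)), "positive")
  expect_equal(b_neg$bf * b_pos$bf, 1)
  expect_equal(b_neg$bf, 0.2)
  expect_equal(b_pos$bf, 5)
  capped <- bayes_factor(rep(-2, 1500), "negative")
  expect_true(capped$capped)
  expect_equal(capped$bf, 1500)
  expect_warning(bayes_factor(rnorm(100)), "1000")
})

test_that("smi_fit accessors expose draws, summaries and plots", {
  arch <- fixture_arch(gamma = -0.5, n_per_site = 8, seed = 61, n_sites = 4)
  cfg <- fast_config(n_completed = 200)
  fit <- sample_smi_posterior(arch, default_truth(), cfg, eta = 0.3, seed = 5)
  expect_equal(fit$eta, 0.3)
  expect_equal(nrow(fit$draws), 200)
  expect_true(all(fit$draws$alpha1 < fit$draws$alpha2))
  expect_true(all(fit$draws$sigma_u > 0))
  rs <- rowSums(as.matrix(fit$level_probs[, 2:4]))
  expect_equal(rs, rep(1, fit$n), tolerance = 1e-9)
  td <- tidy(fit)
  expect_setequal(td$term, c("alpha1", "alpha2", "gamma", "tau", "sigma_u"))
  gl <- suppressWarnings(glance(fit))
  expect_equal(gl$eta, 0.3)
  expect_s3_class(autoplot(fit), "ggplot")
})
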