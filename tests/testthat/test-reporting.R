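fake_fit <- function(draws, u_draws = matrix(0, nrow(draws), 0)) {
  structure(
    list(draws = draws, u_draws = u_draws,
         scales = list(size_center = 0, size_scale = 1, date_center = 0,
                       date_scale = 1, size_transform = "identity"),
         seed = 1L, eta = 0, method = "cut", n = 10,
         config = manure_config()),
    class = "smi_fit"
  )
}

test_that("a null size effect gives flat curves at cutpoint probabilities", {
  draws <- tibble::tibble(chain = 1L, alpha1 = -1, alpha2 = 1, gamma = 0,
                          tau = 0, sigma_u = 0)[rep(1, 50), ]
  curves <- probability_curves(fake_fit(draws), size_grid = c(1, 10, 100))
  low <- curves[curves$level == "low", ]
  med <- curves[curves$level == "medium", ]
  expect_equal(low$median, rep(plogis(-1), 3))
  expect_equal(med$median, rep(plogis(1), 3))
})

test_that("a negative gamma gives curves rising with settlement size", {
  set.seed(2)
  draws <- tibble::tibble(chain = 1L, alpha1 = rnorm(200, -1, 0.1),
                          alpha2 = rnorm(200, 1, 0.1), gamma = -0.5,
                          tau = 0, sigma_u = 0)
  curves <- probability_curves(fake_fit(draws), size_grid = seq(1, 50, by = 7))
  for (lev in c("low", "medium")) {
    expect_true(all(diff(curves$median[curves$level == lev]) > 0))
  }
})

test_that("curve quantiles match empirical quantiles of per-draw probabilities", {
  set.seed(5)
  draws <- tibble::tibble(chain = 1L, alpha1 = rnorm(300, -1, 0.3),
                          alpha2 = rnorm(300, 1, 0.3),
                          gamma = rnorm(300, -0.4, 0.2), tau = 0, sigma_u = 0)
  x0 <- 12
  curves <- probability_curves(fake_fit(draws), size_grid = x0)
  p_draw <- plogis(draws$alpha1 - draws$gamma * x0)
  q <- quantile(p_draw, c(0.05, 0.25, 0.5, 0.75, 0.95))
  low <- curves[curves$level == "low", ]
  expect_equal(unname(unlist(low[, c("lo90", "lo50", "median", "hi50",
                                     "hi90")])),
               unname(q))
})

test_that("curves are monotone in m with nested bands on a fitted posterior", {
  arch <- fixture_arch(gamma = -0.5, n_per_site = 8, seed = 91, n_sites = 4)
  fit <- suppressWarnings(
    sample_cut_posterior(arch, default_truth(),
                         fast_config(n_completed = 200), seed = 7))
  curves <- probability_curves(fit, size_grid = c(0.5, 5, 50))
  low <- curves[curves$level == "low", ]
  med <- curves[curves$level == "medium", ]
  expect_true(all(low$median <= med$median))
  expect_true(all(curves$lo90 <= curves$lo50 & curves$lo50 <= curves$median &
                    curves$median <= curves$hi50 & curves$hi50 <= curves$hi90))
  expect_true(all(curves$lo90 >= 0 & curves$hi90 <= 1))
  expect_s3_class(autoplot(curves), "ggplot")
  # per-site conditioning uses that site's intercept draws
  ps <- probability_curves(fit, size_grid = 5, site_mode = "site",
                           site = colnames(fit$u_draws)[1])
  expect_equal(nrow(ps), 2)
  expect_error(probability_curves(fit, 5, site_mode = "site",
                                  site = "nowhere"), "Unknown site")
})

test_that("summary report is complete, deterministic and reciprocal", {
  arch <- fixture_arch(gamma = -0.5, n_per_site = 8, seed = 95, n_sites = 4)
  cfg <- fast_config(n_completed = 200)
  cut <- sample_cut_posterior(arch, default_truth(), cfg, seed = 3)
  wald <- fit_po_si(arch, default_truth(), cfg)
  curve <- suppressWarnings(
    elpd_curve(arch, default_truth(), cfg, eta_grid = c(0, 1), seed = 13,
               fallback = "none"))

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  # bayes_factor warns at this intentionally small draw count
  p1 <- suppressWarnings(
    summary_report(d1, wald = wald, fits = list(cut = cut), curve = curve))
  p2 <- suppressWarnings(
    summary_report(d2, wald = wald, fits = list(cut = cut), curve = curve))
  expect_setequal(names(p1), c("wald", "bayes_factors", "posteriors",
                               "diagnostics", "elpd_curve", "eta_star"))
  for (nm in names(p1)) {
    expect_identical(readLines(p1[[nm]]), readLines(p2[[nm]]))
  }

  bf_tab <- readr::read_csv(p1[["bayes_factors"]], show_col_types = FALSE)
  expect_true(all(c("bf_negative", "bf_positive", "n_draws") %in%
                    names(bf_tab)))
  expect_equal(bf_tab$bf_negative * bf_tab$bf_positive, 1)

  expect_error(summary_report(withr::local_tempdir()), "at least one")
})
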