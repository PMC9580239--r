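test_that("cumulative probabilities follow the inverse-logit link", {
  expect_equal(po_cumulative_prob(po_params(c(0, 1), gamma = 0),
                                  x_size = 0, m = "low"), 0.5)
  p <- po_params(c(-1, 1), gamma = 1)
  # linear predictor 0.5
  expect_equal(po_cumulative_prob(p, 0.5, m = "low"), plogis(-1.5))
  expect_equal(po_cumulative_prob(p, 0.5, m = "medium"), plogis(0.5))
  expect_equal(po_cumulative_prob(p, 0.5, m = "high"), 1)
  # category probabilities sum to one
  probs <- c(plogis(-1.5), plogis(0.5) - plogis(-1.5), 1 - plogis(0.5))
  expect_equal(sum(probs), 1)
})

test_that("negative gamma makes P(<= m) increase with settlement size", {
  p <- po_params(c(-1, 1), gamma = -0.5)
  x <- seq(-2, 2, by = 0.25)
  for (m in c("low", "medium")) {
    expect_true(all(diff(po_cumulative_prob(p, x, m = m)) > 0))
  }
})

test_that("category probabilities sum to one at machine precision", {
  set.seed(3)
  for (i in 1:50) {
    a1 <- rnorm(1, 0, 3)
    alpha <- c(a1, a1 + rexp(1))
    eta <- rnorm(11, 0, 4)
    lp <- isomanure:::po_category_logprob(alpha, eta)
    expect_equal(rowSums(exp(lp)), rep(1, 11), tolerance = 1e-12)
  }
})

test_that("marginal and site-conditional cumulative probabilities agree", {
  p <- po_params(c(-1, 1), gamma = -0.5, u = c(a = 0.7), sigma_u = 0.6)
  expect_equal(po_cumulative_prob(p, 0.3, site = "a", m = "low"),
               plogis(-1 + 0.15 - 0.7))
  expect_error(po_cumulative_prob(p, 0.3, site = "b", m = "low",
                                  marginal = FALSE), "Unknown site")
  # marginal value integrates the random effect: bracketed by extreme sites
  pm <- po_cumulative_prob(p, 0.3, m = "low", marginal = TRUE)
  expect_gt(pm, plogis(-1 + 0.15 - 2))
  expect_lt(pm, plogis(-1 + 0.15 + 2))
})

test_that("po_loglik matches hand-summed category log probabilities", {
  p <- po_params(c(qlogis(1 / 3), qlogis(2 / 3)), gamma = 0)
  one <- tibble::tibble(level = 2L, x_size = 0, x_date = 0, site = "a")
  expect_equal(po_loglik(p, one), log(1 / 3), tolerance = 1e-12)

  p2 <- po_params(c(-0.8, 0.9), gamma = -0.4, tau = 0.2,
                  u = c(a = 0.3, b = -0.3), sigma_u = 0.5)
  toy <- tibble::tibble(level = c(1L, 2L, 3L), x_size = c(-1, 0, 2),
                        x_date = c(0.5, -1, 0), site = c("a", "b", "a"))
  hand <- 0
  for (i in 1:3) {
    eta <- -0.4 * toy$x_size[i] + 0.2 * toy$x_date[i] + p2$u[toy$site[i]]
    cum <- plogis(c(-0.8, 0.9) - eta)
    cat_p <- c(cum[1], cum[2] - cum[1], 1 - cum[2])
    hand <- hand + log(cat_p[toy$level[i]])
  }
  expect_equal(po_loglik(p2, toy), unname(hand), tolerance = 1e-12)

  # additivity: duplicating an observation doubles its contribution
  dup <- dplyr::bind_rows(toy, toy[2, ])
  expect_equal(po_loglik(p2, dup),
               po_loglik(p2, toy) + po_loglik(p2, toy[2, ]), tolerance = 1e-12)
})

test_that("likelihood is invariant under site relabelling", {
  p <- po_params(c(-1, 1), gamma = -0.3, u = c(a = 0.4, b = -0.2),
                 sigma_u = 0.5)
  toy <- tibble::tibble(level = c(1L, 3L, 2L, 2L), x_size = c(-1, 0, 1, 2),
                        x_date = 0, site = c("a", "b", "a", "b"))
  relabel <- c(a = "z9", b = "k2")
  p_re <- p
  names(p_re$u) <- relabel[names(p$u)]
  toy_re <- dplyr::mutate(toy, site = relabel[site])
  expect_equal(po_loglik(p, toy), po_loglik(p_re, toy_re))
})

test_that("intercept-only fit returns the closed-form cutpoints", {
  counts <- c(25, 50, 25)
  data <- tibble::tibble(
    level = rep(1:3, counts), site = "only",
    size_ha = 1, date_calBC = 1000
  )
  cfg <- manure_config(include_date = FALSE, random_effects = FALSE)
  fit <- fit_po_wald(data, config = cfg, include_size = FALSE)
  est <- setNames(fit$coefficients$estimate, fit$coefficients$term)
  expect_equal(unname(est["alpha1"]), qlogis(0.25), tolerance = 1e-4)
  expect_equal(unname(est["alpha2"]), qlogis(0.75), tolerance = 1e-4)
})

test_that("fixed-effects fit matches the MASS::polr oracle", {
  arch <- fixture_arch(gamma = -0.7, n_per_site = 25, seed = 11, sigma_u = 0)
  truth <- attr(arch, "truth")
  cfg <- manure_config(random_effects = FALSE)
  fit <- fit_po_wald(arch, levels = truth$level, config = cfg)

  des <- isomanure:::build_design(arch, cfg)
  oracle <- MASS::polr(factor(truth$level, ordered = TRUE) ~ x_size + x_date,
                       data = tibble::tibble(x_size = des$x_size,
                                             x_date = des$x_date),
                       Hess = TRUE)
  est <- setNames(fit$coefficients$estimate, fit$coefficients$term)
  se <- setNames(fit$coefficients$std.error, fit$coefficients$term)
  expect_equal(unname(est["gamma"]), unname(coef(oracle)["x_size"]),
               tolerance = 1e-3)
  expect_equal(unname(est["tau"]), unname(coef(oracle)["x_date"]),
               tolerance = 1e-3)
  expect_equal(unname(est[c("alpha1", "alpha2")]), unname(oracle$zeta),
               tolerance = 1e-3)
  o_se <- sqrt(diag(stats::vcov(oracle)))
  expect_equal(unname(se["gamma"]), unname(o_se["x_size"]), tolerance = 0.02)
})

test_that("the mixed likelihood approaches the fixed-effects one as sigma_u -> 0", {
  arch <- fixture_arch(gamma = -0.5, n_per_site = 8, seed = 3)
  truth <- attr(arch, "truth")
  cfg_re <- manure_config()
  cfg_fe <- manure_config(random_effects = FALSE)
  fit_fe <- fit_po_wald(arch, levels = truth$level, config = cfg_fe)
  # evaluate the mixed marginal likelihood near sigma_u = 0 at the FE optimum
  # via the internal objective by refitting with RE and comparing logLik
  fit_re <- fit_po_wald(arch, levels = truth$level, config = cfg_re)
  expect_gte(fit_re$logLik, fit_fe$logLik - 1e-4)
  # with few sites and weak clustering the two fits should largely agree
  g_re <- fit_re$coefficients$estimate[fit_re$coefficients$term == "gamma"]
  g_fe <- fit_fe$coefficients$estimate[fit_fe$coefficients$term == "gamma"]
  expect_equal(g_re, g_fe, tolerance = 0.35)
})

test_that("Wald intervals cover a known settlement-size effect", {
  # gamma is identified across sites, so interval calibration needs a
  # reasonably site-rich design
  cfg <- manure_config()
  hits <- 0L
  n_rep <- 20L
  for (r in seq_len(n_rep)) {
    arch <- fixture_arch(gamma = -0.5, n_per_site = 40, seed = 3000 + r,
                         sigma_u = 0.5, n_sites = 50)
    truth <- attr(arch, "truth")
    fit <- fit_po_wald(arch, levels = truth$level, config = cfg)
    co <- fit$coefficients
    g <- co$estimate[co$term == "gamma"]
    s <- co$std.error[co$term == "gamma"]
    hits <- hits + (g - 1.96 * s <= -0.5 && -0.5 <= g + 1.96 * s)
  }
  expect_gte(hits, round(0.9 * n_rep))
})

test_that("single-imputation pipeline reports a one-sided Wald test", {
  arch <- fixture_arch(gamma = -1, n_per_site = 20, seed = 21)
  fit <- fit_po_si(arch, default_truth(), manure_config())
  expect_s3_class(fit, "po_wald")
  expect_true(!is.na(fit$p_one_sided))
  expect_true(fit$p_one_sided >= 0 && fit$p_one_sided <= 1)
  expect_s3_class(attr(fit, "levels"), "ordered")
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "std.error", "z") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$n, nrow(arch))
})

test_that("degenerate level data are rejected", {
  arch <- fixture_arch(n_per_site = 4, seed = 2)
  expect_error(fit_po_wald(arch, levels = rep(2L, nrow(arch))),
               "distinct")
})
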