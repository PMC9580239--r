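make_arch_row <- function(d15n, rain_min, rain_max = rain_min, id = "s1") {
  tibble::tibble(
    sample_id = id, region = "r", site = "a", phase = "p",
    date_calBC = 3000, size_ha = 10, d15n = d15n,
    rain_min_mm = rain_min, rain_max_mm = rain_max, taxon = NA_character_
  )
}

test_that("charring correction is a subtraction and round-trips", {
  expect_equal(charring_correct(6.0, 0), 6.0)
  expect_equal(charring_correct(6.0, 0.3), 5.7)
  expect_equal(charring_correct(charring_correct(6.0, 0.31), -0.31), 6.0)
  expect_error(charring_correct(Inf, 0), "finite")
})

test_that("near-zero measurement noise pins the level", {
  cp <- calibration_params(2, 5, 8, lambda = -1.5, sigma = 0.01)
  arch <- make_arch_row(predict_d15n(cp, "medium", 500), 500)
  post <- impute_levels(arch, cp)
  expect_gt(post$p_med, 0.999)
  expect_prob_vector(unlist(post[, c("p_low", "p_med", "p_high")]))
})

test_that("a value midway between two close lines splits evenly", {
  # low and medium 1 sigma apart at the observed value; high >= 10 sigma away
  cp <- calibration_params(2, 3, 40, lambda = 0, sigma = 1)
  arch <- make_arch_row(2.5, 500)
  post <- impute_levels(arch, cp)
  expect_equal(post$p_low, 0.5, tolerance = 1e-6)
  expect_equal(post$p_med, 0.5, tolerance = 1e-6)
  expect_lt(post$p_high, 1e-6)
})

test_that("probabilities match a dense numerical integration oracle", {
  cp <- calibration_params(2, 5, 8, lambda = -1.5, sigma = 1)
  d15n_values <- c(-3.5, -2.2, -1.0, 0.4, 1.5)
  arch <- purrr::map_dfr(seq_along(d15n_values), function(i) {
    make_arch_row(d15n_values[i], 400, 600, id = paste0("s", i))
  })
  post <- impute_levels(arch, cp, manure_config(rain_grid = 64))
  # independent oracle: adaptive quadrature over the uniform rainfall prior
  oracle <- t(vapply(d15n_values, function(y) {
    dens <- vapply(1:3, function(m) {
      stats::integrate(function(r) {
        dnorm(y, cp$beta[m] - 1.5 * log(r), cp$sigma) / 200
      }, 400, 600, rel.tol = 1e-10)$value
    }, numeric(1))
    dens / sum(dens)
  }, numeric(3)))
  expect_equal(post$p_low, oracle[, 1], tolerance = 5e-4)
  expect_equal(post$p_med, oracle[, 2], tolerance = 5e-4)
  expect_equal(post$p_high, oracle[, 3], tolerance = 5e-4)
})

test_that("map assignment takes the argmax with ties toward lower levels", {
  expect_equal(as.character(map_assign(
    tibble::tibble(p_low = 0.2, p_med = 0.7, p_high = 0.1))), "medium")
  expect_equal(as.character(map_assign(
    tibble::tibble(p_low = 0.5, p_med = 0.5, p_high = 0))), "low")
  expect_equal(as.character(map_assign(
    tibble::tibble(p_low = 0, p_med = 0.5, p_high = 0.5))), "medium")
  expect_error(map_assign(tibble::tibble(p_low = 0.9, p_med = 0.9,
                                         p_high = 0.1)), "sum to 1")

  cp <- calibration_params(2, 5, 8, lambda = -1.5, sigma = 1)
  arch <- purrr::map_dfr(1:7, function(i) {
    make_arch_row(-4 + i, 400, 600, id = paste0("s", i))
  })
  post <- impute_levels(arch, cp)
  P <- as.matrix(post[, c("p_low", "p_med", "p_high")])
  expect_equal(as.integer(map_assign(post)), apply(P, 1, which.max))
})

test_that("raising d15n never decreases the high-level probability", {
  cp <- calibration_params(2, 5, 8, lambda = -1.5, sigma = 1)
  for (rng in list(c(500, 500), c(350, 700))) {
    arch <- purrr::map_dfr(1:30, function(i) {
      make_arch_row(-8 + 0.5 * i, rng[1], rng[2], id = paste0("s", i))
    })
    post <- impute_levels(arch, cp)
    expect_true(all(diff(post$p_high) >= -1e-9))
  }
})

test_that("widening the rainfall range does not sharpen levels on average", {
  cp <- calibration_params(2, 5, 8, lambda = -1.5, sigma = 1)
  entropy <- function(P) -rowSums(ifelse(P > 0, P * log(P), 0))
  set.seed(7)
  y <- runif(60, -4, 2)
  narrow <- purrr::map_dfr(seq_along(y), function(i) {
    make_arch_row(y[i], 480, 520, id = paste0("s", i))
  })
  wide <- purrr::map_dfr(seq_along(y), function(i) {
    make_arch_row(y[i], 300, 800, id = paste0("s", i))
  })
  e_narrow <- entropy(as.matrix(impute_levels(narrow, cp)[, 2:4]))
  e_wide <- entropy(as.matrix(impute_levels(wide, cp)[, 2:4]))
  expect_gte(mean(e_wide), mean(e_narrow))
})

test_that("imputation integrates calibration uncertainty in draws mode", {
  mod <- generate_modern(default_truth(), 30, seed = 8)
  fit <- suppressWarnings(
    fit_calibration(mod, manure_config(warmup = 300, draws = 500)))
  arch <- make_arch_row(0.2, 400, 600)
  p_draws <- impute_levels(arch, fit, manure_config(calib_mode = "draws"))
  p_plug <- impute_levels(arch, fit, manure_config(calib_mode = "plugin"))
  expect_prob_vector(unlist(p_draws[, 2:4]))
  expect_prob_vector(unlist(p_plug[, 2:4]))
  # both modes agree on the dominant level for a clear-cut value
  expect_equal(as.character(map_assign(p_draws)),
               as.character(map_assign(p_plug)))
})
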