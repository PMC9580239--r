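test_that("generators are deterministic under a fixed seed", {
  a <- generate_modern(default_truth(), 10, seed = 33)
  b <- generate_modern(default_truth(), 10, seed = 33)
  expect_identical(a, b)
  expect_false(identical(a, generate_modern(default_truth(), 10, seed = 34)))

  sp <- scenario_spec(fixture_sites(), seed = 12)
  x <- generate_arch(sp)
  y <- generate_arch(sp)
  expect_identical(x, y)
})

test_that("zero measurement noise puts every point on its level line", {
  truth <- calibration_params(2, 5, 8, lambda = -1.5, sigma = 1e-12)
  mod <- generate_modern(truth, 20, seed = 6)
  lev <- as.integer(mod$level)
  expect_equal(mod$d15n,
               unname(truth$beta[lev]) - 1.5 * log(mod$rainfall_mm),
               tolerance = 1e-9)
})

test_that("null-model level frequencies match the cutpoint probabilities", {
  sites <- fixture_sites(5)
  sp <- scenario_spec(sites, gamma = 0, tau = 0, sigma_u = 0,
                      cutpoints = c(-1, 1), n_per_site = 1000, seed = 19)
  arch <- generate_arch(sp)
  lev <- attr(arch, "truth")$level
  n <- length(lev)
  p_expect <- c(plogis(-1), plogis(1) - plogis(-1), 1 - plogis(1))
  freq <- tabulate(lev, 3) / n
  # three-sigma binomial tolerance at n = 5000
  tol <- 3 * sqrt(p_expect * (1 - p_expect) / n)
  expect_true(all(abs(freq - p_expect) < tol))
})

test_that("a strong negative gamma couples level to settlement size", {
  sp <- scenario_spec(fixture_sites(8), gamma = -2, sigma_u = 0,
                      n_per_site = 250, seed = 23)
  arch <- generate_arch(sp)
  lev <- attr(arch, "truth")$level
  prop_low <- tapply(lev == 1, arch$site, mean)
  sizes <- tapply(arch$size_ha, arch$site, unique)
  expect_gt(cor(rank(sizes), rank(prop_low)), 0)
  # and d15n itself declines with size
  expect_lt(cor(log(arch$size_ha), arch$d15n), 0)
})

test_that("generated archaeological tables satisfy the schema invariants", {
  arch <- fixture_arch(n_per_site = 5, seed = 77)
  expect_true(all(arch$size_ha > 0))
  expect_true(all(arch$rain_min_mm <= arch$rain_max_mm))
  expect_false(any(duplicated(arch$sample_id)))
  truth <- attr(arch, "truth")
  expect_true(all(truth$level %in% 1:3))
  expect_true(all(truth$rainfall_mm >= arch$rain_min_mm &
                    truth$rainfall_mm <= arch$rain_max_mm))
  # write/read round trip preserves the table
  path <- withr::local_tempfile(fileext = ".csv")
  write_arch_table(arch, path)
  expect_equal(read_arch_table(path)$d15n, arch$d15n)
})

test_that("the triangular rainfall emitter stays in range and peaks centrally", {
  sp <- scenario_spec(fixture_sites(2), n_per_site = 2000, seed = 5,
                      rainfall_emitter = "triangular")
  r <- attr(generate_arch(sp), "truth")$rainfall_mm
  expect_true(all(r >= 400 & r <= 600))
  # central third holds more mass than either outer third under the triangle
  expect_gt(mean(r > 466 & r < 533), mean(r <= 466) * 0.8)
})

test_that("regional presets carry the published site covariates", {
  nm <- preset_table1("nmeso")
  brak <- nm[nm$site == "Tell Brak" & nm$phase == "Late Chalcolithic 3-4", ]
  expect_equal(brak$size_ha, 130)
  expect_equal(brak$present_rain_mm, 363)

  ae <- preset_table1("aegean")
  knossos_lba <- ae[ae$site == "Knossos" & ae$phase == "Late Bronze Age", ]
  expect_equal(knossos_lba$size_ha, 60)
  expect_equal(knossos_lba$date_calBC, (1490 + 1430) / 2)

  sg <- preset_table1("swgermany")
  expect_equal(sg$size_ha[sg$site == "Heuneburg"], 100)
  horn <- sg[sg$site == "Hornstaad-Hoernle IA", ]
  expect_equal(horn$size_ha, 0.21)
  expect_equal(horn$present_rain_mm, 740)

  expect_error(preset_table1("atlantis"), "arg")
  # presets feed the generator directly
  arch <- generate_arch(scenario_spec(preset_table1("aegean"),
                                      n_per_site = 3, seed = 1))
  expect_equal(nrow(arch), 3 * nrow(ae))
})
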