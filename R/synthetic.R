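#' Generate a modern calibration table
#'
#' Simulates the modern compilation the calibration model is fitted to: for
#' each manuring level, rainfall is drawn log-uniformly over `rainfall_range`
#' and d15N from `beta_level + lambda * log(rainfall) + Normal(0, sigma)`.
#'
#' @param params Generator truth, a [calibration_params()].
#' @param n_per_level Samples per manuring level (>= 1).
#' @param rainfall_range Length-2 positive range, mm/yr.
#' @param seed Integer seed; identical seeds give identical tables.
#' @return A tibble with columns `d15n`, `rainfall_mm`, `level`, compatible
#'   with [read_modern_table()] / [write_modern_table()].
#' @examples
#' generate_modern(calibration_params(2, 5, 8, -1.5, 1), 5, seed = 1)
#' @export
generate_modern <- function(params, n_per_level,
                            rainfall_range = c(200, 1200), seed = 1L) {
  stopifnot(inherits(params, "calibration_params"))
  if (n_per_level < 1) abort("`n_per_level` must be >= 1.")
  if (length(rainfall_range) != 2 || any(rainfall_range <= 0) ||
      rainfall_range[1] > rainfall_range[2]) {
    abort("`rainfall_range` must be a positive increasing pair.")
  }
  withr::with_seed(seed, {
    lev <- rep(1:3, each = n_per_level)
    r <- exp(runif(length(lev), log(rainfall_range[1]),
                   log(rainfall_range[2])))
    lam <- if (length(params$lambda) == 3) params$lambda[lev] else
      params$lambda
    d15n <- unname(params$beta[lev] + lam * log(r)) +
      rnorm(length(lev), 0, params$sigma)
    tibble::tibble(
      d15n = d15n, rainfall_mm = r,
      level = factor(.levels[lev], .levels, ordered = TRUE)
    )
  })
}

#' Scenario specification for archaeological data generation
#'
#' Describes the study conditions a synthetic archaeological dataset is
#' drawn under: a site layout (covariates), the calibration measurement
#' truth, and the ordinal-model truth (cutpoints, size effect gamma, date
#' effect tau, site random-intercept scale).
#'
#' @param sites A tibble with columns `site`, `region`, `size_ha`,
#'   `date_calBC`, `rain_min_mm`, `rain_max_mm` (one row per site/phase);
#'   e.g. from [preset_table1()].
#' @param calib Measurement truth, a [calibration_params()]; the default
#'   (intercepts 2/5/8 permil, slope -1.5, sigma 1) spans a realistic
#'   2-12 permil range of charred-grain d15N values.
#' @param gamma,tau True settlement-size and date effects on the
#'   standardised covariates.
#' @param sigma_u True site random-intercept scale.
#' @param cutpoints True cutpoints (increasing pair).
#' @param n_per_site Samples per site row (recycled).
#' @param seed Integer seed recorded in the output.
#' @param rainfall_emitter `"uniform"` draws true rainfall uniformly over
#'   each site's range (matching the imputation prior); `"triangular"`
#'   (peak at the range midpoint) deliberately mismatches the prior, the
#'   model-error regime semi-modular inference is designed for.
#' @param size_transform,standardize Covariate handling used to convert
#'   `gamma`/`tau` into per-sample linear predictors; keep identical to the
#'   analysis [manure_config()] so generator truth and estimates share a
#'   scale.
#' @return A list with class `"scenario_spec"`.
#' @export
scenario_spec <- function(sites,
                          calib = calibration_params(2, 5, 8, -1.5, 1),
                          gamma = -0.5, tau = 0, sigma_u = 0.5,
                          cutpoints = c(-1, 1), n_per_site = 10L,
                          seed = 1L,
                          rainfall_emitter = c("uniform", "triangular"),
                          size_transform = c("identity", "log"),
                          standardize = TRUE) {
  rainfall_emitter <- match.arg(rainfall_emitter)
  size_transform <- match.arg(size_transform)
  need <- c("site", "region", "size_ha", "date_calBC",
            "rain_min_mm", "rain_max_mm")
  missing <- setdiff(need, names(sites))
  if (length(missing) > 0) {
    abort(paste0("`sites` is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (any(sites$size_ha <= 0)) abort("Site sizes must be > 0.")
  if (any(sites$rain_min_mm <= 0 | sites$rain_max_mm < sites$rain_min_mm)) {
    abort("Rainfall ranges must be positive with min <= max.")
  }
  if (!(cutpoints[1] < cutpoints[2])) abort("Cutpoints must increase.")
  structure(
    list(sites = tibble::as_tibble(sites), calib = calib, gamma = gamma,
         tau = tau, sigma_u = sigma_u, cutpoints = as.numeric(cutpoints),
         n_per_site = as.integer(n_per_site), seed = as.integer(seed),
         rainfall_emitter = rainfall_emitter,
         size_transform = size_transform, standardize = standardize),
    class = "scenario_spec"
  )
}

#' Generate an archaeological dataset from a scenario
#'
#' Draws a site random intercept per site, a manuring level per sample from
#' the proportional-odds model given the (transformed, standardised) size
#' and date covariates, a true rainfall within the site's range, and a d15N
#' value from the calibration measurement model. The latent truth needed
#' for recovery tests (levels, rainfall, random intercepts, covariate
#' scales) is attached as attribute `"truth"`.
#'
#' @param spec A [scenario_spec()].
#' @return A tibble with the [read_arch_table()] columns; `attr(, "truth")`
#'   holds `level` (integer), `rainfall_mm`, `u` (named), the generator
#'   parameters and the covariate `scales`.
#' @export
generate_arch <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  sites <- spec$sites
  reps <- rep_len(spec$n_per_site, nrow(sites))
  df <- sites[rep(seq_len(nrow(sites)), reps), ]
  n <- nrow(df)
  df$sample_id <- sprintf("s%04d", seq_len(n))
  if (!("phase" %in% names(df))) df$phase <- as.character(df$date_calBC)
  if (!("taxon" %in% names(df))) df$taxon <- "Hordeum/Triticum (synthetic)"

  cfg <- manure_config(size_transform = spec$size_transform,
                       standardize = spec$standardize)
  des <- build_design(df, cfg)

  withr::with_seed(spec$seed, {
    u <- rnorm(des$n_sites, 0, spec$sigma_u)
    names(u) <- des$site_levels
    eta <- spec$gamma * des$x_size + spec$tau * des$x_date +
      u[des$site_idx]
    cum <- plogis(outer(spec$cutpoints, eta, "-"))  # 2 x n
    pr <- rbind(cum[1, ], cum[2, ] - cum[1, ], 1 - cum[2, ])
    v <- runif(n)
    lev <- 1L + (v > cum[1, ]) + (v > cum[2, ])
    r <- switch(spec$rainfall_emitter,
      uniform = runif(n, df$rain_min_mm, df$rain_max_mm),
      triangular = {
        a <- df$rain_min_mm; b <- df$rain_max_mm
        w <- runif(n); wid <- b - a
        ifelse(w < 0.5, a + wid * sqrt(w / 2), b - wid * sqrt((1 - w) / 2))
      })
    lam <- if (length(spec$calib$lambda) == 3) spec$calib$lambda[lev] else
      spec$calib$lambda
    d15n <- unname(spec$calib$beta[lev] + lam * log(r)) +
      rnorm(n, 0, spec$calib$sigma)

    out <- tibble::tibble(
      sample_id = df$sample_id, region = df$region, site = df$site,
      phase = as.character(df$phase), date_calBC = df$date_calBC,
      size_ha = df$size_ha, d15n = d15n,
      rain_min_mm = df$rain_min_mm, rain_max_mm = df$rain_max_mm,
      taxon = df$taxon
    )
    attr(out, "truth") <- list(
      level = lev, rainfall_mm = r, u = u,
      gamma = spec$gamma, tau = spec$tau, sigma_u = spec$sigma_u,
      cutpoints = spec$cutpoints, calib = spec$calib,
      scales = des$scales, seed = spec$seed,
      level_probs = t(pr)
    )
    out
  })
}

#' Site layouts from the published regional site tables
#'
#' Returns a site/phase covariate skeleton for one of the three study
#' regions, with settlement sizes (ha), date midpoints (cal BC) and
#' present-day annual rainfall (mm) copied from the published site table.
#' Past-rainfall ranges are a synthetic convention (+/-20% of present-day
#' rainfall) since the published per-phase ranges live in supplementary
#' data; generator truth (effects, calibration) is left to the caller via
#' [scenario_spec()].
#'
#' @param region `"nmeso"` (northern Mesopotamia), `"aegean"`, or
#'   `"swgermany"` (south-west Germany).
#' @return A tibble with columns `site`, `region`, `phase`, `date_calBC`,
#'   `size_ha`, `present_rain_mm`, `rain_min_mm`, `rain_max_mm`.
#' @examples
#' preset_table1("aegean")
#' @export
preset_table1 <- function(region = c("nmeso", "aegean", "swgermany")) {
  region <- match.arg(region)
  t1 <- table1_sites[table1_sites$region == region, ]
  tibble::tibble(
    site = t1$site, region = t1$region, phase = t1$phase,
    date_calBC = (t1$date_from + t1$date_to) / 2,
    size_ha = t1$size_ha,
    present_rain_mm = t1$present_rain_mm,
    rain_min_mm = 0.8 * t1$present_rain_mm,
    rain_max_mm = 1.2 * t1$present_rain_mm
  )
}

# Published regional site table: site, phase, date range (cal BC, from older
# to younger), settlement size (ha) and present-day annual rainfall (mm).
table1_sites <- local({
  row <- function(region, site, rain, phase, from, to, size) {
    data.frame(region = region, site = site, present_rain_mm = rain,
               phase = phase, date_from = from, date_to = to,
               size_ha = size, stringsAsFactors = FALSE)
  }
  rbind(
    row("nmeso", "Tell Sabi Abyad", 280, "Early Pottery Neolithic-Halaf", 6700, 5850, 1),
    row("nmeso", "Tell Zeidan", 182, "Ubaid-Late Chalcolithic 2", 5300, 3850, 12),
    row("nmeso", "Tell Brak", 363, "Late Chalcolithic 2", 4200, 3900, 55),
    row("nmeso", "Tell Brak", 363, "Late Chalcolithic 3-4", 3900, 3600, 130),
    row("nmeso", "Tell Brak", 363, "Late Chalcolithic 4-5", 3600, 3000, 45),
    row("nmeso", "Tell Brak", 363, "Early Jezireh 0", 3000, 2900, 45),
    row("nmeso", "Tell Brak", 363, "Early Jezireh III-IV", 2500, 2100, 70),
    row("nmeso", "Tell Brak", 363, "Early Jezireh V", 2100, 2000, 45),
    row("nmeso", "Hamoukar", 445, "Late Chalcolithic", 3800, 3500, 15),
    row("nmeso", "Tell Leilan", 446, "Early Jezireh II (Leilan IIId)", 2700, 2600, 90),
    row("nmeso", "Tell Leilan", 446, "Early Jezireh III (Leilan IIa)", 2600, 2300, 90),
    row("nmeso", "Tell Leilan", 446, "Early Jezireh IV (Leilan IIb)", 2300, 2230, 90),
    row("nmeso", "Tell Leilan", 446, "Early Jezireh V (Leilan IIc)", 2230, 2200, 0.1),
    row("aegean", "Knossos", 589, "Early Neolithic", 7000, 6450, 0.3),
    row("aegean", "Knossos", 589, "Late Neolithic", 5500, 4500, 3.125),
    row("aegean", "Knossos", 589, "Final Neolithic", 4500, 3500, 3.125),
    row("aegean", "Knossos", 589, "Late Bronze Age", 1490, 1430, 60),
    row("aegean", "Halai", 561, "Middle-Late Neolithic", 5900, 4850, 0.7),
    row("aegean", "Kouphovouno", 718, "Middle Neolithic", 5800, 5500, 4),
    row("aegean", "Kouphovouno", 718, "Late Neolithic", 5500, 5000, 4),
    row("aegean", "Makriyalos", 443, "Late Neolithic", 5500, 4950, 28),
    row("aegean", "Thessaloniki Toumba", 453, "Middle Bronze Age", 2100, 1650, 0.5),
    row("aegean", "Thessaloniki Toumba", 453, "Late Bronze Age", 1375, 1050, 0.285),
    row("aegean", "Kynos", 579, "Late Bronze Age", 1200, 1050, 3),
    row("swgermany", "Vaihingen an der Enz", 687, "Early Neolithic", 5500, 5070, 6),
    row("swgermany", "Hornstaad-Hoernle IA", 740, "Late Neolithic", 3918, 3902, 0.21),
    row("swgermany", "Sipplingen Osthafen", 893, "Late Neolithic", 4000, 2800, 1.5),
    row("swgermany", "Stuttgart-Muehlhausen Viesenhaeuser Hof", 684, "Early-Middle Neolithic", 5500, 4000, 8),
    row("swgermany", "Eberdingen-Hochdorf Reps", 740, "Early Iron Age (La Tene A)", 450, 400, 15),
    row("swgermany", "Kirchheim-Osterholz Ipf-Zaunaecker", 809, "Early Iron Age (Halstatt D2-3/La Tene A)", 600, 400, 1.1),
    row("swgermany", "Heuneburg", 758, "Early Iron Age (Halstatt D1-D3)", 600, 450, 100)
  )
})
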