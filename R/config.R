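#' Run configuration for the manuring-inference pipeline
#'
#' Collects every tunable knob shared by the calibration, imputation,
#' ordinal-regression and semi-modular inference stages. All model-fitting
#' functions accept a `manure_config` object (or use the defaults).
#'
#' @param eta_grid Numeric vector of influence-parameter values in `[0, 1]`
#'   over which [elpd_curve()] profiles predictive performance. Values must
#'   be unique.
#' @param chains Number of MCMC chains (>= 2 so split-Rhat is meaningful).
#' @param warmup,draws Warmup iterations discarded and post-warmup draws kept
#'   per chain in stage-one samplers.
#' @param seed Integer seed; every stochastic function derives its stream
#'   from this unless given an explicit `seed` argument.
#' @param charring_offset Additive charring correction in permil subtracted
#'   from raw archaeological d15N values. Default 0: inputs are assumed
#'   already charring-corrected.
#' @param size_transform `"identity"` (hectares as-is) or `"log"`
#'   (natural log hectares) applied to settlement size before
#'   standardisation.
#' @param standardize Centre and scale the (transformed) size and date
#'   covariates before fitting. Coefficient priors below are calibrated for
#'   standardised covariates.
#' @param rainfall_prior Prior for unknown past rainfall within a sample's
#'   `[rain_min_mm, rain_max_mm]` range; only `"uniform_range"` is
#'   implemented.
#' @param rain_grid Number of midpoint-rule nodes used to integrate the
#'   rainfall prior.
#' @param calib_mode `"draws"` integrates imputation over the calibration
#'   posterior; `"plugin"` conditions on posterior means.
#' @param include_date Include the (standardised) date covariate tau in the
#'   ordinal model.
#' @param random_effects Include site-level random intercepts.
#' @param direction Direction of the one-sided hypothesis on the
#'   settlement-size effect gamma reported by [bayes_factor()].
#' @param per_level_slope Fit a separate rainfall slope per manuring level in
#'   the calibration model instead of a single common slope.
#' @param n_completed Number of completed (imputed) datasets carried into the
#'   analysis stage of the cut/SMI samplers; capped at the number of
#'   stage-one draws.
#' @param stage2_iter Metropolis sweeps per completed dataset in the
#'   analysis-stage chainlets (warm-started, last state kept).
#' @param loo_method `"psis"` (Pareto-smoothed importance sampling) or
#'   `"kfold"` for [elpd_curve()].
#' @param kfold_k Number of folds when `loo_method = "kfold"`.
#' @param priors Named list of prior hyperparameters:
#'   `beta_sd`, `lambda_sd`, `sigma_scale` (calibration intercepts, slope,
#'   half-normal residual scale), `alpha_sd`, `gap_scale` (first cutpoint and
#'   half-normal cutpoint gap), `coef_sd` (gamma and tau; symmetric about 0
#'   so posterior odds equal the one-sided Bayes factor), `sigma_u_scale`
#'   (half-normal random-effect scale).
#'
#' @return A list with class `"manure_config"`.
#' @examples
#' cfg <- manure_config(draws = 500, eta_grid = c(0, 0.5, 1))
#' cfg$eta_grid
#' @export
manure_config <- function(eta_grid = seq(0, 1, by = 0.1),
                          chains = 2L,
                          warmup = 500L,
                          draws = 1000L,
                          seed = 1L,
                          charring_offset = 0,
                          size_transform = c("identity", "log"),
                          standardize = TRUE,
                          rainfall_prior = "uniform_range",
                          rain_grid = 31L,
                          calib_mode = c("draws", "plugin"),
                          include_date = TRUE,
                          random_effects = TRUE,
                          direction = c("negative", "positive"),
                          per_level_slope = FALSE,
                          n_completed = 400L,
                          stage2_iter = 20L,
                          loo_method = c("psis", "kfold"),
                          kfold_k = 5L,
                          priors = list()) {
  size_transform <- match.arg(size_transform)
  calib_mode <- match.arg(calib_mode)
  direction <- match.arg(direction)
  loo_method <- match.arg(loo_method)
  rainfall_prior <- match.arg(rainfall_prior, "uniform_range")

  default_priors <- list(
    beta_sd = 10, lambda_sd = 10, sigma_scale = 5,
    alpha_sd = 5, gap_scale = 5, coef_sd = 2.5, sigma_u_scale = 1
  )
  unknown <- setdiff(names(priors), names(default_priors))
  if (length(unknown) > 0) {
    abort(paste0("Unknown prior hyperparameter(s): ",
                 paste(unknown, collapse = ", ")))
  }
  priors <- utils::modifyList(default_priors, priors)

  if (!is.numeric(eta_grid) || anyNA(eta_grid) ||
      any(eta_grid < 0 | eta_grid > 1)) {
    abort("`eta_grid` must be numeric values in [0, 1].")
  }
  if (anyDuplicated(eta_grid) > 0) abort("`eta_grid` values must be unique.")
  if (chains < 2) abort("`chains` must be >= 2.")
  if (draws < 1) abort("`draws` must be >= 1.")
  if (rain_grid < 1) abort("`rain_grid` must be >= 1.")

  structure(
    list(
      eta_grid = as.numeric(eta_grid),
      chains = as.integer(chains),
      warmup = as.integer(warmup),
      draws = as.integer(draws),
      seed = as.integer(seed),
      charring_offset = charring_offset,
      size_transform = size_transform,
      standardize = isTRUE(standardize),
      rainfall_prior = rainfall_prior,
      rain_grid = as.integer(rain_grid),
      calib_mode = calib_mode,
      include_date = isTRUE(include_date),
      random_effects = isTRUE(random_effects),
      direction = direction,
      per_level_slope = isTRUE(per_level_slope),
      n_completed = as.integer(n_completed),
      stage2_iter = as.integer(stage2_iter),
      loo_method = loo_method,
      kfold_k = as.integer(kfold_k),
      priors = priors
    ),
    class = "manure_config"
  )
}

#' @export
print.manure_config <- function(x, ...) {
  cat("<manure_config>\n")
  cat("  eta grid:", paste(format(x$eta_grid), collapse = " "), "\n")
  cat("  mcmc:", x$chains, "chains x (", x$warmup, "warmup +", x$draws,
      "draws ), seed", x$seed, "\n")
  cat("  size transform:", x$size_transform,
      if (x$standardize) "(standardised)" else "", "\n")
  cat("  calibration mode:", x$calib_mode,
      "| date:", x$include_date, "| site RE:", x$random_effects, "\n")
  invisible(x)
}

#' Read or write a run configuration as JSON
#'
#' @param path Path to a JSON file mirroring the arguments of
#'   [manure_config()].
#' @return `read_config()` returns a `manure_config`; `write_config()`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(manure_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    abort(paste0("Unknown configuration field(s): ",
                 paste(unknown, collapse = ", ")))
  }
  do.call(manure_config, raw)
}

#' @rdname read_config
#' @param config A `manure_config` object.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "manure_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

# resolve a derived seed for a sub-task, keeping within 32-bit range
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483629)
}
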