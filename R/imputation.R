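#' Charring correction for d15N values
#'
#' Charred (carbonised) grain is slightly enriched in 15N relative to the
#' fresh grain; published archaeological values are usually already
#' corrected, so the default offset is 0.
#'
#' @param d15n_raw Measured d15N, permil.
#' @param offset Charring offset, permil, subtracted from the raw value.
#' @return Corrected d15N. Vectorised.
#' @examples
#' charring_correct(6.0, 0.3)  # 5.7
#' @export
charring_correct <- function(d15n_raw, offset = 0) {
  if (!all(is.finite(d15n_raw)) || !all(is.finite(offset))) {
    abort("`d15n_raw` and `offset` must be finite.")
  }
  d15n_raw - offset
}

#' Per-sample, per-level measurement log densities
#'
#' For each archaeological sample i and manuring level m, computes
#' `L[i, m] = log p(d15n_i | level = m)` under the calibration measurement
#' model, integrating a uniform rainfall prior over the sample's
#' `[rain_min_mm, rain_max_mm]` range (midpoint rule, `config$rain_grid`
#' nodes) and, in `calib_mode = "draws"`, the calibration posterior
#' (Monte-Carlo average over draws). This matrix fully summarises the
#' imputation module's likelihood and is shared by [impute_levels()], the
#' cut/SMI samplers, and [elpd_curve()].
#'
#' @param arch Archaeological table ([read_arch_table()] / [generate_arch()]).
#' @param calib A [fit_calibration()] result or fixed [calibration_params()].
#' @param config A [manure_config()]; uses `charring_offset`, `rain_grid`,
#'   `calib_mode`.
#' @param max_calib_draws Calibration draws used for the Monte-Carlo
#'   integral (evenly thinned); bounds the cost on large posteriors.
#' @return An n x 3 matrix of log densities, columns `low`, `medium`,
#'   `high`, rows named by `sample_id`.
#' @export
level_loglik <- function(arch, calib, config = manure_config(),
                         max_calib_draws = 200L) {
  stopifnot(is.data.frame(arch))
  if (any(arch$rain_min_mm > arch$rain_max_mm)) {
    abort("Invalid rainfall range: rain_min_mm > rain_max_mm.")
  }
  y <- charring_correct(arch$d15n, config$charring_offset)
  n <- length(y)
  G <- config$rain_grid

  # rainfall grid per sample (midpoint rule; degenerate range -> single node)
  lo <- arch$rain_min_mm
  hi <- arch$rain_max_mm
  steps <- (seq_len(G) - 0.5) / G
  logR <- log(outer(lo, rep(1, G)) + outer(hi - lo, steps))

  params_list <- calib_draw_list(calib, config, max_calib_draws)

  acc <- matrix(0, n, 3)
  for (pp in params_list) {
    for (m in 1:3) {
      lam <- if (length(pp$lambda) == 3) pp$lambda[m] else pp$lambda
      mu <- pp$beta[m] + lam * logR
      acc[, m] <- acc[, m] + rowMeans(dnorm(y, mu, pp$sigma))
    }
  }
  L <- log(acc / length(params_list))
  if (any(!is.finite(L) & rowSums(is.finite(L)) == 0)) {
    bad <- which(rowSums(is.finite(L)) == 0)
    abort(paste0("Zero measurement likelihood for sample(s): ",
                 paste(arch$sample_id[bad], collapse = ", ")))
  }
  dimnames(L) <- list(arch$sample_id, .levels)
  L
}

#' Impute manuring-level probabilities for archaeological samples
#'
#' The imputation (cut) stage: converts each sample's d15N value into a
#' posterior probability vector over the three manuring levels under a
#' uniform level prior, a uniform rainfall prior on the sample's range, and
#' (by default) the full calibration posterior. No information from the
#' settlement-size analysis model flows into these probabilities.
#'
#' @inheritParams level_loglik
#' @return A tibble with columns `sample_id`, `p_low`, `p_med`, `p_high`;
#'   each row is nonnegative and sums to 1.
#' @examples
#' cp <- calibration_params(2, 5, 8, -1.5, 0.8)
#' arch <- tibble::tibble(
#'   sample_id = "s1", region = "r", site = "a", phase = "ph",
#'   date_calBC = 3000, size_ha = 10, d15n = 5.0 - 1.5 * log(500),
#'   rain_min_mm = 500, rain_max_mm = 500, taxon = NA_character_
#' )
#' impute_levels(arch, cp)
#' @export
impute_levels <- function(arch, calib, config = manure_config(),
                          max_calib_draws = 200L) {
  L <- level_loglik(arch, calib, config, max_calib_draws)
  P <- exp(L - row_log_sum_exp(L))
  P <- P / rowSums(P)
  tibble::tibble(sample_id = arch$sample_id,
                 p_low = unname(P[, 1]), p_med = unname(P[, 2]),
                 p_high = unname(P[, 3]))
}

#' Most probable manuring level (single imputation)
#'
#' Assigns each sample the level with the highest imputed probability; ties
#' are broken toward the *lower* level, a conservative choice with respect
#' to claiming intensive manuring.
#'
#' @param post A tibble from [impute_levels()] (columns `p_low`, `p_med`,
#'   `p_high`).
#' @return An ordered factor of levels, one per row of `post`.
#' @examples
#' map_assign(tibble::tibble(sample_id = "a",
#'                           p_low = 0.5, p_med = 0.5, p_high = 0))
#' @export
map_assign <- function(post) {
  P <- as.matrix(post[, c("p_low", "p_med", "p_high")])
  if (any(P < 0) || any(abs(rowSums(P) - 1) > 1e-6)) {
    abort("Probability rows must be nonnegative and sum to 1.")
  }
  idx <- max.col(P, ties.method = "first")
  factor(.levels[idx], levels = .levels, ordered = TRUE)
}

# materialise a list of parameter draws from whatever calibration object
calib_draw_list <- function(calib, config, max_calib_draws) {
  if (inherits(calib, "calibration_params")) return(list(calib))
  if (!inherits(calib, "calibration_fit")) {
    abort("`calib` must be a calibration_fit or calibration_params object.")
  }
  if (config$calib_mode == "plugin") return(list(calib$mean))
  d <- calib$draws
  idx <- thin_index(nrow(d), max_calib_draws)
  per_level <- isTRUE(calib$per_level_slope)
  lapply(idx, function(i) {
    list(
      beta = c(d$beta_low[i], d$beta_med[i], d$beta_high[i]),
      lambda = if (per_level) c(d$lambda_low[i], d$lambda_med[i],
                                d$lambda_high[i]) else d$lambda[i],
      sigma = d$sigma[i]
    )
  })
}
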