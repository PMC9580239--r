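#' Fixed calibration parameters
#'
#' Bundles the parameters of the modern d15N measurement model
#' `d15n = beta_level + lambda * log(rainfall_mm) + Normal(0, sigma)`:
#' one intercept per manuring level (ordered low < medium < high), a common
#' rainfall slope on the natural-log scale, and a residual scale. Used as
#' generator truth, as plug-in values for imputation, and as the summary of
#' a fitted [fit_calibration()] posterior.
#'
#' @param beta_low,beta_med,beta_high Level intercepts, permil; must be
#'   strictly increasing.
#' @param lambda Common slope on `log(rainfall_mm)`, permil per log-mm
#'   (empirically negative: wetter sites give lower d15N). For separate
#'   slopes per level supply a length-3 vector (low, medium, high).
#' @param sigma Residual standard deviation, permil (> 0).
#' @return An object of class `"calibration_params"`.
#' @examples
#' calibration_params(2, 5, 8, lambda = -1.5, sigma = 1)
#' @export
calibration_params <- function(beta_low, beta_med, beta_high, lambda, sigma) {
  if (!(beta_low < beta_med && beta_med < beta_high)) {
    abort("Level intercepts must satisfy beta_low < beta_med < beta_high.")
  }
  if (sigma <= 0) abort("`sigma` must be > 0.")
  if (!length(lambda) %in% c(1L, 3L)) {
    abort("`lambda` must have length 1 (common slope) or 3 (per level).")
  }
  structure(
    list(beta = c(low = beta_low, medium = beta_med, high = beta_high),
         lambda = if (length(lambda) == 3) setNames(lambda, .levels)
                  else unname(lambda),
         sigma = sigma),
    class = "calibration_params"
  )
}

#' @export
print.calibration_params <- function(x, ...) {
  cat("<calibration_params>\n")
  cat("  beta (permil):", paste(names(x$beta), format(x$beta, digits = 4),
                                sep = "=", collapse = "  "), "\n")
  cat("  lambda:", paste(format(x$lambda, digits = 4), collapse = " "),
      " sigma:", format(x$sigma, digits = 4), "\n")
  invisible(x)
}

#' Fit the modern d15N calibration model
#'
#' Regresses modern cereal-grain d15N values on manuring level (intercepts)
#' and log mean annual rainfall (slope), yielding the measurement model used
#' to impute manuring levels for archaeological samples. Two fitting modes:
#' `"bayes"` (default) samples the posterior under weakly-informative priors
#' with the intercept ordering `beta_low < beta_med < beta_high` imposed by
#' an ordered parameterisation; `"ls"` returns the ordinary least-squares
#' fit (flat-prior point estimate) with draws simulated from its sampling
#' distribution.
#'
#' @param modern A tibble from [read_modern_table()] or [generate_modern()].
#' @param config A [manure_config()]; `per_level_slope` selects separate
#'   rainfall slopes per level, `priors` sets prior scales, and `chains` /
#'   `warmup` / `draws` / `seed` control the sampler.
#' @param method `"bayes"` or `"ls"`.
#' @return An object of class `"calibration_fit"`: a list with `draws`
#'   (tibble of posterior draws: chain, beta_low, beta_med, beta_high,
#'   lambda (or lambda_low/med/high), sigma), `summary` (posterior mean,
#'   sd, 5%/95% quantiles, split-Rhat, ESS per parameter), `mean`
#'   (a [calibration_params()] at the posterior means), `method`, `n`.
#'   A warning is raised if any split-Rhat exceeds 1.01.
#' @export
fit_calibration <- function(modern, config = manure_config(),
                            method = c("bayes", "ls")) {
  method <- match.arg(method)
  stopifnot(is.data.frame(modern))
  lev <- as.integer(parse_level(modern$level))
  if (anyNA(lev)) abort("Modern table contains unparseable manuring levels.")
  missing_lev <- setdiff(1:3, unique(lev))
  if (length(missing_lev) > 0) {
    abort(paste0("Manuring level(s) absent from the modern data: ",
                 paste(.levels[missing_lev], collapse = ", ")))
  }
  counts <- tabulate(lev, 3)
  if (any(counts < 2)) {
    abort(paste0("Need >= 2 observations per manuring level; got ",
                 paste(.levels, counts, sep = "=", collapse = ", "), "."))
  }
  if (any(modern$rainfall_mm <= 0)) abort("rainfall_mm must be > 0.")

  y <- as.numeric(modern$d15n)
  logr <- log(as.numeric(modern$rainfall_mm))
  per_level <- isTRUE(config$per_level_slope)

  # least-squares reference fit (also used to initialise the sampler)
  fml <- if (per_level) y ~ 0 + factor(lev) + factor(lev):logr
         else y ~ 0 + factor(lev) + logr
  ls_fit <- lm(fml)

  if (method == "ls") {
    draws <- ls_draws(ls_fit, per_level, config)
  } else {
    draws <- calib_mcmc(y, logr, lev, per_level, config, ls_fit)
  }

  par_names <- setdiff(names(draws), c("chain"))
  summary <- purrr::map_dfr(par_names, function(p) {
    mat <- matrix(draws[[p]], ncol = max(draws$chain))
    tibble::tibble(
      term = p,
      mean = mean(draws[[p]]),
      sd = sd(draws[[p]]),
      q5 = unname(quantile(draws[[p]], 0.05)),
      q95 = unname(quantile(draws[[p]], 0.95)),
      rhat = split_rhat(mat),
      ess = ess_basic(mat)
    )
  })
  if (method == "bayes" && any(summary$rhat > 1.01, na.rm = TRUE)) {
    warn(paste0("Calibration sampler may not have converged: max split-Rhat ",
                format(max(summary$rhat, na.rm = TRUE), digits = 4)))
  }

  lam_mean <- if (per_level) {
    c(mean(draws$lambda_low), mean(draws$lambda_med), mean(draws$lambda_high))
  } else {
    mean(draws$lambda)
  }
  mean_params <- calibration_params(
    mean(draws$beta_low), mean(draws$beta_med), mean(draws$beta_high),
    lambda = lam_mean, sigma = mean(draws$sigma)
  )

  structure(
    list(draws = draws, summary = summary, mean = mean_params,
         method = method, n = length(y), per_level_slope = per_level),
    class = "calibration_fit"
  )
}

#' Predict a d15N value from calibration parameters
#'
#' Evaluates the calibration mean line `beta_level + lambda * log(rainfall)`.
#'
#' @param params A [calibration_params()] or a [fit_calibration()] result
#'   (posterior means are used).
#' @param level Manuring level: `"low"`, `"medium"`, `"high"` (or 1:3).
#' @param rainfall_mm Mean annual rainfall, mm/yr (> 0). Vectorised.
#' @return Predicted d15N in permil.
#' @examples
#' p <- calibration_params(2, 5, 8, -1.5, 1)
#' predict_d15n(p, "high", 400)
#' @export
predict_d15n <- function(params, level, rainfall_mm) {
  params <- as_calibration_params(params)
  m <- if (is.numeric(level)) as.integer(level) else
    as.integer(parse_level(level))
  if (anyNA(m) || any(m < 1 | m > 3)) abort("Invalid manuring level.")
  if (any(rainfall_mm <= 0)) abort("`rainfall_mm` must be > 0.")
  lam <- if (length(params$lambda) == 3) params$lambda[m] else params$lambda
  unname(params$beta[m] + lam * log(rainfall_mm))
}

as_calibration_params <- function(x) {
  if (inherits(x, "calibration_params")) return(x)
  if (inherits(x, "calibration_fit")) return(x$mean)
  abort("Expected a calibration_params or calibration_fit object.")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat("<calibration_fit> method:", x$method, " n:", x$n, "\n")
  print(x$summary, n = Inf)
  invisible(x)
}

#' @rdname fit_calibration
#' @param x A `calibration_fit`.
#' @param ... Unused.
#' @method tidy calibration_fit
#' @export
tidy.calibration_fit <- function(x, ...) {
  dplyr::rename(x$summary, estimate = "mean", std.error = "sd",
                conf.low = "q5", conf.high = "q95")
}

#' @rdname fit_calibration
#' @method glance calibration_fit
#' @export
glance.calibration_fit <- function(x, ...) {
  tibble::tibble(n = x$n, method = x$method,
                 max_rhat = max(x$summary$rhat, na.rm = TRUE),
                 min_ess = min(x$summary$ess, na.rm = TRUE))
}

#' @rdname fit_calibration
#' @param object A `calibration_fit`.
#' @param modern Optionally, the modern table to overlay as points.
#' @method autoplot calibration_fit
#' @export
autoplot.calibration_fit <- function(object, modern = NULL, ...) {
  pars <- object$mean
  grid <- tidyr::expand_grid(
    level = factor(.levels, .levels, ordered = TRUE),
    rainfall_mm = exp(seq(log(150), log(1500), length.out = 60))
  )
  grid$d15n <- predict_d15n(pars, grid$level, grid$rainfall_mm)
  p <- ggplot2::ggplot(grid, ggplot2::aes(log(.data$rainfall_mm),
                                          .data$d15n,
                                          colour = .data$level)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "log rainfall (mm/yr)",
                  y = expression(delta^15 * N ~ "(permil)"),
                  colour = "manuring") +
    ggplot2::theme_minimal()
  if (!is.null(modern)) {
    pts <- dplyr::mutate(modern, level = parse_level(.data$level))
    p <- p + ggplot2::geom_point(data = pts, alpha = 0.5)
  }
  p
}

# ---- internals --------------------------------------------------------------

# simulate flat-prior draws from the LS sampling distribution
ls_draws <- function(ls_fit, per_level, config) {
  co <- coef(ls_fit)
  V <- stats::vcov(ls_fit)
  s <- summary(ls_fit)$sigma
  df <- stats::df.residual(ls_fit)
  n_draw <- config$chains * config$draws
  withr::with_seed(derive_seed(config$seed, 11L), {
    ch <- chol(V)
    z <- matrix(rnorm(n_draw * length(co)), n_draw)
    th <- sweep(z %*% ch, 2, co, "+")
    sig <- s * sqrt(df / stats::rchisq(n_draw, df))
    draws_to_tibble(th, sig, per_level, config$chains)
  })
}

draws_to_tibble <- function(th, sig, per_level, chains) {
  out <- tibble::tibble(
    chain = rep(seq_len(chains), each = nrow(th) / chains),
    beta_low = th[, 1], beta_med = th[, 2], beta_high = th[, 3]
  )
  if (per_level) {
    out$lambda_low <- th[, 4]; out$lambda_med <- th[, 5]
    out$lambda_high <- th[, 6]
  } else {
    out$lambda <- th[, 4]
  }
  out$sigma <- sig
  out
}

calib_mcmc <- function(y, logr, lev, per_level, config, ls_fit) {
  pr <- config$priors
  n_lam <- if (per_level) 3L else 1L

  # centre the regressor so intercepts and slope mix near-independently;
  # draws are mapped back to the log(r) = 0 intercept scale afterwards
  mlr <- mean(logr)
  logr_c <- logr - mlr

  # unconstrained state: b_low, log(gap2), log(gap3), lambda(s), log sigma,
  # with the b's on the centred scale
  co <- coef(ls_fit)
  b0 <- sort(co[1:3] + mean(co[4:(3 + n_lam)]) * mlr)
  init <- c(b0[1], log(max(b0[2] - b0[1], 0.1)),
            log(max(b0[3] - b0[2], 0.1)),
            co[4:(3 + n_lam)],
            log(max(summary(ls_fit)$sigma, 0.05)))
  p <- length(init)

  log_post <- function(phi) {
    b1 <- phi[1]; g2 <- exp(phi[2]); g3 <- exp(phi[3])
    beta <- c(b1, b1 + g2, b1 + g2 + g3)
    lam <- phi[4:(3 + n_lam)]
    sigma <- exp(phi[p])
    mu <- beta[lev] + (if (per_level) lam[lev] else lam) * logr_c
    ll <- sum(dnorm(y, mu, sigma, log = TRUE))
    lp <- dnorm(b1, 0, pr$beta_sd, log = TRUE) +
      dhalfnorm_log(g2, pr$beta_sd) + phi[2] +
      dhalfnorm_log(g3, pr$beta_sd) + phi[3] +
      sum(dnorm(lam, 0, pr$lambda_sd, log = TRUE)) +
      dhalfnorm_log(sigma, pr$sigma_scale) + phi[p]
    ll + lp
  }

  all_draws <- vector("list", config$chains)
  for (ch in seq_len(config$chains)) {
    all_draws[[ch]] <- withr::with_seed(
      derive_seed(config$seed, 100L + ch),
      rw_chain(init + rnorm(p, 0, 0.05), log_post,
               warmup = config$warmup, draws = config$draws)
    )
  }
  th <- do.call(rbind, all_draws)
  beta_c <- cbind(th[, 1], th[, 1] + exp(th[, 2]),
                  th[, 1] + exp(th[, 2]) + exp(th[, 3]))
  lam <- th[, 4:(3 + n_lam), drop = FALSE]
  # un-centre: beta = beta_c - lambda * mean(log r)
  beta <- beta_c - (if (per_level) lam else lam[, c(1, 1, 1)]) * mlr
  draws_to_tibble(cbind(beta, lam),
                  exp(th[, ncol(th)]), per_level, config$chains)
}

# generic componentwise adaptive random-walk Metropolis chain
rw_chain <- function(init, log_post, warmup, draws) {
  p <- length(init)
  phi <- init
  lp <- log_post(phi)
  if (!is.finite(lp)) abort("Sampler initialised at zero posterior density.")
  log_s <- rep(log(0.3), p)
  keep <- matrix(NA_real_, draws, p)
  total <- warmup + draws
  for (it in seq_len(total)) {
    for (j in seq_len(p)) {
      prop <- phi
      prop[j] <- phi[j] + exp(log_s[j]) * rnorm(1)
      lp_prop <- log_post(prop)
      acc <- is.finite(lp_prop) && log(runif(1)) < lp_prop - lp
      if (acc) {
        phi <- prop
        lp <- lp_prop
      }
      if (it <= warmup) {
        log_s[j] <- adapt_scale(log_s[j], acc, it, target = 0.44)
      }
    }
    if (it > warmup) keep[it - warmup, ] <- phi
  }
  keep
}
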