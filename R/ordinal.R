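#' Proportional-odds model parameters
#'
#' Parameters of the analysis-stage cumulative-logit model
#' `P(M <= m) = plogis(alpha_m - (gamma * x_size + tau * x_date + u_site))`,
#' with cutpoints `alpha_1 < alpha_2`, settlement-size effect `gamma`
#' (negative gamma: larger settlements receive less manure), date effect
#' `tau`, and site random intercepts `u` with scale `sigma_u`.
#'
#' @param alpha Length-2 increasing numeric vector of cutpoints.
#' @param gamma Settlement-size effect (on the transformed/standardised
#'   size covariate).
#' @param tau Date effect; default 0.
#' @param u Named numeric vector of site random intercepts; default none.
#' @param sigma_u Random-intercept standard deviation; default 0.
#' @return An object of class `"po_params"`.
#' @examples
#' po_params(c(-1, 1), gamma = -0.5)
#' @export
po_params <- function(alpha, gamma, tau = 0, u = numeric(), sigma_u = 0) {
  if (length(alpha) != 2 || !(alpha[1] < alpha[2])) {
    abort("`alpha` must be two increasing cutpoints.")
  }
  if (sigma_u < 0) abort("`sigma_u` must be >= 0.")
  structure(list(alpha = as.numeric(alpha), gamma = gamma, tau = tau,
                 u = u, sigma_u = sigma_u),
            class = "po_params")
}

#' Cumulative manuring-level probability
#'
#' Evaluates `P(M <= m)` under the proportional-odds model for given
#' covariate values. `P(M <= "high")` is identically 1. For a site not
#' named in `params$u`, set `marginal = TRUE` to integrate the random
#' intercept over `Normal(0, sigma_u^2)` (Gauss-Hermite quadrature).
#'
#' @param params A [po_params()] object.
#' @param x_size,x_date Transformed (and standardised, if configured)
#'   settlement-size and date covariates. Vectorised.
#' @param site Site identifier(s) naming entries of `params$u`, or `NULL`.
#' @param m Level: `"low"` or `"medium"` (or 1, 2); `"high"` returns 1.
#' @param marginal Integrate over the random-intercept distribution instead
#'   of conditioning on a site.
#' @param gh_nodes Quadrature nodes for marginal mode.
#' @return Probabilities in `[0, 1]`.
#' @examples
#' po_cumulative_prob(po_params(c(0, 1), gamma = 0), 0, 0, m = "low")  # 0.5
#' @export
po_cumulative_prob <- function(params, x_size, x_date = 0, site = NULL,
                               m, marginal = is.null(site), gh_nodes = 21) {
  m_idx <- if (is.numeric(m)) as.integer(m) else
    as.integer(parse_level(m))
  if (anyNA(m_idx) || any(m_idx < 1 | m_idx > 3)) abort("Invalid level `m`.")
  eta0 <- params$gamma * x_size + params$tau * x_date
  if (any(m_idx == 3)) {
    out <- rep(1, max(length(eta0), length(m_idx)))
    if (all(m_idx == 3)) return(out)
  }
  alpha_m <- params$alpha[pmin(m_idx, 2)]
  if (!marginal) {
    if (is.null(site)) abort("Supply `site` or set `marginal = TRUE`.")
    u <- params$u[as.character(site)]
    if (anyNA(u)) {
      abort(paste0("Unknown site(s) without a random effect: ",
                   paste(unique(site[is.na(u)]), collapse = ", "),
                   ". Use marginal = TRUE to integrate over sites."))
    }
    p <- plogis(alpha_m - eta0 - unname(u))
  } else if (params$sigma_u == 0) {
    p <- plogis(alpha_m - eta0)
  } else {
    gh <- pracma::gaussHermite(gh_nodes)
    u_nodes <- sqrt(2) * params$sigma_u * gh$x
    w <- gh$w / sqrt(pi)
    p <- drop(plogis(outer(alpha_m - eta0, u_nodes, "-")) %*% w)
  }
  ifelse(m_idx == 3, 1, p)
}

#' Proportional-odds log likelihood of assigned levels
#'
#' Sum over observations of the log category probability implied by the
#' cumulative-logit model, conditioning on each observation's site random
#' intercept from `params$u`.
#'
#' @param params A [po_params()] object.
#' @param data A tibble with columns `level` (factor or 1:3), `x_size`,
#'   `x_date` (use 0 if absent from the model) and `site`.
#' @return The log likelihood (scalar); `-Inf` (with a warning) if any
#'   observation falls in a zero-probability category.
#' @export
po_loglik <- function(params, data) {
  m <- if (is.numeric(data$level)) as.integer(data$level) else
    as.integer(parse_level(data$level))
  u <- if (length(params$u) > 0) params$u[as.character(data$site)] else
    rep(0, nrow(data))
  if (anyNA(u)) abort("Data contain sites absent from `params$u`.")
  x_date <- data$x_date %||% 0
  eta <- params$gamma * data$x_size + params$tau * x_date + unname(u)
  lp <- po_category_logprob(params$alpha, eta)
  contrib <- lp[cbind(seq_along(m), m)]
  if (any(!is.finite(contrib))) {
    warn("Zero-probability category encountered; log likelihood is -Inf.")
    return(-Inf)
  }
  sum(contrib)
}

# n x 3 matrix of log category probabilities for linear predictor eta
po_category_logprob <- function(alpha, eta) {
  c1 <- plogis(alpha[1] - eta)
  c2 <- plogis(alpha[2] - eta)
  log(pmax(cbind(c1, c2 - c1, 1 - c2), 0))
}

#' Maximum-likelihood proportional-odds fit with a Wald test
#'
#' Fits the mixed-effects proportional-odds model by maximum likelihood,
#' integrating site random intercepts by Gauss-Hermite quadrature, and
#' reports a one-sided Wald test for the settlement-size effect gamma in
#' the configured direction. This is the analysis stage of the
#' single-imputation strategy (see [fit_po_si()]). With fewer than two
#' sites, or `config$random_effects = FALSE`, a fixed-intercept model is
#' fitted instead.
#'
#' @param data Archaeological tibble with `size_ha`, `date_calBC`, `site`
#'   columns (e.g. from [read_arch_table()] or [generate_arch()]).
#' @param levels Assigned manuring levels (ordered factor or integers 1:3),
#'   one per row of `data`; defaults to a `level` column of `data`.
#' @param config A [manure_config()]; uses `size_transform`, `standardize`,
#'   `include_size`/`include_date` analogues via `random_effects`,
#'   `include_date` and `direction`.
#' @param include_size Include the settlement-size term (disable to fit
#'   intercept-only or date-only models).
#' @param gh_nodes Gauss-Hermite nodes for the random-effect integral.
#' @return An object of class `"po_wald"`: coefficient table (`term`,
#'   `estimate`, `std.error`, `z`), one-sided p-value for gamma,
#'   `sigma_u`, log likelihood, convergence flag, and the covariate scales
#'   used. Supports [tidy()] and [glance()].
#' @export
fit_po_wald <- function(data, levels = NULL, config = manure_config(),
                        include_size = TRUE, gh_nodes = 15) {
  m <- levels %||% data$level
  if (is.null(m)) abort("Supply `levels` or a `level` column in `data`.")
  m <- if (is.numeric(m)) as.integer(m) else as.integer(parse_level(m))
  if (length(unique(m)) < 2) {
    abort("Need >= 2 distinct manuring levels to fit the ordinal model.")
  }
  des <- build_design(data, config)
  use_re <- config$random_effects && des$n_sites >= 2
  use_date <- config$include_date
  gh <- pracma::gaussHermite(gh_nodes)

  # theta: a1, log(gap) [, gamma] [, tau] [, log sigma_u]
  terms <- c("alpha1", "log_gap",
             if (include_size) "gamma",
             if (use_date) "tau",
             if (use_re) "log_sigma_u")
  idx <- setNames(seq_along(terms), terms)
  site_rows <- split(seq_len(des$n), des$site_idx)

  negll <- function(th) {
    alpha <- c(th[1], th[1] + exp(th[2]))
    gamma <- if (include_size) th[idx["gamma"]] else 0
    tau <- if (use_date) th[idx["tau"]] else 0
    eta0 <- gamma * des$x_size + tau * des$x_date
    if (!use_re) {
      lp <- po_category_logprob(alpha, eta0)
      return(-sum(lp[cbind(seq_along(m), m)]))
    }
    sigma_u <- exp(th[idx["log_sigma_u"]])
    u_nodes <- sqrt(2) * sigma_u * gh$x
    logw <- log(gh$w / sqrt(pi))
    # obs x node log category prob for each observation's own category
    ll_site <- vapply(site_rows, function(rows) {
      eta_mat <- outer(eta0[rows], u_nodes, "+")
      c1 <- plogis(alpha[1] - eta_mat)
      c2 <- plogis(alpha[2] - eta_mat)
      mi <- m[rows]
      pmat <- (mi == 1) * c1 + (mi == 2) * (c2 - c1) + (mi == 3) * (1 - c2)
      lmat <- log(pmax(pmat, 1e-300))
      log_sum_exp(logw + colSums(lmat))
    }, numeric(1))
    -sum(ll_site)
  }

  init <- c(qlogis(mean(m == 1) + 1e-3),
            log(max(qlogis(mean(m <= 2) - 1e-3) -
                      qlogis(mean(m == 1) + 1e-3), 0.1)),
            rep(0, include_size + use_date),
            if (use_re) log(0.5))
  opt <- nlminb(init, negll, control = list(iter.max = 500, eval.max = 1000))
  H <- optimHess(opt$par, negll)
  Vok <- TRUE
  V <- tryCatch(solve(H), error = function(e) {
    Vok <<- FALSE
    matrix(NA_real_, length(init), length(init))
  })
  se_th <- sqrt(pmax(diag(V), 0))
  converged <- opt$convergence == 0 && Vok && all(is.finite(se_th))
  if (!converged) {
    warn("Proportional-odds ML fit did not converge cleanly; estimates flagged.")
  }

  th <- opt$par
  est <- c(alpha1 = th[1], alpha2 = th[1] + exp(th[2]),
           if (include_size) c(gamma = th[idx["gamma"]]),
           if (use_date) c(tau = th[idx["tau"]]))
  # delta method for alpha2 = a1 + exp(lgap)
  se <- c(se_th[1],
          sqrt(max(V[1, 1] + exp(2 * th[2]) * V[2, 2] +
                     2 * exp(th[2]) * V[1, 2], 0)),
          if (include_size) se_th[idx["gamma"]],
          if (use_date) se_th[idx["tau"]])
  coefs <- tibble::tibble(term = names(est), estimate = unname(est),
                          std.error = unname(se),
                          z = unname(est) / unname(se))
  sigma_u_hat <- if (use_re) exp(th[idx["log_sigma_u"]]) else 0

  p_one <- NA_real_
  if (include_size) {
    z_gamma <- coefs$z[coefs$term == "gamma"]
    p_one <- if (config$direction == "negative") pnorm(z_gamma) else
      pnorm(z_gamma, lower.tail = FALSE)
  }

  structure(
    list(coefficients = coefs, sigma_u = sigma_u_hat,
         p_one_sided = p_one, direction = config$direction,
         logLik = -opt$objective, converged = converged,
         n = des$n, n_sites = des$n_sites, random_effects = use_re,
         scales = des$scales, include_size = include_size,
         include_date = use_date),
    class = "po_wald"
  )
}

#' Single-imputation pipeline: impute, assign, Wald-test
#'
#' Runs the first inference strategy end to end: impute level probabilities
#' ([impute_levels()]), assign each sample its most probable level
#' ([map_assign()]), then fit the mixed-effects proportional-odds model and
#' report the one-sided Wald test ([fit_po_wald()]).
#'
#' @inheritParams impute_levels
#' @param ... Passed to [fit_po_wald()].
#' @return A `"po_wald"` fit with the assigned levels attached as
#'   attribute `"levels"`.
#' @export
fit_po_si <- function(arch, calib, config = manure_config(), ...) {
  lev <- map_assign(impute_levels(arch, calib, config))
  fit <- fit_po_wald(arch, levels = lev, config = config, ...)
  attr(fit, "levels") <- lev
  fit
}

#' @export
print.po_wald <- function(x, ...) {
  cat("<po_wald> mixed-effects proportional-odds ML fit\n")
  cat("  n =", x$n, " sites =", x$n_sites,
      " random effects:", x$random_effects, "\n")
  print(x$coefficients)
  if (x$random_effects) cat("  sigma_u =", format(x$sigma_u, digits = 4), "\n")
  if (!is.na(x$p_one_sided)) {
    cat("  one-sided p (gamma", x$direction, ") =",
        format(x$p_one_sided, digits = 4), "\n")
  }
  if (!x$converged) cat("  WARNING: fit flagged as non-converged\n")
  invisible(x)
}

#' @rdname fit_po_wald
#' @param x,object A `po_wald` fit.
#' @param ... Unused.
#' @method tidy po_wald
#' @export
tidy.po_wald <- function(x, ...) x$coefficients

#' @rdname fit_po_wald
#' @method glance po_wald
#' @export
glance.po_wald <- function(x, ...) {
  tibble::tibble(n = x$n, n_sites = x$n_sites, logLik = x$logLik,
                 sigma_u = x$sigma_u, p_one_sided = x$p_one_sided,
                 converged = x$converged)
}

# ---- design construction ----------------------------------------------------

# Shared covariate preparation: transform size, standardise both covariates,
# index sites. `scales` from a previous design reapplies identical centring.
build_design <- function(data, config, scales = NULL) {
  x_size_raw <- switch(config$size_transform,
                       identity = data$size_ha,
                       log = log(data$size_ha))
  x_date_raw <- data$date_calBC %||% rep(0, nrow(data))
  if (is.null(scales)) {
    scales <- list(
      size_center = if (config$standardize) mean(x_size_raw) else 0,
      size_scale = if (config$standardize) sd_or_one(x_size_raw) else 1,
      date_center = if (config$standardize) mean(x_date_raw) else 0,
      date_scale = if (config$standardize) sd_or_one(x_date_raw) else 1,
      size_transform = config$size_transform
    )
  }
  site <- factor(as.character(data$site))
  list(
    x_size = (x_size_raw - scales$size_center) / scales$size_scale,
    x_date = (x_date_raw - scales$date_center) / scales$date_scale,
    site = site,
    site_idx = as.integer(site),
    site_levels = levels(site),
    n_sites = nlevels(site),
    n = nrow(data),
    scales = scales
  )
}

sd_or_one <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) 1 else s
}
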