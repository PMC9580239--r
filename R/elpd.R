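# Predictive tuning of the influence parameter eta. The predictive target is
# the observed archaeological d15n values (the only observed outcome; levels
# are latent): p(y_i | theta) = sum_m PO(m | theta, x_i) p(y_i | m), with
# p(y_i | m) the measurement density from level_loglik(). ELPD is estimated
# by leave-one-out cross-validation, by default with Pareto-smoothed
# importance sampling (PSIS) over the posterior draws, with an exact k-fold
# refitting alternative.

# draws x n matrix of log p(y_i | theta_s)
log_pred_matrix <- function(fit) {
  L <- fit$L
  n <- nrow(L)
  d <- fit$draws
  S <- nrow(d)
  lay <- fit$layout
  out <- matrix(NA_real_, S, n)
  for (s in seq_len(S)) {
    eta <- d$gamma[s] * fit$x_size + d$tau[s] * fit$x_date
    if (ncol(fit$u_draws) > 0) eta <- eta + fit$u_draws[s, fit$site_idx]
    lp <- po_category_logprob(c(d$alpha1[s], d$alpha2[s]), eta)
    out[s, ] <- row_log_sum_exp(lp + L)
  }
  out
}

#' ELPD of the SMI posterior as a function of eta
#'
#' For each value of the influence parameter, fits the SMI posterior and
#' estimates the expected log pointwise predictive density (ELPD) of the
#' observed archaeological d15N values by leave-one-out cross-validation.
#' The default estimator is PSIS-LOO (Pareto-smoothed importance sampling);
#' observations whose Pareto shape diagnostic exceeds 0.7 trigger a warning
#' and, when `fallback = "kfold"`, the whole grid point is recomputed by
#' k-fold refitting. `eta_star` is the grid value maximising ELPD.
#'
#' @inheritParams sample_smi_posterior
#' @param eta_grid Numeric vector of eta values; defaults to
#'   `config$eta_grid`. A single value is allowed and returned as-is.
#' @param fallback `"kfold"` (default) to recompute unstable PSIS points by
#'   k-fold cross-validation, or `"none"` to keep the PSIS estimate.
#' @param keep_fits Keep each eta's `smi_fit` in the result (memory-heavy).
#' @return An object of class `"elpd_curve"`: a tibble with columns `eta`,
#'   `elpd`, `elpd_se`, `n_high_k` (observations with Pareto k > 0.7) and
#'   `estimator`, with attributes `eta_star` and (optionally) `fits`.
#' @export
elpd_curve <- function(arch, calib, config = manure_config(),
                       eta_grid = config$eta_grid, seed = config$seed,
                       fallback = c("kfold", "none"), keep_fits = FALSE) {
  fallback <- match.arg(fallback)
  if (length(eta_grid) < 1) abort("`eta_grid` must contain >= 1 value.")
  fits <- list()
  rows <- purrr::map_dfr(seq_along(eta_grid), function(i) {
    eta <- eta_grid[i]
    fit <- sample_smi_posterior(arch, calib, config, eta = eta,
                                seed = derive_seed(seed, 600L + i))
    if (keep_fits) fits[[i]] <<- fit
    res <- psis_loo_elpd(fit, arch, config)
    if (res$n_high_k > 0) {
      warn(paste0("eta = ", format(eta), ": ", res$n_high_k,
                  " observation(s) with Pareto k > 0.7",
                  if (fallback == "kfold") "; falling back to k-fold." else "."))
      if (fallback == "kfold") {
        res <- kfold_elpd(arch, calib, config, eta,
                          seed = derive_seed(seed, 700L + i))
      }
    }
    tibble::tibble(eta = eta, elpd = res$elpd, elpd_se = res$se,
                   n_high_k = res$n_high_k, estimator = res$estimator)
  })
  eta_star <- rows$eta[which.max(rows$elpd)]
  structure(rows, class = c("elpd_curve", class(rows)),
            eta_star = eta_star, fits = if (keep_fits) fits)
}

#' @rdname elpd_curve
#' @param curve An `elpd_curve`.
#' @export
eta_star <- function(curve) attr(curve, "eta_star")

#' @rdname elpd_curve
#' @param object An `elpd_curve`.
#' @param ... Unused.
#' @method autoplot elpd_curve
#' @export
autoplot.elpd_curve <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$eta, .data$elpd)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$elpd - .data$elpd_se,
                                      ymax = .data$elpd + .data$elpd_se),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = attr(object, "eta_star"),
                        linetype = 2, colour = "firebrick") +
    ggplot2::labs(x = expression(eta), y = "ELPD (LOO)") +
    ggplot2::theme_minimal()
}

# ---- PSIS-LOO ---------------------------------------------------------------

psis_loo_elpd <- function(fit, arch, config) {
  des <- build_design(arch, config, scales = fit$scales)
  fit$x_size <- des$x_size
  fit$x_date <- des$x_date
  fit$site_idx <- des$site_idx
  lpm <- log_pred_matrix(fit)
  n <- ncol(lpm)
  elpd_i <- numeric(n)
  khat <- numeric(n)
  for (i in seq_len(n)) {
    sm <- psis_smooth(-lpm[, i])
    lw <- sm$log_weights - log_sum_exp(sm$log_weights)
    elpd_i[i] <- log_sum_exp(lw + lpm[, i])
    khat[i] <- sm$khat
  }
  list(elpd = sum(elpd_i), se = sd(elpd_i) * sqrt(n),
       n_high_k = sum(khat > 0.7), estimator = "psis", khat = khat,
       pointwise = elpd_i)
}

# Pareto-smoothed importance weights from raw log-ratios (Vehtari et al.):
# fit a generalized Pareto distribution to the largest ratios and replace
# them by expected order statistics, truncated at the raw maximum.
psis_smooth <- function(log_ratios) {
  S <- length(log_ratios)
  lw <- log_ratios - max(log_ratios)
  M <- min(ceiling(0.2 * S), ceiling(3 * sqrt(S)))
  if (M < 5 || S < 25) {
    return(list(log_weights = lw, khat = NA_real_))
  }
  ord <- order(lw)
  tail_ids <- ord[(S - M + 1):S]
  cutoff <- lw[ord[S - M]]
  exceed <- exp(lw[tail_ids]) - exp(cutoff)
  if (all(exceed <= 0)) return(list(log_weights = lw, khat = 0))
  gpd <- gpd_fit(sort(exceed))
  if (is.finite(gpd$k)) {
    p <- (seq_len(M) - 0.5) / M
    q <- qgpd(p, gpd$k, gpd$sigma)
    smoothed <- log(exp(cutoff) + q)
    smoothed <- pmin(smoothed, 0)  # truncate at raw max (lw max = 0)
    lw[tail_ids[order(lw[tail_ids])]] <- smoothed
  }
  list(log_weights = lw, khat = gpd$k)
}

# Zhang & Stephens (2009) quasi-Bayesian generalized-Pareto fit; x sorted
# ascending exceedances. Returns shape k (positive = heavy tail, the PSIS
# "Pareto k" diagnostic) and scale sigma.
gpd_fit <- function(x) {
  n <- length(x)
  m <- 30L + floor(sqrt(n))
  jj <- seq_len(m)
  xstar <- x[max(floor(n / 4 + 0.5), 1)]
  if (xstar <= 0) return(list(k = NA_real_, sigma = NA_real_))
  theta <- 1 / x[n] + (1 - sqrt(m / (jj - 0.5))) / (3 * xstar)
  prof <- vapply(theta, function(t) {
    k <- mean(log1p(-t * x))
    n * (log(-t / k) - k - 1)
  }, numeric(1))
  w <- 1 / vapply(seq_len(m),
                  function(j) sum(exp(prof - prof[j])), numeric(1))
  theta_hat <- sum(theta * w)
  k <- mean(log1p(-theta_hat * x))
  list(k = k, sigma = -k / theta_hat)
}

qgpd <- function(p, k, sigma) {
  if (abs(k) < 1e-12) return(-sigma * log1p(-p))
  sigma / k * ((1 - p)^(-k) - 1)
}

# ---- k-fold fallback --------------------------------------------------------

kfold_elpd <- function(arch, calib, config, eta, seed) {
  K <- config$kfold_k
  n <- nrow(arch)
  folds <- withr::with_seed(seed, sample(rep_len(seq_len(K), n)))
  lp_point <- numeric(n)
  full_des <- build_design(arch, config)
  withr::local_seed(derive_seed(seed, 99L))
  for (k in seq_len(K)) {
    train <- arch[folds != k, , drop = FALSE]
    test <- arch[folds == k, , drop = FALSE]
    fit <- sample_smi_posterior(train, calib, config, eta = eta,
                                seed = derive_seed(seed, k))
    des_test <- build_design(test, config, scales = full_des$scales)
    L_test <- level_loglik(test, calib, config)
    d <- fit$draws
    S <- nrow(d)
    lp_mat <- matrix(NA_real_, S, nrow(test))
    for (s in seq_len(S)) {
      eta_lin <- d$gamma[s] * des_test$x_size + d$tau[s] * des_test$x_date
      if (ncol(fit$u_draws) > 0) {
        u <- rep(0, nrow(test))
        known <- match(as.character(des_test$site), colnames(fit$u_draws))
        u[!is.na(known)] <- fit$u_draws[s, known[!is.na(known)]]
        # sites unseen in training: draw from the random-effect distribution
        if (anyNA(known)) {
          u[is.na(known)] <- rnorm(sum(is.na(known)), 0, d$sigma_u[s])
        }
        eta_lin <- eta_lin + u
      }
      lp <- po_category_logprob(c(d$alpha1[s], d$alpha2[s]), eta_lin)
      lp_mat[s, ] <- row_log_sum_exp(lp + L_test)
    }
    lp_point[folds == k] <- apply(lp_mat, 2, log_sum_exp) - log(S)
  }
  list(elpd = sum(lp_point), se = sd(lp_point) * sqrt(n),
       n_high_k = 0L, estimator = "kfold", pointwise = lp_point)
}
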