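#' Pointwise log-likelihood matrix of a fit
#'
#' @param fit an `"rsq_fit"` fitted with `store_loglik = TRUE`.
#' @return matrix (draws x observations), chains concatenated.
#' @export
loglik_matrix <- function(fit) {
  if (is.null(fit$loglik))
    stop("fit was run with store_loglik = FALSE", call. = FALSE)
  do.call(rbind, fit$loglik)
}

#' Watanabe--Akaike information criterion
#'
#' `WAIC = -2 * sum_i [ log mean_d exp(ll[d, i]) - var_d(ll[d, i]) ]`,
#' computed from the pointwise log-likelihood over posterior draws. Lower
#' values indicate better within-sample predictive ability. The standard
#' error comes from the spread of the pointwise contributions.
#'
#' @param pointwise_loglik matrix, draws x observations (>= 100 draws).
#' @return list with `waic`, `se`, `p_waic`, `pointwise` (per-observation
#'   contributions).
#' @export
compute_waic <- function(pointwise_loglik) {
  ll <- as.matrix(pointwise_loglik)
  if (nrow(ll) < 100)
    stop("need at least 100 posterior draws", call. = FALSE)
  bad <- which(!is.finite(ll), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-finite log-likelihood for observation(s) %s",
                 paste(unique(bad[, 2]), collapse = ", ")), call. = FALSE)
  D <- nrow(ll); n <- ncol(ll)
  lpd <- apply(ll, 2, logsumexp) - log(D)
  p_i <- apply(ll, 2, var)
  waic_i <- -2 * (lpd - p_i)
  list(waic = sum(waic_i),
       se = sqrt(n * var(waic_i)),
       p_waic = sum(p_i),
       pointwise = data.frame(lpd = lpd, p_waic = p_i, waic = waic_i))
}

# generalized Pareto fit to tail exceedances (profile-likelihood method
# with a weak prior pulling the shape toward 1/2 for small tails)
gpd_fit_tail <- function(x) {
  x <- sort(x)
  N <- length(x)
  prior <- 3
  M <- 30L + floor(sqrt(N))
  jj <- seq_len(M)
  xstar <- x[max(floor(N / 4 + 0.5), 1)]
  if (xstar <= 0 || x[N] <= 0) return(list(k = NaN, sigma = NaN))
  theta <- 1 / x[N] + (1 - sqrt(M / (jj - 0.5))) / (prior * xstar)
  k_j <- vapply(theta, function(t) -mean(log1p(-t * x)), numeric(1))
  l_j <- N * (log(theta / k_j) + k_j - 1)
  w <- exp(l_j - logsumexp(l_j))
  theta_hat <- sum(theta * w)
  k <- mean(log1p(-theta_hat * x))
  sigma <- -k / theta_hat
  # weak regularization of the shape toward 1/2 for small tail samples
  k_reg <- (N * k + 10 * 0.5) / (N + 10)
  list(k = k_reg, sigma = sigma)
}

qgpd <- function(p, k, sigma) {
  if (abs(k) < 1e-12) return(-sigma * log1p(-p))
  sigma / k * ((1 - p)^(-k) - 1)
}

# Pareto-smoothed importance weights for one observation's log-ratios
psis_weights <- function(lr) {
  D <- length(lr)
  lw <- lr - max(lr)
  M <- ceiling(min(0.2 * D, 3 * sqrt(D)))
  k <- NaN
  if (M >= 5 && sd(lw) > 1e-12) {
    ord <- order(lw)
    tail_idx <- ord[(D - M + 1):D]
    cutoff <- lw[ord[D - M]]
    exc <- exp(lw[tail_idx]) - exp(cutoff)
    if (max(exc) > 0) {
      fit <- gpd_fit_tail(exc)
      k <- fit$k
      if (is.finite(fit$k) && is.finite(fit$sigma) && fit$sigma > 0) {
        qq <- qgpd((rank(lw[tail_idx]) - 0.5) / M, fit$k, fit$sigma)
        lw[tail_idx] <- pmin(log(qq + exp(cutoff)), 0)
      }
    }
  }
  list(lw = lw - logsumexp(lw), k = k)
}

#' Pareto-smoothed importance-sampling leave-one-out cross-validation
#'
#' PSIS-LOO estimate of the expected log pointwise predictive density for
#' a new observation: per observation, importance ratios `1 / p(y_i |
#' theta_d)` are stabilized by replacing their largest 20% with quantiles
#' of a fitted generalized Pareto distribution, then used to reweight the
#' pointwise likelihood. Observations whose Pareto tail shape exceeds 0.7
#' are flagged as unreliable.
#'
#' @param pointwise_loglik matrix, draws x observations (>= 100 draws).
#' @return list with `elpd_loo`, `se`, `pareto_k` (per observation),
#'   `n_flagged` (k > 0.7) and `pointwise`.
#' @export
compute_loo <- function(pointwise_loglik) {
  ll <- as.matrix(pointwise_loglik)
  if (nrow(ll) < 100)
    stop("need at least 100 posterior draws", call. = FALSE)
  if (any(!is.finite(ll)))
    stop("non-finite log-likelihood values", call. = FALSE)
  n <- ncol(ll)
  elpd_i <- numeric(n); k_i <- numeric(n)
  for (i in seq_len(n)) {
    ps <- psis_weights(-ll[, i])
    elpd_i[i] <- logsumexp(ps$lw + ll[, i])
    k_i[i] <- ps$k
  }
  list(elpd_loo = sum(elpd_i),
       se = sqrt(n * var(elpd_i)),
       pareto_k = k_i,
       n_flagged = sum(k_i > 0.7, na.rm = TRUE),
       pointwise = data.frame(elpd = elpd_i, pareto_k = k_i))
}

#' Exact leave-one-out cross-validation for the global model by refitting
#'
#' Brute-force reference for [compute_loo()]: refits the model once per
#' observation and evaluates the posterior predictive density of the held
#' out point. Only practical for small datasets.
#'
#' @param data an [global_model_data()] object (every site needs >= 2
#'   species so no refit loses a site).
#' @param covariate covariate name or `NULL`.
#' @param mcmc an [mcmc_config()].
#' @return list with `elpd_loo` and `pointwise` elpd values.
#' @export
exact_loo_global <- function(data, covariate = NULL, mcmc = mcmc_config()) {
  n <- length(data$y)
  elpd_i <- numeric(n)
  cov_df <- data.frame(mountain_id = data$site_ids, data$V)
  for (i in seq_len(n)) {
    keep <- setdiff(seq_len(n), i)
    d_i <- global_model_data(data$y[keep], data$site_ids[data$site[keep]],
                             cov_df)
    f <- fit_global(d_i, covariate, mcmc, store_loglik = FALSE)
    m <- posterior_matrix(f)
    a_col <- sprintf("alpha_site[%s]", data$site_ids[data$site[i]])
    lp <- dnorm(data$y[i], m[, a_col], sqrt(m[, "sigma2_RS"]), log = TRUE)
    elpd_i[i] <- logsumexp(lp) - log(length(lp))
  }
  list(elpd_loo = sum(elpd_i), pointwise = elpd_i)
}

#' Posterior probability that a slope is negative
#'
#' @param draws numeric vector of posterior draws of the slope.
#' @return fraction of draws strictly below 0.
#' @export
posterior_prob_negative <- function(draws) {
  if (length(draws) < 1) stop("no draws supplied", call. = FALSE)
  mean(draws < 0)
}

#' Bayesian R-squared of a global fit
#'
#' Variance explained at the site level: per posterior draw, the variance
#' of the fitted site means divided by itself plus the residual
#' between-site variance (`sigma2_site` draw); reported as the posterior
#' mean. Always in `[0, 1]` by construction.
#'
#' @param fit a global `"rsq_fit"`.
#' @return list with `estimate` (posterior mean), `sd` and `ci`
#'   (equal-tailed 95%).
#' @export
bayesian_r2 <- function(fit) {
  if (!fit$model %in% c("global", "global_reference"))
    stop("bayesian_r2 is defined for global fits", call. = FALSE)
  X <- fit$data$X
  if (length(fit$site_ids) < 2)
    stop("R-squared needs more than one site", call. = FALSE)
  m <- posterior_matrix(fit)
  theta <- m[, fit$coef_names, drop = FALSE]
  fitted <- theta %*% t(X)
  var_fit <- apply(fitted, 1, var)
  r2 <- var_fit / (var_fit + m[, "sigma2_site"])
  list(estimate = mean(r2), sd = sd(r2),
       ci = unname(quantile(r2, c(0.025, 0.975))))
}

#' Posterior predictive checks
#'
#' Draws replicated datasets from the fitted model and compares per-site
#' summary statistics of the observed log range sizes with their
#' replicated distributions. The tail probability is
#' `P(T_rep >= T_obs)`; values below 0.025 or above 0.975 flag a statistic
#' the model fails to reproduce.
#'
#' @param fit a global or local `"rsq_fit"`.
#' @param statistics subset of `c("mean", "sd", "min", "max")`.
#' @param n_rep number of replicated datasets (posterior draws used).
#' @param seed integer seed (replication is deterministic given the seed).
#' @return data.frame: `site`, `statistic`, `observed`, `p_tail`,
#'   `flagged`.
#' @export
posterior_predictive_check <- function(fit,
                                       statistics = c("mean", "sd", "min", "max"),
                                       n_rep = 200, seed = 1L) {
  statistics <- match.arg(statistics, several.ok = TRUE)
  y <- fit$data$y; site <- fit$data$site
  S <- length(fit$site_ids)
  m <- posterior_matrix(fit)
  idx <- unique(round(seq(1, nrow(m), length.out = n_rep)))
  set.seed(as.integer(seed))
  stat_funs <- list(mean = mean, sd = sd, min = min, max = max)
  obs <- lapply(statistics, function(s)
    tapply(y, site, stat_funs[[s]]))
  count_ge <- lapply(statistics, function(s) numeric(S))
  names(obs) <- names(count_ge) <- statistics
  for (d in idx) {
    if (fit$model == "local") {
      mu <- m[d, sprintf("alpha[%s]", fit$site_ids)][site] +
        m[d, sprintf("beta[%s]", fit$site_ids)][site] * fit$data$v
      sdv <- sqrt(m[d, "sigma2"])
    } else {
      mu <- m[d, sprintf("alpha_site[%s]", fit$site_ids)][site]
      sdv <- sqrt(m[d, "sigma2_RS"])
    }
    yrep <- rnorm(length(y), mu, sdv)
    for (s in statistics) {
      rep_stat <- tapply(yrep, site, stat_funs[[s]])
      count_ge[[s]] <- count_ge[[s]] + (rep_stat >= obs[[s]])
    }
  }
  out <- do.call(rbind, lapply(statistics, function(s) {
    p <- count_ge[[s]] / length(idx)
    data.frame(site = fit$site_ids, statistic = s,
               observed = as.numeric(obs[[s]]), p_tail = as.numeric(p),
               flagged = p < 0.025 | p > 0.975)
  }))
  rownames(out) <- NULL
  out
}

#' Classify local (within-mountain) slopes
#'
#' Per mountain: the sign of the posterior mean slope, the mean/SD ratio,
#' and a low-uncertainty flag when the equal-tailed 95% credible interval
#' excludes 0. Aggregates report the percentage of positive and negative
#' slopes and the low-uncertainty subsets.
#'
#' @param fit a local `"rsq_fit"`.
#' @return list with `table` (per-site data.frame) and `aggregates`
#'   (named percentages: `pct_positive`, `pct_negative`,
#'   `pct_positive_low_unc`, `pct_negative_low_unc`).
#' @export
classify_local_slopes <- function(fit) {
  if (fit$model != "local") stop("needs a local model fit", call. = FALSE)
  m <- posterior_matrix(fit)
  tab <- do.call(rbind, lapply(fit$site_ids, function(id) {
    d <- m[, sprintf("beta[%s]", id)]
    ci <- quantile(d, c(0.025, 0.975))
    mu <- mean(d); sdd <- sd(d)
    data.frame(mountain_id = id, mean = mu, sd = sdd,
               mean_sd_ratio = mu / sdd,
               lower = unname(ci[1]), upper = unname(ci[2]),
               sign = if (mu >= 0) "positive" else "negative",
               low_uncertainty = ci[1] > 0 || ci[2] < 0)
  }))
  rownames(tab) <- NULL
  n <- nrow(tab)
  agg <- c(
    pct_positive = 100 * sum(tab$sign == "positive") / n,
    pct_negative = 100 * sum(tab$sign == "negative") / n,
    pct_positive_low_unc =
      100 * sum(tab$sign == "positive" & tab$low_uncertainty) / n,
    pct_negative_low_unc =
      100 * sum(tab$sign == "negative" & tab$low_uncertainty) / n)
  list(table = tab, aggregates = agg)
}

#' Compare fitted models by WAIC and PSIS-LOO
#'
#' @param fits named list of `"rsq_fit"` objects fitted with stored
#'   log-likelihood on the same data.
#' @return data.frame, one row per model: `waic`, `waic_se`, `p_waic`,
#'   `elpd_loo`, `loo_se`, `max_pareto_k`, `n_flagged`; sorted by WAIC
#'   (best first).
#' @export
compare_models <- function(fits) {
  stopifnot(is.list(fits), length(fits) >= 1)
  nm <- names(fits) %||% paste0("model", seq_along(fits))
  rows <- lapply(seq_along(fits), function(i) {
    ll <- loglik_matrix(fits[[i]])
    w <- compute_waic(ll)
    l <- compute_loo(ll)
    data.frame(model = nm[i], waic = w$waic, waic_se = w$se,
               p_waic = w$p_waic, elpd_loo = l$elpd_loo, loo_se = l$se,
               max_pareto_k = suppressWarnings(max(l$pareto_k, na.rm = TRUE)),
               n_flagged = l$n_flagged)
  })
  out <- do.call(rbind, rows)
  out[order(out$waic), , drop = FALSE]
}
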