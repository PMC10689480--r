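#' MCMC configuration
#'
#' Defaults mirror the headline analysis settings: 3 chains of 50,000
#' iterations with a 20,000-iteration burn-in, run until the effective
#' sample size of every parameter reaches 3,000 (chains are extended in
#' 10,000-iteration increments, at most 5 times, if needed).
#'
#' @param n_chains number of chains (>= 2 required for the potential scale
#'   reduction factor; 1 is allowed but R-hat is then `NA`).
#' @param n_iter iterations per chain, including burn-in.
#' @param burn_in discarded initial iterations (`burn_in < n_iter`).
#' @param target_ess minimal effective sample size demanded of every
#'   parameter before sampling stops; `0` disables extension.
#' @param thin keep every `thin`-th post-burn-in draw.
#' @param seed integer seed; chain `c` uses a seed derived from it.
#' @return class `"rsq_mcmc_config"`.
#' @export
mcmc_config <- function(n_chains = 3L, n_iter = 50000L, burn_in = 20000L,
                        target_ess = 3000, thin = 1L, seed = 1L) {
  n_chains <- as.integer(n_chains); n_iter <- as.integer(n_iter)
  burn_in <- as.integer(burn_in); thin <- as.integer(thin)
  if (n_chains < 1L) stop_field("n_chains", "must be >= 1")
  if (burn_in >= n_iter) stop_field("burn_in", "must be < n_iter")
  if (thin < 1L) stop_field("thin", "must be >= 1")
  if (target_ess < 0) stop_field("target_ess", "must be >= 0")
  structure(list(n_chains = n_chains, n_iter = n_iter, burn_in = burn_in,
                 target_ess = target_ess, thin = thin, seed = as.integer(seed)),
            class = "rsq_mcmc_config")
}

#' Assemble data for the global across-mountain model
#'
#' @param log_range natural-log range size per species.
#' @param mountain_id mountain identifier per species.
#' @param site_covariates data.frame with one row per mountain: a
#'   `mountain_id` column, numeric covariate columns (e.g. `dtr`, `ts`,
#'   `dmat`) and optionally a `land_type` column.
#' @return class `"rsq_global_data"`: list with `y`, `site` (integer index),
#'   `site_ids`, `V` (site-by-covariate matrix), `land_type` (or `NULL`).
#' @export
global_model_data <- function(log_range, mountain_id, site_covariates) {
  if (length(log_range) != length(mountain_id))
    stop("log_range and mountain_id lengths differ", call. = FALSE)
  if (any(!is.finite(log_range)))
    stop("log_range must be finite", call. = FALSE)
  site_ids <- site_covariates$mountain_id
  if (anyDuplicated(site_ids))
    stop("duplicated mountain_id in site_covariates", call. = FALSE)
  if (!all(mountain_id %in% site_ids))
    stop("species reference mountains missing from site_covariates", call. = FALSE)
  present <- site_ids %in% mountain_id
  if (!all(present)) {
    site_covariates <- site_covariates[present, , drop = FALSE]
    site_ids <- site_covariates$mountain_id
  }
  num_cols <- names(site_covariates)[vapply(site_covariates, is.numeric, TRUE)]
  V <- as.matrix(site_covariates[, num_cols, drop = FALSE])
  rownames(V) <- site_ids
  if (any(!is.finite(V)))
    stop("site covariates must be finite", call. = FALSE)
  structure(list(y = as.numeric(log_range),
                 site = match(mountain_id, site_ids),
                 site_ids = site_ids,
                 V = V,
                 land_type = site_covariates$land_type),
            class = "rsq_global_data")
}

# ---- blocked Gibbs engine for the global hierarchical normal model -------
#
# y_s ~ N(alpha_site[site], sigma2_RS)
# alpha_site ~ N(X theta, sigma2_site)         (X: site-level design)
# theta_j ~ N(0, 1/tau0), tau0 = 1e-6 (precision)
# 1/sigma2_RS, 1/sigma2_site ~ Gamma(1e-3, 1e-3)
#
# All full conditionals are conjugate; per-iteration cost is O(S + p^2)
# thanks to per-site sufficient statistics.
fit_global_engine <- function(y, site, X, coef_names, site_ids, mcmc,
                              fix_sigma2_RS = NULL, fix_sigma2_site = NULL,
                              store_loglik = TRUE, loglik_thin = 10L,
                              tau0 = 1e-6, a0 = 1e-3, b0 = 1e-3) {
  n <- length(y); S <- length(site_ids); p <- ncol(X)
  n_s <- tabulate(site, S)
  if (any(n_s == 0)) stop("every site needs at least one species", call. = FALSE)
  Sy <- as.vector(rowsum(y, site))
  sum_y2 <- sum(y * y)
  XtX <- crossprod(X)

  # moment-based initial values: empirical site means, least squares on them
  alpha0 <- Sy / n_s
  theta0 <- tryCatch(qr.solve(XtX + diag(1e-8, p), crossprod(X, alpha0)),
                     error = function(e) rep(0, p))
  res_within <- sum_y2 - sum(Sy^2 / n_s)
  tau_y0 <- 1 / max(res_within / max(n - S, 1), 1e-3)
  tau_a0 <- if (S >= 2) 1 / max(var(alpha0 - drop(X %*% theta0)), 1e-3) else 1
  if (!is.finite(tau_a0)) tau_a0 <- 1

  fixed_y <- !is.null(fix_sigma2_RS)
  fixed_a <- !is.null(fix_sigma2_site)
  if (fixed_y && fix_sigma2_RS <= 0) stop_field("fix_sigma2_RS", "must be > 0")
  if (fixed_a && fix_sigma2_site <= 0) stop_field("fix_sigma2_site", "must be > 0")

  par_names <- c(coef_names, sprintf("alpha_site[%s]", site_ids),
                 "sigma2_RS", "sigma2_site")
  npar <- p + S + 2

  # closed-form fast paths for the ubiquitous 1- and 2-column designs;
  # general Cholesky route for interaction / land-type designs
  x2 <- if (p == 2) X[, 2] else NULL
  run_segment <- function(state, n_it, n_keep, thin, keep_ll_every) {
    alpha <- state$alpha; theta <- state$theta
    tau_y <- state$tau_y; tau_a <- state$tau_a
    draws <- matrix(NA_real_, n_keep, npar)
    ll <- if (store_loglik)
      matrix(NA_real_, ceiling(n_keep / keep_ll_every), n) else NULL
    kept <- 0L; ll_kept <- 0L
    burn <- n_it - n_keep * thin
    for (it in seq_len(n_it)) {
      # alpha_site | .
      prec <- n_s * tau_y + tau_a
      mu_pr <- if (p == 1) rep.int(theta[1], S)
               else if (p == 2) theta[1] + theta[2] * x2
               else drop(X %*% theta)
      alpha <- (tau_y * Sy + tau_a * mu_pr) / prec + rnorm(S) / sqrt(prec)
      # theta | .
      if (p == 1) {
        A11 <- tau_a * S + tau0
        theta <- tau_a * sum(alpha) / A11 + rnorm(1) / sqrt(A11)
      } else if (p == 2) {
        A11 <- tau_a * S + tau0
        A12 <- tau_a * XtX[1, 2]
        A22 <- tau_a * XtX[2, 2] + tau0
        c1 <- tau_a * sum(alpha)
        c2 <- tau_a * sum(alpha * x2)
        L11 <- sqrt(A11); L21 <- A12 / L11; L22 <- sqrt(A22 - L21^2)
        w1 <- c1 / L11; w2 <- (c2 - L21 * w1) / L22
        m2 <- w2 / L22; m1 <- (w1 - L21 * m2) / L11
        z <- rnorm(2)
        u2 <- z[2] / L22; u1 <- (z[1] - L21 * u2) / L11
        theta <- c(m1 + u1, m2 + u2)
      } else {
        A <- tau_a * XtX
        diag(A) <- diag(A) + tau0
        U <- chol(A)
        bvec <- tau_a * crossprod(X, alpha)
        m_th <- backsolve(U, forwardsolve(t(U), bvec))
        theta <- drop(m_th + backsolve(U, rnorm(p)))
      }
      # precision of species-level noise
      if (!fixed_y) {
        sse_y <- sum_y2 - 2 * sum(alpha * Sy) + sum(n_s * alpha^2)
        tau_y <- rgamma(1, a0 + n / 2, rate = b0 + sse_y / 2)
      } else tau_y <- 1 / fix_sigma2_RS
      # precision of site-level noise
      if (!fixed_a) {
        mu_now <- if (p == 1) theta[1]
                  else if (p == 2) theta[1] + theta[2] * x2
                  else drop(X %*% theta)
        r <- alpha - mu_now
        tau_a <- rgamma(1, a0 + S / 2, rate = b0 + sum(r * r) / 2)
      } else tau_a <- 1 / fix_sigma2_site
      if (it > burn && (it - burn) %% thin == 0L) {
        kept <- kept + 1L
        draws[kept, ] <- c(theta, alpha, 1 / tau_y, 1 / tau_a)
        if (store_loglik && kept %% keep_ll_every == 0L) {
          ll_kept <- ll_kept + 1L
          ll[ll_kept, ] <- dnorm(y, alpha[site], 1 / sqrt(tau_y), log = TRUE)
        }
      }
    }
    list(draws = draws[seq_len(kept), , drop = FALSE],
         loglik = if (store_loglik) ll[seq_len(ll_kept), , drop = FALSE],
         state = list(alpha = alpha, theta = theta, tau_y = tau_y, tau_a = tau_a,
                      rng = .Random.seed))
  }

  n_keep0 <- (mcmc$n_iter - mcmc$burn_in) %/% mcmc$thin
  chains <- vector("list", mcmc$n_chains)
  lls <- vector("list", mcmc$n_chains)
  states <- vector("list", mcmc$n_chains)
  for (ch in seq_len(mcmc$n_chains)) {
    set.seed((mcmc$seed + 7919L * ch) %% .Machine$integer.max)
    st <- list(alpha = alpha0, theta = drop(theta0),
               tau_y = if (fixed_y) 1 / fix_sigma2_RS else tau_y0,
               tau_a = if (fixed_a) 1 / fix_sigma2_site else tau_a0)
    seg <- run_segment(st, mcmc$n_iter, n_keep0, mcmc$thin, loglik_thin)
    chains[[ch]] <- seg$draws; lls[[ch]] <- seg$loglik; states[[ch]] <- seg$state
  }

  # ESS-driven extension: add 10,000-iteration segments until every
  # parameter reaches the target, with a hard cap of 5 extensions; the
  # final sweep's ESS doubles as the reported diagnostic
  n_ext <- 0L
  repeat {
    ess <- apply_diag(chains, effective_sample_size_quiet)
    if (mcmc$target_ess <= 0 ||
        all(ess >= mcmc$target_ess, na.rm = TRUE) || n_ext >= 5L) break
    n_ext <- n_ext + 1L
    add_keep <- 10000L %/% mcmc$thin
    for (ch in seq_len(mcmc$n_chains)) {
      assign(".Random.seed", states[[ch]]$rng, envir = globalenv())
      seg <- run_segment(states[[ch]], add_keep * mcmc$thin, add_keep,
                         mcmc$thin, loglik_thin)
      chains[[ch]] <- rbind(chains[[ch]], seg$draws)
      if (store_loglik) lls[[ch]] <- rbind(lls[[ch]], seg$loglik)
      states[[ch]] <- seg$state
    }
  }

  for (ch in seq_along(chains)) colnames(chains[[ch]]) <- par_names
  diagnostics <- data.frame(
    parameter = par_names,
    rhat = if (mcmc$n_chains >= 2) apply_diag(chains, rhat) else NA_real_,
    ess = ess)

  structure(list(model = "global", draws = chains,
                 loglik = if (store_loglik) lls else NULL,
                 par_names = par_names, coef_names = coef_names,
                 site_ids = site_ids,
                 data = list(y = y, site = site, X = X),
                 mcmc = mcmc, diagnostics = diagnostics,
                 n_extensions = n_ext),
            class = "rsq_fit")
}

# apply a per-parameter diagnostic across a list of chain matrices
apply_diag <- function(chains, fun) {
  npar <- ncol(chains[[1]])
  vapply(seq_len(npar), function(j)
    fun(sapply(chains, function(m) m[, j])), numeric(1))
}

#' Fit the global across-mountain hierarchical model
#'
#' Species log range sizes are modelled as normal around a mountain-level
#' mean `alpha_site`, which is itself normal around a linear function of a
#' mountain-level climate covariate:
#' `y_i ~ N(alpha_site[site_i], sigma2_RS)`,
#' `alpha_site ~ N(alpha_V + beta_V * V_site, sigma2_site)`, with flat
#' normal priors (precision 1e-6) on `alpha_V`, `beta_V` and diffuse
#' `Gamma(1e-3, 1e-3)` priors on the two precisions. Sampling is by a
#' systematic-scan blocked Gibbs sampler with closed-form conjugate full
#' conditionals; results are deterministic given `mcmc$seed`.
#'
#' @param data an [global_model_data()] object.
#' @param covariate name of the covariate column in `data$V`, or `NULL`
#'   for an intercept-only model.
#' @param mcmc an [mcmc_config()].
#' @param fix_sigma2_RS,fix_sigma2_site optionally fix a variance instead
#'   of sampling it (used for closed-form validation).
#' @param store_loglik store pointwise log-likelihood draws (needed for
#'   WAIC/LOO)?
#' @param loglik_thin store the log-likelihood of every `loglik_thin`-th
#'   kept draw.
#' @return class `"rsq_fit"`; see [posterior_matrix()], [summary.rsq_fit()].
#' @export
fit_global <- function(data, covariate = NULL, mcmc = mcmc_config(),
                       fix_sigma2_RS = NULL, fix_sigma2_site = NULL,
                       store_loglik = TRUE, loglik_thin = 10L) {
  stopifnot(inherits(data, "rsq_global_data"))
  S <- length(data$site_ids)
  if (is.null(covariate)) {
    X <- matrix(1, S, 1)
    coef_names <- "alpha_V"
  } else {
    if (!covariate %in% colnames(data$V))
      stop(sprintf("covariate '%s' not found", covariate), call. = FALSE)
    v <- data$V[, covariate]
    if (S < 3) stop("need at least 3 sites to estimate a slope", call. = FALSE)
    if (var(v) == 0)
      stop("covariate is constant across sites; slope unidentifiable",
           call. = FALSE)
    X <- cbind(1, v)
    coef_names <- c("alpha_V", "beta_V")
  }
  fit_global_engine(data$y, data$site, X, coef_names, data$site_ids, mcmc,
                    fix_sigma2_RS, fix_sigma2_site, store_loglik, loglik_thin)
}

#' Fit the global model with a two-covariate interaction
#'
#' Site-level design with both main effects and their product. The strong
#' correlation of some covariate pairs makes their interactions
#' untrustworthy, so pairs whose absolute correlation exceeds `cor_guard`
#' are reported with a warning (not an error); a rank-deficient design is
#' an error.
#'
#' @inheritParams fit_global
#' @param covariates length-2 character: the two main-effect columns.
#' @param cor_guard absolute-correlation warning threshold, default 0.6.
#' @return class `"rsq_fit"` with coefficients `alpha_V`, `beta_<v1>`,
#'   `beta_<v2>` and `beta_<v1>:<v2>`.
#' @export
fit_global_interaction <- function(data, covariates, mcmc = mcmc_config(),
                                   cor_guard = 0.6, store_loglik = TRUE,
                                   loglik_thin = 10L) {
  stopifnot(inherits(data, "rsq_global_data"), length(covariates) == 2)
  v1 <- data$V[, covariates[1]]; v2 <- data$V[, covariates[2]]
  r <- cor(v1, v2)
  if (is.finite(r) && abs(r) > cor_guard)
    warning(sprintf("|cor(%s, %s)| = %.2f exceeds guard %.2f; interaction may be unreliable",
                    covariates[1], covariates[2], abs(r), cor_guard),
            call. = FALSE)
  X <- cbind(1, v1, v2, v1 * v2)
  if (qr(X)$rank < 4)
    stop("rank-deficient interaction design", call. = FALSE)
  coef_names <- c("alpha_V", paste0("beta_", covariates[1]),
                  paste0("beta_", covariates[2]),
                  paste0("beta_", covariates[1], ":", covariates[2]))
  fit_global_engine(data$y, data$site, X, coef_names, data$site_ids, mcmc,
                    store_loglik = store_loglik, loglik_thin = loglik_thin)
}

#' Fit the global model with separate island/continental regressions
#'
#' Indicator (cell-means) coding gives each land type its own intercept and
#' slope, so the island and continental range-size/covariate relationships
#' can be compared directly.
#'
#' @inheritParams fit_global
#' @param covariate name of the covariate column.
#' @return class `"rsq_fit"` with coefficients `alpha_island`,
#'   `alpha_continental`, `beta_island`, `beta_continental`.
#' @export
fit_global_by_landtype <- function(data, covariate, mcmc = mcmc_config(),
                                   store_loglik = TRUE, loglik_thin = 10L) {
  stopifnot(inherits(data, "rsq_global_data"))
  lt <- data$land_type
  if (is.null(lt)) stop("data has no land_type", call. = FALSE)
  isl <- lt == "island"
  if (sum(isl) < 2 || sum(!isl) < 2)
    stop("need at least 2 sites of each land type", call. = FALSE)
  v <- data$V[, covariate]
  X <- cbind(as.numeric(isl), as.numeric(!isl), v * isl, v * !isl)
  coef_names <- c("alpha_island", "alpha_continental",
                  "beta_island", "beta_continental")
  fit_global_engine(data$y, data$site, X, coef_names, data$site_ids, mcmc,
                    store_loglik = store_loglik, loglik_thin = loglik_thin)
}

#' Combined posterior draw matrix
#'
#' @param fit an `"rsq_fit"`.
#' @param pars optional character vector of parameter names.
#' @return matrix of post-burn-in draws, chains concatenated in order.
#' @export
posterior_matrix <- function(fit, pars = NULL) {
  m <- do.call(rbind, fit$draws)
  if (!is.null(pars)) m <- m[, pars, drop = FALSE]
  m
}

#' @export
print.rsq_fit <- function(x, ...) {
  cat(sprintf("%s model fit: %d chains x %d kept draws, %d parameters\n",
              x$model, length(x$draws), nrow(x$draws[[1]]),
              length(x$par_names)))
  if (x$n_extensions > 0)
    cat(sprintf("  chains extended %d time(s) to reach the ESS target\n",
                x$n_extensions))
  cat(sprintf("  max R-hat %.4f, min ESS %.0f\n",
              suppressWarnings(max(x$diagnostics$rhat, na.rm = TRUE)),
              min(x$diagnostics$ess, na.rm = TRUE)))
  invisible(x)
}

#' Posterior summaries of a model fit
#'
#' @param object an `"rsq_fit"`.
#' @param probs credible interval probabilities (equal-tailed).
#' @param ... unused.
#' @return data.frame: posterior mean, sd, credible bounds, `prob_negative`,
#'   R-hat and ESS per parameter.
#' @export
summary.rsq_fit <- function(object, probs = c(0.025, 0.975), ...) {
  m <- posterior_matrix(object)
  data.frame(
    parameter = colnames(m),
    mean = colMeans(m),
    sd = apply(m, 2, sd),
    lower = apply(m, 2, quantile, probs[1]),
    upper = apply(m, 2, quantile, probs[2]),
    prob_negative = colMeans(m < 0),
    rhat = object$diagnostics$rhat,
    ess = object$diagnostics$ess,
    row.names = NULL)
}
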