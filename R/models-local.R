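#' Assemble data for the local within-mountain model
#'
#' Each species contributes its log range size and the climate value at its
#' range midpoint. Mountains where the covariate does not vary between at
#' least two species cannot identify a slope; they are flagged and their
#' species excluded from the fit.
#'
#' @param log_range natural-log range size per species.
#' @param mountain_id mountain identifier per species.
#' @param v covariate (e.g. midpoint DTR or TS) per species.
#' @return class `"rsq_local_data"`: `y`, `site`, `site_ids`, `v`,
#'   `flagged_sites` (character, excluded mountains).
#' @export
local_model_data <- function(log_range, mountain_id, v) {
  if (length(log_range) != length(mountain_id) || length(v) != length(log_range))
    stop("log_range, mountain_id and v lengths differ", call. = FALSE)
  if (any(!is.finite(log_range)) || any(!is.finite(v)))
    stop("log_range and v must be finite", call. = FALSE)
  ids <- unique(mountain_id)
  ok <- vapply(ids, function(id) {
    vv <- v[mountain_id == id]
    length(vv) >= 2 && length(unique(vv)) >= 2
  }, logical(1))
  flagged <- ids[!ok]
  keep <- mountain_id %in% ids[ok]
  site_ids <- ids[ok]
  structure(list(y = as.numeric(log_range[keep]),
                 site = match(mountain_id[keep], site_ids),
                 site_ids = site_ids,
                 v = as.numeric(v[keep]),
                 flagged_sites = as.character(flagged)),
            class = "rsq_local_data")
}

#' Fit the local within-mountain model
#'
#' Species log range sizes are regressed on the covariate at the species'
#' range midpoint with mountain-specific intercepts and slopes and a single
#' residual variance shared across all mountains:
#' `y_i ~ N(alpha[site_i] + beta[site_i] * v_i, sigma2)`, flat normal
#' priors (precision 1e-6) on every `alpha` and `beta`, and a diffuse
#' `Gamma(1e-3, 1e-3)` prior on the residual precision. Sampling is a
#' blocked Gibbs sampler: each site's `(alpha, beta)` pair is drawn jointly
#' from its bivariate-normal full conditional, then the shared precision
#' from its gamma full conditional.
#'
#' @param data an [local_model_data()] object.
#' @param mcmc an [mcmc_config()].
#' @param store_loglik,loglik_thin as in [fit_global()].
#' @return class `"rsq_fit"` with parameters `alpha[<id>]`, `beta[<id>]`
#'   and `sigma2`.
#' @export
fit_local <- function(data, mcmc = mcmc_config(), store_loglik = TRUE,
                      loglik_thin = 10L) {
  stopifnot(inherits(data, "rsq_local_data"))
  y <- data$y; site <- data$site; v <- data$v
  S <- length(data$site_ids); n <- length(y)
  tau0 <- 1e-6; a0 <- 1e-3; b0 <- 1e-3

  n_s <- tabulate(site, S)
  Sv <- as.vector(rowsum(v, site))
  Svv <- as.vector(rowsum(v * v, site))
  Sy <- as.vector(rowsum(y, site))
  Svy <- as.vector(rowsum(v * y, site))
  Syy <- as.vector(rowsum(y * y, site))

  # per-site least-squares starts and pooled residual variance
  det_s <- n_s * Svv - Sv^2
  b_ols <- (n_s * Svy - Sv * Sy) / det_s
  a_ols <- (Sy - b_ols * Sv) / n_s
  sse0 <- sum(Syy - 2 * a_ols * Sy - 2 * b_ols * Svy + a_ols^2 * n_s +
                2 * a_ols * b_ols * Sv + b_ols^2 * Svv)
  tau_init <- 1 / max(sse0 / max(n - 2 * S, 1), 1e-3)

  par_names <- c(sprintf("alpha[%s]", data$site_ids),
                 sprintf("beta[%s]", data$site_ids), "sigma2")
  npar <- 2L * S + 1L

  run_segment <- function(state, n_it, n_keep, thin, keep_ll_every) {
    a <- state$a; b <- state$b; tau <- state$tau
    draws <- matrix(NA_real_, n_keep, npar)
    ll <- if (store_loglik)
      matrix(NA_real_, ceiling(n_keep / keep_ll_every), n) else NULL
    kept <- 0L; ll_kept <- 0L
    burn <- n_it - n_keep * thin
    for (it in seq_len(n_it)) {
      # joint (alpha_s, beta_s) conditional, one 2x2 solve per site,
      # vectorised across sites via explicit Cholesky formulas
      A11 <- tau * n_s + tau0
      A12 <- tau * Sv
      A22 <- tau * Svv + tau0
      c1 <- tau * Sy
      c2 <- tau * Svy
      L11 <- sqrt(A11)
      L21 <- A12 / L11
      L22 <- sqrt(A22 - L21^2)
      w1 <- c1 / L11
      w2 <- (c2 - L21 * w1) / L22
      m2 <- w2 / L22
      m1 <- (w1 - L21 * m2) / L11
      z1 <- rnorm(S); z2 <- rnorm(S)
      u2 <- z2 / L22
      u1 <- (z1 - L21 * u2) / L11
      a <- m1 + u1
      b <- m2 + u2
      sse <- sum(Syy - 2 * a * Sy - 2 * b * Svy + a^2 * n_s +
                   2 * a * b * Sv + b^2 * Svv)
      tau <- rgamma(1, a0 + n / 2, rate = b0 + max(sse, 0) / 2)
      if (it > burn && (it - burn) %% thin == 0L) {
        kept <- kept + 1L
        draws[kept, ] <- c(a, b, 1 / tau)
        if (store_loglik && kept %% keep_ll_every == 0L) {
          ll_kept <- ll_kept + 1L
          ll[ll_kept, ] <- dnorm(y, a[site] + b[site] * v, 1 / sqrt(tau),
                                 log = TRUE)
        }
      }
    }
    list(draws = draws[seq_len(kept), , drop = FALSE],
         loglik = if (store_loglik) ll[seq_len(ll_kept), , drop = FALSE],
         state = list(a = a, b = b, tau = tau, rng = .Random.seed))
  }

  n_keep0 <- (mcmc$n_iter - mcmc$burn_in) %/% mcmc$thin
  chains <- vector("list", mcmc$n_chains)
  lls <- vector("list", mcmc$n_chains)
  states <- vector("list", mcmc$n_chains)
  for (ch in seq_len(mcmc$n_chains)) {
    set.seed((mcmc$seed + 7919L * ch) %% .Machine$integer.max)
    st <- list(a = a_ols, b = b_ols, tau = tau_init)
    seg <- run_segment(st, mcmc$n_iter, n_keep0, mcmc$thin, loglik_thin)
    chains[[ch]] <- seg$draws; lls[[ch]] <- seg$loglik; states[[ch]] <- seg$state
  }

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

  structure(list(model = "local", draws = chains,
                 loglik = if (store_loglik) lls else NULL,
                 par_names = par_names,
                 coef_names = c(sprintf("beta[%s]", data$site_ids)),
                 site_ids = data$site_ids,
                 flagged_sites = data$flagged_sites,
                 data = list(y = y, site = site, v = v),
                 mcmc = mcmc, diagnostics = diagnostics,
                 n_extensions = n_ext),
            class = "rsq_fit")
}
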