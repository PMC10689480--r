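test_that("WAIC matches an independently coded pointwise oracle", {
  set.seed(61)
  D <- 150; n <- 6
  ll <- matrix(rnorm(D * n, -1, 0.3), D, n)
  w <- compute_waic(ll)
  # oracle: explicit loops, no shared code
  lpd <- p <- numeric(n)
  for (i in seq_len(n)) {
    lpd[i] <- log(mean(exp(ll[, i])))
    p[i] <- var(ll[, i])
  }
  expect_equal(w$waic, -2 * sum(lpd - p), tolerance = 1e-10)
  expect_equal(w$p_waic, sum(p), tolerance = 1e-10)
  expect_equal(w$se, sqrt(n * var(-2 * (lpd - p))), tolerance = 1e-10)
})

test_that("WAIC doubles under dataset duplication and degenerates cleanly", {
  set.seed(62)
  ll <- matrix(rnorm(500 * 4, -2, 0.5), 500, 4)
  expect_equal(compute_waic(cbind(ll, ll))$waic, 2 * compute_waic(ll)$waic)
  same <- matrix(rep(rnorm(4, -2, 1), each = 200), 200, 4)
  w <- compute_waic(same)
  expect_equal(w$p_waic, 0)
  ll_bad <- ll; ll_bad[3, 2] <- -Inf
  expect_error(compute_waic(ll_bad), "observation")
  expect_error(compute_waic(ll[1:50, ]), "100")
})

test_that("PSIS-LOO degenerates to the plain lpd for identical draws and is order-invariant", {
  set.seed(63)
  vals <- rnorm(5, -1.5, 0.4)
  same <- matrix(rep(vals, each = 300), 300, 5)
  l <- compute_loo(same)
  expect_equal(l$elpd_loo, sum(vals), tolerance = 1e-10)
  ll <- matrix(rnorm(400 * 8, -1, 0.4), 400, 8)
  perm <- sample(8)
  expect_equal(compute_loo(ll[, perm])$elpd_loo, compute_loo(ll)$elpd_loo)
  expect_equal(length(compute_loo(ll)$pareto_k), 8)
})

test_that("the generalized Pareto tail fit recovers known shapes", {
  rgpd <- function(n, k, sigma) sigma / k * (runif(n)^(-k) - 1)
  set.seed(64)
  for (k in c(-0.3, 0.2, 0.6)) {
    x <- rgpd(3000, k, 1)
    fit <- rangesqueeze:::gpd_fit_tail(x)
    expect_equal(fit$k, k, tolerance = 0.12)
    expect_equal(fit$sigma, 1, tolerance = 0.15)
  }
})

test_that("posterior slope probabilities and R2 behave at the limits", {
  expect_equal(posterior_prob_negative(c(-1, -2, -0.1)), 1)
  expect_equal(posterior_prob_negative(c(1, 2, 0.1)), 0)
  set.seed(65)
  expect_equal(posterior_prob_negative(rnorm(20000)), 0.5, tolerance = 0.02)

  # noiseless site means: R2 approaches 1; permuted covariate: near 0
  v <- seq(6, 16, length.out = 12)
  mk_world_fit <- function(vv, sigma_site) {
    y_site <- 6 - 0.2 * vv + rnorm(12, 0, sigma_site)
    y <- rep(y_site, each = 30) + rnorm(360, 0, 0.3)
    gd <- global_model_data(y, rep(sprintf("m%02d", 1:12), each = 30),
                            data.frame(mountain_id = sprintf("m%02d", 1:12),
                                       dtr = vv))
    fit_global(gd, "dtr", quick_mcmc(seed = 66), store_loglik = FALSE)
  }
  f_clean <- mk_world_fit(v, sigma_site = 0.001)
  expect_gt(bayesian_r2(f_clean)$estimate, 0.9)
  f_null <- mk_world_fit(sample(v), sigma_site = 0.5)
  r2_null <- bayesian_r2(f_null)$estimate
  expect_true(r2_null >= 0 && r2_null <= 1)
  expect_lt(r2_null, bayesian_r2(f_clean)$estimate)
})

test_that("posterior predictive checks pass on well-specified data and flag gross misfit", {
  set.seed(67)
  y <- rep(rnorm(8, 5, 0.3), each = 40) + rnorm(320, 0, 0.5)
  gd <- global_model_data(y, rep(sprintf("m%d", 1:8), each = 40),
                          data.frame(mountain_id = sprintf("m%d", 1:8),
                                     dtr = runif(8, 6, 16)))
  f <- fit_global(gd, "dtr", quick_mcmc(seed = 68), store_loglik = FALSE)
  ppc <- posterior_predictive_check(f, n_rep = 200, seed = 5)
  expect_lt(mean(ppc$flagged), 0.1)
  expect_identical(ppc, posterior_predictive_check(f, n_rep = 200, seed = 5))
  # gross misfit: shift the observed responses after fitting
  f_bad <- f
  f_bad$data$y <- f$data$y * 10
  ppc_bad <- posterior_predictive_check(f_bad, statistics = "mean",
                                        n_rep = 200, seed = 5)
  expect_true(all(ppc_bad$flagged))
})

test_that("local slope classification separates sign and uncertainty", {
  set.seed(69)
  f <- fake_local_fit(list(a = rnorm(2000, 0.5, 0.05),
                           b = rnorm(2000, -0.4, 0.05),
                           c = rnorm(2000, 0.05, 0.3),
                           d = rnorm(2000, -0.03, 0.3)))
  cl <- classify_local_slopes(f)
  tab <- cl$table
  expect_equal(tab$sign, c("positive", "negative", "positive", "negative"))
  expect_equal(tab$low_uncertainty, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(unname(cl$aggregates["pct_positive"]), 50)
  expect_equal(unname(cl$aggregates["pct_negative"]), 50)
  expect_equal(unname(cl$aggregates["pct_positive_low_unc"]), 25)
  expect_equal(unname(cl$aggregates["pct_negative_low_unc"]), 25)
  expect_equal(tab$mean_sd_ratio, tab$mean / tab$sd)
})

test_that("model comparison table is sorted and complete", {
  w <- small_world(n_mountains = 8, n_species = 30, seed = 10)
  gd <- rangesqueeze:::world_to_global_data(w)
  fits <- list(dtr = fit_global(gd, "dtr", quick_mcmc(seed = 1), loglik_thin = 2),
               ts = fit_global(gd, "ts", quick_mcmc(seed = 2), loglik_thin = 2))
  cmp <- compare_models(fits)
  expect_setequal(cmp$model, c("dtr", "ts"))
  expect_true(!is.unsorted(cmp$waic))
  expect_true(all(is.finite(cmp$elpd_loo)))
})
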