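test_that("global fits are deterministic given the seed and exchangeable", {
  w <- small_world(n_mountains = 5, n_species = 25, seed = 2)
  gd <- rangesqueeze:::world_to_global_data(w)
  f1 <- fit_global(gd, "dtr", quick_mcmc(seed = 9), store_loglik = FALSE)
  f2 <- fit_global(gd, "dtr", quick_mcmc(seed = 9), store_loglik = FALSE)
  expect_identical(f1$draws, f2$draws)
  # permuting species leaves the sufficient statistics, hence the draws
  perm <- sample(length(gd$y))
  rs <- compute_range_size(w$species)[perm]
  gd_p <- global_model_data(transform_range_sizes(rs),
                            w$species$mountain_id[perm],
                            data.frame(mountain_id = gd$site_ids, gd$V))
  f3 <- fit_global(gd_p, "dtr", quick_mcmc(seed = 9), store_loglik = FALSE)
  expect_equal(posterior_matrix(f1), posterior_matrix(f3))
})

test_that("with variances fixed the intercept posterior matches the conjugate closed form", {
  set.seed(71)
  sigma2 <- 0.25   # species-level variance, known
  sigma2_a <- 0.01 # small site-level variance, known
  y <- rnorm(40, 5, sqrt(sigma2))
  gd <- global_model_data(y, rep("m1", 40),
                          data.frame(mountain_id = "m1", dtr = 10))
  f <- fit_global(gd, covariate = NULL,
                  mcmc_config(n_chains = 2, n_iter = 30000, burn_in = 5000,
                              target_ess = 0, seed = 3),
                  fix_sigma2_RS = sigma2, fix_sigma2_site = sigma2_a,
                  store_loglik = FALSE)
  a <- posterior_matrix(f, "alpha_V")[, 1]
  # everything Gaussian: marginally ybar ~ N(alpha_V, sigma2/n + sigma2_a),
  # prior alpha_V ~ N(0, 1e6), so the posterior is the textbook
  # known-variance normal-mean posterior
  prec_data <- 1 / (sigma2 / 40 + sigma2_a)
  prec <- prec_data + 1e-6
  expect_equal(mean(a), prec_data * mean(y) / prec, tolerance = 0.005)
  expect_equal(sd(a), sqrt(1 / prec), tolerance = 0.01)
})

test_that("the global model recovers a planted negative slope", {
  w <- generate_world(
    world_config(n_mountains = 15, n_species_per_mountain = 60,
                 span_range = c(4000, 6000), singleton_fraction = 0, seed = 12),
    true_parameters(alpha_V = 6, beta_V = -0.1, sigma2_site = 0.04,
                    sigma2_RS = 0.36))
  gd <- rangesqueeze:::world_to_global_data(w)
  f <- fit_global(gd, "dtr", quick_mcmc(seed = 4, n_iter = 4000, burn_in = 1000),
                  store_loglik = FALSE)
  b <- posterior_matrix(f, "beta_V")[, 1]
  expect_lt(abs(mean(b) + 0.1), 4 * sd(b))
  expect_gt(posterior_prob_negative(b), 0.95)
})

test_that("degenerate designs are refused before sampling", {
  y <- rnorm(30)
  ids <- rep(c("a", "b", "c"), each = 10)
  gd_const <- global_model_data(y, ids,
                                data.frame(mountain_id = c("a", "b", "c"),
                                           dtr = c(5, 5, 5)))
  expect_error(fit_global(gd_const, "dtr", quick_mcmc()), "constant")
  gd2 <- global_model_data(y[1:20], ids[1:20],
                           data.frame(mountain_id = c("a", "b"),
                                      dtr = c(5, 7)))
  expect_error(fit_global(gd2, "dtr", quick_mcmc()), "3 sites")
  expect_error(global_model_data(y, rep("zz", 30),
                                 data.frame(mountain_id = "a", dtr = 1)),
               "missing")
})

test_that("interaction fits guard correlation and rank", {
  set.seed(72)
  ids <- sprintf("m%02d", 1:12)
  v1 <- runif(12, 6, 16); v2 <- runif(12, 1, 8)
  y_site <- 5 - 0.1 * v1 + 0.05 * v2 + rnorm(12, 0, 0.1)
  y <- rep(y_site, each = 25) + rnorm(300, 0, 0.4)
  gd <- global_model_data(y, rep(ids, each = 25),
                          data.frame(mountain_id = ids, dtr = v1, ts = v2,
                                     tsdup = v1))
  f <- fit_global_interaction(gd, c("dtr", "ts"),
                              quick_mcmc(seed = 7, n_iter = 4000,
                                         burn_in = 1000),
                              store_loglik = FALSE)
  ci <- quantile(posterior_matrix(f, "beta_dtr:ts")[, 1], c(0.025, 0.975))
  expect_true(ci[1] < 0 && ci[2] > 0)  # no interaction was planted
  expect_error(suppressWarnings(
    fit_global_interaction(gd, c("dtr", "tsdup"), quick_mcmc())), "rank")
  hi <- data.frame(mountain_id = ids, a = v1, b = v1 + rnorm(12, 0, 0.1))
  gd_hi <- global_model_data(y, rep(ids, each = 25), hi)
  expect_warning(fit_global_interaction(gd_hi, c("a", "b"),
                                        quick_mcmc(n_iter = 600, burn_in = 100),
                                        store_loglik = FALSE),
                 "guard")
})

test_that("land-type fits estimate separate island and continental slopes", {
  set.seed(73)
  ids <- sprintf("m%02d", 1:16)
  land <- rep(c("island", "continental"), each = 8)
  v <- c(runif(8, 5, 10), runif(8, 10, 16))
  y_site <- ifelse(land == "island", 6.3, 6.0) - 0.1 * v
  y <- rep(y_site, each = 40) + rnorm(640, 0, 0.4)
  gd <- global_model_data(y, rep(ids, each = 40),
                          data.frame(mountain_id = ids, land_type = land,
                                     dtr = v))
  f <- fit_global_by_landtype(gd, "dtr",
                              quick_mcmc(seed = 8, n_iter = 6000,
                                         burn_in = 1500),
                              store_loglik = FALSE)
  m <- posterior_matrix(f)
  dslope <- m[, "beta_island"] - m[, "beta_continental"]
  ci <- quantile(dslope, c(0.025, 0.975))
  expect_true(ci[1] < 0 && ci[2] > 0)  # equal slopes planted
  dint <- m[, "alpha_island"] - m[, "alpha_continental"]
  expect_gt(mean(dint), 0)             # island intercept planted higher
  gd_one <- global_model_data(y[1:320], rep(ids[1:8], each = 40),
                              data.frame(mountain_id = ids[1:8],
                                         land_type = land[1:8], dtr = v[1:8]))
  expect_error(fit_global_by_landtype(gd_one, "dtr", quick_mcmc()),
               "land type")
})

test_that("chains extend until the ESS target is reached", {
  w <- small_world(n_mountains = 5, n_species = 20, seed = 14)
  gd <- rangesqueeze:::world_to_global_data(w)
  cfg <- mcmc_config(n_chains = 2, n_iter = 1200, burn_in = 1000,
                     target_ess = 800, seed = 2)
  f <- fit_global(gd, "dtr", cfg, store_loglik = FALSE)
  expect_gt(f$n_extensions, 0)
  expect_true(all(f$diagnostics$ess >= 800))
})
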