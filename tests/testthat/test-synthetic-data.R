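test_that("island mountains draw lower DTR than continental ones", {
  cfg <- world_config(n_mountains = 200, island_fraction = 0.5,
                      dtr_island = c(8, 1.5), dtr_continental = c(13, 2),
                      n_species_per_mountain = 1, seed = 11)
  m <- generate_mountains(cfg)
  dtr_by_mtn <- tapply(m$bands$dtr, m$bands$mountain_id, mean)
  land <- m$meta$land_type[match(names(dtr_by_mtn), m$meta$mountain_id)]
  expect_lt(mean(dtr_by_mtn[land == "island"]),
            mean(dtr_by_mtn[land == "continental"]))
})

test_that("mountain bands tile the domain and MAT follows the lapse rate", {
  cfg <- world_config(n_mountains = 12, lapse_rate = 0.5, seed = 2)
  m <- generate_mountains(cfg)
  for (id in m$meta$mountain_id) {
    b <- m$bands[m$bands$mountain_id == id, ]
    i <- match(id, m$meta$mountain_id)
    expect_equal(b$band_lower[1], m$meta$domain_min[i])
    expect_equal(b$band_upper[nrow(b)], m$meta$domain_max[i])
    expect_true(all(diff(b$band_lower) == 100))
    expect_true(all(b$band_upper - b$band_lower == 100))
    # lapse rate: MAT drops by 0.5 degC per 100 m band
    expect_equal(diff(b$mat), rep(-0.5, nrow(b) - 1), tolerance = 1e-10)
  }
  expect_true(all(m$meta$domain_max - m$meta$domain_min >= 1500))
})

test_that("degenerate and deterministic generator contracts hold", {
  empty <- generate_mountains(world_config(n_mountains = 0))
  expect_s3_class(empty, "rsq_mountains")
  expect_equal(nrow(empty$meta), 0)
  cfg <- world_config(n_mountains = 5, n_species_per_mountain = 20, seed = 42)
  expect_identical(generate_mountains(cfg), generate_mountains(cfg))
  expect_identical(generate_world(cfg), generate_world(cfg))
  expect_error(world_config(island_fraction = 1.2), "island_fraction")
  expect_error(world_config(span_range = c(1000, 3000)), "span_range")
  expect_error(world_config(singleton_fraction = -0.1), "singleton_fraction")
})

test_that("zero-variance limit pins species log ranges to the site line", {
  cfg <- world_config(n_mountains = 4, n_species_per_mountain = 30,
                      singleton_fraction = 0, seed = 5)
  tp <- true_parameters(alpha_V = 5, beta_V = -0.1,
                        sigma2_site = 0, sigma2_RS = 0)
  mtns <- generate_mountains(cfg)
  sp <- generate_species_ranges(mtns, tp, cfg)
  v <- attr(sp, "true_covariate")
  expected <- 5 - 0.1 * v[sp$mountain_id]
  expect_equal(log(sp$max_elev - sp$min_elev), unname(expected),
               tolerance = 1e-9)
})

test_that("negative generating slope yields a negative covariate correlation", {
  cfg <- world_config(n_mountains = 40, n_species_per_mountain = 50,
                      singleton_fraction = 0, seed = 7)
  tp <- true_parameters(alpha_V = 5.5, beta_V = -0.10,
                        sigma2_site = 0.01, sigma2_RS = 0.04)
  w <- generate_world(cfg, tp)
  v <- attr(w$species, "true_covariate")
  mean_lr <- tapply(log(w$species$max_elev - w$species$min_elev),
                    w$species$mountain_id, mean)
  expect_lt(cor(v[names(mean_lr)], mean_lr), 0)
})

test_that("within-mountain mean log range obeys the CLT around the site mean", {
  cfg <- world_config(n_mountains = 1, n_species_per_mountain = 1000,
                      singleton_fraction = 0, span_range = c(5000, 6000),
                      seed = 9)
  sigma_RS <- 0.4
  tp <- true_parameters(alpha_V = 5, beta_V = 0, sigma2_site = 0,
                        sigma2_RS = sigma_RS^2)
  w <- generate_world(cfg, tp)
  lr <- log(w$species$max_elev - w$species$min_elev)
  expect_lt(abs(mean(lr) - 5), 3 * sigma_RS / sqrt(1000))
})

test_that("singleton fraction and domain containment are honored", {
  cfg <- world_config(n_mountains = 8, n_species_per_mountain = 200,
                      singleton_fraction = 0.2, seed = 13)
  w <- generate_world(cfg)
  sp <- w$species
  expect_equal(mean(sp$min_elev == sp$max_elev), 0.2, tolerance = 0.01)
  meta <- w$mountains$meta
  for (i in seq_len(nrow(meta))) {
    s <- sp[sp$mountain_id == meta$mountain_id[i], ]
    expect_true(all(s$min_elev >= meta$domain_min[i] - 1e-9))
    expect_true(all(s$max_elev <= meta$domain_max[i] + 1e-9))
  }
})

test_that("paleo series honors stepping, amplitude, and determinism", {
  p <- generate_paleo_series(66, mean = 12, amplitude = 1.4, seed = 3)
  expect_equal(nrow(p), 66)
  expect_equal(p$year, 30 * (0:65))
  expect_lte(max(p$year), 1980)
  expect_equal(max(p$mat) - min(p$mat), 1.4, tolerance = 1e-12)
  expect_identical(p, generate_paleo_series(66, mean = 12, amplitude = 1.4,
                                            seed = 3))
  flat <- generate_paleo_series(10, mean = 8, amplitude = 0)
  expect_equal(delta_mat(flat), 0)
  expect_error(generate_paleo_series(1), "n_points")
})

test_that("suitable habitat span matches its closed form and shrinks with variability", {
  expect_equal(suitable_habitat_span(0, 20, delta_t = 0, lapse_rate = 0.5), 4000)
  expect_equal(suitable_habitat_span(0, 20, delta_t = 20, lapse_rate = 0.5), 0)
  expect_gt(suitable_habitat_span(0, 20, 5), suitable_habitat_span(0, 20, 10))
  # non-increasing in delta_t across random tolerance windows
  set.seed(31)
  for (i in 1:50) {
    tl <- runif(1, -10, 10); tu <- tl + runif(1, 1, 30)
    lapse <- runif(1, 0.2, 1)
    dt <- sort(runif(2, 0, 40))
    expect_gte(suitable_habitat_span(tl, tu, dt[1], lapse),
               suitable_habitat_span(tl, tu, dt[2], lapse))
  }
  expect_error(suitable_habitat_span(0, 20, 5, lapse_rate = 0), "lapse_rate")
  expect_error(suitable_habitat_span(5, 5, 1), "t_upper")
})

test_that("raster pair fixtures have closed-form band means", {
  rp <- generate_raster_pair(c(15, 12), elevation_relief = 2500,
                             climate_fn = function(z) 7, seed = 4)
  zb <- zonal_band_means(rp$dem, rp$climate)
  expect_true(all(abs(zb$mean - 7) < 1e-12))
  lin <- generate_raster_pair(c(20, 20), elevation_relief = 3000,
                              climate_fn = function(z) 30 - 0.004 * z, seed = 6)
  zb2 <- zonal_band_means(lin$dem, lin$climate)
  # brute-force oracle: group pixels by band, average elevation, map through fn
  k <- floor(as.numeric(lin$dem) / 100)
  for (i in seq_len(nrow(zb2))) {
    px <- as.numeric(lin$dem)[k == zb2$band_lower[i] / 100]
    expect_equal(zb2$mean[i], 30 - 0.004 * mean(px), tolerance = 1e-10)
  }
  expect_identical(generate_raster_pair(c(5, 5), seed = 8),
                   generate_raster_pair(c(5, 5), seed = 8))
})
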