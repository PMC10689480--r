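#' Configuration of a synthetic mountain world
#'
#' Bundles every knob of the synthetic-data generator: how many mountains,
#' how many of them are islands, the span of their elevation gradients, the
#' island/continental contrast in diurnal temperature range (DTR), lapse
#' rate, per-mountain species counts and the target fraction of singleton
#' species (range size 0 m).
#'
#' Defaults emulate the structure of a global compilation of mountain
#' floras: 44 gradients of which 15 are on islands, spans between 1500 and
#' 6000 m, island mountains with markedly lower DTR than continental ones
#' (ocean buffering), a 0.5 degC per 100 m lapse rate, about two thousand
#' species ranges per mountain and a modest singleton fraction.
#'
#' @param n_mountains number of mountains.
#' @param island_fraction proportion of mountains that are islands, in
#'   `[0, 1]`.
#' @param span_range length-2 numeric, min/max elevation span in m; the
#'   minimum must be at least 1500 m (the inclusion rule for gradients).
#' @param dtr_island,dtr_continental length-2 numeric `(mean, sd)` of the
#'   mountain-level diurnal temperature range in degC.
#' @param ts_range length-2 numeric, min/max temperature seasonality
#'   (sd of monthly mean temperatures, degC) across mountains.
#' @param lapse_rate temperature lapse rate in degC per 100 m of elevation.
#' @param base_mat_range length-2 numeric, min/max sea-level mean annual
#'   temperature (degC) across mountains.
#' @param ap_range length-2 numeric, min/max annual precipitation (mm).
#' @param n_species_per_mountain single count, or length-2 `(min, max)` from
#'   which per-mountain counts are drawn uniformly.
#' @param singleton_fraction target proportion of species emitted with
#'   `min_elev == max_elev`.
#' @param dtr_elev_slope,ts_elev_slope within-mountain change of DTR / TS in
#'   degC per km of elevation (gives the local model an identifiable
#'   covariate gradient).
#' @param band_noise_sd sd of band-level climate noise (degC).
#' @param paleo_amplitude_range length-2 numeric, min/max max-minus-min
#'   amplitude (degC) of per-mountain paleo mean-annual-temperature series.
#' @param paleo_n_points number of 30-year means per paleo series (67 covers
#'   0--1980 AD in 30-year steps).
#' @param seed integer seed; all generators are pure functions of
#'   (config, seed).
#'
#' @return an object of class `"rsq_world_config"` (a validated list).
#' @seealso [generate_mountains()], [generate_world()]
#' @export
world_config <- function(n_mountains = 44L,
                         island_fraction = 15 / 44,
                         span_range = c(1500, 6000),
                         dtr_island = c(8, 1.5),
                         dtr_continental = c(13, 2),
                         ts_range = c(0.5, 8),
                         lapse_rate = 0.5,
                         base_mat_range = c(10, 28),
                         ap_range = c(500, 3000),
                         n_species_per_mountain = 2000L,
                         singleton_fraction = 0.15,
                         dtr_elev_slope = 0.3,
                         ts_elev_slope = 0.4,
                         band_noise_sd = 0.05,
                         paleo_amplitude_range = c(0.4, 1.5),
                         paleo_n_points = 67L,
                         seed = 1L) {
  cfg <- list(
    n_mountains = as.integer(n_mountains),
    island_fraction = island_fraction,
    span_range = as.numeric(span_range),
    dtr_island = as.numeric(dtr_island),
    dtr_continental = as.numeric(dtr_continental),
    ts_range = as.numeric(ts_range),
    lapse_rate = lapse_rate,
    base_mat_range = as.numeric(base_mat_range),
    ap_range = as.numeric(ap_range),
    n_species_per_mountain = as.numeric(n_species_per_mountain),
    singleton_fraction = singleton_fraction,
    dtr_elev_slope = dtr_elev_slope,
    ts_elev_slope = ts_elev_slope,
    band_noise_sd = band_noise_sd,
    paleo_amplitude_range = as.numeric(paleo_amplitude_range),
    paleo_n_points = as.integer(paleo_n_points),
    seed = as.integer(seed)
  )
  if (is.na(cfg$n_mountains) || cfg$n_mountains < 0L)
    stop_field("n_mountains", "must be a non-negative count")
  if (!is.numeric(island_fraction) || island_fraction < 0 || island_fraction > 1)
    stop_field("island_fraction", "must lie in [0, 1]")
  if (length(cfg$span_range) != 2 || cfg$span_range[1] > cfg$span_range[2])
    stop_field("span_range", "must be (min, max) with min <= max")
  if (cfg$span_range[1] < 1500)
    stop_field("span_range", "minimum span must be >= 1500 m (gradient inclusion rule)")
  if (cfg$dtr_island[2] <= 0 || cfg$dtr_continental[2] <= 0)
    stop_field("dtr_island/dtr_continental", "sd must be > 0")
  if (cfg$lapse_rate <= 0)
    stop_field("lapse_rate", "must be > 0")
  if (cfg$singleton_fraction < 0 || cfg$singleton_fraction > 1)
    stop_field("singleton_fraction", "must lie in [0, 1]")
  if (any(cfg$n_species_per_mountain < 1))
    stop_field("n_species_per_mountain", "must be >= 1")
  if (cfg$band_noise_sd < 0)
    stop_field("band_noise_sd", "must be >= 0")
  if (cfg$paleo_n_points < 2L)
    stop_field("paleo_n_points", "must be >= 2")
  class(cfg) <- "rsq_world_config"
  cfg
}

#' Generating ("true") parameters of the synthetic range-size models
#'
#' Parameters of the generative direction of the hierarchical models: the
#' global model draws a mountain-mean log range size around a linear
#' function of a mountain-level climate covariate, then species log ranges
#' around the mountain mean; the local model draws species log ranges
#' around mountain-specific linear functions of the covariate at the
#' species midpoint.
#'
#' @param alpha_V intercept of the mountain-mean log range size (log-m).
#' @param beta_V slope of mountain-mean log range size per covariate unit.
#' @param sigma2_site between-mountain variance of the mean log range.
#' @param sigma2_RS within-mountain (between-species) variance of log range.
#' @param local_alphas,local_betas optional per-mountain intercepts/slopes
#'   for the local generative model (recycled to the number of mountains).
#' @param sigma2_local shared residual variance of the local model.
#' @return an object of class `"rsq_true_params"`.
#' @export
true_parameters <- function(alpha_V = 6.0, beta_V = -0.1,
                            sigma2_site = 0.09, sigma2_RS = 0.64,
                            local_alphas = NULL, local_betas = NULL,
                            sigma2_local = 0.5) {
  if (sigma2_site < 0) stop_field("sigma2_site", "must be >= 0")
  if (sigma2_RS < 0) stop_field("sigma2_RS", "must be >= 0")
  if (sigma2_local <= 0) stop_field("sigma2_local", "must be > 0")
  structure(list(alpha_V = alpha_V, beta_V = beta_V,
                 sigma2_site = sigma2_site, sigma2_RS = sigma2_RS,
                 local_alphas = local_alphas, local_betas = local_betas,
                 sigma2_local = sigma2_local),
            class = "rsq_true_params")
}

#' Generate synthetic mountains with band-resolved climate tables
#'
#' Draws `config$n_mountains` gradients. Each mountain gets a land type
#' (island/continental), an elevation domain whose span is uniform over
#' `config$span_range` (rounded to whole 100 m bands), a contiguous table
#' of 100 m elevation bands with mean DTR, TS, MAT and AP per band, and a
#' paleo series of 30-year mean annual temperatures. MAT decreases with
#' elevation at `config$lapse_rate` degC per 100 m; island mountains draw
#' their DTR from the island distribution.
#'
#' @param config an [world_config()] object.
#' @return an object of class `"rsq_mountains"`: a list with elements
#'   `meta` (one row per mountain: `mountain_id`, `land_type`,
#'   `domain_min`, `domain_max`), `bands` (per 100 m band: `mountain_id`,
#'   `band_lower`, `band_upper`, `dtr`, `ts`, `mat`, `ap`) and `paleo`
#'   (per mountain: `mountain_id`, `year`, `mat`).
#' @export
generate_mountains <- function(config) {
  stopifnot(inherits(config, "rsq_world_config"))
  n <- config$n_mountains
  if (n == 0L) {
    out <- list(
      meta = data.frame(mountain_id = character(), land_type = character(),
                        domain_min = numeric(), domain_max = numeric()),
      bands = data.frame(mountain_id = character(), band_lower = numeric(),
                         band_upper = numeric(), dtr = numeric(), ts = numeric(),
                         mat = numeric(), ap = numeric()),
      paleo = data.frame(mountain_id = character(), year = numeric(),
                         mat = numeric()),
      config = config)
    class(out) <- "rsq_mountains"
    return(out)
  }
  set.seed(config$seed)
  ids <- sprintf("mtn%03d", seq_len(n))
  n_isl <- round(n * config$island_fraction)
  land <- rep("continental", n)
  land[sample.int(n, n_isl)] <- "island"

  span <- round(runif(n, config$span_range[1], config$span_range[2]) / 100) * 100
  span <- pmax(span, config$span_range[1])
  dmin <- round(runif(n, 0, 500) / 100) * 100
  dmax <- dmin + span

  is_isl <- land == "island"
  mtn_dtr <- numeric(n)
  mtn_dtr[is_isl] <- rnorm(sum(is_isl), config$dtr_island[1], config$dtr_island[2])
  mtn_dtr[!is_isl] <- rnorm(sum(!is_isl), config$dtr_continental[1],
                            config$dtr_continental[2])
  mtn_dtr <- pmax(mtn_dtr, 0.5)
  mtn_ts <- runif(n, config$ts_range[1], config$ts_range[2])
  base_mat <- runif(n, config$base_mat_range[1], config$base_mat_range[2])
  mtn_ap <- runif(n, config$ap_range[1], config$ap_range[2])

  bands <- vector("list", n)
  for (i in seq_len(n)) {
    lo <- seq(dmin[i], dmax[i] - 100, by = 100)
    mid <- lo + 50
    rel_km <- (mid - (dmin[i] + dmax[i]) / 2) / 1000
    bands[[i]] <- data.frame(
      mountain_id = ids[i],
      band_lower = lo,
      band_upper = lo + 100,
      dtr = pmax(mtn_dtr[i] + config$dtr_elev_slope * rel_km +
                   rnorm(length(lo), 0, config$band_noise_sd), 0.1),
      ts = pmax(mtn_ts[i] + config$ts_elev_slope * rel_km +
                  rnorm(length(lo), 0, config$band_noise_sd), 0.1),
      mat = base_mat[i] - config$lapse_rate * mid / 100,
      ap = pmax(mtn_ap[i] * (1 - 0.05 * rel_km) +
                  rnorm(length(lo), 0, 10), 0)
    )
  }

  amp <- runif(n, config$paleo_amplitude_range[1], config$paleo_amplitude_range[2])
  paleo <- vector("list", n)
  for (i in seq_len(n)) {
    mean_mat <- base_mat[i] - config$lapse_rate * ((dmin[i] + dmax[i]) / 2) / 100
    paleo[[i]] <- generate_paleo_series(config$paleo_n_points, mean = mean_mat,
                                        amplitude = amp[i],
                                        seed = config$seed + 1000L + i,
                                        mountain_id = ids[i])
  }

  out <- list(
    meta = data.frame(mountain_id = ids, land_type = land,
                      domain_min = dmin, domain_max = dmax),
    bands = do.call(rbind, bands),
    paleo = do.call(rbind, paleo),
    config = config
  )
  rownames(out$bands) <- NULL
  rownames(out$paleo) <- NULL
  class(out) <- "rsq_mountains"
  out
}

#' Generate a paleo series of 30-year mean annual temperatures
#'
#' Emulates a reconstructed time series of 30-year mean annual temperature
#' taken in 30-year steps from 0 AD onwards, as used to compute the
#' long-term temperature variation of a mountain (max minus min of the
#' series). The shape is a Gaussian random walk rescaled so that the
#' max-minus-min amplitude equals `amplitude` exactly; only that amplitude
#' matters downstream.
#'
#' @param n_points number of 30-year means (>= 2).
#' @param mean series mean level, degC.
#' @param amplitude max minus min of the series, degC (>= 0; 0 gives a
#'   constant series).
#' @param seed integer seed.
#' @param mountain_id identifier attached to the output rows.
#' @return a data.frame with columns `mountain_id`, `year` (AD, starting at
#'   0 in steps of 30) and `mat` (degC).
#' @export
generate_paleo_series <- function(n_points, mean = 10, amplitude = 1,
                                  seed = 1L, mountain_id = "mtn001") {
  if (!is.numeric(n_points) || n_points < 2)
    stop_field("n_points", "must be >= 2")
  if (amplitude < 0) stop_field("amplitude", "must be >= 0")
  n_points <- as.integer(n_points)
  year <- 30 * (seq_len(n_points) - 1)
  if (amplitude == 0) {
    vals <- rep(mean, n_points)
  } else {
    set.seed(as.integer(seed))
    w <- cumsum(rnorm(n_points))
    vals <- (w - min(w)) / (max(w) - min(w)) * amplitude
    vals <- vals - base::mean(vals) + mean
  }
  data.frame(mountain_id = mountain_id, year = year, mat = vals)
}

#' Elevation span of the suitable habitat under the squeeze model
#'
#' Conceptual calculator behind the temperature range squeeze hypothesis.
#' A species tolerates temperatures in `[t_lower, t_upper]`; temperatures
#' at any elevation fluctuate over time by `delta_t` (total width of the
#' temporal variation). With a constant lapse rate, the elevations at which
#' the species never meets a lethal temperature span
#' `max(0, t_upper - t_lower - delta_t) / lapse_rate * 100` meters: the
#' suitable span shrinks linearly as thermal variability grows, reaching 0
#' when the fluctuation equals the tolerance breadth.
#'
#' @param t_lower,t_upper lower/upper lethal temperature limits, degC
#'   (`t_upper > t_lower`).
#' @param delta_t temporal temperature variation width, degC (>= 0).
#' @param lapse_rate lapse rate, degC per 100 m (> 0); default 0.5.
#' @return suitable elevation span in meters (vectorised over `delta_t`).
#' @examples
#' suitable_habitat_span(0, 20, delta_t = 0)   # 4000 m
#' suitable_habitat_span(0, 20, delta_t = 20)  # 0 m, tolerance fully eaten
#' @export
suitable_habitat_span <- function(t_lower, t_upper, delta_t, lapse_rate = 0.5) {
  if (any(lapse_rate <= 0)) stop_field("lapse_rate", "must be > 0")
  if (any(t_upper <= t_lower)) stop_field("t_upper", "must exceed t_lower")
  if (any(delta_t < 0)) stop_field("delta_t", "must be >= 0")
  pmax(0, t_upper - t_lower - delta_t) / lapse_rate * 100
}

#' Generate synthetic species elevation ranges
#'
#' The generative direction of the hierarchical models. Under
#' `model = "global"` every mountain gets a mean log range size
#' `mu_site = alpha_V + beta_V * V_site` (with `V_site` the mountain-mean
#' value of the `driver` covariate over its climate bands), a mountain
#' effect `alpha_site ~ N(mu_site, sigma2_site)`, and species log range
#' sizes `~ N(alpha_site, sigma2_RS)`. Under `model = "local"` each species
#' is first given a midpoint uniform in the mountain domain, the covariate
#' at that midpoint is read from the band table, and the species log range
#' is `N(local_alphas[i] + local_betas[i] * v, sigma2_local)`.
#'
#' Log ranges are back-transformed to meters and positioned uniformly at
#' random among the positions at which the range fits inside the domain
#' (ranges wider than the domain are clipped to it), so range *sizes*
#' follow the stated law exactly whenever they fit. A `singleton_fraction`
#' share of species is collapsed to `min_elev == max_elev` at the range
#' midpoint, reproducing single-observation species without modelling
#' sampling effort.
#'
#' @param mountains an `"rsq_mountains"` object.
#' @param true_params a [true_parameters()] object.
#' @param config the [world_config()] used (supplies species counts,
#'   singleton fraction); its `seed` plus 1 seeds this step unless `seed`
#'   is given.
#' @param model `"global"` or `"local"` generative direction.
#' @param driver which band climate variable drives range sizes
#'   (`"dtr"`, `"ts"`, `"mat"` or `"ap"`).
#' @param seed optional integer seed overriding `config$seed + 1`.
#' @return a data.frame of species range records: `species_id`,
#'   `mountain_id`, `min_elev`, `max_elev`, plus attribute `"true_covariate"`
#'   (the per-mountain `V_site` used, named by mountain).
#' @export
generate_species_ranges <- function(mountains, true_params, config,
                                    model = c("global", "local"),
                                    driver = "dtr", seed = NULL) {
  stopifnot(inherits(mountains, "rsq_mountains"),
            inherits(true_params, "rsq_true_params"))
  model <- match.arg(model)
  if (model == "global" && true_params$sigma2_RS < 0)
    stop_field("sigma2_RS", "must be >= 0")
  meta <- mountains$meta
  n <- nrow(meta)
  if (n == 0L)
    return(data.frame(species_id = character(), mountain_id = character(),
                      min_elev = numeric(), max_elev = numeric()))
  set.seed(as.integer(seed %||% (config$seed + 1L)))

  nsp <- config$n_species_per_mountain
  n_s <- if (length(nsp) == 2) round(runif(n, nsp[1], nsp[2])) else rep(nsp, n)
  n_s <- as.integer(n_s)

  v_site <- vapply(seq_len(n), function(i) {
    b <- mountains$bands[mountains$bands$mountain_id == meta$mountain_id[i], ]
    mean(b[[driver]])
  }, numeric(1))
  names(v_site) <- meta$mountain_id

  if (model == "local") {
    la <- true_params$local_alphas %||% rnorm(n, 5, 0.3)
    lb <- true_params$local_betas %||% rnorm(n, 0, 0.05)
    la <- rep_len(la, n); lb <- rep_len(lb, n)
  }

  recs <- vector("list", n)
  for (i in seq_len(n)) {
    dmin <- meta$domain_min[i]; dmax <- meta$domain_max[i]
    span <- dmax - dmin
    k <- n_s[i]
    if (model == "global") {
      mu_site <- true_params$alpha_V + true_params$beta_V * v_site[i]
      a_site <- rnorm(1, mu_site, sqrt(true_params$sigma2_site))
      logr <- rnorm(k, a_site, sqrt(true_params$sigma2_RS))
      r <- pmin(exp(logr), span)
      mid <- runif(k, dmin + r / 2, dmax - r / 2)
    } else {
      mid <- runif(k, dmin, dmax)
      b <- mountains$bands[mountains$bands$mountain_id == meta$mountain_id[i], ]
      bi <- pmin(findInterval(mid, b$band_lower), nrow(b))
      v <- b[[driver]][bi]
      logr <- rnorm(k, la[i] + lb[i] * v, sqrt(true_params$sigma2_local))
      r <- pmin(exp(logr), span)
      lo <- pmin(pmax(mid - r / 2, dmin), dmax - r)
      mid <- lo + r / 2
    }
    mn <- mid - r / 2
    mx <- mid + r / 2
    if (config$singleton_fraction > 0 && k > 0) {
      ns_single <- round(config$singleton_fraction * k)
      if (ns_single > 0) {
        j <- sample.int(k, ns_single)
        mn[j] <- mx[j] <- mid[j]
      }
    }
    recs[[i]] <- data.frame(
      species_id = sprintf("%s_sp%05d", meta$mountain_id[i], seq_len(k)),
      mountain_id = meta$mountain_id[i],
      min_elev = mn, max_elev = mx)
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  attr(out, "true_covariate") <- v_site
  out
}

#' Generate a complete synthetic world
#'
#' Convenience wrapper: [generate_mountains()] then
#' [generate_species_ranges()], returning everything in one object.
#'
#' @inheritParams generate_species_ranges
#' @param config a [world_config()].
#' @return class `"rsq_world"`: list with `mountains`, `species`,
#'   `true_params`, `config`.
#' @export
generate_world <- function(config = world_config(),
                           true_params = true_parameters(),
                           model = "global", driver = "dtr") {
  mtns <- generate_mountains(config)
  sp <- generate_species_ranges(mtns, true_params, config,
                                model = model, driver = driver)
  structure(list(mountains = mtns, species = sp,
                 true_params = true_params, config = config),
            class = "rsq_world")
}

#' Generate a paired DEM / climate raster fixture
#'
#' Produces two equal-shape numeric grids: a digital elevation model whose
#' values span `[0, elevation_relief]`, and a climate grid whose pixel
#' values are `climate_fn(elevation)` plus optional Gaussian noise. Because
#' the climate is a known function of elevation, zonal band means over the
#' pair have a closed form and the pair serves as a test fixture for
#' [zonal_band_means()].
#'
#' @param shape length-2 integer `(nrow, ncol)`, both positive.
#' @param elevation_relief maximum elevation in m.
#' @param climate_fn function of elevation returning the noise-free climate
#'   value per pixel.
#' @param seed integer seed.
#' @param noise_sd sd of additive climate noise (default 0, noise-free).
#' @return list with matrices `dem` and `climate`.
#' @export
generate_raster_pair <- function(shape, elevation_relief = 3000,
                                 climate_fn = function(z) 25 - 0.005 * z,
                                 seed = 1L, noise_sd = 0) {
  shape <- as.integer(shape)
  if (length(shape) != 2 || any(shape <= 0))
    stop_field("shape", "must be two positive integers")
  set.seed(as.integer(seed))
  dem <- matrix(runif(prod(shape), 0, elevation_relief), shape[1], shape[2])
  clim <- matrix(climate_fn(dem), shape[1], shape[2])
  if (noise_sd > 0) clim <- clim + rnorm(length(clim), 0, noise_sd)
  list(dem = dem, climate = clim)
}

#' @export
print.rsq_world <- function(x, ...) {
  cat("Synthetic mountain world\n")
  cat(sprintf("  mountains: %d (%d island, %d continental)\n",
              nrow(x$mountains$meta),
              sum(x$mountains$meta$land_type == "island"),
              sum(x$mountains$meta$land_type == "continental")))
  cat(sprintf("  species records: %d\n", nrow(x$species)))
  cat(sprintf("  seed: %d\n", x$config$seed))
  invisible(x)
}
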