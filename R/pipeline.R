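build_site_covariates <- function(mountains, kept_meta) {
  rows <- lapply(seq_len(nrow(kept_meta)), function(i) {
    id <- kept_meta$mountain_id[i]
    dom <- c(kept_meta$domain_min[i], kept_meta$domain_max[i])
    b <- mountains$bands[mountains$bands$mountain_id == id, , drop = FALSE]
    cl <- mountain_mean_climate(b, dom)
    p <- mountains$paleo[mountains$paleo$mountain_id == id, , drop = FALSE]
    data.frame(mountain_id = id,
               land_type = kept_meta$land_type[i],
               dtr = cl[["dtr"]], ts = cl[["ts"]], mat = cl[["mat"]],
               ap = cl[["ap"]],
               dmat = if (nrow(p) >= 2) delta_mat(p) else NA_real_)
  })
  do.call(rbind, rows)
}

slope_summary_row <- function(fit, covariate) {
  b <- posterior_matrix(fit, "beta_V")[, 1]
  ci <- quantile(b, c(0.025, 0.975))
  r2 <- bayesian_r2(fit)
  data.frame(covariate = covariate, beta_mean = mean(b), beta_sd = sd(b),
             lower = unname(ci[1]), upper = unname(ci[2]),
             prob_negative = posterior_prob_negative(b),
             r2 = r2$estimate)
}

#' Global-scale analysis pipeline
#'
#' End-to-end across-mountain analysis: preprocessing (validation, mountain
#' filters, gradient standardization, exclusion zones, log transform),
#' mountain-level covariate construction (band means over the standardized
#' domain; max-minus-min of the paleo series for `dmat`), one global
#' hierarchical fit per covariate, WAIC/LOO model comparison and slope
#' summaries, plus the per-mountain table of posterior mean log range
#' sizes with their posterior SDs.
#'
#' @param world an `"rsq_world"` (or a list with `species` records and
#'   `mountains` of class `"rsq_mountains"`).
#' @param std_config a [standardization_config()]; the default (length
#'   2500 m, 250 m exclusion zones, top anchor) mirrors the headline
#'   analysis settings.
#' @param mcmc an [mcmc_config()].
#' @param covariates which mountain-level covariates to fit
#'   (subset of `dtr`, `ts`, `dmat`, `mat`, `ap`).
#' @return class `"rsq_global_report"`: list with `fits`, `comparison`,
#'   `slopes`, `site_table`, `preprocess`, `std_config`, `seed`.
#' @export
run_global_analysis <- function(world, std_config = standardization_config(),
                                mcmc = mcmc_config(),
                                covariates = c("dtr", "ts", "dmat")) {
  pp <- preprocess_dataset(world$species, world$mountains$meta, std_config)
  if (nrow(pp$mountains) < 3)
    stop("run_global_analysis: fewer than 3 mountains retained after preprocessing",
         call. = FALSE)
  site_cov <- build_site_covariates(world$mountains, pp$mountains)
  gd <- global_model_data(pp$records$log_range, pp$records$mountain_id, site_cov)
  fits <- list()
  slopes <- list()
  for (cv in covariates) {
    f <- fit_global(gd, cv, mcmc)
    fits[[cv]] <- f
    slopes[[cv]] <- slope_summary_row(f, cv)
  }
  comparison <- compare_models(fits)
  f1 <- fits[[1]]
  a_cols <- sprintf("alpha_site[%s]", f1$site_ids)
  m <- posterior_matrix(f1, a_cols)
  site_table <- data.frame(mountain_id = f1$site_ids,
                           mean_log_range = colMeans(m),
                           sd_log_range = apply(m, 2, sd))
  site_table <- merge(site_table, site_cov, by = "mountain_id")
  structure(list(fits = fits, comparison = comparison,
                 slopes = do.call(rbind, slopes),
                 site_table = site_table, preprocess = pp,
                 std_config = std_config, seed = mcmc$seed),
            class = "rsq_global_report")
}

#' @export
print.rsq_global_report <- function(x, ...) {
  cat("Global-scale analysis\n")
  cat(sprintf("  mountains retained: %d; species: %d\n",
              nrow(x$preprocess$mountains), nrow(x$preprocess$records)))
  cat("  slope summaries:\n")
  print(x$slopes, row.names = FALSE, digits = 3)
  cat("  model comparison (best WAIC first):\n")
  print(x$comparison, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Local-scale analysis pipeline
#'
#' Within-mountain analysis on the original (non-standardized) gradients:
#' exclusion zones only, climate assigned at each species' range midpoint,
#' one shared-variance local model fit per covariate and the per-mountain
#' slope classification. The long-term temperature variation covariate
#' (`dmat`) is refused: the past-climate reconstructions are far too
#' coarse spatially to resolve variation along an elevation gradient.
#'
#' @param world an `"rsq_world"`.
#' @param exclusion_zone width E in m applied to each original gradient.
#' @param mcmc an [mcmc_config()].
#' @param covariates subset of `c("dtr", "ts")`.
#' @return class `"rsq_local_report"`: per covariate a list with `fit` and
#'   `classification`, plus `preprocess`.
#' @export
run_local_analysis <- function(world, exclusion_zone = 250,
                               mcmc = mcmc_config(),
                               covariates = c("dtr", "ts")) {
  if ("dmat" %in% covariates)
    stop(paste("dmat is not available at the local scale: the spatial",
               "resolution of the past climate data is too low to vary",
               "along a single elevation gradient"), call. = FALSE)
  covariates <- match.arg(covariates, c("dtr", "ts"), several.ok = TRUE)
  pp <- preprocess_dataset(world$species, world$mountains$meta, config = NULL,
                           exclusion_zone = exclusion_zone)
  rec <- assign_midpoint_climate(pp$records, world$mountains$bands,
                                 vars = covariates)
  out <- list()
  for (cv in covariates) {
    ld <- local_model_data(rec$log_range, rec$mountain_id, rec[[cv]])
    f <- fit_local(ld, mcmc)
    out[[cv]] <- list(fit = f, classification = classify_local_slopes(f))
  }
  structure(c(out, list(preprocess = pp, exclusion_zone = exclusion_zone,
                        seed = mcmc$seed)),
            class = "rsq_local_report")
}

#' @export
print.rsq_local_report <- function(x, ...) {
  cat("Local-scale analysis (no gradient standardization)\n")
  for (cv in setdiff(names(x), c("preprocess", "exclusion_zone", "seed"))) {
    agg <- x[[cv]]$classification$aggregates
    cat(sprintf("  %s: %.0f%% positive vs %.0f%% negative (low-uncertainty: %.0f%% vs %.0f%%)\n",
                cv, agg["pct_positive"], agg["pct_negative"],
                agg["pct_positive_low_unc"], agg["pct_negative_low_unc"]))
  }
  invisible(x)
}

#' Sensitivity grid over standardization choices
#'
#' Repeats the global fit for every combination of standardized gradient
#' length, exclusion-zone width and anchoring direction, reporting how the
#' slope estimate and the number of retained mountains respond to the
#' methodological choices. Cells in which too few mountains survive
#' standardization are recorded as excluded rather than failing the grid.
#'
#' @param world an `"rsq_world"`.
#' @param lengths,exclusion_zones,anchors grid dimensions (defaults:
#'   1500/2000/2500 m, 0/250/500 m, top/bottom).
#' @param covariate mountain-level covariate to fit.
#' @param mcmc an [mcmc_config()].
#' @return data.frame with one row per grid cell: `length`,
#'   `exclusion_zone`, `anchor`, `n_mountains`, `beta_mean`, `beta_sd`,
#'   `prob_negative`, `r2`, `sign`, `excluded`.
#' @export
run_sensitivity_grid <- function(world, lengths = c(1500, 2000, 2500),
                                 exclusion_zones = c(0, 250, 500),
                                 anchors = c("top", "bottom"),
                                 covariate = "dtr", mcmc = mcmc_config()) {
  grid <- expand.grid(length = lengths, exclusion_zone = exclusion_zones,
                      anchor = anchors, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    base <- data.frame(length = g$length, exclusion_zone = g$exclusion_zone,
                       anchor = g$anchor, n_mountains = 0L,
                       beta_mean = NA_real_, beta_sd = NA_real_,
                       prob_negative = NA_real_, r2 = NA_real_,
                       sign = NA_character_, excluded = TRUE)
    cfg <- tryCatch(standardization_config(g$length, g$exclusion_zone, g$anchor),
                    error = function(e) NULL)
    if (is.null(cfg)) return(base)
    pp <- preprocess_dataset(world$species, world$mountains$meta, cfg)
    base$n_mountains <- nrow(pp$mountains)
    if (nrow(pp$mountains) < 3) return(base)
    site_cov <- build_site_covariates(world$mountains, pp$mountains)
    gd <- global_model_data(pp$records$log_range, pp$records$mountain_id,
                            site_cov)
    f <- fit_global(gd, covariate, mcmc, store_loglik = FALSE)
    s <- slope_summary_row(f, covariate)
    base$beta_mean <- s$beta_mean; base$beta_sd <- s$beta_sd
    base$prob_negative <- s$prob_negative; base$r2 <- s$r2
    base$sign <- if (s$beta_mean >= 0) "positive" else "negative"
    base$excluded <- FALSE
    base
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
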