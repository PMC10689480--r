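#' Species elevation range size
#'
#' Range size is the difference between the maximum and minimum elevation
#' at which a species was recorded in one mountain. Singletons (a single
#' observation) have range size 0 m.
#'
#' @param records data.frame with columns `min_elev`, `max_elev` (m a.s.l.).
#' @return numeric vector of range sizes in meters (>= 0).
#' @export
compute_range_size <- function(records) {
  rs <- records$max_elev - records$min_elev
  if (any(rs < 0, na.rm = TRUE))
    stop("found records with min_elev > max_elev; run validate_records() first",
         call. = FALSE)
  rs
}

#' Validate species range records
#'
#' Removes rows that cannot be real observations: minimum elevation above
#' the maximum, any elevation above 6500 m (the highest elevation recorded
#' for vascular plants), or non-finite elevations. Rejections are returned,
#' not raised: bad rows typically stem from typographic errors in source
#' floras and are logged with a reason code.
#'
#' @param records data.frame with columns `species_id`, `mountain_id`,
#'   `min_elev`, `max_elev`.
#' @param max_elevation ceiling for plausible elevations, default 6500 m.
#' @return list with `records` (kept rows, invariants guaranteed) and
#'   `rejected` (dropped rows plus a `reason` column with values
#'   `min_gt_max`, `above_6500` or `non_finite`).
#' @export
validate_records <- function(records, max_elevation = 6500) {
  reason <- rep(NA_character_, nrow(records))
  bad_fin <- !is.finite(records$min_elev) | !is.finite(records$max_elev)
  reason[bad_fin] <- "non_finite"
  bad_high <- !bad_fin &
    (records$min_elev > max_elevation | records$max_elev > max_elevation)
  reason[bad_high] <- "above_6500"
  bad_ord <- !bad_fin & !bad_high & records$min_elev > records$max_elev
  reason[bad_ord] <- "min_gt_max"
  keep <- is.na(reason)
  rejected <- records[!keep, , drop = FALSE]
  rejected$reason <- reason[!keep]
  rownames(rejected) <- NULL
  kept <- records[keep, , drop = FALSE]
  rownames(kept) <- NULL
  list(records = kept, rejected = rejected)
}

#' Fraction of singleton species in one mountain
#'
#' @param records data.frame of validated records for a single mountain.
#' @return proportion of records with range size 0, in `[0, 1]`.
#' @export
singleton_fraction <- function(records) {
  if (nrow(records) == 0) stop("no records supplied", call. = FALSE)
  mean(records$max_elev == records$min_elev)
}

#' Detect sampling gaps in a mountain's elevation coverage
#'
#' "Sampled sections" are taken to be the union of the species' elevation
#' intervals (singletons contribute points). A sampling gap is a maximal
#' elevation interval wider than `gap_threshold` lying strictly between two
#' sampled sections; mountains with any such gap have discontinuous
#' sampling.
#'
#' @param records validated records for a single mountain.
#' @param gap_threshold minimal gap width to flag, default 500 m.
#' @return data.frame of gaps with columns `gap_lower`, `gap_upper`,
#'   `width`; zero rows means continuous sampling.
#' @export
detect_sampling_gaps <- function(records, gap_threshold = 500) {
  if (nrow(records) == 0) stop("no records supplied", call. = FALSE)
  o <- order(records$min_elev, records$max_elev)
  lo <- records$min_elev[o]; hi <- records$max_elev[o]
  # merge into disjoint covered intervals
  cov_lo <- lo[1]; cov_hi <- hi[1]
  gaps <- list()
  for (i in seq_along(lo)[-1]) {
    if (lo[i] <= cov_hi) {
      cov_hi <- max(cov_hi, hi[i])
    } else {
      gaps[[length(gaps) + 1L]] <- c(cov_hi, lo[i])
      cov_lo <- lo[i]; cov_hi <- hi[i]
    }
  }
  if (length(gaps) == 0)
    return(data.frame(gap_lower = numeric(), gap_upper = numeric(),
                      width = numeric()))
  g <- do.call(rbind, gaps)
  out <- data.frame(gap_lower = g[, 1], gap_upper = g[, 2],
                    width = g[, 2] - g[, 1])
  out[out$width > gap_threshold, , drop = FALSE]
}

#' Filter mountains by sampling-quality rules
#'
#' Keeps mountains that pass both homogeneity rules: at most
#' `max_singleton_fraction` of species are singletons (a high share of
#' single-observation species signals poor sampling effort and badly
#' underestimated ranges), and no sampling gap wider than `gap_threshold`
#' between sampled sections. Both rules are evaluated on the full,
#' pre-standardization dataset.
#'
#' @param records validated records (all mountains).
#' @param mountains mountain metadata data.frame (`mountain_id`, ...).
#' @param max_singleton_fraction inclusive threshold, default 0.25.
#' @param gap_threshold gap width threshold in m, default 500.
#' @return list with `records`, `mountains` (kept) and `exclusions`
#'   (data.frame `mountain_id`, `reason` in
#'   `{singleton_fraction, sampling_gap}`, `value`).
#' @export
filter_mountains <- function(records, mountains,
                             max_singleton_fraction = 0.25,
                             gap_threshold = 500) {
  ids <- mountains$mountain_id
  excl <- list()
  keep <- logical(length(ids))
  for (i in seq_along(ids)) {
    r <- records[records$mountain_id == ids[i], , drop = FALSE]
    if (nrow(r) == 0) {
      excl[[length(excl) + 1L]] <-
        data.frame(mountain_id = ids[i], reason = "no_records", value = 0)
      next
    }
    sf <- singleton_fraction(r)
    if (sf > max_singleton_fraction) {
      excl[[length(excl) + 1L]] <-
        data.frame(mountain_id = ids[i], reason = "singleton_fraction", value = sf)
      next
    }
    g <- detect_sampling_gaps(r, gap_threshold)
    if (nrow(g) > 0) {
      excl[[length(excl) + 1L]] <-
        data.frame(mountain_id = ids[i], reason = "sampling_gap",
                   value = max(g$width))
      next
    }
    keep[i] <- TRUE
  }
  exclusions <- if (length(excl)) do.call(rbind, excl) else
    data.frame(mountain_id = character(), reason = character(), value = numeric())
  list(records = records[records$mountain_id %in% ids[keep], , drop = FALSE],
       mountains = mountains[keep, , drop = FALSE],
       exclusions = exclusions)
}

#' Standardization configuration for elevation gradients
#'
#' @param length standardized gradient length in m (the study grid uses
#'   1500, 2000 or 2500; other positive values are allowed).
#' @param exclusion_zone width in m of the zones at each end of the
#'   standardized domain (study grid: 0, 250, 500).
#' @param anchor `"top"` keeps the uppermost `length` meters of the
#'   gradient, `"bottom"` the lowermost.
#' @return class `"rsq_std_config"`.
#' @export
standardization_config <- function(length = 2500, exclusion_zone = 250,
                                   anchor = c("top", "bottom")) {
  anchor <- match.arg(anchor)
  if (length <= 0) stop_field("length", "must be > 0")
  if (exclusion_zone < 0) stop_field("exclusion_zone", "must be >= 0")
  if (2 * exclusion_zone >= length)
    stop_field("exclusion_zone", "twice the exclusion zone must be < length")
  structure(list(length = length, exclusion_zone = exclusion_zone,
                 anchor = anchor), class = "rsq_std_config")
}

#' Standardize one mountain's elevation gradient
#'
#' Trims the mountain's domain to a fixed length anchored at its top (or
#' bottom), making gradients of different spans comparable: for anchor
#' `"top"` the new domain is `[domain_max - length, domain_max]`. Species
#' ranges crossing the new boundary are truncated to it (a range reduced to
#' a single point is kept and treated as a singleton downstream); species
#' entirely outside the new domain are dropped. Mountains whose span is
#' shorter than `config$length` cannot be standardized and raise an error;
#' pipelines catch this and log the mountain as excluded.
#'
#' @param records validated records of one mountain.
#' @param domain numeric length-2, the mountain's original
#'   `(domain_min, domain_max)`.
#' @param config a [standardization_config()].
#' @return list with `records` (truncated, in-domain rows) and `domain`
#'   (the new `(min, max)`, width exactly `config$length`).
#' @export
standardize_gradient <- function(records, domain, config) {
  stopifnot(inherits(config, "rsq_std_config"))
  span <- domain[2] - domain[1]
  if (span < config$length)
    stop(sprintf("gradient span %.0f m is shorter than standardized length %.0f m",
                 span, config$length), call. = FALSE)
  new_dom <- if (config$anchor == "top")
    c(domain[2] - config$length, domain[2])
  else
    c(domain[1], domain[1] + config$length)
  inside <- records$max_elev >= new_dom[1] & records$min_elev <= new_dom[2]
  out <- records[inside, , drop = FALSE]
  out$min_elev <- pmax(out$min_elev, new_dom[1])
  out$max_elev <- pmin(out$max_elev, new_dom[2])
  rownames(out) <- NULL
  list(records = out, domain = new_dom)
}

#' Drop species confined to the gradient edges
#'
#' Species found exclusively within `exclusion_zone` meters of the top or
#' bottom of the domain are removed: ranges squeezed against a domain
#' boundary are truncated fractions of the species' potential range and
#' bias range-size analyses. A range exactly touching the inner edge of a
#' zone is kept ("exclusively near" the edge is read as strict
#' containment).
#'
#' @param records records already lying within `domain`.
#' @param domain numeric length-2 `(domain_min, domain_max)`.
#' @param exclusion_zone zone width E in m; `E = 0` is the identity.
#' @return the retained records, unmodified.
#' @export
apply_exclusion_zones <- function(records, domain, exclusion_zone) {
  if (exclusion_zone < 0) stop_field("exclusion_zone", "must be >= 0")
  if (2 * exclusion_zone >= domain[2] - domain[1])
    stop_field("exclusion_zone", "twice the exclusion zone must be < domain width")
  if (nrow(records) > 0 &&
      (any(records$min_elev < domain[1]) || any(records$max_elev > domain[2])))
    stop("records extend outside the domain; standardize/truncate first",
         call. = FALSE)
  if (exclusion_zone == 0) return(records)
  in_bottom <- records$max_elev < domain[1] + exclusion_zone
  in_top <- records$min_elev > domain[2] - exclusion_zone
  out <- records[!(in_bottom | in_top), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Log-transform range sizes with the singleton floor
#'
#' Replaces zero ranges (singletons) by 10 m -- the smallest positive
#' range observable at the data's precision -- then applies the natural
#' log so the data meet the normality assumption of the models.
#'
#' @param range_sizes numeric vector of range sizes in m (>= 0).
#' @param singleton_floor replacement for zero ranges, default 10 m.
#' @return natural-log range sizes, all finite.
#' @export
transform_range_sizes <- function(range_sizes, singleton_floor = 10) {
  if (any(range_sizes < 0, na.rm = TRUE))
    stop("range sizes must be >= 0", call. = FALSE)
  log(ifelse(range_sizes == 0, singleton_floor, range_sizes))
}

#' Run the full preprocessing pipeline
#'
#' Enforces the stage order validate -> filter mountains -> standardize ->
#' exclusion zones -> log transform. Mountains whose span is shorter than
#' the standardized length are excluded (with reason `span_too_short`),
#' which is how a 44-mountain dataset shrinks to the subset that supports a
#' given standardization length.
#'
#' @param records raw species range records.
#' @param mountains mountain metadata (`mountain_id`, `land_type`,
#'   `domain_min`, `domain_max`).
#' @param config a [standardization_config()]; pass `NULL` to skip
#'   standardization (local-scale analyses) and apply `exclusion_zone`
#'   on the original domains.
#' @param exclusion_zone only used when `config` is `NULL`.
#' @param max_singleton_fraction,gap_threshold see [filter_mountains()].
#' @return list: `records` (with `range_size`, `log_range` columns),
#'   `mountains` (kept, with standardized `domain_min`/`domain_max`),
#'   `rejected`, `mountain_exclusions`, `stage_log` (character).
#' @export
preprocess_dataset <- function(records, mountains, config = standardization_config(),
                               exclusion_zone = 250,
                               max_singleton_fraction = 0.25,
                               gap_threshold = 500) {
  stage_log <- character()
  val <- validate_records(records)
  stage_log <- c(stage_log, sprintf("validate: kept %d, rejected %d",
                                    nrow(val$records), nrow(val$rejected)))
  flt <- filter_mountains(val$records, mountains,
                          max_singleton_fraction, gap_threshold)
  stage_log <- c(stage_log, sprintf("filter_mountains: kept %d of %d mountains",
                                    nrow(flt$mountains), nrow(mountains)))
  excl <- flt$exclusions
  kept_m <- flt$mountains
  out_rec <- list(); out_mtn <- list()
  for (i in seq_len(nrow(kept_m))) {
    id <- kept_m$mountain_id[i]
    r <- flt$records[flt$records$mountain_id == id, , drop = FALSE]
    dom <- c(kept_m$domain_min[i], kept_m$domain_max[i])
    if (!is.null(config)) {
      std <- tryCatch(standardize_gradient(r, dom, config), error = function(e) e)
      if (inherits(std, "error")) {
        excl <- rbind(excl, data.frame(mountain_id = id, reason = "span_too_short",
                                       value = dom[2] - dom[1]))
        next
      }
      r <- std$records; dom <- std$domain
      ez <- config$exclusion_zone
    } else {
      ez <- exclusion_zone
    }
    r <- apply_exclusion_zones(r, dom, ez)
    if (nrow(r) == 0) {
      excl <- rbind(excl, data.frame(mountain_id = id, reason = "no_records",
                                     value = 0))
      next
    }
    m <- kept_m[i, , drop = FALSE]
    m$domain_min <- dom[1]; m$domain_max <- dom[2]
    out_rec[[length(out_rec) + 1L]] <- r
    out_mtn[[length(out_mtn) + 1L]] <- m
  }
  if (!is.null(config))
    stage_log <- c(stage_log,
                   sprintf("standardize(length=%g, anchor=%s): kept %d mountains",
                           config$length, config$anchor, length(out_mtn)))
  stage_log <- c(stage_log, sprintf("exclusion_zone(E=%g m) applied",
                                    if (is.null(config)) exclusion_zone
                                    else config$exclusion_zone))
  rec <- if (length(out_rec)) do.call(rbind, out_rec) else
    flt$records[0, , drop = FALSE]
  mtn <- if (length(out_mtn)) do.call(rbind, out_mtn) else
    kept_m[0, , drop = FALSE]
  rownames(rec) <- NULL; rownames(mtn) <- NULL
  rec$range_size <- compute_range_size(rec)
  rec$log_range <- transform_range_sizes(rec$range_size)
  stage_log <- c(stage_log, sprintf("transform: %d species, %d mountains",
                                    nrow(rec), nrow(mtn)))
  list(records = rec, mountains = mtn, rejected = val$rejected,
       mountain_exclusions = excl, stage_log = stage_log)
}
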