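#' Zonal climate means over 100 m elevation bands
#'
#' Groups DEM pixels into half-open elevation bands
#' `[k * band_width, (k + 1) * band_width)` anchored at 0 m a.s.l. and
#' averages the matching climate pixels per band (unweighted pixel mean).
#' Bands containing no pixel are omitted.
#'
#' @param dem numeric matrix/vector of elevations (m), finite.
#' @param climate numeric matrix/vector of the same shape.
#' @param band_width band width in m, default 100.
#' @return data.frame with `band_lower`, `band_upper`, `n_pixels`, `mean`.
#' @export
zonal_band_means <- function(dem, climate, band_width = 100) {
  if (length(dem) != length(climate) ||
      !identical(dim(dem), dim(climate)))
    stop("dem and climate grids must have identical shape", call. = FALSE)
  if (any(!is.finite(dem)))
    stop("dem contains non-finite values", call. = FALSE)
  k <- factor(floor(as.numeric(dem) / band_width))
  sums <- tapply(as.numeric(climate), k, sum)
  counts <- tabulate(k)
  kk <- as.numeric(levels(k))
  out <- data.frame(band_lower = kk * band_width,
                    band_upper = (kk + 1) * band_width,
                    n_pixels = counts,
                    mean = as.vector(sums) / counts)
  rownames(out) <- NULL
  out
}

#' Mountain-level mean climate over a domain
#'
#' Averages band climate values over the bands lying entirely within the
#' (possibly standardized) domain, so that every mountain is described by
#' one value per climate variable. Each band counts once by default
#' (unweighted band mean); set `weight = "pixels"` to weight bands by their
#' pixel counts when an `n_pixels` column is present.
#'
#' @param bands band climate rows of one mountain (columns `band_lower`,
#'   `band_upper` plus climate variables such as `dtr`, `ts`, `mat`, `ap`).
#' @param domain numeric length-2 `(domain_min, domain_max)`.
#' @param vars climate columns to average; defaults to the intersection of
#'   `c("dtr", "ts", "mat", "ap")` with the available columns.
#' @param weight `"none"` (default) or `"pixels"`.
#' @return named numeric vector, one mean per variable.
#' @export
mountain_mean_climate <- function(bands, domain,
                                  vars = intersect(c("dtr", "ts", "mat", "ap"),
                                                   names(bands)),
                                  weight = c("none", "pixels")) {
  weight <- match.arg(weight)
  sel <- bands$band_lower >= domain[1] & bands$band_upper <= domain[2]
  if (!any(sel))
    stop("no climate band lies within the domain", call. = FALSE)
  b <- bands[sel, , drop = FALSE]
  w <- if (weight == "pixels" && "n_pixels" %in% names(b)) b$n_pixels
       else rep(1, nrow(b))
  vapply(vars, function(v) sum(b[[v]] * w) / sum(w), numeric(1))
}

#' Long-term temperature variation of a paleo series
#'
#' The difference between the highest and lowest 30-year mean annual
#' temperature in a mountain's paleo series; one value per mountain,
#' independent of elevation.
#'
#' @param series numeric vector of series values, or a data.frame with a
#'   `mat` column (as returned by [generate_paleo_series()]).
#' @return max minus min, degC (>= 0).
#' @export
delta_mat <- function(series) {
  v <- if (is.data.frame(series)) series$mat else series
  if (length(v) < 2)
    stop("paleo series needs at least 2 values", call. = FALSE)
  max(v) - min(v)
}

#' Climate at species range midpoints
#'
#' Assigns to every species the climate of the 100 m band whose half-open
#' interval `[band_lower, band_upper)` contains the species' range midpoint
#' `(min_elev + max_elev) / 2`, used as the covariate of the local
#' within-mountain model. A midpoint equal to the very top of the highest
#' band is assigned to that band.
#'
#' @param records species range records (`species_id`, `mountain_id`,
#'   `min_elev`, `max_elev`).
#' @param bands band climate table for all mountains (`mountain_id`,
#'   `band_lower`, `band_upper`, climate columns).
#' @param vars climate columns to return, default `c("dtr", "ts")`.
#' @return `records` with a `midpoint` column and one column per requested
#'   climate variable.
#' @export
assign_midpoint_climate <- function(records, bands, vars = c("dtr", "ts")) {
  out <- records
  out$midpoint <- (records$min_elev + records$max_elev) / 2
  for (v in vars) out[[v]] <- NA_real_
  for (id in unique(records$mountain_id)) {
    b <- bands[bands$mountain_id == id, , drop = FALSE]
    b <- b[order(b$band_lower), , drop = FALSE]
    sel <- which(out$mountain_id == id)
    mids <- out$midpoint[sel]
    idx <- findInterval(mids, b$band_lower)
    # half-open bands, but let the exact top of the highest band fall in it
    top_ok <- mids == b$band_upper[nrow(b)]
    idx[top_ok] <- nrow(b)
    bad <- idx < 1 | idx > nrow(b) |
      (!top_ok & mids >= b$band_upper[pmin(pmax(idx, 1), nrow(b))])
    if (any(bad))
      stop(sprintf("midpoint outside all climate bands for species %s",
                   paste(out$species_id[sel][bad], collapse = ", ")),
           call. = FALSE)
    for (v in vars) out[[v]][sel] <- b[[v]][idx]
  }
  out
}
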