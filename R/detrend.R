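#' Smoothing parameter with a 50% frequency cutoff
#'
#' A cubic smoothing spline is defined here by its frequency-response
#' contract: the amplitude of a sinusoid whose period equals
#' `cutoff_years` is damped to exactly 50%.  The roughness-penalty
#' coefficient that achieves this is found numerically by bisection on a
#' long probe sinusoid (ten cutoff periods), measuring the fitted
#' amplitude over the central two thirds to avoid edge effects.  The
#' calibrated value is expressed on the physical year scale
#' (`lambda_unit = lambda_phys / range^3` for [stats::smooth.spline()],
#' whose abscissa is rescaled to the unit interval) and cached per
#' cutoff.
#'
#' @param cutoff_years wavelength (years) at which the amplitude response
#'   is 0.5.
#' @return the penalty coefficient on the physical year scale.
#' @export
spline_cutoff_lambda <- function(cutoff_years = 30) {
  if (!is.finite(cutoff_years) || cutoff_years <= 0) {
    qwa_validation_error("cutoff_years must be > 0")
  }
  key <- sprintf("lambda_%g", cutoff_years)
  cached <- .qwa_env[[key]]
  if (!is.null(cached)) return(cached)
  nyr <- max(100L, ceiling(10 * cutoff_years))
  t <- seq_len(nyr)
  y <- sin(2 * pi * t / cutoff_years)
  ctr <- seq(round(nyr / 6), round(5 * nyr / 6))
  s1 <- sin(2 * pi * t / cutoff_years)[ctr]
  c1 <- cos(2 * pi * t / cutoff_years)[ctr]
  response <- function(lambda_unit) {
    f <- stats::smooth.spline(t, y, lambda = lambda_unit,
                              all.knots = TRUE)$y[ctr]
    co <- stats::coef(stats::lm(f ~ s1 + c1))
    sqrt(co[["s1"]]^2 + co[["c1"]]^2)
  }
  lo <- 1e-14; hi <- 1e2  # response is monotone decreasing in lambda
  for (i in seq_len(80)) {
    mid <- sqrt(lo * hi)
    if (response(mid) > 0.5) lo <- mid else hi <- mid
  }
  lambda_phys <- sqrt(lo * hi) * (nyr - 1)^3
  .qwa_env[[key]] <- lambda_phys
  lambda_phys
}

#' Fit the frequency-calibrated cubic smoothing spline
#'
#' Fits a cubic smoothing spline whose amplitude response at wavelength
#' `cutoff_years` is 50%: fluctuations slower than the cutoff pass into
#' the fitted curve, faster ones are attenuated.  Missing values are left
#' out of the fit and stay missing in the result (no interpolation).
#' A constant series is returned unchanged.
#'
#' @param values numeric series, one value per year (may contain NA).
#' @param years abscissa; defaults to `seq_along(values)`.  Must be
#'   strictly increasing.
#' @param cutoff_years 50% frequency-cutoff wavelength (default 30).
#' @param min_obs minimum number of non-missing values (default 10).
#' @return fitted values, same length as `values`, NA where the input was
#'   missing.
#' @export
smoothing_spline_fit <- function(values, years = seq_along(values),
                                 cutoff_years = 30, min_obs = 10L) {
  stopifnot(length(values) == length(years))
  ok <- is.finite(values)
  if (sum(ok) < min_obs) {
    qwa_validation_error(sprintf(
      "series too short: %d non-missing values (need >= %d)",
      sum(ok), min_obs))
  }
  fitted <- rep(NA_real_, length(values))
  if (stats::sd(values[ok]) == 0) {
    fitted[ok] <- values[ok]
    return(fitted)
  }
  lambda_phys <- spline_cutoff_lambda(cutoff_years)
  rng <- diff(range(years[ok]))
  fit <- stats::smooth.spline(years[ok], values[ok],
                              lambda = lambda_phys / rng^3,
                              all.knots = TRUE)
  fitted[ok] <- stats::predict(fit, years[ok])$y
  fitted
}

#' Spline-ratio indexing of an annual series
#'
#' The detrended index is the ratio of observed to spline-fitted values
#' per year; it removes low-frequency variation (ontogenetic trends,
#' disturbance) while retaining inter-annual variability around 1.
#' Years where the fitted value is not positive are set to NA with a
#' warning, since a ratio index is meaningless there.
#'
#' @inheritParams smoothing_spline_fit
#' @return data frame `year, value, fitted, index`.
#' @export
index_series <- function(values, years = seq_along(values),
                         cutoff_years = 30, min_obs = 10L) {
  fitted <- smoothing_spline_fit(values, years, cutoff_years, min_obs)
  index <- values / fitted
  bad <- is.finite(fitted) & fitted <= 0
  if (any(bad)) {
    warning(sprintf("%d year(s) with non-positive fitted value set to NA",
                    sum(bad)))
    index[bad] <- NA_real_
  }
  data.frame(year = years, value = values, fitted = fitted, index = index)
}

#' Index monthly climate series
#'
#' Each calendar month's across-year series is indexed independently with
#' the same frequency-calibrated spline, for both temperature and
#' precipitation.
#'
#' @param climate climate table (`year, month, tmean, prec`) with a
#'   complete monthly grid.
#' @inheritParams smoothing_spline_fit
#' @return data frame `year, month, variable, value, fitted, index` with
#'   `variable` in `"tmean"`, `"prec"`.
#' @export
index_climate <- function(climate, cutoff_years = 30, min_obs = 10L) {
  validate_climate_grid(climate)
  out <- vector("list", 24)
  i <- 0L
  for (variable in c("tmean", "prec")) {
    for (m in 1:12) {
      sub <- climate[climate$month == m, ]
      sub <- sub[order(sub$year), ]
      idx <- index_series(sub[[variable]], sub$year, cutoff_years, min_obs)
      i <- i + 1L
      out[[i]] <- data.frame(year = idx$year, month = m,
                             variable = variable, value = idx$value,
                             fitted = idx$fitted, index = idx$index,
                             stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Index sector-trait series per tree
#'
#' Builds, for every site x tree x trait x sector combination, the
#' inter-annual series of the trait and applies [index_series()].
#' Series with fewer than `min_obs` retained years are dropped.
#'
#' @param traits a [sector_traits()] table.
#' @param trait_names traits to index (default all seven).
#' @inheritParams smoothing_spline_fit
#' @return long data frame `site_id, tree_id, trait, sector, year, value,
#'   fitted, index`.
#' @export
index_traits <- function(traits,
                         trait_names = c("VA", "VA95", "DH", "KH",
                                         "VD", "RVA", "VG"),
                         cutoff_years = 30, min_obs = 10L) {
  keys <- interaction(traits$site_id, traits$tree_id, traits$sector,
                      drop = TRUE)
  out <- list()
  for (chunk in split(traits, keys)) {
    chunk <- chunk[order(chunk$year), ]
    for (trait in trait_names) {
      v <- chunk[[trait]]
      if (sum(is.finite(v)) < min_obs) next
      idx <- index_series(v, chunk$year, cutoff_years, min_obs)
      out[[length(out) + 1L]] <- data.frame(
        site_id = chunk$site_id[1], tree_id = chunk$tree_id[1],
        trait = trait, sector = chunk$sector[1],
        year = idx$year, value = idx$value, fitted = idx$fitted,
        index = idx$index, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Intra-ring standardized profiles
#'
#' Divides each sector's trait value by the whole-ring value of the same
#' trait in the same tree and year (the pooled-vessel ring value, reported
#' as sector 0 by [sector_traits()]).  Only same-year data enter the
#' standardization, so inter-annual trends and level shifts cancel and
#' the within-ring shape remains.  Discarded sectors yield NA; tree-years
#' without a ring-level value are skipped.
#'
#' @param traits a [sector_traits()] table containing sector 0 rows.
#' @param trait_names traits to standardize (default all seven).
#' @return long data frame `site_id, tree_id, year, trait, sector, value,
#'   ring_value, x_std`.
#' @export
standardize_profiles <- function(traits,
                                 trait_names = c("VA", "VA95", "DH", "KH",
                                                 "VD", "RVA", "VG")) {
  ring_rows <- traits[traits$sector == 0, , drop = FALSE]
  sec_rows <- traits[traits$sector > 0, , drop = FALSE]
  rkey <- function(d) paste(d$site_id, d$tree_id, d$year, sep = "\r")
  ring_idx <- structure(seq_len(nrow(ring_rows)), names = rkey(ring_rows))
  out <- vector("list", length(trait_names))
  for (ti in seq_along(trait_names)) {
    trait <- trait_names[ti]
    rv <- ring_rows[[trait]][ring_idx[rkey(sec_rows)]]
    ok_ring <- is.finite(rv) & rv > 0
    out[[ti]] <- data.frame(
      site_id = sec_rows$site_id, tree_id = sec_rows$tree_id,
      year = sec_rows$year, trait = trait, sector = sec_rows$sector,
      value = sec_rows[[trait]], ring_value = rv,
      x_std = ifelse(ok_ring, sec_rows[[trait]] / rv, NA_real_),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$trait, res$site_id, res$tree_id, res$year,
                   res$sector), ]
  rownames(res) <- NULL
  res
}
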