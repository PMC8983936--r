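#' Configuration for the synthetic vessel-data generator
#'
#' The generator emulates the structure of diffuse-porous beech rings
#' measured at several sites: vessel size declines across the ring after an
#' early-wood plateau, vessel density peaks near the ring end, vessel
#' dimensions drift upward with cambial age (ontogenetic trend), and an
#' inter-annual climate signal couples early-wood vessel size to summer
#' (June-August) precipitation.
#'
#' @param n_sites number of sites.
#' @param trees_per_site trees per site.
#' @param year_start,year_end calendar span of the generated rings
#'   (defaults 1968-2004, i.e. 37 years).
#' @param vessels_per_ring_mean expected vessel count of a ring of average
#'   width (counts scale with ring width).
#' @param ring_width_mean_um mean ring width in micrometres.
#' @param profile_shape list with `va_plateau_end` (relative position where
#'   the early-wood vessel-size plateau ends, default 0.5), `vd_peak`
#'   (relative position of the vessel-density peak, default 0.9) and
#'   `va_end_fraction` (expected vessel area at the ring end as a fraction
#'   of the plateau value, default 0.3).
#' @param ontogenetic_trend fractional increase of expected vessel area per
#'   year of cambial age (default 0.01).
#' @param climate_signal effect size in `[0, 1]` coupling the standardized
#'   log June-August precipitation sum to early-wood (relative position
#'   < 0.5) vessel sizes.
#' @param site_offsets list with numeric vectors `VA` and `VG`:
#'   multiplicative site offsets for vessel area and grouping (recycled to
#'   `n_sites`).
#' @param noise_cv coefficient of variation of the lognormal vessel-size
#'   noise.
#' @param group_fraction fraction of vessels placed in multi-vessel groups
#'   (groups of 2-4; the rest are solitary).
#' @param seed master RNG seed; per-tree substreams are derived from it, so
#'   identical configurations give byte-identical tables.
#' @return An object of class `qwa_synth_config`.
#' @export
synth_config <- function(n_sites = 3,
                         trees_per_site = 5,
                         year_start = 1968,
                         year_end = 2004,
                         vessels_per_ring_mean = 200,
                         ring_width_mean_um = 1300,
                         profile_shape = list(va_plateau_end = 0.5,
                                              vd_peak = 0.9,
                                              va_end_fraction = 0.3),
                         ontogenetic_trend = 0.01,
                         climate_signal = 0.6,
                         site_offsets = list(VA = c(1.0, 1.1, 0.9),
                                             VG = c(0.95, 1.0, 1.15)),
                         noise_cv = 0.4,
                         group_fraction = 0.25,
                         seed = 1L) {
  stopifnot(n_sites >= 1, trees_per_site >= 1, vessels_per_ring_mean >= 1)
  if (year_end <= year_start) {
    qwa_validation_error("year_end must be > year_start")
  }
  if (climate_signal < 0 || climate_signal > 1) {
    qwa_validation_error("climate_signal must lie in [0, 1]")
  }
  if (noise_cv <= 0) qwa_validation_error("noise_cv must be > 0")
  if (group_fraction < 0 || group_fraction > 1) {
    qwa_validation_error("group_fraction must lie in [0, 1]")
  }
  ps <- utils::modifyList(
    list(va_plateau_end = 0.5, vd_peak = 0.9, va_end_fraction = 0.3),
    profile_shape)
  stopifnot(ps$va_plateau_end > 0, ps$va_plateau_end < 1,
            ps$vd_peak > 0, ps$vd_peak < 1, ps$va_end_fraction > 0)
  cfg <- list(
    n_sites = as.integer(n_sites),
    trees_per_site = as.integer(trees_per_site),
    year_start = as.integer(year_start),
    year_end = as.integer(year_end),
    vessels_per_ring_mean = vessels_per_ring_mean,
    ring_width_mean_um = ring_width_mean_um,
    profile_shape = ps,
    ontogenetic_trend = ontogenetic_trend,
    climate_signal = climate_signal,
    site_offsets = list(
      VA = rep_len(site_offsets$VA, n_sites),
      VG = rep_len(site_offsets$VG, n_sites)),
    noise_cv = noise_cv,
    group_fraction = group_fraction,
    seed = as.integer(seed),
    # base expected vessel lumen area of the early-wood plateau (um^2)
    va_plateau_um2 = 2500,
    # strength of the climate multiplier at climate_signal = 1
    climate_beta = 0.2,
    # mixture weight of the density-peak beta component
    vd_beta_weight = 0.45,
    vd_beta_conc = 8
  )
  class(cfg) <- "qwa_synth_config"
  cfg
}

#' Expectation functions of the synthetic generator
#'
#' Returns the deterministic shape functions the generator draws around:
#' the relative expected vessel-area profile `va(p)` (1 on the early-wood
#' plateau) and the probability density `position(p)` of vessel relative
#' positions.  These serve as independent oracles when checking that
#' generated data follow the configured structure.
#'
#' @param config a [synth_config()] object.
#' @return list of functions `va(p)` and `position(p)`.
#' @export
synth_expectation <- function(config) {
  ps <- config$profile_shape
  va <- function(p) {
    ifelse(p <= ps$va_plateau_end, 1,
           1 - (1 - ps$va_end_fraction) * (p - ps$va_plateau_end) /
             (1 - ps$va_plateau_end))
  }
  a <- 1 + ps$vd_peak * (config$vd_beta_conc - 2)
  b <- 1 + (1 - ps$vd_peak) * (config$vd_beta_conc - 2)
  w <- config$vd_beta_weight
  position <- function(p) (1 - w) + w * stats::dbeta(p, a, b)
  list(va = va, position = position)
}

#' Generate a synthetic monthly climate series
#'
#' Monthly mean temperature is a seasonal sinusoid (Mediterranean
#' mountain climate: annual mean 13.3 C, January minimum near 4 C) plus an
#' AR(1) inter-annual anomaly and monthly noise.  Monthly precipitation is
#' a seasonal mean with a summer drought trough, modulated by lognormal
#' monthly anomalies and an inter-annual wetness factor, so sums stay
#' non-negative and right-skewed.
#'
#' @param config a [synth_config()] object.
#' @return data frame `year, month, tmean, prec` covering every month of
#'   the configured span.
#' @export
generate_climate <- function(config) {
  stopifnot(inherits(config, "qwa_synth_config"))
  years <- config$year_start:config$year_end
  ny <- length(years)
  with_seed(config$seed + 101L, {
    # AR(1) annual temperature anomaly, marginal sd 0.7 C
    phi <- 0.3
    a <- numeric(ny)
    a[1] <- stats::rnorm(1, 0, 0.7)
    innov <- stats::rnorm(ny, 0, 0.7 * sqrt(1 - phi^2))
    for (i in seq_len(ny - 1)) a[i + 1] <- phi * a[i] + innov[i + 1]
    wet <- stats::rnorm(ny, 0, 0.15)  # annual log wetness factor
    grid <- expand.grid(month = 1:12, year = years)
    clim_t <- 13.3 - 9.3 * cos(2 * pi * (grid$month - 1) / 12)
    clim_p <- 62 * (1 + 0.45 * cos(2 * pi * (grid$month - 1) / 12))
    iy <- match(grid$year, years)
    tmean <- clim_t + a[iy] + stats::rnorm(nrow(grid), 0, 1.2)
    sdl <- 0.45
    prec <- clim_p * exp(wet[iy]) *
      stats::rlnorm(nrow(grid), meanlog = -sdl^2 / 2, sdlog = sdl)
    data.frame(year = grid$year, month = grid$month,
               tmean = tmean, prec = prec)
  })
}

#' Generate synthetic vessel and ring tables for all sites
#'
#' Per ring, the vessel count is Poisson with mean proportional to ring
#' width; relative positions are drawn from a uniform/beta mixture whose
#' density rises toward the configured density-peak position; expected
#' lumen area is the configured intra-ring profile times the ontogenetic
#' trend, the site offset, and (for early-wood vessels) a multiplier
#' driven by the standardized log June-August precipitation sum, with
#' mean-one lognormal noise on top.  The analyzed xylem area is set so
#' that the relative vessel area fluctuates around one quarter.
#'
#' @param config a [synth_config()] object.
#' @param climate a climate table covering the configured years, as from
#'   [generate_climate()].
#' @return list with data frames `vessels` and `rings` in the layouts of
#'   [read_vessels()] and [read_rings()].
#' @export
generate_stand <- function(config, climate) {
  stopifnot(inherits(config, "qwa_synth_config"))
  years <- config$year_start:config$year_end
  if (!all(years %in% climate$year)) {
    qwa_validation_error("climate does not cover the configured years")
  }
  exp_fun <- synth_expectation(config)
  ps <- config$profile_shape
  a_beta <- 1 + ps$vd_peak * (config$vd_beta_conc - 2)
  b_beta <- 1 + (1 - ps$vd_peak) * (config$vd_beta_conc - 2)

  jja <- climate[climate$month %in% 6:8 & climate$year %in% years, ]
  jja_sum <- tapply(jja$prec, factor(jja$year, levels = years), sum)
  zjja <- as.numeric(scale(log(jja_sum)))
  gamma <- config$climate_signal * config$climate_beta

  n_trees <- config$n_sites * config$trees_per_site
  tree_seeds <- with_seed(config$seed,
                          sample.int(.Machine$integer.max - 1L, n_trees))
  sdl <- sqrt(log(1 + config$noise_cv^2))

  vs <- vector("list", n_trees)
  rs <- vector("list", n_trees)
  idx <- 0L
  for (s in seq_len(config$n_sites)) {
    site <- sprintf("S%d", s)
    for (tr in seq_len(config$trees_per_site)) {
      idx <- idx + 1L
      tree <- sprintf("%s_T%d", site, tr)
      res <- with_seed(tree_seeds[idx], {
        age0 <- sample(5:25, 1)  # cambial age at the first generated ring
        trw <- config$ring_width_mean_um *
          stats::rlnorm(length(years), -0.25^2 / 2, 0.25)
        # tree-level inter-annual noise common to all vessels of a ring
        ring_noise <- stats::rnorm(length(years), 0, 0.1)
        vlist <- vector("list", length(years))
        xylem <- numeric(length(years))
        for (k in seq_along(years)) {
          lambda <- config$vessels_per_ring_mean * trw[k] /
            config$ring_width_mean_um
          n <- max(1L, stats::rpois(1, lambda))
          mix <- stats::runif(n) < config$vd_beta_weight
          p <- ifelse(mix, stats::rbeta(n, a_beta, b_beta), stats::runif(n))
          age <- age0 + k - 1
          mu <- config$va_plateau_um2 * config$site_offsets$VA[s] *
            (1 + config$ontogenetic_trend)^age * exp_fun$va(p) *
            exp(gamma * zjja[k] * (p < 0.5)) * exp(ring_noise[k])
          area <- mu * stats::rlnorm(n, -sdl^2 / 2, sdl)
          gid <- assign_synth_groups(n, config$group_fraction *
                                        config$site_offsets$VG[s],
                                     prefix = sprintf("%s_%d", tree, years[k]))
          vlist[[k]] <- data.frame(
            site_id = site, tree_id = tree, year = years[k],
            vessel_id = sprintf("v%04d", seq_len(n)),
            lumen_area = area, rel_position = p, group_id = gid,
            stringsAsFactors = FALSE)
          rva <- 0.25 * exp(stats::rnorm(1, 0, 0.1))
          xylem[k] <- sum(area) / min(rva, 0.9)
        }
        list(vessels = do.call(rbind, vlist),
             rings = data.frame(site_id = site, tree_id = tree, year = years,
                                trw = trw, xylem_area = xylem,
                                stringsAsFactors = FALSE))
      })
      vs[[idx]] <- res$vessels
      rs[[idx]] <- res$rings
    }
  }
  vessels <- do.call(rbind, vs)
  rings <- do.call(rbind, rs)
  rownames(vessels) <- NULL
  rownames(rings) <- NULL
  list(vessels = vessels, rings = rings)
}

# group labels: a configurable fraction of vessels joins groups of 2-4,
# the rest stay solitary (one group each); sites with a larger grouping
# offset get a proportionally larger grouped fraction
assign_synth_groups <- function(n, grouped_frac, prefix) {
  grouped_frac <- min(1, max(0, grouped_frac))
  in_group <- which(stats::runif(n) < grouped_frac)
  gid <- sprintf("%s_g%04d", prefix, seq_len(n))  # default: solitary
  pool <- sample(in_group)
  gnum <- n
  while (length(pool) >= 2) {
    size <- min(length(pool), sample(2:4, 1))
    gnum <- gnum + 1L
    gid[pool[seq_len(size)]] <- sprintf("%s_g%04d", prefix, gnum)
    pool <- pool[-seq_len(size)]
  }
  gid
}

#' Generate a complete synthetic data set
#'
#' Convenience wrapper running [generate_climate()] and [generate_stand()].
#'
#' @param config a [synth_config()] object.
#' @return list with `vessels`, `rings` and `climate` data frames.
#' @export
generate_dataset <- function(config) {
  climate <- generate_climate(config)
  stand <- generate_stand(config, climate)
  c(stand, list(climate = climate))
}
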