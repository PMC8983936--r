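#' Configuration of a full pipeline run
#'
#' Either paths to vessel/ring/climate CSV inputs or a synthetic
#' configuration must be supplied.
#'
#' @param vessels,rings,climate input CSV paths (ignored in synthetic
#'   mode).
#' @param synthetic a [synth_config()] object, or NULL to read the paths.
#' @param k number of intra-ring sectors, 5 or 10.
#' @param common_period integer years; NULL uses all years present.
#' @param cutoff_years spline frequency-cutoff wavelength (default 30).
#' @param test a [test_config()].
#' @param corr_traits traits whose chronologies enter the climate
#'   correlation (default the robust-by-convention `VA95`; all seven are
#'   computed and reported in the chronology table).
#' @param period_before,period_after calendar windows for the two-period
#'   comparison.
#' @param extreme_k extremes per tail for the extreme-year classifier.
#' @param out_dir output directory (created if missing).
#' @return object of class `qwa_run_config`.
#' @export
run_config <- function(vessels = NULL, rings = NULL, climate = NULL,
                       synthetic = NULL, k = 5, common_period = NULL,
                       cutoff_years = 30, test = test_config(seed = 1L),
                       corr_traits = "VA95",
                       period_before = 1968:1981,
                       period_after = 1990:2004,
                       extreme_k = 5L,
                       out_dir = tempfile("qwa_run_")) {
  if (!k %in% c(5, 10)) qwa_validation_error("k must be 5 or 10")
  if (is.null(synthetic)) {
    for (p in c(vessels, rings, climate)) {
      if (is.null(p) || !file.exists(p)) {
        qwa_validation_error("input paths must exist unless synthetic mode is on")
      }
    }
  } else {
    stopifnot(inherits(synthetic, "qwa_synth_config"))
  }
  stopifnot(inherits(test, "qwa_test_config"))
  structure(list(vessels = vessels, rings = rings, climate = climate,
                 synthetic = synthetic, k = as.integer(k),
                 common_period = common_period,
                 cutoff_years = cutoff_years, test = test,
                 corr_traits = corr_traits,
                 period_before = period_before, period_after = period_after,
                 extreme_k = as.integer(extreme_k), out_dir = out_dir),
            class = "qwa_run_config")
}

#' Run the full analysis pipeline
#'
#' Executes simulate/read, sectorize and filter, trait computation, both
#' standardizations, chronology building, site and period comparisons,
#' climate correlations, and extreme-year classification, writing every
#' result as a tidy CSV plus a JSON manifest into `config$out_dir`.
#' Outputs are pure functions of the configuration, so a rerun with the
#' same config and seed reproduces them byte for byte.
#'
#' @param config a [run_config()].
#' @return (invisibly) a list with all result tables and the manifest.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "qwa_run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  logf <- function(fmt, ...) cat(sprintf(paste0(fmt, "\n"), ...),
                                 file = log_path, append = TRUE)
  cat("", file = log_path)  # truncate

  stage <- function(name, expr) {
    logf("stage %s: start", name)
    res <- tryCatch(expr, error = function(e) {
      logf("stage %s: FAILED: %s", name, conditionMessage(e))
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    logf("stage %s: done", name)
    res
  }

  inputs <- stage("input", {
    if (!is.null(config$synthetic)) {
      ds <- generate_dataset(config$synthetic)
      write_vessels(ds$vessels, file.path(config$out_dir, "vessels.csv"))
      write_rings(ds$rings, file.path(config$out_dir, "rings.csv"))
      write_climate(ds$climate, file.path(config$out_dir, "climate.csv"))
      ds
    } else {
      list(vessels = read_vessels(config$vessels),
           rings = read_rings(config$rings),
           climate = read_climate(config$climate))
    }
  })

  scheme <- sector_scheme(config$k)
  sectorized <- stage("sectorize", assign_sectors(inputs$vessels, scheme))
  filters <- stage("filter",
                   filter_sectors(sectorized, inputs$rings, scheme))
  traits <- stage("traits",
                  sector_traits(sectorized, inputs$rings, scheme, filters))
  profiles <- stage("profiles", standardize_profiles(traits))
  indexed <- stage("index", index_traits(traits,
                                         cutoff_years = config$cutoff_years))
  trw_indexed <- stage("index_trw", {
    rows <- list()
    for (chunk in split(inputs$rings,
                        interaction(inputs$rings$site_id,
                                    inputs$rings$tree_id, drop = TRUE))) {
      chunk <- chunk[order(chunk$year), ]
      idx <- index_series(chunk$trw, chunk$year, config$cutoff_years)
      rows[[length(rows) + 1L]] <- data.frame(
        site_id = chunk$site_id[1], tree_id = chunk$tree_id[1],
        trait = "TRW", sector = 0L, year = idx$year, value = idx$value,
        fitted = idx$fitted, index = idx$index, stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })
  indexed <- rbind(indexed, trw_indexed)
  chron <- stage("chronology",
                 chronology_table(indexed, config$common_period))
  idx_climate <- stage("index_climate",
                       index_climate(inputs$climate, config$cutoff_years))

  site_cmp <- stage("compare_sites", {
    ring_rows <- traits[traits$sector == 0 & !traits$discarded, ]
    rows <- list()
    for (trait in c("VA", "VA95", "DH", "KH", "VD", "RVA", "VG")) {
      v <- ring_rows[[trait]]
      ok <- is.finite(v)
      if (length(unique(ring_rows$site_id[ok])) < 2) next
      cmp <- compare_sites(v[ok], ring_rows$site_id[ok], config$test)
      g <- cmp$global; pw <- cmp$pairwise
      rows[[length(rows) + 1L]] <- data.frame(
        trait = trait, comparison = c(g$comparison, pw$comparison),
        statistic = c(g$statistic, pw$statistic),
        p_raw = c(g$p_raw, pw$p_raw),
        p_adj = c(NA, pw$p_adj),
        scope = c("global", rep("pairwise", nrow(pw))),
        stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })

  period_cmp <- stage("compare_periods", {
    prof <- profiles
    names(prof)[names(prof) == "x_std"] <- "value_std"
    long <- data.frame(site_id = prof$site_id, trait = prof$trait,
                       sector = prof$sector, year = prof$year,
                       value = prof$value_std, stringsAsFactors = FALSE)
    tryCatch(compare_periods(long, config$period_before,
                             config$period_after, config$test),
             qwa_validation_error = function(e) {
               logf("compare_periods skipped: %s", conditionMessage(e))
               NULL
             })
  })

  correlations <- stage("correlate", {
    sel <- chron$chronologies[chron$chronologies$trait %in%
                                config$corr_traits, ]
    if (nrow(sel)) climate_correlations(sel, idx_climate, config$test)
    else NULL
  })

  extremes <- stage("extremes",
                    select_extreme_years(inputs$climate,
                                         config$common_period,
                                         config$extreme_k))

  results <- list(
    traits = traits, filter_sectors = filters$sectors,
    filter_rings = filters$rings, profiles = profiles, indexed = indexed,
    chronology_stats = chron$stats, chronologies = chron$chronologies,
    indexed_climate = idx_climate, site_comparison = site_cmp,
    period_comparison = period_cmp, climate_correlations = correlations,
    extreme_years = as.data.frame(extremes))

  stage("write", {
    for (nm in names(results)) {
      if (!is.null(results[[nm]])) {
        write_table(results[[nm]], file.path(config$out_dir,
                                             paste0(nm, ".csv")))
      }
    }
  })

  manifest <- list(
    package = "qwanat",
    version = as.character(utils::packageVersion("qwanat")),
    k = config$k,
    cutoff_years = config$cutoff_years,
    alpha = config$test$alpha,
    n_permutations = config$test$n_permutations,
    seed = if (!is.null(config$synthetic)) config$synthetic$seed else
      config$test$seed,
    synthetic = !is.null(config$synthetic),
    n_vessels = nrow(inputs$vessels),
    n_rings = nrow(inputs$rings),
    n_sectors_discarded = filters$n_sectors_discarded,
    n_rings_discarded = filters$n_rings_discarded,
    rows = lapply(results, function(x) if (is.null(x)) 0L else nrow(x)))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  logf("run complete")
  invisible(c(results, list(manifest = manifest)))
}
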