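#' Expressed population signal
#'
#' The standard expression `EPS = n rbar / (1 + (n - 1) rbar)`: the
#' estimated fraction of the hypothetical population signal captured by a
#' mean chronology of `n` series whose mean inter-series correlation is
#' `rbar`.
#'
#' @param rbar mean pairwise inter-series correlation.
#' @param n number of series.
#' @return EPS value(s) in `[0, 1]` for `rbar >= 0`.
#' @export
eps_wigley <- function(rbar, n) {
  n * rbar / (1 + (n - 1) * rbar)
}

#' Build a site chronology with robustness statistics
#'
#' Averages per-tree indexed series into a site mean chronology over a
#' common period and computes the mean pairwise Pearson correlation
#' (Rbar, pairwise-complete over the common period) and the expressed
#' population signal ([eps_wigley()]).
#'
#' @param series long data frame `tree_id, year, index` holding one
#'   indexed series per tree.
#' @param common_period integer years defining the common period (default:
#'   all years present).
#' @return An object of class `qwa_chronology`: list with `chronology`
#'   (data frame `year, value, n_trees`), `rbar`, `eps`, `n_series`,
#'   `common_period`.
#' @export
build_chronology <- function(series, common_period = NULL) {
  if (is.null(common_period)) {
    common_period <- sort(unique(series$year))
  }
  sub <- series[series$year %in% common_period, , drop = FALSE]
  trees <- unique(sub$tree_id)
  if (length(trees) < 2) {
    qwa_validation_error("need >= 2 tree series overlapping the common period")
  }
  years <- sort(unique(sub$year))
  mat <- matrix(NA_real_, length(years), length(trees),
                dimnames = list(years, trees))
  mat[cbind(match(sub$year, years), match(sub$tree_id, trees))] <- sub$index
  cors <- c()
  for (i in seq_len(length(trees) - 1)) {
    for (j in (i + 1):length(trees)) {
      ok <- is.finite(mat[, i]) & is.finite(mat[, j])
      if (sum(ok) >= 3 && stats::sd(mat[ok, i]) > 0 && stats::sd(mat[ok, j]) > 0) {
        cors <- c(cors, stats::cor(mat[ok, i], mat[ok, j]))
      }
    }
  }
  rbar <- if (length(cors)) mean(cors) else NA_real_
  n <- length(trees)
  chron <- data.frame(
    year = years,
    value = rowMeans(mat, na.rm = TRUE),
    n_trees = as.integer(rowSums(is.finite(mat))))
  chron$value[chron$n_trees == 0] <- NA_real_
  structure(list(chronology = chron, rbar = rbar,
                 eps = if (is.na(rbar)) NA_real_ else eps_wigley(rbar, n),
                 n_series = n, common_period = range(common_period)),
            class = "qwa_chronology")
}

#' @export
print.qwa_chronology <- function(x, ...) {
  cat(sprintf(
    "qwa chronology: %d series, %d-%d, Rbar = %.3f, EPS = %.3f\n",
    x$n_series, x$common_period[1], x$common_period[2], x$rbar, x$eps))
  invisible(x)
}

#' Chronologies and robustness table for all site x trait x sector series
#'
#' Builds a site chronology per site x trait x sector from a long indexed
#' table (see [index_traits()]) and reports Rbar, EPS and sample size,
#' flagging chronologies below an EPS reporting threshold.
#'
#' @param indexed long data frame `site_id, tree_id, trait, sector, year,
#'   index`.
#' @param common_period integer years; default all years present.
#' @param eps_threshold reporting flag threshold (default 0.85).
#' @return list with `stats` (one row per site x trait x sector: `site_id,
#'   trait, sector, n_series, rbar, eps, robust`) and `chronologies`
#'   (long data frame `site_id, trait, sector, year, value, n_trees`).
#' @export
chronology_table <- function(indexed, common_period = NULL,
                             eps_threshold = 0.85) {
  keys <- interaction(indexed$site_id, indexed$trait, indexed$sector,
                      drop = TRUE)
  stats_rows <- list()
  chron_rows <- list()
  for (chunk in split(indexed, keys)) {
    ch <- tryCatch(build_chronology(chunk, common_period),
                   qwa_validation_error = function(e) NULL)
    if (is.null(ch)) next
    stats_rows[[length(stats_rows) + 1L]] <- data.frame(
      site_id = chunk$site_id[1], trait = chunk$trait[1],
      sector = chunk$sector[1], n_series = ch$n_series,
      rbar = ch$rbar, eps = ch$eps,
      robust = !is.na(ch$eps) && ch$eps >= eps_threshold,
      stringsAsFactors = FALSE)
    cr <- ch$chronology
    chron_rows[[length(chron_rows) + 1L]] <- data.frame(
      site_id = chunk$site_id[1], trait = chunk$trait[1],
      sector = chunk$sector[1], year = cr$year, value = cr$value,
      n_trees = cr$n_trees, stringsAsFactors = FALSE)
  }
  stats <- do.call(rbind, stats_rows)
  chron <- do.call(rbind, chron_rows)
  ord <- order(stats$trait, stats$site_id, stats$sector)
  stats <- stats[ord, ]
  rownames(stats) <- NULL
  rownames(chron) <- NULL
  list(stats = stats, chronologies = chron)
}
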