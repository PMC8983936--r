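#' Configuration for permutation inference
#'
#' @param alpha significance level (default 0.05).
#' @param n_permutations Monte-Carlo permutations (default 9999; the
#'   add-one p-value estimator gives `p >= 1/(n_permutations + 1)`).
#' @param seed RNG seed for the permutation stream (NULL: current stream).
#' @param adjust multiplicity correction; only `"BH"` (Benjamini-Hochberg
#'   step-up) is implemented.
#' @return object of class `qwa_test_config`.
#' @export
test_config <- function(alpha = 0.05, n_permutations = 9999L, seed = NULL,
                        adjust = "BH") {
  if (alpha <= 0 || alpha >= 1) qwa_validation_error("alpha must be in (0, 1)")
  if (n_permutations < 99) qwa_validation_error("n_permutations must be >= 99")
  adjust <- match.arg(adjust, "BH")
  structure(list(alpha = alpha, n_permutations = as.integer(n_permutations),
                 seed = seed, adjust = adjust),
            class = "qwa_test_config")
}

#' Monte-Carlo permutation test of independence
#'
#' Tests whether a numeric response is independent of a group label
#' without distributional assumptions.  The statistic is the maximum
#' absolute standardized group-sum deviation: for group `g`,
#' `T_g = (S_g - n_g m) / sd(S_g)` where `S_g` is the group sum, `m` the
#' grand mean, and `sd(S_g)` the exact standard deviation of `S_g` under
#' random relabelling (`sqrt(n_g (N - n_g) / (N - 1)) * s`, `s` the
#' population SD).  The null distribution is built by Monte-Carlo label
#' permutation and the p-value is the add-one estimator
#' `(b + 1) / (N_perm + 1)`.
#'
#' @param values numeric vector.
#' @param groups group labels, same length.
#' @param config a [test_config()].
#' @return data frame with `comparison`, `statistic`, `p_raw`, `note` and
#'   per-group sizes in the attribute `"n"`.
#' @export
permutation_independence_test <- function(values, groups,
                                          config = test_config()) {
  stopifnot(inherits(config, "qwa_test_config"))
  ok <- is.finite(values) & !is.na(groups)
  values <- values[ok]
  groups <- factor(groups[ok])
  ng <- table(groups)
  if (nlevels(groups) < 2 || any(ng < 2)) {
    qwa_validation_error("need >= 2 groups with >= 2 values each")
  }
  runner <- function() {
    if (stats::sd(values) == 0) {
      return(list(stat = 0, p = 1, note = "degenerate: all values identical"))
    }
    stat <- max_abs_group_z(values, groups)
    nperm <- config$n_permutations
    n <- length(values)
    sizes <- tabulate(groups)
    # the grand mean and population variance are permutation-invariant,
    # so only the group sums need recomputing per relabelling; summing
    # fixed-length blocks of a shuffled value vector is equivalent to
    # shuffling the labels
    mu <- mean(values)
    s2 <- sum((values - mu)^2) / n
    ends <- cumsum(sizes)
    lower <- c(0, ends[-length(ends)])
    sd_s <- sqrt(sizes * (n - sizes) / (n - 1) * s2)
    b <- 0L
    for (i in seq_len(nperm)) {
      cs <- cumsum(values[sample.int(n)])
      sums <- cs[ends] - c(0, cs[lower[-1]])
      if (max(abs((sums - sizes * mu) / sd_s)) >= stat) b <- b + 1L
    }
    list(stat = stat, p = (b + 1) / (nperm + 1), note = "")
  }
  res <- if (is.null(config$seed)) runner() else with_seed(config$seed, runner())
  out <- data.frame(
    comparison = paste(levels(groups), collapse = " vs "),
    statistic = res$stat, p_raw = res$p, note = res$note,
    stringsAsFactors = FALSE)
  attr(out, "n") <- as.integer(ng)
  out
}

# maximum absolute standardized group-sum deviation (groups: factor)
max_abs_group_z <- function(values, groups) {
  n <- length(values)
  ng <- tabulate(groups)
  mu <- mean(values)
  s2 <- sum((values - mu)^2) / n          # population variance
  sums <- rowsum(values, groups, reorder = FALSE)[, 1]
  sd_s <- sqrt(ng * (n - ng) / (n - 1) * s2)
  max(abs((sums - ng * mu) / sd_s))
}

#' Pairwise permutation t-tests
#'
#' Post-hoc two-group comparisons after a global independence test: for
#' every pair of groups the Welch t statistic is referenced against its
#' Monte-Carlo permutation null, and the add-one p-values are
#' Benjamini-Hochberg adjusted across the pair family.
#'
#' @inheritParams permutation_independence_test
#' @return data frame with one row per pair: `comparison, group1, group2,
#'   statistic, n1, n2, p_raw, p_adj`.
#' @export
pairwise_permutation_t <- function(values, groups, config = test_config()) {
  stopifnot(inherits(config, "qwa_test_config"))
  ok <- is.finite(values) & !is.na(groups)
  values <- values[ok]
  groups <- factor(groups[ok])
  lev <- levels(groups)
  if (length(lev) < 2) qwa_validation_error("need >= 2 groups")
  pairs <- utils::combn(lev, 2)
  runner <- function() {
    rows <- vector("list", ncol(pairs))
    for (p in seq_len(ncol(pairs))) {
      g1 <- pairs[1, p]; g2 <- pairs[2, p]
      x <- values[groups == g1]
      y <- values[groups == g2]
      if (length(x) < 2 || length(y) < 2) {
        qwa_validation_error("need >= 2 values per group")
      }
      pooled <- c(x, y)
      n1 <- length(x)
      if (stats::sd(pooled) == 0) {
        stat <- 0; pv <- 1
      } else {
        stat <- welch_t(x, y)
        b <- 0L
        for (i in seq_len(config$n_permutations)) {
          perm <- pooled[sample.int(length(pooled))]
          if (abs(welch_t(perm[seq_len(n1)], perm[-seq_len(n1)])) >=
              abs(stat)) b <- b + 1L
        }
        pv <- (b + 1) / (config$n_permutations + 1)
      }
      rows[[p]] <- data.frame(
        comparison = paste(g1, "vs", g2), group1 = g1, group2 = g2,
        statistic = stat, n1 = length(x), n2 = length(y), p_raw = pv,
        stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  }
  out <- if (is.null(config$seed)) runner() else with_seed(config$seed, runner())
  out$p_adj <- adjust_bh(out$p_raw)
  rownames(out) <- NULL
  out
}

welch_t <- function(x, y) {
  (mean(x) - mean(y)) /
    sqrt(stats::var(x) / length(x) + stats::var(y) / length(y))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin, range-checked wrapper around `stats::p.adjust(method = "BH")`:
#' adjusted values are `min_{j >= i} (m p_(j) / j)` capped at 1, a
#' monotone step-up transform controlling the false discovery rate.
#'
#' @param p p-values in `[0, 1]`.
#' @return adjusted p-values, same order as the input.
#' @export
adjust_bh <- function(p) {
  pp <- p[!is.na(p)]
  if (length(pp) && (any(pp < 0) || any(pp > 1))) {
    qwa_validation_error("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Monthly Spearman climate correlations of sector chronologies
#'
#' Correlates each site x trait x sector chronology with indexed monthly
#' temperature and precipitation over a 24-month window: previous-year
#' January through current-year December, to capture both lagged and
#' immediate associations.  Spearman's rank correlation (average ranks
#' for ties) is used; p-values are Benjamini-Hochberg adjusted within
#' each site x trait x sector x variable family of 24 months.
#'
#' @param chronologies long data frame `site_id, trait, sector, year,
#'   value` (site mean chronologies, see [chronology_table()]).
#' @param indexed_climate output of [index_climate()].
#' @param config a [test_config()] (only `alpha` and `adjust` are used).
#' @param min_overlap minimum overlapping years (default 10).
#' @return data frame `site_id, trait, sector, variable, month_rel,
#'   month, rho, p_raw, p_adj, significant, n` where `month_rel` is
#'   `"previous"` or `"current"`.
#' @export
climate_correlations <- function(chronologies, indexed_climate,
                                 config = test_config(),
                                 min_overlap = 10L) {
  keys <- interaction(chronologies$site_id, chronologies$trait,
                      chronologies$sector, drop = TRUE)
  out <- list()
  for (chunk in split(chronologies, keys)) {
    for (variable in c("tmean", "prec")) {
      fam <- vector("list", 24)
      i <- 0L
      for (rel in c("previous", "current")) {
        for (m in 1:12) {
          cl <- indexed_climate[indexed_climate$variable == variable &
                                  indexed_climate$month == m, ]
          cl_year <- if (rel == "previous") cl$year + 1L else cl$year
          idx <- match(chunk$year, cl_year)
          x <- chunk$value
          y <- cl$index[idx]
          ok <- is.finite(x) & is.finite(y)
          if (sum(ok) < min_overlap) {
            qwa_validation_error(sprintf(
              "only %d overlapping years for %s %s (need >= %d)",
              sum(ok), variable, rel, min_overlap))
          }
          ct <- suppressWarnings(
            stats::cor.test(x[ok], y[ok], method = "spearman",
                            exact = FALSE))
          i <- i + 1L
          fam[[i]] <- data.frame(
            site_id = chunk$site_id[1], trait = chunk$trait[1],
            sector = chunk$sector[1], variable = variable,
            month_rel = rel, month = m,
            rho = unname(ct$estimate), p_raw = ct$p.value, n = sum(ok),
            stringsAsFactors = FALSE)
        }
      }
      fam <- do.call(rbind, fam)
      fam$p_adj <- adjust_bh(fam$p_raw)
      fam$significant <- fam$p_adj <= config$alpha
      out[[length(out) + 1L]] <- fam
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Classify climatically extreme years from the summer trimester
#'
#' For each climate variable the June-August (JJA) value of every year is
#' computed (mean of monthly mean temperatures; sum of monthly
#' precipitation sums) and the `k` years with the highest and lowest
#' values are selected as extreme (ties broken by the earlier calendar
#' year).  Each selected set is verified against the 85th (high tail) or
#' 15th (low tail) percentile of the study period and, when a longer
#' series is supplied, of the full series.
#'
#' @param climate monthly climate table.
#' @param period integer years defining the study period (default: all
#'   years in `climate`).
#' @param k extremes per tail (default 5).
#' @param full_series optional longer climate table for the full-series
#'   percentile check.
#' @return data frame of class `qwa_extreme_years` with one row per
#'   variable x tail x year: `variable, tail, year, jja, percentile_ok,
#'   percentile_ok_full`.
#' @export
select_extreme_years <- function(climate, period = NULL, k = 5L,
                                 full_series = NULL) {
  if (is.null(period)) period <- sort(unique(climate$year))
  if (!all(period %in% climate$year)) {
    qwa_validation_error("period must be within the climate span")
  }
  if (length(period) < 2 * k + 1) {
    qwa_validation_error(sprintf(
      "period of %d years too short for %d extremes per tail",
      length(period), k))
  }
  jja_values <- function(cl, years) {
    sub <- cl[cl$month %in% 6:8 & cl$year %in% years, ]
    data.frame(
      year = sort(unique(sub$year)),
      tmean = as.numeric(tapply(sub$tmean, sub$year, mean)),
      prec = as.numeric(tapply(sub$prec, sub$year, sum)))
  }
  jja <- jja_values(climate, period)
  jja_full <- if (is.null(full_series)) NULL else
    jja_values(full_series, unique(full_series$year))
  out <- list()
  for (variable in c("tmean", "prec")) {
    v <- jja[[variable]]
    hi <- jja$year[order(-v, jja$year)][seq_len(k)]
    lo <- jja$year[order(v, jja$year)][seq_len(k)]
    q85 <- stats::quantile(v, 0.85, type = 7, names = FALSE)
    q15 <- stats::quantile(v, 0.15, type = 7, names = FALSE)
    vf <- if (is.null(jja_full)) NULL else jja_full[[variable]]
    for (tail in c("high", "low")) {
      yrs <- if (tail == "high") hi else lo
      vals <- v[match(yrs, jja$year)]
      ok <- if (tail == "high") vals >= q85 else vals <= q15
      ok_full <- if (is.null(vf)) NA else {
        qf <- stats::quantile(vf, if (tail == "high") 0.85 else 0.15,
                              type = 7, names = FALSE)
        if (tail == "high") vals >= qf else vals <= qf
      }
      out[[length(out) + 1L]] <- data.frame(
        variable = variable, tail = tail, year = yrs, jja = vals,
        percentile_ok = ok, percentile_ok_full = ok_full,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("qwa_extreme_years", class(res))
  res
}

#' Compare two calendar periods per series group
#'
#' Runs the permutation test of independence between two calendar
#' windows (e.g. before and after a land-use change) for every series
#' group in a long table, Benjamini-Hochberg adjusting within each
#' site x trait family across sectors.  Years outside both windows are
#' excluded.
#'
#' @param data long data frame `site_id, trait, sector, year, value`
#'   (e.g. standardized profiles or absolute ring-level values).
#' @param before,after integer year windows.
#' @param config a [test_config()].
#' @return data frame `site_id, trait, sector, statistic, n_before,
#'   n_after, p_raw, p_adj, significant`.
#' @export
compare_periods <- function(data, before = 1968:1981, after = 1990:2004,
                            config = test_config()) {
  if (!length(intersect(data$year, before)) ||
      !length(intersect(data$year, after))) {
    qwa_validation_error("data do not span both periods")
  }
  sub <- data[data$year %in% c(before, after), , drop = FALSE]
  sub$period <- ifelse(sub$year %in% before, "before", "after")
  keys <- interaction(sub$site_id, sub$trait, sub$sector, drop = TRUE)
  rows <- list()
  for (chunk in split(sub, keys)) {
    ok <- is.finite(chunk$value)
    nb <- sum(chunk$period[ok] == "before")
    na_ <- sum(chunk$period[ok] == "after")
    if (nb < 2 || na_ < 2) next
    res <- permutation_independence_test(chunk$value[ok],
                                         chunk$period[ok], config)
    rows[[length(rows) + 1L]] <- data.frame(
      site_id = chunk$site_id[1], trait = chunk$trait[1],
      sector = chunk$sector[1], statistic = res$statistic,
      n_before = nb, n_after = na_, p_raw = res$p_raw,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) qwa_validation_error("no group with enough data in both periods")
  fam <- interaction(out$site_id, out$trait, drop = TRUE)
  out$p_adj <- NA_real_
  for (f in levels(fam)) {
    sel <- fam == f
    out$p_adj[sel] <- adjust_bh(out$p_raw[sel])
  }
  out$significant <- out$p_adj <= config$alpha
  rownames(out) <- NULL
  out
}

#' Compare sites for one trait
#'
#' Global permutation test of independence across sites followed by
#' pairwise permutation t-tests, applied to a vector of ring- or
#' sector-level values.
#'
#' @param values numeric vector.
#' @param sites site labels.
#' @param config a [test_config()].
#' @return list with `global` (one-row data frame) and `pairwise`
#'   (data frame from [pairwise_permutation_t()]).
#' @export
compare_sites <- function(values, sites, config = test_config()) {
  list(global = permutation_independence_test(values, sites, config),
       pairwise = pairwise_permutation_t(values, sites, config))
}
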