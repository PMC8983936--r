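test_that("BH adjustment matches hand-computed step-up values", {
  expect_equal(adjust_bh(0.03), 0.03)
  expect_equal(adjust_bh(c(0.2, 0.2, 0.2)), c(0.2, 0.2, 0.2))
  expect_equal(adjust_bh(c(0.005, 0.04, 0.04)), c(0.015, 0.04, 0.04))
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  # monotone and capped at 1
  set.seed(8)
  p <- runif(50)
  adj <- adjust_bh(p)
  expect_true(all(adj >= p - 1e-12))
  expect_true(all(adj <= 1))
  ord <- order(p)
  expect_true(all(diff(adj[ord]) >= -1e-12))
  expect_error(adjust_bh(c(0.5, 1.2)), class = "qwa_validation_error")
})

test_that("permutation independence test handles degenerate and shifted groups", {
  cfg <- test_config(n_permutations = 499, seed = 42)
  # identical vectors in both groups -> p = 1 with a note
  res <- permutation_independence_test(rep(5, 20), rep(c("a", "b"), 10), cfg)
  expect_equal(res$p_raw, 1)
  expect_match(res$note, "degenerate")
  # large location shift is always detected
  set.seed(1)
  x <- c(rnorm(30), rnorm(30, 4))
  g <- rep(c("a", "b"), each = 30)
  res2 <- permutation_independence_test(x, g, cfg)
  expect_equal(res2$p_raw, 1 / 500)
  # p-values respect the add-one lower bound
  expect_gte(res2$p_raw, 1 / (cfg$n_permutations + 1))
  expect_error(permutation_independence_test(1:5, rep("a", 5), cfg),
               class = "qwa_validation_error")
})

test_that("permutation test has near-nominal size and high power at 2 SD shift", {
  # size under a lognormal null (modest replication; the acceptance suite
  # runs the full-size study)
  cfg <- test_config(n_permutations = 199, seed = NULL)
  set.seed(314)
  rej <- replicate(400, {
    v <- rlnorm(40)
    permutation_independence_test(v, rep(c("a", "b"), each = 20),
                                  cfg)$p_raw <= 0.05
  })
  expect_lt(abs(mean(rej) - 0.05), 0.03)
  # power: 2 SD shift, n = 30 per group
  set.seed(99)
  pow <- replicate(60, {
    v <- c(rnorm(30), rnorm(30, 2))
    permutation_independence_test(v, rep(c("a", "b"), each = 30),
                                  cfg)$p_raw <= 0.05
  })
  expect_gte(mean(pow), 0.99)
})

test_that("pairwise permutation t-tests agree with exhaustive enumeration", {
  cfg <- test_config(n_permutations = 1999, seed = 5)
  set.seed(17)
  x <- rnorm(4); y <- rnorm(4, 1.5)
  res <- pairwise_permutation_t(c(x, y), rep(c("a", "b"), each = 4), cfg)
  exact <- exact_welch_perm_p(x, y)
  mc_err <- 3 * sqrt(exact * (1 - exact) / cfg$n_permutations)
  expect_lt(abs(res$p_raw - exact), 2 / (cfg$n_permutations + 1) + mc_err)
  # three groups produce three pairwise rows with BH across the family
  set.seed(2)
  v <- c(rnorm(10), rnorm(10, 0.5), rnorm(10, 3))
  g <- rep(c("a", "b", "c"), each = 10)
  res3 <- pairwise_permutation_t(v, g, test_config(n_permutations = 199,
                                                   seed = 1))
  expect_equal(nrow(res3), 3)
  expect_equal(res3$p_adj, adjust_bh(res3$p_raw))
  expect_true(all(res3$p_adj >= res3$p_raw - 1e-12))
})

test_that("extreme-year classifier flags 2k years with verified percentiles", {
  set.seed(23)
  years <- 1968:2004
  grid <- expand.grid(month = 1:12, year = years)
  clim <- data.frame(year = grid$year, month = grid$month,
                     tmean = 15 + rnorm(nrow(grid)),
                     prec = rlnorm(nrow(grid), 4, 0.4))
  ex <- select_extreme_years(clim, years, k = 5)
  # 10 of 37 years flagged per variable, tails disjoint
  for (v in c("tmean", "prec")) {
    sub <- ex[ex$variable == v, ]
    expect_equal(nrow(sub), 10)
    expect_length(intersect(sub$year[sub$tail == "high"],
                            sub$year[sub$tail == "low"]), 0)
  }
  # 5-of-37 tails clear the 85th/15th percentile by order statistics
  expect_true(all(ex$percentile_ok))
  # high tail of a monotone series is the last k years
  clim2 <- clim
  clim2$tmean <- clim2$year - 1900 + clim2$month / 100
  ex2 <- select_extreme_years(clim2, years, k = 5)
  expect_setequal(ex2$year[ex2$variable == "tmean" & ex2$tail == "high"],
                  2000:2004)
  expect_setequal(ex2$year[ex2$variable == "tmean" & ex2$tail == "low"],
                  1968:1972)
  expect_error(select_extreme_years(clim, 1968:1977, k = 5),
               "too short", class = "qwa_validation_error")
})

test_that("period comparison excludes gap years and holds size under the null", {
  set.seed(41)
  years <- 1968:2004
  mkdata <- function(shift = 0) {
    do.call(rbind, lapply(1:5, function(s) {
      data.frame(site_id = "S1", trait = "VA", sector = s, year = years,
                 value = rnorm(length(years)) +
                   shift * (years >= 1990) * (s <= 2),
                 stringsAsFactors = FALSE)
    }))
  }
  cfg <- test_config(n_permutations = 199, seed = 9)
  res <- compare_periods(mkdata(0), 1968:1981, 1990:2004, cfg)
  expect_equal(nrow(res), 5)
  expect_equal(unique(res$n_before), 14)  # 1968-1981
  expect_equal(unique(res$n_after), 15)   # 1990-2004; 1982-1989 excluded
  # injected shift in sectors 1-2 is detected there
  res2 <- compare_periods(mkdata(2), 1968:1981, 1990:2004, cfg)
  expect_true(all(res2$significant[res2$sector <= 2]))
  expect_false(any(res2$significant[res2$sector > 2]))
  # null rejections near alpha (raw p across repeated simulated tables)
  set.seed(6)
  praw <- replicate(60, compare_periods(
    mkdata(0)[1:37, ], 1968:1981, 1990:2004,
    test_config(n_permutations = 199))$p_raw)
  expect_lt(mean(praw <= 0.05), 0.15)
})

test_that("climate correlations recover a perfect monotone dependence", {
  set.seed(13)
  years <- 1961:2004
  grid <- expand.grid(month = 1:12, year = years)
  clim <- data.frame(year = grid$year, month = grid$month,
                     tmean = 12 + 6 * sin(2 * pi * grid$month / 12) +
                       rnorm(nrow(grid), 0, 0.8),
                     prec = rlnorm(nrow(grid), 4, 0.3))
  idx <- index_climate(clim)
  jun <- idx[idx$variable == "prec" & idx$month == 6, ]
  chron_years <- 1968:2004
  chron <- data.frame(site_id = "S1", trait = "VA95", sector = 1L,
                      year = chron_years,
                      value = exp(jun$index[match(chron_years, jun$year)]),
                      stringsAsFactors = FALSE)
  res <- climate_correlations(chron, idx, test_config())
  expect_equal(nrow(res), 48)  # 24 months x 2 variables
  hit <- res[res$variable == "prec" & res$month == 6 &
               res$month_rel == "current", ]
  expect_equal(hit$rho, 1, tolerance = 1e-12)
  expect_true(hit$significant)
  # refuses short overlaps
  expect_error(climate_correlations(chron[1:5, ], idx, test_config()),
               "overlap", class = "qwa_validation_error")
})
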