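# Shared fixtures and independent oracles, built in code at test time.

# small deterministic vessel/ring pair for unit tests
make_toy_ring <- function(areas, positions, site = "S1", tree = "S1_T1",
                          year = 2000, trw = 1000, xylem_area = NULL,
                          group_id = NULL) {
  n <- length(areas)
  vessels <- data.frame(
    site_id = site, tree_id = tree, year = year,
    vessel_id = sprintf("v%03d", seq_len(n)),
    lumen_area = areas, rel_position = positions,
    stringsAsFactors = FALSE)
  if (!is.null(group_id)) vessels$group_id <- group_id
  if (is.null(xylem_area)) xylem_area <- sum(areas) / 0.25
  rings <- data.frame(site_id = site, tree_id = tree, year = year,
                      trw = trw, xylem_area = xylem_area,
                      stringsAsFactors = FALSE)
  list(vessels = vessels, rings = rings)
}

# brute-force trait oracle: plain-loop recomputation from the vessel list,
# sharing no code with sector_traits()
oracle_traits <- function(areas, analyzed_area_um2, group_id = NULL) {
  n <- length(areas)
  d <- numeric(n)
  for (i in seq_len(n)) d[i] <- sqrt(4 * areas[i] / pi)
  num5 <- 0; num4 <- 0; kh <- 0; tot <- 0
  for (i in seq_len(n)) {
    num5 <- num5 + d[i]^5
    num4 <- num4 + d[i]^4
    kh <- kh + (d[i] * 1e-6)^4
    tot <- tot + areas[i]
  }
  sorted <- sort(areas)
  h <- (n - 1) * 0.95 + 1
  lo <- floor(h); hi <- ceiling(h)
  va95 <- sorted[lo] + (h - lo) * (sorted[hi] - sorted[lo])
  vg <- if (is.null(group_id)) NA_real_ else n / length(unique(group_id))
  list(VA = tot / n,
       VA95 = va95,
       DH = num5 / num4,
       KH = pi * 998.2 / (128 * 1.002e-9) * kh,
       VD = n / (analyzed_area_um2 * 1e-6),
       RVA = tot / analyzed_area_um2,
       VG = vg)
}

# amplitude of a fitted series at a given period, via sin/cos regression
fitted_amplitude <- function(fitted, t, period) {
  s <- sin(2 * pi * t / period)
  c_ <- cos(2 * pi * t / period)
  co <- coef(lm(fitted ~ s + c_))
  sqrt(co[["s"]]^2 + co[["c_"]]^2)
}

# exhaustive two-group permutation p-value for the Welch t statistic
exact_welch_perm_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  idx <- utils::combn(length(pooled), n1)
  tobs <- abs((mean(x) - mean(y)) /
                sqrt(var(x) / length(x) + var(y) / length(y)))
  hits <- 0L
  for (j in seq_len(ncol(idx))) {
    a <- pooled[idx[, j]]
    b <- pooled[-idx[, j]]
    tj <- abs((mean(a) - mean(b)) /
                sqrt(var(a) / length(a) + var(b) / length(b)))
    if (tj >= tobs - 1e-12) hits <- hits + 1L
  }
  hits / ncol(idx)
}
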