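test_that("equivalent diameter follows the circle formula and scaling", {
  expect_equal(equivalent_diameter(pi * 25), 10)
  expect_equal(equivalent_diameter(314.159265), 20, tolerance = 1e-6)
  a <- c(80, 500, 1234.5)
  expect_equal(equivalent_diameter(4 * a), 2 * equivalent_diameter(a))
  expect_error(equivalent_diameter(0), class = "qwa_validation_error")
  expect_error(equivalent_diameter(-3), class = "qwa_validation_error")
})

test_that("sector assignment uses half-open bins with a closed last bin", {
  mk <- function(p) data.frame(rel_position = p)
  expect_equal(assign_sectors(mk(0.37), sector_scheme(5))$sector, 2L)
  expect_equal(assign_sectors(mk(1.0), sector_scheme(10))$sector, 10L)
  # position 0.5 opens the late-formed wood half
  expect_equal(assign_sectors(mk(0.5), sector_scheme(10))$sector, 6L)
  expect_equal(assign_sectors(mk(0), sector_scheme(5))$sector, 1L)
  # every vessel lands in exactly one sector
  p <- seq(0, 1, by = 0.001)
  s <- assign_sectors(mk(p), sector_scheme(10))$sector
  expect_true(all(s >= 1 & s <= 10))
  expect_equal(s, pmin(floor(p * 10) + 1, 10))
})

test_that("sector and ring filters discard exactly the offending units", {
  # ring A: sector 1 has 4 vessels (discard), sector 2 has 5 (keep)
  toyA <- make_toy_ring(areas = rep(100, 9),
                        positions = c(0.05, 0.1, 0.15, 0.18,
                                      0.25, 0.3, 0.33, 0.36, 0.39),
                        year = 2000, trw = 1000)
  # ring B: huge vessel -> radius 45 um > sector width 40 um at k = 5
  #   (trw 200 um): ring discarded
  big <- pi * 45^2
  toyB <- make_toy_ring(areas = c(rep(50, 6), big),
                        positions = c(0.1, 0.12, 0.14, 0.16, 0.18, 0.19, 0.15),
                        year = 2001, trw = 200)
  vessels <- rbind(toyA$vessels, toyB$vessels)
  rings <- rbind(toyA$rings, toyB$rings)
  scheme <- sector_scheme(5)
  fl <- filter_sectors(assign_sectors(vessels, scheme), rings, scheme)

  s2000 <- fl$sectors[fl$sectors$year == 2000, ]
  expect_equal(s2000$discarded, c(TRUE, FALSE, TRUE, TRUE, TRUE))
  expect_equal(s2000$reason[1], "min_vessels")
  r2001 <- fl$rings[fl$rings$year == 2001, ]
  expect_true(r2001$discarded)
  expect_equal(r2001$reason, "sector_width")
  expect_equal(r2001$sector_width_um, 40)
  expect_equal(r2001$max_radius_um, 45)
  expect_false(fl$rings$discarded[fl$rings$year == 2000])
  expect_equal(fl$n_rings_discarded, 1L)
  # vessels of an unknown ring raise an error
  orphan <- toyA$vessels; orphan$year <- 1890
  expect_error(filter_sectors(assign_sectors(orphan, scheme), rings, scheme),
               "no ring record", class = "qwa_validation_error")
})

test_that("trait formulas match hand-computed values", {
  # two vessels of equivalent diameter 10 and 20 um
  areas <- pi * c(25, 100)
  toy <- make_toy_ring(areas, c(0.1, 0.15), trw = 1000, xylem_area = 1e5)
  tr <- sector_traits(toy$vessels, toy$rings, sector_scheme(5))
  ring <- tr[tr$sector == 0, ]
  expect_equal(ring$DH, (10^5 + 20^5) / (10^4 + 20^4), tolerance = 1e-12)
  expect_equal(ring$DH, 19.412, tolerance = 1e-4)
  # KH: hand evaluation of the Hagen-Poiseuille sum
  kh_hand <- pi * 998.2 / (128 * 1.002e-9) * ((10e-6)^4 + (20e-6)^4)
  expect_equal(ring$KH, kh_hand, tolerance = 1e-12)
  expect_equal(ring$VD, 2 / (1e5 * 1e-6))
  expect_equal(ring$RVA, sum(areas) / 1e5)

  # degenerate distribution: identical vessels
  same <- make_toy_ring(rep(pi * 25, 8), seq(0.05, 0.4, length.out = 8))
  trs <- sector_traits(same$vessels, same$rings, sector_scheme(5))
  ring <- trs[trs$sector == 0, ]
  expect_equal(ring$DH, 10)
  expect_equal(ring$VA95, ring$VA)

  # grouping index: 6 solitary vessels + one group of 4 -> 10 / 7
  grp <- make_toy_ring(rep(100, 10), seq(0.05, 0.45, length.out = 10),
                       group_id = c(paste0("s", 1:6), rep("G", 4)))
  trg <- sector_traits(grp$vessels, grp$rings, sector_scheme(5))
  expect_equal(trg$VG[trg$sector == 0], 10 / 7, tolerance = 1e-12)
})

test_that("KH scales as the fourth power and DH linearly in diameter", {
  set.seed(11)
  areas <- rlnorm(40, 7, 0.4)
  toy <- make_toy_ring(areas, runif(40))
  tr1 <- sector_traits(toy$vessels, toy$rings, sector_scheme(5))
  scaled <- toy
  scaled$vessels$lumen_area <- areas * 9  # diameters scaled by 3
  tr2 <- sector_traits(scaled$vessels, scaled$rings, sector_scheme(5))
  r1 <- tr1[tr1$sector == 0, ]; r2 <- tr2[tr2$sector == 0, ]
  expect_equal(r2$KH / r1$KH, 3^4, tolerance = 1e-10)
  expect_equal(r2$DH / r1$DH, 3, tolerance = 1e-10)
  # DH bounds: between min and max diameter, above the plain mean
  d <- equivalent_diameter(areas)
  expect_gte(r1$DH, mean(d))
  expect_lte(r1$DH, max(d))
  expect_gte(r1$DH, min(d))
})

test_that("sector vessel counts are conserved and sector traits match a brute-force oracle", {
  set.seed(202)
  for (rep in 1:100) {
    n <- sample(10:60, 1)
    k <- sample(c(5L, 10L), 1)
    areas <- rlnorm(n, 7, 0.5)
    pos <- runif(n)
    gid <- sample(sprintf("g%d", 1:max(2, n %/% 2)), n, replace = TRUE)
    toy <- make_toy_ring(areas, pos, group_id = gid,
                         xylem_area = sum(areas) / 0.2)
    scheme <- sector_scheme(k)
    sv <- assign_sectors(toy$vessels, scheme)
    tr <- sector_traits(sv, toy$rings, scheme)
    expect_equal(sum(tr$n_vessels[tr$sector > 0]), n)

    # whole-ring traits against the oracle
    o <- oracle_traits(areas, toy$rings$xylem_area, gid)
    ring <- tr[tr$sector == 0, ]
    for (trait in names(o)) {
      expect_equal(ring[[trait]], o[[trait]], tolerance = 1e-9,
                   label = sprintf("ring %s (rep %d)", trait, rep))
    }
    # one random retained sector against the oracle
    kept <- tr[tr$sector > 0 & !tr$discarded, ]
    if (nrow(kept)) {
      s <- kept$sector[sample.int(nrow(kept), 1)]
      sel <- sv$sector == s
      os <- oracle_traits(areas[sel], toy$rings$xylem_area / k, gid[sel])
      row <- kept[kept$sector == s, ]
      for (trait in names(os)) {
        expect_equal(row[[trait]], os[[trait]], tolerance = 1e-9,
                     label = sprintf("sector %s (rep %d)", trait, rep))
      }
    }
  }
})

test_that("coordinate-based group detection reproduces known contact clusters", {
  # two touching vessels (centres 25 um apart, radii 10 + 12 + 3 gap = 25
  # -> not touching at exactly 25; bring them to 24) and one solitary
  areas <- pi * c(10^2, 12^2, 8^2)
  toy <- make_toy_ring(areas, c(0.1, 0.12, 0.4))
  toy$vessels$x_um <- c(0, 24, 500)
  toy$vessels$y_um <- c(0, 0, 0)
  tr <- sector_traits(toy$vessels, toy$rings, sector_scheme(5))
  expect_equal(tr$VG[tr$sector == 0], 3 / 2)
  # no group_id and no coordinates -> VG is NA
  toy$vessels$x_um <- NULL; toy$vessels$y_um <- NULL
  tr2 <- sector_traits(toy$vessels, toy$rings, sector_scheme(5))
  expect_true(is.na(tr2$VG[tr2$sector == 0]))
})

test_that("ring summary equals brute-force totals and equal-area RVA averaging", {
  set.seed(5)
  toy <- make_toy_ring(rlnorm(30, 7, 0.4), runif(30))
  smry <- ring_vessel_summary(toy$vessels, toy$rings)
  expect_equal(smry$n_vessels, 30L)
  expect_equal(smry$total_lumen_area, sum(toy$vessels$lumen_area))
  expect_equal(smry$rva, sum(toy$vessels$lumen_area) / toy$rings$xylem_area)
  # two equal-area sectors with RVA 0.2 and 0.3 average to ring RVA 0.25
  a1 <- 0.2 * 5e4; a2 <- 0.3 * 5e4
  toy2 <- make_toy_ring(c(a1, a2), c(0.2, 0.7), xylem_area = 1e5)
  scheme2 <- sector_scheme(2)
  sv2 <- assign_sectors(toy2$vessels, scheme2)
  fl2 <- filter_sectors(sv2, toy2$rings, scheme2, min_vessels = 1L)
  tr <- sector_traits(sv2, toy2$rings, scheme2, filters = fl2)
  expect_equal(tr$RVA[tr$sector == 0], 0.25)
  expect_equal(mean(tr$RVA[tr$sector > 0]), 0.25)
})
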