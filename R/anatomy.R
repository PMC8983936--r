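#' Equivalent circular diameter of a vessel lumen
#'
#' Diameter of the circle with the same area: `d = 2 sqrt(A / pi)`.
#'
#' @param lumen_area lumen area(s) in um^2; must be > 0.
#' @return diameter(s) in um.
#' @export
equivalent_diameter <- function(lumen_area) {
  if (any(!is.finite(lumen_area)) || any(lumen_area <= 0)) {
    qwa_validation_error("lumen_area must be finite and > 0")
  }
  2 * sqrt(lumen_area / pi)
}

#' Intra-ring sector scheme
#'
#' Partitions the relative radial position axis `[0, 1]` into `k`
#' equal-width sectors.  Sectors are half-open `[l, u)` with the last one
#' closed at 1.  The early-formed / late-formed wood split sits at
#' relative position 0.5: sectors entirely below 0.5 belong to the early
#' formed wood.
#'
#' @param k number of sectors; 5 and 10 are the conventional choices.
#' @return An object of class `qwa_sector_scheme` with elements `k`,
#'   `breaks` and `efw_lfw_split`.
#' @export
sector_scheme <- function(k = 5) {
  k <- as.integer(k)
  if (is.na(k) || k < 2) qwa_validation_error("k must be an integer >= 2")
  structure(list(k = k, breaks = seq(0, 1, length.out = k + 1),
                 efw_lfw_split = 0.5),
            class = "qwa_sector_scheme")
}

#' Assign vessels to intra-ring sectors
#'
#' Sector `s = floor(rel_position * k) + 1`, with `rel_position = 1`
#' mapped into the last sector.
#'
#' @param vessels vessel data frame (see [read_vessels()]).
#' @param scheme a [sector_scheme()].
#' @return `vessels` with an integer `sector` column appended.
#' @export
assign_sectors <- function(vessels, scheme = sector_scheme(5)) {
  stopifnot(inherits(scheme, "qwa_sector_scheme"))
  s <- floor(vessels$rel_position * scheme$k) + 1L
  vessels$sector <- as.integer(pmin(s, scheme$k))
  vessels
}

#' Apply the sector and ring retention filters
#'
#' Two filters guard sector estimates: a sector is discarded when it holds
#' fewer than five vessels (too shallow a sample for a quantile or mean),
#' and a whole ring is discarded when the width of a sector
#' (`trw / k`, um) is not larger than the maximum vessel radius found in
#' that sector, because then single vessels straddle sector borders and
#' positional assignment is unreliable.
#'
#' @param vessels sector-labelled vessels (see [assign_sectors()]).
#' @param rings ring data frame (see [read_rings()]); every vessel's ring
#'   must be present.
#' @param scheme the [sector_scheme()] used for the labels.
#' @param min_vessels minimum vessel count per retained sector (default 5).
#' @return list with
#'   \describe{
#'     \item{sectors}{data frame `site_id, tree_id, year, sector,
#'       n_vessels, discarded, reason` covering every ring x sector cell
#'       (cells with zero vessels included);}
#'     \item{rings}{data frame `site_id, tree_id, year, sector_width_um,
#'       max_radius_um, discarded, reason`;}
#'     \item{n_sectors_discarded, n_rings_discarded}{counts.}
#'   }
#' @export
filter_sectors <- function(vessels, rings, scheme = sector_scheme(5),
                           min_vessels = 5L) {
  stopifnot(inherits(scheme, "qwa_sector_scheme"))
  k <- scheme$k
  ring_key <- function(d) paste(d$site_id, d$tree_id, d$year, sep = "\r")
  rk <- ring_key(rings)
  vk <- ring_key(vessels)
  orphan <- which(!(vk %in% rk))
  if (length(orphan)) {
    qwa_validation_error(sprintf(
      "no ring record for vessel in %s / %s / %d",
      vessels$site_id[orphan[1]], vessels$tree_id[orphan[1]],
      vessels$year[orphan[1]]))
  }
  # full ring x sector grid
  grid <- merge(rings[c("site_id", "tree_id", "year", "trw")],
                data.frame(sector = seq_len(k)))
  cnt <- stats::aggregate(list(n_vessels = vessels$year),
                          by = vessels[c("site_id", "tree_id", "year", "sector")],
                          FUN = length)
  grid <- merge(grid, cnt, all.x = TRUE,
                by = c("site_id", "tree_id", "year", "sector"))
  grid$n_vessels[is.na(grid$n_vessels)] <- 0L
  grid$discarded <- grid$n_vessels < min_vessels
  grid$reason <- ifelse(grid$discarded, "min_vessels", "")

  # ring filter: sector width must exceed the largest vessel radius of
  # any of the ring's sectors
  radius <- equivalent_diameter(vessels$lumen_area) / 2
  maxr <- tapply(radius, vk, max)
  ring_tab <- rings[c("site_id", "tree_id", "year", "trw")]
  ring_tab$sector_width_um <- ring_tab$trw / k
  ring_tab$max_radius_um <- as.numeric(maxr[rk])
  ring_tab$discarded <- !is.na(ring_tab$max_radius_um) &
    ring_tab$sector_width_um <= ring_tab$max_radius_um
  ring_tab$reason <- ifelse(ring_tab$discarded, "sector_width", "")
  ring_tab$trw <- NULL

  grid <- grid[order(grid$site_id, grid$tree_id, grid$year, grid$sector), ]
  grid$trw <- NULL
  rownames(grid) <- NULL
  rownames(ring_tab) <- NULL
  list(sectors = grid,
       rings = ring_tab,
       n_sectors_discarded = sum(grid$discarded),
       n_rings_discarded = sum(ring_tab$discarded))
}

#' Compute anatomical traits per sector and per ring
#'
#' For every retained sector (and for the whole ring, reported as sector
#' 0) the following traits are computed from the vessel list:
#' \describe{
#'   \item{VA}{mean vessel lumen area (um^2);}
#'   \item{VA95}{95th percentile of lumen area (um^2), linear-interpolation
#'     quantile;}
#'   \item{DH}{hydraulically weighted mean diameter
#'     `sum(d^5) / sum(d^4)` (um) over equivalent circular diameters;}
#'   \item{KH}{theoretical hydraulic conductivity by the Hagen-Poiseuille
#'     law, `pi * rho / (128 * eta) * sum(d_i^4)` with diameters in m and
#'     pure water at 20 C (rho = 998.2 kg m^-3,
#'     eta = 1.002e-9 MPa s), in kg m MPa^-1 s^-1;}
#'   \item{VD}{vessel density, vessels per mm^2 of analyzed xylem (the
#'     sector's share of the analyzed area is `xylem_area / k`);}
#'   \item{RVA}{relative vessel area, total lumen area over analyzed
#'     area;}
#'   \item{VG}{vessel grouping index, vessels per vessel group (a solitary
#'     vessel is a group of one).}
#' }
#' Sectors failing a filter keep their row with `discarded = TRUE` and NA
#' traits; rings failing the sector-width filter are fully discarded.
#'
#' @param vessels sector-labelled vessels (see [assign_sectors()]).
#' @param rings ring data frame.
#' @param scheme the [sector_scheme()] used.
#' @param filters result of [filter_sectors()]; computed internally when
#'   `NULL`.
#' @param group_gap_um wall allowance (um) for vessel-group detection from
#'   `x_um`/`y_um` coordinates when `group_id` is absent: two vessels are
#'   contacting when their centres are closer than `r_i + r_j +
#'   group_gap_um`.  With neither `group_id` nor coordinates, VG is NA.
#' @return data frame of class `qwa_sector_traits` with one row per ring
#'   x sector (sector 0 = whole ring) and columns `site_id, tree_id, year,
#'   sector, n_vessels, VA, VA95, DH, KH, VD, RVA, VG, discarded, reason`.
#' @export
sector_traits <- function(vessels, rings, scheme = sector_scheme(5),
                          filters = NULL, group_gap_um = 3) {
  stopifnot(inherits(scheme, "qwa_sector_scheme"))
  if (is.null(vessels$sector)) vessels <- assign_sectors(vessels, scheme)
  if (is.null(filters)) filters <- filter_sectors(vessels, rings, scheme)
  k <- scheme$k

  ring_key <- function(d) paste(d$site_id, d$tree_id, d$year, sep = "\r")
  rk <- ring_key(rings)
  ring_discard <- structure(filters$rings$discarded, names = ring_key(filters$rings))
  sect_key <- paste(ring_key(filters$sectors), filters$sectors$sector)
  sect_discard <- structure(filters$sectors$discarded, names = sect_key)

  isplit <- split(seq_len(nrow(vessels)), factor(ring_key(vessels), levels = rk))
  has_group <- !is.null(vessels$group_id)
  has_xy <- !is.null(vessels$x_um) && !is.null(vessels$y_um)
  nmeta <- 5L  # site, tree, year, sector, n_vessels
  tcols <- c("VA", "VA95", "DH", "KH", "VD", "RVA", "VG")
  out <- vector("list", length(rk))
  for (i in seq_along(rk)) {
    ring <- rings[i, ]
    ii <- isplit[[i]]
    area <- vessels$lumen_area[ii]
    sect <- vessels$sector[ii]
    gid <- if (has_group) vessels$group_id[ii] else NULL
    xx <- if (has_xy) vessels$x_um[ii] else NULL
    yy <- if (has_xy) vessels$y_um[ii] else NULL
    r_disc <- isTRUE(ring_discard[[rk[i]]])
    mat <- matrix(NA_real_, k + 1, length(tcols),
                  dimnames = list(NULL, tcols))
    nv <- integer(k + 1)
    disc <- logical(k + 1)
    reason <- character(k + 1)
    for (s in 0:k) {
      sel <- if (s == 0) seq_along(area) else which(sect == s)
      n <- length(sel)
      s_disc <- if (s == 0) FALSE else
        isTRUE(sect_discard[[paste(rk[i], s)]])
      discarded <- r_disc || s_disc || n == 0L
      nv[s + 1] <- n
      disc[s + 1] <- discarded
      reason[s + 1] <- if (r_disc) "sector_width" else
        if (s_disc) "min_vessels" else if (n == 0L) "no_vessels" else ""
      if (!discarded) {
        area_share <- if (s == 0) ring$xylem_area else ring$xylem_area / k
        mat[s + 1, ] <- compute_traits(
          area[sel], area_share, group_gap_um,
          group_id = gid[sel], x = xx[sel], y = yy[sel])
      }
    }
    out[[i]] <- data.frame(
      site_id = ring$site_id, tree_id = ring$tree_id, year = ring$year,
      sector = 0:k, n_vessels = nv, mat,
      discarded = disc, reason = reason, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("qwa_sector_traits", class(res))
  res
}

# trait vector for one vessel subset over a given analyzed area (um^2)
compute_traits <- function(area, area_um2, group_gap_um,
                           group_id = NULL, x = NULL, y = NULL) {
  d <- equivalent_diameter(area)         # um
  d_m <- d * 1e-6                        # m
  kh_coef <- pi * .QWA_WATER_DENSITY / (128 * .QWA_WATER_VISCOSITY)
  n_groups <- count_vessel_groups(area, group_gap_um, group_id, x, y)
  c(
    VA = mean(area),
    VA95 = as.numeric(stats::quantile(area, 0.95, type = 7, names = FALSE)),
    DH = sum(d^5) / sum(d^4),
    KH = kh_coef * sum(d_m^4),
    VD = length(area) / (area_um2 * 1e-6),  # vessels per mm^2
    RVA = sum(area) / area_um2,
    VG = if (is.na(n_groups)) NA_real_ else length(area) / n_groups
  )
}

# number of vessel groups in a vessel subset: from explicit group_id when
# present, else single-link clustering on centre coordinates, else NA
count_vessel_groups <- function(area, group_gap_um, group_id = NULL,
                                x = NULL, y = NULL) {
  if (!is.null(group_id) && !anyNA(group_id)) {
    return(length(unique(group_id)))
  }
  if (!is.null(x) && !is.null(y) && length(x) && !anyNA(x) && !anyNA(y)) {
    return(single_link_groups(x, y, equivalent_diameter(area) / 2,
                              group_gap_um))
  }
  NA_integer_
}

# union-find single-link clustering: vessels whose centres are closer
# than r_i + r_j + gap belong to one group
single_link_groups <- function(x, y, r, gap) {
  n <- length(x)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2) < r[i] + r[j] + gap) {
          parent[find(i)] <- find(j)
        }
      }
    }
  }
  length(unique(vapply(seq_len(n), find, 1L)))
}

#' Per-ring vessel summary
#'
#' Aggregates the raw vessel list to ring totals: vessel count, total
#' lumen area, and whole-ring relative vessel area.
#'
#' @param vessels vessel data frame.
#' @param rings ring data frame.
#' @return data frame `site_id, tree_id, year, n_vessels,
#'   total_lumen_area, rva`.
#' @export
ring_vessel_summary <- function(vessels, rings) {
  key <- function(d) paste(d$site_id, d$tree_id, d$year, sep = "\r")
  vk <- key(vessels)
  n <- tapply(vessels$lumen_area, vk, length)
  tot <- tapply(vessels$lumen_area, vk, sum)
  rk <- key(rings)
  out <- rings[c("site_id", "tree_id", "year", "xylem_area")]
  out$n_vessels <- as.integer(ifelse(is.na(n[rk]), 0L, n[rk]))
  out$total_lumen_area <- as.numeric(ifelse(is.na(tot[rk]), 0, tot[rk]))
  out$rva <- out$total_lumen_area / out$xylem_area
  out$xylem_area <- NULL
  rownames(out) <- NULL
  out
}
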