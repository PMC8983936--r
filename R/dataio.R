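#' Read a vessel table
#'
#' Reads a CSV of individually measured vessels, one row per vessel, with
#' header `site_id,tree_id,year,vessel_id,lumen_area_um2,rel_position`
#' and optional columns `group_id`, `x_um`, `y_um` (tangential/radial
#' centroid coordinates used for vessel-group detection when `group_id`
#' is absent).
#'
#' `rel_position` is the relative radial position of the vessel centroid
#' within its ring: 0 at the inner ring border (earliest formed wood),
#' 1 at the outer border.  Both bounds are accepted.
#'
#' @param path path to a CSV file.
#' @return A data frame with columns `site_id`, `tree_id`, `year`,
#'   `vessel_id`, `lumen_area` (um^2), `rel_position`, `group_id`
#'   (NA when absent), and `x_um`/`y_um` when present in the file.
#' @export
read_vessels <- function(path) {
  df <- read_qwa_csv(path)
  required <- c("site_id", "tree_id", "year", "vessel_id",
                "lumen_area_um2", "rel_position")
  check_columns(df, required, path)
  df$year <- check_numeric(df, "year", path, integer = TRUE)
  df$lumen_area_um2 <- check_numeric(df, "lumen_area_um2", path)
  df$rel_position <- check_numeric(df, "rel_position", path)
  bad <- which(df$lumen_area_um2 <= 0)
  if (length(bad)) {
    qwa_validation_error(sprintf(
      "%s: lumen_area_um2 must be > 0 (first offending row %d)", path, bad[1]))
  }
  bad <- which(df$rel_position < 0 | df$rel_position > 1)
  if (length(bad)) {
    qwa_validation_error(sprintf(
      "%s: rel_position must lie in [0, 1] (first offending row %d)", path, bad[1]))
  }
  key <- paste(df$site_id, df$tree_id, df$year, df$vessel_id, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup)) {
    qwa_validation_error(sprintf(
      "%s: duplicate (site, tree, year, vessel_id) key at row %d", path, dup[1]))
  }
  out <- data.frame(
    site_id = as.character(df$site_id),
    tree_id = as.character(df$tree_id),
    year = df$year,
    vessel_id = as.character(df$vessel_id),
    lumen_area = df$lumen_area_um2,
    rel_position = df$rel_position,
    group_id = if ("group_id" %in% names(df)) {
      gi <- as.character(df$group_id)
      gi[!is.na(gi) & gi == ""] <- NA_character_
      gi
    } else NA_character_,
    stringsAsFactors = FALSE
  )
  for (cc in c("x_um", "y_um")) {
    if (cc %in% names(df)) out[[cc]] <- check_numeric(df, cc, path)
  }
  out
}

#' Read a ring table
#'
#' CSV with header `site_id,tree_id,year,trw_um,xylem_area_um2`: one row
#' per dated ring carrying the ring width and the analyzed xylem area.
#'
#' @param path path to a CSV file.
#' @return A data frame with columns `site_id`, `tree_id`, `year`,
#'   `trw` (um) and `xylem_area` (um^2).
#' @export
read_rings <- function(path) {
  df <- read_qwa_csv(path)
  check_columns(df, c("site_id", "tree_id", "year", "trw_um", "xylem_area_um2"), path)
  df$year <- check_numeric(df, "year", path, integer = TRUE)
  df$trw_um <- check_numeric(df, "trw_um", path)
  df$xylem_area_um2 <- check_numeric(df, "xylem_area_um2", path)
  bad <- which(df$trw_um <= 0)
  if (length(bad)) {
    qwa_validation_error(sprintf(
      "%s: trw_um must be > 0 (first offending row %d)", path, bad[1]))
  }
  bad <- which(df$xylem_area_um2 <= 0)
  if (length(bad)) {
    qwa_validation_error(sprintf(
      "%s: xylem_area_um2 must be > 0 (first offending row %d)", path, bad[1]))
  }
  key <- paste(df$site_id, df$tree_id, df$year, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup)) {
    qwa_validation_error(sprintf(
      "%s: duplicate (site, tree, year) ring at row %d", path, dup[1]))
  }
  data.frame(
    site_id = as.character(df$site_id),
    tree_id = as.character(df$tree_id),
    year = df$year,
    trw = df$trw_um,
    xylem_area = df$xylem_area_um2,
    stringsAsFactors = FALSE
  )
}

#' Read a monthly climate table
#'
#' CSV with header `year,month,tmean,prec` in the usual gridded-product
#' layout: monthly mean temperature (degrees C) and monthly precipitation
#' sum (mm).  The monthly grid must be complete over the spanned years.
#'
#' @param path path to a CSV file.
#' @return A data frame with columns `year`, `month`, `tmean`, `prec`,
#'   ordered by year then month.
#' @export
read_climate <- function(path) {
  df <- read_qwa_csv(path)
  check_columns(df, c("year", "month", "tmean", "prec"), path)
  df$year <- check_numeric(df, "year", path, integer = TRUE)
  df$month <- check_numeric(df, "month", path, integer = TRUE)
  df$tmean <- check_numeric(df, "tmean", path)
  df$prec <- check_numeric(df, "prec", path)
  if (any(df$month < 1 | df$month > 12)) {
    qwa_validation_error(sprintf("%s: month must be in 1..12", path))
  }
  bad <- which(df$prec < 0)
  if (length(bad)) {
    qwa_validation_error(sprintf(
      "%s: prec must be >= 0 (first offending row %d)", path, bad[1]))
  }
  validate_climate_grid(df, path)
  df <- df[order(df$year, df$month), c("year", "month", "tmean", "prec")]
  rownames(df) <- NULL
  df
}

# complete-grid check shared by read_climate and the indexing functions
validate_climate_grid <- function(climate, label = "climate") {
  want <- expand.grid(month = 1:12,
                      year = min(climate$year):max(climate$year))
  have <- paste(climate$year, climate$month)
  dup <- which(duplicated(have))
  if (length(dup)) {
    qwa_validation_error(sprintf(
      "%s: duplicate (year, month) at row %d", label, dup[1]))
  }
  missing <- !(paste(want$year, want$month) %in% have)
  if (any(missing)) {
    miss <- want[missing, , drop = FALSE]
    qwa_validation_error(sprintf(
      "%s: monthly grid incomplete; missing %s", label,
      paste(sprintf("%d-%02d", miss$year, miss$month), collapse = ", ")))
  }
  invisible(TRUE)
}

#' Write a table as CSV with full numeric precision
#'
#' Doubles are serialized with 17 significant digits so that a
#' write-then-read round trip restores every value bit for bit.
#'
#' @param df data frame to write.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      v <- out[[j]]
      s <- sprintf("%.17g", v)
      s[is.na(v)] <- NA_character_
      out[[j]] <- s
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Write vessel, ring, and climate tables in their canonical dialect
#'
#' These writers emit the exact column layouts that [read_vessels()],
#' [read_rings()] and [read_climate()] expect, so round trips are the
#' identity.
#'
#' @param vessels,rings,climate data frames as returned by the
#'   corresponding readers (or by [generate_stand()] / [generate_climate()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vessels <- function(vessels, path) {
  out <- data.frame(
    site_id = vessels$site_id, tree_id = vessels$tree_id,
    year = vessels$year, vessel_id = vessels$vessel_id,
    lumen_area_um2 = vessels$lumen_area,
    rel_position = vessels$rel_position,
    stringsAsFactors = FALSE
  )
  if (!is.null(vessels$group_id)) out$group_id <- vessels$group_id
  for (cc in c("x_um", "y_um")) if (!is.null(vessels[[cc]])) out[[cc]] <- vessels[[cc]]
  write_table(out, path)
}

#' @rdname write_vessels
#' @export
write_rings <- function(rings, path) {
  write_table(data.frame(
    site_id = rings$site_id, tree_id = rings$tree_id, year = rings$year,
    trw_um = rings$trw, xylem_area_um2 = rings$xylem_area,
    stringsAsFactors = FALSE
  ), path)
}

#' @rdname write_vessels
#' @export
write_climate <- function(climate, path) {
  write_table(climate[, c("year", "month", "tmean", "prec")], path)
}

# ---- internal helpers -------------------------------------------------------

read_qwa_csv <- function(path) {
  if (!file.exists(path)) {
    qwa_validation_error(sprintf("file not found: %s", path))
  }
  utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                  check.names = TRUE)
}

check_columns <- function(df, required, path) {
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    qwa_validation_error(sprintf(
      "%s: missing required column(s): %s", path, paste(miss, collapse = ", ")))
  }
  invisible(TRUE)
}

check_numeric <- function(df, col, path, integer = FALSE) {
  raw <- df[[col]]
  val <- suppressWarnings(as.numeric(raw))
  bad <- which(is.na(val) & !is.na(raw) & raw != "NA")
  if (length(bad)) {
    qwa_validation_error(sprintf(
      "%s: column %s is not numeric at row %d (value '%s')",
      path, col, bad[1], raw[bad[1]]))
  }
  if (integer) {
    frac <- which(!is.na(val) & val != round(val))
    if (length(frac)) {
      qwa_validation_error(sprintf(
        "%s: column %s must be integer at row %d", path, col, frac[1]))
    }
    val <- as.integer(round(val))
  }
  val
}
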