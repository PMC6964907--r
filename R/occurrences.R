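#' Occurrence sets
#'
#' An `occurrence_set` holds the point records for one species in one season:
#' longitude/latitude in decimal degrees (WGS84) plus a free-text source tag
#' per record. Constructors validate coordinate ranges and drop exact
#' duplicate coordinate pairs, mirroring how locality dumps from survey and
#' aggregator databases are ingested before niche modeling.
#'
#' @param species_id Species identifier string.
#' @param season `"breeding"` or `"winter"`.
#' @param lon,lat Numeric vectors of coordinates in decimal degrees.
#' @param source_tag Character vector of provenance tags (recycled).
#' @param dedup Collapse exact-duplicate coordinate pairs (default `TRUE`;
#'   synthetic samplers that must preserve draw multiplicity turn this off).
#' @return An object of class `occurrence_set`: a list with `species_id`,
#'   `season`, and a data frame `records` with columns `lon`, `lat`,
#'   `source_tag`.
#' @export
occurrence_set <- function(species_id, season = c("breeding", "winter"),
                           lon, lat, source_tag = "", dedup = TRUE) {
  season <- match.arg(season)
  stopifnot(length(lon) == length(lat))
  if (length(lon) == 0L) stop("occurrence_set: no records")
  bad <- !is.finite(lon) | !is.finite(lat) |
    lon < -180 | lon > 180 | lat < -90 | lat > 90
  if (any(bad)) stop("occurrence_set: coordinates out of range")
  rec <- data.frame(lon = as.numeric(lon), lat = as.numeric(lat),
                    source_tag = rep_len(as.character(source_tag), length(lon)),
                    stringsAsFactors = FALSE)
  if (dedup) rec <- rec[!duplicated(rec[, c("lon", "lat")]), , drop = FALSE]
  rownames(rec) <- NULL
  structure(list(species_id = as.character(species_id), season = season,
                 records = rec, n_dropped = 0L),
            class = "occurrence_set")
}

#' @export
print.occurrence_set <- function(x, ...) {
  cat(sprintf("<occurrence_set> %s [%s]: %d records\n",
              x$species_id, x$season, nrow(x$records)))
  invisible(x)
}

#' Number of records in an occurrence set
#' @param occ An `occurrence_set`.
#' @return Integer count.
#' @export
n_records <- function(occ) nrow(occ$records)

#' Read an occurrence table from CSV
#'
#' Reads point records for one species/season from a delimited file with a
#' header. Rows with unparsable or out-of-range coordinates are dropped and
#' counted (reported in the `n_dropped` field); exact duplicate coordinate
#' pairs are collapsed.
#'
#' @param path Path to a CSV (or TSV, see `sep`) file with a header row.
#' @param species_id,season Passed through to the resulting set.
#' @param lon_col,lat_col Column names holding longitude and latitude.
#' @param source_col Optional column name for a provenance tag.
#' @param sep Field separator.
#' @return An `occurrence_set`; the attribute-like field `n_dropped` holds the
#'   number of invalid rows removed.
#' @export
read_occurrences <- function(path, species_id, season = c("breeding", "winter"),
                             lon_col = "longitude", lat_col = "latitude",
                             source_col = NULL, sep = ",") {
  season <- match.arg(season)
  if (!file.exists(path)) stop("read_occurrences: file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  for (cl in c(lon_col, lat_col)) {
    if (!cl %in% names(tab)) stop("read_occurrences: missing column '", cl, "'")
  }
  lon <- suppressWarnings(as.numeric(tab[[lon_col]]))
  lat <- suppressWarnings(as.numeric(tab[[lat_col]]))
  ok <- is.finite(lon) & is.finite(lat) &
    lon >= -180 & lon <= 180 & lat >= -90 & lat <= 90
  n_dropped <- sum(!ok)
  if (!any(ok)) stop("read_occurrences: no valid records in ", path)
  tag <- if (!is.null(source_col) && source_col %in% names(tab)) {
    as.character(tab[[source_col]])[ok]
  } else basename(path)
  occ <- occurrence_set(species_id, season, lon[ok], lat[ok], tag)
  occ$n_dropped <- n_dropped
  occ
}

#' Write an occurrence set to CSV
#'
#' Writes the dialect read by [read_occurrences()] (header,
#' `longitude`/`latitude` columns).
#'
#' @param occ An `occurrence_set`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_occurrences <- function(occ, path) {
  out <- data.frame(species = occ$species_id,
                    longitude = occ$records$lon,
                    latitude = occ$records$lat,
                    source = occ$records$source_tag)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Replace the record table, preserving metadata.
.with_records <- function(occ, rec) {
  occ$records <- rec
  rownames(occ$records) <- NULL
  occ
}

#' Keep only records west of a longitude cutoff
#'
#' Restricts a locality set to records strictly west of `lon_cutoff`
#' (longitude < cutoff), the standard way of trimming continent-wide survey
#' records to the region relevant to a western focal site.
#'
#' @param occ An `occurrence_set`.
#' @param lon_cutoff Longitude cutoff in decimal degrees, default -104.
#' @return The filtered `occurrence_set` (possibly empty; a warning is issued
#'   if all records are removed). Record order is preserved.
#' @export
filter_west_of <- function(occ, lon_cutoff = -104) {
  stopifnot(lon_cutoff >= -180, lon_cutoff <= 180)
  keep <- occ$records$lon < lon_cutoff
  if (!any(keep)) warning("filter_west_of: no records west of ", lon_cutoff)
  .with_records(occ, occ$records[keep, , drop = FALSE])
}

#' Spatially thin an occurrence set
#'
#' Removes records until all retained pairs are more than `min_km` apart
#' (great-circle distance). The algorithm shuffles record order with the seed,
#' then iteratively deletes the record with the most neighbours within
#' `min_km`, breaking ties by the lowest shuffled index, until no violating
#' pair remains. Output order follows the input.
#'
#' @param occ An `occurrence_set`.
#' @param min_km Minimum allowed pairwise distance in km (> 0); default 20.
#' @param seed Integer seed fixing the tie-breaking shuffle.
#' @return A thinned `occurrence_set`, a subset of the input.
#' @export
thin_occurrences <- function(occ, min_km = 20, seed = 1L) {
  stopifnot(min_km > 0)
  n <- nrow(occ$records)
  if (n <= 1L) return(occ)
  pts <- as.matrix(occ$records[, c("lon", "lat")])
  dm <- pairwise_km(pts)
  perm <- with_seed(seed, sample.int(n))
  adj <- dm <= min_km
  diag(adj) <- FALSE
  alive <- rep(TRUE, n)
  repeat {
    deg <- rowSums(adj[, alive, drop = FALSE]) * alive
    if (max(deg) == 0) break
    # candidates in shuffled order; remove the max-degree record, ties by
    # lowest position in the shuffled order
    degp <- deg[perm]
    victim <- perm[which.max(degp)]
    alive[victim] <- FALSE
    adj[victim, ] <- FALSE
    adj[, victim] <- FALSE
  }
  .with_records(occ, occ$records[alive, , drop = FALSE])
}

# Save/restore .Random.seed so seeded helpers do not disturb the caller's RNG.
.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
with_seed <- function(seed, code) {
  old <- .Random.seed_exists()
  on.exit(.restore_seed(old))
  set.seed(seed)
  code
}

#' Randomly subsample an occurrence set
#'
#' Uniform sampling without replacement down to at most `max_n` records,
#' used to cap very dense locality sets. Seed-reproducible; record order
#' follows the input.
#'
#' @param occ An `occurrence_set`.
#' @param max_n Maximum number of records to keep (>= 1); default 1500.
#' @param seed Integer seed.
#' @return An `occurrence_set` with `min(n, max_n)` records.
#' @export
subsample <- function(occ, max_n = 1500, seed = 1L) {
  stopifnot(max_n >= 1)
  n <- nrow(occ$records)
  if (n <= max_n) return(occ)
  keep <- sort(with_seed(seed, sample.int(n, max_n)))
  .with_records(occ, occ$records[keep, , drop = FALSE])
}
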