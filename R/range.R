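#' Threshold rules for converting suitability to presence/absence
#'
#' The default rule is the percentile training-presence threshold: the
#' suitability cutoff below which the lowest fraction `percentile` of
#' training-presence suitabilities fall, so at least `1 - percentile` of the
#' training presences remain predicted present. A `fixed_value` rule applies
#' a constant cutoff instead.
#'
#' @param kind `"percentile_training_presence"` or `"fixed_value"`.
#' @param percentile Fraction in (0, 1) for the percentile rule
#'   (default 0.10).
#' @param value Cutoff for the `fixed_value` rule.
#' @return Object of class `threshold_rule`.
#' @export
threshold_rule <- function(kind = c("percentile_training_presence",
                                    "fixed_value"),
                           percentile = 0.10, value = NA_real_) {
  kind <- match.arg(kind)
  if (kind == "percentile_training_presence") {
    stopifnot(percentile > 0, percentile < 1)
  } else {
    stopifnot(is.finite(value))
  }
  structure(list(kind = kind, percentile = percentile, value = value),
            class = "threshold_rule")
}

#' Resolve a threshold from training-presence suitabilities
#'
#' For the percentile rule, returns the k-th smallest training value with
#' `k = ceiling(p * n)` (nearest rank, no interpolation): the largest cutoff
#' at which at least `1 - p` of training presences are still predicted
#' present under the `>=` comparison of [binarize()].
#'
#' @param training_suitabilities Numeric vector of suitabilities of the
#'   training presences (nonempty for the percentile rule).
#' @param rule A [threshold_rule()].
#' @return The threshold value.
#' @export
resolve_threshold <- function(training_suitabilities, rule = threshold_rule()) {
  if (rule$kind == "fixed_value") return(rule$value)
  v <- training_suitabilities[is.finite(training_suitabilities)]
  if (!length(v)) stop("resolve_threshold: no training suitabilities")
  k <- ceiling(rule$percentile * length(v))
  sort(v)[k]
}

#' Threshold a suitability map into a binary range map
#'
#' Cells with suitability `>= threshold` become present (1), others absent
#' (0); nodata is preserved.
#'
#' @param map A `suitability_map`.
#' @param threshold Cutoff value.
#' @param species_id,season,gcm_label Provenance carried onto the result.
#' @return A `binary_range_map`.
#' @export
binarize <- function(map, threshold, species_id = NA_character_,
                     season = NA_character_, gcm_label = NA_character_) {
  vals <- ifelse(is.na(map$values), NA_real_,
                 as.numeric(map$values >= threshold))
  binary_range_map(vals, map, threshold, species_id = species_id,
                   season = season, epoch_label = map$epoch_label,
                   gcm_label = gcm_label)
}

#' Distance from a focal site to the nearest predicted presence
#'
#' Returns 0 if the site's own cell is predicted present, otherwise the
#' minimum great-circle distance (km) from the site to the centre of any
#' present cell. If the map has no present cell, returns `NA_real_` — the
#' "not computed" sentinel used when a model predicts no range at all.
#'
#' @param range_map A `binary_range_map`.
#' @param site Length-2 numeric `c(lon, lat)`; must fall inside the grid
#'   extent.
#' @return Distance in km, or `NA_real_` if no cell is present.
#' @export
distance_to_site <- function(range_map, site) {
  stopifnot(length(site) == 2)
  idx <- .cell_index(range_map, site[1], site[2])
  if (is.na(idx$row)) stop("distance_to_site: site outside grid extent")
  v <- range_map$values[idx$row, idx$col]
  if (!is.na(v) && v == 1) return(0)
  cc <- cell_centers(range_map)
  pres <- as.numeric(t(range_map$values)) == 1
  pres[is.na(pres)] <- FALSE
  if (!any(pres)) return(NA_real_)
  min(haversine_km(matrix(site, ncol = 2),
                   cbind(cc$lon[pres], cc$lat[pres])))
}
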