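#' Levins inverse-concentration niche breadth of a suitability map
#'
#' Normalises the suitability values over the non-nodata cells to a
#' probability distribution `p` and returns `B_raw = 1 / sum(p_i^2)` (between
#' 1 for a point mass and `n` for a uniform map) and the standardised
#' `B_std = (B_raw - 1) / (n - 1)` in \[0, 1\]. Invariant to positive
#' rescaling of the map.
#'
#' @param map A `suitability_map` (or a numeric matrix/vector of
#'   suitabilities).
#' @param species_id,season,epoch_label Provenance carried onto the record;
#'   default from the map where available.
#' @return Data frame with one row: `species_id`, `season`, `epoch`,
#'   `n_cells`, `B_raw`, `B_std`.
#' @export
levins_breadth <- function(map, species_id = NA_character_,
                           season = NA_character_,
                           epoch_label = NA_character_) {
  if (inherits(map, "suitability_map")) {
    if (is.na(epoch_label)) epoch_label <- map$epoch_label
    v <- as.numeric(map$values)
  } else {
    v <- as.numeric(map)
  }
  v <- v[!is.na(v)]
  n <- length(v)
  if (n < 2) stop("levins_breadth: need at least two valid cells")
  if (any(v < 0)) stop("levins_breadth: negative suitabilities")
  s <- sum(v)
  if (s <= 0) stop("levins_breadth: all-zero suitability")
  p <- v / s
  B <- 1 / sum(p^2)
  data.frame(species_id = species_id, season = season, epoch = epoch_label,
             n_cells = n, B_raw = B, B_std = (B - 1) / (n - 1),
             stringsAsFactors = FALSE)
}

#' Pearson (or Spearman) correlation between matched breadth scores
#'
#' Product-moment correlation with a two-sided p-value from the t
#' distribution on `n - 2` degrees of freedom; `method = "spearman"` gives
#' the rank-order variant.
#'
#' @param x,y Matched numeric vectors, `n >= 3`, neither constant.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return List with `r`, `p_value`, `n`, `method`.
#' @export
breadth_correlation <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("breadth_correlation: need n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("breadth_correlation: constant vector")
  ct <- stats::cor.test(x, y, method = method, exact = FALSE)
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x),
       method = method)
}

#' Correlation matrix between breadth score sets
#'
#' Convenience wrapper producing the lower-triangular correlation layout
#' used when comparing breadth across season/epoch combinations.
#'
#' @param scores Named list of equal-length numeric vectors (one per
#'   season/epoch combination, matched by species).
#' @param method Correlation method, as in [breadth_correlation()].
#' @return Data frame with columns `a`, `b`, `r`, `p_value`.
#' @export
breadth_correlation_matrix <- function(scores, method = "pearson") {
  nm <- names(scores)
  out <- list()
  for (i in seq_along(nm)[-1]) {
    for (j in seq_len(i - 1)) {
      ct <- breadth_correlation(scores[[nm[i]]], scores[[nm[j]]],
                                method = method)
      out[[length(out) + 1L]] <- data.frame(a = nm[i], b = nm[j],
                                            r = ct$r, p_value = ct$p_value)
    }
  }
  do.call(rbind, out)
}
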