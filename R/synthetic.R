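#' Synthetic species with a known climatic niche
#'
#' Ground-truth niches are Gaussian product kernels in bioclimatic space:
#' suitability at a cell with climate `e` is
#' `max_prevalence * prod_j exp(-((e_j - mu_j) / sigma_j)^2 / 2)`, where `mu`
#' is the (season-specific) niche centre and `sigma` the per-variable
#' tolerance. Winter niches are the breeding niche shifted by
#' `seasonal_offset`. The kernel is smooth, unimodal and bounded in
#' \[0, `max_prevalence`\], and its logarithm is an exact quadratic in the
#' climate variables, so a niche model with linear + quadratic features can
#' represent it perfectly.
#'
#' @param species_id Identifier string.
#' @param niche_center Numeric length-19 vector `mu` (native layer units).
#' @param niche_width Numeric length-19 vector of strictly positive
#'   tolerances `sigma`.
#' @param seasonal_offset Length-19 shift added to the centre for the winter
#'   season (default all zero: a climatic resident).
#' @param max_prevalence Peak suitability in (0, 1].
#' @return Object of class `synthetic_species`.
#' @export
synthetic_species <- function(species_id, niche_center, niche_width,
                              seasonal_offset = rep(0, 19),
                              max_prevalence = 1) {
  stopifnot(length(niche_center) == 19, length(niche_width) == 19,
            length(seasonal_offset) == 19,
            all(niche_width > 0),
            max_prevalence > 0, max_prevalence <= 1)
  structure(list(species_id = species_id,
                 niche_center = as.numeric(niche_center),
                 niche_width = as.numeric(niche_width),
                 seasonal_offset = as.numeric(seasonal_offset),
                 max_prevalence = max_prevalence),
            class = "synthetic_species")
}

#' Epoch climate shifts
#'
#' Describes how a past epoch's climate differs from the present stack:
#' per-layer affine change plus an optional per-layer latitudinal gradient,
#' `v' = scale * v + add + lat_gradient * (lat - mean lat)`. The zero shift
#' (`scale = 1`, `add = 0`, `lat_gradient = 0`) is the identity.
#'
#' @param add,scale,lat_gradient Length-19 numeric vectors (scalars recycle).
#' @return Object of class `epoch_shift`.
#' @export
epoch_shift <- function(add = 0, scale = 1, lat_gradient = 0) {
  structure(list(add = rep_len(as.numeric(add), 19L),
                 scale = rep_len(as.numeric(scale), 19L),
                 lat_gradient = rep_len(as.numeric(lat_gradient), 19L)),
            class = "epoch_shift")
}

#' Generate a smooth synthetic climate stack
#'
#' Each of the 19 layers is a deterministic plane
#' `intercept + ns_gradient * (lat - lat0) + ew_gradient * (lon - lon0)`
#' (gradients per degree, anchored at the grid's south-west cell centre)
#' plus spatially autocorrelated Gaussian noise obtained by smoothing white
#' noise with a separable moving-average kernel and rescaling to the
#' requested marginal standard deviation. With `noise_sd = 0` the layers
#' reproduce the closed-form plane exactly. Deterministic per seed.
#'
#' @param nrow,ncol Grid dimensions.
#' @param xll,yll,cellsize Grid geometry in decimal degrees.
#' @param intercept,ns_gradient,ew_gradient,noise_sd Per-layer parameters
#'   (length 19 or scalar).
#' @param smooth_window Half-width (cells) of the smoothing window for the
#'   noise field.
#' @param seed Integer seed.
#' @param epoch_label Label stored on the stack.
#' @return A `bioclim_stack`.
#' @export
make_climate <- function(nrow = 50, ncol = 50, xll = -125, yll = 30,
                         cellsize = 0.1,
                         intercept = seq(0, 180, length.out = 19),
                         ns_gradient = 1, ew_gradient = 0.5,
                         noise_sd = 0, smooth_window = 3, seed = 1L,
                         epoch_label = "present") {
  stopifnot(nrow > 0, ncol > 0)
  intercept <- rep_len(intercept, 19L)
  ns_gradient <- rep_len(ns_gradient, 19L)
  ew_gradient <- rep_len(ew_gradient, 19L)
  noise_sd <- rep_len(noise_sd, 19L)
  geom <- list(nrow = nrow, ncol = ncol, xll = xll, yll = yll,
               cellsize = cellsize)
  cc <- cell_centers(geom)
  lat0 <- yll + 0.5 * cellsize
  lon0 <- xll + 0.5 * cellsize
  dlat <- matrix(cc$lat - lat0, nrow, ncol, byrow = TRUE)
  dlon <- matrix(cc$lon - lon0, nrow, ncol, byrow = TRUE)
  arr <- array(NA_real_, c(nrow, ncol, 19L))
  with_seed(seed, {
    for (j in 1:19) {
      lay <- intercept[j] + ns_gradient[j] * dlat + ew_gradient[j] * dlon
      if (noise_sd[j] > 0) {
        z <- matrix(stats::rnorm(nrow * ncol), nrow, ncol)
        z <- .smooth_matrix(z, smooth_window)
        z <- z / stats::sd(z) * noise_sd[j]
        lay <- lay + z
      }
      arr[, , j] <- lay
    }
  })
  bioclim_stack(arr, xll, yll, cellsize, epoch_label)
}

# Separable moving-average smoother with edge renormalisation.
.smooth_matrix <- function(m, half_width) {
  if (half_width < 1) return(m)
  k <- rep(1, 2 * half_width + 1)
  sm_rows <- function(x) {
    t(apply(x, 1, function(v) {
      num <- stats::filter(v, k, sides = 2)
      den <- stats::filter(rep(1, length(v)), k, sides = 2)
      out <- as.numeric(num / den)
      # fill NA edges from partial sums
      na <- is.na(out)
      if (any(na)) {
        for (i in which(na)) {
          lo <- max(1, i - half_width); hi <- min(length(v), i + half_width)
          out[i] <- mean(v[lo:hi])
        }
      }
      out
    }))
  }
  t(sm_rows(t(sm_rows(m))))
}

#' Apply an epoch shift to a climate stack
#'
#' @param stack A `bioclim_stack`.
#' @param shift An `epoch_shift`.
#' @param epoch_label Label for the shifted stack.
#' @return A `bioclim_stack` with identical geometry.
#' @export
apply_epoch_shift <- function(stack, shift, epoch_label = "LGM") {
  stopifnot(inherits(shift, "epoch_shift"))
  cc <- cell_centers(stack)
  latm <- matrix(cc$lat, stack$nrow, stack$ncol, byrow = TRUE)
  lat_anom <- latm - mean(cc$lat)
  arr <- stack$values
  for (j in 1:19) {
    arr[, , j] <- shift$scale[j] * stack$values[, , j] + shift$add[j] +
      shift$lat_gradient[j] * lat_anom
  }
  bioclim_stack(arr, stack$xll, stack$yll, stack$cellsize, epoch_label,
                dimnames(stack$values)[[3]])
}

# Season-specific niche centre.
.season_center <- function(spec, season) {
  if (season == "winter") spec$niche_center + spec$seasonal_offset
  else spec$niche_center
}

#' Ground-truth suitability of a synthetic species
#'
#' Evaluates the Gaussian product kernel of a [synthetic_species()] on every
#' cell of a climate stack.
#'
#' @param spec A `synthetic_species`.
#' @param stack A `bioclim_stack`.
#' @param season `"breeding"` or `"winter"`.
#' @return A `suitability_map` on the `cloglog` (bounded) scale with values
#'   in \[0, `max_prevalence`\].
#' @export
true_suitability <- function(spec, stack, season = c("breeding", "winter")) {
  season <- match.arg(season)
  mu <- .season_center(spec, season)
  logs <- matrix(0, stack$nrow, stack$ncol)
  for (j in 1:19) {
    logs <- logs - ((stack$values[, , j] - mu[j]) / spec$niche_width[j])^2 / 2
  }
  vals <- spec$max_prevalence * exp(logs)
  suitability_map(vals, stack, scale = "cloglog",
                  epoch_label = stack$epoch_label, clamped = FALSE)
}

#' Sample presence points proportional to true suitability
#'
#' Cells are drawn (with replacement) with probability proportional to the
#' species' true suitability; each record is placed at the sampled cell's
#' centre, so extraction recovers exactly the climate that generated it.
#'
#' @param spec A `synthetic_species`.
#' @param stack A `bioclim_stack`.
#' @param season Season to sample.
#' @param n Number of presence records (> 0).
#' @param seed Integer seed.
#' @return An `occurrence_set` of exactly `n` records (duplicate cells are
#'   retained so the empirical cell frequencies converge to the suitability
#'   distribution; model fitting collapses duplicate cells downstream).
#' @export
sample_presences <- function(spec, stack, season = c("breeding", "winter"),
                             n, seed = 1L) {
  season <- match.arg(season)
  if (n <= 0) stop("sample_presences: n must be positive")
  suit <- true_suitability(spec, stack, season)
  cc <- cell_centers(stack)
  w <- as.numeric(t(suit$values))  # row-major to match cell_centers order
  w[is.na(w)] <- 0
  if (sum(w) <= 0) stop("sample_presences: suitability is zero everywhere")
  idx <- with_seed(seed, sample.int(length(w), n, replace = TRUE, prob = w))
  occurrence_set(spec$species_id, season, cc$lon[idx], cc$lat[idx],
                 "synthetic", dedup = FALSE)
}

#' Ground-truth residency status of a synthetic species
#'
#' Applies the pipeline's own thresholding, distance and classification rules
#' to the *true* (not fitted) suitability surfaces, yielding the reference
#' statuses that parameter-recovery tests compare against. For the percentile
#' threshold rule the training-presence suitability distribution is taken in
#' its sampling limit: the suitability value of a presence drawn proportional
#' to suitability, i.e. the suitability-weighted distribution of cell values;
#' the threshold resolved on the present-epoch map is applied to both epochs.
#'
#' @param spec A `synthetic_species`.
#' @param present_stack,lgm_stack `bioclim_stack`s for the two epochs.
#' @param site Length-2 numeric `c(lon, lat)` of the focal site.
#' @param rule A [threshold_rule()].
#' @param D Presence distance in km (default 100).
#' @return Named list `list(lgm = status, present = status)` with statuses as
#'   in [classify_status()], plus attribute `distances` (a data frame of the
#'   four season/epoch distances).
#' @export
true_status <- function(spec, present_stack, lgm_stack, site,
                        rule = threshold_rule(), D = 100) {
  dist_se <- matrix(NA_real_, 2, 2,
                    dimnames = list(c("breeding", "winter"),
                                    c("present", "lgm")))
  for (season in c("breeding", "winter")) {
    s_now <- true_suitability(spec, present_stack, season)
    s_lgm <- true_suitability(spec, lgm_stack, season)
    thr <- if (rule$kind == "fixed_value") rule$value else {
      v <- as.numeric(s_now$values)
      v <- v[!is.na(v) & v > 0]
      .weighted_nearest_rank(v, v / sum(v), rule$percentile)
    }
    for (ep in c("present", "lgm")) {
      m <- if (ep == "present") s_now else s_lgm
      bin <- binarize(m, thr, species_id = spec$species_id, season = season)
      dist_se[season, ep] <- distance_to_site(bin, site)
    }
  }
  out <- list(
    lgm = classify_status(dist_se["breeding", "lgm"],
                          dist_se["winter", "lgm"], D),
    present = classify_status(dist_se["breeding", "present"],
                              dist_se["winter", "present"], D))
  attr(out, "distances") <- as.data.frame(dist_se)
  out
}

# p-quantile (nearest rank) of values with sampling weights: the smallest
# value v(k) whose cumulative weight reaches p.
.weighted_nearest_rank <- function(values, weights, p) {
  o <- order(values)
  cw <- cumsum(weights[o])
  values[o][which(cw >= p * cw[length(cw)])[1]]
}
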