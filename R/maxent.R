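#' Build a background sample for niche-model fitting
#'
#' The accessible study area is the minimum convex polygon (MCP) of the
#' occurrence records, buffered outward by `buffer_km`; a cell is eligible if
#' its centre lies inside the MCP or within `buffer_km` (great-circle) of the
#' MCP boundary, and it carries valid climate. `n_bg` eligible cells are then
#' sampled uniformly without replacement. With fewer than three distinct,
#' non-collinear records the study area falls back to the buffered bounding
#' box of the records (flagged in the result). `buffer_km = Inf` selects the
#' full valid extent of the stack.
#'
#' @param occ An `occurrence_set`.
#' @param stack A `bioclim_stack` for the training epoch.
#' @param buffer_km Buffer distance in km around the MCP (default 150).
#' @param n_bg Number of background cells to draw (default 10000); if fewer
#'   cells are eligible, all are used with a warning.
#' @param seed Integer seed for the draw.
#' @return Object of class `background_sample`: `points` (data frame of
#'   `lon`, `lat`), `climate` (n x 19 matrix), `hull` (MCP vertices or
#'   `NULL`), `buffer_km`, `n_background`, `fallback_bbox` flag.
#' @export
build_background <- function(occ, stack, buffer_km = 150, n_bg = 10000,
                             seed = 1L) {
  cc <- cell_centers(stack)
  valid <- !is.na(stack$values[, , 1][cbind(cc$row, cc$col)])
  pts <- unique(occ$records[, c("lon", "lat")])
  hull <- NULL
  fallback <- FALSE
  if (is.infinite(buffer_km)) {
    eligible <- valid
  } else {
    hull <- .convex_hull(pts)
    if (is.null(hull)) {
      fallback <- TRUE
      rl <- range(pts$lon); rt <- range(pts$lat)
      # degree padding from the km buffer (generous at the local latitude)
      dlat <- buffer_km / 111.195
      dlon <- buffer_km / (111.195 * max(cos(mean(rt) * pi / 180), 0.1))
      eligible <- valid & cc$lon >= rl[1] - dlon & cc$lon <= rl[2] + dlon &
        cc$lat >= rt[1] - dlat & cc$lat <= rt[2] + dlat
    } else {
      eligible <- valid & .in_buffered_hull(cc$lon, cc$lat, hull, buffer_km)
    }
  }
  if (!any(eligible)) stop("build_background: no eligible background cells")
  idx <- which(eligible)
  if (length(idx) < n_bg) {
    warning("build_background: only ", length(idx),
            " eligible cells (requested ", n_bg, "); using all")
  } else {
    idx <- sort(with_seed(seed, sample(idx, n_bg)))
  }
  clim <- extract_climate(stack, cc$lon[idx], cc$lat[idx])
  structure(list(points = data.frame(lon = cc$lon[idx], lat = cc$lat[idx]),
                 climate = clim, hull = hull, buffer_km = buffer_km,
                 n_background = length(idx), fallback_bbox = fallback),
            class = "background_sample")
}

# MCP vertices (closed ring) or NULL for degenerate (collinear / < 3) input.
.convex_hull <- function(pts) {
  if (nrow(pts) < 3L) return(NULL)
  h <- grDevices::chull(pts$lon, pts$lat)
  if (length(h) < 3L) return(NULL)
  ring <- as.matrix(pts[h, c("lon", "lat")])
  # collinearity: shoelace area of the hull
  x <- ring[, 1]; y <- ring[, 2]
  area <- abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  if (area < 1e-12) return(NULL)
  rbind(ring, ring[1, , drop = FALSE])
}

# Membership in the km-buffered hull: inside the polygon (expanded by a
# hair so exact-boundary cell centres count as inside), or within buffer_km
# of its boundary.
.in_buffered_hull <- function(lon, lat, hull, buffer_km) {
  p <- cbind(lon, lat)
  ctr <- colMeans(hull[-nrow(hull), , drop = FALSE])
  hull_eps <- sweep(sweep(hull, 2, ctr) * (1 + 1e-7), 2, ctr, "+")
  inside <- mgcv::in.out(hull_eps, p)
  out <- inside
  todo <- which(!inside)
  if (length(todo) && buffer_km > 0) {
    d <- geosphere::dist2Line(p[todo, , drop = FALSE], hull,
                              distfun = geosphere::distHaversine)
    dk <- d[, "distance"] / 1000 * (.EARTH_RADIUS_M / 6378137)
    out[todo] <- dk <= buffer_km
  }
  out
}

# Phillips & Dudik-style per-class regularization tables: interpolate the
# base beta against the number of presence samples m.
.beta_table <- list(
  linear    = list(m = c(10, 30, 100),       b = c(1.0, 0.2, 0.05)),
  quadratic = list(m = c(10, 17, 30, 100),   b = c(1.3, 0.8, 0.5, 0.05)),
  product   = list(m = c(0, 10, 17, 30, 100), b = c(2.6, 1.6, 0.9, 0.55, 0.05)),
  hinge     = list(m = c(0, 1),              b = c(0.5, 0.5)),
  threshold = list(m = c(0, 100),            b = c(2.0, 1.0))
)
.base_beta <- function(class, m) {
  tb <- .beta_table[[class]]
  stats::approx(tb$m, tb$b, xout = m, rule = 2)$y
}

#' Define a feature expansion over a background sample
#'
#' Fits the feature dictionary of a maximum-entropy niche model: per-variable
#' min/max normalisation over the background plus feature definitions for the
#' requested classes. Variables are first scaled to `z = (v - min) / (max -
#' min)` over the background; features are then `z` (linear), `z^2`
#' (quadratic), `z_a * z_b` (product, all variable pairs), forward hinges
#' `max(0, (z - k) / (1 - k))` at evenly spaced knots `k`, and step functions
#' `z >= k` (threshold). Variables constant over the background are dropped
#' with a warning.
#'
#' Feature classes default to the standard presence-count ladder: fewer than
#' 10 presences use linear only; 10-14 add quadratic; 15-79 add hinge; 80 or
#' more add product (threshold features stay off unless requested).
#'
#' @param background A `background_sample` or an n x 19 climate matrix.
#' @param classes Character vector from `c("linear", "quadratic", "product",
#'   "hinge", "threshold")`, or `"auto"` to use the presence-count ladder.
#' @param n_presences Presence count used when `classes = "auto"`.
#' @param n_hinge_knots Hinge knots per variable (default 50).
#' @param n_threshold_knots Threshold knots per variable (default 10).
#' @return Object of class `feature_expansion`: `defs` data frame (`class`,
#'   `var1`, `var2`, `knot`), `var_min`, `var_max`, `classes`.
#' @export
feature_expansion <- function(background, classes = "auto",
                              n_presences = NULL, n_hinge_knots = 50,
                              n_threshold_knots = 10) {
  clim <- if (inherits(background, "background_sample")) background$climate
          else as.matrix(background)
  if (identical(classes, "auto")) {
    if (is.null(n_presences))
      stop("feature_expansion: n_presences required for classes = 'auto'")
    classes <- if (n_presences < 10) "linear"
      else if (n_presences < 15) c("linear", "quadratic")
      else if (n_presences < 80) c("linear", "quadratic", "hinge")
      else c("linear", "quadratic", "product", "hinge")
  }
  classes <- match.arg(classes,
                       c("linear", "quadratic", "product", "hinge",
                         "threshold"), several.ok = TRUE)
  vmin <- apply(clim, 2, min, na.rm = TRUE)
  vmax <- apply(clim, 2, max, na.rm = TRUE)
  keep <- which(vmax - vmin > 0)
  if (length(keep) < ncol(clim))
    warning("feature_expansion: dropping constant variable(s): ",
            paste(setdiff(seq_len(ncol(clim)), keep), collapse = ", "))
  defs <- list()
  add <- function(class, var1, var2 = NA_integer_, knot = NA_real_) {
    defs[[length(defs) + 1L]] <<- data.frame(class = class, var1 = var1,
                                             var2 = var2, knot = knot)
  }
  for (j in keep) {
    if ("linear" %in% classes) add("linear", j)
    if ("quadratic" %in% classes) add("quadratic", j)
  }
  if ("product" %in% classes && length(keep) > 1) {
    for (a in seq_along(keep)[-length(keep)]) {
      for (b in (a + 1):length(keep)) add("product", keep[a], keep[b])
    }
  }
  if ("hinge" %in% classes) {
    for (j in keep) {
      knots <- seq(0, 1, length.out = n_hinge_knots + 1L)[1:n_hinge_knots]
      for (k in knots) add("hinge", j, knot = k)
    }
  }
  if ("threshold" %in% classes) {
    for (j in keep) {
      knots <- seq(0, 1,
                   length.out = n_threshold_knots + 2L)[2:(n_threshold_knots + 1L)]
      for (k in knots) add("threshold", j, knot = k)
    }
  }
  defs <- do.call(rbind, defs)
  rownames(defs) <- NULL
  structure(list(defs = defs, var_min = vmin, var_max = vmax,
                 classes = classes, n_vars = ncol(clim)),
            class = "feature_expansion")
}

#' Expand climate values into model features
#'
#' Pure function of the stored definitions: scales each variable by the
#' background min/max and evaluates every feature. With `clamp = TRUE`,
#' scaled values are clipped to \[0, 1\] before feature evaluation, so all
#' features stay within \[0, 1\] even outside the training range; with
#' `clamp = FALSE` linear/quadratic/product features extrapolate.
#'
#' @param values Numeric matrix (n x 19) or a single 19-vector of climate
#'   values.
#' @param expansion A `feature_expansion`.
#' @param clamp Clip scaled variables to the training range (default TRUE).
#' @return Numeric matrix n x n_features.
#' @export
expand_features <- function(values, expansion, clamp = TRUE) {
  if (is.null(dim(values))) values <- matrix(values, nrow = 1)
  if (ncol(values) != expansion$n_vars)
    stop("expand_features: expected ", expansion$n_vars, " variables, got ",
         ncol(values))
  rng <- expansion$var_max - expansion$var_min
  z <- sweep(sweep(values, 2, expansion$var_min), 2,
             ifelse(rng > 0, rng, 1), "/")
  if (clamp) z <- pmin(pmax(z, 0), 1)
  defs <- expansion$defs
  out <- matrix(NA_real_, nrow(values), nrow(defs))
  for (i in seq_len(nrow(defs))) {
    d <- defs[i, ]
    out[, i] <- switch(d$class,
      linear = z[, d$var1],
      quadratic = z[, d$var1]^2,
      product = z[, d$var1] * z[, d$var2],
      hinge = pmax(0, (z[, d$var1] - d$knot) / (1 - d$knot)),
      threshold = as.numeric(z[, d$var1] >= d$knot))
  }
  colnames(out) <- paste0(defs$class, ".", defs$var1,
                          ifelse(is.na(defs$var2), "",
                                 paste0(".", defs$var2)),
                          ifelse(is.na(defs$knot), "",
                                 sprintf("@%.3f", defs$knot)))
  out
}

# Default per-feature L1 penalties: reg_multiplier * base(class, m) *
# sd_presence(f_j) / sqrt(m), floored so separable features stay finite.
.default_beta <- function(P, defs, reg_multiplier) {
  m <- nrow(P)
  s <- apply(P, 2, stats::sd)
  s[!is.finite(s)] <- 0
  base <- vapply(defs$class, .base_beta, numeric(1), m = m)
  pmax(reg_multiplier * base * s / sqrt(m), 1e-4)
}

#' Fit a maximum-entropy niche model
#'
#' Maximises the L1-penalised maxent log-likelihood
#' `mean_p eta(x_p) - log sum_bg exp(eta(x_i)) - sum_j beta_j |lambda_j|`,
#' where `eta = sum_j lambda_j f_j` and the Gibbs density
#' `q(x) = exp(eta(x)) / Z` is normalised over the background sample, by
#' cyclic coordinate descent with soft-thresholding; each coordinate takes a
#' damped Newton step halved until the penalised objective does not decrease,
#' so the objective trace is non-decreasing by construction. Features
#' constant over the background are dropped with a warning before fitting.
#'
#' @param presences Feature matrix of presence records (rows) produced by
#'   [expand_features()].
#' @param background Feature matrix of background cells.
#' @param reg_multiplier Global multiplier on the default per-feature
#'   penalties (default 1).
#' @param max_iter Maximum number of full coordinate sweeps (default 1000).
#' @param tol Convergence tolerance on the penalised objective change per
#'   sweep (default 1e-5).
#' @param beta Optional per-feature penalty vector (recycled) overriding the
#'   defaults; `beta = 0` fits unpenalised.
#' @return Object of class `maxent_model`: `lambda`, `beta`, `log_partition`
#'   (log Z over the background), `entropy` (of the fitted background
#'   distribution), `presence_means`, `converged`, `iterations`,
#'   `objective_trace`, `kept` (indices of retained features).
#' @export
fit_maxent <- function(presences, background, reg_multiplier = 1,
                       max_iter = 1000, tol = 1e-5, beta = NULL) {
  P <- as.matrix(presences); F <- as.matrix(background)
  if (nrow(P) < 1) stop("fit_maxent: need at least one presence")
  if (nrow(F) < 2) stop("fit_maxent: need at least two background points")
  if (ncol(P) != ncol(F)) stop("fit_maxent: feature dimension mismatch")
  rng <- apply(F, 2, function(v) diff(range(v)))
  kept <- which(rng > 0)
  if (length(kept) < ncol(F))
    warning("fit_maxent: dropping ", ncol(F) - length(kept),
            " degenerate feature(s)")
  if (!length(kept)) stop("fit_maxent: all features degenerate")
  P <- P[, kept, drop = FALSE]; Fk <- F[, kept, drop = FALSE]
  J <- ncol(Fk); n <- nrow(Fk)
  if (is.null(beta)) {
    cls <- sub("\\..*$", "", colnames(Fk))
    if (!all(cls %in% names(.beta_table))) cls <- rep("linear", J)
    b <- .default_beta(P, data.frame(class = cls), reg_multiplier)
  } else {
    b <- rep_len(beta, J) * 1  # explicit beta is used as given
  }
  mu <- colMeans(P)
  lambda <- numeric(J)
  eta <- numeric(n)
  # objective pieces tracked incrementally: mean presence linear predictor
  # (changes by delta * mu[j] on a coordinate update), log-partition, penalty
  mean_pe <- 0
  lse <- .logsumexp(eta)
  pen <- 0
  cur <- mean_pe - lse - pen
  trace <- cur
  converged <- FALSE
  it <- 0L
  for (sweep_i in seq_len(max_iter)) {
    it <- sweep_i
    prev <- cur
    w <- exp(eta - lse)
    for (j in seq_len(J)) {
      fj <- Fk[, j]
      ef <- sum(w * fj)
      g <- mu[j] - ef
      v <- max(sum(w * fj^2) - ef^2, 1e-10)
      target <- lambda[j] + g / v
      newl <- sign(target) * max(abs(target) - b[j] / v, 0)
      delta <- newl - lambda[j]
      if (delta == 0) next
      # halve the step until the penalized objective does not decrease
      repeat {
        cand_eta <- eta + delta * fj
        cand_lse <- .logsumexp(cand_eta)
        cand_pen <- pen + b[j] * (abs(lambda[j] + delta) - abs(lambda[j]))
        cand <- mean_pe + delta * mu[j] - cand_lse - cand_pen
        if (cand >= cur - 1e-12) {
          lambda[j] <- lambda[j] + delta
          mean_pe <- mean_pe + delta * mu[j]
          eta <- cand_eta; lse <- cand_lse; pen <- cand_pen; cur <- cand
          w <- exp(eta - lse)
          break
        }
        delta <- delta / 2
        if (abs(delta) < 1e-12) break
      }
    }
    trace <- c(trace, cur)
    if (cur - prev < tol && cur - prev >= 0) { converged <- TRUE; break }
  }
  logZ <- .logsumexp(eta)
  q <- exp(eta - logZ)
  H <- -sum(q * ifelse(q > 0, log(q), 0))
  structure(list(lambda = stats::setNames(lambda, colnames(Fk)),
                 beta = b, kept = kept,
                 log_partition = logZ, entropy = H,
                 presence_means = mu,
                 bg_expectations = colSums(q * Fk),
                 n_presences = nrow(P), n_background = n,
                 converged = converged, iterations = it,
                 objective_trace = trace),
            class = "maxent_model")
}

# numerically stable log-sum-exp
.logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf(
    "<maxent_model> %d features (%d nonzero), %d presences, %d bg cells\n",
    length(x$lambda), sum(x$lambda != 0), x$n_presences, x$n_background))
  cat(sprintf("  converged: %s after %d sweeps; entropy %.4f\n",
              x$converged, x$iterations, x$entropy))
  invisible(x)
}

#' Project a fitted niche model onto a climate stack
#'
#' Computes the linear predictor on every valid cell and returns either the
#' raw Gibbs density (normalised over the *training* background, so raw
#' values summed over the training cells equal 1) or the bounded cloglog
#' output `1 - exp(-exp(H) * raw)` with `H` the entropy of the fitted
#' background distribution. With `clamp = TRUE`, projection-epoch climate is
#' truncated to the training range before feature expansion; with
#' `extrapolate = FALSE`, cells with any variable outside the training range
#' become nodata.
#'
#' @param object A `maxent_model`.
#' @param expansion The `feature_expansion` the model was fitted with.
#' @param stack A `bioclim_stack` to project onto.
#' @param clamp Clamp covariates to the training range (default TRUE).
#' @param extrapolate Keep cells outside the training range (default TRUE).
#' @param scale `"cloglog"` or `"raw"`.
#' @param ... Unused.
#' @return A `suitability_map`.
#' @export
predict.maxent_model <- function(object, expansion, stack, clamp = TRUE,
                                 extrapolate = TRUE,
                                 scale = c("cloglog", "raw"), ...) {
  scale <- match.arg(scale)
  cc <- cell_centers(stack)
  clim <- extract_climate(stack, cc$lon, cc$lat)
  ok <- stats::complete.cases(clim)
  if (!extrapolate) {
    inr <- rep(TRUE, nrow(clim))
    for (j in seq_len(ncol(clim))) {
      inr <- inr & clim[, j] >= expansion$var_min[j] &
        clim[, j] <= expansion$var_max[j]
    }
    ok <- ok & !is.na(inr) & inr
  }
  vals <- rep(NA_real_, nrow(clim))
  if (any(ok)) {
    Fm <- expand_features(clim[ok, , drop = FALSE], expansion, clamp = clamp)
    Fm <- Fm[, object$kept, drop = FALSE]
    eta <- drop(Fm %*% object$lambda)
    raw <- exp(eta - object$log_partition)
    vals[ok] <- if (scale == "raw") raw else
      1 - exp(-exp(object$entropy) * raw)
  }
  m <- matrix(vals, stack$nrow, stack$ncol, byrow = TRUE)
  suitability_map(m, stack, scale = scale, epoch_label = stack$epoch_label,
                  clamped = clamp)
}

#' Write a fitted model as a plain-text lambdas file plus JSON metadata
#'
#' @param model A `maxent_model`.
#' @param expansion Its `feature_expansion`.
#' @param path Base path; writes `<path>.lambdas` (tab-separated feature
#'   descriptor, lambda, beta) and `<path>.json` (normalisers, entropy,
#'   training metadata, variable ranges).
#' @return Base path, invisibly.
#' @export
write_maxent <- function(model, expansion, path) {
  defs <- expansion$defs[model$kept, , drop = FALSE]
  lam <- data.frame(feature = names(model$lambda),
                    class = defs$class, var1 = defs$var1, var2 = defs$var2,
                    knot = defs$knot, lambda = unname(model$lambda),
                    beta = model$beta)
  utils::write.table(lam, paste0(path, ".lambdas"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  meta <- list(log_partition = model$log_partition, entropy = model$entropy,
               n_presences = model$n_presences,
               n_background = model$n_background,
               converged = model$converged, iterations = model$iterations,
               var_min = unname(expansion$var_min),
               var_max = unname(expansion$var_max),
               classes = expansion$classes)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
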