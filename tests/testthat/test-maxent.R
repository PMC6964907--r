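# Background construction, feature expansion, the penalized maxent fit and
# projection.

test_that("background from a square of corner occurrences covers the grid", {
  st <- make_climate(nrow = 10, ncol = 10, xll = 0, yll = 0, cellsize = 0.1,
                     noise_sd = 0, seed = 1)
  cc <- cell_centers(st)
  corners <- occ_from(c(min(cc$lon), min(cc$lon), max(cc$lon), max(cc$lon)),
                      c(min(cc$lat), max(cc$lat), min(cc$lat), max(cc$lat)))
  bg <- suppressWarnings(
    build_background(corners, st, buffer_km = 0, n_bg = 200, seed = 1))
  # hull through the corner cell centres covers every cell centre
  expect_equal(bg$n_background, 100)
  expect_false(bg$fallback_bbox)

  # buffer large enough to cover everything: identical eligibility
  bg2 <- suppressWarnings(
    build_background(occ_from(c(0.35, 0.45, 0.41), c(0.35, 0.45, 0.52)),
                     st, buffer_km = 5000, n_bg = 200, seed = 1))
  expect_equal(bg2$n_background, 100)

  # fewer eligible cells than requested warns and uses all
  expect_warning(
    build_background(corners, st, buffer_km = 0, n_bg = 500, seed = 1),
    "eligible")
})

test_that("hull eligibility matches a brute-force convex-polygon test", {
  st <- make_climate(nrow = 20, ncol = 20, xll = 0, yll = 0, cellsize = 0.1,
                     noise_sd = 0, seed = 1)
  cc <- cell_centers(st)
  set.seed(42)
  pts <- occ_from(runif(12, 0.2, 1.7), runif(12, 0.3, 1.8))
  bg <- suppressWarnings(
    build_background(pts, st, buffer_km = 0, n_bg = 10000, seed = 1))
  # oracle: a point is inside a convex polygon iff it lies on the inner side
  # of every edge (cross-product sign test), with on-edge points included
  hull_idx <- grDevices::chull(pts$records$lon, pts$records$lat)
  hp <- as.matrix(pts$records[hull_idx, c("lon", "lat")])
  inside_convex <- function(x, y) {
    n <- nrow(hp)
    s <- sapply(seq_len(n), function(i) {
      a <- hp[i, ]; b <- hp[if (i == n) 1 else i + 1, ]
      (b[1] - a[1]) * (y - a[2]) - (b[2] - a[2]) * (x - a[1])
    })
    all(s >= -1e-9) || all(s <= 1e-9)
  }
  oracle <- mapply(inside_convex, cc$lon, cc$lat)
  got <- paste(bg$points$lon, bg$points$lat)
  want <- paste(cc$lon[oracle], cc$lat[oracle])
  expect_setequal(got, want)
})

test_that("collinear occurrences fall back to a buffered bounding box", {
  st <- make_climate(nrow = 10, ncol = 10, xll = 0, yll = 0, cellsize = 0.1,
                     noise_sd = 0, seed = 1)
  line <- occ_from(c(0.15, 0.45, 0.75), c(0.55, 0.55, 0.55))
  bg <- suppressWarnings(
    build_background(line, st, buffer_km = 10, n_bg = 1000, seed = 1))
  expect_true(bg$fallback_bbox)
  expect_gt(bg$n_background, 0)
})

test_that("feature expansion honours normalization, knots and clamping", {
  set.seed(8)
  clim <- matrix(runif(19 * 60, 10, 30), 60, 19)
  expn <- feature_expansion(clim, classes = c("linear", "quadratic",
                                              "product", "hinge",
                                              "threshold"),
                            n_hinge_knots = 4, n_threshold_knots = 3)
  # linear feature of a variable at its background min is 0, quadratic at
  # the background max is 1
  vmin <- apply(clim, 2, min); vmax <- apply(clim, 2, max)
  F1 <- expand_features(matrix(vmin, 1), expn)
  expect_true(all(F1[, grepl("^linear", colnames(F1))] == 0))
  F2 <- expand_features(matrix(vmax, 1), expn)
  expect_true(all(F2[, grepl("^quadratic", colnames(F2))] == 1))

  # hinge by hand: knot k on the scaled axis; below 0, above (z-k)/(1-k)
  hcols <- which(expn$defs$class == "hinge" & expn$defs$var1 == 1)
  k <- expn$defs$knot[hcols[2]]
  test_z <- c(k / 2, k, (1 + k) / 2)
  v <- vmin[1] + test_z * (vmax[1] - vmin[1])
  rowvals <- sapply(v, function(vv) {
    x <- vmin; x[1] <- vv
    expand_features(matrix(x, 1), expn)[1, hcols[2]]
  })
  expect_equal(unname(rowvals), c(0, 0, ((1 + k) / 2 - k) / (1 - k)),
               tolerance = 1e-10)

  # clamping clips scaled values into [0, 1]; unclamped extrapolates
  over <- vmax + (vmax - vmin)
  Fc <- expand_features(matrix(over, 1), expn, clamp = TRUE)
  expect_true(all(Fc >= 0 & Fc <= 1))
  Fu <- expand_features(matrix(over, 1), expn, clamp = FALSE)
  expect_true(any(Fu > 1))

  expect_error(expand_features(matrix(1, 1, 5), expn), "expected 19")
})

test_that("auto feature classes follow the presence-count ladder", {
  clim <- matrix(runif(19 * 30), 30, 19)
  classes_for <- function(m)
    feature_expansion(clim, classes = "auto", n_presences = m)$classes
  expect_equal(classes_for(5), "linear")
  expect_equal(classes_for(12), c("linear", "quadratic"))
  expect_equal(classes_for(40), c("linear", "quadratic", "hinge"))
  expect_equal(classes_for(200),
               c("linear", "quadratic", "product", "hinge"))
})

test_that("a no-signal feature fits lambda = 0 with uniform raw output", {
  # single binary feature with equal presence and background means
  F <- cbind(rep(c(0, 1), each = 10))
  P <- cbind(rep(c(0, 1), each = 5))
  colnames(F) <- colnames(P) <- "linear.1"
  m <- fit_maxent(P, F, beta = 0)
  expect_equal(unname(m$lambda), 0, tolerance = 1e-6)
  raw <- exp(0 - m$log_partition)
  expect_equal(raw * nrow(F), 1, tolerance = 1e-9)
})

test_that("unpenalized single-feature fit matches a 1-D root-finding oracle", {
  # two background cells with f = 0 and f = 1; presence mean 0.8.
  # the maxent condition is E_q[f] = e^l / (1 + e^l) = 0.8
  F <- cbind(c(0, 1)); P <- cbind(c(1, 1, 1, 1, 0))
  colnames(F) <- colnames(P) <- "linear.1"
  m <- fit_maxent(P, F, beta = 0, tol = 1e-12, max_iter = 5000)
  oracle <- uniroot(function(l) exp(l) / (1 + exp(l)) - 0.8, c(-10, 10),
                    tol = 1e-12)$root
  expect_equal(unname(m$lambda), oracle, tolerance = 1e-4)

  # an enormous penalty shrinks lambda to zero
  m0 <- fit_maxent(P, F, beta = 1e6)
  expect_equal(unname(m0$lambda), 0)
})

test_that("the penalized objective is non-decreasing across sweeps", {
  world <- make_test_world()
  sp <- species_at(world$present, -117.5, 35.5)
  occ <- sample_presences(sp, world$present, "breeding", 200, seed = 2)
  bg <- build_background(occ, world$present, buffer_km = Inf, n_bg = 500,
                         seed = 1)
  expn <- feature_expansion(bg, classes = c("linear", "quadratic", "hinge"),
                            n_hinge_knots = 5)
  P <- expand_features(extract_climate(world$present, occ$records$lon,
                                       occ$records$lat), expn)
  F <- expand_features(bg$climate, expn)
  m <- fit_maxent(P, F)
  expect_true(all(diff(m$objective_trace) >= -1e-12))
  expect_true(m$converged)
})

test_that("fitted models satisfy the KKT feature-matching bound", {
  world <- make_test_world(seed = 11)
  sp <- species_at(world$present, -118, 34.5)
  occ <- sample_presences(sp, world$present, "breeding", 150, seed = 5)
  bg <- build_background(occ, world$present, buffer_km = Inf, n_bg = 600,
                         seed = 2)
  expn <- feature_expansion(bg, classes = c("linear", "quadratic"))
  P <- expand_features(extract_climate(world$present, occ$records$lon,
                                       occ$records$lat), expn)
  F <- expand_features(bg$climate, expn)
  m <- fit_maxent(P, F, tol = 1e-8)
  gap <- abs(m$presence_means - m$bg_expectations)
  expect_true(all(gap <= m$beta + 1e-3))
})

test_that("raw output normalizes to 1 over the training background", {
  world <- make_test_world(seed = 13)
  sp <- species_at(world$present, -119, 34)
  occ <- sample_presences(sp, world$present, "breeding", 120, seed = 6)
  bg <- build_background(occ, world$present, buffer_km = Inf, n_bg = 400,
                         seed = 3)
  expn <- feature_expansion(bg, classes = c("linear", "quadratic"))
  P <- expand_features(extract_climate(world$present, occ$records$lon,
                                       occ$records$lat), expn)
  F <- expand_features(bg$climate, expn)
  m <- fit_maxent(P, F)
  raw_bg <- exp(drop(F[, m$kept, drop = FALSE] %*% m$lambda) -
                  m$log_partition)
  expect_equal(sum(raw_bg), 1, tolerance = 1e-9)
  # and the stored entropy is the entropy of that distribution
  expect_equal(m$entropy, -sum(raw_bg * log(raw_bg)), tolerance = 1e-9)
})

test_that("an all-zero model projects a uniform raw map", {
  world <- make_test_world(nrow = 12, ncol = 12)
  sp <- species_at(world$present, -119, 34)
  occ <- sample_presences(sp, world$present, "breeding", 50, seed = 1)
  bg <- build_background(occ, world$present, buffer_km = Inf, n_bg = 144,
                         seed = 1)
  expn <- feature_expansion(bg, classes = "linear")
  P <- expand_features(extract_climate(world$present, occ$records$lon,
                                       occ$records$lat), expn)
  F <- expand_features(bg$climate, expn)
  m <- fit_maxent(P, F, beta = 1e9)  # forces lambda = 0
  mp <- predict(m, expn, world$present, scale = "raw")
  expect_equal(max(mp$values) - min(mp$values), 0, tolerance = 1e-12)
  expect_equal(sum(mp$values), 1, tolerance = 1e-9)  # bg = whole grid here
})

test_that("clamped and unclamped projections differ only at out-of-range cells", {
  world <- make_test_world(nrow = 12, ncol = 12, noise_sd = 0)
  st <- world$present
  sp <- species_at(st, -119.2, 33.8)
  occ <- sample_presences(sp, st, "breeding", 100, seed = 4)
  bg <- build_background(occ, st, buffer_km = Inf, n_bg = 144, seed = 1)
  expn <- feature_expansion(bg, classes = "linear")
  P <- expand_features(extract_climate(st, occ$records$lon,
                                       occ$records$lat), expn)
  F <- expand_features(bg$climate, expn)
  m <- fit_maxent(P, F)
  # perturb a variable the sparse fit actually uses, at one cell, far above
  # the training range
  used <- names(which(m$lambda != 0))
  expect_gt(length(used), 0)
  j <- as.integer(sub("linear\\.", "", used[1]))
  st2 <- st
  st2$values[3, 4, j] <- max(st$values[, , j]) + 100
  pc <- predict(m, expn, st2, clamp = TRUE, scale = "raw")
  pu <- predict(m, expn, st2, clamp = FALSE, scale = "raw")
  dif <- abs(pc$values - pu$values) > 1e-15
  expect_true(dif[3, 4])
  expect_equal(sum(dif), 1)
  # extrapolate = FALSE masks that cell instead
  pn <- predict(m, expn, st2, clamp = FALSE, extrapolate = FALSE,
                scale = "raw")
  expect_true(is.na(pn$values[3, 4]))
  expect_equal(sum(is.na(pn$values)), 1)
})

test_that("fitted suitability rank-matches truth for quadratic-niche species", {
  world <- make_test_world()
  st <- world$present
  sp <- species_at(st, -117.6, 35.4, width_mult = 2)
  occ <- sample_presences(sp, st, "breeding", 400, seed = 11)
  bg <- build_background(occ, st, buffer_km = Inf, n_bg = 800, seed = 3)
  expn <- feature_expansion(bg, classes = c("linear", "quadratic"))
  P <- expand_features(extract_climate(st, occ$records$lon,
                                       occ$records$lat), expn)
  F <- expand_features(bg$climate, expn)
  m <- fit_maxent(P, F)
  mp <- predict(m, expn, st, scale = "raw")
  ts <- true_suitability(sp, st, "breeding")
  rho <- cor(as.numeric(mp$values), as.numeric(ts$values),
             method = "spearman")
  expect_gte(rho, 0.9)
})

test_that("model serialization writes a readable lambdas file and metadata", {
  world <- make_test_world(nrow = 10, ncol = 10)
  sp <- species_at(world$present, -119.2, 33.8)
  occ <- sample_presences(sp, world$present, "breeding", 60, seed = 2)
  bg <- build_background(occ, world$present, buffer_km = Inf, n_bg = 100,
                         seed = 1)
  expn <- feature_expansion(bg, classes = c("linear", "quadratic"))
  P <- expand_features(extract_climate(world$present, occ$records$lon,
                                       occ$records$lat), expn)
  F <- expand_features(bg$climate, expn)
  m <- fit_maxent(P, F)
  base <- tempfile()
  on.exit(unlink(paste0(base, c(".lambdas", ".json"))))
  write_maxent(m, expn, base)
  lam <- read.delim(paste0(base, ".lambdas"))
  expect_equal(nrow(lam), length(m$lambda))
  expect_equal(lam$lambda, unname(m$lambda))
  meta <- jsonlite::read_json(paste0(base, ".json"))
  expect_equal(meta$entropy, m$entropy, tolerance = 1e-12)
  expect_equal(meta$n_background, m$n_background)
})
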