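# Synthetic climate, epoch shifts, ground-truth suitability and sampling.

test_that("noise-free climate reproduces the closed-form plane", {
  st <- make_climate(nrow = 6, ncol = 5, xll = 0, yll = 0, cellsize = 1,
                     intercept = 10, ns_gradient = 2, ew_gradient = 0.5,
                     noise_sd = 0, seed = 1)
  cc <- cell_centers(st)
  expected <- 10 + 2 * (cc$lat - 0.5) + 0.5 * (cc$lon - 0.5)
  for (j in c(1, 7, 19)) {
    expect_equal(as.numeric(t(st$values[, , j])), expected, tolerance = 1e-12)
  }
})

test_that("climate generation is seed-deterministic", {
  a <- make_climate(nrow = 12, ncol = 12, noise_sd = 1, seed = 3)
  b <- make_climate(nrow = 12, ncol = 12, noise_sd = 1, seed = 3)
  c2 <- make_climate(nrow = 12, ncol = 12, noise_sd = 1, seed = 4)
  expect_identical(a$values, b$values)
  expect_false(identical(a$values, c2$values))
})

test_that("epoch shifts act cellwise and the zero shift is the identity", {
  st <- make_climate(nrow = 10, ncol = 10, noise_sd = 1, seed = 5)
  same <- apply_epoch_shift(st, epoch_shift(), "copy")
  expect_equal(same$values, st$values, ignore_attr = TRUE)

  plus2 <- apply_epoch_shift(st, epoch_shift(add = c(2, rep(0, 18))), "p2")
  expect_equal(mean(plus2$values[, , 1]) - mean(st$values[, , 1]), 2,
               tolerance = 1e-12)
  expect_equal(plus2$values[, , 2], st$values[, , 2], ignore_attr = TRUE)

  sc <- rep(1, 19); sc[5] <- 0.5
  half5 <- apply_epoch_shift(st, epoch_shift(scale = sc), "h5")
  expect_equal(var(as.numeric(half5$values[, , 5])),
               var(as.numeric(st$values[, , 5])) / 4, tolerance = 1e-12)
})

test_that("true suitability follows the Gaussian product kernel", {
  world <- make_test_world(nrow = 12, ncol = 12)
  st <- world$present
  cc <- cell_centers(st)
  mu <- climate_at(st, cc$lon[40], cc$lat[40])
  sp <- synthetic_species("g", mu, niche_width = rep(5, 19),
                          max_prevalence = 0.8)
  suit <- true_suitability(sp, st, "breeding")
  # peak value at the niche-centre cell equals max_prevalence
  expect_equal(suit$values[cc$row[40], cc$col[40]], 0.8, tolerance = 1e-12)
  expect_true(all(suit$values <= 0.8 + 1e-12))

  # infinite widths: uniform suitability at max_prevalence
  wide <- synthetic_species("w", mu, niche_width = rep(1e9, 19),
                            max_prevalence = 0.5)
  su2 <- true_suitability(wide, st, "breeding")
  expect_equal(range(su2$values), c(0.5, 0.5), tolerance = 1e-9)

  # hand-computed 4-cell, 2-informative-layer case
  arr <- array(0, c(2, 2, 19))
  arr[, , 1] <- matrix(c(0, 1, 2, 3), 2, 2)
  arr[, , 2] <- matrix(c(1, 1, 0, 0), 2, 2)
  tiny <- bioclim_stack(arr, 0, 0, 1)
  mu2 <- rep(0, 19); mu2[1] <- 1; mu2[2] <- 1
  wid <- rep(1e9, 19); wid[1] <- 2; wid[2] <- 1
  spt <- synthetic_species("h", mu2, wid)
  got <- true_suitability(spt, tiny, "breeding")$values
  expected <- exp(-((arr[, , 1] - 1) / 2)^2 / 2) * exp(-(arr[, , 2] - 1)^2 / 2)
  expect_equal(got, expected, tolerance = 1e-12)
})

test_that("the winter niche is the breeding niche shifted by the offset", {
  world <- make_test_world(nrow = 12, ncol = 12)
  st <- world$present
  mu <- climate_at(st, -119, 33.5)
  off <- rep(0, 19); off[1] <- 3
  sp <- synthetic_species("s", mu, rep(4, 19), seasonal_offset = off)
  sb <- true_suitability(sp, st, "breeding")
  sw <- true_suitability(sp, st, "winter")
  # winter suitability equals breeding suitability of a species centred at
  # mu + offset
  sp2 <- synthetic_species("s2", mu + off, rep(4, 19))
  expect_equal(sw$values, true_suitability(sp2, st, "breeding")$values)
  expect_false(isTRUE(all.equal(sb$values, sw$values)))
})

test_that("presences are sampled proportionally to suitability", {
  world <- make_test_world(nrow = 10, ncol = 10, noise_sd = 0)
  st <- world$present
  cc <- cell_centers(st)
  # concentrate all suitability in one cell with narrow widths
  sp <- species_at(st, cc$lon[55], cc$lat[55], width_mult = 0.01)
  occ <- sample_presences(sp, st, "breeding", 50, seed = 2)
  expect_equal(unique(occ$records$lon), cc$lon[55])
  expect_equal(unique(occ$records$lat), cc$lat[55])

  expect_error(sample_presences(sp, st, "breeding", 0), "positive")

  # uniform suitability: per-cell counts within 4-sigma multinomial bounds
  flat <- synthetic_species("f", climate_at(st, cc$lon[1], cc$lat[1]),
                            niche_width = rep(1e9, 19))
  n <- 10000
  occ2 <- sample_presences(flat, st, "breeding", n, seed = 3)
  expect_equal(n_records(occ2), n)
  all_cells <- paste(round(cc$lon, 6), round(cc$lat, 6))
  cnt <- table(factor(paste(round(occ2$records$lon, 6),
                            round(occ2$records$lat, 6)),
                      levels = all_cells))
  p <- 1 / 100
  bound <- 4 * sqrt(n * p * (1 - p))
  expect_true(all(abs(cnt - n * p) <= bound))
})

test_that("true_status matches a brute-force per-cell evaluation", {
  world <- make_test_world(nrow = 16, ncol = 16)
  site <- stack_center(world$present)
  set.seed(21)
  for (k in 1:6) {
    cc <- cell_centers(world$present)
    i <- sample(nrow(cc), 1)
    off <- rep(0, 19); off[1] <- sample(c(0, 30), 1)
    sp <- species_at(world$present, cc$lon[i], cc$lat[i],
                     id = paste0("r", k), width_mult = runif(1, 0.5, 2),
                     seasonal_offset = off)
    rule <- threshold_rule("fixed_value", value = 0.3)
    got <- true_status(sp, world$present, world$lgm, site, rule, D = 20)
    # oracle: evaluate the kernel on every cell directly and classify
    oracle_dist <- function(stack, season) {
      suit <- true_suitability(sp, stack, season)
      pres <- which(t(suit$values) >= 0.3)
      if (!length(pres)) return(NA_real_)
      min(ref_haversine_km(site[1], site[2], cc$lon[pres], cc$lat[pres]))
    }
    ob <- oracle_dist(world$lgm, "breeding")
    ow <- oracle_dist(world$lgm, "winter")
    cls <- function(b, w, D) {
      bi <- !is.na(b) && b <= D; wi <- !is.na(w) && w <= D
      if (bi && wi) "resident" else if (bi) "breeding" else if (wi) "winter"
      else "not_present"
    }
    expect_equal(got$lgm, cls(ob, ow, 20))
    expect_equal(got$present,
                 cls(oracle_dist(world$present, "breeding"),
                     oracle_dist(world$present, "winter"), 20))
  }
})

test_that("species whose site cell stays suitable at both epochs are residents", {
  world <- make_test_world(nrow = 16, ncol = 16, lgm_add = 0,
                           lgm_lat_gradient = 0)
  site <- stack_center(world$present)
  sp <- species_at(world$present, site[1], site[2], width_mult = 3)
  st <- true_status(sp, world$present, world$lgm, site)
  expect_equal(st$lgm, "resident")
  expect_equal(st$present, "resident")
})
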