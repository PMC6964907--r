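# Shared builders for small synthetic worlds used across test files.

# A well-conditioned two-epoch world: layer gradients differ in direction and
# magnitude so the 19 layers are not collinear, and mild smooth noise breaks
# exact planarity. Cellsize 0.2 deg over 30x30 cells ~ a 60x60 km window.
make_test_world <- function(nrow = 30, ncol = 30, seed = 7, noise_sd = 1,
                            lgm_add = -4, lgm_lat_gradient = 0.3) {
  pres <- make_climate(
    nrow = nrow, ncol = ncol, xll = -120, yll = 33, cellsize = 0.2,
    ns_gradient = seq(2, 4, length.out = 19) * rep(c(1, -1), length.out = 19),
    ew_gradient = seq(-3, 3, length.out = 19),
    noise_sd = noise_sd, seed = seed, epoch_label = "present")
  shift <- epoch_shift(add = lgm_add, lat_gradient = lgm_lat_gradient)
  lgm <- apply_epoch_shift(pres, shift, epoch_label = "LGM-CCSM")
  list(present = pres, lgm = lgm)
}

# Climate at a grid point, as a niche-centre seed.
climate_at <- function(stack, lon, lat) {
  as.numeric(extract_climate(stack, lon, lat))
}

# Species centred on the climate of (lon, lat) at the present epoch, with
# widths proportional to each layer's spread so every layer is informative.
species_at <- function(stack, lon, lat, id = "sp", width_mult = 2,
                       seasonal_offset = rep(0, 19), max_prevalence = 1) {
  spread <- apply(apply(stack$values, 3, as.numeric), 2, stats::sd,
                  na.rm = TRUE)
  synthetic_species(id, climate_at(stack, lon, lat),
                    niche_width = width_mult * pmax(spread, 1e-6),
                    seasonal_offset = seasonal_offset,
                    max_prevalence = max_prevalence)
}

# Centre coordinates of a stack.
stack_center <- function(stack) {
  cc <- cell_centers(stack)
  c(mean(cc$lon), mean(cc$lat))
}

# Tiny occurrence set from coordinate vectors.
occ_from <- function(lon, lat, id = "sp", season = "breeding") {
  occurrence_set(id, season, lon, lat)
}

# Reference haversine used as an independent check (plain formula, mean
# earth radius 6371.0088 km).
ref_haversine_km <- function(lon1, lat1, lon2, lat2) {
  rad <- pi / 180
  dlat <- (lat2 - lat1) * rad
  dlon <- (lon2 - lon1) * rad
  a <- sin(dlat / 2)^2 + cos(lat1 * rad) * cos(lat2 * rad) * sin(dlon / 2)^2
  2 * 6371.0088 * asin(pmin(1, sqrt(a)))
}
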