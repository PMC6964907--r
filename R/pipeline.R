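#' Run configuration for the full per-species workflow
#'
#' Collects every tunable of the pipeline with defaults matching the study
#' design the package implements: a focal site near the La Brea tar pits, a
#' 100 km presence distance, a -104 degree longitude cutoff, optional > 20 km
#' spatial thinning, subsampling to at most 1500 records, a 150 km buffered
#' minimum-convex-polygon background (infinite buffer = full extent), 10000
#' background cells, regularization multiplier 1, 1000 optimizer sweeps
#' (5000 for the sensitivity preset), clamped projection with extrapolation,
#' and the 10th-percentile training-presence threshold on the cloglog output.
#'
#' @param site Length-2 `c(lon, lat)` of the focal site.
#' @param D Presence distance in km.
#' @param lon_cutoff Western-locality cutoff in decimal degrees; `NULL`
#'   disables the filter.
#' @param thin Logical: apply spatial thinning?
#' @param thin_km Minimum pairwise distance for thinning (km).
#' @param subsample_max Maximum records retained per species/season.
#' @param buffer_km Background MCP buffer (km); `Inf` = whole valid extent.
#' @param n_bg Background cells to sample.
#' @param reg_multiplier Global regularization multiplier.
#' @param max_iter Optimizer sweep cap (1000 default; 5000 preset mirrors the
#'   no-clamping sensitivity variant).
#' @param tol Optimizer convergence tolerance.
#' @param clamp,extrapolate Projection flags.
#' @param feature_classes `"auto"` or explicit feature class vector.
#' @param n_hinge_knots Hinge knots per variable.
#' @param rule A [threshold_rule()].
#' @param output_scale `"cloglog"` or `"raw"`.
#' @param seed Integer base seed.
#' @return Object of class `run_config` (a list).
#' @export
run_config <- function(site = c(-118.356, 34.063), D = 100,
                       lon_cutoff = -104, thin = FALSE, thin_km = 20,
                       subsample_max = 1500, buffer_km = 150, n_bg = 10000,
                       reg_multiplier = 1, max_iter = 1000, tol = 1e-5,
                       clamp = TRUE, extrapolate = TRUE,
                       feature_classes = "auto", n_hinge_knots = 50,
                       rule = threshold_rule(), output_scale = "cloglog",
                       seed = 1L) {
  cfg <- list(site = site, D = D, lon_cutoff = lon_cutoff, thin = thin,
              thin_km = thin_km, subsample_max = subsample_max,
              buffer_km = buffer_km, n_bg = n_bg,
              reg_multiplier = reg_multiplier, max_iter = max_iter,
              tol = tol, clamp = clamp, extrapolate = extrapolate,
              feature_classes = feature_classes,
              n_hinge_knots = n_hinge_knots, rule = rule,
              output_scale = output_scale, seed = as.integer(seed))
  cfg$hash <- config_hash(cfg)
  structure(cfg, class = "run_config")
}

#' Provenance hash of a configuration
#'
#' MD5 of the JSON serialisation, stamped into every report so each output
#' row is traceable to the exact configuration that produced it.
#'
#' @param cfg A `run_config` (or any list).
#' @return Character MD5 hash.
#' @export
config_hash <- function(cfg) {
  cfg$hash <- NULL
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(cfg, f, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(f))
}

# species-specific deterministic sub-seed below 2^31
.sub_seed <- function(seed, species_id, k = 0L) {
  h <- sum(utf8ToInt(species_id) * seq_along(utf8ToInt(species_id)))
  as.integer((as.numeric(seed) * 10007 + h * 13 + k) %% .Machine$integer.max)
}

#' Run the full workflow for one species
#'
#' Filters the seasonal occurrence sets (longitude cutoff, optional
#' thinning, subsampling), builds a background sample per season, fits a
#' maximum-entropy niche model, projects it onto the training-epoch stack
#' and each past-epoch stack, resolves the training-presence threshold,
#' binarizes, measures the distance from the focal site to the nearest
#' predicted cell, classifies residency status at each epoch, and computes
#' Levins niche breadths. Deterministic given the configuration seed.
#'
#' @param species_id Species identifier.
#' @param occ_breeding,occ_winter `occurrence_set`s for the two seasons
#'   (either may be `NULL` to skip a season).
#' @param present_stack A `bioclim_stack` for the training epoch.
#' @param lgm_stacks Named list of `bioclim_stack`s for past-epoch
#'   projections (names are GCM labels).
#' @param config A [run_config()].
#' @return Object of class `species_result`: `species_id`, `predictions`
#'   (data frame: season, epoch, gcm, threshold, distance_km, n_presences),
#'   `statuses` (data frame: epoch, gcm, status), `breadths` (data frame),
#'   `config_hash`, `log` (filter drop counts).
#' @export
run_species <- function(species_id, occ_breeding, occ_winter,
                        present_stack, lgm_stacks, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(names(lgm_stacks)) && length(lgm_stacks))
    names(lgm_stacks) <- paste0("GCM", seq_along(lgm_stacks))
  occs <- list(breeding = occ_breeding, winter = occ_winter)
  preds <- list(); breadths <- list(); logrows <- list()
  for (season in names(occs)) {
    occ <- occs[[season]]
    if (is.null(occ)) next
    n0 <- n_records(occ)
    if (!is.null(config$lon_cutoff)) occ <- filter_west_of(occ, config$lon_cutoff)
    n_west <- n_records(occ)
    if (config$thin)
      occ <- thin_occurrences(occ, config$thin_km,
                              seed = .sub_seed(config$seed, species_id, 1L))
    n_thin <- n_records(occ)
    occ <- subsample(occ, config$subsample_max,
                     seed = .sub_seed(config$seed, species_id, 2L))
    n_used <- n_records(occ)
    logrows[[season]] <- data.frame(species_id = species_id, season = season,
                                    n_input = n0, n_after_lon = n_west,
                                    n_after_thin = n_thin, n_used = n_used)
    bg <- build_background(occ, present_stack, config$buffer_km, config$n_bg,
                           seed = .sub_seed(config$seed, species_id, 3L))
    # presence climate: collapse records to unique cells, drop nodata cells
    clim_p <- extract_climate(present_stack, occ$records$lon, occ$records$lat)
    idx <- .cell_index(present_stack, occ$records$lon, occ$records$lat)
    keep <- !duplicated(idx) & stats::complete.cases(clim_p)
    n_nodata <- sum(!stats::complete.cases(clim_p))
    clim_p <- clim_p[keep, , drop = FALSE]
    if (!nrow(clim_p)) stop("run_species: no presences on valid cells (",
                            species_id, ", ", season, ")")
    expn <- feature_expansion(bg, classes = config$feature_classes,
                              n_presences = nrow(clim_p),
                              n_hinge_knots = config$n_hinge_knots)
    Pm <- expand_features(clim_p, expn, clamp = TRUE)
    Fm <- expand_features(bg$climate, expn, clamp = TRUE)
    model <- suppressWarnings(
      fit_maxent(Pm, Fm, reg_multiplier = config$reg_multiplier,
                 max_iter = config$max_iter, tol = config$tol))
    train_map <- predict(model, expn, present_stack, clamp = config$clamp,
                         extrapolate = TRUE, scale = config$output_scale)
    train_suit <- extract_suitability(train_map, clim_p, expn, model, config)
    thr <- resolve_threshold(train_suit, config$rule)
    epochs <- c(list(present = present_stack), lgm_stacks)
    for (ep in names(epochs)) {
      st <- epochs[[ep]]
      mp <- if (ep == "present") train_map else
        predict(model, expn, st, clamp = config$clamp,
                extrapolate = config$extrapolate,
                scale = config$output_scale)
      bin <- binarize(mp, thr, species_id = species_id, season = season,
                      gcm_label = ep)
      dist <- distance_to_site(bin, config$site)
      preds[[paste(season, ep)]] <- data.frame(
        species_id = species_id, season = season,
        epoch = if (ep == "present") "present" else "lgm",
        gcm = ep, threshold = thr, distance_km = dist,
        n_presences = nrow(clim_p), n_dropped_nodata = n_nodata,
        converged = model$converged)
      breadths[[paste(season, ep)]] <- cbind(
        levins_breadth(mp, species_id = species_id, season = season,
                       epoch_label = ep),
        epoch_kind = if (ep == "present") "present" else "lgm")
    }
  }
  preds <- do.call(rbind, c(preds, make.row.names = FALSE))
  statuses <- list()
  for (ep in unique(preds$gcm)) {
    sub <- preds[preds$gcm == ep, ]
    bkm <- sub$distance_km[sub$season == "breeding"]
    wkm <- sub$distance_km[sub$season == "winter"]
    statuses[[ep]] <- data.frame(
      species_id = species_id,
      epoch = unique(sub$epoch), gcm = ep,
      status = classify_status(if (length(bkm)) bkm else NA_real_,
                               if (length(wkm)) wkm else NA_real_,
                               config$D))
  }
  structure(list(species_id = species_id, predictions = preds,
                 statuses = do.call(rbind, c(statuses,
                                             make.row.names = FALSE)),
                 breadths = do.call(rbind, c(breadths,
                                             make.row.names = FALSE)),
                 config_hash = config$hash,
                 log = do.call(rbind, c(logrows, make.row.names = FALSE))),
            class = "species_result")
}

# suitability of the training presences on the training map (cell lookup;
# falls back to direct model evaluation for presences, which is identical
# because presences sit on cell centres)
extract_suitability <- function(train_map, clim_p, expn, model, config) {
  Fm <- expand_features(clim_p, expn, clamp = TRUE)
  Fm <- Fm[, model$kept, drop = FALSE]
  eta <- drop(Fm %*% model$lambda)
  raw <- exp(eta - model$log_partition)
  if (config$output_scale == "raw") raw else
    1 - exp(-exp(model$entropy) * raw)
}

#' Run a batch of species, tolerating per-species failures
#'
#' Applies [run_species()] to each entry; a failing species is recorded as
#' an error row instead of aborting the batch.
#'
#' @param species_list Named list; each element a list with elements
#'   `breeding` and/or `winter` (`occurrence_set`s).
#' @param present_stack,lgm_stacks,config As in [run_species()].
#' @return List with `results` (named list of `species_result`) and `errors`
#'   (data frame of species_id, message).
#' @export
run_batch <- function(species_list, present_stack, lgm_stacks,
                      config = run_config()) {
  results <- list(); errors <- list()
  for (sp in names(species_list)) {
    entry <- species_list[[sp]]
    res <- tryCatch(
      run_species(sp, entry$breeding, entry$winter, present_stack,
                  lgm_stacks, config),
      error = function(e) e)
    if (inherits(res, "error")) {
      errors[[sp]] <- data.frame(species_id = sp,
                                 message = conditionMessage(res))
    } else {
      results[[sp]] <- res
    }
  }
  list(results = results,
       errors = if (length(errors))
         do.call(rbind, c(errors, make.row.names = FALSE))
       else data.frame(species_id = character(), message = character()))
}

#' Aggregate per-species results into report tables
#'
#' Builds the distance/status table (one row per species, the per-species
#' distance-and-status layout), the shift cross-tabulation, the turnover
#' statistic, and the breadth table, recomputing every aggregate from the
#' per-species rows. Optionally writes them to CSV/JSON files.
#'
#' @param results List of `species_result` objects (e.g. from
#'   [run_batch()]`$results`).
#' @param groups Optional named character vector mapping species_id to a
#'   provenance group (default: all `"inferred"`).
#' @param gcm GCM label whose LGM predictions feed the tables (default: the
#'   first non-present label found).
#' @param dir Optional output directory; when given, writes
#'   `species_table.csv`, `shift_table.csv`, `turnover.json`,
#'   `breadths.csv`.
#' @return List with `species_table`, `shift_table`, `turnover`,
#'   `breadths`, `summary`.
#' @export
make_reports <- function(results, groups = NULL, gcm = NULL, dir = NULL) {
  if (!length(results)) {
    species_table <- data.frame(species_id = character(),
                                group = character(),
                                breeding_km = numeric(),
                                winter_km = numeric(),
                                lgm_status = character(),
                                present_status = character(),
                                config_hash = character())
    out <- list(species_table = species_table, shift_table = NULL,
                turnover = NULL, breadths = NULL, summary = NULL)
  } else {
    preds <- do.call(rbind, c(lapply(results, `[[`, "predictions"),
                              make.row.names = FALSE))
    if (is.null(gcm)) {
      gcms <- setdiff(unique(preds$gcm), "present")
      gcm <- if (length(gcms)) gcms[1] else "present"
    }
    rows <- lapply(results, function(r) {
      p <- r$predictions
      pick <- function(season, g) {
        v <- p$distance_km[p$season == season & p$gcm == g]
        if (length(v)) v[1] else NA_real_
      }
      s <- r$statuses
      data.frame(
        species_id = r$species_id,
        breeding_km = pick("breeding", gcm),
        winter_km = pick("winter", gcm),
        present_breeding_km = pick("breeding", "present"),
        present_winter_km = pick("winter", "present"),
        lgm_status = s$status[s$gcm == gcm][1],
        present_status = s$status[s$gcm == "present"][1],
        config_hash = r$config_hash)
    })
    species_table <- do.call(rbind, c(rows, make.row.names = FALSE))
    species_table$group <- if (is.null(groups)) "inferred"
      else unname(groups[species_table$species_id])
    shift <- cross_tabulate(species_table[, c("species_id", "group",
                                              "lgm_status",
                                              "present_status")])
    summ <- summarize_residency(species_table)
    a <- sum(species_table$lgm_status %in% .presence_states &
               species_table$present_status %in% .presence_states)
    b <- sum(species_table$lgm_status %in% .presence_states &
               !(species_table$present_status %in% .presence_states))
    cc <- sum(!(species_table$lgm_status %in% .presence_states) &
                species_table$present_status %in% .presence_states)
    turnover <- list(a = a, b = b, c = cc,
                     turnover = if (a + min(b, cc) > 0)
                       simpson_turnover(a, b, cc) else NA_real_)
    breadths <- do.call(rbind, c(lapply(results, `[[`, "breadths"),
                                 make.row.names = FALSE))
    out <- list(species_table = species_table, shift_table = shift,
                turnover = turnover, breadths = breadths, summary = summ)
  }
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(out$species_table,
                     file.path(dir, "species_table.csv"), row.names = FALSE)
    if (!is.null(out$shift_table))
      utils::write.csv(out$shift_table$counts,
                       file.path(dir, "shift_table.csv"), row.names = FALSE)
    else
      utils::write.csv(data.frame(lgm_status = character(),
                                  present_status = character()),
                       file.path(dir, "shift_table.csv"), row.names = FALSE)
    if (!is.null(out$turnover))
      jsonlite::write_json(out$turnover, file.path(dir, "turnover.json"),
                           auto_unbox = TRUE, digits = NA)
    if (!is.null(out$breadths))
      utils::write.csv(out$breadths, file.path(dir, "breadths.csv"),
                       row.names = FALSE)
  }
  out
}
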