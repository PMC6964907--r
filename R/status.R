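#' Residency status levels
#'
#' Status of a species at a site in one epoch. `resident`, `breeding`,
#' `winter` and `not_present` are assigned from seasonal distances by
#' [classify_status()]; `migrant` and `extinct` come only from species
#' metadata (natural history), never from model distances; `unknown` marks
#' unresolvable rows.
#'
#' @return Character vector of the seven recognised status levels.
#' @export
status_levels <- function() {
  c("resident", "breeding", "winter", "migrant", "not_present", "extinct",
    "unknown")
}

# presence states: the species occurs at the site in some season
.presence_states <- c("resident", "breeding", "winter", "migrant")

#' Classify residency status from seasonal distances
#'
#' A species is counted present in a season when its distance from the focal
#' site to the nearest predicted cell is `<= D` km. Present in both seasons
#' gives `resident`; breeding season only, `breeding`; winter season only,
#' `winter`; neither, `not_present`. The `NA` sentinel (no predicted range
#' that season) counts as farther than `D`.
#'
#' @param breeding_km,winter_km Distances in km, or `NA` for "no predicted
#'   range".
#' @param D Presence distance threshold in km (> 0), default 100.
#' @return One of `"resident"`, `"breeding"`, `"winter"`, `"not_present"`.
#' @export
classify_status <- function(breeding_km, winter_km, D = 100) {
  stopifnot(D > 0)
  if ((!is.na(breeding_km) && breeding_km < 0) ||
      (!is.na(winter_km) && winter_km < 0))
    stop("classify_status: negative distance")
  b <- !is.na(breeding_km) && breeding_km <= D
  w <- !is.na(winter_km) && winter_km <= D
  if (b && w) "resident" else if (b) "breeding" else if (w) "winter"
  else "not_present"
}

#' Cross-tabulate residency shifts between epochs
#'
#' Counts species by ordered (LGM status, present status) pair, overall and
#' within each provenance group (`documented` at the site, `inferred` from
#' niche models only, `congeneric` stand-ins for genus-level
#' identifications). `unknown` statuses are tallied separately, never merged.
#'
#' @param rows Data frame with columns `species_id`, `group`, `lgm_status`,
#'   `present_status`.
#' @return Object of class `shift_table`: `counts` (data frame of
#'   `lgm_status`, `present_status`, one column per group, `total`),
#'   `n_species`, `groups`.
#' @export
cross_tabulate <- function(rows) {
  need <- c("species_id", "group", "lgm_status", "present_status")
  stopifnot(all(need %in% names(rows)))
  if (anyDuplicated(rows$species_id))
    stop("cross_tabulate: duplicate species_id")
  groups <- c("documented", "inferred", "congeneric")
  bad <- setdiff(unique(rows$group), groups)
  if (length(bad)) stop("cross_tabulate: unknown group(s): ",
                        paste(bad, collapse = ", "))
  lev <- status_levels()
  pair <- expand.grid(lgm_status = lev, present_status = lev,
                      stringsAsFactors = FALSE)
  counts <- pair
  for (g in groups) {
    sub <- rows[rows$group == g, ]
    counts[[g]] <- mapply(function(l, p) {
      sum(sub$lgm_status == l & sub$present_status == p)
    }, pair$lgm_status, pair$present_status)
  }
  counts$total <- rowSums(counts[, groups, drop = FALSE])
  counts <- counts[order(counts$lgm_status, counts$present_status), ]
  rownames(counts) <- NULL
  structure(list(counts = counts, n_species = nrow(rows), groups = groups),
            class = "shift_table")
}

#' @export
print.shift_table <- function(x, ...) {
  cat(sprintf("<shift_table> %d species\n", x$n_species))
  print(x$counts[x$counts$total > 0, ], row.names = FALSE)
  invisible(x)
}

#' Look up one cell of a shift table
#'
#' @param table A `shift_table`.
#' @param lgm_status,present_status Status pair (LGM first).
#' @param group One of `"documented"`, `"inferred"`, `"congeneric"`, or
#'   `"total"`.
#' @return Integer count.
#' @export
shift_count <- function(table, lgm_status, present_status, group = "total") {
  ct <- table$counts
  hit <- ct$lgm_status == lgm_status & ct$present_status == present_status
  if (!any(hit)) return(0L)
  as.integer(ct[[group]][hit])
}

#' Simpson's measure of species turnover between two lists
#'
#' `min(b, c) / (a + min(b, c))`, where `a` species are shared between the
#' two epochs' lists and `b`, `c` are unique to each. Symmetric in `b`, `c`;
#' ranges over \[0, 1\].
#'
#' @param a Count of species present at both epochs.
#' @param b,c Counts of species unique to each epoch.
#' @return Turnover fraction.
#' @export
simpson_turnover <- function(a, b, c) {
  stopifnot(a >= 0, b >= 0, c >= 0)
  if (a + min(b, c) == 0) stop("simpson_turnover: undefined for a = b = c = 0")
  min(b, c) / (a + min(b, c))
}

#' Per-epoch residency summaries
#'
#' Counts and fractions of each status at each epoch, over species with a
#' known status at that epoch; also reports how many species are in a
#' presence state (resident/breeding/winter/migrant) at each epoch.
#'
#' @param rows Data frame with `lgm_status` and `present_status` columns.
#' @return List with a `summary` data frame (`epoch`, `status`, `count`,
#'   `denominator`, `fraction`) and `presence` (named vector of presence
#'   counts per epoch).
#' @export
summarize_residency <- function(rows) {
  out <- list()
  pres <- c(lgm = NA_integer_, present = NA_integer_)
  for (ep in c("lgm", "present")) {
    st <- rows[[paste0(ep, "_status")]]
    known <- st[st != "unknown" & !is.na(st)]
    denom <- length(known)
    tab <- table(factor(known, levels = status_levels()))
    out[[ep]] <- data.frame(epoch = ep, status = names(tab),
                            count = as.integer(tab), denominator = denom,
                            fraction = as.numeric(tab) / denom)
    pres[ep] <- sum(known %in% .presence_states)
  }
  list(summary = do.call(rbind, c(out, make.row.names = FALSE)),
       presence = pres)
}

#' Count species that shifted between presence states
#'
#' Off-diagonal count over status pairs where both epochs' statuses are
#' presence states (resident, breeding, winter, migrant): species present at
#' both epochs whose seasonal occupancy changed.
#'
#' @param table A `shift_table`.
#' @return Integer count.
#' @export
count_shifters <- function(table) {
  ct <- table$counts
  keep <- ct$lgm_status %in% .presence_states &
    ct$present_status %in% .presence_states &
    ct$lgm_status != ct$present_status
  sum(ct$total[keep])
}

#' Compare within-distance verdicts between two model runs
#'
#' For each (species, season) pair present in both runs, compares the
#' "within `D` km of the site" verdict under each run. Pairs where both runs
#' predict absence agree (both say the species was not there). Returns the
#' agreement fraction over species, the disagreeing species, and the paired
#' distances for plotting.
#'
#' @param run_a,run_b Data frames with columns `species_id`, `season`,
#'   `distance_km` (`NA` = no predicted range).
#' @param D Presence distance in km (default 100).
#' @return List with `pairs` (per species/season verdicts and distances),
#'   `agreement` (fraction of species whose verdicts agree in every shared
#'   season), and `disagreements` (data frame of conflicting pairs).
#' @export
compare_scenarios <- function(run_a, run_b, D = 100) {
  key <- c("species_id", "season")
  m <- merge(run_a[, c(key, "distance_km")], run_b[, c(key, "distance_km")],
             by = key, suffixes = c("_a", "_b"))
  if (!nrow(m)) stop("compare_scenarios: no shared (species, season) pairs")
  within <- function(d) !is.na(d) & d <= D
  m$within_a <- within(m$distance_km_a)
  m$within_b <- within(m$distance_km_b)
  m$agree <- m$within_a == m$within_b
  by_sp <- tapply(m$agree, m$species_id, all)
  list(pairs = m,
       agreement = mean(by_sp),
       disagreements = m[!m$agree, , drop = FALSE])
}
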