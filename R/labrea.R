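#' The La Brea landbird table
#'
#' Loads the packaged per-species table for the La Brea tar-pit avifauna:
#' 187 landbird species with their documentation status at the site, the
#' distances (km) from the site to the nearest predicted breeding and
#' wintering occurrence at the Last Glacial Maximum, and the residency
#' status assigned at each epoch. The file ships verbatim as printed
#' (including entries such as `">500"`, `"NC"`, `"0?"` and qualifier marks);
#' this loader parses it into analysis-ready columns.
#'
#' Parsing rules: `NC` (not computed: the model predicted no range that
#' season) and empty cells become `NA` distances; `>500` becomes 500 with
#' `distance_censored = TRUE`; a trailing `?` on a distance or status marks
#' the row `uncertain`; a trailing `*` on a status marks it `most_probable`;
#' `not present (extinct)` parses to status `extinct`; the introduced-species
#' footnote parses to `not_present` with `introduced = TRUE`. Groups derive
#' from the documentation column: `Y` = `documented` (identified remains),
#' `N` = `inferred` (niche model only), `?` = `congeneric` (stand-in for a
#' genus-level identification).
#'
#' @param path Path to the TSV; defaults to the packaged copy.
#' @return Data frame with one row per species: `species_id`, `common_name`,
#'   `scientific_name`, `group`, `specimens`, `breeding_km`, `winter_km`,
#'   `distance_censored`, `lgm_status`, `present_status`, `uncertain`,
#'   `most_probable`, `extinct`, `introduced`, `modeled`.
#' @export
labrea_table <- function(path = system.file("extdata",
                                            "labrea_birds_table1.tsv",
                                            package = "paleoniche")) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           encoding = "UTF-8", check.names = FALSE)
  stopifnot(nrow(raw) > 0)
  parse_km <- function(x) {
    x <- trimws(x)
    censored <- grepl("^>", x)
    x2 <- sub("^>", "", sub("\\?$", "", x))
    val <- suppressWarnings(as.numeric(x2))
    val[x %in% c("", "NC", "NA")] <- NA_real_
    list(km = val, censored = censored, queried = grepl("\\?$", x))
  }
  b <- parse_km(raw$lgm_breeding_km)
  w <- parse_km(raw$lgm_winter_km)
  lgm_raw <- trimws(raw$lgm_status)
  pres_raw <- trimws(raw$present_status)
  norm_status <- function(s) gsub(" ", "_", sub("[*?]$", "", s))
  lgm <- norm_status(lgm_raw)
  pres <- norm_status(sub("\\^2\\^$", "", pres_raw))
  extinct <- grepl("extinct", pres_raw)
  pres[extinct] <- "extinct"
  introduced <- grepl("\\^2\\^$", pres_raw)
  grp <- c(Y = "documented", N = "inferred", `?` = "congeneric")
  # common names are unique in the printed table; scientific names are not
  # (one binomial is printed for two rows), so common names key the rows
  out <- data.frame(
    species_id = raw$common_name,
    common_name = raw$common_name,
    scientific_name = raw$scientific_name,
    group = unname(grp[trimws(raw$present_at_la_brea)]),
    specimens = raw$specimens_pits,
    breeding_km = b$km,
    winter_km = w$km,
    distance_censored = b$censored | w$censored,
    lgm_status = lgm,
    present_status = pres,
    uncertain = grepl("\\?$", lgm_raw) | grepl("\\?$", pres_raw) |
      b$queried | w$queried,
    most_probable = grepl("\\*$", lgm_raw) | grepl("\\*$", pres_raw),
    extinct = extinct,
    introduced = introduced,
    stringsAsFactors = FALSE
  )
  # species excluded from niche modeling carry no usable distances
  out$modeled <- !out$extinct & !(is.na(out$breeding_km) & is.na(out$winter_km))
  stopifnot(out$lgm_status %in% status_levels(),
            out$present_status %in% status_levels(),
            !anyNA(out$group))
  out
}

#' Check printed statuses against the distance-rule classifier
#'
#' Re-derives the LGM residency status of every modeled species from its
#' printed seasonal distances via [classify_status()] and compares it with
#' the printed status. Rows whose breeding or winter distance equals `D`
#' exactly sit on the presence boundary, where the printed table is known to
#' be internally inconsistent; all such rows are routed to the
#' boundary-conflict report regardless of agreement. Extinct and unmodeled
#' species are exempt (their statuses come from natural-history metadata,
#' not from models).
#'
#' @param tab Data frame from [labrea_table()] (or of the same layout).
#' @param D Presence distance in km (default 100).
#' @return List with `checked` (per-row comparison for modeled species:
#'   `species_id`, `breeding_km`, `winter_km`, `printed`, `derived`,
#'   `agree`, `boundary`), `boundary_conflicts` (boundary rows),
#'   `mismatches` (non-boundary rows where derived and printed disagree),
#'   `n_checked`, `n_agree`.
#' @export
check_status_consistency <- function(tab, D = 100) {
  sub <- tab[tab$modeled, , drop = FALSE]
  derived <- mapply(classify_status, sub$breeding_km, sub$winter_km,
                    MoreArgs = list(D = D))
  boundary <- (!is.na(sub$breeding_km) & sub$breeding_km == D) |
    (!is.na(sub$winter_km) & sub$winter_km == D)
  checked <- data.frame(species_id = sub$species_id,
                        common_name = sub$common_name,
                        breeding_km = sub$breeding_km,
                        winter_km = sub$winter_km,
                        printed = sub$lgm_status,
                        derived = unname(derived),
                        agree = sub$lgm_status == derived,
                        boundary = boundary,
                        stringsAsFactors = FALSE)
  list(checked = checked,
       boundary_conflicts = checked[checked$boundary, , drop = FALSE],
       mismatches = checked[!checked$agree & !checked$boundary, ,
                            drop = FALSE],
       n_checked = nrow(checked),
       n_agree = sum(checked$agree))
}
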