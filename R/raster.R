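#' Bioclimatic raster stacks
#'
#' A `bioclim_stack` is a set of 19 co-registered raster layers (BIO1-BIO19)
#' for one epoch/GCM, stored as a `nrow x ncol x 19` array with `NA` marking
#' nodata. Registration is cell-centre: row 1 is the northernmost row, column
#' 1 the westernmost column, and the coordinate of cell (r, c) is the centre
#' of that cell. The nodata mask is shared across layers (a cell missing in
#' any layer is masked in all).
#'
#' @param values `nrow x ncol x n_layers` numeric array (or a list of 19
#'   matrices), `NA` = nodata.
#' @param xll,yll Longitude/latitude of the *outer corner* of the lower-left
#'   cell, decimal degrees.
#' @param cellsize Cell size in decimal degrees (square cells).
#' @param epoch_label Label such as `"present"`, `"LGM-CCSM"`.
#' @param layer_names Layer names; defaults to `BIO1..BIO19`.
#' @return An object of class `bioclim_stack`.
#' @export
bioclim_stack <- function(values, xll, yll, cellsize,
                          epoch_label = "present", layer_names = NULL) {
  if (is.list(values)) values <- simplify2array(values)
  stopifnot(length(dim(values)) == 3)
  nl <- dim(values)[3]
  if (nl != 19L) stop("bioclim_stack: expected 19 layers, got ", nl)
  if (is.null(layer_names)) layer_names <- paste0("BIO", seq_len(nl))
  # union the nodata mask across layers
  mask <- apply(is.na(values), c(1, 2), any)
  if (any(mask)) values[rep(mask, nl)] <- NA  # array recycling over layers
  dimnames(values) <- list(NULL, NULL, layer_names)
  structure(list(values = values,
                 nrow = dim(values)[1], ncol = dim(values)[2],
                 xll = xll, yll = yll, cellsize = cellsize,
                 epoch_label = epoch_label),
            class = "bioclim_stack")
}

#' @export
print.bioclim_stack <- function(x, ...) {
  cat(sprintf("<bioclim_stack> %s: %d x %d cells, %d layers, cellsize %g deg\n",
              x$epoch_label, x$nrow, x$ncol, dim(x$values)[3], x$cellsize))
  invisible(x)
}

# Geometry descriptor used for equality checks and for derived maps.
.grid_geom <- function(g) list(nrow = g$nrow, ncol = g$ncol, xll = g$xll,
                               yll = g$yll, cellsize = g$cellsize)
.same_geom <- function(a, b, tol = 1e-9) {
  ga <- .grid_geom(a); gb <- .grid_geom(b)
  ga$nrow == gb$nrow && ga$ncol == gb$ncol &&
    abs(ga$xll - gb$xll) < tol && abs(ga$yll - gb$yll) < tol &&
    abs(ga$cellsize - gb$cellsize) < tol
}

#' Cell-centre coordinates of a grid
#'
#' @param g A `bioclim_stack`, `suitability_map`, or `binary_range_map`.
#' @return Data frame with columns `row`, `col`, `lon`, `lat`, in row-major
#'   order (row 1 = northernmost).
#' @export
cell_centers <- function(g) {
  rows <- rep(seq_len(g$nrow), each = g$ncol)
  cols <- rep(seq_len(g$ncol), times = g$nrow)
  data.frame(row = rows, col = cols,
             lon = g$xll + (cols - 0.5) * g$cellsize,
             lat = g$yll + (g$nrow - rows + 0.5) * g$cellsize)
}

# lon/lat -> (row, col); NA when outside the extent.
.cell_index <- function(g, lon, lat) {
  col <- floor((lon - g$xll) / g$cellsize) + 1L
  row <- g$nrow - floor((lat - g$yll) / g$cellsize)
  bad <- col < 1L | col > g$ncol | row < 1L | row > g$nrow
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  data.frame(row = row, col = col)
}

#' Extract climate values at point locations
#'
#' Point-in-cell lookup with cell-centre registration: each point receives
#' the 19 layer values of the cell containing it.
#'
#' @param stack A `bioclim_stack`.
#' @param lon,lat Coordinate vectors in decimal degrees.
#' @return Matrix `n x 19` of climate values; rows of points falling outside
#'   the extent or on nodata cells are `NA`.
#' @export
extract_climate <- function(stack, lon, lat) {
  idx <- .cell_index(stack, lon, lat)
  nl <- dim(stack$values)[3]
  out <- matrix(NA_real_, length(lon), nl,
                dimnames = list(NULL, dimnames(stack$values)[[3]]))
  ok <- !is.na(idx$row)
  if (any(ok)) {
    flat <- cbind(idx$row[ok], idx$col[ok])
    for (j in seq_len(nl)) out[ok, j] <- stack$values[, , j][flat]
  }
  out
}

#' Read one ESRI ASCII grid
#'
#' Parses the plain-text Arc/Info ASCII raster format (`ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, `nodata_value` header followed by
#' row-major values, first row = northernmost).
#'
#' @param path File path.
#' @return List with `values` (matrix, `NA` = nodata), `xll`, `yll`,
#'   `cellsize`.
#' @export
read_esri_ascii <- function(path) {
  if (!file.exists(path)) stop("read_esri_ascii: file not found: ", path)
  lines <- readLines(path, n = 6L)
  hdr <- list()
  n_hdr <- 0L
  for (ln in lines) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(tok) == 2 && !is.na(suppressWarnings(as.numeric(tok[2]))) &&
        is.na(suppressWarnings(as.numeric(tok[1])))) {
      hdr[[tolower(tok[1])]] <- as.numeric(tok[2])
      n_hdr <- n_hdr + 1L
    } else break
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("read_esri_ascii: malformed header in ", path)
  vals <- scan(path, what = numeric(), skip = n_hdr, quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc)
    stop("read_esri_ascii: expected ", nr * nc, " values, got ", length(vals))
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  list(values = m, xll = hdr$xllcorner, yll = hdr$yllcorner,
       cellsize = hdr$cellsize)
}

#' Write one matrix as an ESRI ASCII grid
#'
#' @param values Numeric matrix (row 1 = northernmost row); `NA` written as
#'   the nodata value.
#' @param path Output path.
#' @param xll,yll,cellsize Grid geometry (corner registration of the header).
#' @param nodata Nodata sentinel to write (default -9999).
#' @return `path`, invisibly.
#' @export
write_esri_ascii <- function(values, path, xll, yll, cellsize,
                             nodata = -9999) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("ncols", ncol(values)),
               paste("nrows", nrow(values)),
               paste("xllcorner", format(xll, digits = 15)),
               paste("yllcorner", format(yll, digits = 15)),
               paste("cellsize", format(cellsize, digits = 15)),
               paste("NODATA_value", nodata)), con)
  v <- values
  v[is.na(v)] <- nodata
  utils::write.table(format(v, trim = TRUE, digits = 10, scientific = FALSE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a 19-layer bioclim stack from ESRI ASCII grids
#'
#' All layers must share the grid geometry exactly; nodata masks are unioned.
#'
#' @param paths Character vector of exactly 19 raster paths, in BIO1..BIO19
#'   order.
#' @param epoch_label Epoch/GCM label stored on the stack.
#' @return A `bioclim_stack`.
#' @export
read_stack <- function(paths, epoch_label = "present") {
  if (length(paths) != 19L)
    stop("read_stack: expected 19 layer paths, got ", length(paths))
  first <- read_esri_ascii(paths[1])
  arr <- array(NA_real_, c(nrow(first$values), ncol(first$values), 19L))
  arr[, , 1] <- first$values
  for (j in 2:19) {
    lay <- read_esri_ascii(paths[j])
    if (nrow(lay$values) != nrow(first$values) ||
        ncol(lay$values) != ncol(first$values) ||
        abs(lay$xll - first$xll) > 1e-9 ||
        abs(lay$yll - first$yll) > 1e-9 ||
        abs(lay$cellsize - first$cellsize) > 1e-9) {
      stop("read_stack: geometry mismatch in layer ", j,
           " (", paths[j], ")")
    }
    arr[, , j] <- lay$values
  }
  bioclim_stack(arr, first$xll, first$yll, first$cellsize, epoch_label)
}

#' Write a bioclim stack as 19 ESRI ASCII grids
#'
#' @param stack A `bioclim_stack`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix; files are `<prefix>_BIO<k>.asc`.
#' @return Character vector of the 19 paths written, invisibly.
#' @export
write_stack <- function(stack, dir, prefix = "clim") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, sprintf("%s_BIO%d.asc", prefix, 1:19))
  for (j in 1:19) {
    write_esri_ascii(stack$values[, , j], paths[j],
                     stack$xll, stack$yll, stack$cellsize)
  }
  invisible(paths)
}

#' Suitability maps
#'
#' Raster of model output for one (species, season, epoch, GCM), either on
#' the `raw` scale (Gibbs density normalised over the training background) or
#' the bounded `cloglog` scale in \[0, 1\].
#'
#' @param values Numeric matrix (`NA` = nodata), row 1 northernmost.
#' @param geom A `bioclim_stack` (or any grid object) supplying geometry.
#' @param scale `"raw"` or `"cloglog"`.
#' @param epoch_label,clamped Provenance fields.
#' @return Object of class `suitability_map`.
#' @export
suitability_map <- function(values, geom, scale = c("cloglog", "raw"),
                            epoch_label = geom$epoch_label, clamped = TRUE) {
  scale <- match.arg(scale)
  stopifnot(nrow(values) == geom$nrow, ncol(values) == geom$ncol)
  if (scale == "raw" && any(values < 0, na.rm = TRUE))
    stop("suitability_map: negative raw values")
  if (scale == "cloglog" &&
      any(values < 0 | values > 1, na.rm = TRUE))
    stop("suitability_map: cloglog values outside [0, 1]")
  structure(c(list(values = values), .grid_geom(geom),
              list(scale = scale, epoch_label = epoch_label,
                   clamped = clamped)),
            class = "suitability_map")
}

#' @export
print.suitability_map <- function(x, ...) {
  cat(sprintf("<suitability_map> %s [%s]: %d x %d, range %.4g..%.4g\n",
              x$epoch_label, x$scale, x$nrow, x$ncol,
              min(x$values, na.rm = TRUE), max(x$values, na.rm = TRUE)))
  invisible(x)
}

#' Binary range maps
#'
#' Presence/absence raster obtained by thresholding a suitability map;
#' values 1 (present), 0 (absent), `NA` (nodata).
#'
#' @param values Matrix of 0/1/NA.
#' @param geom Grid-geometry source object.
#' @param threshold Threshold value used.
#' @param species_id,season,epoch_label,gcm_label Provenance fields.
#' @return Object of class `binary_range_map`.
#' @export
binary_range_map <- function(values, geom, threshold,
                             species_id = NA_character_,
                             season = NA_character_,
                             epoch_label = geom$epoch_label,
                             gcm_label = NA_character_) {
  stopifnot(all(values %in% c(0, 1) | is.na(values)))
  structure(c(list(values = values), .grid_geom(geom),
              list(threshold = threshold, species_id = species_id,
                   season = season, epoch_label = epoch_label,
                   gcm_label = gcm_label)),
            class = "binary_range_map")
}

#' @export
print.binary_range_map <- function(x, ...) {
  cat(sprintf(
    "<binary_range_map> %s %s %s: %d present / %d valid cells (thr %.4g)\n",
    x$species_id, x$season, x$epoch_label,
    sum(x$values == 1, na.rm = TRUE), sum(!is.na(x$values)), x$threshold))
  invisible(x)
}
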