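#' Digital elevation model grid
#'
#' A `dem_grid` is a regular elevation raster registered to cell centres, with
#' row 1 at the north-west corner. Coordinates are metric and planar (a
#' UTM-like projection is assumed); `xll`/`yll` give the lower-left *corner*
#' of the grid as in the ESRI ASCII convention.
#'
#' @param elevation numeric matrix of elevations (m); row 1 is the northern
#'   edge.
#' @param cellsize cell edge length in metres.
#' @param xll,yll x/y coordinate of the lower-left corner of the lower-left
#'   cell (m).
#' @param nodata sentinel value marking missing cells (stored as `NA`
#'   internally).
#' @return An object of class `dem_grid`.
#' @export
dem_grid <- function(elevation, cellsize, xll = 0, yll = 0, nodata = -9999) {
  if (!is.matrix(elevation) || nrow(elevation) < 1 || ncol(elevation) < 1)
    stop("elevation must be a non-empty matrix", call. = FALSE)
  if (!is.numeric(cellsize) || length(cellsize) != 1 || cellsize <= 0)
    stop("cellsize must be a single positive number", call. = FALSE)
  elevation[!is.na(elevation) & elevation == nodata] <- NA_real_
  structure(
    list(elevation = elevation, cellsize = cellsize,
         xll = xll, yll = yll, nodata = nodata,
         slope_deg = NULL, slope_pct = NULL, aspect_deg = NULL),
    class = "dem_grid"
  )
}

#' @export
print.dem_grid <- function(x, ...) {
  z <- x$elevation
  cat(sprintf("<dem_grid> %d x %d cells, %.6g m resolution\n",
              nrow(z), ncol(z), x$cellsize))
  cat(sprintf("  extent: x [%.6g, %.6g], y [%.6g, %.6g]\n",
              x$xll, x$xll + ncol(z) * x$cellsize,
              x$yll, x$yll + nrow(z) * x$cellsize))
  cat(sprintf("  elevation: [%.6g, %.6g] m, %d nodata cell(s)\n",
              suppressWarnings(min(z, na.rm = TRUE)),
              suppressWarnings(max(z, na.rm = TRUE)), sum(is.na(z))))
  if (!is.null(x$slope_deg)) cat("  slope/aspect grids: present\n")
  invisible(x)
}

dem_extent <- function(dem) {
  c(xmin = dem$xll, xmax = dem$xll + ncol(dem$elevation) * dem$cellsize,
    ymin = dem$yll, ymax = dem$yll + nrow(dem$elevation) * dem$cellsize)
}

# cell centre coordinates
dem_centres <- function(dem) {
  nr <- nrow(dem$elevation); nc <- ncol(dem$elevation)
  list(x = dem$xll + (seq_len(nc) - 0.5) * dem$cellsize,
       y = dem$yll + (nr - seq_len(nr) + 0.5) * dem$cellsize)
}

# row/col of the cell containing each point; NA outside the extent.
# Points on the far east/north edge belong to the last cell.
dem_cell_index <- function(dem, x, y) {
  nr <- nrow(dem$elevation); nc <- ncol(dem$elevation)
  cs <- dem$cellsize
  j <- floor((x - dem$xll) / cs) + 1
  i_south <- floor((y - dem$yll) / cs) + 1
  j[x == dem$xll + nc * cs] <- nc
  i_south[y == dem$yll + nr * cs] <- nr
  i <- nr - i_south + 1
  bad <- is.na(x) | is.na(y) | j < 1 | j > nc | i < 1 | i > nr
  i[bad] <- NA_integer_; j[bad] <- NA_integer_
  list(row = as.integer(i), col = as.integer(j))
}

#' Read a DEM from an ESRI ASCII grid
#'
#' Parses the plain-text ESRI ASCII raster format (`ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, optional `NODATA_value` header
#' followed by rows of elevations, north first).
#'
#' @param path path to a `.asc`/`.txt` ESRI ASCII grid.
#' @return A [dem_grid()].
#' @export
read_dem <- function(path) {
  if (!file.exists(path)) stop("DEM file not found: ", path, call. = FALSE)
  if (grepl("\\.tiff?$", path, ignore.case = TRUE))
    stop("GeoTIFF input is not supported; supply an ESRI ASCII grid (.asc)",
         call. = FALSE)
  lines <- readLines(path, n = 6L)
  hdr <- list()
  n_hdr <- 0L
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) == 2 && grepl("^[A-Za-z_]+$", parts[1])) {
      hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
      n_hdr <- n_hdr + 1L
    } else break
  }
  req <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(req %in% names(hdr)))
    stop("not an ESRI ASCII grid (missing header fields): ", path,
         call. = FALSE)
  nodata <- hdr[["nodata_value"]] %||% -9999
  vals <- scan(path, what = numeric(), skip = n_hdr, quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc)
    stop(sprintf("ESRI ASCII grid has %d values, expected %d", length(vals),
                 nr * nc), call. = FALSE)
  z <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  dem_grid(z, cellsize = hdr$cellsize, xll = hdr$xllcorner,
           yll = hdr$yllcorner, nodata = nodata)
}

#' Write a DEM as an ESRI ASCII grid
#'
#' @param dem a [dem_grid()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dem <- function(dem, path) {
  z <- dem$elevation
  z[is.na(z)] <- dem$nodata
  hdr <- c(
    sprintf("ncols %d", ncol(z)),
    sprintf("nrows %d", nrow(z)),
    sprintf("xllcorner %.10g", dem$xll),
    sprintf("yllcorner %.10g", dem$yll),
    sprintf("cellsize %.10g", dem$cellsize),
    sprintf("NODATA_value %.10g", dem$nodata)
  )
  body <- apply(z, 1, function(r) paste(format(r, trim = TRUE, digits = 15),
                                        collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Derive slope and aspect grids (Horn's method)
#'
#' Computes slope and aspect with Horn's 3x3 finite-difference kernel, the
#' standard method of GIS terrain toolboxes. Border cells use a replicated
#' edge. Slope is carried both in degrees, `atan(|grad|)`, and as rise/run
#' percent, `100 |grad|`. Aspect is the downslope direction in degrees
#' clockwise from north; flat cells (zero gradient) are `NA`.
#'
#' @param dem a [dem_grid()] of at least 3x3 cells.
#' @return The input `dem_grid` with `slope_deg`, `slope_pct` and
#'   `aspect_deg` matrices filled in.
#' @export
compute_slope_aspect <- function(dem) {
  z <- dem$elevation
  nr <- nrow(z); nc <- ncol(z)
  if (nr < 3 || nc < 3)
    stop("slope/aspect needs a grid of at least 3x3 cells", call. = FALSE)
  cs <- dem$cellsize
  zp <- rbind(z[1, , drop = FALSE], z, z[nr, , drop = FALSE])
  zp <- cbind(zp[, 1, drop = FALSE], zp, zp[, nc, drop = FALSE])
  sh <- function(dr, dc) zp[(1 + dr):(nr + dr), (1 + dc):(nc + dc)]
  # neighbours: a b c / d e f / g h i with row 1 = north, col + = east
  a <- sh(0, 0); b <- sh(0, 1); cc <- sh(0, 2)
  d <- sh(1, 0);                f  <- sh(1, 2)
  g <- sh(2, 0); h <- sh(2, 1); ii <- sh(2, 2)
  gx <- ((cc + 2 * f + ii) - (a + 2 * d + g)) / (8 * cs)   # d z / d east
  gy <- ((a + 2 * b + cc) - (g + 2 * h + ii)) / (8 * cs)   # d z / d north
  grad <- sqrt(gx^2 + gy^2)
  dem$slope_deg <- atan(grad) * 180 / pi
  dem$slope_pct <- 100 * grad
  aspect <- (atan2(-gx, -gy) * 180 / pi) %% 360
  aspect[grad == 0] <- NA_real_
  dem$aspect_deg <- aspect
  dem
}

#' Annotate GPS fixes with terrain attributes
#'
#' Samples elevation, slope and aspect from a DEM at each fix. The default
#' sampling is nearest-cell (the value of the enclosing cell); bilinear
#' interpolation between the four surrounding cell centres is available for
#' elevation only.
#'
#' @param fixes a data frame with `x` and `y` columns (metres, same CRS as
#'   the DEM).
#' @param dem a [dem_grid()]; slope/aspect grids are derived on the fly if
#'   absent.
#' @param method `"nearest"` (default) or `"bilinear"` (elevation only;
#'   slope/aspect stay nearest-cell).
#' @param max_outside_frac hard-error threshold on the fraction of fixes
#'   falling outside the DEM extent (default 0.05).
#' @return The input data frame with `elevation`, `slope_deg`, `slope_pct`
#'   and `aspect_deg` columns appended (`NA` for out-of-extent fixes).
#' @export
annotate_fixes <- function(fixes, dem, method = c("nearest", "bilinear"),
                           max_outside_frac = 0.05) {
  method <- match.arg(method)
  assert_columns(fixes, c("x", "y"), "fixes")
  if (is.null(dem$slope_deg)) dem <- compute_slope_aspect(dem)
  idx <- dem_cell_index(dem, fixes$x, fixes$y)
  outside <- is.na(idx$row)
  n_out <- sum(outside)
  if (n_out > 0) {
    frac <- n_out / nrow(fixes)
    if (frac > max_outside_frac)
      stop(sprintf("%d of %d fixes (%.1f%%) fall outside the DEM extent",
                   n_out, nrow(fixes), 100 * frac), call. = FALSE)
    warning(sprintf("%d fix(es) outside the DEM extent annotated as NA",
                    n_out), call. = FALSE)
  }
  lin <- cbind(idx$row, idx$col)
  elev <- dem$elevation[lin]
  if (method == "bilinear") elev <- bilinear_elevation(dem, fixes$x, fixes$y)
  out <- fixes
  out$elevation <- elev
  out$slope_deg <- dem$slope_deg[lin]
  out$slope_pct <- dem$slope_pct[lin]
  out$aspect_deg <- dem$aspect_deg[lin]
  attr(out, "annotation") <- list(method = method, n_outside = n_out)
  tibble::as_tibble(out)
}

# bilinear interpolation between the four surrounding cell centres,
# clamped to the centre lattice at the borders
bilinear_elevation <- function(dem, x, y) {
  ctr <- dem_centres(dem)
  nr <- nrow(dem$elevation); nc <- ncol(dem$elevation)
  cs <- dem$cellsize
  fx <- (x - ctr$x[1]) / cs            # fractional column offset
  fy <- (ctr$y[1] - y) / cs            # fractional row offset (north first)
  j0 <- pmin(pmax(floor(fx), 0), nc - 2); i0 <- pmin(pmax(floor(fy), 0), nr - 2)
  tx <- pmin(pmax(fx - j0, 0), 1); ty <- pmin(pmax(fy - i0, 0), 1)
  z <- dem$elevation
  z00 <- z[cbind(i0 + 1, j0 + 1)]; z01 <- z[cbind(i0 + 1, j0 + 2)]
  z10 <- z[cbind(i0 + 2, j0 + 1)]; z11 <- z[cbind(i0 + 2, j0 + 2)]
  out <- (1 - ty) * ((1 - tx) * z00 + tx * z01) +
    ty * ((1 - tx) * z10 + tx * z11)
  ext <- dem_extent(dem)
  out[is.na(x) | is.na(y) | x < ext["xmin"] | x > ext["xmax"] |
        y < ext["ymin"] | y > ext["ymax"]] <- NA_real_
  out
}
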