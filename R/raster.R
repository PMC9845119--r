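#' Georeferenced single-band raster
#'
#' Lightweight container for the rasters this package exchanges: a numeric or
#' integer matrix (row 1 = northernmost row) plus a square pixel size in
#' metres, the world coordinate of the top-left corner, and an opaque CRS tag
#' carried through unmodified.
#'
#' @param values Numeric or integer matrix.
#' @param pixel_size Pixel edge length in metres (> 0).
#' @param xmin,ymax World coordinates of the top-left corner of pixel (1, 1).
#' @param crs Opaque coordinate-reference tag (any string), or `NA`.
#' @return An object of class `crown_raster`.
#' @export
crown_raster <- function(values, pixel_size, xmin = 0, ymax = NULL, crs = NA_character_) {
  if (!is.matrix(values)) stop("`values` must be a matrix")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || !is.finite(pixel_size) ||
      pixel_size <= 0) {
    stop("`pixel_size` must be a single positive number (metres)")
  }
  if (is.null(ymax)) ymax <- nrow(values) * pixel_size
  structure(
    list(values = values, pixel_size = as.numeric(pixel_size),
         xmin = as.numeric(xmin), ymax = as.numeric(ymax), crs = crs),
    class = "crown_raster"
  )
}

#' @export
print.crown_raster <- function(x, ...) {
  cat(sprintf("<crown_raster> %d x %d px @ %g m/px\n", nrow(x$values),
              ncol(x$values), x$pixel_size))
  cat(sprintf("  extent: x [%g, %g], y [%g, %g]%s\n",
              x$xmin, x$xmin + ncol(x$values) * x$pixel_size,
              x$ymax - nrow(x$values) * x$pixel_size, x$ymax,
              if (is.na(x$crs)) "" else paste0("  crs: ", x$crs)))
  invisible(x)
}

#' @export
dim.crown_raster <- function(x) dim(x$values)

# world coordinates of pixel centres; r, c are 1-based matrix indices
pixel_to_world <- function(raster, r, c) {
  list(x = raster$xmin + (c - 0.5) * raster$pixel_size,
       y = raster$ymax - (r - 0.5) * raster$pixel_size)
}

assert_binary_mask <- function(raster, arg = "mask") {
  v <- raster$values
  bad <- unique(v[!(v %in% c(0, 1))])
  if (length(bad)) {
    stop(sprintf("`%s` must be binary {0,1}; found value(s): %s", arg,
                 paste(utils::head(bad, 5), collapse = ", ")))
  }
  invisible(raster)
}

#' Coerce a raster to a binary mask
#'
#' Values > 0 become 1 (with a warning when any value other than 0/1 is
#' present), matching the usual treatment of probability or label rasters
#' passed where a binary mask is expected. Negative values are an error.
#'
#' @param raster A `crown_raster`.
#' @return A binary `crown_raster`.
#' @export
as_binary_mask <- function(raster) {
  v <- raster$values
  if (any(v < 0, na.rm = TRUE)) stop("mask contains negative values")
  if (any(!(v %in% c(0, 1)))) {
    warning("coercing values > 0 to 1")
    v[] <- as.integer(v > 0)
    raster$values <- v
  } else {
    raster$values[] <- as.integer(v)
  }
  raster
}

#' Read an ESRI ASCII grid
#'
#' Reads the plain-text `.asc` raster format (ncols/nrows/xllcorner/yllcorner/
#' cellsize header followed by row-major values, first row = north).
#'
#' @param path File path.
#' @param crs Optional CRS tag to attach (the format itself carries none).
#' @return A `crown_raster`.
#' @export
read_asc <- function(path, crs = NA_character_) {
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
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr))) {
    stop("not an ESRI ASCII grid: missing header field(s) ",
         paste(setdiff(need, names(hdr)), collapse = ", "))
  }
  vals <- scan(path, skip = n_hdr, quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc) stop("value count does not match header dimensions")
  if (!is.null(hdr$nodata_value)) vals[vals == hdr$nodata_value] <- NA_real_
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  crown_raster(m, pixel_size = hdr$cellsize, xmin = hdr$xllcorner,
               ymax = hdr$yllcorner + nr * hdr$cellsize, crs = crs)
}

#' Write an ESRI ASCII grid
#'
#' @param raster A `crown_raster`.
#' @param path Output file path.
#' @param digits Significant digits for non-integer values.
#' @return `path`, invisibly.
#' @export
write_asc <- function(raster, path, digits = 10) {
  v <- raster$values
  nr <- nrow(v); nc <- ncol(v)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", nc),
    sprintf("nrows %d", nr),
    sprintf("xllcorner %.10g", raster$xmin),
    sprintf("yllcorner %.10g", raster$ymax - nr * raster$pixel_size),
    sprintf("cellsize %.10g", raster$pixel_size)
  ), con)
  fmt <- if (is.integer(v) || all(v == round(v), na.rm = TRUE)) "%d" else
    paste0("%.", digits, "g")
  for (r in seq_len(nr)) {
    row <- v[r, ]
    if (fmt == "%d") row <- as.integer(row)
    writeLines(paste(sprintf(fmt, row), collapse = " "), con)
  }
  invisible(path)
}
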