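#' Extract per-crown records from a label scene
#'
#' Produces one row per instance label: pixel count, crown area in m2, crown
#' diameter `CD = 2 * sqrt(area / pi)` (the diameter of the circle with the
#' crown's area), and the world-coordinate centroid (mean of pixel centres).
#' Crowns below the minimum mappable area are dropped; the default 0.25 m2
#' is the smallest crown still clearly identifiable in 0.25 m imagery.
#'
#' @param scene A `label_scene` from [dcr()].
#' @param min_area_m2 Minimum crown area to retain, in m2.
#' @return A data frame with columns `tree_id`, `n_pixels`, `area_m2`,
#'   `cd_m`, `x`, `y`.
#' @export
extract_crowns <- function(scene, min_area_m2 = 0.25) {
  stopifnot(inherits(scene, "label_scene"))
  lab <- scene$labels
  ps <- scene$pixel_size
  idx <- which(lab > 0)
  if (!length(idx)) {
    return(data.frame(tree_id = integer(0), n_pixels = integer(0),
                      area_m2 = numeric(0), cd_m = numeric(0),
                      x = numeric(0), y = numeric(0)))
  }
  rr <- (idx - 1L) %% nrow(lab) + 1L
  cc <- (idx - 1L) %/% nrow(lab) + 1L
  l <- lab[idx]
  n_pix <- as.integer(tapply(l, l, length))
  ids <- as.integer(names(tapply(l, l, length)))
  w <- pixel_to_world(scene, rr, cc)
  cx <- as.numeric(tapply(w$x, l, mean))
  cy <- as.numeric(tapply(w$y, l, mean))
  area <- n_pix * ps^2
  out <- data.frame(tree_id = ids, n_pixels = n_pix, area_m2 = area,
                    cd_m = 2 * sqrt(area / pi), x = cx, y = cy)
  out <- out[out$area_m2 >= min_area_m2, , drop = FALSE]
  out <- out[order(out$tree_id), , drop = FALSE]  # tapply sorts ids lexically
  rownames(out) <- NULL
  out
}

#' Buffer radius for a given crown expansion
#'
#' For an area-based expansion the crown (treated as a circle of diameter
#' `CD`) must grow to `(1 + expansion)` times its area, giving a buffer of
#' `(sqrt(1 + expansion) - 1) * CD / 2`; for a diameter-based expansion the
#' diameter itself is scaled, giving `expansion * CD / 2`.
#'
#' @param cd_m Crown diameter(s) in metres.
#' @param expansion Fractional expansion (default 0.27, the shrinkage of
#'   boundary-weighted crown predictions relative to manual delineations).
#' @param mode `"area"` (default) or `"diameter"`.
#' @return Buffer radius in metres.
#' @export
buffer_radius <- function(cd_m, expansion = 0.27, mode = c("area", "diameter")) {
  mode <- match.arg(mode)
  if (expansion < 0) stop("`expansion` must be >= 0")
  if (mode == "area") (sqrt(1 + expansion) - 1) * cd_m / 2
  else expansion * cd_m / 2
}

#' Expand crowns and dissolve them into canopy cover
#'
#' Dilates each labelled crown outward by its own buffer radius (Euclidean
#' dilation on the pixel grid) so its area grows by approximately the
#' expansion fraction, then unions the dilated crowns into a single cover
#' raster. Touching or near-touching crowns dissolve into continuous cover
#' features, mimicking the closed canopy the segmentation's inter-crown gaps
#' artificially opened.
#'
#' Cover is anti-aliased: each pixel holds the approximate fraction of it
#' covered by the buffered crowns, `clamp(1/2 + r - max(0, d - 3/8), 0, 1)`,
#' where `d` is the Euclidean distance (pixels) to the nearest crown pixel
#' centre and 3/8 px is the orientation-averaged sub-pixel offset between
#' pixel-centre distances and the true (smooth) crown boundary. Fractional
#' accounting keeps dissolved areas accurate even when the buffer radius is
#' a small fraction of a pixel; threshold at 0.5 (see [cover_mask()]) for a
#' binary cover geometry. Union is by per-pixel maximum, so overlapping
#' buffers are dissolved, never double counted.
#'
#' @param scene A `label_scene`.
#' @param records Crown table from [extract_crowns()]; crowns dropped there
#'   (below the area threshold) are excluded from cover.
#' @inheritParams buffer_radius
#' @return A `crown_raster` of dissolved cover fractions in \[0, 1\].
#' @export
expand_crowns <- function(scene, records = extract_crowns(scene),
                          expansion = 0.27, mode = c("area", "diameter")) {
  mode <- match.arg(mode)
  if (expansion < 0) stop("`expansion` must be >= 0")
  lab <- scene$labels
  ps <- scene$pixel_size
  cover <- matrix(0, nrow(lab), ncol(lab))
  for (i in seq_len(nrow(records))) {
    id <- records$tree_id[i]
    r_px <- buffer_radius(records$cd_m[i], expansion, mode) / ps
    sel <- matrix(as.integer(lab == id), nrow(lab), ncol(lab))
    if (r_px <= 0) {
      cover <- pmax(cover, sel)
    } else {
      d <- edt_to_set_cpp(sel)
      frac <- pmin(1, pmax(0, 0.5 + r_px - pmax(0, d - 0.375)))
      frac[sel == 1L] <- 1
      cover <- pmax(cover, frac)
    }
  }
  crown_raster(cover, pixel_size = ps, xmin = scene$xmin, ymax = scene$ymax,
               crs = scene$crs)
}

#' Binary cover mask from fractional cover
#'
#' @param cover Fractional cover raster from [expand_crowns()].
#' @param threshold Coverage fraction above which a pixel counts as covered.
#' @return A binary `crown_raster`.
#' @export
cover_mask <- function(cover, threshold = 0.5) {
  cover$values <- matrix(as.integer(cover$values >= threshold),
                         nrow(cover$values), ncol(cover$values))
  cover
}

#' Total cover area of a (fractional) cover raster, in m2
#' @param cover A cover `crown_raster`.
#' @return Area in m2.
#' @export
cover_area_m2 <- function(cover) sum(cover$values) * cover$pixel_size^2

#' Aggregate trees and cover to a hectare grid
#'
#' Bins tree centroids into half-open square cells `[x, x + cell) x
#' [y, y + cell)` aligned to `grid_origin`, and reports per cell: tree
#' density (trees per hectare), canopy cover (percent of the cell covered by
#' the dissolved expanded crowns) and carbon density (sum of per-tree
#' aboveground carbon, MgC per hectare; 0 where no `agc_kg` column is
#' present). Trees falling outside the grid extent are counted in an
#' overflow bin and reported, never silently dropped.
#'
#' @param records Crown table with `x`, `y` (and optionally `agc_kg`).
#' @param cover Binary cover `crown_raster` from [expand_crowns()], or `NULL`
#'   to skip cover.
#' @param grid_origin Numeric `c(x0, y0)`: lower-left corner of cell (1, 1).
#' @param cell_size Cell edge in metres (default 100 m = 1 ha).
#' @param n_cols,n_rows Grid dimensions in cells; by default derived from the
#'   cover raster's extent, which must then be supplied.
#' @return A `hectare_grid`: list with `cells` (data frame: `cell_row`,
#'   `cell_col`, `x0`, `y0`, `n_trees`, `density_ha`, `cover_pct`,
#'   `carbon_mgc_ha`), `overflow` (count of out-of-grid trees), `cell_size`,
#'   `grid_origin`.
#' @export
aggregate_hectares <- function(records, cover = NULL, grid_origin = NULL,
                               cell_size = 100, n_cols = NULL, n_rows = NULL) {
  if (is.null(grid_origin)) {
    if (is.null(cover)) stop("supply `grid_origin` or a cover raster")
    grid_origin <- c(cover$xmin, cover$ymax - nrow(cover$values) * cover$pixel_size)
  }
  if (is.null(n_cols) || is.null(n_rows)) {
    if (is.null(cover)) stop("supply `n_cols`/`n_rows` or a cover raster")
    ext_x <- ncol(cover$values) * cover$pixel_size
    ext_y <- nrow(cover$values) * cover$pixel_size
    n_cols <- max(1L, as.integer(ceiling(ext_x / cell_size - 1e-9)))
    n_rows <- max(1L, as.integer(ceiling(ext_y / cell_size - 1e-9)))
  }
  x0 <- grid_origin[1]; y0 <- grid_origin[2]
  cell_area_ha <- cell_size^2 / 1e4

  cells <- expand.grid(cell_row = seq_len(n_rows), cell_col = seq_len(n_cols))
  cells$x0 <- x0 + (cells$cell_col - 1L) * cell_size
  cells$y0 <- y0 + (cells$cell_row - 1L) * cell_size
  key <- function(row, col) (row - 1L) * n_cols + col
  cells$n_trees <- 0L
  cells$carbon_mgc_ha <- 0
  overflow <- 0L

  if (nrow(records)) {
    ic <- floor((records$x - x0) / cell_size) + 1L
    ir <- floor((records$y - y0) / cell_size) + 1L
    inside <- ic >= 1L & ic <= n_cols & ir >= 1L & ir <= n_rows
    overflow <- sum(!inside)
    if (any(inside)) {
      k <- key(ir[inside], ic[inside])
      counts <- table(k)
      ck <- key(cells$cell_row, cells$cell_col)
      cells$n_trees[match(as.integer(names(counts)), ck)] <- as.integer(counts)
      if (!is.null(records$agc_kg)) {
        agc <- records$agc_kg[inside]
        agc[is.na(agc)] <- 0
        sums <- tapply(agc, k, sum)
        cells$carbon_mgc_ha[match(as.integer(names(sums)), ck)] <-
          as.numeric(sums) / 1000 / cell_area_ha
      }
    }
  }
  cells$density_ha <- cells$n_trees / cell_area_ha

  cells$cover_pct <- 0
  if (!is.null(cover)) {
    idx <- which(cover$values > 0)
    if (length(idx)) {
      rr <- (idx - 1L) %% nrow(cover$values) + 1L
      cc <- (idx - 1L) %/% nrow(cover$values) + 1L
      w <- pixel_to_world(cover, rr, cc)
      ic <- floor((w$x - x0) / cell_size) + 1L
      ir <- floor((w$y - y0) / cell_size) + 1L
      inside <- ic >= 1L & ic <= n_cols & ir >= 1L & ir <= n_rows
      if (any(inside)) {
        k <- key(ir[inside], ic[inside])
        a <- tapply(cover$values[idx][inside], k, sum)  # fractional areas
        ck <- key(cells$cell_row, cells$cell_col)
        cells$cover_pct[match(as.integer(names(a)), ck)] <-
          as.numeric(a) * cover$pixel_size^2 / cell_size^2 * 100
      }
    }
  }
  cells <- cells[, c("cell_row", "cell_col", "x0", "y0", "n_trees",
                     "density_ha", "cover_pct", "carbon_mgc_ha")]
  structure(list(cells = cells, overflow = overflow, cell_size = cell_size,
                 grid_origin = c(x0, y0)),
            class = "hectare_grid")
}

#' @export
print.hectare_grid <- function(x, ...) {
  cat(sprintf("<hectare_grid> %d cell(s) of %g m, %d tree(s), overflow %d\n",
              nrow(x$cells), x$cell_size, sum(x$cells$n_trees), x$overflow))
  invisible(x)
}

#' Convert a hectare-grid band to a raster
#'
#' @param grid A `hectare_grid`.
#' @param band One of `"density_ha"`, `"cover_pct"`, `"carbon_mgc_ha"`,
#'   `"n_trees"`.
#' @return A `crown_raster` with one cell per grid cell.
#' @export
grid_band_raster <- function(grid, band = c("density_ha", "cover_pct",
                                            "carbon_mgc_ha", "n_trees")) {
  band <- match.arg(band)
  cells <- grid$cells
  nr <- max(cells$cell_row); nc <- max(cells$cell_col)
  m <- matrix(0, nr, nc)
  # cell_row counts up from the grid origin (south), raster row 1 is north
  m[cbind(nr - cells$cell_row + 1L, cells$cell_col)] <- cells[[band]]
  crown_raster(m, pixel_size = grid$cell_size, xmin = grid$grid_origin[1],
               ymax = grid$grid_origin[2] + nr * grid$cell_size)
}
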