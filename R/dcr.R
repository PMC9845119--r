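#' Euclidean distance transform of a crown mask
#'
#' Computes, for every foreground pixel, the exact Euclidean distance (in
#' pixel units) to the nearest background pixel. The image border is treated
#' as adjacent to background, so crowns truncated by a tile edge still get
#' finite distances; background pixels hold 0.
#'
#' @param mask A binary `crown_raster` (values in \{0, 1\}).
#' @return A numeric matrix of distances, same shape as the mask.
#' @seealso [detect_centres()], [dcr()]
#' @export
distance_transform <- function(mask) {
  stopifnot(inherits(mask, "crown_raster"))
  assert_binary_mask(mask)
  m <- mask$values
  storage.mode(m) <- "integer"
  edt_cpp(m)
}

#' Detect crown centres as local maxima of the distance transform
#'
#' A pixel is a centre candidate when its distance value is unchanged by an
#' `m` x `m` maximum filter, i.e. it is the farthest-from-background pixel
#' within its neighbourhood. Plateaus (8-connected groups of candidates with
#' equal eligibility) are merged and represented by their smallest row-major
#' pixel, so regions of constant distance yield a single centre.
#'
#' @param dt Distance matrix from [distance_transform()].
#' @param m Side of the maximum filter in pixels; odd, >= 1. The value bounds
#'   the smallest object that can be separated (default 3, which together
#'   with 0.25 m pixels resolves crowns down to the 0.25 m2 minimum).
#' @return A data frame with columns `row`, `col` (1-based pixel indices of
#'   each centre, ordered by row-major index) and attribute `m`.
#' @export
detect_centres <- function(dt, m = 3L) {
  if (length(m) != 1L || !is.finite(m) || m < 1 || m %% 2 == 0) {
    stop("`m` must be a single odd positive integer")
  }
  m <- as.integer(m)
  mf <- maxfilter_cpp(dt, m)
  cand <- (dt > 0) & (dt == mf)
  centres <- data.frame(row = integer(0), col = integer(0))
  if (any(cand)) {
    comp <- cc_label_cpp(matrix(as.integer(cand), nrow(dt), ncol(dt)), 8L)
    k <- max(comp)
    rows <- integer(k); cols <- integer(k)
    # component labels are assigned in row-major discovery order, so the
    # first pixel of each component is its smallest row-major candidate
    idx <- which(comp > 0)
    rr <- (idx - 1L) %% nrow(dt) + 1L
    cc <- (idx - 1L) %/% nrow(dt) + 1L
    lab <- comp[idx]
    rowmajor <- (rr - 1L) * ncol(dt) + cc
    for (j in seq_len(k)) {
      sel <- lab == j
      i <- which.min(rowmajor[sel])
      rows[j] <- rr[sel][i]; cols[j] <- cc[sel][i]
    }
    o <- order((rows - 1L) * ncol(dt) + cols)
    centres <- data.frame(row = rows[o], col = cols[o])
  }
  attr(centres, "m") <- m
  centres
}

#' Relabel a crown mask by penalised nearest-centre assignment
#'
#' Every foreground pixel x is assigned to the centre c minimising
#' `d(x, c) = ||x - c|| + penalty_weight * B(x, c)`, where `B` counts the
#' background pixels on the Bresenham line from c to x (endpoints excluded).
#' The additive background penalty keeps a crown from claiming pixels across
#' a gap: with the default weight (the grid diagonal) any assignment whose
#' line crosses background is strictly worse than any gap-free one. Ties are
#' broken towards the smallest centre index, so the output is deterministic.
#'
#' @param mask A binary `crown_raster`.
#' @param centres Centre table from [detect_centres()].
#' @param penalty_weight Non-negative penalty per background pixel crossed,
#'   or `"auto"` (default) for the grid diagonal in pixels.
#' @return A `label_scene`: list with `labels` (integer matrix, 0 background,
#'   1..K instances numbered by centre order), `centres`, `penalty_weight`,
#'   and the mask's georeferencing.
#' @export
relabel <- function(mask, centres, penalty_weight = "auto") {
  stopifnot(inherits(mask, "crown_raster"))
  assert_binary_mask(mask)
  lambda <- resolve_penalty(penalty_weight, dim(mask$values))
  mv <- mask$values; storage.mode(mv) <- "integer"
  if (nrow(centres) == 0L) {
    if (any(mv != 0L)) {
      stop("no centres but the mask has foreground: treat the scene as zero ",
           "crowns explicitly, or lower the max-filter size `m`")
    }
    labels <- matrix(0L, nrow(mv), ncol(mv))
  } else {
    cm <- as.matrix(centres[, c("row", "col")])
    storage.mode(cm) <- "integer"
    labels <- relabel_cpp(mv, cm, lambda)
  }
  structure(
    list(labels = labels, centres = centres, penalty_weight = lambda,
         pixel_size = mask$pixel_size, xmin = mask$xmin, ymax = mask$ymax,
         crs = mask$crs),
    class = "label_scene"
  )
}

resolve_penalty <- function(penalty_weight, dims) {
  if (identical(penalty_weight, "auto")) return(sqrt(sum(dims^2)))
  if (!is.numeric(penalty_weight) || length(penalty_weight) != 1L ||
      !is.finite(penalty_weight) || penalty_weight < 0) {
    stop("`penalty_weight` must be \"auto\" or a single number >= 0")
  }
  as.numeric(penalty_weight)
}

#' @export
print.label_scene <- function(x, ...) {
  cat(sprintf("<label_scene> %d x %d px, %d instance(s), penalty %g\n",
              nrow(x$labels), ncol(x$labels), nrow(x$centres),
              x$penalty_weight))
  invisible(x)
}

#' Fill gaps inside single crowns
#'
#' Background regions that are not 4-connected to the scene exterior and are
#' bordered (8-neighbourhood) by exactly one label are converted to that
#' label; holes bordered by two or more labels, and corridors reaching the
#' image edge, are left untouched. This repairs the artificial gaps a
#' boundary-weighted segmentation model leaves inside large crowns without
#' ever merging neighbouring crowns.
#'
#' @param scene A `label_scene`.
#' @return The scene with single-label holes filled.
#' @export
fill_holes <- function(scene) {
  stopifnot(inherits(scene, "label_scene"))
  lab <- scene$labels
  nr <- nrow(lab); nc <- ncol(lab)
  bg <- matrix(as.integer(lab == 0L), nr, nc)
  if (!any(bg == 1L)) return(scene)
  comp <- cc_label_cpp(bg, 4L)
  border <- unique(c(comp[1, ], comp[nr, ], comp[, 1], comp[, nc]))
  interior <- setdiff(seq_len(max(comp)), c(0L, border))
  if (!length(interior)) return(scene)
  # census of labels 8-adjacent to each interior background component
  shifts <- expand.grid(dr = -1:1, dc = -1:1)
  shifts <- shifts[!(shifts$dr == 0 & shifts$dc == 0), ]
  fill_with <- rep(NA_integer_, max(comp))
  multi <- rep(FALSE, max(comp))
  for (s in seq_len(nrow(shifts))) {
    dr <- shifts$dr[s]; dc <- shifts$dc[s]
    r_src <- seq_len(nr); c_src <- seq_len(nc)
    r_dst <- r_src + dr; c_dst <- c_src + dc
    ok_r <- r_dst >= 1 & r_dst <= nr; ok_c <- c_dst >= 1 & c_dst <= nc
    cm <- comp[r_src[ok_r], c_src[ok_c], drop = FALSE]
    lm <- lab[r_dst[ok_r], c_dst[ok_c], drop = FALSE]
    sel <- cm > 0 & lm > 0
    if (!any(sel)) next
    pairs <- unique(cbind(cm[sel], lm[sel]))
    for (i in seq_len(nrow(pairs))) {
      k <- pairs[i, 1]; l <- pairs[i, 2]
      if (is.na(fill_with[k])) fill_with[k] <- l
      else if (fill_with[k] != l) multi[k] <- TRUE
    }
  }
  for (k in interior) {
    if (!multi[k] && !is.na(fill_with[k])) lab[comp == k] <- fill_with[k]
  }
  scene$labels <- lab
  scene
}

#' Rebuild a label scene from a label raster
#'
#' Wraps an integer label raster (e.g. read back from disk) as a
#' `label_scene` so the geometry operations can consume it. Centres are not
#' recoverable from labels alone and are left empty.
#'
#' @param raster A `crown_raster` of instance labels (0 = background).
#' @return A `label_scene`.
#' @export
as_label_scene <- function(raster) {
  stopifnot(inherits(raster, "crown_raster"))
  v <- raster$values
  if (any(v < 0) || any(v != round(v))) {
    stop("label raster must hold non-negative integers")
  }
  storage.mode(v) <- "integer"
  structure(
    list(labels = v, centres = data.frame(row = integer(0), col = integer(0)),
         penalty_weight = NA_real_, pixel_size = raster$pixel_size,
         xmin = raster$xmin, ymax = raster$ymax, crs = raster$crs),
    class = "label_scene"
  )
}

#' Detect centre and relabel (DCR): separate clumped crowns
#'
#' Runs the full crown-separation chain on a binary prediction mask:
#' distance transform, centre detection by maximum-filter invariance,
#' penalised nearest-centre relabelling, and single-crown hole filling.
#' The output is deterministic for fixed inputs.
#'
#' @inheritParams distance_transform
#' @inheritParams detect_centres
#' @inheritParams relabel
#' @param fill Fill single-label holes after relabelling (default `TRUE`).
#' @return A `label_scene` with one instance per detected centre.
#' @examples
#' mask <- crown_raster(matrix(0L, 16, 16), pixel_size = 0.25)
#' mask$values[4:12, 4:12] <- 1L
#' scene <- dcr(mask)
#' table(scene$labels)
#' @export
dcr <- function(mask, m = 3L, penalty_weight = "auto", fill = TRUE) {
  mask <- as_binary_mask(mask)
  dt <- distance_transform(mask)
  centres <- detect_centres(dt, m)
  scene <- relabel(mask, centres, penalty_weight)
  if (fill) scene <- fill_holes(scene)
  scene
}
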