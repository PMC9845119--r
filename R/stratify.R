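#' Land-cover layer of polygons
#'
#' A stratification into the six land-cover classes used to route each tree
#' to its allometric chain. Features are polygons (outer rings, no holes)
#' with a `class` attribute and an optional `protected` flag; the feature
#' order in the source file is meaningful (boundary and overlap cases are
#' resolved by first feature wins).
#'
#' @param features List of features; each a list with `class` (one of
#'   [landcover_classes()]), `ring` (n x 2 matrix of x,y vertices, closed or
#'   open) and optionally `protected` (logical).
#' @param crs Opaque CRS tag.
#' @return An object of class `landcover_layer`.
#' @export
landcover_layer <- function(features, crs = NA_character_) {
  valid <- landcover_classes()
  for (i in seq_along(features)) {
    f <- features[[i]]
    if (is.null(f$class) || !(f$class %in% valid)) {
      stop("feature ", i, " has unknown land-cover class `", f$class,
           "`; valid classes: ", paste(valid, collapse = ", "))
    }
    if (is.null(f$ring) || !is.matrix(f$ring) || ncol(f$ring) != 2 ||
        nrow(f$ring) < 3) {
      stop("feature ", i, " needs an n x 2 vertex matrix with n >= 3")
    }
  }
  structure(list(features = features, crs = crs), class = "landcover_layer")
}

#' @export
print.landcover_layer <- function(x, ...) {
  cls <- vapply(x$features, `[[`, "", "class")
  cat(sprintf("<landcover_layer> %d feature(s): %s\n", length(cls),
              paste(sprintf("%s (%d)", names(table(cls)), table(cls)),
                    collapse = ", ")))
  invisible(x)
}

# Even-odd ray casting; points exactly on an edge count as inside, so
# boundary trees are captured by the first feature that owns the edge.
point_in_ring <- function(px, py, ring) {
  n <- nrow(ring)
  if (all(ring[1, ] == ring[n, ])) { ring <- ring[-n, , drop = FALSE]; n <- n - 1 }
  inside <- rep(FALSE, length(px))
  on_edge <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]
    xj <- ring[j, 1]; yj <- ring[j, 2]
    # collinear and within segment bounds -> on the boundary
    cross <- (xj - xi) * (py - yi) - (yj - yi) * (px - xi)
    on_seg <- cross == 0 &
      px >= pmin(xi, xj) & px <= pmax(xi, xj) &
      py >= pmin(yi, yj) & py <= pmax(yi, yj)
    on_edge <- on_edge | on_seg
    hits <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, hits)
    j <- i
  }
  inside | on_edge
}

#' Assign a land-cover class to each tree
#'
#' Each tree takes the class of the first feature (in file order) whose
#' polygon contains its centroid; trees outside every feature take
#' `default_class` and are flagged `outside_landcover`. Assignment depends
#' only on the centroid, so every tree gets exactly one class.
#'
#' @param records Tree table with world coordinates `x`, `y`.
#' @param layer A `landcover_layer`, or a categorical `crown_raster` plus
#'   `value_map` (named vector mapping cell values to class names).
#' @param default_class Class for trees outside all features; mandatory.
#' @param value_map Required when `layer` is a raster.
#' @return `records` with columns `landcover` and (updated) `flags`.
#' @export
assign_class <- function(records, layer, default_class, value_map = NULL) {
  if (missing(default_class) || !(default_class %in% landcover_classes())) {
    stop("`default_class` is mandatory and must be one of the six classes")
  }
  n <- nrow(records)
  cls <- rep(NA_character_, n)
  if (inherits(layer, "landcover_layer")) {
    unassigned <- seq_len(n)
    for (f in layer$features) {
      if (!length(unassigned)) break
      hit <- point_in_ring(records$x[unassigned], records$y[unassigned], f$ring)
      cls[unassigned[hit]] <- f$class
      unassigned <- unassigned[!hit]
    }
  } else if (inherits(layer, "crown_raster")) {
    if (is.null(value_map)) stop("raster layers need a `value_map`")
    if (!all(value_map %in% landcover_classes())) {
      stop("value_map contains unknown classes")
    }
    cc <- floor((records$x - layer$xmin) / layer$pixel_size) + 1L
    rr <- floor((layer$ymax - records$y) / layer$pixel_size) + 1L
    inside <- rr >= 1 & rr <= nrow(layer$values) & cc >= 1 & cc <= ncol(layer$values)
    v <- rep(NA_real_, n)
    v[inside] <- layer$values[cbind(rr[inside], cc[inside])]
    hit <- !is.na(v) & as.character(v) %in% names(value_map)
    cls[hit] <- unname(value_map[as.character(v[hit])])
  } else {
    stop("`layer` must be a landcover_layer or a categorical crown_raster")
  }
  out <- is.na(cls)
  cls[out] <- default_class
  records$landcover <- cls
  if (is.null(records$flags)) records$flags <- ""
  if (any(out)) {
    records$flags[out] <- ifelse(nzchar(records$flags[out]),
                                 paste0(records$flags[out], ";outside_landcover"),
                                 "outside_landcover")
  }
  records
}

#' Read a land-cover layer from GeoJSON
#'
#' Accepts a FeatureCollection of Polygon features with a `class` property
#' (and optional `protected`); only the outer ring of each polygon is used.
#'
#' @param path GeoJSON file path.
#' @return A `landcover_layer`.
#' @export
read_landcover_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  if (is.null(gj$type) || gj$type != "FeatureCollection") {
    stop("expected a GeoJSON FeatureCollection")
  }
  features <- lapply(gj$features, function(f) {
    if (f$geometry$type != "Polygon") {
      stop("only Polygon features are supported, got ", f$geometry$type)
    }
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]],
                                  function(p) c(p[[1]], p[[2]])))
    list(class = f$properties$class, ring = ring,
         protected = isTRUE(f$properties$protected))
  })
  landcover_layer(features)
}

#' Write a land-cover layer to GeoJSON
#'
#' @param layer A `landcover_layer`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_landcover_geojson <- function(layer, path) {
  feats <- lapply(layer$features, function(f) {
    ring <- f$ring
    if (!all(ring[1, ] == ring[nrow(ring), ])) ring <- rbind(ring, ring[1, ])
    list(
      type = "Feature",
      properties = list(class = f$class, protected = isTRUE(f$protected)),
      geometry = list(
        type = "Polygon",
        coordinates = list(lapply(seq_len(nrow(ring)),
                                  function(i) as.numeric(ring[i, ])))
      )
    )
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
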