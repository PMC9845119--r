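#' Configuration for a synthetic crown scene
#'
#' Describes a clumped-crown scene standing in for the binary output of a
#' crown segmentation model: circular (optionally elliptical) crowns with
#' lognormal radii, a controllable fraction of crowns placed touching or
#' overlapping an earlier crown, and a mandatory seed. The default radius
#' distribution, lognormal(meanlog = log(1), sdlog = 0.6) metres, puts most
#' crowns in the 0.25-15 m2 range that dominates real tree populations in
#' agricultural mosaics.
#'
#' @param grid_shape Integer `c(rows, cols)` in pixels.
#' @param pixel_size Pixel edge in metres (default 0.25).
#' @param n_crowns Number of crowns to place.
#' @param radius_meanlog,radius_sdlog Lognormal parameters of the crown
#'   radius in metres.
#' @param clump_fraction Fraction of crowns (after the first) placed
#'   touching/overlapping a previously placed crown, in \[0, 1\].
#' @param axis_ratio_range Range of ellipse axis ratios; `c(1, 1)` = circles.
#' @param seed Mandatory integer seed.
#' @return A `scene_config` list.
#' @export
scene_config <- function(grid_shape = c(64L, 64L), pixel_size = 0.25,
                         n_crowns = 8L, radius_meanlog = log(1),
                         radius_sdlog = 0.6, clump_fraction = 0.5,
                         axis_ratio_range = c(1, 1), seed) {
  if (missing(seed)) stop("`seed` is mandatory")
  stopifnot(length(grid_shape) == 2, all(grid_shape >= 1), pixel_size > 0,
            n_crowns >= 0, clump_fraction >= 0, clump_fraction <= 1,
            radius_sdlog >= 0, length(axis_ratio_range) == 2,
            all(axis_ratio_range >= 1))
  list(grid_shape = as.integer(grid_shape), pixel_size = pixel_size,
       n_crowns = as.integer(n_crowns), radius_meanlog = radius_meanlog,
       radius_sdlog = radius_sdlog, clump_fraction = clump_fraction,
       axis_ratio_range = axis_ratio_range, seed = as.integer(seed))
}

#' Generate a synthetic crown scene with ground-truth instances
#'
#' Places crowns sequentially: a crown is either "clumped" (centred at
#' roughly touching distance from a random earlier crown, producing the
#' merged blobs DCR must separate) or placed disjoint from all earlier
#' crowns by rejection sampling. Crowns are rasterized as filled ellipses on
#' pixel centres; in the ground truth, later-placed crowns own contested
#' pixels. When a crowded grid admits no position for the sampled radius
#' within `max_tries` attempts, the radius is shrunk by 10 percent and
#' placement retried, so the radius distribution is truncated by
#' feasibility; an error is raised only if even a one-pixel crown cannot be
#' placed. A pure function of its config: the same config (seed included)
#' returns a bit-identical scene.
#'
#' @param cfg A [scene_config()].
#' @param max_tries Placement retries per crown before giving up.
#' @return List: `mask` (binary `crown_raster`), `truth` (integer label
#'   matrix, ground-truth instances), `crowns` (data frame of placed crowns:
#'   `id`, `row`, `col`, `radius_px`, `clumped`), `cfg`.
#' @export
make_scene <- function(cfg, max_tries = 200L) {
  set.seed(cfg$seed)
  nr <- cfg$grid_shape[1]; nc <- cfg$grid_shape[2]
  truth <- matrix(0L, nr, nc)
  n <- cfg$n_crowns
  crowns <- data.frame(id = integer(0), row = numeric(0), col = numeric(0),
                       radius_px = numeric(0), clumped = logical(0))
  if (n > 0) {
    radii_px <- pmax(1, stats::rlnorm(n, cfg$radius_meanlog, cfg$radius_sdlog) /
                       cfg$pixel_size)
    radii_px <- pmin(radii_px, min(nr, nc) / 3)
    clumped <- c(FALSE, stats::runif(max(0, n - 1)) < cfg$clump_fraction)
    ratios <- stats::runif(n, cfg$axis_ratio_range[1], cfg$axis_ratio_range[2])
    angles <- stats::runif(n, 0, pi)
    for (i in seq_len(n)) {
      ri <- radii_px[i]
      placed <- FALSE
      while (!placed && ri >= 1) {
      for (t in seq_len(max_tries)) {
        if (clumped[i] && nrow(crowns) > 0) {
          j <- sample.int(nrow(crowns), 1)
          theta <- stats::runif(1, 0, 2 * pi)
          d <- (ri + crowns$radius_px[j]) * stats::runif(1, 0.6, 0.95)
          cr <- crowns$row[j] + d * sin(theta)
          cc <- crowns$col[j] + d * cos(theta)
          ok <- cr >= 1 && cr <= nr && cc >= 1 && cc <= nc
        } else {
          cr <- stats::runif(1, 1 + ri, nr - ri)
          cc <- stats::runif(1, 1 + ri, nc - ri)
          ok <- is.finite(cr) && is.finite(cc)
          if (ok && nrow(crowns) > 0) {
            dd <- sqrt((crowns$row - cr)^2 + (crowns$col - cc)^2)
            ok <- all(dd > crowns$radius_px + ri + 2)  # 8-disconnected gap
          }
        }
        if (ok) {
          crowns <- rbind(crowns, data.frame(id = i, row = cr, col = cc,
                                             radius_px = ri,
                                             clumped = clumped[i]))
          truth <- rasterize_ellipse(truth, cr, cc, ri, ri / ratios[i],
                                     angles[i], i)
          placed <- TRUE
          break
        }
      }
      # a crowded grid may not admit the sampled radius anywhere: shrink it
      # and retry, so the radius distribution is truncated by feasibility
      if (!placed) ri <- ri * 0.9
      }
      if (!placed) {
        stop(sprintf("could not place crown %d of %d after %d tries (%d placed)",
                     i, n, max_tries, nrow(crowns)))
      }
    }
  }
  mask <- crown_raster(matrix(as.integer(truth > 0), nr, nc),
                       pixel_size = cfg$pixel_size)
  list(mask = mask, truth = truth, crowns = crowns, cfg = cfg)
}

# fill pixels whose centre lies inside the ellipse (semi-axes a >= b,
# rotated by phi) centred at (cr, cc); label overwrites earlier crowns
rasterize_ellipse <- function(grid, cr, cc, a, b, phi, label) {
  nr <- nrow(grid); nc <- ncol(grid)
  r0 <- max(1L, floor(cr - a)); r1 <- min(nr, ceiling(cr + a))
  c0 <- max(1L, floor(cc - a)); c1 <- min(nc, ceiling(cc + a))
  if (r0 > r1 || c0 > c1) return(grid)
  rs <- r0:r1; cs <- c0:c1
  dr <- outer(rs - cr, rep(1, length(cs)))
  dc <- outer(rep(1, length(rs)), cs - cc)
  u <- dr * cos(phi) + dc * sin(phi)
  v <- -dr * sin(phi) + dc * cos(phi)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  sub <- grid[rs, cs, drop = FALSE]
  sub[inside] <- label
  grid[rs, cs] <- sub
  grid
}

#' Configuration for a synthetic CD-DBH-AGB calibration table
#'
#' @param n_trees Number of trees.
#' @param cd_meanlog,cd_sdlog Lognormal parameters of crown diameter (m).
#' @param cd_min Lower truncation of CD in metres (default 1, keeping the
#'   linear CD-DBH line comfortably above its zero crossing).
#' @param model Generating CD-to-DBH model: `"linear"` (DBH =
#'   -4.665 + 5.102 CD) or `"log"` (log-scale intercept 1.154, slope 1.248,
#'   CD scaled by 1.27).
#' @param noise `"none"`, `"gaussian_dbh"` (additive on DBH),
#'   `"gaussian_both"` (additive on CD and DBH, equal sd -- the
#'   errors-in-both-variables setting major axis regression assumes), or
#'   `"lognormal_dbh"` (median-preserving multiplicative on DBH).
#' @param noise_sd Noise scale: cm for the Gaussian options, sdlog for the
#'   lognormal option.
#' @param agb Generating AGB equation: `"savanna_power"`,
#'   `"plantation_power"` or `"chave"`.
#' @param E,rho Parameters of the chave form.
#' @param agb_noise_sdlog Optional median-preserving lognormal noise on AGB.
#' @param seed Mandatory integer seed.
#' @return A `table_config` list.
#' @export
table_config <- function(n_trees = 1000L, cd_meanlog = log(2), cd_sdlog = 0.35,
                         cd_min = 1, model = c("linear", "log"),
                         noise = c("none", "gaussian_dbh", "gaussian_both",
                                   "lognormal_dbh"),
                         noise_sd = 0, agb = c("savanna_power",
                                               "plantation_power", "chave"),
                         E = 0.5, rho = 0.54, agb_noise_sdlog = 0, seed) {
  if (missing(seed)) stop("`seed` is mandatory")
  stopifnot(n_trees >= 1, noise_sd >= 0, agb_noise_sdlog >= 0, cd_min > 0)
  list(n_trees = as.integer(n_trees), cd_meanlog = cd_meanlog,
       cd_sdlog = cd_sdlog, cd_min = cd_min, model = match.arg(model),
       noise = match.arg(noise), noise_sd = noise_sd, agb = match.arg(agb),
       E = E, rho = rho, agb_noise_sdlog = agb_noise_sdlog,
       seed = as.integer(seed))
}

#' Generate a synthetic field-tree table
#'
#' Samples crown diameters, derives noiseless DBH and AGB from the configured
#' generating equations, then applies the configured noise. The noiseless
#' truth columns (`cd_true`, `dbh_true`, `agb_true`) are retained so
#' parameter-recovery tests can compare against the generating values.
#'
#' @param cfg A [table_config()].
#' @return Data frame: `tree_id`, `cd_true`, `cd_m`, `dbh_true`, `dbh_cm`,
#'   `agb_true`, `agb_kg`.
#' @export
make_allometry_table <- function(cfg) {
  set.seed(cfg$seed)
  n <- cfg$n_trees
  cd <- pmax(cfg$cd_min, stats::rlnorm(n, cfg$cd_meanlog, cfg$cd_sdlog))
  gen_dbh <- function(cdv) {
    if (cfg$model == "linear") -4.665 + 5.102 * cdv
    else exp(1.154 + 1.248 * log(cdv * 1.27))
  }
  dbh_true <- gen_dbh(cd)
  cd_obs <- cd
  dbh_obs <- dbh_true
  if (cfg$noise == "gaussian_dbh") {
    dbh_obs <- dbh_true + stats::rnorm(n, 0, cfg$noise_sd)
  } else if (cfg$noise == "gaussian_both") {
    cd_obs <- cd + stats::rnorm(n, 0, cfg$noise_sd)
    dbh_obs <- dbh_true + stats::rnorm(n, 0, cfg$noise_sd)
  } else if (cfg$noise == "lognormal_dbh") {
    dbh_obs <- dbh_true * exp(stats::rnorm(n, 0, cfg$noise_sd))
  }
  eq <- switch(cfg$agb,
               savanna_power = agb_equation("power", a = 0.091, b = 2.472),
               plantation_power = agb_equation("power", a = 0.202, b = 2.447),
               chave = agb_equation("chave", E = cfg$E, rho = cfg$rho))
  agb_true <- agb_from_dbh(pmax(dbh_true, 1e-12), eq)
  attributes(agb_true) <- NULL
  agb_obs <- agb_true
  if (cfg$agb_noise_sdlog > 0) {
    agb_obs <- agb_true * exp(stats::rnorm(n, 0, cfg$agb_noise_sdlog))
  }
  data.frame(tree_id = seq_len(n), cd_true = cd, cd_m = cd_obs,
             dbh_true = dbh_true, dbh_cm = dbh_obs,
             agb_true = agb_true, agb_kg = agb_obs)
}

#' Generate a synthetic land-cover layer of labelled rectangles
#'
#' Random axis-aligned rectangles within the extent, labelled by cycling
#' through the requested classes; overlaps are legitimate and resolved by
#' the first-feature-wins rule of [assign_class()]. Deterministic per seed.
#'
#' @param extent Numeric `c(xmin, xmax, ymin, ymax)` in world coordinates.
#' @param n_polygons Number of rectangles.
#' @param classes Classes to cycle through (subset of [landcover_classes()]).
#' @param seed Mandatory integer seed.
#' @param min_frac,max_frac Rectangle edge as a fraction of the extent edge.
#' @return A `landcover_layer`.
#' @export
make_landcover <- function(extent, n_polygons, classes = landcover_classes(),
                           seed, min_frac = 0.2, max_frac = 0.6) {
  if (missing(seed)) stop("`seed` is mandatory")
  set.seed(as.integer(seed))
  w <- extent[2] - extent[1]; h <- extent[4] - extent[3]
  features <- lapply(seq_len(n_polygons), function(i) {
    rw <- stats::runif(1, min_frac, max_frac) * w
    rh <- stats::runif(1, min_frac, max_frac) * h
    x0 <- stats::runif(1, extent[1], extent[2] - rw)
    y0 <- stats::runif(1, extent[3], extent[4] - rh)
    list(class = classes[(i - 1) %% length(classes) + 1],
         ring = cbind(c(x0, x0 + rw, x0 + rw, x0, x0),
                      c(y0, y0, y0 + rh, y0 + rh, y0)))
  })
  landcover_layer(features)
}
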