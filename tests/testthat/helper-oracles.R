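# Brute-force reference implementations of the crown-separation stages,
# written independently of the package's compiled path. All are O(n^2)-ish
# and meant for grids up to ~64 x 64.

# Euclidean distance to the nearest background pixel, all-pairs minimum,
# with the image border treated as background (one-pixel zero ring).
oracle_edt <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(0L, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- mask
  bg <- which(pad == 0L)
  bgr <- (bg - 1) %% (nr + 2) + 1
  bgc <- (bg - 1) %/% (nr + 2) + 1
  out <- matrix(0, nr, nc)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      if (mask[r, c] != 0) {
        out[r, c] <- sqrt(min((bgr - (r + 1))^2 + (bgc - (c + 1))^2))
      }
    }
  }
  out
}

oracle_maxfilter <- function(x, m) {
  h <- (m - 1) / 2
  nr <- nrow(x); nc <- ncol(x)
  out <- x
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      out[r, c] <- max(x[max(1, r - h):min(nr, r + h),
                         max(1, c - h):min(nc, c + h)])
    }
  }
  out
}

# candidates where dt equals its windowed max; 8-connected candidate groups
# merged to the smallest row-major member, centres ordered row-major
oracle_detect_centres <- function(dt, m) {
  cand <- dt > 0 & dt == oracle_maxfilter(dt, m)
  nr <- nrow(cand); nc <- ncol(cand)
  seen <- matrix(FALSE, nr, nc)
  centres <- NULL
  for (rm in seq_len(nr * nc)) {         # row-major scan
    r <- (rm - 1) %/% nc + 1
    c <- (rm - 1) %% nc + 1
    if (!cand[r, c] || seen[r, c]) next
    stack <- list(c(r, c))               # flood fill this plateau group
    seen[r, c] <- TRUE
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (dr in -1:1) for (dc in -1:1) {
        rr <- p[1] + dr; cc <- p[2] + dc
        if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc &&
            cand[rr, cc] && !seen[rr, cc]) {
          seen[rr, cc] <- TRUE
          stack[[length(stack) + 1]] <- c(rr, cc)
        }
      }
    }
    centres <- rbind(centres, c(r, c))   # first row-major member represents
  }
  if (is.null(centres)) {
    data.frame(row = integer(0), col = integer(0))
  } else {
    data.frame(row = centres[, 1], col = centres[, 2])
  }
}

# Bresenham line from (r0,c0) to (r1,c1); returns matrix of all points incl.
# endpoints, in walk order
oracle_bresenham <- function(r0, c0, r1, c1) {
  dr <- abs(r1 - r0); dc <- abs(c1 - c0)
  sr <- if (r0 < r1) 1 else -1
  sc <- if (c0 < c1) 1 else -1
  err <- dc - dr
  pts <- matrix(c(r0, c0), ncol = 2)
  r <- r0; c <- c0
  while (!(r == r1 && c == c1)) {
    e2 <- 2 * err
    if (e2 > -dr) { err <- err - dr; c <- c + sc }
    if (e2 < dc)  { err <- err + dc; r <- r + sr }
    pts <- rbind(pts, c(r, c))
  }
  pts
}

oracle_bg_on_line <- function(mask, r0, c0, r1, c1) {
  pts <- oracle_bresenham(r0, c0, r1, c1)
  n <- nrow(pts)
  if (n <= 2) return(0L)
  mid <- pts[2:(n - 1), , drop = FALSE]
  sum(mask[cbind(mid[, 1], mid[, 2])] == 0)
}

# exhaustive penalised nearest-centre assignment, ties to smallest index
oracle_relabel <- function(mask, centres, lambda) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      if (mask[r, c] == 0) next
      best <- 0L; bestd <- Inf
      for (j in seq_len(nrow(centres))) {
        d <- sqrt((r - centres$row[j])^2 + (c - centres$col[j])^2)
        if (lambda > 0) {
          d <- d + lambda * oracle_bg_on_line(mask, centres$row[j],
                                              centres$col[j], r, c)
        }
        if (d < bestd) { bestd <- d; best <- j }
      }
      lab[r, c] <- best
    }
  }
  lab
}

# flood-fill background from the border (4-connectivity); remaining
# background components bordered (8-neighbourhood) by one label are filled
oracle_fill_holes <- function(lab) {
  nr <- nrow(lab); nc <- ncol(lab)
  comp <- matrix(0L, nr, nc)
  nextc <- 0L
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (lab[r, c] != 0 || comp[r, c] != 0) next
    nextc <- nextc + 1L
    stack <- list(c(r, c)); comp[r, c] <- nextc
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (s in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        rr <- p[1] + s[1]; cc <- p[2] + s[2]
        if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc &&
            lab[rr, cc] == 0 && comp[rr, cc] == 0) {
          comp[rr, cc] <- nextc
          stack[[length(stack) + 1]] <- c(rr, cc)
        }
      }
    }
  }
  exterior <- unique(c(comp[1, ], comp[nr, ], comp[, 1], comp[, nc]))
  for (k in setdiff(seq_len(nextc), c(0L, exterior))) {
    px <- which(comp == k)
    nb <- integer(0)
    for (p in px) {
      r <- (p - 1) %% nr + 1; c <- (p - 1) %/% nr + 1
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc <- c + dc
        if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc && lab[rr, cc] > 0) {
          nb <- c(nb, lab[rr, cc])
        }
      }
    }
    nb <- unique(nb)
    if (length(nb) == 1) lab[px] <- nb
  }
  lab
}

oracle_dcr <- function(mask, m = 3L, lambda = NULL) {
  if (is.null(lambda)) lambda <- sqrt(nrow(mask)^2 + ncol(mask)^2)
  dt <- oracle_edt(mask)
  centres <- oracle_detect_centres(dt, m)
  if (nrow(centres) == 0) return(matrix(0L, nrow(mask), ncol(mask)))
  oracle_fill_holes(oracle_relabel(mask, centres, lambda))
}

# random binary mask with smoothed blobs (threshold of a blurred noise field)
random_mask <- function(seed, nr = 24, nc = 24, density = 0.45) {
  set.seed(seed)
  x <- matrix(stats::rnorm(nr * nc), nr, nc)
  k <- 3
  sm <- x
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    sm[r, c] <- mean(x[max(1, r - 1):min(nr, r + 1),
                       max(1, c - 1):min(nc, c + 1)])
  }
  matrix(as.integer(sm > stats::quantile(sm, 1 - density)), nr, nc)
}

disk_mask <- function(n, radius, centre = c((n + 1) / 2, (n + 1) / 2)) {
  m <- matrix(0L, n, n)
  for (r in seq_len(n)) for (c in seq_len(n)) {
    if ((r - centre[1])^2 + (c - centre[2])^2 <= radius^2) m[r, c] <- 1L
  }
  m
}
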