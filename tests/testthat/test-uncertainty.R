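test_that("relative and summed bias match hand evaluation exactly", {
  expect_equal(bias_relative(c(3, 4, 5), c(3, 4, 5)), 0)
  expect_equal(bias_relative(10, 8), 20)
  expect_equal(bias_relative(c(10, 20), c(8, 22)), 5, tolerance = 1e-12)

  expect_equal(bias_summed(c(2, 3), c(2, 3)), 0)
  expect_equal(bias_summed(c(10, 20), c(8, 18)), 4 / 30, tolerance = 1e-12)
  # sign-symmetric: overprediction of the same magnitude gives the same value
  expect_equal(bias_summed(c(10, 20), c(12, 22)), 4 / 30, tolerance = 1e-12)
  # permutation invariance
  expect_equal(bias_summed(c(20, 10), c(18, 8)), bias_summed(c(10, 20), c(8, 18)))

  expect_error(bias_relative(c(0, 1), c(1, 1)), "undefined")
  expect_error(bias_summed(c(1, -1), c(1, 1)), "undefined")
})

test_that("bias_relative is zero iff predictions match on positive residual cases", {
  set.seed(4)
  obs <- runif(20, 1, 10)
  pred <- obs - abs(rnorm(20, 0.5, 0.2))  # one-sided residuals: no cancellation
  expect_gt(bias_relative(obs, pred), 0)
  expect_equal(bias_relative(obs, obs), 0)
})

test_that("area-weighted national uncertainty is a convex combination", {
  b <- c(farmland = 10, natural_forest = 50)
  w <- c(farmland = 0.9, natural_forest = 0.1)
  expect_equal(national_uncertainty(b, w), 14)
  # equal biases collapse to the common value; zero weights contribute nothing
  expect_equal(national_uncertainty(setNames(c(7, 7), c("farmland", "urban_builtup")),
                                    setNames(c(0.4, 0.6), c("farmland", "urban_builtup"))), 7)
  expect_equal(national_uncertainty(setNames(c(10, 99), c("farmland", "urban_builtup")),
                                    setNames(c(1, 0), c("farmland", "urban_builtup"))), 10)
  # signs never cancel
  expect_equal(national_uncertainty(setNames(c(-10, 10), c("farmland", "urban_builtup")),
                                    setNames(c(0.5, 0.5), c("farmland", "urban_builtup"))), 10)
  # bounded by the extreme class biases
  set.seed(9)
  for (i in 1:20) {
    b <- setNames(rnorm(3, 0, 30), c("farmland", "urban_builtup", "natural_forest"))
    w <- c(stats::runif(3)); w <- setNames(w / sum(w), names(b))
    u <- national_uncertainty(b, w)
    expect_gte(u, min(abs(b)) - 1e-12)
    expect_lte(u, max(abs(b)) + 1e-12)
  }
  expect_error(national_uncertainty(c(farmland = 1), c(urban_builtup = 1)),
               "mismatch")
  expect_error(national_uncertainty(setNames(c(1, 1), c("farmland", "urban_builtup")),
                                    setNames(c(0.7, 0.7), c("farmland", "urban_builtup"))),
               "sum to 1")
})

make_ens_inputs <- function(noise_sd, n_cal = 400, n_trees = 300, seed = 50) {
  set.seed(seed)
  cd_cal <- pmax(1, rlnorm(n_cal, log(2.5), 0.5))
  dbh <- -4.665 + 5.102 * cd_cal
  if (noise_sd > 0) dbh <- dbh * exp(rnorm(n_cal, 0, noise_sd))
  trees <- data.frame(
    cd_m = pmax(1, rlnorm(n_trees, log(2.5), 0.5)),
    x = runif(n_trees, 0, 400), y = runif(n_trees, 0, 400),
    landcover = sample(c("farmland", "savanna_shrubland"), n_trees, TRUE))
  list(cal = data.frame(cd_m = cd_cal, dbh_cm = dbh), trees = trees)
}

test_that("ensemble uncertainty is zero for a noiseless table and deterministic", {
  inp <- make_ens_inputs(0)
  r <- ensemble_uncertainty(inp$cal, inp$trees, seeds = 1:4)
  expect_true(all(abs(r$per_class) < 1e-10))
  r2 <- ensemble_uncertainty(inp$cal, inp$trees, seeds = 1:4)
  expect_identical(r$per_class, r2$per_class)
  expect_equal(r$runs_used, 4L)
})

test_that("ensemble rRMSE matches a literal re-implementation of the loop", {
  inp <- make_ens_inputs(0.3)
  r <- ensemble_uncertainty(inp$cal, inp$trees, seeds = 1:4)

  # independent spreadsheet-style re-implementation
  n <- nrow(inp$cal)
  preds <- sapply(1:4, function(s) {
    set.seed(s)
    idx <- sample.int(n, floor(n / 2))
    x <- inp$cal$cd_m[idx]; y <- inp$cal$dbh_cm[idx]
    sxx <- sum((x - mean(x))^2); syy <- sum((y - mean(y))^2)
    sxy <- sum((x - mean(x)) * (y - mean(y)))
    b <- (syy - sxx + sqrt((syy - sxx)^2 + 4 * sxy^2)) / (2 * sxy)
    a <- mean(y) - b * mean(x)
    dbh <- a + b * inp$trees$cd_m
    agb <- ifelse(dbh <= 0, 0,
                  ifelse(inp$trees$landcover == "savanna_shrubland",
                         0.091 * dbh^2.472, 0.202 * dbh^2.447))
    0.47 * agb
  })
  cell <- paste(inp$trees$landcover,
                floor(inp$trees$y / 100), floor(inp$trees$x / 100), sep = "|")
  agg <- apply(preds, 2, function(p) tapply(p, cell, sum))
  rr <- apply(agg, 1, sd) / rowMeans(agg) * 100
  want <- tapply(rr, sub("\\|.*$", "", rownames(agg)), mean)
  expect_equal(r$per_class[names(want)], want, tolerance = 1e-12)
})

test_that("ensemble rRMSE is non-decreasing along a noise grid", {
  vals <- vapply(c(0, 0.1, 0.2, 0.3), function(ns) {
    inp <- make_ens_inputs(ns)
    mean(ensemble_uncertainty(inp$cal, inp$trees, seeds = 1:4)$per_class)
  }, 0)
  expect_true(all(diff(vals) >= -1e-9))
  expect_lt(vals[1], 1e-10)
})

test_that("plot-level evaluation sums tree carbon inside plots", {
  ring <- function(x0, x1, y0, y1) cbind(c(x0, x1, x1, x0, x0),
                                         c(y0, y0, y1, y1, y0))
  trees <- data.frame(x = c(5, 6, 50), y = c(5, 6, 50),
                      agc_kg = c(40000, 41000, 1000))
  plots <- list(list(plot_id = "p1", ring = ring(0, 10, 0, 10)),
                list(plot_id = "p2", ring = ring(40, 60, 40, 60)),
                list(plot_id = "p3", ring = ring(80, 90, 80, 90)))
  # perfect predictions give zero error
  r0 <- plot_level_eval(trees, plots[1:2], c(p1 = 81, p2 = 1), unit = "Mg")
  expect_equal(r0$rrmse_pct, 0)
  expect_equal(r0$bias_relative_pct, 0)
  expect_equal(r0$bias_summed, 0)

  # a single plot with observed 121 and predicted 81 (plot sums in MgC):
  # summed-total bias 40/121
  r1 <- plot_level_eval(trees, plots[1], c(p1 = 121), unit = "Mg")
  expect_equal(r1$pairs$y_pred, 81)
  expect_equal(r1$bias_summed, 40 / 121, tolerance = 1e-12)
  expect_equal(r1$bias_summed, 0.331, tolerance = 2e-3)

  # plots without trees are retained at prediction 0
  r2 <- plot_level_eval(trees, plots, c(p1 = 81, p2 = 1, p3 = 2))
  expect_equal(r2$pairs$n_trees, c(2L, 1L, 0L))
  expect_equal(r2$pairs$y_pred[3], 0)
})

test_that("plot statistics match a spreadsheet-style oracle on synthetic plots", {
  set.seed(15)
  ring <- function(x0, x1, y0, y1) cbind(c(x0, x1, x1, x0, x0),
                                         c(y0, y0, y1, y1, y0))
  trees <- data.frame(x = runif(300, 0, 300), y = runif(300, 0, 300),
                      agc_kg = rlnorm(300, 4, 1))
  plots <- lapply(1:15, function(i) {
    x0 <- runif(1, 0, 270); y0 <- runif(1, 0, 270)
    list(plot_id = paste0("p", i), ring = ring(x0, x0 + 30, y0, y0 + 30))
  })
  truth <- vapply(plots, function(p) {
    sum(trees$agc_kg[trees$x >= min(p$ring[, 1]) & trees$x <= max(p$ring[, 1]) &
                       trees$y >= min(p$ring[, 2]) & trees$y <= max(p$ring[, 2])])
  }, 0) / 1000
  obs <- truth * exp(rnorm(15, 0, 0.2))
  names(obs) <- paste0("p", 1:15)
  r <- plot_level_eval(trees, plots, obs)
  expect_equal(r$pairs$y_pred, truth, tolerance = 1e-12)
  expect_equal(r$rrmse_pct, sqrt(mean((obs - truth)^2)) / mean(obs) * 100,
               tolerance = 1e-12)
  expect_equal(r$bias_relative_pct, mean((obs - truth) / obs) * 100,
               tolerance = 1e-12)
  expect_equal(r$bias_summed, abs(sum(obs - truth)) / sum(obs),
               tolerance = 1e-12)
})
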