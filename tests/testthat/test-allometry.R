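test_that("major axis regression recovers exact lines and is symmetric", {
  x <- c(1, 2, 3, 5, 8)
  fit <- fit_major_axis(x, 2 * x + 1)
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_equal(fit$intercept, 1, tolerance = 1e-12)
  expect_equal(fit$correction, 1)

  # swapping axes inverts the slope (symmetry of the major axis)
  set.seed(5)
  x <- rnorm(200, 10, 3)
  y <- 1.7 * x - 2 + rnorm(200, 0, 1)
  a <- fit_major_axis(x, y)
  b <- fit_major_axis(y, x)
  expect_equal(b$slope, 1 / a$slope, tolerance = 1e-10)

  # scale equivariance on collinear data: slope(kx, y) = slope(x, y) / k
  # (for noisy data the major axis is not equivariant under one-axis
  # rescaling; only the errors-in-both-variables geometry is preserved)
  k <- 3.7
  xe <- c(1, 2, 3, 5, 8); ye <- 2 * xe + 1
  expect_equal(fit_major_axis(k * xe, ye)$slope, 2 / k, tolerance = 1e-10)

  expect_error(fit_major_axis(1:5, rep(2, 5)), "degenerate")
  expect_error(fit_major_axis(1:2, 1:2), "at least 3")
})

test_that("major axis regression recovers generating coefficients under symmetric noise", {
  set.seed(101)
  n <- 10000
  cd <- pmax(1, rlnorm(n, log(2), 0.35))
  dbh <- -4.665 + 5.102 * cd
  x <- cd + rnorm(n, 0, 0.5)
  y <- dbh + rnorm(n, 0, 0.5)
  fit <- fit_major_axis(x, y)
  expect_equal(fit$slope, 5.102, tolerance = 0.02)
  expect_lt(abs(fit$intercept - (-4.665)), 0.2)
})

test_that("log MA fit with Baskerville correction recovers the generating model", {
  # noiseless power law: exact recovery, correction 1
  cd <- seq(0.5, 10, length.out = 50)
  dbh <- exp(1.154) * (cd * 1.27)^1.248
  fit <- fit_log_ma_baskerville(cd, dbh)
  expect_equal(fit$intercept, 1.154, tolerance = 1e-9)
  expect_equal(fit$slope, 1.248, tolerance = 1e-9)
  expect_equal(fit$correction, 1, tolerance = 1e-9)

  # lognormal noise: sigma recovered within 5%, correction >= 1 always
  set.seed(7)
  n <- 10000
  cd <- rlnorm(n, log(4), 1)  # forest crowns spanning ~0.5-30 m
  dbh <- exp(1.154) * (cd * 1.27)^1.248 * exp(rnorm(n, 0, 0.3315))
  fit <- fit_log_ma_baskerville(cd, dbh)
  expect_equal(fit$sigma, 0.3315, tolerance = 0.05)
  expect_gte(fit$correction, 1)

  expect_error(fit_log_ma_baskerville(c(1, -1, 2), c(1, 2, 3)), "2")
})

test_that("half-sample averaged fit is deterministic and near the full fit", {
  set.seed(31)
  n <- 2000
  cd <- pmax(1, rlnorm(n, log(2), 0.35))
  dbh <- -4.665 + 5.102 * cd + rnorm(n, 0, 0.5)
  cd <- cd + rnorm(n, 0, 0.5)
  a <- fit_half_sample_average(cd, dbh, "linear_ma", seeds = 1:4)
  b <- fit_half_sample_average(cd, dbh, "linear_ma", seeds = 1:4)
  expect_identical(a$slope, b$slope)
  expect_equal(a$seeds, 1:4)
  full <- fit_major_axis(cd, dbh)
  expect_equal(a$slope, full$slope, tolerance = 0.05)
})

test_that("DBH predictions evaluate the printed equations", {
  linear <- allometric_model("linear_ma", intercept = -4.665, slope = 5.102)
  expect_equal(dbh_from_cd(5, linear), -4.665 + 5.102 * 5)   # 20.845 cm
  expect_equal(dbh_from_cd(5, linear), 20.845)
  expect_equal(dbh_from_cd(4.665 / 5.102, linear), 0)        # domain root

  logm <- allometric_model("log_ma_baskerville", intercept = 1.154,
                           slope = 1.248, sigma = 0.3315)
  want <- exp(1.154 + 1.248 * log(1.27)) * exp(0.3315^2 / 2)
  expect_equal(dbh_from_cd(1, logm), want, tolerance = 1e-12)
  expect_equal(want, 4.51, tolerance = 0.01)

  # log form is positive and strictly increasing over a wide CD range
  cd <- exp(seq(log(0.01), log(100), length.out = 500))
  p <- dbh_from_cd(cd, logm)
  expect_true(all(p > 0))
  expect_true(all(diff(p) > 0))
  expect_error(dbh_from_cd(-1, logm), "positive")
})

test_that("AGB equations match an independent high-precision re-evaluation", {
  eq4 <- agb_equation("power", a = 0.091, b = 2.472)
  eq5 <- agb_equation("power", a = 0.202, b = 2.447)
  expect_equal(agb_from_dbh(1, eq4), 0.091)
  expect_equal(agb_from_dbh(1, eq5), 0.202)

  chave <- agb_equation("chave", E = 0, rho = 1)
  expect_equal(agb_from_dbh(1, chave), exp(1.803), tolerance = 1e-12)
  expect_equal(exp(1.803), 6.068, tolerance = 1e-3)

  # independent re-evaluation on random inputs, both families
  set.seed(77)
  dbh <- exp(runif(10000, log(0.5), log(300)))
  E <- runif(1, 0, 1); rho <- runif(1, 0.3, 0.9)
  eqc <- agb_equation("chave", E = E, rho = rho)
  ref_power <- vapply(dbh, function(d) 0.091 * exp(2.472 * log(d)), 0)
  ref_chave <- vapply(dbh, function(d) {
    exp(1.803 - 0.976 * E + 0.976 * log(rho) + 2.673 * log(d) -
          0.0299 * log(d)^2)
  }, 0)
  expect_equal(agb_from_dbh(dbh, eq4), ref_power, tolerance = 1e-9)
  expect_equal(agb_from_dbh(dbh, eqc), ref_chave, tolerance = 1e-9)

  # AGB strictly increasing in DBH over (0, 1000] cm for both families
  grid <- exp(seq(log(1e-3), log(1000), length.out = 2000))
  expect_true(all(diff(agb_from_dbh(grid, eq4)) > 0))
  expect_true(all(diff(agb_from_dbh(grid, eq5)) > 0))
  expect_true(all(diff(agb_from_dbh(grid, eqc)) > 0))

  # non-positive DBH yields zero biomass, flagged
  v <- agb_from_dbh(c(-1, 0, 10), eq4)
  expect_equal(v[1:2], c(0, 0), ignore_attr = TRUE)
  expect_equal(attr(v, "flagged"), c(TRUE, TRUE, FALSE))

  expect_error(agb_equation("chave", rho = 0.54), "E")
})

test_that("carbon fraction and chained conversion behave", {
  expect_equal(agc_from_agb(0), 0)
  expect_equal(agc_from_agb(100), 47)
  expect_equal(agc_from_agb(1000), 470)
  expect_error(agc_from_agb(-5), ">= 0")
})

test_that("class dispatch routes each land cover to its equation chain", {
  tab <- default_allometry_table(E = 0.4)
  rec <- data.frame(
    cd_m = c(5, 5, 5, 0.6),
    landcover = c("natural_forest", "savanna_shrubland", "farmland",
                  "savanna_shrubland"))
  out <- apply_allometry(rec, tab)

  # savanna: linear CD-DBH then the non-forest power law
  dbh_sav <- -4.665 + 5.102 * 5
  expect_equal(out$dbh_cm[2], dbh_sav)
  expect_equal(out$agb_kg[2], 0.091 * dbh_sav^2.472, tolerance = 1e-12)
  # farmland: same DBH, plantation power law
  expect_equal(out$agb_kg[3], 0.202 * dbh_sav^2.447, tolerance = 1e-12)
  # natural forest: log model with Baskerville, then pantropical form
  dbh_nf <- exp(1.154 + 1.248 * log(5 * 1.27)) * exp(0.3315^2 / 2)
  expect_equal(out$dbh_cm[1], dbh_nf, tolerance = 1e-12)
  expect_equal(out$agb_kg[1],
               exp(1.803 - 0.976 * 0.4 + 0.976 * log(0.54) +
                     2.673 * log(dbh_nf) - 0.0299 * log(dbh_nf)^2),
               tolerance = 1e-12)
  expect_equal(out$agc_kg, 0.47 * out$agb_kg)

  # tiny crown below the linear domain: zero biomass and a flag
  expect_lt(out$dbh_cm[4], 0)
  expect_equal(out$agb_kg[4], 0)
  expect_match(out$flags[4], "below_allometry_domain")
  expect_false(any(grepl("below_allometry_domain", out$flags[1:3])))

  # natural forest without E is refused loudly
  expect_error(apply_allometry(rec, default_allometry_table()), "E")
})

test_that("model files round-trip bit-exactly", {
  set.seed(12)
  x <- rlnorm(100, 1, 0.4); y <- exp(0.9) * (x * 1.27)^1.3 * exp(rnorm(100, 0, 0.2))
  fit <- fit_log_ma_baskerville(x, y)
  p <- withr::local_tempfile(fileext = ".txt")
  write_allometric_model(fit, p)
  back <- read_allometric_model(p)
  expect_identical(back$intercept, fit$intercept)
  expect_identical(back$slope, fit$slope)
  expect_identical(back$sigma, fit$sigma)
  expect_identical(back$correction, fit$correction)
  expect_identical(back$form, fit$form)

  m <- fit_half_sample_average(x, y, "log_ma_baskerville", seeds = c(9L, 8L, 7L, 6L))
  write_allometric_model(m, p)
  expect_identical(read_allometric_model(p)$seeds, c(9L, 8L, 7L, 6L))
})
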