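#' Major axis regression
#'
#' Fits the major axis (errors-in-both-variables, equal error variance) line
#' through (x, y): the first principal axis of the sample covariance,
#'   slope = (Syy - Sxx + sqrt((Syy - Sxx)^2 + 4 Sxy^2)) / (2 Sxy),
#'   intercept = mean(y) - slope * mean(x).
#' Unlike ordinary least squares, the fit is symmetric in x and y (swapping
#' the axes inverts the slope), which is appropriate when both variables --
#' here crown diameter and stem diameter -- carry measurement error.
#'
#' @param x,y Numeric vectors of equal length, n >= 3.
#' @return An `allometric_model` with `form = "linear_ma"`, `intercept`,
#'   `slope`, `sigma` (sd of vertical residuals on the fitted scale) and
#'   `correction = 1`.
#' @export
fit_major_axis <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 points")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("non-finite values in input")
  sxx <- stats::var(x) * (length(x) - 1)
  syy <- stats::var(y) * (length(y) - 1)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  if (sxy == 0) stop("degenerate major-axis fit: zero covariance between x and y")
  slope <- (syy - sxx + sqrt((syy - sxx)^2 + 4 * sxy^2)) / (2 * sxy)
  intercept <- mean(y) - slope * mean(x)
  resid <- y - (intercept + slope * x)
  allometric_model("linear_ma", intercept, slope, sigma = stats::sd(resid))
}

#' Logarithmic major axis regression with Baskerville correction
#'
#' Fits `ln(dbh) ~ ln(cd * cd_scale)` by major axis regression and attaches
#' the Baskerville back-transformation factor `exp(sigma^2 / 2)`, which
#' corrects the downward bias of the naive exponential back-transform
#' (the mean of a lognormal exceeds the exponential of the log-scale mean).
#' `cd_scale` defaults to 1.27: in dense natural forest the boundary-weighted
#' segmentation underestimates crown diameters by 27 percent, so the crown
#' diameter entering the model is pre-scaled.
#'
#' @param cd,dbh Positive numeric vectors (crown diameter m, stem diameter cm).
#' @param cd_scale Multiplier applied to cd before the log fit.
#' @return An `allometric_model` with `form = "log_ma_baskerville"`:
#'   `intercept`/`slope` on the log scale, `sigma` the sd of vertical
#'   log-scale residuals, `correction = exp(sigma^2 / 2)`.
#' @export
fit_log_ma_baskerville <- function(cd, dbh, cd_scale = 1.27) {
  bad <- which(!(is.finite(cd) & cd > 0) | !(is.finite(dbh) & dbh > 0))
  if (length(bad)) {
    stop("cd and dbh must be positive and finite; offending row(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  fit <- fit_major_axis(log(cd * cd_scale), log(dbh))
  allometric_model("log_ma_baskerville", fit$intercept, fit$slope,
                   sigma = fit$sigma, cd_scale = cd_scale)
}

#' Construct an allometric CD-to-DBH model
#'
#' @param form `"linear_ma"` or `"log_ma_baskerville"`.
#' @param intercept,slope Coefficients (log-scale for the log form).
#' @param sigma Residual standard deviation on the fitted scale.
#' @param cd_scale CD multiplier for the log form (ignored for linear).
#' @param seeds Optional integer seeds recorded by ensemble fitting.
#' @return An object of class `allometric_model`.
#' @export
allometric_model <- function(form = c("linear_ma", "log_ma_baskerville"),
                             intercept, slope, sigma = 0, cd_scale = 1.27,
                             seeds = NULL) {
  form <- match.arg(form)
  correction <- if (form == "log_ma_baskerville") exp(sigma^2 / 2) else 1
  structure(list(form = form, intercept = intercept, slope = slope,
                 sigma = sigma, correction = correction,
                 cd_scale = if (form == "log_ma_baskerville") cd_scale else NA_real_,
                 seeds = seeds),
            class = "allometric_model")
}

#' @export
print.allometric_model <- function(x, ...) {
  cat(sprintf("<allometric_model> %s: intercept %.6g, slope %.6g, sigma %.6g, correction %.6g\n",
              x$form, x$intercept, x$slope, x$sigma, x$correction))
  invisible(x)
}

#' Four-run half-sample averaged fit
#'
#' Fits the CD-to-DBH model on `k` random half-samples of the data and
#' averages the coefficients (and, for the log form, sigma), the protocol
#' used to stabilise allometric fits against sampling variation. Seeds are
#' recorded in the returned model so the fit is reproducible.
#'
#' @inheritParams fit_major_axis
#' @param form `"linear_ma"` or `"log_ma_baskerville"`.
#' @param k Number of runs (default 4).
#' @param subsample Fraction of the data per run (default 0.5).
#' @param seeds Integer vector of length `k`.
#' @param cd_scale Passed to [fit_log_ma_baskerville()].
#' @return An averaged `allometric_model` carrying `seeds`.
#' @export
fit_half_sample_average <- function(x, y, form = c("linear_ma", "log_ma_baskerville"),
                                    k = 4L, subsample = 0.5, seeds = seq_len(k),
                                    cd_scale = 1.27) {
  form <- match.arg(form)
  if (length(seeds) != k) stop("need one seed per run")
  n <- length(x)
  if (floor(n * subsample) < 3) stop("too few points for half-sampling")
  fits <- lapply(seq_len(k), function(i) {
    set.seed(seeds[i])
    idx <- sample.int(n, floor(n * subsample))
    if (form == "linear_ma") fit_major_axis(x[idx], y[idx])
    else fit_log_ma_baskerville(x[idx], y[idx], cd_scale)
  })
  allometric_model(form,
                   intercept = mean(vapply(fits, `[[`, 0, "intercept")),
                   slope = mean(vapply(fits, `[[`, 0, "slope")),
                   sigma = mean(vapply(fits, `[[`, 0, "sigma")),
                   cd_scale = cd_scale, seeds = as.integer(seeds))
}

#' Predict stem diameter from crown diameter
#'
#' Linear form: `DBH = intercept + slope * CD`. Log form:
#' `DBH = exp(intercept + slope * ln(CD * cd_scale)) * exp(sigma^2 / 2)`.
#' The linear form can return non-positive diameters for very small crowns
#' (below the root of the line); those values are returned as-is so the
#' caller can flag them -- see [apply_allometry()], which zeroes the biomass
#' of such trees and marks them `below_allometry_domain`.
#'
#' @param cd Crown diameter(s), metres, > 0.
#' @param model An `allometric_model`.
#' @return Predicted DBH in cm (same length as `cd`).
#' @export
dbh_from_cd <- function(cd, model) {
  stopifnot(inherits(model, "allometric_model"))
  if (any(!is.finite(cd) | cd <= 0)) stop("cd must be positive and finite")
  if (model$form == "linear_ma") {
    model$intercept + model$slope * cd
  } else {
    exp(model$intercept + model$slope * log(cd * model$cd_scale)) * model$correction
  }
}

#' Construct a DBH-to-AGB equation
#'
#' Two families: a power law `AGB = a * DBH^b` (kg, DBH cm), and the
#' pantropical moist-forest form
#' `AGB = exp(1.803 - 0.976 E + 0.976 ln(rho) + 2.673 ln(DBH)
#'        - 0.0299 (ln DBH)^2)`
#' where `E` is the environmental stress covariate of the site and `rho` the
#' wood density (specific gravity). `rho` defaults to 0.54, an
#' abundance-weighted average for Rwandan natural forest; `E` has no default
#' and must be supplied explicitly for the pantropical form.
#'
#' @param form `"power"` or `"chave"`.
#' @param a,b Power-law coefficient and exponent (power form).
#' @param E Environmental stress scalar (chave form; mandatory).
#' @param rho Wood density (chave form).
#' @param id Optional identifier carried into tree tables.
#' @return An object of class `agb_equation`.
#' @export
agb_equation <- function(form = c("power", "chave"), a = NULL, b = NULL,
                         E = NULL, rho = 0.54, id = NULL) {
  form <- match.arg(form)
  if (form == "power") {
    if (is.null(a) || is.null(b) || a <= 0 || b <= 0) {
      stop("power form needs a > 0 and b > 0")
    }
  } else {
    if (is.null(E) || !is.finite(E)) {
      stop("the pantropical (chave) form requires an explicit environmental ",
           "stress scalar E; there is no default")
    }
    if (!is.finite(rho) || rho <= 0) stop("rho must be positive")
  }
  structure(list(form = form, a = a, b = b, E = E, rho = rho,
                 id = if (is.null(id)) form else id),
            class = "agb_equation")
}

#' Predict aboveground biomass from stem diameter
#'
#' Non-positive DBH never yields negative biomass: the prediction is 0 and
#' the `flagged` attribute marks the offending entries.
#'
#' @param dbh DBH in cm.
#' @param eq An [agb_equation()].
#' @return AGB in kg, with attribute `flagged` (logical vector) when any
#'   input was non-positive.
#' @export
agb_from_dbh <- function(dbh, eq) {
  stopifnot(inherits(eq, "agb_equation"))
  bad <- !is.finite(dbh) | dbh <= 0
  d <- ifelse(bad, 1, dbh)  # placeholder, overwritten below
  agb <- if (eq$form == "power") {
    eq$a * d^eq$b
  } else {
    ld <- log(d)
    exp(1.803 - 0.976 * eq$E + 0.976 * log(eq$rho) + 2.673 * ld - 0.0299 * ld^2)
  }
  agb[bad] <- 0
  if (any(bad)) attr(agb, "flagged") <- bad
  agb
}

#' Convert aboveground biomass to aboveground carbon
#'
#' Applies the standard carbon fraction of dry biomass, 0.47.
#'
#' @param agb AGB in kg (>= 0).
#' @return AGC in kg.
#' @export
agc_from_agb <- function(agb) {
  if (any(agb < 0, na.rm = TRUE)) stop("agb must be >= 0")
  0.47 * agb
}

#' Default land-cover allometry dispatch table
#'
#' Routes each of the six land-cover classes to its CD-to-DBH model and
#' DBH-to-AGB equation: natural forest uses the logarithmic major-axis model
#' (log-scale intercept 1.154, slope 1.248, sigma 0.3315, CD pre-scaled by
#' 1.27) with the pantropical biomass form; savannas and shrublands use the
#' linear major-axis model (DBH = -4.665 + 5.102 CD) with the East-African
#' non-forest power law (a = 0.091, b = 2.472); plantations, farmland and
#' urban areas use the linear model with the plantation power law
#' (a = 0.202, b = 2.447).
#'
#' @param E Environmental stress scalar for the natural-forest equation
#'   (mandatory when natural forest trees are present).
#' @param rho Wood density for the natural-forest equation.
#' @return Named list: per class, a list with `dbh_model` and `agb_eq`.
#' @export
default_allometry_table <- function(E = NULL, rho = 0.54) {
  linear <- allometric_model("linear_ma", intercept = -4.665, slope = 5.102)
  logma <- allometric_model("log_ma_baskerville", intercept = 1.154,
                            slope = 1.248, sigma = 0.3315, cd_scale = 1.27)
  eq4 <- agb_equation("power", a = 0.091, b = 2.472, id = "savanna_power")
  eq5 <- agb_equation("power", a = 0.202, b = 2.447, id = "plantation_power")
  eq7 <- if (!is.null(E)) agb_equation("chave", E = E, rho = rho,
                                       id = "pantropical") else NULL
  list(
    natural_forest = list(dbh_model = logma, agb_eq = eq7),
    savanna_shrubland = list(dbh_model = linear, agb_eq = eq4),
    eucalyptus_plantation = list(dbh_model = linear, agb_eq = eq5),
    non_eucalyptus_plantation = list(dbh_model = linear, agb_eq = eq5),
    farmland = list(dbh_model = linear, agb_eq = eq5),
    urban_builtup = list(dbh_model = linear, agb_eq = eq5)
  )
}

#' The six land-cover classes
#' @return Character vector of valid class names.
#' @export
landcover_classes <- function() {
  c("natural_forest", "savanna_shrubland", "eucalyptus_plantation",
    "non_eucalyptus_plantation", "farmland", "urban_builtup")
}

#' Apply class-specific allometry to a tree table
#'
#' Adds `dbh_cm`, `agb_kg`, `agc_kg`, `equation_id` and `flags` to a crown
#' table that carries `cd_m` and `landcover`. Trees whose linear DBH
#' prediction is non-positive get zero biomass and the flag
#' `below_allometry_domain` (the linear line crosses zero near CD 0.91 m, so
#' crowns between the 0.25 m2 minimum and about 0.66 m2 fall below the
#' model's domain).
#'
#' @param records Tree table with columns `cd_m` and `landcover`.
#' @param table Dispatch table from [default_allometry_table()] (or a
#'   modified copy).
#' @return `records` with the carbon columns appended.
#' @export
apply_allometry <- function(records, table = default_allometry_table()) {
  if (!all(c("cd_m", "landcover") %in% names(records))) {
    stop("records must have columns `cd_m` and `landcover`")
  }
  unknown <- setdiff(unique(records$landcover), names(table))
  if (length(unknown)) {
    stop("no allometry entry for class(es): ", paste(unknown, collapse = ", "))
  }
  n <- nrow(records)
  records$dbh_cm <- NA_real_
  records$agb_kg <- NA_real_
  records$agc_kg <- NA_real_
  records$equation_id <- NA_character_
  if (is.null(records$flags)) records$flags <- ""
  for (cls in unique(records$landcover)) {
    sel <- which(records$landcover == cls)
    chain <- table[[cls]]
    if (is.null(chain$agb_eq)) {
      stop("class `", cls, "` has no AGB equation configured (for natural ",
           "forest, pass the environmental stress E to the dispatch table)")
    }
    dbh <- dbh_from_cd(records$cd_m[sel], chain$dbh_model)
    agb <- agb_from_dbh(dbh, chain$agb_eq)
    flagged <- attr(agb, "flagged")
    attributes(agb) <- NULL
    records$dbh_cm[sel] <- dbh
    records$agb_kg[sel] <- agb
    records$agc_kg[sel] <- agc_from_agb(agb)
    records$equation_id[sel] <- chain$agb_eq$id
    if (!is.null(flagged) && any(flagged)) {
      i <- sel[flagged]
      records$flags[i] <- ifelse(nzchar(records$flags[i]),
                                 paste0(records$flags[i], ";below_allometry_domain"),
                                 "below_allometry_domain")
    }
  }
  records
}

#' Write an allometric model to a plain-text file
#'
#' Key/value text with full double precision (`%.17g`), so a write/read
#' round-trip reproduces the model bit-exactly.
#'
#' @param model An `allometric_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_allometric_model <- function(model, path) {
  stopifnot(inherits(model, "allometric_model"))
  num <- function(x) sprintf("%.17g", x)
  lines <- c(
    paste0("form: ", model$form),
    paste0("intercept: ", num(model$intercept)),
    paste0("slope: ", num(model$slope)),
    paste0("sigma: ", num(model$sigma)),
    paste0("cd_scale: ", num(model$cd_scale))
  )
  if (!is.null(model$seeds)) {
    lines <- c(lines, paste0("seeds: ", paste(model$seeds, collapse = ",")))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read an allometric model written by [write_allometric_model()]
#' @param path File path.
#' @return An `allometric_model`.
#' @export
read_allometric_model <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, ": ", fixed = TRUE)
  keys <- vapply(kv, `[[`, "", 1)
  vals <- vapply(kv, function(p) paste(p[-1], collapse = ": "), "")
  names(vals) <- keys
  seeds <- if ("seeds" %in% keys) {
    as.integer(strsplit(vals[["seeds"]], ",")[[1]])
  } else NULL
  allometric_model(vals[["form"]],
                   intercept = as.numeric(vals[["intercept"]]),
                   slope = as.numeric(vals[["slope"]]),
                   sigma = as.numeric(vals[["sigma"]]),
                   cd_scale = as.numeric(vals[["cd_scale"]]),
                   seeds = seeds)
}
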