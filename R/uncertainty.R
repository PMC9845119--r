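#' Mean relative bias (percent)
#'
#' The relative systematic error of predictions against observations,
#' `bias = 100 / N * sum((y_obs - y_pred) / y_obs)`. Positive values mean
#' underprediction on average.
#'
#' @param y_obs,y_pred Paired numeric vectors; `y_obs` must be non-zero.
#' @return Bias in percent.
#' @export
bias_relative <- function(y_obs, y_pred) {
  check_pairs(y_obs, y_pred)
  if (any(y_obs == 0)) stop("bias_relative is undefined for y_obs = 0")
  mean((y_obs - y_pred) / y_obs) * 100
}

#' Summed-total bias (fraction)
#'
#' `|sum(y_obs - y_pred)| / |sum(y_obs)|`: the absolute error of the summed
#' prediction relative to the summed observation, the form used when the
#' evaluation unit is an aggregate (e.g. plot totals against inventory
#' totals). Sign-symmetric by construction.
#'
#' @inheritParams bias_relative
#' @return Bias as a fraction (not percent).
#' @export
bias_summed <- function(y_obs, y_pred) {
  check_pairs(y_obs, y_pred)
  denom <- abs(sum(y_obs))
  if (denom == 0) stop("bias_summed is undefined when sum(y_obs) = 0")
  abs(sum(y_obs - y_pred)) / denom
}

check_pairs <- function(y_obs, y_pred) {
  if (length(y_obs) != length(y_pred)) stop("y_obs and y_pred must be paired")
  if (!length(y_obs)) stop("empty input")
  if (!all(is.finite(y_obs)) || !all(is.finite(y_pred))) {
    stop("non-finite values in input")
  }
  invisible(NULL)
}

#' Relative root-mean-square error (percent)
#'
#' `rRMSE = 100 * RMSE / mean(y_obs)`.
#'
#' @inheritParams bias_relative
#' @return rRMSE in percent.
#' @export
rrmse <- function(y_obs, y_pred) {
  check_pairs(y_obs, y_pred)
  m <- mean(y_obs)
  if (m == 0) stop("rrmse is undefined when mean(y_obs) = 0")
  sqrt(mean((y_obs - y_pred)^2)) / m * 100
}

#' Area-weighted national uncertainty
#'
#' Combines per-class bias magnitudes into a single national figure by
#' weighting each class by its fraction of the total area:
#' `sum(w_c * |bias_c|)`. Absolute values are used so that over- and
#' under-predicting classes do not cancel.
#'
#' @param per_class_bias Named numeric vector of per-class biases (percent).
#' @param area_weights Named numeric vector of area fractions, same names,
#'   non-negative, summing to 1.
#' @return Weighted uncertainty, percent.
#' @export
national_uncertainty <- function(per_class_bias, area_weights) {
  missing_w <- setdiff(names(per_class_bias), names(area_weights))
  missing_b <- setdiff(names(area_weights), names(per_class_bias))
  if (length(missing_w) || length(missing_b)) {
    stop("stratum mismatch; missing weight(s): ",
         paste(missing_w, collapse = ", "), "; missing bias(es): ",
         paste(missing_b, collapse = ", "))
  }
  w <- area_weights[names(per_class_bias)]
  if (any(w < 0)) stop("area weights must be >= 0")
  if (abs(sum(w) - 1) > 1e-9) stop("area weights must sum to 1")
  sum(w * abs(per_class_bias))
}

#' Half-sample ensemble uncertainty of the crown-to-carbon conversion
#'
#' Quantifies how the sampling variability of the CD-to-DBH calibration data
#' propagates into mapped carbon: fits `k_runs` models on random half-samples
#' of the calibration table, predicts per-tree carbon with each, aggregates
#' carbon per (land-cover class, hectare cell), computes the rRMSE across
#' runs for each cell (sd across runs / mean across runs), and averages the
#' cell rRMSEs per class. Deterministic given the seeds, which are recorded
#' in the output.
#'
#' @param cd_dbh Calibration table with columns `cd_m` and `dbh_cm`.
#' @param trees Tree table with `cd_m`, `landcover`, `x`, `y`.
#' @param k_runs Number of ensemble members (default 4).
#' @param subsample Fraction of the calibration data per run (default 0.5).
#' @param seeds Integer seeds, one per run (default `1:k_runs`).
#' @param form Model form fitted in each run (see [fit_major_axis()]).
#' @param agb_table Dispatch table from [default_allometry_table()]; the
#'   fitted CD-to-DBH model replaces the table's `dbh_model` per run, the
#'   AGB equations are reused as configured.
#' @param cell_size,grid_origin Hectare-grid geometry for the aggregation.
#' @param cd_scale Passed to the log-form fit.
#' @return List: `per_class` (named mean rRMSE in percent per class),
#'   `cells` (data frame with per-cell run values and rRMSE), `seeds`,
#'   `runs_used`, `runs_excluded`, and `rrmse_definition`.
#' @export
ensemble_uncertainty <- function(cd_dbh, trees, k_runs = 4L, subsample = 0.5,
                                 seeds = seq_len(k_runs),
                                 form = c("linear_ma", "log_ma_baskerville"),
                                 agb_table = default_allometry_table(),
                                 cell_size = 100, grid_origin = c(0, 0),
                                 cd_scale = 1.27) {
  form <- match.arg(form)
  if (length(seeds) != k_runs) stop("need one seed per run")
  n <- nrow(cd_dbh)
  if (n < 6) stop("calibration table too small for half-sampling (need n >= 6)")
  runs <- list()
  excluded <- 0L
  for (i in seq_len(k_runs)) {
    set.seed(seeds[i])
    idx <- sample.int(n, floor(n * subsample))
    model <- tryCatch({
      if (form == "linear_ma") {
        fit_major_axis(cd_dbh$cd_m[idx], cd_dbh$dbh_cm[idx])
      } else {
        fit_log_ma_baskerville(cd_dbh$cd_m[idx], cd_dbh$dbh_cm[idx], cd_scale)
      }
    }, error = function(e) NULL)
    if (is.null(model)) { excluded <- excluded + 1L; next }
    tab <- agb_table
    for (cls in names(tab)) tab[[cls]]$dbh_model <- model
    pred <- apply_allometry(trees, tab)
    runs[[length(runs) + 1L]] <- pred$agc_kg
  }
  if (length(runs) < 2) stop("fewer than two non-degenerate runs; cannot form an ensemble")

  ic <- floor((trees$x - grid_origin[1]) / cell_size)
  ir <- floor((trees$y - grid_origin[2]) / cell_size)
  cell_id <- paste(trees$landcover, ir, ic, sep = "|")
  agg <- lapply(runs, function(agc) tapply(agc, cell_id, sum))
  mat <- do.call(cbind, agg)  # rows: class|cell, cols: runs
  mu <- rowMeans(mat)
  sdv <- apply(mat, 1, stats::sd)
  cell_rrmse <- ifelse(mu == 0, NA_real_, sdv / mu * 100)
  cls <- sub("\\|.*$", "", rownames(mat))
  per_class <- tapply(cell_rrmse, cls, function(v) mean(v, na.rm = TRUE))
  cells <- data.frame(class = cls, cell = rownames(mat), mean_agc_kg = mu,
                      sd_agc_kg = sdv, rrmse_pct = cell_rrmse,
                      row.names = NULL)
  list(per_class = per_class[order(names(per_class))], cells = cells,
       seeds = as.integer(seeds), runs_used = length(runs),
       runs_excluded = excluded,
       rrmse_definition = "sd/mean across runs per (class, ha cell), averaged per class, percent")
}

#' Plot-level evaluation of predicted carbon
#'
#' Sums the predicted aboveground carbon of trees whose centroids fall inside
#' each field plot and compares against the measured plot values. Plots with
#' no predicted trees are retained with prediction 0.
#'
#' @param trees Tree table with `x`, `y`, `agc_kg`.
#' @param plots List of plot features: each a list with `plot_id` and `ring`
#'   (n x 2 vertex matrix).
#' @param field_values Named numeric vector of observed values keyed by
#'   `plot_id`, in the same unit the predictions should be compared in
#'   (predicted sums are reported in both kg and Mg).
#' @param unit `"Mg"` (default) to compare `field_values` against predicted
#'   sums in Mg, or `"kg"`.
#' @return List: `pairs` (data frame `plot_id`, `y_obs`, `y_pred`,
#'   `n_trees`), `rrmse_pct`, `bias_relative_pct`, `bias_summed`.
#' @export
plot_level_eval <- function(trees, plots, field_values, unit = c("Mg", "kg")) {
  unit <- match.arg(unit)
  ids <- vapply(plots, `[[`, "", "plot_id")
  if (!all(ids %in% names(field_values))) {
    stop("field_values missing plot(s): ",
         paste(setdiff(ids, names(field_values)), collapse = ", "))
  }
  y_pred <- numeric(length(plots))
  n_in <- integer(length(plots))
  for (i in seq_along(plots)) {
    inside <- point_in_ring(trees$x, trees$y, plots[[i]]$ring)
    n_in[i] <- sum(inside)
    y_pred[i] <- sum(trees$agc_kg[inside])
  }
  if (unit == "Mg") y_pred <- y_pred / 1000
  y_obs <- unname(field_values[ids])
  pairs <- data.frame(plot_id = ids, y_obs = y_obs, y_pred = y_pred,
                      n_trees = n_in)
  list(pairs = pairs,
       rrmse_pct = rrmse(y_obs, y_pred),
       bias_relative_pct = bias_relative(y_obs, y_pred),
       bias_summed = bias_summed(y_obs, y_pred))
}
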