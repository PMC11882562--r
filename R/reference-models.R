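# Published reference equations for cv. Tieguanyin, from a 10-plantation,
# three-season field survey (Anxi County, Fujian). Coefficients are kept
# digit-for-digit as published; concentrations are percent dry mass.

#' Published catechin regression models for cv. Tieguanyin
#'
#' The seven per-catechin linear calibration equations relating percent
#' dry-mass concentration to the eight meteorological factors
#' ([meteo_factors()]), as published for *Camellia sinensis* cv.
#' Tieguanyin from a 10-plantation, three-season field survey, together
#' with their reported RMSEP/RMSECV/RMSEC validation errors. These serve
#' as the default generating model of the synthetic-data module and as a
#' worked-example fixture for the optimizer.
#'
#' @return A `coef_table`: data frame with one row per catechin, columns
#'   `response`, `intercept`, the eight factor slopes, and
#'   `rmsep`/`rmsecv`/`rmsec`. The `provenance` attribute is
#'   `"tieguanyin-reference"`.
#' @seealso [coef_table()], [get_model()], [tieguanyin_factor_box()]
#' @export
#' @examples
#' tieguanyin_models()
#' predict(get_model(tieguanyin_models(), "egcg"), tieguanyin_optima()$egcg)
tieguanyin_models <- function() {
  tb <- data.frame(
    response = c("egc", "c", "ec", "egcg", "gcg", "ecg", "cg"),
    intercept = c(0.14, -1.08, 1.538, 8.637, -0.633, 1.27, -0.122),
    rainfall = c(-0.009, -0.054, -0.002, 0.367, 0.031, 0.094, 0.0005),
    temp_avg = c(-0.002, 0.122, -0.006, -0.042, 0.011, 0.06, 0.001),
    eat = c(-0.0002, -0.002, 0.0001, -0.002, -0.0004, -0.002, -0.00004),
    temp_max = c(0.012, -0.006, -0.0029, 0.079, 0.037, 0.078, 0.008),
    temp_min = c(-0.002, -0.077, -0.001, -0.031, 0.002, -0.01, -0.0003),
    humidity = c(0.003, 0.038, -0.005, 0.024, 0.005, 0.001, 0.001),
    ground_temp = c(0.004, -0.048, 0.005, -0.087, 0.009, -0.012, -0.0005),
    irradiance = c(0.000004, -0.000003, 0.000003, -0.00001, -0.00004,
                   -0.00004, -0.000002),
    rmsep = c(0.00042, 0.00229, 0.00049, 0.01184, 0.00105, 0.00325, 0.00020),
    rmsecv = c(0.00044, 0.00242, 0.00057, 0.01329, 0.00120, 0.00363, 0.00021),
    rmsec = c(0.00044, 0.00538, 0.00051, 0.01559, 0.00206, 0.00847, 0.00038),
    stringsAsFactors = FALSE
  )
  coef_table(tb, provenance = "tieguanyin-reference")
}

#' Meteorological box and optimal conditions for cv. Tieguanyin
#'
#' `tieguanyin_factor_box()` returns the per-factor lower/upper bounds
#' spanned by the published optimal growing conditions (the feasible box
#' of the published optimisation); `tieguanyin_optima()` returns the
#' published optimal factor vectors for the EGCG, ECG and C targets.
#' Units follow [meteo_factors()]. The minimum-temperature coordinate is
#' identical in every published optimum, so its box is degenerate.
#'
#' @return `tieguanyin_factor_box()`: data frame with columns `factor`,
#'   `low`, `high`. `tieguanyin_optima()`: named list of three named
#'   numeric factor vectors (`egcg`, `ecg`, `c`).
#' @export
#' @examples
#' tieguanyin_factor_box()
tieguanyin_factor_box <- function() {
  data.frame(
    factor = meteo_factors(),
    low = c(1.13, 12.72, 223.50, 26.9, -3.60, 75.50, 14.36, 1283.50),
    high = c(9.78, 25.53, 553.74, 35.30, -3.60, 96.34, 30.65, 8421.08),
    stringsAsFactors = FALSE
  )
}

#' @rdname tieguanyin_factor_box
#' @export
tieguanyin_optima <- function() {
  mk <- function(x) stats::setNames(x, meteo_factors())
  list(
    egcg = mk(c(9.78, 12.72, 553.74, 35.30, -3.60, 96.34, 14.36, 8421.08)),
    ecg = mk(c(9.78, 25.53, 223.50, 35.30, -3.60, 75.50, 30.65, 1283.50)),
    c = mk(c(1.13, 25.53, 223.50, 26.9, -3.6, 96.34, 14.36, 1283.50))
  )
}

# ---- model class and coefficient tables ------------------------------------

#' Construct a per-catechin linear model
#'
#' A `catechin_model` holds the intercept and the eight factor slopes of
#' one response (units: percent dry mass per factor unit), plus optional
#' RMSEC/RMSECV/RMSEP error metrics.
#'
#' @param response Response name (e.g. `"egcg"`).
#' @param intercept Intercept (percent dry mass).
#' @param coefficients Named numeric vector of the eight factor slopes,
#'   names as in [meteo_factors()].
#' @param rmsec,rmsecv,rmsep Optional error metrics (percent dry mass).
#' @return Object of class `catechin_model`.
#' @export
catechin_model <- function(response, intercept, coefficients,
                           rmsec = NA_real_, rmsecv = NA_real_,
                           rmsep = NA_real_) {
  if (!setequal(names(coefficients), meteo_factors())) {
    stop("`coefficients` must be named by the 8 meteorological factors",
         call. = FALSE)
  }
  for (m in c(rmsec, rmsecv, rmsep)) {
    if (!is.na(m) && m < 0) stop("error metrics must be >= 0", call. = FALSE)
  }
  structure(
    list(response = response,
         intercept = as.numeric(intercept),
         coefficients = coefficients[meteo_factors()],
         rmsec = rmsec, rmsecv = rmsecv, rmsep = rmsep),
    class = "catechin_model"
  )
}

#' Predict a catechin concentration from meteorological conditions
#'
#' Evaluates `intercept + sum(slope_j * x_j)`. Predictions from a linear
#' calibration can fall below zero outside the calibrated region; they
#' are returned as-is with a warning, never silently clipped.
#'
#' @param object A [catechin_model()].
#' @param newdata Named numeric factor vector, or a data frame with the
#'   eight factor columns (one prediction per row).
#' @param warn_negative Warn when a prediction is negative. Default TRUE.
#' @param ... Unused.
#' @return Numeric prediction(s), percent dry mass.
#' @export
predict.catechin_model <- function(object, newdata, warn_negative = TRUE,
                                   ...) {
  fac <- meteo_factors()
  if (is.data.frame(newdata)) {
    missing <- setdiff(fac, names(newdata))
    if (length(missing) > 0L) {
      stop("`newdata` is missing factor column(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    x <- as.matrix(newdata[, fac, drop = FALSE])
  } else {
    missing <- setdiff(fac, names(newdata))
    if (length(missing) > 0L) {
      stop("`newdata` is missing factor(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    x <- matrix(newdata[fac], nrow = 1L, dimnames = list(NULL, fac))
  }
  pred <- drop(object$intercept + x %*% object$coefficients)
  if (warn_negative && any(pred < 0)) {
    warning(sprintf("%d negative prediction(s) for '%s' (linear model %s",
                    sum(pred < 0), object$response,
                    "extrapolation); values returned unclipped"),
            call. = FALSE)
  }
  unname(pred)
}

#' @export
print.catechin_model <- function(x, ...) {
  cat(sprintf("<catechin_model> %s: %.4g + %s\n", x$response, x$intercept,
              paste(sprintf("%.4g*%s", x$coefficients,
                            names(x$coefficients)), collapse = " + ")))
  if (!is.na(x$rmsec)) {
    cat(sprintf("  RMSEC %.4g  RMSECV %.4g  RMSEP %.4g\n",
                x$rmsec, x$rmsecv, x$rmsep))
  }
  invisible(x)
}

#' Coefficient tables: one row per response
#'
#' A `coef_table` is a data frame with columns `response`, `intercept`,
#' the eight factor slopes and optional `rmsep`/`rmsecv`/`rmsec` columns,
#' with a `provenance` attribute (`"fitted"`, a file path, or
#' `"tieguanyin-reference"`). `get_model()` extracts one row as a
#' [catechin_model()]; `models_to_table()` assembles a table from a list
#' of models.
#'
#' @param table Data frame in the layout above.
#' @param provenance Free-text provenance tag.
#' @return A `coef_table` data frame.
#' @export
coef_table <- function(table, provenance = "fitted") {
  needed <- c("response", "intercept", meteo_factors())
  missing <- setdiff(needed, names(table))
  if (length(missing) > 0L) {
    stop("coefficient table missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(table$response)) {
    stop("coefficient table has duplicated responses", call. = FALSE)
  }
  structure(table, class = c("coef_table", "data.frame"),
            provenance = provenance)
}

#' @rdname coef_table
#' @param response Response name to extract.
#' @export
get_model <- function(table, response) {
  i <- match(response, table$response)
  if (is.na(i)) {
    stop(sprintf("response '%s' not present in the coefficient table",
                 response), call. = FALSE)
  }
  row <- table[i, ]
  catechin_model(
    response = row$response,
    intercept = row$intercept,
    coefficients = unlist(row[meteo_factors()]),
    rmsec = if ("rmsec" %in% names(row)) row$rmsec else NA_real_,
    rmsecv = if ("rmsecv" %in% names(row)) row$rmsecv else NA_real_,
    rmsep = if ("rmsep" %in% names(row)) row$rmsep else NA_real_
  )
}

#' @rdname coef_table
#' @param models List of [catechin_model()] objects.
#' @export
models_to_table <- function(models, provenance = "fitted") {
  rows <- lapply(models, function(m) {
    cbind(data.frame(response = m$response, intercept = m$intercept,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(m$coefficients)),
          data.frame(rmsep = m$rmsep, rmsecv = m$rmsecv, rmsec = m$rmsec))
  })
  coef_table(do.call(rbind, rows), provenance = provenance)
}

#' Read/write a coefficient table CSV
#'
#' Column layout mirrors the published model table: `response,
#' intercept, <eight factor slopes>, rmsep, rmsecv, rmsec`.
#'
#' @param path File path.
#' @return `read_coef_table()`: a [coef_table()]; `write_coef_table()`:
#'   `path`, invisibly.
#' @export
read_coef_table <- function(path) {
  tb <- utils::read.csv(path, stringsAsFactors = FALSE)
  coef_table(tb, provenance = path)
}

#' @rdname read_coef_table
#' @param table A [coef_table()].
#' @export
write_coef_table <- function(table, path) {
  out <- as.data.frame(table)
  num <- vapply(out, is.numeric, logical(1L))
  out[num] <- lapply(out[num], function(x) format(x, digits = 15L,
                                                  scientific = FALSE,
                                                  trim = TRUE))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
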