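# Domain vocabulary: the eight season-aggregate meteorological factors and
# the seven catechin monomers, in canonical column order.

#' Canonical meteorological factor names
#'
#' The eight season-aggregate weather factors used throughout the package,
#' in canonical order: rainy-day mean rainfall (mm/day), average air
#' temperature (degC), effective accumulated temperature statistic (degC),
#' maximum and minimum air temperature (degC), average relative humidity
#' (%), average 10-cm ground temperature (degC) and average daily
#' irradiance (lux).
#'
#' @return Character vector of length 8.
#' @export
#' @examples
#' meteo_factors()
meteo_factors <- function() {
  c("rainfall", "temp_avg", "eat", "temp_max", "temp_min",
    "humidity", "ground_temp", "irradiance")
}

#' Catechin monomer names and group membership
#'
#' Seven catechin monomers quantified as percent dry leaf mass: EGC, C
#' (catechin), EC, EGCG, GCG, ECG and CG. The esterified (galloylated)
#' monomers EGCG, GCG, ECG and CG form the TEC group; the non-esterified
#' EGC, C and EC form the TNEC group.
#'
#' @return `catechin_names()`: character vector of length 7.
#'   `catechin_groups()`: named list with elements `tec` and `tnec`.
#' @export
#' @examples
#' catechin_groups()$tec
catechin_names <- function() {
  c("egc", "c", "ec", "egcg", "gcg", "ecg", "cg")
}

#' @rdname catechin_names
#' @export
catechin_groups <- function() {
  list(tec = c("egcg", "gcg", "ecg", "cg"),
       tnec = c("egc", "c", "ec"))
}

seasons_allowed <- function() c("spring", "summer", "autumn")

#' Effective accumulated temperature statistic
#'
#' Daily heat accumulation above the biological zero of the crop (10 degC
#' for tea), averaged over the observation period. By default days colder
#' than the biological zero contribute nothing (the usual growing-degree
#' convention); with `clip_negative = FALSE` the literal daily difference
#' is averaged, so cold days subtract.
#'
#' @param daily_mean_temps Numeric vector of daily mean air temperatures
#'   (degC) over the growing period.
#' @param biological_zero Base temperature (degC) below which no
#'   growth-relevant heat accumulates. Default 10.
#' @param clip_negative If `TRUE` (default), negative daily excesses are
#'   clipped to zero before averaging.
#' @return Mean daily effective temperature excess (degC).
#' @export
#' @examples
#' compute_eat(c(20, 30))            # 15
#' compute_eat(c(8, 12))             # 1: only the 12-degree day counts
#' compute_eat(c(8, 12), clip_negative = FALSE)  # 0
compute_eat <- function(daily_mean_temps, biological_zero = 10,
                        clip_negative = TRUE) {
  if (length(daily_mean_temps) == 0L) {
    stop("`daily_mean_temps` must be a non-empty temperature sequence",
         call. = FALSE)
  }
  if (anyNA(daily_mean_temps)) {
    stop("`daily_mean_temps` contains missing values", call. = FALSE)
  }
  excess <- daily_mean_temps - biological_zero
  if (clip_negative) excess <- pmax(excess, 0)
  mean(excess)
}

#' Mean rainfall on rainy days
#'
#' Total rainfall over days with measurable precipitation divided by the
#' number of such days; dry days do not dilute the average. With no rainy
#' day in the period the function returns 0 and warns rather than divide
#' by zero.
#'
#' @param daily_rain Numeric vector of daily rainfall totals (mm), all
#'   non-negative.
#' @param measurable_threshold Rainfall strictly above this value (mm)
#'   counts as measurable. Default 0; stations reporting a trace floor
#'   may use e.g. 0.1.
#' @return Mean rainfall (mm/day) over rainy days.
#' @export
#' @examples
#' rainy_day_rainfall(c(0, 5, 0, 3))  # 4
rainy_day_rainfall <- function(daily_rain, measurable_threshold = 0) {
  if (length(daily_rain) == 0L) {
    stop("`daily_rain` must be a non-empty rainfall sequence", call. = FALSE)
  }
  if (anyNA(daily_rain) || any(daily_rain < 0)) {
    stop("`daily_rain` must be non-negative with no missing values",
         call. = FALSE)
  }
  rainy <- daily_rain[daily_rain > measurable_threshold]
  if (length(rainy) == 0L) {
    warning("no days with measurable precipitation; returning 0",
            call. = FALSE)
    return(0)
  }
  sum(rainy) / length(rainy)
}

#' Catechin group sums
#'
#' Total esterified catechins (TEC = EGCG + GCG + ECG + CG), total
#' non-esterified catechins (TNEC = EGC + C + EC) and total catechins
#' (TC = TEC + TNEC), all in percent dry mass.
#'
#' `group_sums()` works on a named numeric vector of the seven monomers;
#' `add_group_sums()` appends/overwrites `tec`, `tnec` and `tc` columns on
#' a dataset data frame.
#'
#' @param monomers Named numeric vector containing all seven monomers
#'   (names as in [catechin_names()]).
#' @return Named numeric vector `c(tec, tnec, tc)`.
#' @export
#' @examples
#' group_sums(c(egc = 1, c = 1, ec = 1, egcg = 1, gcg = 1, ecg = 1, cg = 1))
group_sums <- function(monomers) {
  missing <- setdiff(catechin_names(), names(monomers))
  if (length(missing) > 0L) {
    stop("missing catechin monomer(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  g <- catechin_groups()
  tec <- sum(monomers[g$tec])
  tnec <- sum(monomers[g$tnec])
  c(tec = tec, tnec = tnec, tc = tec + tnec)
}

#' @rdname group_sums
#' @param data Dataset data frame with the seven monomer columns.
#' @export
add_group_sums <- function(data) {
  missing <- setdiff(catechin_names(), names(data))
  if (length(missing) > 0L) {
    stop("missing catechin monomer(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  g <- catechin_groups()
  data$tec <- rowSums(data[, g$tec, drop = FALSE])
  data$tnec <- rowSums(data[, g$tnec, drop = FALSE])
  data$tc <- data$tec + data$tnec
  data
}

# ---- dataset validation and CSV I/O ----------------------------------------

#' Validate a site-by-season dataset
#'
#' Checks the canonical tabular layout: one row per (site, season), a
#' `site` and `season` column, all eight meteorological factor columns,
#' optionally the seven catechin columns and `expr_`-prefixed gene
#' expression columns. Seasons must come from spring/summer/autumn;
#' (site, season) pairs must be unique; physical range constraints on the
#' weather factors are enforced.
#'
#' @param data Data frame to validate.
#' @param require_catechins If `TRUE`, the seven monomer columns must be
#'   present.
#' @return `data`, invisibly, on success; otherwise an error.
#' @export
validate_dataset <- function(data, require_catechins = FALSE) {
  if (!is.data.frame(data) || nrow(data) == 0L) {
    stop("dataset must be a non-empty data frame", call. = FALSE)
  }
  needed <- c("site", "season", meteo_factors())
  if (require_catechins) needed <- c(needed, catechin_names())
  missing <- setdiff(needed, names(data))
  if (length(missing) > 0L) {
    stop("dataset is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad_season <- setdiff(unique(as.character(data$season)), seasons_allowed())
  if (length(bad_season) > 0L) {
    stop("unknown season value(s): ", paste(bad_season, collapse = ", "),
         call. = FALSE)
  }
  key <- paste(data$site, data$season, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- data[duplicated(key), c("site", "season")][1L, ]
    stop(sprintf("duplicate (site, season) record: (%s, %s)",
                 dup$site, dup$season), call. = FALSE)
  }
  num_cols <- intersect(c(meteo_factors(), catechin_names(),
                          grep("^expr_", names(data), value = TRUE)),
                        names(data))
  for (col in num_cols) {
    if (!is.numeric(data[[col]])) {
      stop(sprintf("column '%s' must be numeric", col), call. = FALSE)
    }
  }
  with_feat <- function(cond, what) {
    if (any(!cond)) {
      stop(sprintf("invalid %s in row(s): %s", what,
                   paste(utils::head(which(!cond), 5L), collapse = ", ")),
           call. = FALSE)
    }
  }
  with_feat(data$rainfall >= 0, "rainfall (must be >= 0)")
  with_feat(data$humidity >= 0 & data$humidity <= 100,
            "humidity (must be within [0, 100])")
  with_feat(data$irradiance >= 0, "irradiance (must be >= 0)")
  with_feat(data$eat >= 0, "EAT (must be >= 0)")
  with_feat(data$temp_min <= data$temp_avg + 1e-9 &
              data$temp_avg <= data$temp_max + 1e-9,
            "temperature ordering (min <= avg <= max)")
  if (require_catechins) {
    for (m in catechin_names()) {
      with_feat(data[[m]] >= 0, sprintf("%s concentration (must be >= 0)", m))
    }
  }
  invisible(data)
}

#' Read and write the canonical dataset CSV
#'
#' Plain UTF-8 CSV with a header, one row per (site, season) and the
#' canonical column names `site, season, rainfall, temp_avg, eat,
#' temp_max, temp_min, humidity, ground_temp, irradiance`, optionally the
#' seven monomer columns (plus `tec`/`tnec`/`tc`) and `expr_`-prefixed
#' expression columns. Writing then reading a dataset is lossless to
#' numeric precision (values are serialised with 15 significant digits).
#'
#' @param path File path.
#' @param require_catechins Passed to [validate_dataset()].
#' @return `read_dataset()` returns the validated data frame;
#'   `write_dataset()` returns `path` invisibly.
#' @export
read_dataset <- function(path, require_catechins = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  data <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  validate_dataset(data, require_catechins = require_catechins)
  data
}

#' @rdname read_dataset
#' @param data Dataset data frame.
#' @export
write_dataset <- function(data, path) {
  validate_dataset(data)
  out <- data
  num <- vapply(out, is.numeric, logical(1L))
  out[num] <- lapply(out[num], function(x) format(x, digits = 15L,
                                                  scientific = FALSE,
                                                  trim = TRUE))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Average replicate rows to per-(site, season) means
#'
#' Field surveys carry several biological replicates per plantation and
#' season; the modelling stages consume their means. All numeric columns
#' are averaged within each (site, season) cell.
#'
#' @param data Data frame with `site` and `season` columns, possibly with
#'   repeated (site, season) rows.
#' @return Data frame with one row per (site, season), ordered by site
#'   then season.
#' @export
average_replicates <- function(data) {
  if (!all(c("site", "season") %in% names(data))) {
    stop("`data` must have 'site' and 'season' columns", call. = FALSE)
  }
  num <- names(data)[vapply(data, is.numeric, logical(1L))]
  agg <- stats::aggregate(data[num],
                          by = list(site = data$site, season = data$season),
                          FUN = mean)
  agg <- agg[order(agg$site, match(agg$season, seasons_allowed())), ]
  rownames(agg) <- NULL
  agg
}
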