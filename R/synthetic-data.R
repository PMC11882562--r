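# Synthetic survey generator: meteorological factors uniform within a
# per-factor box, catechins from the reference linear models plus Gaussian
# noise, and qPCR Ct pairs whose implied 2^-ddCt follows configured
# log-linear factor responses.

default_site_ids <- function(n_sites) {
  study <- c("BM", "WY", "YL1", "YL2", "JY1", "JY2", "GH", "GXLG", "GD",
             "HXY")
  if (n_sites <= length(study)) return(study[seq_len(n_sites)])
  c(study, sprintf("S%02d", seq.int(length(study) + 1L, n_sites)))
}

#' Default meteorological sampling bounds
#'
#' The per-factor box the generator draws from. It matches the feasible
#' box of the reference optimisation ([tieguanyin_factor_box()]) except
#' for the minimum temperature, whose reference box is degenerate (a
#' single value): a degenerate factor cannot be identified by any
#' downstream regression, so the generator widens it to \[-3.6, 15\] degC,
#' a realistic spread of seasonal night minima for the study region.
#'
#' @return Data frame with columns `factor`, `low`, `high`.
#' @export
default_meteo_bounds <- function() {
  box <- tieguanyin_factor_box()
  box$high[box$factor == "temp_min"] <- 15.0
  box
}

#' Default per-catechin noise standard deviations
#'
#' Residual standard deviation (percent dry mass) of the generated
#' catechins around the reference linear models: ten times each
#' response's published calibration RMSEC. The published RMSEC values
#' (e.g. 0.01559 for EGCG, a response spanning several percent) are far
#' smaller than typical field variability, so they are scaled up to give
#' the generator a realistic signal-to-noise regime; the choice is a
#' documented convention, not an estimate of the study's noise.
#'
#' @return Named numeric vector over the seven monomers.
#' @export
default_noise_sd <- function() {
  tb <- tieguanyin_models()
  stats::setNames(tb$rmsec * 10, tb$response)
}

#' Configuration for the synthetic survey generator
#'
#' Bundles everything [generate_dataset()] needs: the site/season layout,
#' the per-factor sampling box, the generating coefficient table, the
#' per-response noise level and optional gene-expression links. The seed
#' is mandatory: every synthetic dataset is reproducible by construction.
#'
#' @param n_sites Number of plantation sites. Default 10, the study
#'   layout.
#' @param seasons Subset of spring/summer/autumn. Default all three.
#' @param meteo_bounds Data frame `factor, low, high`
#'   (default [default_meteo_bounds()]).
#' @param coefficients Generating [coef_table()]
#'   (default [tieguanyin_models()]).
#' @param noise_sd Named per-response noise SD in percent dry mass
#'   (default [default_noise_sd()]), or a single number recycled.
#' @param expression_links Optional named list: gene -> named numeric
#'   vector of per-factor log2 slopes (sparse; unnamed factors get 0).
#' @param seed Integer seed. Mandatory.
#' @return Object of class `generator_config` (a list).
#' @export
#' @examples
#' cfg <- generator_config(seed = 1)
#' d <- generate_dataset(cfg)
#' head(d)
generator_config <- function(n_sites = 10,
                             seasons = c("spring", "summer", "autumn"),
                             meteo_bounds = default_meteo_bounds(),
                             coefficients = tieguanyin_models(),
                             noise_sd = default_noise_sd(),
                             expression_links = NULL,
                             seed) {
  if (missing(seed) || is.null(seed) || is.na(seed)) {
    stop("`seed` is mandatory in a generator config", call. = FALSE)
  }
  if (n_sites < 1L) stop("`n_sites` must be >= 1", call. = FALSE)
  seasons <- match.arg(seasons, seasons_allowed(), several.ok = TRUE)
  stopifnot(is.data.frame(meteo_bounds),
            all(c("factor", "low", "high") %in% names(meteo_bounds)))
  missing_fac <- setdiff(meteo_factors(), meteo_bounds$factor)
  if (length(missing_fac) > 0L) {
    stop("meteo_bounds missing factor(s): ",
         paste(missing_fac, collapse = ", "), call. = FALSE)
  }
  if (any(meteo_bounds$low > meteo_bounds$high)) {
    bad <- meteo_bounds$factor[meteo_bounds$low > meteo_bounds$high]
    stop("low > high for factor(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (length(noise_sd) == 1L && is.null(names(noise_sd))) {
    noise_sd <- stats::setNames(rep(noise_sd, 7L), catechin_names())
  }
  if (any(noise_sd < 0)) stop("`noise_sd` must be >= 0", call. = FALSE)
  structure(
    list(n_sites = as.integer(n_sites), seasons = seasons,
         meteo_bounds = meteo_bounds, coefficients = coefficients,
         noise_sd = noise_sd, expression_links = expression_links,
         seed = as.integer(seed)),
    class = "generator_config"
  )
}

#' Read a generator configuration from a YAML file
#'
#' Keys mirror the arguments of [generator_config()]; `meteo_bounds` is a
#' mapping factor -> `[low, high]`, `expression_links` a mapping gene ->
#' mapping factor -> slope. `seed` is required.
#'
#' @param path YAML file path.
#' @return A [generator_config()].
#' @export
read_generator_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$seed)) stop("config file must set `seed`", call. = FALSE)
  bounds <- default_meteo_bounds()
  if (!is.null(y$meteo_bounds)) {
    for (f in names(y$meteo_bounds)) {
      i <- match(f, bounds$factor)
      if (is.na(i)) stop("unknown factor in meteo_bounds: ", f,
                         call. = FALSE)
      bounds$low[i] <- y$meteo_bounds[[f]][[1L]]
      bounds$high[i] <- y$meteo_bounds[[f]][[2L]]
    }
  }
  links <- NULL
  if (!is.null(y$expression_links)) {
    links <- lapply(y$expression_links, function(g) unlist(g))
  }
  noise <- default_noise_sd()
  if (!is.null(y$noise_sd)) {
    ns <- unlist(y$noise_sd)
    if (is.null(names(ns))) noise[] <- ns else noise[names(ns)] <- ns
  }
  generator_config(
    n_sites = if (is.null(y$n_sites)) 10 else y$n_sites,
    seasons = if (is.null(y$seasons)) seasons_allowed() else
      unlist(y$seasons),
    meteo_bounds = bounds, noise_sd = noise,
    expression_links = links, seed = y$seed
  )
}

#' Generate meteorological records
#'
#' Draws each factor independently and uniformly within its bounds for
#' every (site, season) cell, then repairs each record so that
#' `temp_min <= temp_avg <= temp_max` by sorting the three temperature
#' values. Deterministic under a fixed seed.
#'
#' @param config A [generator_config()].
#' @return Dataset data frame (`site`, `season`, eight factor columns).
#' @export
generate_meteo <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  sites <- default_site_ids(config$n_sites)
  grid <- expand.grid(season = config$seasons, site = sites,
                      stringsAsFactors = FALSE)[, c("site", "season")]
  n <- nrow(grid)
  set.seed(config$seed)
  b <- config$meteo_bounds
  vals <- lapply(meteo_factors(), function(f) {
    i <- match(f, b$factor)
    stats::runif(n, b$low[i], b$high[i])
  })
  names(vals) <- meteo_factors()
  data <- cbind(grid, as.data.frame(vals))
  temps <- t(apply(data[, c("temp_min", "temp_avg", "temp_max")], 1L, sort))
  data$temp_min <- temps[, 1L]
  data$temp_avg <- temps[, 2L]
  data$temp_max <- temps[, 3L]
  rownames(data) <- NULL
  validate_dataset(data)
  data
}

#' Generate catechin concentrations from a linear generating model
#'
#' For every record, each monomer is `intercept + sum(slope_j * x_j) +
#' N(0, noise_sd^2)`. Negative draws are floored at zero (observed
#' concentrations cannot be negative); the flooring count is reported
#' via `message()` and attached as attribute `n_floored` so callers can
#' assert it is rare. Group sums TEC/TNEC/TC are recomputed from the
#' floored monomers.
#'
#' @param data Dataset with meteorological columns.
#' @param coefficients Generating [coef_table()] covering all seven
#'   monomers.
#' @param noise_sd Named per-response noise SD, or single number.
#' @param seed Integer seed.
#' @return `data` with the seven monomer columns and `tec`/`tnec`/`tc`
#'   appended; attribute `n_floored` counts floored draws.
#' @export
generate_catechins <- function(data, coefficients = tieguanyin_models(),
                               noise_sd = default_noise_sd(), seed) {
  validate_dataset(data)
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  if (length(noise_sd) == 1L && is.null(names(noise_sd))) {
    noise_sd <- stats::setNames(rep(noise_sd, 7L), catechin_names())
  }
  missing_resp <- setdiff(catechin_names(), coefficients$response)
  if (length(missing_resp) > 0L) {
    stop("coefficient table missing response(s): ",
         paste(missing_resp, collapse = ", "), call. = FALSE)
  }
  set.seed(seed)
  n_floored <- 0L
  for (resp in catechin_names()) {
    model <- get_model(coefficients, resp)
    mu <- predict(model, data, warn_negative = FALSE)
    y <- mu + stats::rnorm(nrow(data), 0, noise_sd[[resp]])
    n_floored <- n_floored + sum(y < 0)
    data[[resp]] <- pmax(y, 0)
  }
  if (n_floored > 0L) {
    message(sprintf("generate_catechins: floored %d negative draw(s) at 0",
                    n_floored))
  }
  data <- add_group_sums(data)
  attr(data, "n_floored") <- n_floored
  data
}

#' Generate a qPCR Ct table with factor-linked expression
#'
#' For each gene with a link vector v, the underlying log2 relative
#' expression of a sample is `sum(v_j * z_j) + N(0, noise_log2^2)` where
#' z are the within-dataset standardized meteorological factors
#' (multiplicative noise on the expression scale). Ct pairs are
#' constructed so that the 2^-ddCt chain of [delta_delta_ct()] recovers
#' exactly these relative expressions: `ct_reference` is drawn around
#' `base_ct` and `ct_target = ct_reference + base_dct - log2_expression`.
#'
#' @param data Dataset with meteorological columns.
#' @param expression_links Named list gene -> named numeric per-factor
#'   log2 slopes (unnamed factors count 0).
#' @param reference_gene Internal reference gene name (default
#'   `"GAPDH"`); may not appear among the link targets.
#' @param seed Integer seed.
#' @param noise_log2 SD of log2 expression noise. Default 0.25.
#' @param base_ct Mean reference-gene Ct. Default 20.
#' @param base_dct Baseline (ct_target - ct_reference) at expression 1.
#'   Default 5.
#' @return Long data frame: `site, season, gene, ct_target,
#'   ct_reference`.
#' @export
generate_qpcr <- function(data, expression_links, reference_gene = "GAPDH",
                          seed, noise_log2 = 0.25, base_ct = 20,
                          base_dct = 5) {
  validate_dataset(data)
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  if (is.null(expression_links) || length(expression_links) == 0L) {
    stop("`expression_links` must name at least one gene", call. = FALSE)
  }
  if (reference_gene %in% names(expression_links)) {
    stop(sprintf("reference gene '%s' may not be a link target",
                 reference_gene), call. = FALSE)
  }
  set.seed(seed)
  x <- as.matrix(data[, meteo_factors()])
  z <- scale(x)
  z[is.nan(z)] <- 0  # constant factor column: no contribution
  out <- list()
  for (gene in names(expression_links)) {
    v <- stats::setNames(numeric(8L), meteo_factors())
    link <- expression_links[[gene]]
    bad <- setdiff(names(link), meteo_factors())
    if (length(bad) > 0L) {
      stop("unknown factor(s) in link for gene ", gene, ": ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    v[names(link)] <- link
    log2_expr <- drop(z %*% v) +
      if (noise_log2 > 0) stats::rnorm(nrow(data), 0, noise_log2) else 0
    ct_ref <- base_ct + stats::rnorm(nrow(data), 0, 0.1)
    out[[gene]] <- data.frame(
      site = data$site, season = data$season, gene = gene,
      ct_target = ct_ref + base_dct - log2_expr,
      ct_reference = ct_ref, stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Generate a full synthetic survey dataset
#'
#' Runs [generate_meteo()] then [generate_catechins()] (and, when
#' expression links are configured, [generate_qpcr()], attached as
#' attribute `qpcr`). Sub-stage seeds are derived deterministically from
#' the config seed.
#'
#' @param config A [generator_config()].
#' @return Dataset data frame with meteorological, catechin and group-sum
#'   columns; attribute `qpcr` holds the Ct table when links are set.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  data <- generate_meteo(config)
  data <- generate_catechins(data, coefficients = config$coefficients,
                             noise_sd = config$noise_sd,
                             seed = config$seed + 1L)
  if (!is.null(config$expression_links)) {
    attr(data, "qpcr") <- generate_qpcr(
      data, config$expression_links, seed = config$seed + 2L
    )
  }
  attr(data, "provenance") <- sprintf("synthetic(seed=%d)", config$seed)
  data
}
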