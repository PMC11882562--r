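# Per-catechin ordinary least squares on all eight meteorological factors,
# with the chemometric validation triple: RMSEC (calibration residual),
# RMSECV (cross-validation) and RMSEP (held-out prediction).

design_matrix <- function(data) {
  as.matrix(data[, meteo_factors()])
}

check_full_rank <- function(X) {
  Xc <- cbind(1, X)
  qrd <- qr(Xc)
  if (qrd$rank < ncol(Xc)) {
    keep <- qrd$pivot[seq_len(qrd$rank)]
    dropped <- setdiff(seq_len(ncol(Xc)), keep)
    cols <- colnames(Xc) %||% c("(intercept)", colnames(X))
    cols[1L] <- "(intercept)"
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(cols[dropped], collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Fit a per-catechin OLS model on the eight meteorological factors
#'
#' Least-squares fit of `response ~ rainfall + ... + irradiance` with
#' intercept. RMSEC (root mean squared calibration residual on the
#' training records) is attached to the returned model. Requires at
#' least 10 records (8 slopes + intercept + 1) and a full-rank design.
#'
#' @param data Dataset data frame containing the factor columns and the
#'   response column.
#' @param response Response column name.
#' @return A [catechin_model()] with `rmsec` filled.
#' @export
#' @examples
#' d <- generate_dataset(generator_config(seed = 2))
#' fit_ols(d, "egcg")
fit_ols <- function(data, response) {
  validate_dataset(data)
  if (!response %in% names(data)) {
    stop("response column not found: ", response, call. = FALSE)
  }
  if (nrow(data) < 10L) {
    stop("need at least 10 records to fit 8 slopes plus intercept",
         call. = FALSE)
  }
  X <- design_matrix(data)
  check_full_rank(X)
  y <- data[[response]]
  fit <- stats::lm.fit(cbind(`(intercept)` = 1, X), y)
  beta <- fit$coefficients
  rmsec <- sqrt(mean(fit$residuals^2))
  catechin_model(
    response = response,
    intercept = beta[["(intercept)"]],
    coefficients = beta[meteo_factors()],
    rmsec = rmsec
  )
}

#' Cross-validated prediction error (RMSECV)
#'
#' Root mean squared out-of-fold prediction error of the OLS model.
#' `folds = "loo"` (default) performs leave-one-out; an integer k gives
#' k-fold cross-validation with a deterministic seeded fold assignment.
#' `folds = n` is identical to leave-one-out.
#'
#' @param data Dataset data frame.
#' @param response Response column name.
#' @param folds `"loo"` or an integer number of folds in \[2, n\].
#' @param seed Seed for the k-fold assignment (required when `folds` is
#'   numeric and `< n`).
#' @return RMSECV in percent dry mass.
#' @export
rmsecv <- function(data, response, folds = "loo", seed = NULL) {
  validate_dataset(data)
  n <- nrow(data)
  if (identical(folds, "loo")) {
    assign <- seq_len(n)
  } else {
    folds <- as.integer(folds)
    if (folds < 2L || folds > n) {
      stop("`folds` must be 'loo' or an integer in [2, n]", call. = FALSE)
    }
    if (folds == n) {
      assign <- seq_len(n)
    } else {
      if (is.null(seed)) {
        stop("k-fold cross-validation requires a `seed`", call. = FALSE)
      }
      set.seed(seed)
      assign <- sample(rep_len(seq_len(folds), n))
    }
  }
  X <- cbind(`(intercept)` = 1, design_matrix(data))
  y <- data[[response]]
  if (is.null(y)) stop("response column not found: ", response,
                       call. = FALSE)
  err <- numeric(n)
  for (f in unique(assign)) {
    test <- assign == f
    Xtr <- X[!test, , drop = FALSE]
    if (qr(Xtr)$rank < ncol(Xtr)) {
      stop(sprintf("fold %s has a rank-deficient training design", f),
           call. = FALSE)
    }
    beta <- stats::lm.fit(Xtr, y[!test])$coefficients
    err[test] <- y[test] - drop(X[test, , drop = FALSE] %*% beta)
  }
  sqrt(mean(err^2))
}

#' Held-out prediction error (RMSEP)
#'
#' Fits the OLS model on the training dataset and reports the root mean
#' squared prediction error on the test dataset. Train and test must be
#' disjoint in (site, season) unless `allow_overlap = TRUE` (useful only
#' for the degenerate check RMSEP == RMSEC on identical sets).
#'
#' @param train,test Dataset data frames.
#' @param response Response column name.
#' @param allow_overlap Permit shared (site, season) records.
#' @return RMSEP in percent dry mass.
#' @export
rmsep <- function(train, test, response, allow_overlap = FALSE) {
  validate_dataset(train)
  validate_dataset(test)
  if (!allow_overlap) {
    shared <- intersect(paste(train$site, train$season),
                        paste(test$site, test$season))
    if (length(shared) > 0L) {
      stop("train and test overlap in (site, season): ",
           paste(utils::head(shared, 3L), collapse = "; "), call. = FALSE)
    }
  }
  model <- fit_ols(train, response)
  pred <- predict(model, test, warn_negative = FALSE)
  sqrt(mean((test[[response]] - pred)^2))
}

#' Seeded stratified train/test split
#'
#' Splits a dataset into train and test parts, by default 70/30
#' stratified by season so every season keeps representation in both
#' parts.
#'
#' @param data Dataset data frame.
#' @param prop Training proportion. Default 0.7.
#' @param stratify Column to stratify on (`"season"` by default), or
#'   `NULL` for a simple random split.
#' @param seed Integer seed (mandatory).
#' @return List with elements `train` and `test`.
#' @export
split_dataset <- function(data, prop = 0.7, stratify = "season", seed) {
  if (missing(seed)) stop("`seed` is mandatory for the split", call. = FALSE)
  if (prop <= 0 || prop >= 1) stop("`prop` must be in (0, 1)", call. = FALSE)
  set.seed(seed)
  n <- nrow(data)
  idx <- seq_len(n)
  if (is.null(stratify)) {
    train_idx <- sort(sample(idx, round(prop * n)))
  } else {
    strata <- split(idx, data[[stratify]])
    train_idx <- sort(unlist(lapply(strata, function(s) {
      sample(s, max(1L, round(prop * length(s))))
    }), use.names = FALSE))
  }
  list(train = data[train_idx, , drop = FALSE],
       test = data[-train_idx, , drop = FALSE])
}

#' Fit the full model table with validation metrics
#'
#' Fits one OLS model per catechin, computes RMSECV (leave-one-out by
#' default) and, when `prop < 1`, RMSEP on a seeded stratified held-out
#' split, and assembles everything into a [coef_table()] in the
#' published model-table layout.
#'
#' @param data Dataset with catechin columns.
#' @param responses Responses to fit (default all seven monomers).
#' @param folds Passed to [rmsecv()].
#' @param prop Training proportion for the RMSEP split, or 1 to skip
#'   RMSEP.
#' @param seed Seed for the split (and k-fold assignment).
#' @return A [coef_table()] with provenance `"fitted"`.
#' @export
fit_model_table <- function(data, responses = catechin_names(),
                            folds = "loo", prop = 0.7, seed = 1) {
  validate_dataset(data, require_catechins = TRUE)
  parts <- if (prop < 1) split_dataset(data, prop = prop, seed = seed)
  models <- lapply(responses, function(r) {
    m <- fit_ols(data, r)
    m$rmsecv <- rmsecv(data, r, folds = folds, seed = seed)
    if (prop < 1) m$rmsep <- rmsep(parts$train, parts$test, r)
    m
  })
  models_to_table(models)
}
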