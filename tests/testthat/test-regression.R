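test_that("noise-free synthetic data returns the generating coefficients", {
  cfg <- generator_config(seed = 41)
  d <- generate_meteo(cfg)
  d <- generate_catechins(d, noise_sd = 0, seed = 41)
  tb <- tieguanyin_models()
  for (resp in catechin_names()) {
    fit <- fit_ols(d, resp)
    truth <- get_model(tb, resp)
    expect_lt(max(abs(fit$coefficients - truth$coefficients)), 1e-6)
    expect_lt(abs(fit$intercept - truth$intercept), 1e-6)
    expect_lt(fit$rmsec, 1e-9)
  }
})

test_that("coefficient error shrinks with sample size under noise", {
  rmse_at <- function(n_sites, seed) {
    d <- generate_dataset(generator_config(n_sites = n_sites, seed = seed))
    tb <- tieguanyin_models()
    errs <- unlist(lapply(catechin_names(), function(resp) {
      fit <- fit_ols(d, resp)
      truth <- get_model(tb, resp)
      fit$coefficients - truth$coefficients
    }))
    sqrt(mean(errs^2))
  }
  expect_lt(rmse_at(100, seed = 42), rmse_at(10, seed = 42))
})

test_that("degenerate fits are handled explicitly", {
  d <- generate_dataset(generator_config(seed = 43))
  d$flat <- 3.2
  fit <- fit_ols(d, "flat")
  expect_equal(fit$intercept, 3.2, tolerance = 1e-9)
  expect_lt(max(abs(fit$coefficients)), 1e-9)
  expect_equal(fit$rmsec, 0, tolerance = 1e-12)
  # duplicated factor information: named rank-deficiency error
  d2 <- d
  d2$eat <- 2 * d2$temp_avg
  expect_error(fit_ols(d2, "egcg"), "rank deficient")
  expect_error(fit_ols(d[1:5, ], "egcg"), "at least 10")
})

test_that("prediction is affine in the meteorological vector", {
  tb <- tieguanyin_models()
  m <- get_model(tb, "ecg")
  set.seed(44)
  for (rep in 1:10) {
    m1 <- setNames(runif(8, 0, 10), meteo_factors())
    m2 <- setNames(runif(8, 0, 10), meteo_factors())
    a <- runif(1)
    expect_equal(predict(m, a * m1 + (1 - a) * m2, warn_negative = FALSE),
                 a * predict(m, m1, warn_negative = FALSE) +
                   (1 - a) * predict(m, m2, warn_negative = FALSE),
                 tolerance = 1e-10)
  }
})

test_that("the reference equations reproduce the published optima", {
  tb <- tieguanyin_models()
  opt <- tieguanyin_optima()
  expect_equal(round(predict(get_model(tb, "egcg"), opt$egcg), 2), 14.46)
  # published C optimum printed as 4.58 from unrounded internals; the
  # printed rounded coefficients give 4.61, within 1% relative
  c_hat <- predict(get_model(tb, "c"), opt$c)
  expect_equal(round(c_hat, 2), 4.61)
  expect_lt(abs(c_hat - 4.58) / 4.58, 0.01)
  expect_equal(predict(get_model(tb, "egcg"),
                       setNames(rep(0, 8), meteo_factors())), 8.637)
  # negative extrapolations are flagged, not clipped
  far <- setNames(rep(0, 8), meteo_factors())
  far["ground_temp"] <- 200
  expect_warning(p <- predict(get_model(tb, "egcg"), far), "negative")
  expect_lt(p, 0)
})

test_that("cross-validation error behaves like an out-of-sample error", {
  cfg <- generator_config(seed = 45)
  d <- generate_meteo(cfg)
  d0 <- generate_catechins(d, noise_sd = 0, seed = 45)
  expect_lt(rmsecv(d0, "egcg"), 1e-6)
  # k = n folds is exactly leave-one-out
  expect_equal(rmsecv(d0, "gcg", folds = nrow(d0)),
               rmsecv(d0, "gcg", folds = "loo"), tolerance = 1e-12)
  # RMSECV >= RMSEC in nearly all noisy replicates
  wins <- 0L
  for (r in 1:50) {
    dn <- generate_catechins(d, seed = 500 + r)
    if (rmsecv(dn, "egcg") >= fit_ols(dn, "egcg")$rmsec) wins <- wins + 1L
  }
  expect_gte(wins / 50, 0.9)
})

test_that("held-out prediction error matches its definition", {
  cfg <- generator_config(n_sites = 20, seed = 46)
  d <- generate_meteo(cfg)
  d0 <- generate_catechins(d, noise_sd = 0, seed = 46)
  parts <- split_dataset(d0, seed = 46)
  expect_lt(rmsep(parts$train, parts$test, "egcg"), 1e-6)
  expect_error(rmsep(d0, d0[1:12, ], "egcg"), "overlap")
  # identical sets under the override: RMSEP equals RMSEC
  expect_equal(rmsep(d0, d0, "egcg", allow_overlap = TRUE),
               fit_ols(d0, "egcg")$rmsec, tolerance = 1e-10)
  # noisy 70/30 split: error within twice the generating noise
  dn <- generate_catechins(d, seed = 47)
  parts <- split_dataset(dn, seed = 47)
  expect_lt(rmsep(parts$train, parts$test, "egcg"),
            2 * default_noise_sd()[["egcg"]])
})

test_that("stratified splits keep each season in both parts", {
  d <- generate_dataset(generator_config(seed = 48))
  parts <- split_dataset(d, prop = 0.7, seed = 48)
  expect_setequal(unique(parts$train$season),
                  c("spring", "summer", "autumn"))
  expect_setequal(unique(parts$test$season),
                  c("spring", "summer", "autumn"))
  expect_equal(nrow(parts$train) + nrow(parts$test), nrow(d))
  expect_identical(split_dataset(d, seed = 48)$train$site,
                   parts$train$site)
  expect_error(split_dataset(d, prop = 0.7), "seed")
})

test_that("the fitted model table mirrors the published layout", {
  d <- generate_dataset(generator_config(seed = 49))
  tab <- fit_model_table(d, seed = 49)
  expect_s3_class(tab, "coef_table")
  expect_setequal(tab$response, catechin_names())
  expect_true(all(c("rmsep", "rmsecv", "rmsec") %in% names(tab)))
  expect_true(all(tab$rmsec >= 0 & tab$rmsecv >= 0 & tab$rmsep >= 0))
  path <- withr::local_tempfile(fileext = ".csv")
  write_coef_table(tab, path)
  back <- read_coef_table(path)
  expect_equal(back$intercept, tab$intercept, tolerance = 1e-9)
})
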