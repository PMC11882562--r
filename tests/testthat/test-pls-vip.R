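test_that("PLS1 with full components reproduces least squares", {
  set.seed(11)
  for (rep in 1:5) {
    X <- matrix(rnorm(30 * 8), 30, 8,
                dimnames = list(NULL, meteo_factors()))
    y <- rnorm(30)
    fit <- fit_pls1(X, y, ncomp = 8)
    ols <- lm.fit(cbind(1, X), y)$coefficients
    expect_equal(unname(fit$coefficients), unname(ols[-1L]),
                 tolerance = 1e-8)
    expect_equal(fit$intercept, unname(ols[1L]), tolerance = 1e-8)
  }
})

test_that("exact linear responses are fitted exactly", {
  set.seed(12)
  X <- matrix(rnorm(25 * 8), 25, 8, dimnames = list(NULL, meteo_factors()))
  b <- rnorm(8)
  y <- drop(2 + X %*% b)
  fit8 <- fit_pls1(X, y, ncomp = 8)
  expect_lt(max(abs(predict(fit8, X) - y)), 1e-8)
  auto <- fit_pls1(X, y, ncomp = "auto")
  expect_lt(max(abs(predict(auto, X) - y)), 1e-6)
})

test_that("single-predictor PLS equals simple regression", {
  set.seed(13)
  X <- matrix(rnorm(20), 20, 1, dimnames = list(NULL, "rainfall"))
  y <- 1 + 2 * X[, 1L] + rnorm(20, 0, 0.3)
  fit <- fit_pls1(X, y, ncomp = 1)
  ols <- coef(lm(y ~ X[, 1L]))
  expect_equal(unname(fit$coefficients), unname(ols[2L]),
               tolerance = 1e-10)
  expect_equal(vip_scores(fit), c(rainfall = 1))
})

test_that("scores are orthogonal and weights unit-norm", {
  d <- generate_dataset(generator_config(seed = 14))
  X <- as.matrix(d[, meteo_factors()])
  for (resp in c("egcg", "c", "cg")) {
    fit <- fit_pls1(X, d[[resp]], ncomp = 4)
    G <- crossprod(fit$Tm)
    expect_lt(max(abs(G[upper.tri(G)])), 1e-8)
    expect_equal(unname(colSums(fit$W^2)), rep(1, fit$ncomp),
                 tolerance = 1e-12)
  }
})

test_that("degenerate inputs are refused", {
  X <- matrix(rnorm(16), 8, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(fit_pls1(X, rep(1, 8)), "degenerate response")
  expect_error(fit_pls1(X[1:2, ], rnorm(2)), "at least 3")
  fit <- fit_pls1(X, rnorm(8), ncomp = 2)
  expect_error(fit_pls1(X, rnorm(8), ncomp = 9), "ncomp")
})

test_that("VIP scores satisfy Wold's normalization on every fit", {
  d <- generate_dataset(generator_config(seed = 15))
  X <- as.matrix(d[, meteo_factors()])
  for (resp in catechin_names()) {
    for (a in c(1, 3, "auto")) {
      fit <- fit_pls1(X, d[[resp]], ncomp = a, response = resp)
      v <- vip_scores(fit)
      expect_equal(sum(v^2), 8, tolerance = 1e-9)
      expect_true(all(v >= 0))
    }
  }
})

test_that("a single driving factor takes the whole importance budget", {
  # orthogonal zero-mean design, noise-free response on factor 3 only
  Q <- orthogonal_design(16, 8, seed = 16)
  colnames(Q) <- meteo_factors()
  y <- 3 * Q[, 3L]
  fit <- fit_pls1(Q, y, ncomp = 1)
  v <- vip_scores(fit)
  expect_equal(unname(v[3L]), sqrt(8), tolerance = 1e-8)
  expect_lt(max(v[-3L]), 1e-8)
  expect_identical(names(which(v > 1)), "eat")
})

test_that("VIP agrees with the mixOmics reference implementation", {
  d <- generate_dataset(generator_config(seed = 17))
  X <- as.matrix(d[, meteo_factors()])
  for (resp in c("egcg", "ec")) {
    for (a in c(2L, 4L)) {
      fit <- fit_pls1(X, d[[resp]], ncomp = a)
      ref <- mixOmics::pls(X, d[[resp]], ncomp = a, mode = "regression",
                           scale = TRUE)
      expect_equal(unname(vip_scores(fit)),
                   unname(mixOmics::vip(ref)[, a]), tolerance = 1e-6)
    }
  }
})

test_that("screening selects strictly above the threshold", {
  d <- generate_dataset(generator_config(seed = 18))
  vt <- vip_table(d, responses = c("egcg", "ecg"), ncomp = 2)
  links <- screen_factors(vt)
  expect_true(all(links$vip > 1))
  manual <- sum(vt$vip > 1)
  expect_equal(nrow(links), manual)
  all_links <- screen_factors(vt, threshold = 0)
  expect_equal(nrow(all_links), 16L)
  expect_identical(colnames(vt$selected), c("egcg", "ecg"))
})

test_that("a rainfall-only driver is screened out of eight factors", {
  # synthetic EGCG driven only by rainfall at study noise, n = 300
  b <- default_meteo_bounds()
  hits <- 0L
  n_rep <- 100L
  for (r in seq_len(n_rep)) {
    cfg <- generator_config(n_sites = 100, seed = 5000 + r)
    d <- generate_meteo(cfg)
    set.seed(6000 + r)
    d$egcg <- 8.637 + 0.367 * d$rainfall + rnorm(nrow(d), 0, 0.1559)
    fit <- fit_pls1(as.matrix(d[, meteo_factors()]), d$egcg, ncomp = 2)
    v <- vip_scores(fit)
    if (v[["rainfall"]] > 1 && which.max(v) == 1L) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.95)
})

test_that("VIP tables write and reload consistently", {
  d <- generate_dataset(generator_config(seed = 19))
  vt <- vip_table(d, responses = c("egcg", "c"), ncomp = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  links <- withr::local_tempfile(fileext = ".csv")
  write_vip_table(vt, path, links)
  back <- utils::read.csv(path)
  expect_equal(back$egcg, unname(vt$vip[, "egcg"]), tolerance = 1e-9)
  lk <- utils::read.csv(links)
  expect_true(all(lk$vip > 1))
})
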