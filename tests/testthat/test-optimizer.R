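test_that("problem construction validates targets, boxes and thresholds", {
  tb <- tieguanyin_models()
  box <- tieguanyin_factor_box()
  pr <- build_problem("egcg", tb, box,
                      thresholds = data.frame(
                        response = c("gcg", "ecg", "cg"),
                        low = c(0, 0, 0), high = c(5, 8, 1)))
  expect_setequal(pr$members, c("gcg", "ecg", "cg"))  # never the target
  expect_equal(unname(pr$box[, "low"]), box$low)
  expect_error(build_problem("theanine", tb, box), "theanine")
  expect_error(build_problem("egcg", tb, box,
                             thresholds = data.frame(
                               response = c("gcg", "ecg", "cg"),
                               low = c(2, 0, 0), high = c(1, 8, 1))),
               "low > high")
  expect_error(build_problem("egcg", tb, box), "thresholds")
  d <- generate_dataset(generator_config(seed = 61))
  pr2 <- build_problem("egcg", tb, d)
  expect_equal(unname(pr2$box["rainfall", ]), range(d$rainfall))
  expect_equal(pr2$thresholds$low,
               vapply(pr2$members, function(m) min(d[[m]]), numeric(1L)),
               ignore_attr = TRUE)
})

test_that("the box-only optimum follows the coefficient sign rule", {
  tb <- tieguanyin_models()
  box <- tieguanyin_factor_box()
  m <- get_model(tb, "c")
  res <- solve_lp(build_problem("c", tb, box, group = "none"))
  expect_equal(res$status, "optimal")
  expected <- ifelse(m$coefficients > 0, box$high, box$low)
  expect_equal(unname(res$argmax), unname(expected))
  expect_equal(res$objective,
               predict(m, res$argmax, warn_negative = FALSE))
  expect_length(res$binding, 8L)
})

test_that("the solver matches the 256-vertex oracle on random problems", {
  set.seed(62)
  n_problems <- 200L
  for (i in seq_len(n_problems)) {
    box <- random_box()
    tb <- random_coef_table("y", box)
    pr <- build_problem("y", tb, box, group = "none")
    a <- solve_lp(pr)
    b <- vertex_oracle(pr)
    expect_identical(a$status, "optimal")
    expect_equal(a$objective, b$objective, tolerance = 1e-12)
    expect_equal(unname(a$argmax), unname(b$argmax), tolerance = 1e-12)
  }
})

test_that("the oracle refuses grouped problems and handles 1-factor boxes", {
  tb <- tieguanyin_models()
  d <- generate_dataset(generator_config(seed = 63))
  pr <- build_problem("egcg", tb, d)
  expect_error(vertex_oracle(pr), "box-only")
})

# Independent grouped-LP oracle: SciPy's HiGHS solver through the system
# python. Maximizes obj over box + two-sided linear constraints.
scipy_lp_max <- function(obj_b, A, lo, hi, box_lo, box_hi) {
  prob <- list(c = -obj_b,
               A_ub = rbind(A, -A),
               b_ub = c(hi, -lo),
               lo = box_lo, hi = box_hi)
  fin <- tempfile(fileext = ".json")
  fout <- tempfile(fileext = ".json")
  fpy <- tempfile(fileext = ".py")
  jsonlite::write_json(prob, fin, digits = NA)
  writeLines(c(
    "import json, sys",
    "import numpy as np",
    "from scipy.optimize import linprog",
    "p = json.load(open(sys.argv[1]))",
    "res = linprog(c=np.array(p['c']), A_ub=np.array(p['A_ub']),",
    "              b_ub=np.array(p['b_ub']),",
    "              bounds=list(zip(p['lo'], p['hi'])), method='highs')",
    "json.dump({'success': bool(res.success),",
    "           'fun': float(res.fun) if res.success else None},",
    "          open(sys.argv[2], 'w'))"
  ), fpy)
  status <- system2("python", c(fpy, fin, fout), stdout = FALSE)
  stopifnot(status == 0L)
  out <- jsonlite::read_json(fout)
  stopifnot(isTRUE(out$success))
  -out$fun
}

test_that("grouped optima respect thresholds and agree with HiGHS", {
  tb <- tieguanyin_models()
  d <- generate_dataset(generator_config(seed = 64))
  fac <- meteo_factors()
  l <- vapply(fac, function(f) min(d[[f]]), numeric(1L))
  u <- vapply(fac, function(f) max(d[[f]]), numeric(1L))
  for (target in c("egcg", "ecg", "c", "ec")) {
    pr <- build_problem(target, tb, d)
    res <- solve_lp(pr)
    expect_identical(res$status, "optimal")
    # feasibility of the reported point
    expect_true(all(res$argmax >= l - 1e-9 * pmax(1, abs(l)) &
                      res$argmax <= u + 1e-9 * pmax(1, abs(u))))
    for (i in seq_along(pr$members)) {
      expect_gte(res$co_predictions[[i]], pr$thresholds$low[i] - 1e-9)
      expect_lte(res$co_predictions[[i]], pr$thresholds$high[i] + 1e-9)
    }
    obj <- get_model(tb, target)
    rows <- lapply(pr$members, function(m) get_model(tb, m))
    A <- do.call(rbind, lapply(rows, function(m)
      unname(m$coefficients)))
    b0 <- vapply(rows, function(m) m$intercept, numeric(1L))
    ref <- scipy_lp_max(unname(obj$coefficients), A,
                        lo = pr$thresholds$low - b0,
                        hi = pr$thresholds$high - b0,
                        box_lo = unname(l), box_hi = unname(u))
    expect_equal(res$objective, ref + obj$intercept, tolerance = 1e-7)
  }
})

test_that("adding thresholds never improves the optimum", {
  tb <- tieguanyin_models()
  set.seed(65)
  for (i in 1:20) {
    d <- generate_dataset(generator_config(n_sites = 5,
                                           seed = 6500 + i))
    for (target in c("egcg", "egc")) {
      free <- solve_lp(build_problem(target, tb, d, group = "none"))
      cons <- solve_lp(build_problem(target, tb, d))
      if (cons$status == "optimal") {
        expect_lte(cons$objective, free$objective + 1e-9)
      }
    }
  }
})

test_that("impossible thresholds are certified infeasible", {
  tb <- tieguanyin_models()
  box <- tieguanyin_factor_box()
  thr <- data.frame(response = c("gcg", "ecg", "cg"),
                    low = c(0, 50, 0), high = c(5, 60, 1))
  res <- solve_lp(build_problem("egcg", tb, box, thresholds = thr))
  expect_identical(res$status, "infeasible")
  expect_match(res$certificate, "ecg")
  # non-finite box with a paying direction is unbounded
  box2 <- box
  box2$high[box2$factor == "rainfall"] <- Inf
  res2 <- solve_lp(build_problem("egcg", tb, box2, group = "none"))
  expect_identical(res2$status, "unbounded")
})

test_that("importance weights steer the argmax but not the reporting", {
  tb <- tieguanyin_models()
  box <- tieguanyin_factor_box()
  w1 <- setNames(rep(1, 8), meteo_factors())
  base <- solve_lp(build_problem("egcg", tb, box, group = "none"))
  same <- solve_lp(build_problem("egcg", tb, box, group = "none",
                                 objective_weights = w1))
  expect_equal(same$argmax, base$argmax)
  # zero weight on rainfall: the rainfall term no longer pays, so the
  # tie-break sends it to its lower bound and the raw prediction drops
  w0 <- w1
  w0["rainfall"] <- 0
  res <- solve_lp(build_problem("egcg", tb, box, group = "none",
                                objective_weights = w0))
  expect_equal(unname(res$argmax["rainfall"]), 1.13)
  m <- get_model(tb, "egcg")
  expect_equal(res$objective, predict(m, res$argmax, warn_negative = FALSE))
  expect_lt(res$objective, base$objective)
  expect_error(build_problem("egcg", tb, box, group = "none",
                             objective_weights = w1[-1]), "rainfall")
})

test_that("group reports tabulate each member and its group sum", {
  tb <- tieguanyin_models()
  box <- tieguanyin_factor_box()
  rep_tec <- optimize_group_report("tec", tb, box, box_only = TRUE)
  expect_setequal(rep_tec$target, catechin_groups()$tec)
  expect_true(all(rep_tec$status == "optimal"))
  for (i in seq_len(nrow(rep_tec))) {
    preds <- unlist(rep_tec[i, paste0("pred_", catechin_groups()$tec)])
    expect_equal(rep_tec$tec_sum[i], sum(preds), tolerance = 1e-9)
    expect_equal(rep_tec$objective[i],
                 unname(preds[paste0("pred_", rep_tec$target[i])]),
                 tolerance = 1e-12)
  }
  # published worked example: TEC at the ECG optimum exceeds 19%
  opt <- tieguanyin_optima()$ecg
  tec_at <- sum(vapply(catechin_groups()$tec, function(m)
    predict(get_model(tb, m), opt, warn_negative = FALSE), numeric(1L)))
  expect_gte(tec_at, 19)
  expect_equal(round(tec_at, 2), 20.46)
  expect_error(optimize_group_report("tec", tb[tb$response != "cg", ],
                                     box, box_only = TRUE), "cg")
})
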