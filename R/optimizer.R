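# Grouped linear programming over the meteorological box: maximize one
# catechin's predicted concentration subject to per-factor bounds and
# two-sided linear threshold constraints on the other catechins of its
# group (TEC or TNEC). The objective and all constraints are linear, so
# the optimum sits at a vertex of the feasible polytope; the solver
# enumerates every candidate vertex (active-set combinations of box
# bounds and group thresholds) exactly, which is both exact and
# deterministic at this problem size (8 variables, at most 6 threshold
# rows). Ties are broken toward the lexicographically smallest argmax.

as_factor_box <- function(bounds) {
  fac <- meteo_factors()
  if (is.data.frame(bounds) && all(c("factor", "low", "high") %in%
                                   names(bounds))) {
    i <- match(fac, bounds$factor)
    if (anyNA(i)) {
      stop("factor box missing factor(s): ",
           paste(fac[is.na(i)], collapse = ", "), call. = FALSE)
    }
    box <- cbind(low = bounds$low[i], high = bounds$high[i])
  } else if (is.data.frame(bounds)) {
    validate_dataset(bounds)
    x <- as.matrix(bounds[, fac])
    box <- cbind(low = apply(x, 2L, min), high = apply(x, 2L, max))
  } else {
    stop("`bounds` must be a factor box or a dataset data frame",
         call. = FALSE)
  }
  rownames(box) <- fac
  if (any(box[, "low"] > box[, "high"])) {
    bad <- fac[box[, "low"] > box[, "high"]]
    stop("low > high for factor(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  box
}

#' Build a grouped catechin optimization problem
#'
#' Formulates the linear program "maximize the predicted concentration of
#' `target` over the meteorological box, keeping every other catechin of
#' the same group (TEC or TNEC) between thresholds". The box is taken
#' from an explicit `factor, low, high` table or from the observed
#' per-factor min/max of a dataset; co-member thresholds default to each
#' co-member's observed min/max when a dataset is supplied, and can be
#' overridden or dropped (`group = "none"` gives the box-only problem).
#'
#' @param target Target catechin name.
#' @param models [coef_table()] covering the target (and, with group
#'   constraints, its co-members).
#' @param bounds Factor box data frame (`factor, low, high`) or a
#'   dataset whose observed ranges define the box.
#' @param group `"auto"` (constrain the target's TEC/TNEC co-members) or
#'   `"none"` (box-only).
#' @param thresholds Optional data frame `response, low, high` giving
#'   explicit co-member thresholds; required when `group = "auto"` and
#'   `bounds` is not a dataset.
#' @param objective_weights Optional named per-factor weights (e.g. VIP
#'   scores) multiplying the target's slopes in the objective. The
#'   reported objective remains the unweighted predicted concentration
#'   at the argmax; the weights only steer which optimum is selected.
#' @return Object of class `opt_problem`.
#' @export
#' @examples
#' pr <- build_problem("c", tieguanyin_models(), tieguanyin_factor_box(),
#'                     group = "none")
#' solve_lp(pr)
build_problem <- function(target, models, bounds, group = c("auto", "none"),
                          thresholds = NULL, objective_weights = NULL) {
  group <- match.arg(group)
  if (!target %in% models$response) {
    stop(sprintf("target '%s' not present in the coefficient table",
                 target), call. = FALSE)
  }
  box <- as_factor_box(bounds)  # non-finite bounds surface in solve_lp
  grp <- catechin_groups()
  group_name <- if (target %in% grp$tec) "tec" else
    if (target %in% grp$tnec) "tnec" else NA_character_
  members <- character(0)
  thr <- NULL
  if (group == "auto") {
    if (is.na(group_name)) {
      stop(sprintf("target '%s' belongs to no catechin group", target),
           call. = FALSE)
    }
    members <- setdiff(grp[[group_name]], target)
    if (is.null(thresholds)) {
      if (!(is.data.frame(bounds) && "site" %in% names(bounds))) {
        stop("group thresholds must be supplied explicitly unless ",
             "`bounds` is a dataset", call. = FALSE)
      }
      miss <- setdiff(members, names(bounds))
      if (length(miss) > 0L) {
        stop("dataset lacks co-member column(s): ",
             paste(miss, collapse = ", "), call. = FALSE)
      }
      thresholds <- data.frame(
        response = members,
        low = vapply(members, function(m) min(bounds[[m]]), numeric(1L)),
        high = vapply(members, function(m) max(bounds[[m]]), numeric(1L)),
        stringsAsFactors = FALSE
      )
    }
    i <- match(members, thresholds$response)
    if (anyNA(i)) {
      stop("thresholds missing co-member(s): ",
           paste(members[is.na(i)], collapse = ", "), call. = FALSE)
    }
    thr <- thresholds[i, c("response", "low", "high")]
    if (any(thr$low > thr$high)) {
      bad <- thr$response[thr$low > thr$high]
      stop("threshold low > high for: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    rownames(thr) <- NULL
  }
  if (!is.null(objective_weights)) {
    miss <- setdiff(meteo_factors(), names(objective_weights))
    if (length(miss) > 0L) {
      stop("objective_weights missing factor(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    if (any(objective_weights < 0)) {
      stop("objective_weights must be >= 0", call. = FALSE)
    }
    objective_weights <- objective_weights[meteo_factors()]
  }
  structure(
    list(target = target, models = models, box = box,
         group_name = group_name, members = members, thresholds = thr,
         objective_weights = objective_weights, sense = "max"),
    class = "opt_problem"
  )
}

#' @export
print.opt_problem <- function(x, ...) {
  cat(sprintf("<opt_problem> maximize %s over the 8-factor box", x$target))
  if (length(x$members) > 0L) {
    cat(sprintf(" with %s thresholds on %s", toupper(x$group_name),
                paste(x$members, collapse = ", ")))
  }
  cat("\n")
  invisible(x)
}

model_row <- function(models, response) {
  m <- get_model(models, response)
  list(b0 = m$intercept, b = m$coefficients)
}

# objective used for vertex selection; per-factor weights (e.g. VIP
# scores) rescale the slopes without touching the reported prediction
objective_row <- function(problem) {
  obj <- model_row(problem$models, problem$target)
  if (!is.null(problem$objective_weights)) {
    obj$b <- obj$b * problem$objective_weights
  }
  obj
}

opt_result <- function(status, argmax = NULL, objective = NA_real_,
                       co_predictions = NULL, binding = character(0),
                       certificate = NULL) {
  structure(list(status = status, argmax = argmax, objective = objective,
                 co_predictions = co_predictions, binding = binding,
                 certificate = certificate),
            class = "opt_result")
}

#' @export
print.opt_result <- function(x, ...) {
  cat(sprintf("<opt_result> status: %s", x$status))
  if (x$status == "optimal") {
    cat(sprintf(", objective %.4f\n  argmax: %s\n", x$objective,
                paste(sprintf("%s=%.4g", names(x$argmax), x$argmax),
                      collapse = ", ")))
    if (length(x$binding) > 0L) {
      cat("  binding:", paste(x$binding, collapse = "; "), "\n")
    }
  } else {
    if (!is.null(x$certificate)) cat(" (", x$certificate, ")", sep = "")
    cat("\n")
  }
  invisible(x)
}

# lexicographic comparison: TRUE if a < b
lex_less <- function(a, b, tol = 1e-12) {
  d <- a - b
  i <- which(abs(d) > tol)
  if (length(i) == 0L) return(FALSE)
  d[i[1L]] < 0
}

#' Solve a grouped catechin optimization problem exactly
#'
#' Exact maximization of the linear objective over the box plus group
#' threshold constraints. Box-only problems are solved by the sign rule
#' (each factor at its upper bound iff its slope is strictly positive,
#' lower bound otherwise -- the lexicographically smallest optimal
#' vertex). Grouped problems are solved by exhaustive active-set vertex
#' enumeration: every combination of binding threshold rows and box
#' bounds that can define a vertex is solved and checked for
#' feasibility; the best feasible vertex wins, ties broken toward the
#' lexicographically smallest argmax over the factor order.
#'
#' @param problem An [build_problem()] object.
#' @param tol Feasibility/tie tolerance. Default 1e-9.
#' @return An `opt_result`: `status` (`"optimal"`, `"infeasible"` or
#'   `"unbounded"`), `argmax` (named factor vector), `objective`
#'   (percent dry mass, equal to the target prediction at the argmax),
#'   `co_predictions` (co-member predictions at the argmax) and
#'   `binding` (constraints active at the optimum).
#' @export
solve_lp <- function(problem, tol = 1e-9) {
  stopifnot(inherits(problem, "opt_problem"))
  obj <- objective_row(problem)
  box <- problem$box
  if (any(!is.finite(box))) {
    dir <- ifelse(obj$b > 0, !is.finite(box[, "high"]),
                  ifelse(obj$b < 0, !is.finite(box[, "low"]), FALSE))
    if (any(dir)) return(opt_result("unbounded"))
  }
  if (length(problem$members) == 0L) {
    x <- ifelse(obj$b > 0, box[, "high"], box[, "low"])
    names(x) <- rownames(box)
    return(finish_result(problem, x, tol))
  }
  # grouped problem: active-set vertex enumeration
  m <- length(problem$members)
  rows <- lapply(problem$members, function(r) model_row(problem$models, r))
  A <- do.call(rbind, lapply(rows, function(r) r$b))      # m x 8
  lo <- problem$thresholds$low - vapply(rows, `[[`, numeric(1L), "b0")
  hi <- problem$thresholds$high - vapply(rows, `[[`, numeric(1L), "b0")
  # quick single-row infeasibility certificate
  for (i in seq_len(m)) {
    rng <- range_over_box(A[i, ], box)
    if (rng[1L] > hi[i] + tol || rng[2L] < lo[i] - tol) {
      return(opt_result(
        "infeasible",
        certificate = sprintf(
          "threshold on '%s' ([%.6g, %.6g]) cannot be met inside the box",
          problem$members[i], problem$thresholds$low[i],
          problem$thresholds$high[i])))
    }
  }
  scale_obj <- max(1, abs(obj$b0) +
                     sum(abs(obj$b) * apply(abs(box), 1L, max)))
  box_tol <- tol * pmax(1, apply(abs(box), 1L, max))
  p <- nrow(box)
  # candidate vertices: every combination of active threshold rows (one
  # side per co-member at most) x free-variable subsets x box-bound
  # assignments for the remaining variables
  bound_grid <- function(idx) {
    g <- as.matrix(expand.grid(rep(list(1:2), length(idx))))
    lowm <- matrix(box[idx, "low"], nrow(g), length(idx), byrow = TRUE)
    highm <- matrix(box[idx, "high"], nrow(g), length(idx), byrow = TRUE)
    ifelse(g == 1L, lowm, highm)
  }
  cands <- list(bound_grid(seq_len(p)))  # all pure box vertices
  sides <- as.matrix(expand.grid(rep(list(0:2), m)))
  for (s in seq_len(nrow(sides))) {
    side <- sides[s, ]
    act <- which(side > 0L)
    k <- length(act)
    if (k == 0L || k > p) next
    rhs <- ifelse(side[act] == 1L, lo[act], hi[act])
    Asub <- A[act, , drop = FALSE]
    for (fs in utils::combn(p, k, simplify = FALSE)) {
      Af <- Asub[, fs, drop = FALSE]
      qrAf <- qr(Af)  # rank test with qr's scale-aware tolerance
      if (qrAf$rank < k) next
      fixed <- setdiff(seq_len(p), fs)
      XF <- bound_grid(fixed)  # 2^(p-k) x (p-k)
      rhs_adj <- matrix(rhs, nrow(XF), k, byrow = TRUE) -
        XF %*% t(Asub[, fixed, drop = FALSE])
      sol <- t(solve(qrAf, t(rhs_adj)))  # 2^(p-k) x k
      X <- matrix(0, nrow(XF), p)
      X[, fs] <- sol
      X[, fixed] <- XF
      cands[[length(cands) + 1L]] <- X
    }
  }
  X <- do.call(rbind, cands)
  # feasibility: inside the box and within every threshold slab
  ok <- rep(TRUE, nrow(X))
  for (j in seq_len(p)) {
    ok <- ok & X[, j] >= box[j, "low"] - box_tol[j] &
      X[, j] <= box[j, "high"] + box_tol[j]
  }
  G <- X %*% t(A)
  for (i in seq_len(m)) {
    ok <- ok & G[, i] >= lo[i] - tol * max(1, abs(lo[i])) &
      G[, i] <= hi[i] + tol * max(1, abs(hi[i]))
  }
  if (!any(ok)) {
    return(opt_result("infeasible",
                      certificate = "joint group thresholds infeasible"))
  }
  X <- X[ok, , drop = FALSE]
  vals <- obj$b0 + drop(X %*% obj$b)
  tied <- which(vals >= max(vals) - tol * scale_obj)
  Xt <- X[tied, , drop = FALSE]
  pick <- do.call(order, as.data.frame(Xt))[1L]
  x <- stats::setNames(Xt[pick, ], rownames(box))
  finish_result(problem, x, tol)
}

range_over_box <- function(a, box) {
  lo <- sum(pmin(a * box[, "low"], a * box[, "high"]))
  hi <- sum(pmax(a * box[, "low"], a * box[, "high"]))
  c(lo, hi)
}

finish_result <- function(problem, x, tol) {
  obj <- model_row(problem$models, problem$target)
  val <- obj$b0 + sum(obj$b * x)
  box <- problem$box
  binding <- character(0)
  for (j in seq_len(nrow(box))) {
    f <- rownames(box)[j]
    if (abs(x[j] - box[j, "low"]) <= tol * max(1, abs(box[j, "low"]))) {
      binding <- c(binding, sprintf("%s at lower bound %.6g", f,
                                    box[j, "low"]))
    } else if (abs(x[j] - box[j, "high"]) <=
               tol * max(1, abs(box[j, "high"]))) {
      binding <- c(binding, sprintf("%s at upper bound %.6g", f,
                                    box[j, "high"]))
    }
  }
  co <- NULL
  if (length(problem$members) > 0L) {
    co <- vapply(problem$members, function(r) {
      rm <- model_row(problem$models, r)
      rm$b0 + sum(rm$b * x)
    }, numeric(1L))
    for (i in seq_along(problem$members)) {
      thr <- problem$thresholds[i, ]
      if (abs(co[i] - thr$low) <= tol * max(1, abs(thr$low))) {
        binding <- c(binding, sprintf("%s at lower threshold %.6g",
                                      problem$members[i], thr$low))
      } else if (abs(co[i] - thr$high) <= tol * max(1, abs(thr$high))) {
        binding <- c(binding, sprintf("%s at upper threshold %.6g",
                                      problem$members[i], thr$high))
      }
    }
  }
  opt_result("optimal", argmax = x, objective = val, co_predictions = co,
             binding = binding)
}

#' Brute-force vertex oracle for box-only problems
#'
#' Evaluates the objective at all `2^p` vertices of the factor box and
#' returns the exact maximum under the same lexicographic tie-break as
#' [solve_lp()]. Only defined for box-only problems; it exists as an
#' independent check of the solver.
#'
#' @param problem A box-only [build_problem()] object.
#' @return An `opt_result`.
#' @export
vertex_oracle <- function(problem) {
  stopifnot(inherits(problem, "opt_problem"))
  if (length(problem$members) > 0L) {
    stop("vertex_oracle only handles box-only problems", call. = FALSE)
  }
  obj <- objective_row(problem)
  box <- problem$box
  p <- nrow(box)
  grid <- as.matrix(expand.grid(rep(list(1:2), p)))
  best <- NULL
  for (g in seq_len(nrow(grid))) {
    x <- ifelse(grid[g, ] == 1L, box[, "low"], box[, "high"])
    names(x) <- rownames(box)
    val <- obj$b0 + sum(obj$b * x)
    if (is.null(best) || val > best$val + 1e-12) {
      best <- list(val = val, x = x)
    } else if (val >= best$val - 1e-12 && lex_less(x, best$x)) {
      best$x <- x
    }
  }
  finish_result(problem, best$x, 1e-9)
}

#' Optimize every catechin of a group and report
#'
#' Runs [build_problem()] + [solve_lp()] for each member of the TEC or
#' TNEC group in turn (each time constraining the remaining members,
#' unless `box_only = TRUE`) and tabulates the optimal conditions, the
#' optimized concentration, the co-member predictions and the group sum
#' at each optimum.
#'
#' @param group `"tec"` or `"tnec"`.
#' @param models [coef_table()] covering the whole group.
#' @param bounds Factor box or dataset (see [build_problem()]).
#' @param thresholds Optional explicit thresholds (see
#'   [build_problem()]).
#' @param box_only Drop the group constraints. Default FALSE.
#' @return Data frame: `target`, `status`, the eight optimal factor
#'   values, `objective`, one `pred_*` column per group member, the
#'   group sum, and `binding` (semicolon-joined). Attribute `results`
#'   holds the full `opt_result` list.
#' @export
optimize_group_report <- function(group = c("tec", "tnec"), models, bounds,
                                  thresholds = NULL, box_only = FALSE) {
  group <- match.arg(group)
  members <- catechin_groups()[[group]]
  miss <- setdiff(members, models$response)
  if (length(miss) > 0L) {
    stop("coefficient table missing group member(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  results <- list()
  rows <- list()
  for (target in members) {
    pr <- build_problem(target, models, bounds,
                        group = if (box_only) "none" else "auto",
                        thresholds = thresholds)
    res <- solve_lp(pr)
    results[[target]] <- res
    if (res$status != "optimal") {
      rows[[target]] <- data.frame(target = target, status = res$status,
                                   stringsAsFactors = FALSE)
      next
    }
    preds <- stats::setNames(numeric(length(members)), members)
    preds[target] <- res$objective
    if (!is.null(res$co_predictions)) {
      preds[names(res$co_predictions)] <- res$co_predictions
    } else {
      for (mbr in setdiff(members, target)) {
        preds[mbr] <- predict(get_model(models, mbr), res$argmax,
                              warn_negative = FALSE)
      }
    }
    row <- cbind(
      data.frame(target = target, status = res$status,
                 stringsAsFactors = FALSE),
      as.data.frame(as.list(res$argmax)),
      data.frame(objective = res$objective),
      stats::setNames(as.data.frame(as.list(preds)),
                      paste0("pred_", members))
    )
    row[[paste0(group, "_sum")]] <- sum(preds)
    row$binding <- paste(res$binding, collapse = "; ")
    rows[[target]] <- row
  }
  out <- do.call(rbind, lapply(rows, function(r) {
    all_cols <- unique(unlist(lapply(rows, names)))
    for (cc in setdiff(all_cols, names(r))) r[[cc]] <- NA
    r[all_cols]
  }))
  rownames(out) <- NULL
  attr(out, "results") <- results
  out
}
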