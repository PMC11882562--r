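# Single-response partial least squares (PLS1) by sequential NIPALS
# extraction, with Wold's Variable Importance in Projection. X and y are
# autoscaled (mean 0, unit variance) before fitting -- the chemometrics
# default for predictors on mixed scales -- and VIP is computed in the
# scaled space.

#' Fit a single-response PLS model (PLS1)
#'
#' Sequential NIPALS extraction on autoscaled data: for each component,
#' the weight vector is the normalized covariance `X'y`, scores
#' `t = X w`, y-loading `q = t'y / t't`, x-loadings `p = X't / t't`, and
#' X and y are deflated before the next component. Extraction is
#' deterministic (no random initialization). With `ncomp = "auto"` the
#' component count minimizing the leave-one-out RMSECV is chosen, capped
#' at `min(n - 1, ncol(X))`, ties resolved toward fewer components.
#'
#' @param X Numeric matrix (n x p) of predictors (columns named).
#' @param y Numeric response vector of length n.
#' @param ncomp Number of latent components, or `"auto"`.
#' @param response Response label carried in the fit.
#' @return Object of class `pls1_fit`: weights `W` (p x A, unit-norm
#'   columns), x-loadings `P`, y-loadings `q`, scores `Tm` (mutually
#'   orthogonal columns), centring/scaling vectors, the implied
#'   regression coefficients on the original scale, and `ncomp`.
#' @export
#' @examples
#' cfg <- generator_config(seed = 4)
#' d <- generate_dataset(cfg)
#' f <- fit_pls1(as.matrix(d[, meteo_factors()]), d$egcg, ncomp = 2)
#' vip_scores(f)
fit_pls1 <- function(X, y, ncomp = "auto", response = "y") {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  p <- ncol(X)
  if (n != length(y)) stop("nrow(X) must equal length(y)", call. = FALSE)
  if (n < 3L) stop("need at least 3 samples to fit PLS", call. = FALSE)
  if (stats::sd(y) == 0) stop("degenerate response: y is constant",
                              call. = FALSE)
  x_sd <- apply(X, 2L, stats::sd)
  if (all(x_sd == 0)) stop("all predictor columns are constant",
                           call. = FALSE)
  a_max <- min(n - 1L, p)
  if (identical(ncomp, "auto")) {
    cv <- vapply(seq_len(a_max), function(a) pls1_loo_rmsecv(X, y, a),
                 numeric(1L))
    ncomp <- which.min(cv)  # which.min takes the first minimum: fewer comps
  }
  ncomp <- as.integer(ncomp)
  if (ncomp < 1L || ncomp > a_max) {
    stop(sprintf("ncomp must be in [1, %d]", a_max), call. = FALSE)
  }
  core <- pls1_core(X, y, ncomp)
  structure(c(core, list(response = response)), class = "pls1_fit")
}

# NIPALS extraction in scaled space; constant columns get scale 1 so they
# contribute nothing without producing NaN.
pls1_core <- function(X, y, ncomp) {
  x_center <- colMeans(X)
  x_scale <- apply(X, 2L, stats::sd)
  x_scale[x_scale == 0] <- 1
  y_center <- mean(y)
  y_scale <- stats::sd(y)
  Xs <- scale(X, center = x_center, scale = x_scale)
  ys <- (y - y_center) / y_scale
  n <- nrow(Xs); p <- ncol(Xs)
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  Tm <- matrix(0, n, ncomp); q <- numeric(ncomp)
  Xd <- Xs; yd <- ys
  a_used <- 0L
  for (a in seq_len(ncomp)) {
    w <- drop(crossprod(Xd, yd))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break  # X carries no further covariance with y
    w <- w / nw
    t_a <- drop(Xd %*% w)
    tt <- sum(t_a^2)
    if (tt < 1e-12) break
    q_a <- sum(t_a * yd) / tt
    p_a <- drop(crossprod(Xd, t_a)) / tt
    W[, a] <- w; P[, a] <- p_a; Tm[, a] <- t_a; q[a] <- q_a
    Xd <- Xd - tcrossprod(t_a, p_a)
    yd <- yd - q_a * t_a
    a_used <- a
  }
  if (a_used == 0L) {
    stop("could not extract any PLS component (no X-y covariance)",
         call. = FALSE)
  }
  W <- W[, seq_len(a_used), drop = FALSE]
  P <- P[, seq_len(a_used), drop = FALSE]
  Tm <- Tm[, seq_len(a_used), drop = FALSE]
  q <- q[seq_len(a_used)]
  # regression vector in scaled space: B = W (P'W)^-1 q
  b_scaled <- drop(W %*% solve(crossprod(P, W), q))
  b <- b_scaled * y_scale / x_scale
  b0 <- y_center - sum(b * x_center)
  list(W = W, P = P, q = q, Tm = Tm, ncomp = a_used,
       x_center = x_center, x_scale = x_scale,
       y_center = y_center, y_scale = y_scale,
       coefficients = stats::setNames(b, colnames(X)), intercept = b0)
}

#' @export
predict.pls1_fit <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  drop(object$intercept + X %*% object$coefficients)
}

#' @export
print.pls1_fit <- function(x, ...) {
  cat(sprintf("<pls1_fit> response '%s', %d component(s), p = %d\n",
              x$response, x$ncomp, nrow(x$W)))
  invisible(x)
}

# Leave-one-out RMSECV of a PLS1 fit with a fixed component count.
pls1_loo_rmsecv <- function(X, y, ncomp) {
  n <- nrow(X)
  err <- numeric(n)
  for (i in seq_len(n)) {
    Xi <- X[-i, , drop = FALSE]
    yi <- y[-i]
    if (stats::sd(yi) == 0) return(Inf)
    fit <- tryCatch(pls1_core(Xi, yi, min(ncomp, nrow(Xi) - 1L)),
                    error = function(e) NULL)
    if (is.null(fit)) return(Inf)
    pred <- drop(fit$intercept + X[i, , drop = FALSE] %*% fit$coefficients)
    err[i] <- y[i] - pred
  }
  sqrt(mean(err^2))
}

#' Variable Importance in Projection (VIP) scores
#'
#' Wold's VIP for a fitted PLS1 model:
#' `VIP_j = sqrt(p * sum_a SS_a w_aj^2 / sum_a SS_a)` with unit-norm
#' weight vectors `w_a` and `SS_a = q_a^2 t_a't_a` the response variance
#' explained by component a (in autoscaled space). By construction
#' `sum_j VIP_j^2 = p`, so VIP > 1 marks predictors carrying more than an
#' equal share of the explained response variance.
#'
#' @param fit A [fit_pls1()] model.
#' @return Named numeric vector of VIP scores (one per predictor).
#' @export
vip_scores <- function(fit) {
  stopifnot(inherits(fit, "pls1_fit"))
  ss <- fit$q^2 * colSums(fit$Tm^2)
  if (sum(ss) <= 0) {
    stop("zero explained response variance; VIP undefined", call. = FALSE)
  }
  p <- nrow(fit$W)
  vip <- sqrt(p * drop(fit$W^2 %*% ss) / sum(ss))
  stats::setNames(vip, rownames(fit$W) %||% names(fit$coefficients))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' VIP table over many responses
#'
#' Fits one PLS1 model per response on the eight meteorological factors
#' and collects VIP scores into a factors x responses matrix.
#'
#' @param data Dataset data frame with the factor columns and the
#'   response columns.
#' @param responses Character vector of response column names (default:
#'   all catechin columns present).
#' @param ncomp Components per fit, or `"auto"` (leave-one-out RMSECV).
#' @param log2_responses Model `log2(response)` instead of the raw value
#'   (useful for expression responses). Default FALSE.
#' @param threshold Selection threshold stored with the table. Default 1.
#' @return Object of class `vip_table`: list with `vip` (p x r matrix),
#'   `threshold`, `selected` (logical matrix `vip > threshold`) and
#'   `ncomp` (per response).
#' @export
vip_table <- function(data, responses = NULL, ncomp = "auto",
                      log2_responses = FALSE, threshold = 1) {
  validate_dataset(data)
  if (is.null(responses)) {
    responses <- intersect(catechin_names(), names(data))
  }
  if (length(responses) == 0L) stop("no responses to fit", call. = FALSE)
  X <- as.matrix(data[, meteo_factors()])
  vip <- matrix(NA_real_, nrow = length(meteo_factors()),
                ncol = length(responses),
                dimnames = list(meteo_factors(), responses))
  used <- stats::setNames(integer(length(responses)), responses)
  for (r in responses) {
    y <- data[[r]]
    if (is.null(y)) stop("response column not found: ", r, call. = FALSE)
    if (log2_responses) {
      if (any(y <= 0)) {
        stop("log2 transform requires strictly positive response: ", r,
             call. = FALSE)
      }
      y <- log2(y)
    }
    fit <- fit_pls1(X, y, ncomp = ncomp, response = r)
    vip[, r] <- vip_scores(fit)
    used[r] <- fit$ncomp
  }
  structure(list(vip = vip, threshold = threshold,
                 selected = vip > threshold, ncomp = used),
            class = "vip_table")
}

#' @export
print.vip_table <- function(x, ...) {
  cat(sprintf("<vip_table> %d factors x %d responses, threshold %.3g\n",
              nrow(x$vip), ncol(x$vip), x$threshold))
  print(round(x$vip, 3))
  invisible(x)
}

#' Screen influential factors by VIP threshold
#'
#' Returns the factor-to-response association links whose VIP score
#' strictly exceeds the threshold (VIP > 1 by default) -- the link list
#' behind factor-gene-catechin association reports.
#'
#' @param vip A [vip_table()].
#' @param threshold Strict selection threshold. Default: the table's own.
#' @return Data frame `factor, response, vip`, ordered by response then
#'   descending VIP.
#' @export
screen_factors <- function(vip, threshold = NULL) {
  stopifnot(inherits(vip, "vip_table"))
  if (is.null(threshold)) threshold <- vip$threshold
  sel <- which(vip$vip > threshold, arr.ind = TRUE)
  links <- data.frame(
    factor = rownames(vip$vip)[sel[, 1L]],
    response = colnames(vip$vip)[sel[, 2L]],
    vip = vip$vip[sel],
    stringsAsFactors = FALSE
  )
  links <- links[order(links$response, -links$vip), ]
  rownames(links) <- NULL
  links
}

#' Write a VIP table and its link list to CSV
#'
#' @param vip A [vip_table()].
#' @param path CSV path for the factors x responses matrix.
#' @param links_path Optional CSV path for the thresholded link list.
#' @return `path`, invisibly.
#' @export
write_vip_table <- function(vip, path, links_path = NULL) {
  stopifnot(inherits(vip, "vip_table"))
  out <- data.frame(factor = rownames(vip$vip), vip$vip, check.names = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  if (!is.null(links_path)) {
    utils::write.csv(screen_factors(vip), links_path, row.names = FALSE,
                     quote = FALSE)
  }
  invisible(path)
}
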