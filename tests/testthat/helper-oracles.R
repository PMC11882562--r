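# Independent test oracles, kept free of the package's own code paths.

# Brute-force UPGMA (average-linkage) agglomeration on the original
# pairwise Euclidean distances, with the same deterministic conventions
# as the package: merge the closest pair, and order each merged cluster
# with the alphabetically-smallest-label subtree first.
bf_leaf_order <- function(mat) {
  D <- as.matrix(stats::dist(mat, method = "euclidean"))
  clusters <- as.list(rownames(mat))
  while (length(clusters) > 1L) {
    best <- NULL
    for (i in seq_len(length(clusters) - 1L)) {
      for (j in seq.int(i + 1L, length(clusters))) {
        d <- mean(D[clusters[[i]], clusters[[j]]])
        if (is.null(best) || d < best$d) best <- list(i = i, j = j, d = d)
      }
    }
    a <- clusters[[best$i]]
    b <- clusters[[best$j]]
    merged <- if (min(a) <= min(b)) c(a, b) else c(b, a)
    clusters <- c(clusters[-c(best$i, best$j)], list(merged))
  }
  clusters[[1L]]
}

# Orthogonal zero-mean design: n x p matrix with orthonormal, zero-mean
# columns (every column lies in the orthogonal complement of the
# constant vector).
orthogonal_design <- function(n, p, seed) {
  set.seed(seed)
  m <- matrix(rnorm(n * p), n, p)
  q <- qr.Q(qr(scale(m, scale = FALSE)))[, seq_len(p), drop = FALSE]
  colnames(q) <- paste0("f", seq_len(p))
  q
}

# Random coefficient table over the eight factors for optimizer stress
# tests; slopes are scaled per factor so every factor matters at the
# box scale, and `zero_frac` of slopes are exactly zero to exercise
# tie-breaking.
random_coef_table <- function(responses, box, zero_frac = 0.1) {
  span <- pmax(box$high - box$low, 1e-3)
  rows <- lapply(responses, function(r) {
    b <- rnorm(8) / span
    b[runif(8) < zero_frac] <- 0
    df <- data.frame(response = r, intercept = rnorm(1),
                     stringsAsFactors = FALSE)
    df[meteo_factors()] <- as.list(b)
    df
  })
  coef_table(do.call(rbind, rows))
}

# Random factor box around the reference study ranges.
random_box <- function() {
  ref <- tieguanyin_factor_box()
  lo <- ref$low - abs(ref$low) * runif(8, 0, 0.3)
  hi <- ref$high + abs(ref$high) * runif(8, 0, 0.3)
  data.frame(factor = ref$factor, low = lo, high = hi,
             stringsAsFactors = FALSE)
}

expect_meteo_equal <- function(x, y, tol = 1e-9) {
  expect_equal(unname(x[meteo_factors()]), unname(y[meteo_factors()]),
               tolerance = tol)
}
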