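# qPCR processing: relative expression by the 2^-ddCt method against an
# internal reference gene and a reference plantation, dilution-series
# amplification efficiency, and deterministic Euclidean hierarchical
# clustering leaf orders for heatmap-style reporting.

#' Relative expression by the 2^-ddCt method
#'
#' For each gene and sample, `dCt = ct_target - ct_reference`; relative
#' expression versus the reference sample is `2^-(dCt - dCt_ref)`. The
#' reference sample is a plantation site (e.g. the BM garden); with
#' `per_season = TRUE` (default) each season is normalized to that
#' site's record of the same season, with `per_season = FALSE` a single
#' global reference record (site + `reference_season`) is used for all
#' samples. Replicate Ct rows are averaged per (site, season, gene)
#' before the calculation.
#'
#' @param qpcr Long data frame `site, season, gene, ct_target,
#'   ct_reference` (replicate rows allowed).
#' @param reference_site Reference plantation id. Default `"BM"`.
#' @param per_season Normalize within season (default) or to one global
#'   reference record.
#' @param reference_season Season of the global reference record when
#'   `per_season = FALSE`.
#' @return Genes x samples matrix of relative expressions (> 0); sample
#'   columns named `site_season`. Class `expression_matrix`.
#' @export
#' @examples
#' q <- data.frame(site = c("BM", "GD"), season = "spring", gene = "CsCHS1",
#'                 ct_target = c(24, 25), ct_reference = c(21, 20))
#' delta_delta_ct(q)  # BM = 1, GD = 2^-2
delta_delta_ct <- function(qpcr, reference_site = "BM", per_season = TRUE,
                           reference_season = "spring") {
  need <- c("site", "season", "gene", "ct_target", "ct_reference")
  miss <- setdiff(need, names(qpcr))
  if (length(miss) > 0L) {
    stop("qpcr table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  cts <- c(qpcr$ct_target, qpcr$ct_reference)
  if (anyNA(cts) || any(cts <= 0 | cts >= 60)) {
    stop("Ct values must lie in (0, 60) with no missing entries",
         call. = FALSE)
  }
  # average replicates
  agg <- stats::aggregate(qpcr[c("ct_target", "ct_reference")],
                          by = list(site = qpcr$site, season = qpcr$season,
                                    gene = qpcr$gene),
                          FUN = mean)
  agg$dct <- agg$ct_target - agg$ct_reference
  agg$sample <- paste(agg$site, agg$season, sep = "_")
  genes <- sort(unique(agg$gene))
  samples <- unique(agg$sample[order(agg$site,
                                     match(agg$season, seasons_allowed()))])
  mat <- matrix(NA_real_, length(genes), length(samples),
                dimnames = list(genes, samples))
  for (i in seq_len(nrow(agg))) {
    mat[agg$gene[i], agg$sample[i]] <- agg$dct[i]
  }
  if (anyNA(mat)) {
    holes <- which(is.na(mat), arr.ind = TRUE)
    stop(sprintf("missing Ct record(s), e.g. gene '%s' sample '%s'",
                 rownames(mat)[holes[1L, 1L]],
                 colnames(mat)[holes[1L, 2L]]), call. = FALSE)
  }
  ref_dct <- matrix(NA_real_, length(genes), length(samples),
                    dimnames = dimnames(mat))
  if (per_season) {
    season_of <- sub("^.*_", "", samples)
    for (s in unique(season_of)) {
      ref_sample <- paste(reference_site, s, sep = "_")
      if (!ref_sample %in% samples) {
        stop(sprintf("reference sample '%s' absent for season '%s'",
                     ref_sample, s), call. = FALSE)
      }
      ref_dct[, season_of == s] <- mat[, ref_sample]
    }
  } else {
    ref_sample <- paste(reference_site, reference_season, sep = "_")
    if (!ref_sample %in% samples) {
      stop(sprintf("global reference sample '%s' is absent", ref_sample),
           call. = FALSE)
    }
    ref_dct[] <- mat[, ref_sample]
  }
  expr <- 2^-(mat - ref_dct)
  structure(expr, class = c("expression_matrix", "matrix", "array"))
}

#' Amplification efficiency from a cDNA dilution series
#'
#' Standard-curve estimate: regress Ct on log10 of relative template
#' amount (the reciprocal of the dilution factor) and convert the slope
#' to `E = 10^(-1/slope) - 1`. A perfectly doubling assay has slope
#' -log2(10) ~= -3.3219 and efficiency exactly 1. Slopes outside
#' (-10, -1) trigger an "implausible efficiency" warning.
#'
#' @param dilution Numeric vector of dilution factors (e.g. 5, 25, 125),
#'   at least three distinct values.
#' @param ct Matching Ct values.
#' @return List: `efficiency`, `slope` (cycles per decade of template),
#'   `intercept`, `r_squared`.
#' @export
#' @examples
#' amplification_efficiency(c(5, 25, 125), c(20, 20 + log2(5), 20 + log2(25)))
amplification_efficiency <- function(dilution, ct) {
  if (length(dilution) != length(ct)) {
    stop("`dilution` and `ct` must have equal length", call. = FALSE)
  }
  if (length(unique(dilution)) < 3L) {
    stop("need at least 3 distinct dilution levels", call. = FALSE)
  }
  if (any(dilution <= 0)) stop("dilution factors must be > 0", call. = FALSE)
  log_amount <- log10(1 / dilution)
  fit <- stats::lm(ct ~ log_amount)
  slope <- unname(coef(fit)[2L])
  if (!is.finite(slope) || slope >= -1 || slope <= -10) {
    warning(sprintf("implausible efficiency: slope %.4g outside (-10, -1)",
                    slope), call. = FALSE)
  }
  sst <- sum((ct - mean(ct))^2)
  r2 <- if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else NA_real_
  list(
    efficiency = 10^(-1 / slope) - 1,
    slope = slope,
    intercept = unname(coef(fit)[1L]),
    r_squared = r2
  )
}

# Deterministic leaf order of an hclust tree: at every internal node the
# subtree containing the smallest label (by sort order) goes left, which
# removes the dependence on input row order.
ordered_leaves <- function(hc) {
  labels <- hc$labels
  rec <- function(i) {
    if (i < 0) return(labels[-i])
    left <- rec(hc$merge[i, 1L])
    right <- rec(hc$merge[i, 2L])
    if (min(left) <= min(right)) c(left, right) else c(right, left)
  }
  rec(nrow(hc$merge))
}

#' Deterministic hierarchical-clustering leaf order
#'
#' Euclidean-distance agglomerative clustering (average linkage by
#' default) of the rows or columns of a matrix, returning the leaf
#' order for heatmap-style displays. The order is made deterministic by
#' placing, at every merge, the subtree containing the alphabetically
#' smallest label first.
#'
#' @param mat Numeric matrix with row and column names (e.g. the log2
#'   expression matrix).
#' @param margin `"rows"` or `"cols"`.
#' @param method Linkage: `"average"` (default), `"complete"`,
#'   `"single"` or `"ward.D2"`.
#' @return Character vector of labels in leaf order; attribute `hclust`
#'   carries the underlying tree.
#' @export
hclust_leaf_order <- function(mat, margin = c("rows", "cols"),
                              method = c("average", "complete", "single",
                                         "ward.D2")) {
  margin <- match.arg(margin)
  method <- match.arg(method)
  m <- if (margin == "rows") mat else t(mat)
  if (nrow(m) < 2L) stop("need at least 2 items to cluster", call. = FALSE)
  if (any(!is.finite(m))) {
    stop("matrix contains non-finite values", call. = FALSE)
  }
  if (is.null(rownames(m))) rownames(m) <- as.character(seq_len(nrow(m)))
  hc <- stats::hclust(stats::dist(m, method = "euclidean"),
                      method = method)
  out <- ordered_leaves(hc)
  attr(out, "hclust") <- hc
  out
}

#' Log2 view of an expression matrix
#'
#' @param expr An [delta_delta_ct()] expression matrix (all values > 0).
#' @return Matrix of log2 relative expressions (reference sample at 0).
#' @export
log2_expression <- function(expr) {
  if (any(expr <= 0)) stop("expression values must be > 0", call. = FALSE)
  out <- log2(unclass(expr))
  out
}

#' Attach relative expression values to a dataset
#'
#' Joins a genes x samples expression matrix onto a site-by-season
#' dataset as `expr_<gene>` columns (matching on `site_season`), so the
#' PLS/VIP screen can treat gene expressions as responses alongside the
#' catechins.
#'
#' @param data Dataset data frame.
#' @param expr An [delta_delta_ct()] expression matrix.
#' @return `data` with one `expr_<gene>` column per gene.
#' @export
merge_expression <- function(data, expr) {
  validate_dataset(data)
  key <- paste(data$site, data$season, sep = "_")
  miss <- setdiff(key, colnames(expr))
  if (length(miss) > 0L) {
    stop("expression matrix lacks sample(s): ",
         paste(utils::head(miss, 3L), collapse = ", "), call. = FALSE)
  }
  for (g in rownames(expr)) {
    data[[paste0("expr_", g)]] <- as.numeric(expr[g, key])
  }
  data
}

#' Write an expression matrix (genes as rows) to CSV
#'
#' @param expr Expression matrix.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(expr, path) {
  out <- data.frame(gene = rownames(expr), unclass(expr),
                    check.names = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
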