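# Descriptive stages: pairwise Pearson correlation with significance
# stars and principal component analysis of standardized catechin
# profiles.

#' Significance stars for p-values
#'
#' Star codes with closed upper boundaries: `***` for p <= 0.001, `**`
#' for 0.001 < p <= 0.01, `*` for 0.01 < p <= 0.05, empty otherwise.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of star codes.
#' @export
#' @examples
#' significance_stars(c(0.0005, 0.005, 0.03, 0.2))
significance_stars <- function(p) {
  ifelse(p <= 0.001, "***",
         ifelse(p <= 0.01, "**",
                ifelse(p <= 0.05, "*", "")))
}

#' Pairwise Pearson correlation with significance stars
#'
#' Pearson r with two-sided t-test p-values for every pair of the
#' requested variables (e.g. catechins against gene expressions), plus
#' the star codes of [significance_stars()]. No multiple-testing
#' correction is applied by default; `adjust = "BH"` switches the stars
#' (and the `p` matrix) to Benjamini-Hochberg adjusted values.
#'
#' @param data Data frame holding the variables.
#' @param vars1 Character vector of variable names (rows of the output).
#' @param vars2 Second variable set (columns); defaults to `vars1`.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return Object of class `cor_report`: list of matrices `r`, `p`,
#'   `stars`, and `n` (sample size).
#' @export
pearson_with_stars <- function(data, vars1, vars2 = vars1,
                               adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  vars <- union(vars1, vars2)
  miss <- setdiff(vars, names(data))
  if (length(miss) > 0L) {
    stop("variable(s) not in data: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(data)
  if (n < 4L) stop("need at least 4 observations per pair", call. = FALSE)
  for (v in vars) {
    if (stats::sd(data[[v]]) == 0) {
      stop(sprintf("correlation undefined: variable '%s' has zero variance",
                   v), call. = FALSE)
    }
  }
  r <- matrix(NA_real_, length(vars1), length(vars2),
              dimnames = list(vars1, vars2))
  p <- r
  for (a in vars1) {
    for (b in vars2) {
      if (identical(a, b)) {
        r[a, b] <- 1
        p[a, b] <- 0
      } else {
        ct <- stats::cor.test(data[[a]], data[[b]], method = "pearson")
        r[a, b] <- unname(ct$estimate)
        p[a, b] <- ct$p.value
      }
    }
  }
  if (adjust == "BH") {
    off <- !(outer(vars1, vars2, FUN = "=="))
    p[off] <- stats::p.adjust(p[off], method = "BH")
  }
  structure(list(r = r, p = p, stars = structure(significance_stars(p),
                                                 dim = dim(p),
                                                 dimnames = dimnames(p)),
                 n = n),
            class = "cor_report")
}

#' @export
print.cor_report <- function(x, ...) {
  cat(sprintf("<cor_report> %d x %d Pearson correlations, n = %d\n",
              nrow(x$r), ncol(x$r), x$n))
  disp <- matrix(sprintf("%.2f%s", x$r, x$stars), nrow = nrow(x$r),
                 dimnames = dimnames(x$r))
  print(disp, quote = FALSE)
  invisible(x)
}

#' Write a correlation report in long CSV form
#'
#' @param report A [pearson_with_stars()] result.
#' @param path CSV path (`var1, var2, r, p, stars`).
#' @return `path`, invisibly.
#' @export
write_cor_report <- function(report, path) {
  long <- expand.grid(var1 = rownames(report$r), var2 = colnames(report$r),
                      stringsAsFactors = FALSE)
  long$r <- as.vector(report$r)
  long$p <- as.vector(report$p)
  long$stars <- as.vector(report$stars)
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Principal component analysis of catechin profiles
#'
#' PCA of the seven monomer concentrations across samples. By default
#' variables are standardized (correlation-matrix PCA), so the component
#' variances sum to the number of variables. Loading signs are fixed
#' deterministically: in every component the largest-magnitude loading
#' is made positive (the sign of a principal axis is otherwise
#' arbitrary).
#'
#' @param data Dataset with the seven catechin columns.
#' @param variables Variables to decompose (default the seven monomers).
#' @param standardize Correlation-matrix PCA (default `TRUE`);
#'   `FALSE` for covariance-matrix PCA.
#' @return Object of class `pca_result`: `sdev`, `prop_var`, `cum_var`,
#'   `loadings` (variables x components), `scores` (samples x
#'   components).
#' @export
#' @examples
#' d <- generate_dataset(generator_config(seed = 3))
#' p <- pca_catechins(d)
#' sum(p$sdev^2)  # 7 for 7 standardized variables
pca_catechins <- function(data, variables = catechin_names(),
                          standardize = TRUE) {
  miss <- setdiff(variables, names(data))
  if (length(miss) > 0L) {
    stop("variable(s) not in data: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(data) < 3L) stop("need at least 3 samples", call. = FALSE)
  x <- as.matrix(data[, variables, drop = FALSE])
  if (standardize) {
    sds <- apply(x, 2L, stats::sd)
    if (any(sds == 0)) {
      stop("constant variable(s) under standardization: ",
           paste(variables[sds == 0], collapse = ", "), call. = FALSE)
    }
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = standardize)
  flip <- apply(pc$rotation, 2L, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  loadings <- sweep(pc$rotation, 2L, flip, `*`)
  scores <- sweep(pc$x, 2L, flip, `*`)
  var_comp <- pc$sdev^2
  structure(
    list(sdev = pc$sdev, prop_var = var_comp / sum(var_comp),
         cum_var = cumsum(var_comp) / sum(var_comp),
         loadings = loadings, scores = scores,
         standardized = standardize),
    class = "pca_result"
  )
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("<pca_result> %d components (%s PCA)\n", length(x$sdev),
              if (x$standardized) "correlation-matrix" else
                "covariance-matrix"))
  tab <- rbind(sdev = x$sdev, prop_var = x$prop_var, cum_var = x$cum_var)
  colnames(tab) <- paste0("PC", seq_along(x$sdev))
  print(round(tab, 4))
  invisible(x)
}

#' Write a PCA result to CSV
#'
#' Two files: component summary (`component, sdev, prop_var, cum_var`)
#' and, optionally, the loadings matrix.
#'
#' @param pca A [pca_catechins()] result.
#' @param path Summary CSV path.
#' @param loadings_path Optional loadings CSV path.
#' @return `path`, invisibly.
#' @export
write_pca_result <- function(pca, path, loadings_path = NULL) {
  summ <- data.frame(component = paste0("PC", seq_along(pca$sdev)),
                     sdev = pca$sdev, prop_var = pca$prop_var,
                     cum_var = pca$cum_var)
  utils::write.csv(summ, path, row.names = FALSE, quote = FALSE)
  if (!is.null(loadings_path)) {
    lo <- data.frame(variable = rownames(pca$loadings), pca$loadings,
                     check.names = FALSE)
    utils::write.csv(lo, loadings_path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
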