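# End-to-end orchestration: simulate -> screen (PLS/VIP) -> fit (models +
# validation metrics) -> optimize (grouped LP) -> express (qPCR) ->
# stats (correlation, PCA), with deterministic seeded outputs.

pipeline_stages <- function() {
  c("simulate", "screen", "fit", "optimize", "express", "stats")
}

#' Run the full analysis pipeline
#'
#' Executes the requested stages in dependency order against either a
#' synthetic survey (a [generator_config()], which carries the mandatory
#' seed) or an existing dataset CSV (then `seed` must be given
#' explicitly, since the fit stage draws a held-out split). Every stage
#' writes its report CSV under `out_dir` and logs one structured line;
#' outputs are byte-identical across runs with the same config and seed.
#'
#' Outputs: `dataset.csv`, `vip_table.csv` + `vip_links.csv`,
#' `model_table.csv` (published-table layout), `optimization_tec.csv` +
#' `optimization_tnec.csv`, `expression_matrix.csv` + `leaf_order_*.txt`
#' (when qPCR links are configured), `correlation.csv`,
#' `pca_summary.csv` + `pca_loadings.csv`.
#'
#' @param config A [generator_config()], or a path to a dataset CSV.
#' @param out_dir Output directory (created if needed).
#' @param stages Subset of `simulate, screen, fit, optimize, express,
#'   stats`. Default: all that apply.
#' @param seed Seed override; mandatory when `config` is a file path.
#' @param ncomp PLS components for the screen stage (`"auto"` or a
#'   count). Default `"auto"`.
#' @return Invisible named list of written file paths.
#' @export
#' @examples
#' \donttest{
#' out <- run_pipeline(generator_config(seed = 11), tempfile("mc_run"))
#' names(out)
#' }
run_pipeline <- function(config, out_dir, stages = pipeline_stages(),
                         seed = NULL, ncomp = "auto") {
  stages <- match.arg(stages, pipeline_stages(), several.ok = TRUE)
  if (inherits(config, "generator_config")) {
    if (is.null(seed)) seed <- config$seed
  } else if (is.character(config) && length(config) == 1L) {
    if (is.null(seed)) {
      stop("`seed` is mandatory when running from a dataset file",
           call. = FALSE)
    }
    stages <- setdiff(stages, "simulate")
  } else {
    stop("`config` must be a generator_config or a dataset CSV path",
         call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- list()
  log_stage <- function(stage, ...) {
    message(sprintf("[%s] seed=%d %s", stage, seed,
                    paste(sprintf("%s=%s", names(list(...)), list(...)),
                          collapse = " ")))
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  if ("simulate" %in% stages) {
    data <- run_stage("simulate", generate_dataset(config))
    qpcr <- attr(data, "qpcr")
    written$dataset <- file.path(out_dir, "dataset.csv")
    write_dataset(data, written$dataset)
    if (!is.null(qpcr)) {
      written$qpcr <- file.path(out_dir, "qpcr.csv")
      utils::write.csv(qpcr, written$qpcr, row.names = FALSE, quote = FALSE)
    }
    log_stage("simulate", rows = nrow(data))
  } else {
    data <- run_stage("load", read_dataset(config, require_catechins = TRUE))
    qpcr <- NULL
    qpcr_path <- file.path(dirname(config), "qpcr.csv")
    if (file.exists(qpcr_path)) {
      qpcr <- utils::read.csv(qpcr_path, stringsAsFactors = FALSE)
    }
    log_stage("load", rows = nrow(data))
  }

  if ("screen" %in% stages) {
    vt <- run_stage("screen", vip_table(data, ncomp = ncomp))
    written$vip_table <- file.path(out_dir, "vip_table.csv")
    written$vip_links <- file.path(out_dir, "vip_links.csv")
    write_vip_table(vt, written$vip_table, written$vip_links)
    log_stage("screen", responses = ncol(vt$vip),
              links = nrow(screen_factors(vt)))
  }

  if ("fit" %in% stages) {
    tab <- run_stage("fit", fit_model_table(data, seed = seed))
    written$model_table <- file.path(out_dir, "model_table.csv")
    write_coef_table(tab, written$model_table)
    log_stage("fit", responses = nrow(tab))
  } else {
    tab <- NULL
  }

  if ("optimize" %in% stages) {
    if (is.null(tab)) tab <- run_stage("fit", fit_model_table(data,
                                                              seed = seed))
    for (grp in c("tec", "tnec")) {
      rep_grp <- run_stage("optimize",
                           optimize_group_report(grp, tab, data))
      written[[paste0("optimization_", grp)]] <-
        file.path(out_dir, sprintf("optimization_%s.csv", grp))
      out <- rep_grp
      out$binding <- gsub(",", ";", out$binding)
      utils::write.csv(out, written[[paste0("optimization_", grp)]],
                       row.names = FALSE, quote = FALSE)
    }
    log_stage("optimize", groups = "tec+tnec")
  }

  if ("express" %in% stages && !is.null(qpcr)) {
    expr <- run_stage("express", delta_delta_ct(qpcr))
    written$expression_matrix <- file.path(out_dir,
                                           "expression_matrix.csv")
    write_expression_matrix(expr, written$expression_matrix)
    lg <- log2_expression(expr)
    for (ax in c("rows", "cols")) {
      ord <- run_stage("express", hclust_leaf_order(lg, margin = ax))
      f <- file.path(out_dir, sprintf("leaf_order_%s.txt", ax))
      writeLines(ord, f)
      written[[paste0("leaf_order_", ax)]] <- f
    }
    log_stage("express", genes = nrow(expr), samples = ncol(expr))
  }

  if ("stats" %in% stages) {
    cr <- run_stage("stats",
                    pearson_with_stars(data, catechin_names()))
    written$correlation <- file.path(out_dir, "correlation.csv")
    write_cor_report(cr, written$correlation)
    pca <- run_stage("stats", pca_catechins(data))
    written$pca_summary <- file.path(out_dir, "pca_summary.csv")
    written$pca_loadings <- file.path(out_dir, "pca_loadings.csv")
    write_pca_result(pca, written$pca_summary, written$pca_loadings)
    log_stage("stats", pc1_pc2_var = sprintf("%.1f%%",
                                             100 * pca$cum_var[2L]))
  }

  invisible(written)
}

#' Write the reference worked-example fixtures
#'
#' Materialises the cv. Tieguanyin reference inputs as ready-to-run CSV
#' files: the published coefficient table (`reference_models.csv`), the
#' per-factor optimisation box (`factor_box.csv`), the published optimal
#' factor vectors (`optimal_conditions.csv`) and the predictions of the
#' reference models at those optima (`demo_predictions.csv`).
#'
#' @param dir Output directory (created if needed).
#' @return Invisible named list of file paths.
#' @export
#' @examples
#' \donttest{
#' make_demo_fixtures(tempfile("mc_demo"))
#' }
make_demo_fixtures <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- list(
    models = file.path(dir, "reference_models.csv"),
    box = file.path(dir, "factor_box.csv"),
    optima = file.path(dir, "optimal_conditions.csv"),
    predictions = file.path(dir, "demo_predictions.csv")
  )
  tb <- tieguanyin_models()
  write_coef_table(tb, files$models)
  utils::write.csv(tieguanyin_factor_box(), files$box, row.names = FALSE,
                   quote = FALSE)
  opt <- tieguanyin_optima()
  opt_df <- cbind(data.frame(target = names(opt)),
                  do.call(rbind, lapply(opt, function(x)
                    as.data.frame(as.list(x)))))
  rownames(opt_df) <- NULL
  utils::write.csv(opt_df, files$optima, row.names = FALSE, quote = FALSE)
  grp <- catechin_groups()
  preds <- do.call(rbind, lapply(names(opt), function(tg) {
    at <- opt[[tg]]
    monomers <- vapply(catechin_names(), function(m)
      predict(get_model(tb, m), at, warn_negative = FALSE), numeric(1L))
    data.frame(target = tg,
               prediction = round(monomers[[tg]], 2L),
               tec_at_optimum = round(sum(monomers[grp$tec]), 2L),
               tnec_at_optimum = round(sum(monomers[grp$tnec]), 2L))
  }))
  utils::write.csv(preds, files$predictions, row.names = FALSE,
                   quote = FALSE)
  invisible(files)
}
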