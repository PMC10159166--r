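#' Full pipeline configuration
#'
#' Bundles the stage configurations of the end-to-end analysis: synthetic
#' data generation (or an externally supplied block set), drift filtering,
#' feature extraction, IQR outlier filtering, min-max normalization,
#' per-draw PCA, the Monte Carlo under-sampling benchmark, metric
#' distributions and the MANOVA comparison of feature spaces.
#'
#' @param synth a [synth_config()] describing the dataset to generate.
#' @param filter_cutoff,filter_order high-pass filter settings
#'   (see [highpass_filter()]).
#' @param outlier_n,outlier_rule IQR outlier settings
#'   (see [remove_outliers()]).
#' @param features a [feature_config()].
#' @param classifiers character vector of registry names to benchmark.
#' @param R Monte Carlo draws per space.
#' @param spaces subset of `c("15d", "7d")`.
#' @param pca_threshold cumulative-variance threshold for component
#'   selection in the reduced space.
#' @param seed master seed; the same draw seeds are used in both spaces so
#'   15D and 7D results are paired draw-by-draw.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(synth = synth_config(),
                            filter_cutoff = 0.05, filter_order = 2L,
                            outlier_n = 6, outlier_rule = "as_printed",
                            features = feature_config(),
                            classifiers = classifier_names(),
                            R = 50L, spaces = c("15d", "7d"),
                            pca_threshold = 0.90, seed = 1L) {
  spaces <- match.arg(spaces, several.ok = TRUE)
  structure(list(synth = synth, filter_cutoff = filter_cutoff,
                 filter_order = filter_order, outlier_n = outlier_n,
                 outlier_rule = outlier_rule, features = features,
                 classifiers = classifiers, R = as.integer(R),
                 spaces = spaces, pca_threshold = pca_threshold,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the end-to-end classification benchmark
#'
#' Executes: synthetic generation (unless `blocks` is supplied) ->
#' high-pass filtering -> feature extraction -> IQR outlier removal ->
#' min-max normalization -> [optional per-draw PCA] -> Monte Carlo
#' under-sampling benchmark of the requested classifiers -> metric
#' distributions -> MANOVA comparison of the 15D and 7D metric
#' distributions (when both spaces are run).
#'
#' @param config a [pipeline_config()].
#' @param blocks optionally a pre-made `block_set`; when supplied the
#'   synthetic stage is skipped.
#' @return list of class `stim_results` with elements `features`
#'   (normalized table), `retention` (fraction kept per IQR multiplier),
#'   `pca` (global scree model), `ensembles` and `metrics` (per space, per
#'   classifier), `manova` (per-classifier 15D-vs-7D tests, groupwise
#'   location tests and the paired-difference test) and the `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), blocks = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(blocks)) {
    synth <- config$synth
    synth$seed <- config$seed
    blocks <- generate_dataset(synth)
  }
  blocks <- filter_blocks(blocks, cutoff = config$filter_cutoff,
                          order = config$filter_order)
  tab <- extract_feature_table(blocks, cfg = config$features)
  retention <- suppressWarnings(
    retention_curve(tab, 1:10, rule = config$outlier_rule))
  tab <- suppressWarnings(
    remove_outliers(tab, n = config$outlier_n,
                    rule = config$outlier_rule))$table
  tab <- minmax_normalize(tab)
  pca_global <- fit_pca(tab)

  ensembles <- list()
  metrics <- list()
  for (space in config$spaces) {
    ens <- run_benchmark(tab, specs = config$classifiers, R = config$R,
                         seed = config$seed, space = space,
                         pca_threshold = config$pca_threshold)
    ensembles[[space]] <- ens
    metrics[[space]] <- lapply(ens, metric_distributions)
  }

  manova_res <- NULL
  if (all(c("15d", "7d") %in% config$spaces)) {
    manova_res <- compare_spaces(metrics[["15d"]], metrics[["7d"]])
  }
  structure(list(features = tab, retention = retention, pca = pca_global,
                 ensembles = ensembles, metrics = metrics,
                 manova = manova_res, config = config),
            class = "stim_results")
}

#' MANOVA comparison of 15D versus 7D metric distributions
#'
#' For each classifier, a one-way MANOVA on the per-draw
#' (balanced accuracy, F1, MCC) triples with feature space as the group;
#' plus, pooling all classifiers, the per-group one-sample location tests
#' and the paired per-draw difference test (valid because both spaces
#' share common random numbers).
#'
#' @param metrics_15d,metrics_7d named lists of [metric_distributions()]
#'   results (one per classifier), draws aligned.
#' @return list with `per_classifier` (named list of `manova_result`),
#'   `group_7d`, `group_15d` (location tests) and `paired`.
#' @export
compare_spaces <- function(metrics_15d, metrics_7d) {
  triple <- function(md) as.matrix(md[, c("bal_acc", "f1", "mcc")])
  per_clf <- lapply(names(metrics_15d), function(nm) {
    x15 <- triple(metrics_15d[[nm]])
    x7 <- triple(metrics_7d[[nm]])
    if (nrow(x15) < ncol(x15) + 2L) return(NULL) # too few draws to test
    oneway_manova(rbind(x15, x7),
                  rep(c("15d", "7d"), c(nrow(x15), nrow(x7))))
  })
  names(per_clf) <- names(metrics_15d)
  all15 <- do.call(rbind, lapply(metrics_15d, triple))
  all7 <- do.call(rbind, lapply(metrics_7d, triple))
  list(per_classifier = per_clf,
       group_15d = group_location_test(all15),
       group_7d = group_location_test(all7),
       paired = paired_location_test(all15, all7))
}

#' @export
print.stim_results <- function(x, ...) {
  cat("Plant-stimulus classification results\n")
  cat(sprintf("  %d feature rows after cleaning; retention at n = %s: %.3f\n",
              nrow(x$features), names(x$retention)[6] %||% "6",
              unname(x$retention["6"])))
  for (space in names(x$metrics)) {
    cat(sprintf("  space %s (R = %d draws):\n", space, x$config$R))
    for (nm in names(x$metrics[[space]])) {
      s <- attr(x$metrics[[space]][[nm]], "summary")
      cat(sprintf("    %-13s bal_acc %.3f  f1 %.3f  mcc %.3f\n", nm,
                  s["mean", "bal_acc"], s["mean", "f1"], s["mean", "mcc"]))
    }
  }
  invisible(x)
}
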