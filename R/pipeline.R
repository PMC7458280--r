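#' Run the full epistasis-detection pipeline
#'
#' Chains the analysis stages in their canonical order on a genotype table
#' (or a simulation config): per-SNP QC (MAF, Hardy-Weinberg), genetic-model
#' selection from genotype odds ratios, information-gain and pairwise
#' interaction-information analysis with the attribute dendrogram, the MDR
#' combination search with optional permutation test, weighted-effect-coded
#' interaction regression on the training partition of a stratified
#' hold-out split, and ROC evaluation of the interaction-only classifier
#' with a Youden cutoff applied to the hold-out subjects.
#'
#' Each stage is also exported on its own ([qc_report()], [model_report()],
#' [ig_report()], [interaction_report()], [build_dendrogram()],
#' [mdr_search()], [mdr_permutation_test()], [wec_interaction_analysis()],
#' [roc_curve()]); this orchestrator wires them together deterministically
#' and, when `out_dir` is given, writes every table as TSV plus one
#' consolidated JSON report via [write_report()].
#'
#' @param x A [genotype_table()] or a [simulation_config()] (simulated via
#'   [generate_genotypes()] first).
#' @param pair Character pair of SNP names for the regression/ROC stages;
#'   default `NULL` picks the pair with the largest positive interaction
#'   information.
#' @param test_fraction,split_seed Hold-out settings (see [holdout_split()]).
#' @param max_k,folds,mdr_seed MDR search settings.
#' @param n_perm Permutations for the MDR test; 0 skips it.
#' @param reference Reference genotype category for the WEC fits.
#' @param out_dir Optional output directory for TSV/JSON files.
#' @return An `epistasis_report` list with elements `qc`, `models`, `ig`,
#'   `interactions`, `dendrogram`, `mdr`, `mdr_permutation`, `wec`,
#'   `roc`, `cutoff`, `holdout_metrics`, `split`, `pair`.
#' @export
run_epistasis_pipeline <- function(x, pair = NULL,
                                   test_fraction = 36 / 318, split_seed = 1L,
                                   max_k = 4, folds = 10, mdr_seed = 1L,
                                   n_perm = 0,
                                   reference = "derived",
                                   out_dir = NULL) {
  gm <- if (inherits(x, "sim_config")) generate_genotypes(x) else x
  stopifnot(inherits(gm, "geno_tbl"))

  qc <- qc_report(gm)
  models <- model_report(gm)
  ig <- ig_report(gm)
  interactions <- interaction_report(gm)
  dendro <- build_dendrogram(gm)

  split <- holdout_split(gm, test_fraction, split_seed)
  gm_train <- gm[split$train_indices, ]

  mdr <- mdr_search(gm_train, max_k = max_k, folds = folds, seed = mdr_seed)
  top_combo <- mdr$snps[[1]]
  mdr_perm <- if (n_perm > 0) {
    mdr_permutation_test(gm_train, top_combo, n_perm = n_perm,
                         folds = folds, seed = mdr_seed)
  } else NULL

  if (is.null(pair)) {
    best <- interactions %>% arrange(desc(.data$interaction_bits)) %>% slice(1)
    pair <- c(best$snp_a, best$snp_b)
  }

  wec <- wec_interaction_analysis(gm, pair[1], pair[2],
                                  reference_a = reference, reference_b = reference,
                                  subset = split$train_indices)
  fit <- wec$interaction_only
  train_scores <- fit$fitted
  train_truth <- gm_train$status[!is.na(gm_train[[pair[1]]]) & !is.na(gm_train[[pair[2]]])]
  roc <- roc_curve(train_scores, train_truth)
  cut <- youden_cutoff(roc)

  gm_test <- gm[split$test_indices, ]
  test_scores <- predict_wec_interaction(
    fit,
    genotype_category(gm_test[[pair[1]]]),
    genotype_category(gm_test[[pair[2]]])
  )
  holdout_metrics <- apply_cutoff(test_scores, cut$cutoff, gm_test$status)

  report <- structure(
    list(qc = qc, models = models, ig = ig, interactions = interactions,
         dendrogram = dendro, mdr = mdr, mdr_permutation = mdr_perm,
         wec = wec, roc = roc, cutoff = cut,
         holdout_metrics = holdout_metrics,
         split = split, pair = pair,
         n_subjects = nrow(gm)),
    class = "epistasis_report"
  )
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Write an epistasis report to disk
#'
#' Emits one TSV per tabular stage, the dendrogram as Newick, and a single
#' consolidated JSON report with sections for QC, model selection,
#' information gain, pairwise interactions, MDR, the regression comparison
#' and the ROC summary. Every number in the JSON is copied from the stage
#' results (no recomputation).
#'
#' @param report An `epistasis_report`.
#' @param out_dir Output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) readr::write_tsv(df, file.path(out_dir, name), progress = FALSE)
  w(report$qc, "qc.tsv")
  w(report$models, "genetic_models.tsv")
  w(report$ig, "information_gain.tsv")
  w(report$interactions, "interactions.tsv")
  w(tidy(report$dendrogram), "dendrogram_merges.tsv")
  writeLines(report$dendrogram$newick, file.path(out_dir, "dendrogram.nwk"))
  w(as_tibble(report$mdr) %>% select(-"snps"), "mdr_search.tsv")
  w(tidy(report$roc), "roc_points.tsv")
  for (nm in c("full", "interaction_only", "additive")) {
    w(tidy(report$wec[[nm]]), paste0("wec_", nm, "_coefficients.tsv"))
  }
  json <- list(
    n_subjects = report$n_subjects,
    pair = report$pair,
    qc = report$qc,
    genetic_models = report$models,
    information_gain = report$ig,
    interactions = report$interactions,
    mdr_best = as_tibble(report$mdr) %>% slice(1) %>% select(-"snps"),
    mdr_permutation_p = if (is.null(report$mdr_permutation)) NULL else
      report$mdr_permutation$p_value,
    regression = report$wec$comparison$models,
    regression_lr_tests = report$wec$comparison$lr_tests,
    roc = glance(report$roc),
    youden = report$cutoff,
    holdout = report$holdout_metrics
  )
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.epistasis_report <- function(x, ...) {
  cat("Epistasis analysis of", x$n_subjects, "subjects,",
      length(snp_names_from_report(x)), "SNPs\n")
  cat("  focal pair:", paste(x$pair, collapse = " x "), "\n")
  cat(sprintf("  best MDR model: %s (test bal. acc. %.3f, CVC %d/%d)\n",
              x$mdr$combo[1], x$mdr$mean_test_bal_acc[1], x$mdr$cvc[1],
              attr(x$mdr, "folds")))
  if (!is.null(x$mdr_permutation)) {
    cat(sprintf("  MDR permutation p = %.4g\n", x$mdr_permutation$p_value))
  }
  g <- glance(x$wec$interaction_only)
  cat(sprintf("  interaction-only fit: logLik %.3f, LR chi2 %.3f (df %d), McFadden R2 %.3f\n",
              g$log_likelihood, g$lr_chi2, g$df, g$mcfadden_r2))
  cat(sprintf("  training AUC %.3f, Youden cutoff %.3f, hold-out accuracy %.3f\n",
              x$roc$auc, x$cutoff$cutoff, x$holdout_metrics$accuracy))
  invisible(x)
}

snp_names_from_report <- function(x) unique(x$qc$snp)

#' Interaction-information heatmap
#'
#' @param object An `epistasis_report`.
#' @param ... Unused.
#' @return A ggplot tile map of pairwise interaction information (percent),
#'   synergy in warm colours, redundancy in cool.
#' @method autoplot epistasis_report
#' @export
autoplot.epistasis_report <- function(object, ...) {
  d <- object$interactions
  ggplot(d, aes(x = .data$snp_a, y = .data$snp_b, fill = .data$interaction_percent)) +
    geom_tile() +
    scale_fill_gradient2(low = "steelblue", mid = "white", high = "firebrick",
                         name = "I(A;B;C) [%]") +
    labs(x = NULL, y = NULL, title = "Pairwise interaction information") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 45, hjust = 1))
}
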