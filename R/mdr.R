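#' Multifactor Dimensionality Reduction
#'
#' From-scratch MDR: each multilocus genotype cell of an attribute
#' combination is labelled high- or low-risk by comparing its case:control
#' ratio to the overall training ratio (class-balanced weighting), subjects
#' are classified by their cell label, and combinations are ranked by mean
#' test balanced accuracy under stratified k-fold cross-validation with
#' cross-validation consistency (CVC) as tiebreak.
#'
#' @name mdr
NULL

cell_keys <- function(gm, combo) {
  cols <- lapply(combo, function(s) gm[[s]])
  ok <- Reduce(`&`, lapply(cols, function(x) !is.na(x)))
  key <- do.call(paste, c(cols, sep = "|"))
  key[!ok] <- NA_character_
  key
}

#' Label multilocus genotype cells high/low risk
#'
#' With balanced weighting, a cell is high-risk when
#' `cases_cell / (controls_cell * n_cases / n_controls) >= 1`, i.e. its
#' case:control ratio meets the overall training ratio; ties go to high
#' (common MDR convention). Cells never seen in training are `"unseen"`.
#'
#' @param gm_train Training [genotype_table()].
#' @param combo Character vector of SNP (attribute) names.
#' @return A `mdr_cells` list: `cell_labels` (named character vector over
#'   observed cells), `combo`, `case_weight` (the training
#'   `n_cases / n_controls` ratio), `n_dropped` (missing-genotype subjects).
#' @export
mdr_label_cells <- function(gm_train, combo) {
  stopifnot(all(combo %in% snp_names(gm_train)))
  key <- cell_keys(gm_train, combo)
  ok <- !is.na(key)
  key <- key[ok]
  status <- gm_train$status[ok]
  n_cases <- sum(status == 1)
  n_controls <- sum(status == 0)
  if (n_cases == 0 || n_controls == 0) abort("training data needs both classes")
  cases <- tapply(status == 1, key, sum)
  controls <- tapply(status == 0, key, sum)
  # cases/controls >= n_cases/n_controls, robust to zero controls
  high <- cases * n_controls >= controls * n_cases
  labels <- ifelse(high, "high", "low")
  structure(
    list(cell_labels = labels, combo = combo,
         case_weight = n_cases / n_controls,
         n_dropped = sum(!ok)),
    class = "mdr_cells"
  )
}

#' Classify subjects by their MDR cell label
#'
#' @param gm A [genotype_table()].
#' @param cells A [mdr_label_cells()] result.
#' @param unseen_policy Prediction for subjects whose cell was unseen in
#'   training: `"control"` (default), `"case"`, or `"abstain"` (`NA`,
#'   excluded from metrics).
#' @return Integer predictions (1 = case, 0 = control, `NA` = abstain or
#'   missing genotype).
#' @export
mdr_classify <- function(gm, cells, unseen_policy = c("control", "case", "abstain")) {
  unseen_policy <- match.arg(unseen_policy)
  key <- cell_keys(gm, cells$combo)
  lab <- as.vector(cells$cell_labels[key])
  pred <- ifelse(lab == "high", 1L, 0L)
  unseen <- is.na(lab) & !is.na(key)
  pred[unseen] <- switch(unseen_policy, control = 0L, case = 1L, abstain = NA_integer_)
  pred[is.na(key)] <- NA_integer_
  pred
}

stratified_folds <- function(status, folds, seed) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  fold <- integer(length(status))
  for (cls in unique(status)) {
    idx <- sample(which(status == cls))
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold
}

bal_acc <- function(pred, truth) {
  ok <- !is.na(pred) & !is.na(truth)
  pred <- pred[ok]; truth <- truth[ok]
  sens <- sum(pred == 1 & truth == 1) / sum(truth == 1)
  spec <- sum(pred == 0 & truth == 0) / sum(truth == 0)
  (sens + spec) / 2
}

# CV evaluation of one combo over a fixed fold assignment; key-level
# implementation (no genotype_table rebuilds) for search speed.
cv_eval_combo <- function(key, status, fold, folds, unseen_policy = "control") {
  train_ba <- test_ba <- numeric(folds)
  for (f in seq_len(folds)) {
    tr <- fold != f & !is.na(key)
    te <- fold == f & !is.na(key)
    k_tr <- key[tr]; s_tr <- status[tr]
    n_ca <- sum(s_tr == 1); n_co <- sum(s_tr == 0)
    cases <- tapply(s_tr == 1, k_tr, sum)
    controls <- tapply(s_tr == 0, k_tr, sum)
    high_cells <- names(cases)[cases * n_co >= controls * n_ca]
    predict_keys <- function(k) {
      p <- ifelse(k %in% high_cells, 1L, 0L)
      if (unseen_policy == "abstain") p[!k %in% names(cases)] <- NA_integer_
      if (unseen_policy == "case") p[!k %in% names(cases)] <- 1L
      p
    }
    train_ba[f] <- bal_acc(predict_keys(k_tr), s_tr)
    test_ba[f] <- bal_acc(predict_keys(key[te]), status[te])
  }
  list(train = train_ba, test = test_ba)
}

#' Exhaustive MDR combination search with cross-validation
#'
#' Evaluates every attribute combination of order `1..max_k` under
#' stratified `folds`-fold cross-validation. Within each order k, the combo
#' with the best training balanced accuracy in a fold earns a CVC increment
#' for that fold. Combinations are ranked by mean test balanced accuracy,
#' ties broken by CVC.
#'
#' @param gm A [genotype_table()].
#' @param max_k Largest combination order searched.
#' @param folds Number of CV folds (stratified by class).
#' @param seed Seed for the fold assignment.
#' @param unseen_policy Passed to the classifier; see [mdr_classify()].
#' @param force Allow searches beyond the combinatorial guard
#'   (> 20 attributes with `max_k > 4`).
#' @return An `mdr_search` tibble ranked best-first: `combo` (names joined
#'   by `" x "`), `snps` (list-column), `k`, `mean_train_bal_acc`,
#'   `mean_test_bal_acc`, `cvc`, `rank`; attributes `folds` and `seed`.
#' @export
mdr_search <- function(gm, max_k = 2, folds = 10, seed = 1L,
                       unseen_policy = "control", force = FALSE) {
  snps <- snp_names(gm)
  if (max_k > length(snps)) abort("max_k exceeds the number of attributes")
  if (folds < 2) abort("folds must be >= 2")
  if (length(snps) > 20 && max_k > 4 && !force) {
    abort("refusing an exhaustive search over >20 attributes at k>4; set force=TRUE")
  }
  status <- gm$status
  fold <- stratified_folds(status, folds, seed)
  rows <- list()
  for (k in seq_len(max_k)) {
    combos <- combn(snps, k, simplify = FALSE)
    evals <- purrr::map(combos, function(cb) {
      cv_eval_combo(cell_keys(gm, cb), status, fold, folds, unseen_policy)
    })
    train_mat <- do.call(rbind, purrr::map(evals, "train"))
    best_per_fold <- apply(train_mat, 2, which.max)
    cvc <- tabulate(best_per_fold, nbins = length(combos))
    rows[[k]] <- tibble(
      combo = purrr::map_chr(combos, paste, collapse = " x "),
      snps = combos,
      k = k,
      mean_train_bal_acc = purrr::map_dbl(evals, ~ mean(.x$train)),
      mean_test_bal_acc = purrr::map_dbl(evals, ~ mean(.x$test)),
      cvc = cvc
    )
  }
  out <- bind_rows(rows) %>%
    arrange(desc(.data$mean_test_bal_acc), desc(.data$cvc)) %>%
    mutate(rank = row_number())
  attr(out, "folds") <- folds
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("mdr_search", class(out))
  out
}

#' Permutation test for an MDR model
#'
#' Permutes the phenotype labels `n_perm` times, re-runs the stratified CV
#' evaluation of the given combination, and reports the add-one permutation
#' p-value for the observed mean test balanced accuracy:
#' `p = (1 + #\{perm >= observed\}) / (1 + n_perm)`.
#'
#' @param gm A [genotype_table()].
#' @param combo Character vector of attribute names.
#' @param n_perm Number of permutations (>= 100).
#' @param folds,seed CV settings as in [mdr_search()].
#' @return A list: `p_value`, `observed` (mean test balanced accuracy),
#'   `perm_stats`, `n_perm`.
#' @export
mdr_permutation_test <- function(gm, combo, n_perm = 1000, folds = 10, seed = 1L) {
  if (n_perm < 100) abort("n_perm must be >= 100")
  status <- gm$status
  key <- cell_keys(gm, combo)
  fold <- stratified_folds(status, folds, seed)
  observed <- mean(cv_eval_combo(key, status, fold, folds)$test)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  perm_stats <- vapply(seq_len(n_perm), function(i) {
    s_perm <- sample(status)
    f_perm <- stratified_folds(s_perm, folds, seed + i)
    mean(cv_eval_combo(key, s_perm, f_perm, folds)$test)
  }, numeric(1))
  list(
    p_value = (1 + sum(perm_stats >= observed)) / (1 + n_perm),
    observed = observed,
    perm_stats = perm_stats,
    n_perm = n_perm
  )
}

#' Fit and evaluate one MDR model on a train/test split
#'
#' Labels cells on the training subjects and reports [evaluate_classifier()]
#' metrics on both partitions.
#'
#' @param gm A [genotype_table()].
#' @param combo Character vector of attribute names.
#' @param split A [holdout_split()] result; `NULL` evaluates train = test =
#'   all subjects.
#' @param unseen_policy See [mdr_classify()].
#' @return A list: `cells`, `train_metrics`, `test_metrics` (one-row
#'   tibbles).
#' @export
mdr_fit <- function(gm, combo, split = NULL, unseen_policy = "control") {
  if (is.null(split)) {
    tr_idx <- te_idx <- seq_len(nrow(gm))
  } else {
    tr_idx <- split$train_indices
    te_idx <- split$test_indices
  }
  gm_tr <- gm[tr_idx, ]
  gm_te <- gm[te_idx, ]
  cells <- mdr_label_cells(gm_tr, combo)
  list(
    cells = cells,
    train_metrics = evaluate_classifier(mdr_classify(gm_tr, cells, unseen_policy), gm_tr$status),
    test_metrics = evaluate_classifier(mdr_classify(gm_te, cells, unseen_policy), gm_te$status)
  )
}
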