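#' Classification metrics from predicted and true binary labels
#'
#' Builds the 2x2 confusion table (case = 1) and derives balanced accuracy,
#' accuracy, sensitivity, specificity, precision, Cohen's kappa, F1, the
#' diagnostic odds ratio with a Woolf 95% CI (Haldane +0.5 correction on any
#' zero cell), and a Pearson chi-square (no continuity correction) with its
#' p-value. Missing predictions (an abstaining classifier) are excluded and
#' counted.
#'
#' @param predictions Predicted labels in `{0, 1}`, `NA` allowed (abstain).
#' @param truth True labels in `{0, 1}`; both classes must be present.
#' @return A one-row tibble with the metric columns plus the confusion cells
#'   `tp`, `fp`, `fn`, `tn` and `n_abstain`.
#' @examples
#' evaluate_classifier(c(1, 0, 1, 0), c(1, 0, 0, 0))
#' @export
evaluate_classifier <- function(predictions, truth) {
  stopifnot(length(predictions) == length(truth))
  if (length(unique(truth[!is.na(truth)])) < 2) {
    abort("truth must contain both classes")
  }
  n_abstain <- sum(is.na(predictions))
  ok <- !is.na(predictions) & !is.na(truth)
  p <- predictions[ok]; t_ <- truth[ok]
  tp <- sum(p == 1 & t_ == 1)
  fp <- sum(p == 1 & t_ == 0)
  fn <- sum(p == 0 & t_ == 1)
  tn <- sum(p == 0 & t_ == 0)
  n <- tp + fp + fn + tn
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  acc <- (tp + tn) / n
  bal <- (sens + spec) / 2
  f1 <- if (!is.na(prec) && prec + sens > 0) 2 * prec * sens / (prec + sens) else NA_real_
  p_e <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  kappa <- if (p_e < 1) (acc - p_e) / (1 - p_e) else 0
  cells <- c(tp, fp, fn, tn)
  corrected <- any(cells == 0)
  cc <- if (corrected) cells + 0.5 else cells
  or <- (cc[1] * cc[4]) / (cc[2] * cc[3])
  se_log <- sqrt(sum(1 / cc))
  ci <- exp(log(or) + c(-1, 1) * 1.96 * se_log)
  obs <- matrix(cells, 2)
  expd <- outer(rowSums(obs), colSums(obs)) / n
  chi2 <- if (all(expd > 0)) sum((obs - expd)^2 / expd) else NA_real_
  tibble(
    balanced_accuracy = bal, accuracy = acc,
    sensitivity = sens, specificity = spec, precision = prec,
    kappa = kappa, f1 = f1,
    odds_ratio = or, or_ci_low = ci[1], or_ci_high = ci[2],
    or_corrected = corrected,
    chi2 = chi2,
    chi2_p = if (is.na(chi2)) NA_real_ else pchisq(chi2, 1, lower.tail = FALSE),
    tp = tp, fp = fp, fn = fn, tn = tn, n_abstain = n_abstain
  )
}
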