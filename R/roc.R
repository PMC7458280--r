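#' ROC curve, AUC and Hanley-McNeil standard error
#'
#' Builds the ROC curve over all distinct score thresholds (predict case at
#' score >= threshold). The AUC is computed by the trapezoid rule, which
#' equals the Mann-Whitney concordance probability with ties counted 1/2;
#' its standard error follows Hanley & McNeil, the 95% CI is
#' `AUC +/- 1.96 SE` truncated to `[0, 1]`, and `z = (AUC - 0.5)/SE` tests
#' the no-discrimination null.
#'
#' @param scores Numeric classifier scores (higher = more case-like).
#' @param truth Binary labels (1 = case); both classes required.
#' @return An `epi_roc` list: `points` tibble (`threshold`, `tpf`, `fpf`),
#'   `auc`, `auc_se`, `auc_ci`, `z`, `p_value`, `n_cases`, `n_controls`,
#'   `degenerate` (constant scores).
#' @export
roc_curve <- function(scores, truth) {
  ok <- !is.na(scores) & !is.na(truth)
  scores <- scores[ok]; truth <- as.integer(truth[ok])
  if (length(unique(truth)) < 2) abort("truth must contain both classes")
  n1 <- sum(truth == 1); n0 <- sum(truth == 0)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpf <- vapply(thr, function(t) sum(scores >= t & truth == 1) / n1, numeric(1))
  fpf <- vapply(thr, function(t) sum(scores >= t & truth == 0) / n0, numeric(1))
  auc <- sum(diff(fpf) * (head(tpf, -1) + tpf[-1]) / 2)
  degenerate <- length(unique(scores)) == 1
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) + (n0 - 1) * (q2 - auc^2)) /
               (n1 * n0))
  ci <- pmin(pmax(auc + c(-1, 1) * 1.96 * se, 0), 1)
  z <- if (se > 0) (auc - 0.5) / se else NA_real_
  structure(
    list(points = tibble(threshold = thr, tpf = tpf, fpf = fpf),
         auc = auc, auc_se = se, auc_ci = ci,
         z = z,
         p_value = if (is.na(z)) NA_real_ else 2 * stats::pnorm(-abs(z)),
         n_cases = n1, n_controls = n0, degenerate = degenerate),
    class = "epi_roc"
  )
}

#' @export
print.epi_roc <- function(x, ...) {
  cat(sprintf("ROC: AUC %.3f (SE %.3f, 95%% CI %.3f-%.3f), %d cases / %d controls\n",
              x$auc, x$auc_se, x$auc_ci[1], x$auc_ci[2], x$n_cases, x$n_controls))
  invisible(x)
}

#' Youden-optimal classification cutoff
#'
#' Returns the score threshold maximizing the Youden index `J = TPF - FPF`;
#' ties are broken toward higher specificity (the larger threshold).
#'
#' @param curve An `epi_roc` from [roc_curve()].
#' @return A list: `cutoff`, `j` (maximum Youden index), `tpf`, `fpf`.
#' @export
youden_cutoff <- function(curve) {
  pts <- curve$points %>% filter(is.finite(.data$threshold))
  j <- pts$tpf - pts$fpf
  best <- which(j == max(j))
  pick <- best[which.max(pts$threshold[best])]
  list(cutoff = pts$threshold[pick], j = j[pick],
       tpf = pts$tpf[pick], fpf = pts$fpf[pick])
}

#' Apply a score cutoff and compute classification metrics
#'
#' Predicts case at `score >= cutoff` (closed on the case side) and
#' evaluates via [evaluate_classifier()].
#'
#' @param scores Numeric scores.
#' @param cutoff Decision threshold.
#' @param truth Binary labels.
#' @return A one-row metrics tibble (see [evaluate_classifier()]).
#' @export
apply_cutoff <- function(scores, cutoff, truth) {
  evaluate_classifier(as.integer(scores >= cutoff), truth)
}

#' ROC points as a tibble
#'
#' @param x An `epi_roc`.
#' @param ... Unused.
#' @method tidy epi_roc
#' @export
tidy.epi_roc <- function(x, ...) x$points

#' @rdname tidy.epi_roc
#' @method glance epi_roc
#' @export
glance.epi_roc <- function(x, ...) {
  tibble(auc = x$auc, auc_se = x$auc_se,
         auc_ci_low = x$auc_ci[1], auc_ci_high = x$auc_ci[2],
         z = x$z, p_value = x$p_value,
         n_cases = x$n_cases, n_controls = x$n_controls)
}

#' Plot an ROC curve
#'
#' @param object An `epi_roc`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot epi_roc
#' @export
autoplot.epi_roc <- function(object, ...) {
  ggplot(object$points, aes(x = .data$fpf, y = .data$tpf)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey60") +
    geom_step() +
    coord_equal() +
    labs(x = "False positive fraction (1 - specificity)",
         y = "True positive fraction (sensitivity)",
         title = sprintf("AUC = %.3f (95%% CI %.3f-%.3f)",
                         object$auc, object$auc_ci[1], object$auc_ci[2])) +
    theme_minimal()
}
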