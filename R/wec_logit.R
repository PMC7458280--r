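#' Weighted-effect-coded design matrices and logistic model fitting
#'
#' Weighted effect coding (WEC) expresses category effects as deviations
#' from the sample-frequency-weighted mean, so the count-weighted sum of the
#' category effects is zero and effects are interpretable under unbalanced
#' classes. The interaction block extends the idea to a two-factor cell
#' surface with weighted zero sums along every row and column, which is what
#' lets a model with *only* interaction terms represent pure epistasis.
#'
#' @name wec
NULL

genotype_category <- function(g) {
  factor(c("ancestral", "heterozygous", "derived")[g + 1L],
         levels = c("ancestral", "heterozygous", "derived"))
}

#' Main-effect coding columns for one categorical factor
#'
#' Builds the `G - 1` columns of a coding scheme for a factor with `G`
#' categories. For WEC, the column of non-reference category `g` is 1 on
#' `g`, `-n_g / n_ref` on the reference and 0 elsewhere, so the fitted
#' effects satisfy the count-weighted zero sum `sum_g n_g b_g = 0`.
#'
#' @param f Factor (or vector coerced to factor) of category labels.
#' @param scheme `"wec"`, `"effect"` (unweighted, -1 on the reference), or
#'   `"dummy"` (0 on the reference).
#' @param reference Reference category label; defaults to the last level.
#' @return Numeric matrix with one named column per non-reference category.
#' @examples
#' f <- factor(rep(c("A", "B"), c(60, 40)))
#' build_wec_main(f, reference = "B") # 1 on A, -1.5 on B
#' @export
build_wec_main <- function(f, scheme = c("wec", "effect", "dummy"), reference = NULL) {
  scheme <- match.arg(scheme)
  f <- as.factor(f)
  counts <- table(f)
  if (any(counts == 0)) {
    abort(paste("empty categories:", paste(names(counts)[counts == 0], collapse = ", ")))
  }
  if (is.null(reference)) reference <- levels(f)[nlevels(f)]
  if (!reference %in% levels(f)) abort(paste("unknown reference category:", reference))
  others <- setdiff(levels(f), reference)
  x <- vapply(others, function(g) {
    col <- as.numeric(f == g)
    col[f == reference] <- switch(scheme,
      wec = -counts[[g]] / counts[[reference]],
      effect = -1,
      dummy = 0
    )
    col
  }, numeric(length(f)))
  colnames(x) <- others
  x
}

#' Two-factor design with a weighted-effect-coded interaction block
#'
#' Constructs the `(G-1)(H-1)` interaction columns for factors A and B: the
#' column of non-reference cell `(i, j)` takes 1 in cell `(i, j)`,
#' `-n_ij / n_aj` in `(ref_A, j)`, `-n_ij / n_ib` in `(i, ref_B)`,
#' `+n_ij / n_ab` in `(ref_A, ref_B)` and 0 elsewhere (`n` are cell counts).
#' Every column has count-weighted zero sums along each row and column of
#' the A x B table, so the fitted interaction surface satisfies
#' `sum_i n_ij b_ij = 0` for every j and `sum_j n_ij b_ij = 0` for every i,
#' and all cell effects are recoverable from the estimated ones. The span of
#' the block does not depend on the reference cell, so the log-likelihood
#' and the coefficients of cells shared between reference choices are
#' invariant.
#'
#' @param fa,fb Factors (categories of SNP A and SNP B).
#' @param reference_a,reference_b Reference category per factor; default
#'   last level.
#' @param interaction_only Drop the main-effect blocks, keeping intercept +
#'   interaction columns only.
#' @param scheme Coding for the main-effect blocks (and the weighting of the
#'   interaction block); only `"wec"` implements the weighted constraints,
#'   `"effect"` and `"dummy"` are provided for comparison fits.
#' @return A `coded_design` list: `x` (model matrix without intercept),
#'   `cell_counts`, `references`, `scheme`, `interaction_only`,
#'   `interaction_cols` (names of the interaction block).
#' @export
build_wec_interaction <- function(fa, fb, reference_a = NULL, reference_b = NULL,
                                  interaction_only = FALSE,
                                  scheme = c("wec", "effect", "dummy")) {
  scheme <- match.arg(scheme)
  fa <- as.factor(fa); fb <- as.factor(fb)
  stopifnot(length(fa) == length(fb))
  cells <- table(fa, fb)
  if (any(cells == 0)) {
    empty <- which(cells == 0, arr.ind = TRUE)
    abort(paste0("empty A x B cells: ",
                 paste(rownames(cells)[empty[, 1]], colnames(cells)[empty[, 2]],
                       sep = "/", collapse = ", ")))
  }
  if (is.null(reference_a)) reference_a <- levels(fa)[nlevels(fa)]
  if (is.null(reference_b)) reference_b <- levels(fb)[nlevels(fb)]
  if (!reference_a %in% levels(fa)) abort(paste("unknown reference:", reference_a))
  if (!reference_b %in% levels(fb)) abort(paste("unknown reference:", reference_b))
  oa <- setdiff(levels(fa), reference_a)
  ob <- setdiff(levels(fb), reference_b)
  n <- length(fa)
  int_cols <- list()
  for (i in oa) {
    for (j in ob) {
      if (scheme == "wec") {
        nij <- cells[i, j]
        col <- numeric(n)
        col[fa == i & fb == j] <- 1
        col[fa == reference_a & fb == j] <- -nij / cells[reference_a, j]
        col[fa == i & fb == reference_b] <- -nij / cells[i, reference_b]
        col[fa == reference_a & fb == reference_b] <- nij / cells[reference_a, reference_b]
      } else {
        col <- build_wec_main(fa, scheme, reference_a)[, i] *
          build_wec_main(fb, scheme, reference_b)[, j]
      }
      int_cols[[paste(i, j, sep = "-")]] <- col
    }
  }
  xi <- do.call(cbind, int_cols)
  if (interaction_only) {
    x <- xi
  } else {
    xa <- build_wec_main(fa, scheme, reference_a)
    xb <- build_wec_main(fb, scheme, reference_b)
    colnames(xa) <- paste0("A:", colnames(xa))
    colnames(xb) <- paste0("B:", colnames(xb))
    x <- cbind(xa, xb, xi)
  }
  structure(
    list(x = x, cell_counts = cells,
         references = c(a = reference_a, b = reference_b),
         scheme = scheme, interaction_only = interaction_only,
         interaction_cols = colnames(xi)),
    class = "coded_design"
  )
}

#' Maximum-likelihood logistic regression (Newton-Raphson)
#'
#' Fits a Bernoulli-logit model by Newton-Raphson with step halving.
#' Convergence requires the gradient max-norm below `tol` within `max_iter`
#' iterations (otherwise the fit is flagged non-converged). Standard errors
#' come from the inverse observed information; the likelihood-ratio
#' chi-square and McFadden pseudo-R2 are reported against the
#' intercept-only null.
#'
#' @param x Design matrix (no intercept column) or a `coded_design`.
#' @param y Binary outcome vector (both classes required).
#' @param tol Gradient max-norm convergence tolerance.
#' @param max_iter Iteration cap.
#' @return A `logit_fit` list: `coefficients`, `se`, `vcov`, `log_likelihood`,
#'   `null_log_likelihood`, `lr_chi2`, `df`, `lr_p`, `mcfadden_r2`,
#'   `fitted`, `converged`, `separation`, `n`, `design`.
#' @export
fit_logistic <- function(x, y, tol = 1e-8, max_iter = 100) {
  design <- NULL
  if (inherits(x, "coded_design")) {
    design <- x
    x <- x$x
  }
  if (is.null(x)) {
    xm <- matrix(numeric(0), nrow = length(y), ncol = 0)
  } else {
    xm <- as.matrix(x)
  }
  y <- as.numeric(y)
  stopifnot(all(y %in% c(0, 1)), nrow(xm) == length(y))
  if (sum(y) == 0 || sum(y) == length(y)) abort("outcome must contain both classes")
  xm <- cbind(`(Intercept)` = 1, xm)
  qr_x <- qr(xm)
  if (qr_x$rank < ncol(xm)) {
    drop <- colnames(xm)[-qr_x$pivot[seq_len(qr_x$rank)]]
    abort(paste("design is rank deficient; collinear columns:",
                paste(drop, collapse = ", ")))
  }
  beta <- numeric(ncol(xm))
  ll <- function(b) {
    eta <- drop(xm %*% b)
    sum(y * eta - log1p(exp(eta)))
  }
  ll_old <- ll(beta)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(xm %*% beta)
    p <- plogis(eta)
    grad <- drop(crossprod(xm, y - p))
    if (max(abs(grad)) < tol) {
      converged <- TRUE
      break
    }
    w <- p * (1 - p)
    info <- crossprod(xm, xm * w)
    step <- solve(info, grad)
    # step halving keeps the likelihood ascent monotone
    for (h in 0:20) {
      cand <- beta + step / 2^h
      ll_new <- ll(cand)
      if (ll_new >= ll_old - 1e-12) break
    }
    beta <- cand
    ll_old <- ll_new
  }
  eta <- drop(xm %*% beta)
  p <- plogis(eta)
  info <- crossprod(xm, xm * p * (1 - p))
  vc <- solve(info)
  se <- sqrt(diag(vc))
  n1 <- sum(y); n0 <- length(y) - n1
  pb <- n1 / length(y)
  ll_null <- n1 * log(pb) + n0 * log(1 - pb)
  ll_fit <- ll(beta)
  lr <- max(2 * (ll_fit - ll_null), 0)
  df <- ncol(xm) - 1L
  names(beta) <- names(se) <- colnames(xm)
  structure(
    list(coefficients = beta, se = se, vcov = vc,
         log_likelihood = ll_fit, null_log_likelihood = ll_null,
         lr_chi2 = lr, df = df,
         lr_p = if (df > 0) pchisq(lr, df, lower.tail = FALSE) else 1,
         mcfadden_r2 = 1 - ll_fit / ll_null,
         fitted = p, converged = converged,
         separation = any(abs(beta) > 15),
         n = length(y), design = design),
    class = "logit_fit"
  )
}

#' @export
print.logit_fit <- function(x, ...) {
  cat("Logistic fit:", x$n, "subjects,", x$df, "df\n")
  cat(sprintf("  logLik %.3f (null %.3f), LR chi2 %.3f, p %.4g, McFadden R2 %.3f\n",
              x$log_likelihood, x$null_log_likelihood, x$lr_chi2, x$lr_p, x$mcfadden_r2))
  if (!x$converged) cat("  WARNING: not converged\n")
  if (x$separation) cat("  WARNING: possible separation (|coef| > 15)\n")
  print(tidy(x), n = Inf)
  invisible(x)
}

#' Coefficient table of a logistic fit
#'
#' @param x A `logit_fit`.
#' @param ... Unused.
#' @return A tibble: `term`, `estimate`, `std_error`, `ci_half_width`
#'   (1.96 x SE), `conf_low`, `conf_high`, `wald_chi2` (z^2), `p_value`.
#' @method tidy logit_fit
#' @export
tidy.logit_fit <- function(x, ...) {
  z <- x$coefficients / x$se
  tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std_error = unname(x$se),
    ci_half_width = 1.96 * unname(x$se),
    conf_low = unname(x$coefficients - 1.96 * x$se),
    conf_high = unname(x$coefficients + 1.96 * x$se),
    wald_chi2 = unname(z^2),
    p_value = unname(pchisq(z^2, 1, lower.tail = FALSE))
  )
}

#' @rdname tidy.logit_fit
#' @method glance logit_fit
#' @export
glance.logit_fit <- function(x, ...) {
  tibble(
    log_likelihood = x$log_likelihood,
    null_log_likelihood = x$null_log_likelihood,
    lr_chi2 = x$lr_chi2, df = x$df, lr_p = x$lr_p,
    mcfadden_r2 = x$mcfadden_r2,
    aic = -2 * x$log_likelihood + 2 * (x$df + 1),
    n = x$n, converged = x$converged
  )
}

#' Recover the full weighted-effect interaction surface from a fit
#'
#' Applies the weighted zero-sum constraints to reconstruct the effects of
#' the reference row, reference column and reference cell from the
#' estimated interaction coefficients.
#'
#' @param fit A `logit_fit` whose design came from
#'   [build_wec_interaction()] with `scheme = "wec"`.
#' @return A matrix of cell interaction effects over all A x B categories.
#' @export
wec_cell_effects <- function(fit) {
  design <- fit$design
  if (is.null(design) || design$scheme != "wec") {
    abort("fit does not carry a WEC coded_design")
  }
  cells <- design$cell_counts
  ra <- design$references[["a"]]; rb <- design$references[["b"]]
  theta <- matrix(0, nrow(cells), ncol(cells), dimnames = dimnames(cells))
  for (nm in design$interaction_cols) {
    ij <- strsplit(nm, "-", fixed = TRUE)[[1]]
    theta[ij[1], ij[2]] <- fit$coefficients[[nm]]
  }
  oa <- setdiff(rownames(cells), ra)
  ob <- setdiff(colnames(cells), rb)
  for (j in ob) theta[ra, j] <- -sum(cells[oa, j] * theta[oa, j]) / cells[ra, j]
  for (i in oa) theta[i, rb] <- -sum(cells[i, ob] * theta[i, ob]) / cells[i, rb]
  theta[ra, rb] <- -sum(cells[oa, rb] * theta[oa, rb]) / cells[ra, rb]
  theta
}

#' Score new subjects with a fitted WEC interaction-only model
#'
#' The interaction-only model's linear predictor for a subject in cell
#' `(k, l)` is `intercept + theta_kl`, with the full cell surface
#' reconstructed by [wec_cell_effects()]; the training-set cell counts fix
#' the coding, so new subjects are scored by cell membership alone.
#'
#' @param fit A `logit_fit` from a WEC `interaction_only` design.
#' @param fa,fb Genotype category factors of the new subjects (same levels
#'   as training).
#' @return Predicted case probabilities (`NA` for missing genotypes).
#' @export
predict_wec_interaction <- function(fit, fa, fb) {
  theta <- wec_cell_effects(fit)
  fa <- as.character(fa); fb <- as.character(fb)
  eta <- rep(NA_real_, length(fa))
  ok <- !is.na(fa) & !is.na(fb)
  eta[ok] <- fit$coefficients[["(Intercept)"]] + theta[cbind(fa[ok], fb[ok])]
  plogis(eta)
}

#' Compare fitted logistic models
#'
#' Per-model summary plus likelihood-ratio tests for declared nested pairs;
#' a pair whose degrees of freedom do not increase raises an error (use AIC
#' from the summary instead).
#'
#' @param fits Named list of `logit_fit` objects on the same subjects.
#' @param nested_pairs Optional list of `c(smaller, larger)` name pairs to
#'   LR-test.
#' @return A list of tibbles `models` and `lr_tests`.
#' @export
compare_models <- function(fits, nested_pairs = NULL) {
  stopifnot(is.list(fits), !is.null(names(fits)))
  ns <- vapply(fits, function(f) f$n, numeric(1))
  if (length(unique(ns)) != 1) abort("models were fitted on different subject counts")
  models <- purrr::imap_dfr(fits, function(f, nm) {
    dplyr::bind_cols(tibble(model = nm), glance(f))
  })
  lr_tests <- NULL
  if (!is.null(nested_pairs)) {
    lr_tests <- purrr::map_dfr(nested_pairs, function(pr) {
      small <- fits[[pr[1]]]; big <- fits[[pr[2]]]
      ddf <- big$df - small$df
      if (ddf <= 0) abort(paste("pair", pr[1], "->", pr[2], "is not df-nested; compare by AIC"))
      chi2 <- max(2 * (big$log_likelihood - small$log_likelihood), 0)
      tibble(smaller = pr[1], larger = pr[2],
             delta_ll = big$log_likelihood - small$log_likelihood,
             lr_chi2 = chi2, df = ddf,
             p_value = pchisq(chi2, ddf, lower.tail = FALSE))
    })
  }
  list(models = models, lr_tests = lr_tests)
}

#' Weighted-effect-coded interaction analysis for one SNP pair
#'
#' Fits the three models the epistasis analysis compares: the full model
#' (WEC main effects + interaction block, 8 df for two 3-category SNPs),
#' the interaction-only model (intercept + 4 interaction columns), and the
#' additive-only model (each SNP as a numeric 0/1/2 dose, 2 df).
#'
#' @param gm A [genotype_table()].
#' @param snp_a,snp_b SNP names.
#' @param reference_a,reference_b Reference genotype categories
#'   (`"ancestral"`, `"heterozygous"`, `"derived"`); default `"derived"`,
#'   the minor-homozygote reference.
#' @param subset Optional row indices (e.g. a training partition).
#' @return A `wec_analysis` list: `full`, `interaction_only`, `additive`
#'   (`logit_fit`s), `comparison` (from [compare_models()]), `cell_counts`.
#' @export
wec_interaction_analysis <- function(gm, snp_a, snp_b,
                                     reference_a = "derived",
                                     reference_b = "derived",
                                     subset = NULL) {
  if (!is.null(subset)) gm <- gm[subset, ]
  ok <- !is.na(gm[[snp_a]]) & !is.na(gm[[snp_b]])
  gm <- gm[ok, ]
  fa <- droplevels(genotype_category(gm[[snp_a]]))
  fb <- droplevels(genotype_category(gm[[snp_b]]))
  y <- gm$status
  full <- fit_logistic(build_wec_interaction(fa, fb, reference_a, reference_b), y)
  int_only <- fit_logistic(
    build_wec_interaction(fa, fb, reference_a, reference_b, interaction_only = TRUE), y)
  additive <- fit_logistic(
    cbind(dose_a = as.numeric(gm[[snp_a]]), dose_b = as.numeric(gm[[snp_b]])), y)
  structure(
    list(full = full, interaction_only = int_only, additive = additive,
         comparison = compare_models(
           list(additive = additive, interaction_only = int_only, full = full),
           nested_pairs = list(c("interaction_only", "full"))),
         cell_counts = table(fa, fb, gm$status),
         snps = c(snp_a, snp_b)),
    class = "wec_analysis"
  )
}
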