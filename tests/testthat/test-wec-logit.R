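sim_two_snp_gm <- function(n = 400, maf_a = 0.4, maf_b = 0.35, seed = 1) {
  withr::with_seed(seed, {
    draw <- function(maf) sample(0:2, n, replace = TRUE,
                                 prob = c((1 - maf)^2, 2 * maf * (1 - maf), maf^2))
    ga <- draw(maf_a); gb <- draw(maf_b)
    status <- rbinom(n, 1, plogis(-1 + 0.4 * (ga == 1 & gb == 1) - 0.3 * (ga == 2)))
    tibble::tibble(ga = ga, gb = gb, status = status)
  })
}

tibble_to_gm <- function(df) {
  genotype_table(tibble::tibble(
    sample = paste0("S", seq_len(nrow(df))),
    status = as.integer(df$status),
    snpA = as.integer(df$ga),
    snpB = as.integer(df$gb)
  ))
}

geno_factor <- function(g) {
  factor(c("ancestral", "heterozygous", "derived")[g + 1],
         levels = c("ancestral", "heterozygous", "derived"))
}

test_that("WEC main columns carry the -n_g/n_ref reference weight", {
  f <- factor(rep(c("A", "B"), c(60, 40)))
  x <- build_wec_main(f, reference = "B")
  expect_equal(colnames(x), "A")
  expect_equal(unique(x[f == "A", 1]), 1)
  expect_equal(unique(x[f == "B", 1]), -1.5)
  # balanced counts reduce WEC to unweighted effect coding
  fb <- factor(rep(c("A", "B"), each = 50))
  expect_equal(build_wec_main(fb, "wec", "B"), build_wec_main(fb, "effect", "B"))
  expect_error(build_wec_main(factor("A", levels = c("A", "B"))), "empty categories")
})

test_that("fitted WEC main effects satisfy the weighted zero sum and refit oracle", {
  withr::with_seed(2, {
    f <- factor(sample(c("a", "b", "c"), 300, replace = TRUE, prob = c(0.5, 0.3, 0.2)))
    y <- rbinom(300, 1, plogis(-0.5 + 0.6 * (f == "a") - 0.4 * (f == "b")))
  })
  counts <- table(f)
  fit_c <- fit_logistic(build_wec_main(f, reference = "c"), y)
  b <- fit_c$coefficients[c("a", "b")]
  b_ref <- -sum(counts[c("a", "b")] * b) / counts[["c"]]
  expect_equal(sum(counts * c(b[["a"]], b[["b"]], b_ref)), 0, tolerance = 1e-8)
  # switching the reference reproduces the recovered effect directly
  fit_a <- fit_logistic(build_wec_main(f, reference = "a"), y)
  expect_equal(unname(fit_a$coefficients[["c"]]), b_ref, tolerance = 1e-6)
  expect_equal(fit_a$log_likelihood, fit_c$log_likelihood, tolerance = 1e-8)
})

test_that("balanced 2x2 WEC interaction is the classical +/-1 product pattern", {
  fa <- factor(rep(c("x", "y"), each = 50))
  fb <- factor(rep(rep(c("u", "v"), each = 25), 2))
  d <- build_wec_interaction(fa, fb, reference_a = "y", reference_b = "v",
                             interaction_only = TRUE)
  expect_equal(ncol(d$x), 1)
  expect_equal(sort(unique(d$x[, 1])), c(-1, 1))
  expect_equal(d$x[fa == "x" & fb == "u", 1][1], 1)
  expect_equal(d$x[fa == "x" & fb == "v", 1][1], -1)
})

test_that("3x3 interaction block has 4 named columns and errors on empty cells", {
  withr::with_seed(7, {
    ga <- sample(0:2, 500, replace = TRUE, prob = c(0.4, 0.4, 0.2))
    gb <- sample(0:2, 500, replace = TRUE, prob = c(0.45, 0.4, 0.15))
  })
  d <- build_wec_interaction(geno_factor(ga), geno_factor(gb),
                             reference_a = "derived", reference_b = "derived",
                             interaction_only = TRUE)
  expect_setequal(colnames(d$x),
                  c("heterozygous-heterozygous", "heterozygous-ancestral",
                    "ancestral-heterozygous", "ancestral-ancestral"))
  sparse_a <- geno_factor(c(rep(0, 10), rep(1, 10)))
  sparse_b <- geno_factor(c(rep(0, 10), rep(1, 10)))
  expect_error(build_wec_interaction(droplevels(sparse_a), droplevels(sparse_b)),
               "empty A x B cells")
})

test_that("WEC interaction surface satisfies both weighted zero-sum families", {
  df <- sim_two_snp_gm(n = 600, seed = 3)
  fa <- geno_factor(df$ga); fb <- geno_factor(df$gb)
  fit <- fit_logistic(build_wec_interaction(fa, fb, "derived", "derived",
                                            interaction_only = TRUE), df$status)
  theta <- wec_cell_effects(fit)
  cells <- table(fa, fb)
  for (j in colnames(cells)) {
    expect_equal(sum(cells[, j] * theta[, j]), 0, tolerance = 1e-8)
  }
  for (i in rownames(cells)) {
    expect_equal(sum(cells[i, ] * theta[i, ]), 0, tolerance = 1e-8)
  }
})

test_that("reference choice changes neither likelihood nor shared cell effects", {
  df <- sim_two_snp_gm(n = 500, seed = 4)
  fa <- geno_factor(df$ga); fb <- geno_factor(df$gb)
  refs <- list(c("derived", "derived"), c("heterozygous", "heterozygous"),
               c("ancestral", "ancestral"))
  fits <- lapply(refs, function(r) {
    fit_logistic(build_wec_interaction(fa, fb, r[1], r[2], interaction_only = TRUE),
                 df$status)
  })
  lls <- vapply(fits, function(f) f$log_likelihood, numeric(1))
  expect_equal(max(lls) - min(lls), 0, tolerance = 1e-8)
  # the full reconstructed surfaces coincide, so shared coefficients do too
  thetas <- lapply(fits, wec_cell_effects)
  expect_equal(thetas[[1]], thetas[[2]], tolerance = 1e-6)
  expect_equal(thetas[[1]], thetas[[3]], tolerance = 1e-6)
  # intercepts agree as well (the weighted grand mean)
  ints <- vapply(fits, function(f) f$coefficients[["(Intercept)"]], numeric(1))
  expect_equal(max(ints) - min(ints), 0, tolerance = 1e-6)
})

test_that("intercept-only fits have the closed-form MLE and likelihood", {
  y <- c(rep(1, 64), rep(0, 218))
  fit <- fit_logistic(NULL, y)
  expect_equal(unname(fit$coefficients[["(Intercept)"]]), log(64 / 218), tolerance = 1e-8)
  p <- 64 / 282
  expect_equal(fit$log_likelihood, 282 * (p * log(p) + (1 - p) * log(1 - p)),
               tolerance = 1e-8)
  expect_equal(round(fit$log_likelihood, 2), -151.03)
})

test_that("the Newton fit matches glm on random designs", {
  withr::with_seed(9, {
    for (i in 1:5) {
      n <- 250
      x <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("x1", "x2", "x3")))
      y <- rbinom(n, 1, plogis(0.3 + x %*% c(0.8, -0.5, 0)))
      fit <- fit_logistic(x, y)
      ref <- glm(y ~ x, family = binomial())
      expect_true(fit$converged)
      expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-6)
      expect_equal(unname(fit$se), unname(sqrt(diag(vcov(ref)))), tolerance = 1e-3)
      expect_equal(fit$log_likelihood, as.numeric(logLik(ref)), tolerance = 1e-8)
      # score equation: fitted probabilities sum to the case count
      expect_equal(sum(fit$fitted), sum(y), tolerance = 1e-6)
    }
  })
})

test_that("dummy, effect and WEC codings of the saturated model agree in LL", {
  withr::with_seed(10, {
    f <- factor(sample(c("a", "b", "c"), 200, replace = TRUE))
    y <- rbinom(200, 1, plogis(0.5 * (f == "a") - 0.5 * (f == "c")))
  })
  lls <- vapply(c("dummy", "effect", "wec"), function(s) {
    fit_logistic(build_wec_main(f, s, reference = "c"), y)$log_likelihood
  }, numeric(1))
  expect_equal(max(lls) - min(lls), 0, tolerance = 1e-8)
})

test_that("rank deficiency and separation are reported", {
  x <- cbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8))
  expect_error(fit_logistic(x, c(0, 1, 0, 1)), "collinear.*b")
  sep <- fit_logistic(cbind(z = c(rep(0, 20), rep(1, 20))),
                      c(rep(0, 20), rep(1, 20)))
  expect_true(sep$separation)
})

test_that("brute-force grid maximization agrees on a 2-parameter toy problem", {
  withr::with_seed(14, {
    x <- matrix(rnorm(80), 80, 1, dimnames = list(NULL, "x"))
    y <- rbinom(80, 1, plogis(0.5 + 0.9 * x[, 1]))
  })
  fit <- fit_logistic(x, y)
  grid <- expand.grid(b0 = seq(-2, 2, by = 0.01), b1 = seq(-2, 3, by = 0.01))
  ll <- function(b0, b1) sum(y * (b0 + b1 * x[, 1]) - log1p(exp(b0 + b1 * x[, 1])))
  lls <- mapply(ll, grid$b0, grid$b1)
  best <- grid[which.max(lls), ]
  expect_equal(unname(fit$coefficients[["(Intercept)"]]), best$b0, tolerance = 1e-2)
  expect_equal(unname(fit$coefficients[["x"]]), best$b1, tolerance = 1e-2)
})

test_that("model comparison reports per-model stats and nested LR tests", {
  df <- sim_two_snp_gm(n = 400, seed = 5)
  an <- wec_interaction_analysis(
    tibble_to_gm(df), "snpA", "snpB",
    reference_a = "derived", reference_b = "derived")
  cmp <- an$comparison
  expect_setequal(cmp$models$model, c("additive", "interaction_only", "full"))
  expect_equal(cmp$models$df[cmp$models$model == "full"], 8)
  expect_equal(cmp$models$df[cmp$models$model == "interaction_only"], 4)
  expect_equal(cmp$models$df[cmp$models$model == "additive"], 2)
  lr <- cmp$lr_tests
  expect_equal(lr$df, 4)
  expect_gte(lr$lr_chi2, 0)
  # identical models give LR chi2 = 0
  same <- compare_models(list(m1 = an$full, m2 = an$full))
  expect_equal(diff(same$models$log_likelihood), 0)
  expect_error(compare_models(list(a = an$full, b = an$additive),
                              nested_pairs = list(c("a", "b"))), "nested")
})
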