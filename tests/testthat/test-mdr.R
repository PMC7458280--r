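make_epistatic_gm <- function(n_cases = 1000, n_controls = 1000, n_noise = 3,
                              high = 0.8, low = 0.2, seed = 1) {
  noise <- if (n_noise > 0) paste0("noise", seq_len(n_noise)) else character(0)
  snps <- tibble::tibble(
    name = c("locA", "locB", noise),
    maf = rep(0.5, 2 + n_noise)
  )
  cfg <- simulation_config(
    n_cases, n_controls, snps,
    epistatic_pair = list(snp_a = "locA", snp_b = "locB",
                          penetrance = xor_penetrance(high, low)),
    seed = seed
  )
  generate_genotypes(cfg)
}

test_that("cell labeling compares case:control ratios to the training ratio", {
  df <- tibble::tibble(
    sample = paste0("S", 1:20),
    status = c(rep(1L, 5), rep(0L, 15)),
    rs1 = c(rep(0L, 5), rep(0L, 5), rep(1L, 10))
  )
  cells <- mdr_label_cells(genotype_table(df), "rs1")
  # cell 0: 5 cases / 5 controls, overall ratio 1:3 -> weighted ratio 3 -> high
  expect_equal(unname(cells$cell_labels[["0"]]), "high")
  # cell 1: 0 cases -> low
  expect_equal(unname(cells$cell_labels[["1"]]), "low")
  expect_equal(cells$case_weight, 5 / 15)
})

test_that("ratio-based labeling is invariant to duplicating every control", {
  gm <- make_gm(n_cases = 15, n_controls = 25, n_snps = 2, seed = 6)
  dup <- tibble::as_tibble(gm)
  ctrl <- dup[dup$status == 0, ]
  ctrl$sample <- paste0(ctrl$sample, "_dup")
  dup <- genotype_table(dplyr::bind_rows(dup, ctrl))
  l1 <- mdr_label_cells(gm, c("rs1", "rs2"))$cell_labels
  l2 <- mdr_label_cells(dup, c("rs1", "rs2"))$cell_labels
  expect_identical(l1[order(names(l1))], l2[order(names(l2))])
})

test_that("ties at the threshold label high; one-class training errors", {
  df <- tibble::tibble(
    sample = paste0("S", 1:8),
    status = rep(c(1L, 0L), 4),
    rs1 = rep(0L, 8)
  )
  cells <- mdr_label_cells(genotype_table(df), "rs1")
  expect_equal(unname(cells$cell_labels[["0"]]), "high") # ratio exactly at threshold
  one_class <- df
  one_class$status <- c(1L, rep(0L, 7))
  gm_oc <- genotype_table(one_class)
  expect_error(mdr_label_cells(gm_oc[gm_oc$status == 0, , drop = FALSE], "rs1"),
               "both classes")
})

test_that("XOR penetrance labeling recovers the analytic high/low map", {
  gm <- make_epistatic_gm(high = 0.9, low = 0.1, n_noise = 0, seed = 4)
  cells <- mdr_label_cells(gm, c("locA", "locB"))
  for (a in 0:2) {
    for (b in 0:2) {
      expected <- if ((a %% 2) != (b %% 2)) "high" else "low"
      expect_equal(unname(cells$cell_labels[[paste(a, b, sep = "|")]]), expected)
    }
  }
})

test_that("classification follows cell labels and the unseen policy", {
  train <- genotype_table(tibble::tibble(
    sample = paste0("T", 1:8),
    status = c(1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L),
    rs1 = c(0L, 0L, 1L, 1L, 1L, 1L, 1L, 1L)
  ))
  cells <- mdr_label_cells(train, "rs1")
  new <- genotype_table(tibble::tibble(
    sample = paste0("N", 1:3), status = c(1L, 0L, 0L),
    rs1 = c(0L, 1L, 2L) # 2 unseen in training
  ))
  expect_equal(mdr_classify(new, cells, "control"), c(1L, 0L, 0L))
  expect_equal(mdr_classify(new, cells, "case"), c(1L, 0L, 1L))
  pred <- mdr_classify(new, cells, "abstain")
  expect_true(is.na(pred[3]))
  m <- evaluate_classifier(pred, new$status)
  expect_equal(m$n_abstain, 1)
})

test_that("a single informative locus wins the k = 1 search with full CVC", {
  snps <- tibble::tibble(name = c("sig", paste0("noise", 1:4)), maf = rep(0.5, 5))
  # penetrance depends on the 'sig' dose only; 'noise1' is a dummy partner
  pen <- outer(c(0.1, 0.45, 0.8), rep(1, 3))
  cfg <- simulation_config(1000, 1000, snps,
                           epistatic_pair = list(snp_a = "sig", snp_b = "noise1",
                                                 penetrance = pen),
                           seed = 11)
  gm <- generate_genotypes(cfg)
  res <- mdr_search(gm, max_k = 1, folds = 10, seed = 2)
  expect_equal(res$combo[1], "sig")
  expect_equal(res$cvc[1], 10)
})

test_that("search is deterministic given the seed", {
  gm <- make_epistatic_gm(n_cases = 200, n_controls = 200, n_noise = 2, seed = 5)
  r1 <- mdr_search(gm, max_k = 2, folds = 5, seed = 9)
  r2 <- mdr_search(gm, max_k = 2, folds = 5, seed = 9)
  expect_identical(r1$combo, r2$combo)
  expect_identical(r1$mean_test_bal_acc, r2$mean_test_bal_acc)
})

test_that("the combinatorial guard refuses runaway searches unless forced", {
  df <- tibble::tibble(sample = paste0("S", 1:30),
                       status = rep(c(1L, 0L), 15))
  for (j in 1:21) df[[paste0("rs", j)]] <- rep(0:2, 10)
  gm <- genotype_table(df)
  expect_error(mdr_search(gm, max_k = 5, folds = 2), "force")
})

test_that("permutation p-values behave at the boundaries", {
  # perfectly separable signal: no permutation generically reaches it
  df <- tibble::tibble(
    sample = paste0("S", 1:60),
    status = rep(c(1L, 0L), each = 30),
    rs1 = rep(c(2L, 0L), each = 30)
  )
  gm <- genotype_table(df)
  pt <- mdr_permutation_test(gm, "rs1", n_perm = 100, folds = 5, seed = 3)
  expect_equal(pt$observed, 1)
  expect_equal(pt$p_value, 1 / 101)

  # sanity bound: an observed statistic below the permutation median cannot
  # look significant
  gm2 <- make_gm(n_cases = 40, n_controls = 40, n_snps = 1, seed = 12)
  pt2 <- mdr_permutation_test(gm2, "rs1", n_perm = 100, folds = 5, seed = 3)
  expect_true(pt2$observed >= stats::median(pt2$perm_stats) || pt2$p_value > 0.5)
  expect_gt(pt2$p_value, 1 / 101)
})

test_that("classification metrics satisfy their algebraic identities", {
  withr::with_seed(31, {
    for (i in 1:20) {
      truth <- sample(0:1, 60, replace = TRUE, prob = c(0.6, 0.4))
      if (length(unique(truth)) < 2) next
      pred <- sample(0:1, 60, replace = TRUE)
      m <- evaluate_classifier(pred, truth)
      expect_equal(m$balanced_accuracy, (m$sensitivity + m$specificity) / 2,
                   tolerance = 1e-12)
      if (!is.na(m$f1)) {
        expect_equal(m$f1, 2 * m$precision * m$sensitivity /
                       (m$precision + m$sensitivity), tolerance = 1e-12)
      }
      expect_true(all(unlist(m[c("sensitivity", "specificity", "accuracy")]) >= 0))
      expect_true(all(unlist(m[c("sensitivity", "specificity", "accuracy")]) <= 1))
    }
  })
})

test_that("metric extremes: perfect and all-control classifiers", {
  truth <- c(1, 1, 0, 0, 0)
  perfect <- evaluate_classifier(truth, truth)
  expect_equal(perfect$kappa, 1)
  expect_equal(perfect$f1, 1)
  expect_equal(perfect$balanced_accuracy, 1)
  allc <- evaluate_classifier(rep(0, 5), truth)
  expect_equal(allc$sensitivity, 0)
  expect_equal(allc$specificity, 1)
  expect_equal(allc$balanced_accuracy, 0.5)
  expect_error(evaluate_classifier(rep(1, 4), rep(1, 4)), "both classes")
})

test_that("a 19/36 hold-out confusion yields 52.78% accuracy", {
  # 4 athletes and 15 sedentary classified correctly out of 9 + 27
  pred <- c(rep(1, 4), rep(0, 5), rep(0, 15), rep(1, 12))
  truth <- c(rep(1, 9), rep(0, 27))
  m <- evaluate_classifier(pred, truth)
  expect_equal(round(m$accuracy, 4), 0.5278)
})

test_that("mdr_fit reports train and test metrics for a hold-out", {
  gm <- make_epistatic_gm(n_cases = 150, n_controls = 150, n_noise = 1, seed = 8)
  sp <- holdout_split(gm, 0.2, seed = 2)
  fit <- mdr_fit(gm, c("locA", "locB"), sp)
  expect_gt(fit$train_metrics$balanced_accuracy, 0.6)
  expect_gt(fit$test_metrics$balanced_accuracy, 0.5)
})
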