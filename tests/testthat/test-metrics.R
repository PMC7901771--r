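test_that("metrics reproduce the published worked examples", {
  # balanced 200-sample independent set, merged-seq model (SC)
  m <- compute_metrics(tp = 80, fn = 20, tn = 73, fp = 27)
  expect_equal(round(m$sensitivity, 3), 0.800)
  expect_equal(round(m$specificity, 3), 0.730)
  expect_equal(round(m$accuracy, 3), 0.765)
  expect_equal(round(m$mcc, 2), 0.53)

  # the HS counterpart
  m <- compute_metrics(tp = 73, fn = 27, tn = 75, fp = 25)
  expect_equal(round(m$accuracy, 2), 0.74)
  expect_equal(round(m$mcc, 2), 0.48)

  expect_equal(compute_metrics(tp = 25, tn = 25, fp = 25, fn = 25)$mcc, 0)

  m <- compute_metrics(tp = 50, tn = 50, fp = 0, fn = 0)
  expect_equal(unlist(m), c(sensitivity = 1, specificity = 1,
                            accuracy = 1, mcc = 1))
})

test_that("zero-denominator metrics are flagged undefined, not NaN", {
  m <- compute_metrics(tp = 0, fn = 0, tn = 5, fp = 5)
  expect_true(is.na(m$sensitivity))
  expect_false(is.nan(m$sensitivity))
  expect_true(is.na(m$mcc))
  expect_equal(m$specificity, 0.5)
  expect_error(compute_metrics(tp = 0, tn = 0, fp = 0, fn = 0), "at least one")
})

test_that("metrics agree with a brute-force recount on random inputs", {
  withr::with_seed(101, {
    for (case in 1:1000) {
      counts <- sample(0:40, 4, replace = TRUE)
      if (sum(counts) == 0) counts[1] <- 1
      truth <- rep(c(1, 0, 0, 1), counts)
      predicted <- rep(c(1, 0, 1, 0), counts)
      perm <- sample(length(truth))
      oracle <- naive_metrics_from_pairs(truth[perm], predicted[perm])
      cc <- confusion_counts(truth[perm], predicted[perm])
      expect_equal(unlist(cc),
                   c(tp = oracle$tp, tn = oracle$tn,
                     fp = oracle$fp, fn = oracle$fn))
      m <- compute_metrics(cc)
      expect_equal(m$sensitivity, oracle$sensitivity)
      expect_equal(m$specificity, oracle$specificity)
      expect_equal(m$accuracy, oracle$accuracy)
      expect_equal(m$mcc, oracle$mcc)
    }
  })
})

test_that("balanced sets satisfy accuracy == (SN + SP) / 2 exactly", {
  withr::with_seed(11, {
    for (case in 1:50) {
      npos <- sample(5:50, 1)
      tp <- sample(0:npos, 1)
      tn <- sample(0:npos, 1)
      m <- compute_metrics(tp = tp, fn = npos - tp, tn = tn, fp = npos - tn)
      expect_equal(m$accuracy, (m$sensitivity + m$specificity) / 2)
    }
  })
})

test_that("ROC/AUC covers the boundary and exchangeable cases", {
  labels <- rep(c(1, 0), each = 100)
  perfect <- c(runif(100, 0.6, 1), runif(100, 0, 0.4))
  expect_equal(roc_auc(perfect, labels)$auc, 1.0)
  expect_equal(roc_auc(1 - perfect, labels)$auc, 0.0)

  withr::with_seed(77, {
    scores <- runif(2000)
    y <- rep(c(0, 1), 1000)
    expect_lt(abs(roc_auc(scores, y)$auc - 0.5), 0.03)
  })

  expect_error(roc_auc(runif(5), rep(1, 5)), "positive and.*negative")
})

test_that("AUC is invariant under strictly monotone score transforms", {
  withr::with_seed(13, {
    scores <- rnorm(300)
    y <- rbinom(300, 1, plogis(scores))
    a0 <- roc_auc(scores, y)$auc
    expect_equal(roc_auc(exp(scores), y)$auc, a0)
    expect_equal(roc_auc(qlogis(plogis(scores)), y)$auc, a0)
    expect_equal(roc_auc(rank(scores), y)$auc, a0)
  })
})

test_that("AUC matches an independent implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(29, {
    scores <- round(runif(200), 2)   # forces ties
    y <- rbinom(200, 1, 0.5)
    ours <- roc_auc(scores, y)$auc
    ref <- as.numeric(pROC::auc(pROC::roc(y, scores, quiet = TRUE,
                                          direction = "<")))
    expect_equal(ours, ref, tolerance = 1e-12)
  })
})

test_that("ROC point list runs from (0,0) to (1,1) monotonically", {
  withr::with_seed(31, {
    r <- roc_auc(runif(50), rbinom(50, 1, 0.5))
    expect_equal(r$points$fpr[1], 0)
    expect_equal(r$points$tpr[1], 0)
    expect_equal(r$points$fpr[nrow(r$points)], 1)
    expect_equal(r$points$tpr[nrow(r$points)], 1)
    expect_true(all(diff(r$points$fpr) >= 0))
    expect_true(all(diff(r$points$tpr) >= 0))
  })
})

test_that("relative improvement reproduces the comparison arithmetic", {
  expect_equal(relative_improvement(85.61, 71.18, digits = 2), 20.27)
  expect_equal(relative_improvement(80.00, 68.76, digits = 2), 16.34)
  expect_equal(relative_improvement(42, 42), 0)
  expect_warning(out <- relative_improvement(5, 0), "zero baseline")
  expect_true(is.na(out))
})

test_that("comparison tables embed the published improvement figures", {
  ours <- tibble::tibble(predictor = "merged-seq", dataset = "SC_200",
                         ac = 76.5, sn = 80.00, sp = 73.00, mcc = 0.53)
  tab <- comparison_table(ours)   # reference: best published AC = iPseU-CNN
  our_row <- tab[tab$source == "ours", ]
  expect_equal(our_row$impr_ac, 4.08)
  expect_equal(our_row$impr_sn, 16.34)
  expect_equal(our_row$impr_mcc, 12.76)

  # empty published set -> our metrics only
  tab0 <- comparison_table(ours, published = published_benchmarks()[0, ])
  expect_equal(nrow(tab0), 1L)
  expect_true(is.na(tab0$impr_ac))

  # mismatched metric sets -> absent cells
  partial <- tibble::tibble(predictor = "x", dataset = "SC_200", ac = 70)
  tabp <- comparison_table(partial)
  expect_true(is.na(tabp$sn[tabp$source == "ours"]))
})
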