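test_that("confusion cells count the four outcomes", {
  cc <- count_confusion(c(TRUE, TRUE, FALSE, FALSE),
                        c(TRUE, FALSE, TRUE, FALSE))
  expect_identical(unlist(cc[c("tp", "fn", "fp", "tn")]),
                   c(tp = 1L, fn = 1L, fp = 1L, tn = 1L))
  cc2 <- count_confusion(rep(c("cleaved", "not_cleaved"), c(5, 5)),
                         rep(c("cleaved", "not_cleaved"), c(5, 5)))
  expect_identical(unlist(cc2), c(tp = 5L, tn = 5L, fp = 0L, fn = 0L))
  cc3 <- count_confusion(c(TRUE, TRUE, FALSE, FALSE, FALSE),
                         rep(TRUE, 5))
  expect_identical(unlist(cc3), c(tp = 2L, tn = 0L, fp = 3L, fn = 0L))
  expect_error(count_confusion(TRUE, c(TRUE, FALSE)), "length")
  expect_error(count_confusion("yes", "yes"), "unknown label")
})

test_that("derived statistics match independent literal formulas", {
  set.seed(13)
  for (i in 1:25) {
    q <- as.list(rpois(4, 40) + 1)
    names(q) <- c("tp", "tn", "fp", "fn")
    m <- compute_metrics(do.call(confusion_counts, q))
    with(q, {
      expect_equal(m$ccr, (tp + tn) / (tp + tn + fp + fn))
      expect_equal(m$sensitivity, tp / (tp + fn))
      expect_equal(m$specificity, tn / (tn + fp))
      expect_equal(m$ppv, tp / (tp + fp))
      expect_equal(m$npv, tn / (tn + fn))
      expect_equal(m$mcc, (tp * tn - fp * fn) /
                     sqrt(tp + fp) / sqrt(tp + fn) /
                     sqrt(tn + fp) / sqrt(tn + fn))
      expect_equal(m$sensitivity * (tp + fn), tp)
    })
  }
})

test_that("zero denominators give undefined metrics, never NaN", {
  m <- compute_metrics(confusion_counts(tp = 0, tn = 7, fp = 0, fn = 0))
  expect_identical(m$ccr, 1.0)
  expect_true(is.na(m$sensitivity))
  expect_true(is.na(m$ppv))
  expect_identical(m$specificity, 1.0)
  expect_false(any(is.nan(unlist(m[c("ccr", "specificity", "npv")]))))
  expect_error(compute_metrics(confusion_counts(0, 0, 0, 0)), "zero")
  expect_output(print(m), "undefined")
})

test_that("MCC is symmetric under class swap and negates under inversion", {
  set.seed(14)
  for (i in 1:20) {
    q <- rpois(4, 30) + 1
    m <- compute_metrics(confusion_counts(q[1], q[2], q[3], q[4]))
    swapped <- compute_metrics(confusion_counts(q[2], q[1], q[4], q[3]))
    expect_equal(swapped$mcc, m$mcc)
    inverted <- compute_metrics(confusion_counts(q[4], q[3], q[2], q[1]))
    expect_equal(inverted$mcc, -m$mcc)
  }
})

test_that("rank AUC equals the exhaustive pairwise probability", {
  expect_identical(roc_auc(c(TRUE, FALSE), c(0.9, 0.1)), 1.0)
  expect_identical(roc_auc(c(TRUE, FALSE, TRUE), rep(0.3, 3)), 0.5)
  expect_error(roc_auc(c(TRUE, TRUE), c(0.1, 0.9)), "both classes")

  set.seed(15)
  for (i in 1:40) {
    n <- sample(5:20, 1)
    labels <- c(TRUE, FALSE, runif(n - 2) < 0.4)
    scores <- round(runif(n), 2)  # rounding forces ties
    pairs <- expand.grid(p = scores[labels], n = scores[!labels])
    brute <- mean((pairs$p > pairs$n) + 0.5 * (pairs$p == pairs$n))
    expect_equal(roc_auc(labels, scores), brute)
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(16)
  labels <- runif(60) < 0.3
  labels[1:2] <- c(TRUE, FALSE)
  scores <- runif(60)
  a <- roc_auc(labels, scores)
  expect_equal(roc_auc(labels, plogis(5 * scores - 1)), a)
  expect_equal(roc_auc(labels, scores^3 + 2), a)
  expect_equal(roc_auc(labels, rank(scores)), a)
})

test_that("rank AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(17)
  labels <- runif(80) < 0.3
  labels[1:2] <- c(TRUE, FALSE)
  scores <- round(runif(80), 1)
  expect_equal(roc_auc(labels, scores),
               as.numeric(pROC::auc(pROC::roc(labels, scores,
                                              quiet = TRUE,
                                              direction = "<"))))
})

test_that("evaluate_model chains scores, threshold, confusion and metrics", {
  set.seed(18)
  sites <- separable_sites(10)
  model <- train_logistic(sites, scheme = "AA", seed = 1)
  rep_ <- evaluate_model(model, sites)
  expect_s3_class(rep_, "metrics_report")
  # internal consistency: metrics derive from the stored counts
  again <- compute_metrics(rep_$counts)
  for (f in c("ccr", "sensitivity", "specificity", "ppv", "npv", "mcc")) {
    expect_identical(rep_[[f]], again[[f]])
  }
  expect_false(is.na(rep_$auc))
  expect_true(is.na(evaluate_model(known_motif_model(), sites)$auc))

  # all-0.5 scores with the >= convention call everything cleaved
  flat <- model
  flat$parameters$weights[] <- 0
  flat$parameters$intercept <- 0
  r2 <- evaluate_model(flat, sites)
  expect_identical(r2$sensitivity, 1.0)
  expect_identical(r2$specificity, 0.0)

  expect_error(evaluate_model(model, sites[0, ]), "labelled")
})

test_that("comparison tables have the criteria-by-model layout and CCR ranking", {
  set.seed(19)
  sites <- separable_sites(10)
  good <- evaluate_model(train_logistic(sites, scheme = "AA", seed = 1),
                         sites)
  rule <- evaluate_model(known_motif_model(), sites)
  cmp <- compare_models(list(rule = rule, logistic = good, rule2 = rule))
  expect_identical(dim(cmp$table), c(11L, 3L))
  expect_identical(rownames(cmp$table)[c(1, 5, 10, 11)],
                   c("True Positives", "Correct Classification",
                     "Correlation", "AUC"))
  expect_identical(cmp$table[, "rule"], cmp$table[, "rule2"])
  expect_identical(cmp$ranking[1], "logistic")
  expect_identical(cmp$table["AUC", "rule"], "-")
  expect_error(compare_models(list(a = good)), "at least two")
})
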