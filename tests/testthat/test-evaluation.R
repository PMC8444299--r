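test_that("youden_cutoff separates a clean gap at its midpoint", {
  labs <- factor(c("low", "low", "high", "high"), levels = c("low", "high"))
  expect_equal(youden_cutoff(c(0.1, 0.2, 0.8, 0.9), labs), 0.5)
  # degenerate: constant probabilities carry no information, J = 0 anywhere;
  # the lowest candidate is returned
  labs2 <- factor(c("low", "high", "low", "high"), levels = c("low", "high"))
  ct <- youden_cutoff(c(0.4, 0.4, 0.4, 0.4), labs2)
  expect_lte(ct, 0.4)
  expect_error(youden_cutoff(c(0.1, 0.9), factor(c("high", "high"),
                                                 levels = c("low", "high"))),
               "both classes")
})

test_that("youden_cutoff attains the brute-force maximal J on random instances", {
  set.seed(101)
  worst <- 0
  for (k in 1:100) {
    n <- sample(8:20, 1)
    p <- round(runif(n), 2)          # ties on purpose
    y <- random_labels(n)
    labs <- factor(ifelse(y, "high", "low"), levels = c("low", "high"))
    ct <- youden_cutoff(p, labs)
    pred <- p >= ct
    J <- sum(pred & y) / sum(y) + sum(!pred & !y) / sum(!y) - 1
    worst <- max(worst, abs(J - oracle_youden_J(p, y)))
  }
  expect_lt(worst, 1e-12)
})

test_that("confusion reproduces the reported low-positive orientation", {
  # observed/predicted counts of the descriptor branch's external test
  labs <- factor(rep(c("low", "high"), c(127, 182)), levels = c("low", "high"))
  pred <- factor(c(rep("low", 98), rep("high", 29),
                   rep("low", 25), rep("high", 157)),
                 levels = c("low", "high"))
  cm <- confusion(pred, labs, positive_class = "low")
  expect_equal(c(cm$TP, cm$FN, cm$FP, cm$TN), c(98, 29, 25, 157))
  # flipping the positive class swaps TP<->TN and FN<->FP
  cm2 <- confusion(pred, labs, positive_class = "high")
  expect_equal(c(cm2$TP, cm2$FN, cm2$FP, cm2$TN), c(cm$TN, cm$FP, cm$FN, cm$TP))
  # all-correct predictions
  cm3 <- confusion(labs, labs, positive_class = "low")
  expect_equal(c(cm3$FN, cm3$FP), c(0, 0))
})

test_that("metrics matches a naive recount on random confusion matrices", {
  set.seed(202)
  worst <- 0
  for (k in 1:200) {
    cts <- sample(1:200, 4, replace = TRUE)
    cm <- confusion_counts(cts[1], cts[2], cts[3], cts[4])
    m <- metrics(cm)
    o <- oracle_metrics(cts[1], cts[2], cts[3], cts[4])
    for (nm in names(o)) worst <- max(worst, abs(m[[nm]] - o[[nm]]))
    worst <- max(worst, abs(m$BAC - (m$sensitivity + m$specificity) / 2))
    if (!identical(m$recall, m$sensitivity)) worst <- Inf
  }
  expect_lt(worst, 1e-12)
})

test_that("metrics handles perfect and degenerate matrices", {
  m <- metrics(confusion_counts(10, 0, 0, 10))
  for (nm in c("ACC", "BAC", "sensitivity", "specificity", "F_measure",
               "precision", "recall", "MCC")) {
    expect_equal(m[[nm]], 1.0)
  }
  # zero denominators surface as NA with warnings, never 0
  w <- capture_warnings(m2 <- metrics(confusion_counts(0, 0, 5, 5)))
  expect_true(any(grepl("undefined", w)))
  expect_true(is.na(m2$sensitivity))
  expect_true(is.na(m2$MCC))
  expect_equal(m2$ACC, 0.5)
  expect_error(metrics(confusion_counts(0, 0, 0, 0)), "empty")
})

test_that("roc_auc equals the pairwise count and the trapezoidal curve area", {
  labs <- factor(c("low", "low", "high", "high"), levels = c("low", "high"))
  expect_equal(roc_auc(c(0.1, 0.2, 0.8, 0.9), labs), 1.0)
  expect_equal(roc_auc(c(0.5, 0.5, 0.5, 0.5), labs), 0.5)
  set.seed(303)
  worst <- 0
  for (k in 1:100) {
    n <- sample(10:30, 1)
    p <- round(runif(n), 2)
    y <- random_labels(n)
    labs <- factor(ifelse(y, "high", "low"), levels = c("low", "high"))
    auc <- roc_auc(p, labs)
    worst <- max(worst, abs(auc - oracle_auc_pairwise(p, y)),
                 abs(auc - oracle_auc_trapezoid(roc_points(p, labs))))
  }
  expect_lt(worst, 1e-12)
})

test_that("roc_auc agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(404)
  p <- runif(60)
  y <- random_labels(60)
  labs <- factor(ifelse(y, "high", "low"), levels = c("low", "high"))
  ref <- as.numeric(suppressMessages(pROC::auc(pROC::roc(y, p, quiet = TRUE))))
  expect_equal(roc_auc(p, labs), ref, tolerance = 1e-12)
})

test_that("probability tables validate ids and ranges", {
  expect_error(probability_table(c("a", "a"), c(0.1, 0.2)), "duplicate")
  expect_error(probability_table("a", 1.2), "\\[0, 1\\]")
  pt <- probability_table(c("a", "b"), c(0.2, 0.9), "m")
  labs <- setNames(factor(c("low", "high"), levels = c("low", "high")),
                   c("b", "a"))
  # id-based alignment, not positional
  expect_equal(roc_auc(pt, labs), 0)
  expect_error(roc_auc(pt, setNames(labs, c("b", "zzz"))), "mismatch")
})
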