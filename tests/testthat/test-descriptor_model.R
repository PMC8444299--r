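test_that("descriptor-table filtering removes string, missing and constant columns", {
  lib <- molecule_library(paste0("m", 1:10), rep("CCO", 10))
  raw <- data.frame(
    A = rnorm(10), B = rep(3.2, 10), C = letters[1:10],
    D = c(rnorm(9), NA), E = rnorm(10), G = rep(0, 10),
    row.names = paste0("m", 1:10), stringsAsFactors = FALSE)
  tab <- build_descriptor_table(lib, provider = raw)
  expect_setequal(colnames(tab), c("A", "E"))
  log <- attr(tab, "filter_log")
  expect_equal(log$removed[log$rule == "string_type"], 1L)
  expect_equal(log$removed[log$rule == "missing_or_nonfinite"], 1L)
  expect_equal(log$removed[log$rule == "zero_variance"], 2L)
  expect_false(any(!is.finite(tab)))
})

test_that("the RDKit provider yields a large finite numeric panel", {
  tab <- build_descriptor_table(fx_library())
  expect_gt(ncol(tab), 100L)
  expect_equal(rownames(tab), fx_library()$id)
  expect_true(all(is.finite(tab)))
  expect_true(all(c("MolWt", "MolLogP", "TPSA") %in% colnames(tab)))
})

test_that("logloss matches hand arithmetic and clips extremes", {
  expect_equal(logloss(c(1, 0), c(1, 0)), 0)
  expect_equal(logloss(c(1, 0, 1, 0), rep(0.5, 4)), log(2))
  expect_equal(logloss(c(1, 0), c(0.8, 0.4)), -mean(log(c(0.8, 0.6))))
  expect_true(is.finite(logloss(c(1, 0), c(0, 1))))  # clipped, not Inf
  expect_equal(logloss(factor(c("high", "low"), levels = c("low", "high")),
                       c(0.8, 0.4)),
               logloss(c(1, 0), c(0.8, 0.4)))
})

make_planted_table <- function(n = 200, p = 12, seed = 71) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(paste0("m", 1:n), paste0("V", 1:p)))
  x[, "V5"] <- rnorm(n)
  y <- factor(ifelse(x[, "V5"] > 0, "high", "low"), levels = c("low", "high"))
  x <- cbind(x, CONST = 1)
  list(x = x, y = y)
}

test_that("permutation importance finds a planted causal column", {
  pl <- make_planted_table()
  cfg <- model_config(top_k = 5, seed = 3,
                      hyperparameters = list(ntree = 200))
  sel <- select_by_permutation_importance(pl$x, pl$y, cfg)
  expect_equal(sel[1], "V5")
  imp <- attr(sel, "importance")
  expect_gt(imp[["V5"]], max(imp[setdiff(names(imp), "V5")]))
  # a constant column has exactly zero importance
  expect_identical(unname(imp[["CONST"]]), 0)
  # determinism under the same seed
  sel2 <- select_by_permutation_importance(pl$x, pl$y, cfg)
  expect_identical(sel, sel2)
})

test_that("top_k at or above the column count returns all columns", {
  pl <- make_planted_table(n = 60, p = 6)
  cfg <- model_config(top_k = ncol(pl$x), seed = 3,
                      hyperparameters = list(ntree = 100))
  sel <- select_by_permutation_importance(pl$x, pl$y, cfg)
  expect_setequal(sel, colnames(pl$x))
  cfg$top_k <- 100L
  expect_warning(sel2 <- select_by_permutation_importance(pl$x, pl$y, cfg),
                 "exceeds")
  expect_setequal(sel2, colnames(pl$x))
})

test_that("training selects by CV logloss, beats the prevalence floor, and predicts per-row", {
  pl <- make_planted_table(n = 160, p = 8, seed = 72)
  cfg <- model_config(seed = 4, hyperparameters = list(ntree = 200))
  dm <- train_descriptor_classifier(pl$x, pl$y, cfg)
  expect_s3_class(dm, "descriptor_model")
  prevalence <- mean(pl$y == "high")
  floor_ll <- logloss(pl$y, rep(prevalence, length(pl$y)))
  expect_lt(dm$cv_logloss, floor_ll)
  pt <- predict_descriptor_proba(dm, pl$x)
  expect_equal(nrow(pt), nrow(pl$x))
  expect_true(all(pt$p >= 0 & pt$p <= 1))
  # row-order permutation permutes the output identically
  perm <- sample(nrow(pl$x))
  pt2 <- predict_descriptor_proba(dm, pl$x[perm, ])
  expect_equal(pt2$p, pt$p[perm])
  # single-row prediction works
  expect_equal(nrow(predict_descriptor_proba(dm, pl$x[1, , drop = FALSE])), 1L)
  # missing column is fatal and named
  expect_error(predict_descriptor_proba(dm, pl$x[, -2]), colnames(pl$x)[2])
})

test_that("a fold stripped of one class aborts with a clear error", {
  x <- matrix(rnorm(40), 8, 5, dimnames = list(paste0("m", 1:8), NULL))
  y <- factor(rep(c("low", "high"), c(6, 2)), levels = c("low", "high"))
  expect_error(
    train_descriptor_classifier(x, y, model_config(cv_folds = 5, seed = 1,
                                                   holdout_fraction = 0)),
    "missing a class")
})

test_that("the algorithm sweep picks the lowest-logloss candidate", {
  pl <- make_planted_table(n = 120, p = 6, seed = 73)
  cfg <- model_config(seed = 5, sweep = c("rf", "logistic"),
                      hyperparameters = list(ntree = 150))
  dm <- train_descriptor_classifier(pl$x, pl$y, cfg)
  expect_equal(nrow(dm$cv_table), 2L)
  expect_equal(dm$algorithm,
               dm$cv_table$algorithm[which.min(dm$cv_table$logloss)])
})
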