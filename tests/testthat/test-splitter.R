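test_that("stratified_split reproduces the 4:1 class allocation exactly", {
  lab <- setNames(rep(c("low", "high"), c(636, 909)), paste0("m", 1:1545))
  sp <- stratified_split(lab, 0.2, seed = 99)
  cts <- sp$counts
  expect_equal(unname(cts["low", "test"]), 127)
  expect_equal(unname(cts["high", "test"]), 182)
  expect_equal(sum(cts[, "test"]), 309)
  expect_equal(sum(cts[, "train"]), 1236)
})

test_that("stratified_split is a deterministic partition with largest-remainder counts", {
  set.seed(5)
  for (k in 1:20) {
    n_low <- sample(10:200, 1); n_high <- sample(10:200, 1)
    frac <- runif(1, 0.1, 0.4)
    lab <- setNames(sample(rep(c("low", "high"), c(n_low, n_high))),
                    paste0("m", seq_len(n_low + n_high)))
    sp <- stratified_split(lab, frac, seed = k)
    # partition: every id on exactly one side
    expect_setequal(names(sp$assignment), names(lab))
    expect_true(all(sp$assignment %in% c("train", "test")))
    # largest-remainder arithmetic, recomputed independently
    n <- n_low + n_high
    share <- c(high = n_high, low = n_low) * frac
    base <- floor(share)
    rem <- round(frac * n) - sum(base)
    if (rem > 0) {
      extra <- order(share - base, decreasing = TRUE)[seq_len(rem)]
      base[extra] <- base[extra] + 1
    }
    expect_equal(unname(sp$counts["high", "test"]), unname(base[["high"]]))
    expect_equal(unname(sp$counts["low", "test"]), unname(base[["low"]]))
    # determinism
    sp2 <- stratified_split(lab, frac, seed = k)
    expect_identical(sp$assignment, sp2$assignment)
  }
  expect_equal(unname(stratified_split(
    setNames(rep(c("low", "high"), c(10, 10)), paste0("x", 1:20)),
    0.2, 1)$counts[, "test"]), c(2, 2), ignore_attr = TRUE)
})

test_that("pca_chemspace recovers structure deterministically", {
  # rank-1 data: one component explains everything
  set.seed(21)
  t_lin <- rnorm(50)
  X <- outer(t_lin, runif(11, 0.5, 2))
  rep1 <- pca_chemspace(X)
  expect_equal(rep1$explained[1], 1.0, tolerance = 1e-10)
  # explained variances non-increasing, sum <= 1
  Y <- matrix(rnorm(50 * 11), 50, 11)
  rep2 <- pca_chemspace(Y)
  expect_true(all(diff(rep2$explained) <= 1e-12))
  expect_lte(sum(rep2$explained), 1 + 1e-12)
  # invariant (up to sign) under column reordering
  perm <- sample(11)
  rep3 <- pca_chemspace(Y[, perm])
  for (j in 1:3) {
    expect_equal(abs(stats::cor(rep2$scores[, j], rep3$scores[, j])), 1,
                 tolerance = 1e-8)
  }
  expect_error(pca_chemspace(matrix(1, 10, 5)), "non-constant")
})

test_that("pca_chemspace recovers a planted 3-factor subspace", {
  set.seed(22)
  L <- qr.Q(qr(matrix(rnorm(11 * 3), 11, 3)))       # orthonormal loadings
  FS <- matrix(rnorm(400 * 3), 400, 3) %*% diag(c(3, 2, 1))
  X <- FS %*% t(L) + matrix(rnorm(400 * 11, sd = 0.05), 400, 11)
  rep <- pca_chemspace(X)
  # standardization rescales the loading directions by 1/sd(column)
  L_std <- diag(1 / apply(X, 2, sd)) %*% L
  Q1 <- qr.Q(qr(L_std))
  Q2 <- qr.Q(qr(rep$loadings))
  angles <- acos(pmin(svd(t(Q1) %*% Q2)$d, 1)) * 180 / pi
  expect_true(all(angles < 5))
})

test_that("split_overlap_report flags constructed imbalance only", {
  set.seed(23)
  n <- 1000
  scores <- matrix(rnorm(n * 3), n, 3,
                   dimnames = list(paste0("m", 1:n), paste0("PC", 1:3)))
  rep <- list(scores = scores)
  # random subset: balanced
  asg <- setNames(sample(rep(c("train", "test"), c(800, 200))),
                  rownames(scores))
  bal <- split_overlap_report(asg, rep)
  expect_false(any(bal$flagged))
  # top 20% of PC1 as test: PC1 flagged
  asg2 <- setNames(rep("train", n), rownames(scores))
  asg2[order(scores[, 1], decreasing = TRUE)[1:200]] <- "test"
  imb <- split_overlap_report(asg2, rep)
  expect_true(imb$flagged[imb$component == "PC1"])
  # identical train/test score sets give SMD 0
  sc <- rbind(scores[1:50, ], scores[1:50, ])
  rownames(sc) <- paste0("z", 1:100)
  asg3 <- setNames(rep(c("train", "test"), each = 50), rownames(sc))
  zero <- split_overlap_report(asg3, list(scores = sc))
  expect_equal(zero$smd, rep(0, 3), tolerance = 1e-12)
})
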