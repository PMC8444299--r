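# Small synthetic image task: class "high" images carry a bright block in
# the upper-left quadrant, class "low" in the lower-right.  Learnable by a
# tiny CNN in a handful of epochs at 16 px.
make_toy_image_task <- function(n_mol = 24, poses = 2, px = 16, seed = 1) {
  set.seed(seed)
  mk_img <- function(cls) {
    img <- array(1, dim = c(px, px, 3))
    q <- px / 2
    block <- matrix(runif(q * q, 0, 0.3), q, q)
    if (cls == "high") img[1:q, 1:q, 1] <- block
    else img[(q + 1):px, (q + 1):px, 3] <- block
    img
  }
  ids <- sprintf("t%03d", 1:n_mol)
  cls <- rep(c("low", "high"), length.out = n_mol)
  snaps <- lapply(seq_len(n_mol), function(i) {
    structure(list(molecule_id = ids[i], theta_deg = NA,
                   poses = matrix(0, poses, 3),
                   images = replicate(poses, mk_img(cls[i]),
                                      simplify = FALSE)),
              class = "snapshot_set")
  })
  names(snaps) <- ids
  list(snaps = snaps, labels = setNames(cls, ids), ids = ids)
}

test_that("split_deepsnap makes a 3:1 CL-matched, leakage-free partition", {
  lib <- molecule_library(paste0("m", 1:8), rep("C", 8),
                          cl_value = c(0.2, 0.4, 0.6, 0.8, 1.2, 1.5, 2, 3))
  sp <- split_deepsnap(lib, seed = 9)
  expect_equal(length(sp$training), 6L)
  expect_equal(length(sp$validation), 2L)
  # disjoint and exhaustive
  expect_length(intersect(sp$training, sp$validation), 0L)
  expect_setequal(c(sp$training, sp$validation), lib$id)
  expect_error(split_deepsnap(lib[1:3, ], seed = 1), "at least 4")
  # CL distributions of the two sides stay close (blocked randomization)
  set.seed(10)
  cl <- rexp(400)
  names(cl) <- paste0("x", 1:400)
  sp2 <- split_deepsnap(cl, seed = 11)
  ks <- suppressWarnings(stats::ks.test(cl[sp2$training],
                                        cl[sp2$validation])$statistic)
  expect_lt(unname(ks), 0.2)
})

test_that("aggregate_median uses the even-count convention and ignores order", {
  expect_equal(aggregate_median(c(0.1, 0.5, 0.9)), 0.5)
  expect_equal(aggregate_median(c(0.2, 0.4, 0.6, 0.8)), 0.5)
  set.seed(12)
  p <- runif(9)
  expect_equal(aggregate_median(p), aggregate_median(sample(p)))
  expect_error(aggregate_median(numeric(0)), "no probabilities")
})

test_that("train_cnn learns the toy task and selects the min-val-loss epoch", {
  toy <- make_toy_image_task()
  tr_ds <- image_dataset(toy$snaps[1:16], toy$labels)
  va_ds <- image_dataset(toy$snaps[17:24], toy$labels)
  cfg <- cnn_config(max_epochs = 8, input_px = 16, seed = 2,
                    channels = c(4L, 8L, 8L), batch_size = 8)
  fit <- train_cnn(tr_ds, va_ds, cfg)
  expect_s3_class(fit, "cnn_model")
  expect_equal(fit$status, "ok")
  expect_lte(nrow(fit$trace), cfg$max_epochs)
  # selected epoch is the argmin of the stored validation-loss trace
  expect_equal(fit$selected_epoch, which.min(fit$trace$val_loss))
  expect_gt(fit$trace$val_auc[fit$selected_epoch], 0.8)
  # per-image prediction: count, range, inference determinism
  p <- predict_image_proba(fit, toy$snaps[[1]])
  expect_length(p, 2L)
  expect_true(all(p >= 0 & p <= 1))
  dup <- toy$snaps[[1]]
  dup$images <- c(dup$images, dup$images[1])
  p2 <- predict_image_proba(fit, dup)
  expect_equal(p2[3], p2[1])
  # molecule-level probability invariant to pose ordering
  rev_snap <- toy$snaps[[1]]
  rev_snap$images <- rev(rev_snap$images)
  expect_equal(aggregate_median(predict_image_proba(fit, rev_snap)),
               aggregate_median(p))
  # training is reproducible under the same seed
  fit2 <- train_cnn(tr_ds, va_ds, cfg)
  expect_equal(fit$trace$val_loss, fit2$trace$val_loss, tolerance = 1e-12)
  expect_error(train_cnn(image_dataset(toy$snaps[c(1, 3)], toy$labels),
                         va_ds, cfg), "both classes")
})

test_that("grid selection maximizes AUC with the documented tie-breaks", {
  results <- data.frame(
    theta_deg = c(145, 105, 145, 65), learning_rate = c(1e-3, 1e-5, 1e-5, 1e-5),
    max_epochs = c(15, 30, 30, 30), val_auc = c(0.70, 0.88, 0.88, 0.80))
  w <- select_grid_winner(results)
  expect_equal(w$theta_deg, 145)          # AUC tie -> larger theta
  expect_equal(w$learning_rate, 1e-5)
  r2 <- results
  r2$theta_deg <- 105
  r2$val_auc <- c(0.8, 0.8, 0.8, 0.8)
  r2$learning_rate <- c(1e-3, 1e-4, 1e-5, 1e-6)
  expect_equal(select_grid_winner(r2)$learning_rate, 1e-6)  # then lower lr
  # single condition wins trivially
  expect_equal(nrow(select_grid_winner(results[2, ])), 1L)
})

test_that("grid_search records diverged conditions as AUC 0.500 and recovers the argmax", {
  lib <- molecule_library(paste0("m", 1:8), rep("C", 8),
                          cl_value = c(0.2, 0.4, 0.6, 0.8, 1.2, 1.5, 2, 3))
  confs <- lapply(lib$id, function(id) {
    conformer3d("C", matrix(0, 1, 3),
                data.frame(i = integer(), j = integer(), order = integer()))
  })
  names(confs) <- lib$id
  conditions <- data.frame(theta_deg = c(360, 360, 360),
                           learning_rate = c(1e-3, 1e-4, 1e-2),
                           max_epochs = c(5, 5, 5))
  fake_auc <- c(0.81, 0.93, NA)            # third condition diverges
  k_call <- 0
  fake_trainer <- function(tr_ds, va_ds, cfg, verbose = FALSE) {
    k_call <<- k_call + 1
    if (is.na(fake_auc[k_call])) {
      structure(list(weights = NULL, trace = data.frame(),
                     selected_epoch = NA_integer_, status = "diverged",
                     config = cfg, px = 16L), class = "cnn_model")
    } else {
      structure(list(weights = list(), selected_epoch = 1L, status = "ok",
                     trace = data.frame(epoch = 1, train_loss = 0.5,
                                        val_loss = 0.5,
                                        val_auc = fake_auc[k_call]),
                     config = cfg, px = 16L), class = "cnn_model")
    }
  }
  gs <- grid_search(lib, confs, conditions, style = render_style(image_px = 16),
                    seed = 3, trainer = fake_trainer)
  expect_equal(gs$results$val_auc, c(0.81, 0.93, 0.500))
  expect_equal(gs$results$status, c("ok", "ok", "diverged"))
  expect_equal(gs$winner$learning_rate, 1e-4)
  # the wide export has one AUC column per angle
  wide <- grid_result_table(gs$results)
  expect_true("theta_360" %in% colnames(wide))
  all_div <- function(...) structure(list(weights = NULL, trace = data.frame(),
                                          selected_epoch = NA_integer_,
                                          status = "diverged"),
                                     class = "cnn_model")
  expect_error(grid_search(lib, confs, conditions,
                           style = render_style(image_px = 16),
                           seed = 3, trainer = all_div), "diverged")
})
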