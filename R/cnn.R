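#' Configuration for the snapshot CNN
#'
#' The published protocol swept learning rates 1e-7..1e-3 and maximum
#' epochs 15..300 on a large backbone; the in-package default is a small
#' 3-block convolutional network trainable on a CPU, with the protocol
#' itself (per-epoch validation loss, minimum-validation-loss epoch
#' selection, median aggregation over poses) preserved exactly.
#'
#' @param learning_rate Adam learning rate (> 0).
#' @param max_epochs Maximum training epochs (>= 1).
#' @param batch_size Minibatch size.
#' @param seed Integer seed for initialization and shuffling.
#' @param input_px Expected image side length (images are rendered at this
#'   size; 64 px is the desk-scale default, 256 px the protocol value).
#' @param architecture `"small"` (3 conv blocks + global average pooling)
#'   or `"wide"` (more channels, for fidelity runs).
#' @param channels Integer vector of channels per conv block.
#' @param strides Convolution stride per block; the default stride-2 first
#'   block halves the resolution early, which keeps CPU training fast.
#' @return A `cnn_config` list.
#' @export
cnn_config <- function(learning_rate = 1e-3, max_epochs = 30L,
                       batch_size = 32L, seed = 1L, input_px = 64L,
                       architecture = c("small", "wide"),
                       channels = NULL, strides = c(2L, 1L, 1L)) {
  architecture <- match.arg(architecture)
  stopifnot(learning_rate > 0, max_epochs >= 1L, batch_size >= 1L,
            input_px >= 8L, length(strides) == 3L, all(strides >= 1L))
  if (is.null(channels)) {
    channels <- if (architecture == "small") c(12L, 24L, 48L)
                else c(24L, 48L, 96L)
  }
  stopifnot(length(channels) == 3L)
  structure(list(learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 input_px = as.integer(input_px),
                 architecture = architecture,
                 channels = as.integer(channels),
                 strides = as.integer(strides)),
            class = "cnn_config")
}

# Per-block spatial sizes: conv (k=3, pad=1, given stride) then 2x2 pooling.
cnn_dims <- function(px, config) {
  h_in <- integer(3); h_conv <- integer(3); h_out <- integer(3)
  h <- px
  for (l in 1:3) {
    h_in[l] <- h
    h_conv[l] <- (h + 2L - 3L) %/% config$strides[l] + 1L
    if (h_conv[l] < 2L || h_conv[l] %% 2L != 0L) {
      stop("image size ", px, " px incompatible with the conv strides",
           call. = FALSE)
    }
    h_out[l] <- h_conv[l] %/% 2L
    h <- h_out[l]
  }
  list(h_in = h_in, h_conv = h_conv, h_out = h_out)
}

#' The learning-rate / epoch grid of the published protocol
#'
#' @param theta_deg Angle increments to include.
#' @param learning_rate Learning rates to include.
#' @param max_epochs Epoch budgets to include.
#' @return Data.frame of conditions (one row per combination).
#' @export
deepsnap_grid <- function(theta_deg = c(65, 85, 105, 145),
                          learning_rate = c(1e-7, 1e-6, 1e-5, 1e-4, 1e-3),
                          max_epochs = c(15, 30, 60, 100, 300)) {
  expand.grid(theta_deg = theta_deg, learning_rate = learning_rate,
              max_epochs = max_epochs, KEEP.OUT.ATTRS = FALSE)
}

#' Split training molecules into DeepSnap-Training and DeepSnap-Validation
#'
#' Molecules are sorted by clearance value, partitioned into consecutive
#' blocks of 4, and one member of each block is assigned at random to the
#' validation side, giving a 3:1 split whose CL distributions match by
#' construction.  All snapshots of a molecule end up on exactly one side.
#' A final partial block of size r contributes one validation member with
#' probability r/4.  Falls back to the class label as the sort key when no
#' continuous endpoint is available.
#'
#' @param mols A [molecule_library()] (or named numeric vector of CL
#'   values).
#' @param seed Integer seed.
#' @return List with `training` and `validation` id vectors.
#' @export
split_deepsnap <- function(mols, seed = 1L) {
  if (is.numeric(mols)) {
    ids <- names(mols); cl <- unname(mols)
    if (is.null(ids)) ids <- paste0("mol_", seq_along(cl))
  } else {
    ids <- mols$id
    cl <- mols$cl_value
    if (all(is.na(cl))) cl <- as.numeric(mols$label)   # label fallback
  }
  n <- length(ids)
  if (n < 4L) stop("need at least 4 molecules for a 3:1 split", call. = FALSE)
  ord <- order(cl)                    # stable: ties keep input order
  ids <- ids[ord]
  set.seed(seed)
  val <- character(0)
  n_full <- n %/% 4L
  for (b in seq_len(n_full)) {
    block <- ids[((b - 1L) * 4L + 1L):(b * 4L)]
    val <- c(val, sample(block, 1L))
  }
  r <- n %% 4L
  if (r > 0L && stats::rbinom(1L, 1L, r / 4) == 1L) {
    val <- c(val, sample(ids[(n_full * 4L + 1L):n], 1L))
  }
  list(training = setdiff(ids, val), validation = val)
}

# ---- network internals -----------------------------------------------------

cnn_init <- function(config, n_channels_in = 3L) {
  set.seed(config$seed)
  ch <- c(n_channels_in, config$channels)
  he <- function(fan_in, nrow, ncol) {
    matrix(stats::rnorm(nrow * ncol, sd = sqrt(2 / fan_in)), nrow, ncol)
  }
  w <- list()
  for (l in 1:3) {
    fan_in <- 9L * ch[l]
    w[[paste0("W", l)]] <- he(fan_in, fan_in, ch[l + 1L])
    w[[paste0("b", l)]] <- numeric(ch[l + 1L])
  }
  w$Wd <- he(ch[4L], ch[4L], 1L)
  w$bd <- 0
  w
}

cnn_forward <- function(w, X, px, config, keep_cache = FALSE) {
  ch <- c(3L, config$channels)
  dims <- cnn_dims(px, config)
  cache <- list(A0 = X)
  A <- X
  for (l in 1:3) {
    Z <- cpp_conv_fwd(A, dims$h_in[l], dims$h_in[l], ch[l],
                      w[[paste0("W", l)]], w[[paste0("b", l)]],
                      3L, 1L, config$strides[l])
    R <- pmax(Z, 0)
    mp <- cpp_maxpool_fwd(R, dims$h_conv[l], dims$h_conv[l], ch[l + 1L])
    if (keep_cache) {
      cache[[paste0("Z", l)]] <- Z
      cache[[paste0("amax", l)]] <- mp$amax
      cache[[paste0("A", l)]] <- mp$Y
    }
    A <- mp$Y
  }
  # global average pooling over the final map of each channel
  B <- ncol(A)
  H <- dims$h_out[3L]
  g <- matrix(0, ch[4L], B)
  hw <- H * H
  for (c in seq_len(ch[4L])) {
    rows <- ((c - 1L) * hw + 1L):(c * hw)
    g[c, ] <- colMeans(A[rows, , drop = FALSE])
  }
  logits <- as.numeric(crossprod(g, w$Wd)) + w$bd
  out <- list(logits = logits, prob = 1 / (1 + exp(-logits)), g = g,
              dims = dims)
  if (keep_cache) out$cache <- cache
  out
}

cnn_backward <- function(w, fwd, y, px, config) {
  ch <- c(3L, config$channels)
  dims <- fwd$dims
  B <- length(y)
  dlogit <- (fwd$prob - y) / B        # BCE-with-logits gradient
  grads <- list(Wd = fwd$g %*% dlogit, bd = sum(dlogit))
  H <- dims$h_out[3L]
  hw <- H * H
  dA <- matrix(0, hw * ch[4L], B)
  for (c in seq_len(ch[4L])) {        # backprop through average pooling
    rows <- ((c - 1L) * hw + 1L):(c * hw)
    dA[rows, ] <- matrix(w$Wd[c] * dlogit / hw, hw, B, byrow = TRUE)
  }
  for (l in 3:1) {
    dR <- cpp_maxpool_bwd(dA, fwd$cache[[paste0("amax", l)]],
                          dims$h_conv[l], dims$h_conv[l], ch[l + 1L])
    dZ <- dR * (fwd$cache[[paste0("Z", l)]] > 0)
    A_prev <- fwd$cache[[paste0("A", l - 1L)]]
    bwd <- cpp_conv_bwd(A_prev, dZ, dims$h_in[l], dims$h_in[l], ch[l],
                        w[[paste0("W", l)]], 3L, 1L, config$strides[l])
    grads[[paste0("W", l)]] <- bwd$dW
    grads[[paste0("b", l)]] <- as.numeric(bwd$db)
    dA <- bwd$dX
  }
  grads
}

adam_step <- function(w, grads, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (nm in names(w)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    w[[nm]] <- w[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(w = w, state = state)
}

dataset_to_matrix <- function(ds) {
  imgs <- ds$images
  px <- dim(imgs[[1L]])[1L]
  X <- vapply(imgs, function(im) 1 - as.vector(im), numeric(px * px * 3L))
  list(X = X, px = px)
}

predict_proba_matrix <- function(model, X, px, batch = 256L) {
  n <- ncol(X)
  p <- numeric(n)
  for (start in seq(1L, n, by = batch)) {
    idx <- start:min(start + batch - 1L, n)
    p[idx] <- cnn_forward(model$weights, X[, idx, drop = FALSE], px,
                          model$config)$prob
  }
  p
}

#' Train the snapshot CNN
#'
#' Binary classifier over individual snapshot images, trained with Adam on
#' binary cross-entropy.  Training and validation loss are recorded every
#' epoch; the returned artifact is the weight snapshot of the epoch with
#' the lowest validation loss (first occurrence on ties).  A NaN/Inf loss
#' aborts the run with status `"diverged"`.
#'
#' @param train_ds,val_ds `image_dataset`s (see [image_dataset()]) with
#'   both classes present on both sides.
#' @param config A [cnn_config()].
#' @param verbose Print per-epoch progress.
#' @return A `cnn_model` list: `weights` (selected epoch), `trace`
#'   (per-epoch data.frame), `selected_epoch`, `status`, `config`.
#' @export
train_cnn <- function(train_ds, val_ds, config = cnn_config(),
                      verbose = FALSE) {
  for (side in list(train = train_ds, val = val_ds)) {
    if (length(unique(side$info$class)) < 2L) {
      stop("both classes must be present on both sides of the split",
           call. = FALSE)
    }
  }
  tr <- dataset_to_matrix(train_ds)
  va <- dataset_to_matrix(val_ds)
  px <- tr$px
  if (px != config$input_px) {
    stop("image size ", px, " px does not match config input_px ",
         config$input_px, call. = FALSE)
  }
  y_tr <- as.numeric(train_ds$info$class == "high")
  y_va <- as.numeric(val_ds$info$class == "high")
  w <- cnn_init(config)
  state <- list(m = lapply(w, function(p) p * 0),
                v = lapply(w, function(p) p * 0))
  model <- list(weights = w, config = config, px = px)
  best <- list(loss = Inf, epoch = NA_integer_, weights = w)
  trace <- data.frame(epoch = integer(), train_loss = numeric(),
                      val_loss = numeric(), val_auc = numeric())
  n <- ncol(tr$X)
  t_step <- 0L
  status <- "ok"
  set.seed(config$seed + 1L)
  for (epoch in seq_len(config$max_epochs)) {
    perm <- sample.int(n)
    ep_loss <- 0; ep_n <- 0L
    for (start in seq(1L, n, by = config$batch_size)) {
      idx <- perm[start:min(start + config$batch_size - 1L, n)]
      fwd <- cnn_forward(w, tr$X[, idx, drop = FALSE], px, config,
                         keep_cache = TRUE)
      bl <- logloss(y_tr[idx], fwd$prob)
      if (!is.finite(bl)) { status <- "diverged"; break }
      ep_loss <- ep_loss + bl * length(idx); ep_n <- ep_n + length(idx)
      grads <- cnn_backward(w, fwd, y_tr[idx], px, config)
      t_step <- t_step + 1L
      upd <- adam_step(w, grads, state, config$learning_rate, t_step)
      w <- upd$w; state <- upd$state
    }
    if (status == "diverged") break
    model$weights <- w
    p_val <- predict_proba_matrix(model, va$X, px)
    val_loss <- logloss(y_va, p_val)
    if (!is.finite(val_loss)) { status <- "diverged"; break }
    mol_p <- tapply(p_val, val_ds$info$molecule_id, stats::median)
    mol_y <- tapply(y_va, val_ds$info$molecule_id, function(v) v[1L])
    val_auc <- tryCatch(
      roc_auc(as.numeric(mol_p),
              factor(ifelse(mol_y[names(mol_p)] == 1, "high", "low"),
                     levels = c("low", "high"))),
      error = function(e) NA_real_)
    trace <- rbind(trace, data.frame(epoch = epoch,
                                     train_loss = ep_loss / ep_n,
                                     val_loss = val_loss,
                                     val_auc = val_auc))
    if (val_loss < best$loss) {
      best <- list(loss = val_loss, epoch = epoch, weights = w)
    }
    if (verbose) {
      message(sprintf("epoch %3d  train %.4f  val %.4f  val AUC %.3f",
                      epoch, ep_loss / ep_n, val_loss, val_auc))
    }
  }
  if (status == "diverged" && is.na(best$epoch)) {
    out <- list(weights = NULL, trace = trace, selected_epoch = NA_integer_,
                status = "diverged", config = config, px = px)
    class(out) <- "cnn_model"
    return(out)
  }
  out <- list(weights = best$weights, trace = trace,
              selected_epoch = best$epoch, status = status, config = config,
              px = px)
  class(out) <- "cnn_model"
  out
}

#' @export
print.cnn_model <- function(x, ...) {
  cat("snapshot CNN (", x$config$architecture, ", ", x$px, " px): status ",
      x$status, sep = "")
  if (!is.na(x$selected_epoch)) {
    cat(", selected epoch ", x$selected_epoch, " (val loss ",
        format(min(x$trace$val_loss), digits = 4), ")", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Per-image probabilities for a snapshot set
#'
#' @param model A trained `cnn_model`.
#' @param snapshots A `snapshot_set` or `image_dataset`.
#' @return Numeric vector of P(high), order-aligned with the poses.
#' @export
predict_image_proba <- function(model, snapshots) {
  if (is.null(model$weights)) stop("model diverged; no weights", call. = FALSE)
  imgs <- if (inherits(snapshots, "snapshot_set")) snapshots$images
          else snapshots$images
  px <- dim(imgs[[1L]])[1L]
  if (px != model$px) {
    stop("image size ", px, " px does not match the model (", model$px,
         " px)", call. = FALSE)
  }
  X <- vapply(imgs, function(im) 1 - as.vector(im), numeric(px * px * 3L))
  predict_proba_matrix(model, X, px)
}

#' Median aggregation of per-image probabilities
#'
#' The molecule-level probability is the sample median over its snapshot
#' probabilities (mean of the two central order statistics for an even
#' count).
#'
#' @param p Numeric vector of per-image probabilities (length >= 1).
#' @return The molecule probability.
#' @export
aggregate_median <- function(p) {
  if (length(p) == 0L) stop("no probabilities to aggregate", call. = FALSE)
  stats::median(p)
}

#' Molecule-level probabilities for an image dataset
#'
#' Runs [predict_image_proba()] over a dataset and aggregates to one
#' median probability per molecule.
#'
#' @param model A `cnn_model`.
#' @param ds An `image_dataset`.
#' @param model_tag Tag for the output table.
#' @return A [probability_table()].
#' @export
predict_molecule_proba <- function(model, ds, model_tag = "deepsnap") {
  p <- predict_image_proba(model, ds)
  agg <- tapply(p, ds$info$molecule_id, aggregate_median)
  probability_table(names(agg), as.numeric(agg), model_tag)
}

#' Select the winning grid-search condition
#'
#' Winner is the condition with the highest validation AUC; ties go to the
#' larger angle increment, then the lower learning rate.  Exposed
#' separately so the ranking rule can be exercised on any result table.
#'
#' @param results Data.frame with columns `theta_deg`, `learning_rate`,
#'   `max_epochs`, `val_auc`.
#' @return The winning row of `results`.
#' @export
select_grid_winner <- function(results) {
  stopifnot(nrow(results) >= 1L)
  ord <- order(-results$val_auc, -results$theta_deg, results$learning_rate)
  results[ord[1L], , drop = FALSE]
}

#' Hyperparameter grid search for the image branch
#'
#' For each condition (angle increment x learning rate x epoch budget):
#' render snapshots, apply the 3:1 CL-sorted blocked split, train the CNN,
#' select the minimum-validation-loss epoch, and record the molecule-level
#' validation AUC.  Diverged conditions are recorded with AUC 0.500.  The
#' winner is chosen by [select_grid_winner()].
#'
#' @param mols Training [molecule_library()] (with `cl_value` or labels).
#' @param conformers Named list of [conformer3d()]s covering the ids.
#' @param conditions Data.frame of conditions (see [deepsnap_grid()]).
#' @param style A [render_style()].
#' @param config Base [cnn_config()]; each condition overrides
#'   `learning_rate` and `max_epochs`.
#' @param seed Integer seed for the split.
#' @param verbose Print progress.
#' @param trainer Training function with the signature of [train_cnn()];
#'   replaceable for dry runs.
#' @return List with `results` (conditions + `val_auc`, `selected_epoch`,
#'   `status`), `winner` (row), `model` (the winning `cnn_model`).
#' @export
grid_search <- function(mols, conformers, conditions, style = render_style(),
                        config = cnn_config(), seed = 1L, verbose = FALSE,
                        trainer = train_cnn) {
  stopifnot(nrow(conditions) >= 1L)
  labels <- stats::setNames(as.character(mols$label), mols$id)
  split <- split_deepsnap(mols, seed = seed)
  snap_cache <- list()
  results <- conditions
  results$val_auc <- NA_real_
  results$selected_epoch <- NA_integer_
  results$status <- NA_character_
  models <- vector("list", nrow(conditions))
  for (k in seq_len(nrow(conditions))) {
    th <- conditions$theta_deg[k]
    key <- as.character(th)
    if (is.null(snap_cache[[key]])) {
      snap_cache[[key]] <- lapply(mols$id, function(id) {
        snapshot_molecule(conformers[[id]], th, style, molecule_id = id)
      })
      names(snap_cache[[key]]) <- mols$id
    }
    snaps <- snap_cache[[key]]
    tr_ds <- image_dataset(snaps[split$training], labels)
    va_ds <- image_dataset(snaps[split$validation], labels)
    cfg <- config
    cfg$learning_rate <- conditions$learning_rate[k]
    cfg$max_epochs <- as.integer(conditions$max_epochs[k])
    fit <- trainer(tr_ds, va_ds, cfg, verbose = verbose)
    if (fit$status == "diverged") {
      results$val_auc[k] <- 0.500
      results$status[k] <- "diverged"
    } else {
      results$val_auc[k] <- fit$trace$val_auc[fit$selected_epoch]
      results$selected_epoch[k] <- fit$selected_epoch
      results$status[k] <- "ok"
    }
    models[[k]] <- fit
    if (verbose) {
      message(sprintf("condition %d/%d: theta=%g lr=%g epochs=%d -> AUC %.3f",
                      k, nrow(conditions), th, cfg$learning_rate,
                      cfg$max_epochs, results$val_auc[k]))
    }
  }
  if (all(results$status == "diverged")) {
    stop("all grid conditions diverged", call. = FALSE)
  }
  winner <- select_grid_winner(results)
  idx <- as.integer(rownames(winner))
  list(results = results, winner = winner, model = models[[idx]],
       split = split)
}

#' Reshape grid-search results into the protocol's wide layout
#'
#' Rows are learning rate x epoch budget, one column of validation AUC per
#' angle increment.
#'
#' @param results The `results` data.frame from [grid_search()].
#' @return Wide data.frame.
#' @export
grid_result_table <- function(results) {
  thetas <- sort(unique(results$theta_deg), decreasing = TRUE)
  base <- unique(results[, c("learning_rate", "max_epochs")])
  base <- base[order(-base$learning_rate, base$max_epochs), , drop = FALSE]
  for (th in thetas) {
    col <- vapply(seq_len(nrow(base)), function(i) {
      hit <- results$theta_deg == th &
        results$learning_rate == base$learning_rate[i] &
        results$max_epochs == base$max_epochs[i]
      if (any(hit)) results$val_auc[which(hit)[1L]] else NA_real_
    }, 0.0)
    base[[paste0("theta_", th)]] <- col
  }
  rownames(base) <- NULL
  base
}
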