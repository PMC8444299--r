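#' Configuration for the descriptor-branch classifier
#'
#' Mirrors the descriptor-branch protocol: a 20% holdout is set aside for
#' permutation importance, five-fold stratified cross-validation scores
#' candidate algorithms by logloss, the top 100 descriptors by permutation
#' importance are kept, and the winner is refit on 100% of the training
#' data.
#'
#' @param algorithm `"rf"` (random forest, the default and documented
#'   winner), `"gbm"` (gradient boosting) or `"logistic"` (regularized
#'   logistic regression).
#' @param hyperparameters Named list passed to the algorithm (e.g.
#'   `ntree`, `nrounds`, `alpha`).
#' @param cv_folds Number of stratified CV folds (>= 2).
#' @param holdout_fraction Fraction held out for permutation importance.
#' @param top_k Number of descriptors to keep (capped at the table width).
#' @param n_repeats Permutation repeats per descriptor.
#' @param sweep Optional character vector of algorithms to compare by CV
#'   logloss; `NULL` fits only `algorithm`.
#' @param seed Integer seed.
#' @return A `model_config` list.
#' @export
model_config <- function(algorithm = c("rf", "gbm", "logistic"),
                         hyperparameters = list(), cv_folds = 5L,
                         holdout_fraction = 0.20, top_k = 100L,
                         n_repeats = 10L, sweep = NULL, seed = 1L) {
  algorithm <- match.arg(algorithm)
  stopifnot(cv_folds >= 2L, holdout_fraction >= 0, holdout_fraction < 1,
            top_k >= 1L, n_repeats >= 1L)
  structure(list(algorithm = algorithm, hyperparameters = hyperparameters,
                 cv_folds = as.integer(cv_folds),
                 holdout_fraction = holdout_fraction,
                 top_k = as.integer(top_k), n_repeats = as.integer(n_repeats),
                 sweep = sweep, seed = as.integer(seed)),
            class = "model_config")
}

#' Binary cross-entropy (logloss)
#'
#' `-(1/n) sum(y log p + (1-y) log(1-p))` with probabilities clipped at
#' `eps` for numerical stability.
#'
#' @param y Observed classes (`low`/`high` factor/character or 0/1).
#' @param p Predicted P(high).
#' @param eps Clipping bound.
#' @return Mean logloss.
#' @export
logloss <- function(y, p, eps = 1e-15) {
  if (is.factor(y) || is.character(y)) y <- as.character(y) == "high"
  y <- as.numeric(y)
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

stratified_folds <- function(labels, k, seed) {
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

holdout_partition <- function(labels, fraction, seed) {
  sp <- stratified_split(stats::setNames(as.character(labels),
                                         seq_along(labels)),
                         test_fraction = fraction, seed = seed)
  which(sp$assignment == "test")
}

fit_algorithm <- function(x, y, algorithm, hp, seed) {
  y <- factor(as.character(y), levels = c("low", "high"))
  set.seed(seed)
  if (algorithm == "rf") {
    ntree <- if (!is.null(hp$ntree)) hp$ntree else 500L
    fit <- randomForest::randomForest(x, y, ntree = ntree)
    pred <- function(newx) {
      unname(stats::predict(fit, newx, type = "prob")[, "high"])
    }
  } else if (algorithm == "gbm") {
    nrounds <- if (!is.null(hp$nrounds)) hp$nrounds else 150L
    fit <- xgboost::xgboost(
      data = x, label = as.numeric(y == "high"), nrounds = nrounds,
      params = list(objective = "binary:logistic",
                    max_depth = if (!is.null(hp$max_depth)) hp$max_depth else 4L,
                    eta = if (!is.null(hp$eta)) hp$eta else 0.1,
                    nthread = 1L, seed = seed),
      verbose = 0)
    pred <- function(newx) unname(stats::predict(fit, newx))
  } else if (algorithm == "logistic") {
    alpha <- if (!is.null(hp$alpha)) hp$alpha else 0.5
    fit <- glmnet::cv.glmnet(x, y, family = "binomial", alpha = alpha,
                             nfolds = 5L)
    pred <- function(newx) {
      as.numeric(stats::predict(fit, newx, s = "lambda.min",
                                type = "response"))
    }
  } else stop("unknown algorithm: ", algorithm, call. = FALSE)
  list(fit = fit, predict_proba = pred, algorithm = algorithm)
}

#' Rank descriptors by permutation importance
#'
#' Fits the configured classifier on the non-holdout portion and measures,
#' for each descriptor, the mean increase in holdout logloss over
#' `n_repeats` random permutations of that column.  Permuting a constant
#' column changes nothing, so its importance is exactly zero.
#'
#' @param table Filtered numeric descriptor matrix (rows = molecules).
#' @param labels `low`/`high` labels aligned with the rows.
#' @param config A [model_config()].
#' @return Character vector of the `top_k` descriptor names in descending
#'   importance, with the full named importance vector in
#'   `attr(x, "importance")`.
#' @export
select_by_permutation_importance <- function(table, labels,
                                             config = model_config()) {
  x <- as.matrix(table)
  labels <- factor(as.character(labels), levels = c("low", "high"))
  if (length(unique(labels)) < 2L) stop("both classes required", call. = FALSE)
  top_k <- config$top_k
  if (top_k > ncol(x)) {
    warning("top_k (", top_k, ") exceeds descriptor count (", ncol(x),
            "); returning all descriptors", call. = FALSE)
    top_k <- ncol(x)
  }
  if (config$holdout_fraction <= 0) {
    stop("permutation importance needs holdout_fraction > 0", call. = FALSE)
  }
  ho <- holdout_partition(labels, config$holdout_fraction, config$seed)
  fit <- fit_algorithm(x[-ho, , drop = FALSE], labels[-ho],
                       config$algorithm, config$hyperparameters, config$seed)
  xh <- x[ho, , drop = FALSE]
  yh <- labels[ho]
  base_ll <- logloss(yh, fit$predict_proba(xh))
  nh <- nrow(xh)
  R <- config$n_repeats
  set.seed(config$seed + 1L)
  perms <- replicate(R, sample.int(nh), simplify = FALSE)
  imp <- vapply(seq_len(ncol(x)), function(j) {
    stacked <- do.call(rbind, lapply(perms, function(pm) {
      xp <- xh; xp[, j] <- xh[pm, j]; xp
    }))
    p <- fit$predict_proba(stacked)
    lls <- vapply(seq_len(R), function(r) {
      logloss(yh, p[((r - 1L) * nh + 1L):(r * nh)])
    }, 0.0)
    mean(lls) - base_ll
  }, 0.0)
  names(imp) <- colnames(x)
  ord <- order(-imp, names(imp))      # name tie-break keeps this deterministic
  out <- names(imp)[ord][seq_len(top_k)]
  attr(out, "importance") <- imp[ord]
  out
}

#' Train the descriptor-branch classifier
#'
#' Stratified `cv_folds`-fold cross-validation (on the non-holdout portion)
#' reports mean logloss per candidate algorithm; the lowest-logloss
#' algorithm is refit on 100% of the supplied training rows.
#'
#' @param table Descriptor matrix restricted to the selected descriptors.
#' @param labels `low`/`high` labels aligned with the rows.
#' @param config A [model_config()].
#' @return A `descriptor_model` list: the fitted artifact, `algorithm`,
#'   `features`, `cv_logloss`, the per-algorithm `cv_table`, `config`.
#' @export
train_descriptor_classifier <- function(table, labels,
                                        config = model_config()) {
  x <- as.matrix(table)
  labels <- factor(as.character(labels), levels = c("low", "high"))
  algos <- if (!is.null(config$sweep)) config$sweep else config$algorithm
  ho <- holdout_partition(labels, config$holdout_fraction, config$seed)
  xcv <- if (length(ho)) x[-ho, , drop = FALSE] else x
  ycv <- if (length(ho)) labels[-ho] else labels
  fold <- stratified_folds(ycv, config$cv_folds, config$seed + 2L)
  for (f in seq_len(config$cv_folds)) {
    if (length(unique(ycv[fold != f])) < 2L ||
        length(unique(ycv[fold == f])) < 2L) {
      stop("CV fold ", f, " is missing a class; reduce cv_folds or add data",
           call. = FALSE)
    }
  }
  cv_ll <- vapply(algos, function(alg) {
    lls <- vapply(seq_len(config$cv_folds), function(f) {
      fit <- fit_algorithm(xcv[fold != f, , drop = FALSE], ycv[fold != f],
                           alg, config$hyperparameters, config$seed + f)
      logloss(ycv[fold == f], fit$predict_proba(xcv[fold == f, , drop = FALSE]))
    }, 0.0)
    mean(lls)
  }, 0.0)
  best <- algos[which.min(cv_ll)]
  final <- fit_algorithm(x, labels, best, config$hyperparameters, config$seed)
  out <- list(fit = final, algorithm = best, features = colnames(x),
              cv_logloss = unname(cv_ll[which.min(cv_ll)]),
              cv_table = data.frame(algorithm = algos, logloss = unname(cv_ll),
                                    stringsAsFactors = FALSE),
              config = config)
  class(out) <- "descriptor_model"
  out
}

#' @export
print.descriptor_model <- function(x, ...) {
  cat("descriptor model:", x$algorithm, "on", length(x$features),
      "descriptors; CV logloss", format(x$cv_logloss, digits = 4), "\n")
  invisible(x)
}

#' Predict P(high clearance) from the descriptor model
#'
#' @param model A `descriptor_model`.
#' @param table Descriptor matrix containing the model's selected columns
#'   (rows named by molecule id).
#' @return A [probability_table()] with tag `"descriptor"`.
#' @export
predict_descriptor_proba <- function(model, table) {
  x <- as.matrix(table)
  missing <- setdiff(model$features, colnames(x))
  if (length(missing)) {
    stop("descriptor table lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  x <- x[, model$features, drop = FALSE]
  p <- model$fit$predict_proba(x)
  ids <- if (!is.null(rownames(x))) rownames(x) else
    paste0("mol_", seq_len(nrow(x)))
  probability_table(ids, p, "descriptor")
}
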