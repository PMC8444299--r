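#' Fit the combined clearance classifier
#'
#' Runs the full two-branch protocol on a labeled molecule library:
#' stratified 4:1 train/test split; descriptor branch (filtered descriptor
#' table, permutation-importance top-k selection, cross-validated
#' classifier, refit on all training data); image branch (seeded 3D
#' embedding, multi-angle ball-and-stick snapshots, 3:1 CL-sorted blocked
#' train/validation split, CNN trained to the minimum-validation-loss
#' epoch, median aggregation over poses); then the ensemble (probability
#' mean) and consensus (agreement subset) combinations.  Test-set metrics
#' for all four models are computed at each model's own Youden-index
#' cutoff.
#'
#' @param mols A [molecule_library()] with `cl_value` or `label`.
#' @param theta_deg Snapshot angle increment in degrees (default 145,
#'   giving 8 poses per molecule).
#' @param test_fraction Test fraction for the stratified split.
#' @param style A [render_style()]; the desk-scale default renders 64 px
#'   images.
#' @param config A [model_config()] for the descriptor branch.
#' @param cnn A [cnn_config()] for the image branch.
#' @param positive_class Orientation for reported metrics (default
#'   `"low"`, matching the reported confusion-matrix orientation).
#' @param seed Integer seed governing split, embedding, selection and
#'   training.
#' @param verbose Print stage progress.
#' @return An object of class `clsnap`; see [print.clsnap()],
#'   [summary.clsnap()], [predict.clsnap()], [plot.clsnap()].
#' @export
clsnap <- function(mols, theta_deg = 145, test_fraction = 0.2,
                   style = render_style(image_px = 64L),
                   config = model_config(), cnn = cnn_config(),
                   positive_class = c("low", "high"), seed = 1L,
                   verbose = TRUE) {
  positive_class <- match.arg(positive_class)
  stopifnot(inherits(mols, "molecule_library"))
  if (all(is.na(mols$label))) stop("molecules must carry cl_value or label",
                                   call. = FALSE)
  say <- function(...) if (verbose) message(...)
  config$seed <- seed
  cnn$seed <- seed

  say("embedding 3D conformers (", nrow(mols), " molecules)...")
  conformers <- embed_molecules(mols, seed = seed)
  failed <- attr(conformers, "failures")
  if (length(failed)) {
    # excluded from the whole pipeline so both branches see the same set
    mols <- mols[!mols$id %in% failed, ]
    class(mols) <- c("molecule_library", "data.frame")
  }
  labels <- stats::setNames(mols$label, mols$id)

  split <- stratified_split(labels, test_fraction, seed)
  train_ids <- names(split$assignment)[split$assignment == "train"]
  test_ids <- names(split$assignment)[split$assignment == "test"]

  say("descriptor branch: table, selection, CV...")
  table <- build_descriptor_table(mols)
  chem <- pca_chemspace(table[, intersect(chemspace_parameters(),
                                          colnames(table)), drop = FALSE])
  overlap <- split_overlap_report(split, chem)
  feats <- select_by_permutation_importance(
    table[train_ids, , drop = FALSE], labels[train_ids], config)
  dmodel <- train_descriptor_classifier(
    table[train_ids, feats, drop = FALSE], labels[train_ids], config)
  p_md <- predict_descriptor_proba(dmodel, table[test_ids, , drop = FALSE])

  say("image branch: rendering ", length(mols$id), " x ",
      floor(360 / theta_deg)^3, " snapshots...")
  snaps <- lapply(mols$id, function(id) {
    snapshot_molecule(conformers[[id]], theta_deg, style, molecule_id = id)
  })
  names(snaps) <- mols$id
  ds_split <- split_deepsnap(mols[mols$id %in% train_ids, ], seed = seed)
  tr_ds <- image_dataset(snaps[ds_split$training], labels)
  va_ds <- image_dataset(snaps[ds_split$validation], labels)
  say("image branch: training CNN (max ", cnn$max_epochs, " epochs)...")
  cmodel <- train_cnn(tr_ds, va_ds, cnn, verbose = verbose)
  if (cmodel$status == "diverged") {
    stop("image branch diverged; lower the learning rate", call. = FALSE)
  }
  te_ds <- image_dataset(snaps[test_ids], labels)
  p_ds <- predict_molecule_proba(cmodel, te_ds)
  p_ds <- probability_table(p_ds$id[match(test_ids, p_ds$id)],
                            p_ds$p[match(test_ids, p_ds$id)], "deepsnap")

  say("combining branches and evaluating...")
  p_ens <- ensemble_mean(p_md, p_ds)
  test_labels <- labels[test_ids]
  eval_one <- function(pt) {
    ct <- youden_cutoff(pt, test_labels)
    cm <- confusion(pt, test_labels, ct, positive_class)
    list(cutoff = ct, cm = cm,
         metrics = metrics(cm, auc = roc_auc(pt, test_labels)),
         classes = stats::setNames(
           factor(ifelse(pt$p >= ct, "high", "low"),
                  levels = c("low", "high")), pt$id))
  }
  ev <- list(descriptor = eval_one(p_md), deepsnap = eval_one(p_ds),
             ensemble = eval_one(p_ens))
  cons <- consensus_filter(ev$descriptor$classes, ev$deepsnap$classes)
  cons_metrics <- if (cons$n_retained > 0L) {
    cm <- confusion(cons$classes, test_labels[cons$retained_ids],
                    positive_class = positive_class)
    metrics(cm)
  } else NULL

  metrics_table <- do.call(rbind, c(
    lapply(ev, function(e) as.data.frame(e$metrics)),
    if (!is.null(cons_metrics)) list(consensus = as.data.frame(cons_metrics))))
  metrics_table <- cbind(model = rownames(metrics_table), metrics_table)
  rownames(metrics_table) <- NULL

  out <- list(
    molecules = mols, split = split, theta_deg = theta_deg, style = style,
    chemspace = chem, overlap = overlap,
    descriptor_model = dmodel, selected_features = feats,
    cnn_model = cmodel, deepsnap_split = ds_split,
    probabilities = list(descriptor = p_md, deepsnap = p_ds,
                         ensemble = p_ens),
    cutoffs = vapply(ev, `[[`, 0.0, "cutoff"),
    confusions = lapply(ev, `[[`, "cm"),
    consensus = cons, consensus_metrics = cons_metrics,
    metrics = metrics_table, positive_class = positive_class,
    embed_failures = failed, seed = seed
  )
  class(out) <- "clsnap"
  out
}

#' @export
print.clsnap <- function(x, digits = 3, ...) {
  cat("Combined clearance classifier (clsnap)\n")
  cat("  molecules: ", nrow(x$molecules), "  (train ",
      sum(x$split$assignment == "train"), " / test ",
      sum(x$split$assignment == "test"), ")\n", sep = "")
  cat("  image branch: theta ", x$theta_deg, " deg -> ",
      floor(360 / x$theta_deg)^3, " poses/molecule at ",
      x$style$image_px, " px; selected epoch ",
      x$cnn_model$selected_epoch, "\n", sep = "")
  cat("  descriptor branch: ", x$descriptor_model$algorithm, " on ",
      length(x$selected_features), " descriptors (CV logloss ",
      format(x$descriptor_model$cv_logloss, digits = 4), ")\n", sep = "")
  cat("\nTest-set metrics (positive class: ", x$positive_class, "):\n",
      sep = "")
  tab <- x$metrics
  num <- vapply(tab, is.numeric, TRUE)
  tab[num] <- lapply(tab[num], round, digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
summary.clsnap <- function(object, ...) {
  x <- object
  cat("== Split ==\n"); print(x$split)
  cat("\n== Chemical space ==\n"); print(x$chemspace)
  flagged <- x$overlap$component[x$overlap$flagged]
  cat(if (length(flagged)) paste("flagged components:",
                                 paste(flagged, collapse = ", "))
      else "train/test balanced on all components (|SMD| <= 0.25)", "\n")
  cat("\n== Descriptor branch ==\n"); print(x$descriptor_model)
  cat("top descriptors:",
      paste(head(x$selected_features, 8L), collapse = ", "), "...\n")
  cat("\n== Image branch ==\n"); print(x$cnn_model)
  cat("\n== Combination ==\n"); print(x$consensus)
  cat("\n"); print(x)
  invisible(x)
}

#' Predict clearance classes for new molecules
#'
#' Applies both trained branches to new structures (descriptors + 3D
#' embedding + snapshots), combines them, and classifies at the cutoffs
#' fixed when the model was fit.  Molecules on which the branches disagree
#' get `NA` as consensus class.
#'
#' @param object A fitted `clsnap` model.
#' @param newdata A [molecule_library()] (labels not required).
#' @param seed Seed for the 3D embedding of the new structures.
#' @param ... Unused.
#' @return Data.frame with per-branch and combined probabilities and
#'   classes.
#' @export
predict.clsnap <- function(object, newdata, seed = object$seed, ...) {
  stopifnot(inherits(newdata, "molecule_library"))
  # unfiltered provider table: variance filtering is a training-time step
  # and must not hide columns the model selected
  table <- as.matrix(descriptor_provider_rdkit(newdata))
  p_md <- predict_descriptor_proba(object$descriptor_model, table)
  conformers <- embed_molecules(newdata, seed = seed)
  failed <- attr(conformers, "failures")
  ids <- setdiff(newdata$id, failed)
  snaps <- lapply(ids, function(id) {
    snapshot_molecule(conformers[[id]], object$theta_deg, object$style,
                      molecule_id = id)
  })
  dummy <- stats::setNames(rep("low", length(ids)), ids)  # labels unused
  ds <- image_dataset(snaps, dummy)
  p_im <- predict_molecule_proba(object$cnn_model, ds)
  res <- data.frame(id = newdata$id, stringsAsFactors = FALSE)
  res$p_descriptor <- p_md$p[match(res$id, p_md$id)]
  res$p_deepsnap <- p_im$p[match(res$id, p_im$id)]
  res$p_ensemble <- (res$p_descriptor + res$p_deepsnap) / 2
  cl_of <- function(p, cut) ifelse(p >= cut, "high", "low")
  res$class_descriptor <- cl_of(res$p_descriptor,
                                object$cutoffs[["descriptor"]])
  res$class_deepsnap <- cl_of(res$p_deepsnap, object$cutoffs[["deepsnap"]])
  res$class_ensemble <- cl_of(res$p_ensemble, object$cutoffs[["ensemble"]])
  res$class_consensus <- ifelse(
    !is.na(res$class_descriptor) & !is.na(res$class_deepsnap) &
      res$class_descriptor == res$class_deepsnap,
    res$class_descriptor, NA_character_)
  res
}

#' ROC curves of the fitted models
#'
#' Plots test-set ROC curves for the descriptor, snapshot and ensemble
#' models (the consensus model predicts classes, not rankings, so it has
#' no curve).
#'
#' @param x A fitted `clsnap` model.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.clsnap <- function(x, ...) {
  test_ids <- names(x$split$assignment)[x$split$assignment == "test"]
  labels <- stats::setNames(x$molecules$label,
                            x$molecules$id)[test_ids]
  cols <- c(descriptor = "#1b9e77", deepsnap = "#d95f02",
            ensemble = "#7570b3")
  graphics::plot(c(0, 1), c(0, 1), type = "l", lty = 3, col = "grey50",
                 xlab = "False positive rate", ylab = "True positive rate",
                 main = "Test-set ROC", ...)
  for (nm in names(cols)) {
    pts <- roc_points(x$probabilities[[nm]], labels)
    graphics::lines(pts$fpr, pts$tpr, col = cols[[nm]], lwd = 2)
  }
  auc <- vapply(names(cols), function(nm) {
    x$metrics$AUC[x$metrics$model == nm]
  }, 0.0)
  graphics::legend("bottomright", bty = "n", lwd = 2, col = cols,
                   legend = sprintf("%s (AUC %.3f)", names(cols), auc))
  invisible(x)
}
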