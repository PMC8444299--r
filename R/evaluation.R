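#' Probability table for one model
#'
#' The currency passed between branches and the combiner: one predicted
#' positive-class probability per molecule.  Probabilities throughout the
#' package score the "high" clearance class (score 1 = CL >= 1 L/h/kg).
#'
#' @param id Molecule ids (unique).
#' @param p Probabilities in \[0, 1\].
#' @param model_tag Short model name (e.g. `"descriptor"`, `"deepsnap"`).
#' @return A `probability_table` data.frame with columns `id`, `p`,
#'   `model_tag`.
#' @export
probability_table <- function(id, p, model_tag = "model") {
  id <- as.character(id)
  if (anyDuplicated(id)) stop("duplicate ids in probability table", call. = FALSE)
  p <- as.numeric(p)
  stopifnot(length(p) == length(id))
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  out <- data.frame(id = id, p = p, model_tag = model_tag,
                    stringsAsFactors = FALSE)
  class(out) <- c("probability_table", "data.frame")
  out
}

check_two_classes <- function(labels) {
  nm <- names(labels)
  labels <- factor(as.character(labels), levels = c("low", "high"))
  names(labels) <- nm
  if (anyNA(labels)) stop("labels must be 'low'/'high' without NA", call. = FALSE)
  if (length(unique(labels)) < 2L) {
    stop("both classes must be present", call. = FALSE)
  }
  labels
}

align_probs <- function(probs, labels) {
  if (inherits(probs, "probability_table") || is.data.frame(probs)) {
    p <- probs$p
    names(p) <- probs$id
  } else {
    p <- probs
  }
  if (!is.null(names(p)) && !is.null(names(labels))) {
    if (!setequal(names(p), names(labels))) {
      diffs <- c(setdiff(names(p), names(labels)),
                 setdiff(names(labels), names(p)))
      stop("probability/label id mismatch: ", paste(diffs, collapse = ", "),
           call. = FALSE)
    }
    p <- p[names(labels)]
  }
  stopifnot(length(p) == length(labels))
  p
}

#' Youden-index optimal cutoff
#'
#' Returns the probability cutoff maximizing J = sensitivity +
#' specificity - 1.  Candidate cutoffs are the midpoints between adjacent
#' sorted unique probabilities, plus below-minimum and above-maximum
#' sentinels; ties are broken toward the lowest cutoff.
#'
#' @param probs A [probability_table()] or numeric vector of P(high).
#' @param labels Factor/character of observed classes (`low`/`high`),
#'   named by id when `probs` is a table.
#' @return The cutoff (numeric scalar); molecules with `p >= cutoff` are
#'   classified "high".
#' @export
youden_cutoff <- function(probs, labels) {
  if (inherits(probs, "probability_table")) {
    if (is.null(names(labels))) names(labels) <- probs$id
  }
  labels <- check_two_classes(stats::setNames(
    as.character(labels), names(labels)))
  p <- align_probs(probs, labels)
  y <- labels == "high"
  u <- sort(unique(p))
  cand <- c(u[1L] - 1e-6, if (length(u) > 1L) (u[-1L] + u[-length(u)]) / 2,
            u[length(u)] + 1e-6)
  cand <- pmin(pmax(cand, 0), 1)
  npos <- sum(y); nneg <- sum(!y)
  j <- vapply(cand, function(ct) {
    pred_high <- p >= ct
    sum(pred_high & y) / npos + sum(!pred_high & !y) / nneg - 1
  }, 0.0)
  cand[which.max(j)]  # which.max takes the first (lowest) maximizer
}

#' Confusion matrix at a cutoff
#'
#' Predicted class is "high" iff `p >= cutoff`; the `positive_class`
#' argument then orients the counts.  With `positive_class = "low"` (the
#' default used in the reported tables) TP counts molecules observed and
#' predicted low-clearance.
#'
#' @param probs A [probability_table()], numeric P(high), or predicted
#'   classes (factor/character `low`/`high`, in which case `cutoff` is
#'   ignored).
#' @param labels Observed classes.
#' @param cutoff Probability cutoff (e.g. from [youden_cutoff()]).
#' @param positive_class Which class counts as positive, `"low"` or
#'   `"high"`.
#' @return A `confusion_matrix` list with counts `TP`, `FN`, `TN`, `FP`,
#'   `n` and the orientation used.
#' @export
confusion <- function(probs, labels, cutoff = 0.5,
                      positive_class = c("low", "high")) {
  positive_class <- match.arg(positive_class)
  if (inherits(probs, "probability_table")) {
    if (is.null(names(labels))) names(labels) <- probs$id
  }
  nm <- names(labels)
  labels <- factor(as.character(labels), levels = c("low", "high"))
  names(labels) <- nm
  if (anyNA(labels)) stop("labels must be 'low'/'high'", call. = FALSE)
  if (is.character(probs) || is.factor(probs)) {
    pred <- factor(as.character(probs), levels = c("low", "high"))
    if (anyNA(pred)) stop("predicted classes must be 'low'/'high'", call. = FALSE)
  } else {
    p <- align_probs(probs, labels)
    pred <- factor(ifelse(p >= cutoff, "high", "low"), levels = c("low", "high"))
  }
  stopifnot(length(pred) == length(labels))
  pos <- positive_class
  neg <- setdiff(c("low", "high"), pos)
  cm <- list(TP = sum(pred == pos & labels == pos),
             FN = sum(pred == neg & labels == pos),
             FP = sum(pred == pos & labels == neg),
             TN = sum(pred == neg & labels == neg),
             positive_class = pos, cutoff = cutoff)
  cm$n <- cm$TP + cm$FN + cm$FP + cm$TN
  class(cm) <- "confusion_matrix"
  cm
}

#' Construct a confusion matrix from counts
#'
#' @param TP,FN,FP,TN Nonnegative integer counts.
#' @param positive_class Orientation of the counts.
#' @return A `confusion_matrix`.
#' @export
confusion_counts <- function(TP, FN, FP, TN,
                             positive_class = c("low", "high")) {
  positive_class <- match.arg(positive_class)
  stopifnot(TP >= 0, FN >= 0, FP >= 0, TN >= 0)
  cm <- list(TP = TP, FN = FN, FP = FP, TN = TN,
             positive_class = positive_class, cutoff = NA_real_,
             n = TP + FN + FP + TN)
  class(cm) <- "confusion_matrix"
  cm
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$TP, x$FN, x$FP, x$TN), 2, 2, byrow = TRUE,
              dimnames = list(observed = c("positive", "negative"),
                              predicted = c("positive", "negative")))
  cat("confusion matrix (positive class:", x$positive_class, ")\n")
  print(m)
  invisible(x)
}

safe_div <- function(num, den, what) {
  if (den == 0) {
    warning(what, " undefined (zero denominator)", call. = FALSE)
    return(NA_real_)
  }
  num / den
}

#' Nine-metric classification report
#'
#' Computes ACC, BAC, sensitivity, specificity, F-measure, precision,
#' recall and MCC from a confusion matrix; recall equals sensitivity and
#' BAC is the mean of sensitivity and specificity.  Metrics with a zero
#' denominator are reported as `NA` with a warning, never as 0.
#'
#' @param cm A `confusion_matrix` (from [confusion()] or
#'   [confusion_counts()]).
#' @param auc Optional AUC to carry into the report (absent for consensus
#'   models, whose predictions are classes, not rankings).
#' @return A `metrics_report` list.
#' @export
metrics <- function(cm, auc = NA_real_) {
  stopifnot(inherits(cm, "confusion_matrix"))
  if (cm$n == 0) stop("empty confusion matrix", call. = FALSE)
  TP <- cm$TP; FN <- cm$FN; FP <- cm$FP; TN <- cm$TN
  sens <- safe_div(TP, TP + FN, "sensitivity")
  spec <- safe_div(TN, TN + FP, "specificity")
  prec <- safe_div(TP, TP + FP, "precision")
  f <- if (is.na(prec) || is.na(sens) || (prec + sens) == 0) {
    warning("F-measure undefined", call. = FALSE); NA_real_
  } else 2 * prec * sens / (prec + sens)
  mcc_den <- sqrt(as.numeric(TP + FP)) * sqrt(as.numeric(TP + FN)) *
    sqrt(as.numeric(TN + FP)) * sqrt(as.numeric(TN + FN))
  mcc <- if (mcc_den == 0) {
    warning("MCC undefined (zero denominator)", call. = FALSE); NA_real_
  } else (as.numeric(TP) * TN - as.numeric(FP) * FN) / mcc_den
  rep <- list(n = cm$n, AUC = auc,
              BAC = if (is.na(sens) || is.na(spec)) NA_real_ else (sens + spec) / 2,
              ACC = (TP + TN) / cm$n,
              sensitivity = sens, specificity = spec,
              F_measure = f, precision = prec, recall = sens, MCC = mcc,
              cutoff = cm$cutoff, positive_class = cm$positive_class)
  class(rep) <- "metrics_report"
  rep
}

#' @export
print.metrics_report <- function(x, digits = 3, ...) {
  cat("n =", x$n, " (positive class:", x$positive_class, ")\n")
  vals <- unlist(x[c("AUC", "BAC", "ACC", "sensitivity", "specificity",
                     "F_measure", "precision", "recall", "MCC")])
  print(round(vals, digits))
  if (!is.na(x$cutoff)) cat("cutoff:", format(x$cutoff, digits = 4), "\n")
  invisible(x)
}

#' @export
as.data.frame.metrics_report <- function(x, ...) {
  data.frame(n = x$n, AUC = x$AUC, BAC = x$BAC, ACC = x$ACC,
             sensitivity = x$sensitivity, specificity = x$specificity,
             F_measure = x$F_measure, precision = x$precision,
             recall = x$recall, MCC = x$MCC, cutoff = x$cutoff)
}

#' Write a metrics report to JSON or CSV
#'
#' @param x A `metrics_report`.
#' @param path Output path; format chosen by extension (`.json` or `.csv`).
#' @return Invisibly, `path`.
#' @export
write_metrics <- function(x, path) {
  if (tolower(tools::file_ext(path)) == "json") {
    jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  } else {
    write.csv(as.data.frame(x), path, row.names = FALSE)
  }
  invisible(path)
}

#' Area under the ROC curve
#'
#' Computed as the normalized Mann-Whitney U statistic:
#' P(p_high > p_low) + 0.5 P(tie) over all (high, low) pairs, where "high"
#' is the score-positive class.
#'
#' @param probs A [probability_table()] or numeric vector of P(high).
#' @param labels Observed classes (`low`/`high`).
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(probs, labels) {
  if (inherits(probs, "probability_table")) {
    if (is.null(names(labels))) names(labels) <- probs$id
  }
  labels <- check_two_classes(stats::setNames(as.character(labels),
                                              names(labels)))
  p <- align_probs(probs, labels)
  y <- labels == "high"
  r <- rank(p, ties.method = "average")
  npos <- sum(y); nneg <- sum(!y)
  (sum(r[y]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' ROC curve points
#'
#' False-positive and true-positive rates over all thresholds, for
#' plotting; the trapezoidal area under these points equals [roc_auc()].
#'
#' @inheritParams roc_auc
#' @return Data.frame with columns `fpr`, `tpr`, `cutoff`.
#' @export
roc_points <- function(probs, labels) {
  if (inherits(probs, "probability_table")) {
    if (is.null(names(labels))) names(labels) <- probs$id
  }
  labels <- check_two_classes(stats::setNames(as.character(labels),
                                              names(labels)))
  p <- align_probs(probs, labels)
  y <- labels == "high"
  ord <- order(p, decreasing = TRUE)
  p <- p[ord]; y <- y[ord]
  # pool tied scores
  keep <- c(p[-1] != p[-length(p)], TRUE)
  tpr <- cumsum(y) / sum(y)
  fpr <- cumsum(!y) / sum(!y)
  data.frame(fpr = c(0, fpr[keep]), tpr = c(0, tpr[keep]),
             cutoff = c(Inf, p[keep]))
}
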