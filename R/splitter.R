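#' Stratified train/test split with largest-remainder class allocation
#'
#' The total test count is `round(test_fraction * n)`.  Each class
#' receives the floor of its proportional share; remaining units go to the
#' classes with the largest fractional parts.  Membership within a class
#' is random given the seed.
#'
#' @param labels Named factor/character of classes (`low`/`high`), names
#'   are molecule ids.
#' @param test_fraction Fraction assigned to the test side (default 0.2,
#'   i.e. a 4:1 split).
#' @param seed Integer seed.
#' @return A `split_assignment` list: `assignment` (named character,
#'   `"train"`/`"test"`), per-class count table, the seed.
#' @export
stratified_split <- function(labels, test_fraction = 0.2, seed = 1L) {
  lab <- stats::setNames(as.character(labels), names(labels))
  if (is.null(names(lab))) names(lab) <- paste0("mol_", seq_along(lab))
  stopifnot(test_fraction >= 0, test_fraction < 1)
  classes <- sort(unique(lab))
  sizes <- vapply(classes, function(cl) sum(lab == cl), 0L)
  if (any(sizes == 0L)) stop("every class needs at least one member", call. = FALSE)
  n <- length(lab)
  n_test <- round(test_fraction * n)
  share <- sizes * test_fraction
  base <- floor(share)
  rem <- n_test - sum(base)
  if (rem > 0) {
    extra <- order(share - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1L
  } else if (rem < 0) {
    cut <- order(share - base)[seq_len(-rem)]
    base[cut] <- base[cut] - 1L
  }
  assignment <- stats::setNames(rep("train", n), names(lab))
  set.seed(seed)
  for (k in seq_along(classes)) {
    ids <- names(lab)[lab == classes[k]]
    test_ids <- sample(ids, base[k])
    assignment[test_ids] <- "test"
  }
  counts <- table(class = lab, split = factor(assignment,
                                              levels = c("train", "test")))
  out <- list(assignment = assignment, counts = counts, seed = seed,
              test_fraction = test_fraction)
  class(out) <- "split_assignment"
  out
}

#' @export
print.split_assignment <- function(x, ...) {
  cat("stratified split (test fraction ", x$test_fraction, ", seed ",
      x$seed, ")\n", sep = "")
  print(x$counts)
  invisible(x)
}

#' PCA chemical-space summary
#'
#' Standardized (correlation-structure) principal component analysis of a
#' small set of physicochemical parameters, used to verify that a split
#' covers chemical space evenly.  Component signs are fixed so the
#' largest-magnitude loading of each component is positive.
#'
#' @param table Numeric matrix/data.frame (molecules x parameters), e.g. a
#'   descriptor table restricted to [chemspace_parameters()].
#' @param n_components Number of components (default 3).
#' @return A `chemspace_report` list: `scores` (n x k), `loadings`,
#'   `explained` (variance fractions), `parameters`.
#' @export
pca_chemspace <- function(table, n_components = 3L) {
  x <- as.matrix(table)
  storage.mode(x) <- "double"
  if (nrow(x) < 3L) stop("need at least 3 molecules", call. = FALSE)
  keep <- apply(x, 2L, function(col) stats::var(col) > 0)
  if (sum(keep) < n_components) {
    stop("fewer non-constant parameters (", sum(keep),
         ") than components (", n_components, ")", call. = FALSE)
  }
  x <- x[, keep, drop = FALSE]
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  k <- min(n_components, ncol(pc$rotation))
  load <- pc$rotation[, seq_len(k), drop = FALSE]
  scores <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {           # deterministic sign convention
    if (load[which.max(abs(load[, j])), j] < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  expl <- (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)]
  out <- list(scores = scores, loadings = load, explained = expl,
              parameters = colnames(x))
  class(out) <- "chemspace_report"
  out
}

#' @export
print.chemspace_report <- function(x, ...) {
  cat("chemical-space PCA over", length(x$parameters), "parameters\n")
  cat("explained variance:",
      paste(sprintf("%.1f%%", 100 * x$explained), collapse = ", "), "\n")
  invisible(x)
}

#' Default open chemical-space parameter set
#'
#' Open substitutes for the classical molecular-property panel used in
#' chemical-space PCA (weight, lipophilicity, polar surface area, H-bond
#' donors/acceptors, aromaticity, flexibility, ring content).  All are
#' columns of the default descriptor provider.
#'
#' @return Character vector of descriptor names.
#' @export
chemspace_parameters <- function() {
  c("MolWt", "MolLogP", "TPSA", "NumHAcceptors", "NumHDonors",
    "NumAromaticRings", "NumRotatableBonds", "RingCount",
    "HeavyAtomCount", "FractionCSP3", "NumSaturatedRings")
}

#' Train/test balance summary over PCA components
#'
#' Standardized mean difference (SMD) between train and test scores for
#' each component; components with |SMD| > 0.25 are flagged as imbalanced.
#'
#' @param assignment A [stratified_split()] result (or named
#'   `"train"`/`"test"` vector).
#' @param report A [pca_chemspace()] result whose score rows are named by
#'   (or aligned with) the same ids.
#' @param flag_threshold |SMD| above which a component is flagged.
#' @return Data.frame with one row per component: means, SDs, `smd`,
#'   `flagged`.
#' @export
split_overlap_report <- function(assignment, report, flag_threshold = 0.25) {
  asg <- if (inherits(assignment, "split_assignment")) assignment$assignment
         else assignment
  scores <- report$scores
  if (!is.null(rownames(scores)) && !is.null(names(asg))) {
    common <- intersect(rownames(scores), names(asg))
    scores <- scores[common, , drop = FALSE]
    asg <- asg[common]
  }
  stopifnot(nrow(scores) == length(asg))
  tr <- asg == "train"
  res <- lapply(seq_len(ncol(scores)), function(j) {
    a <- scores[tr, j]; b <- scores[!tr, j]
    sp <- sqrt((stats::var(a) + stats::var(b)) / 2)
    smd <- if (sp == 0) 0 else (mean(a) - mean(b)) / sp
    data.frame(component = colnames(scores)[j],
               train_mean = mean(a), train_sd = stats::sd(a),
               test_mean = mean(b), test_sd = stats::sd(b),
               smd = smd, flagged = abs(smd) > flag_threshold,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
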