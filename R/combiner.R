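#' Ensemble combination: mean of two probability tables
#'
#' The ensemble model's probability for a molecule is the arithmetic mean
#' of the two branch probabilities.
#'
#' @param pA,pB [probability_table()]s over identical id sets.
#' @param model_tag Tag for the combined table.
#' @return A [probability_table()].
#' @export
ensemble_mean <- function(pA, pB, model_tag = "ensemble") {
  if (!setequal(pA$id, pB$id)) {
    diffs <- c(setdiff(pA$id, pB$id), setdiff(pB$id, pA$id))
    stop("id mismatch between branches: ", paste(diffs, collapse = ", "),
         call. = FALSE)
  }
  b <- pB$p[match(pA$id, pB$id)]
  probability_table(pA$id, (pA$p + b) / 2, model_tag)
}

#' Consensus combination: agreement subset of two class vectors
#'
#' Retains only molecules on which both branches predict the same class;
#' the agreed class is the consensus prediction.  Disagreements are
#' dropped (and counted), so the consensus model covers fewer molecules.
#'
#' @param classA,classB Named factors/characters (`low`/`high`) over
#'   identical id sets, each obtained at its branch's own cutoff.
#' @return A `consensus_result` list: `retained_ids`, `classes` (named
#'   factor over retained ids), `n_input`, `n_retained`.
#' @export
consensus_filter <- function(classA, classB) {
  a <- stats::setNames(as.character(classA), names(classA))
  b <- stats::setNames(as.character(classB), names(classB))
  if (is.null(names(a)) || is.null(names(b))) {
    if (length(a) != length(b)) stop("class vectors must align", call. = FALSE)
    names(a) <- names(b) <- paste0("mol_", seq_along(a))
  }
  if (!setequal(names(a), names(b))) {
    diffs <- c(setdiff(names(a), names(b)), setdiff(names(b), names(a)))
    stop("id mismatch between branches: ", paste(diffs, collapse = ", "),
         call. = FALSE)
  }
  b <- b[names(a)]
  agree <- a == b
  if (!any(agree)) {
    warning("branches agree on no molecule; consensus set is empty",
            call. = FALSE)
  }
  out <- list(retained_ids = names(a)[agree],
              classes = factor(a[agree], levels = c("low", "high")),
              n_input = length(a), n_retained = sum(agree))
  class(out) <- "consensus_result"
  out
}

#' @export
print.consensus_result <- function(x, ...) {
  cat("consensus model:", x$n_retained, "of", x$n_input,
      "molecules retained (", x$n_input - x$n_retained, "disagreements )\n")
  invisible(x)
}
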