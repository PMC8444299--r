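#' RDKit descriptor provider
#'
#' Computes the full RDKit 2D descriptor panel (~210 named numeric
#' descriptors) for every molecule through the python backend.  This is
#' the default open descriptor set standing in for commercial descriptor
#' engines; any function mapping a molecule library to a named numeric
#' table can be plugged into [build_descriptor_table()] instead.
#'
#' @param mols A [molecule_library()].
#' @return Data.frame of descriptors with molecule ids as row names.
#' @export
descriptor_provider_rdkit <- function(mols) {
  inp <- tempfile(fileext = ".tsv"); on.exit(unlink(inp), add = TRUE)
  out <- tempfile(fileext = ".csv"); on.exit(unlink(out), add = TRUE)
  write_smiles_tsv(mols$id, mols$smiles, inp)
  run_chemtools(c("descriptors", shQuote(inp), shQuote(out)))
  tab <- read.csv(out, stringsAsFactors = FALSE, check.names = FALSE)
  rownames(tab) <- tab$id
  tab$id <- NULL
  tab[match(mols$id, rownames(tab)), , drop = FALSE]
}

#' Build and filter a descriptor table
#'
#' Runs the provider, then applies the cleaning rules: non-numeric
#' (string-type) columns are removed, columns with missing or non-finite
#' values are removed, and zero-variance columns are removed.  The filter
#' log records how many columns each rule dropped.
#'
#' @param mols A [molecule_library()].
#' @param provider A provider function (default
#'   [descriptor_provider_rdkit()]) or a precomputed data.frame with
#'   molecule ids as row names.
#' @return Numeric matrix (molecules x descriptors) with attribute
#'   `filter_log`.
#' @export
build_descriptor_table <- function(mols, provider = descriptor_provider_rdkit) {
  raw <- if (is.function(provider)) provider(mols) else provider
  raw <- as.data.frame(raw)
  if (!is.null(mols$id)) {
    if (!all(mols$id %in% rownames(raw))) {
      stop("descriptor provider failed for molecule(s): ",
           paste(setdiff(mols$id, rownames(raw)), collapse = ", "),
           call. = FALSE)
    }
    raw <- raw[mols$id, , drop = FALSE]
  }
  is_num <- vapply(raw, is.numeric, TRUE)
  n_string <- sum(!is_num)
  tab <- as.matrix(raw[, is_num, drop = FALSE])
  storage.mode(tab) <- "double"
  bad_vals <- apply(tab, 2L, function(col) any(!is.finite(col)))
  n_missing <- sum(bad_vals)
  tab <- tab[, !bad_vals, drop = FALSE]
  zero_var <- apply(tab, 2L, function(col) stats::var(col) == 0)
  n_const <- sum(zero_var)
  tab <- tab[, !zero_var, drop = FALSE]
  log <- data.frame(rule = c("string_type", "missing_or_nonfinite",
                             "zero_variance"),
                    removed = c(n_string, n_missing, n_const),
                    stringsAsFactors = FALSE)
  attr(tab, "filter_log") <- log
  tab
}
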