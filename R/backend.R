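#' Locate the python interpreter used for the RDKit backend
#'
#' The cheminformatics primitives (SMILES parsing, descriptor calculation,
#' 3D embedding) are delegated to RDKit through the bundled helper script.
#' The interpreter is taken from `options(clsnap.python=)`, the
#' `CLSNAP_PYTHON` environment variable, or the first of `python3`/`python`
#' on the PATH.
#'
#' @return Path to the python executable.
#' @export
clsnap_python <- function() {
  p <- getOption("clsnap.python", "")
  if (!nzchar(p)) p <- Sys.getenv("CLSNAP_PYTHON", "")
  if (!nzchar(p)) {
    for (cand in c("python", "python3")) {
      hit <- Sys.which(cand)
      if (nzchar(hit)) { p <- hit; break }
    }
  }
  if (!nzchar(p)) {
    stop("no python interpreter found; set options(clsnap.python=) ",
         "or the CLSNAP_PYTHON environment variable", call. = FALSE)
  }
  p
}

chemtools_path <- function() {
  p <- system.file("python", "chemtools.py", package = "clsnap")
  if (!nzchar(p)) stop("bundled chemtools.py not found; is clsnap installed?",
                       call. = FALSE)
  p
}

run_chemtools <- function(args) {
  out <- suppressWarnings(
    system2(clsnap_python(), c(shQuote(chemtools_path()), args),
            stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) {
    stop("chemistry backend failed (exit ", status, "):\n",
         paste(out, collapse = "\n"), call. = FALSE)
  }
  invisible(out)
}

write_smiles_tsv <- function(ids, smiles, path) {
  writeLines(paste(ids, smiles, sep = "\t"), path)
}

#' Parse and canonicalize SMILES strings
#'
#' Batched call into the RDKit backend.  Invalid entries are reported, not
#' dropped, so callers can warn with record numbers.
#'
#' @param smiles Character vector of SMILES strings.
#' @param ids Optional ids (defaults to index).
#' @return A data.frame with columns `id`, `ok`, `canonical_smiles`,
#'   `heavy_atoms`, `mol_weight`, `error`, in input order.
#' @export
parse_smiles <- function(smiles, ids = as.character(seq_along(smiles))) {
  stopifnot(length(smiles) == length(ids))
  if (length(smiles) == 0L) {
    return(data.frame(id = character(), ok = logical(),
                      canonical_smiles = character(), heavy_atoms = integer(),
                      mol_weight = numeric(), error = character(),
                      stringsAsFactors = FALSE))
  }
  inp <- tempfile(fileext = ".tsv"); on.exit(unlink(inp), add = TRUE)
  out <- tempfile(fileext = ".tsv"); on.exit(unlink(out), add = TRUE)
  write_smiles_tsv(ids, smiles, inp)
  run_chemtools(c("parse", shQuote(inp), shQuote(out)))
  res <- read.delim(out, stringsAsFactors = FALSE, colClasses = c(
    id = "character", ok = "integer", canonical_smiles = "character",
    heavy_atoms = "integer", mol_weight = "numeric", error = "character"))
  res$ok <- res$ok == 1L
  res[match(ids, res$id), , drop = FALSE]
}
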