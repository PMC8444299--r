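#' Construct a molecule library
#'
#' The unit of data flowing through the pipeline: one row per molecule with
#' its structure, optional continuous clearance endpoint (L/h/kg) and
#' optional binary class label.
#'
#' @param id Character vector of unique molecule ids.
#' @param smiles SMILES strings, one per molecule.
#' @param cl_value Optional nonnegative clearance values in L/h/kg.
#' @param label Optional factor/character with levels `low`/`high`; derived
#'   from `cl_value` at `threshold` when absent.
#' @param threshold Clearance dichotomization threshold in L/h/kg; the
#'   positive ("high") class is `cl_value >= threshold`.
#' @return A `molecule_library` (a data.frame with columns `id`, `smiles`,
#'   `cl_value`, `label`).
#' @export
molecule_library <- function(id, smiles, cl_value = NULL, label = NULL,
                             threshold = 1.0) {
  id <- as.character(id)
  smiles <- as.character(smiles)
  stopifnot(length(id) == length(smiles))
  if (anyDuplicated(id)) {
    stop("molecule ids must be unique; duplicated: ",
         paste(unique(id[duplicated(id)]), collapse = ", "), call. = FALSE)
  }
  if (is.null(cl_value)) cl_value <- rep(NA_real_, length(id))
  stopifnot(length(cl_value) == length(id))
  if (any(!is.na(cl_value) & cl_value < 0)) {
    stop("cl_value must be nonnegative", call. = FALSE)
  }
  if (is.null(label)) {
    label <- factor(rep(NA_character_, length(id)), levels = c("low", "high"))
    has <- !is.na(cl_value)
    label[has] <- label_from_cl(cl_value[has], threshold)
  } else {
    label <- factor(as.character(label), levels = c("low", "high"))
    if (anyNA(label) && !all(is.na(label))) {
      stop("labels must all be 'low' or 'high' (or all absent)", call. = FALSE)
    }
  }
  out <- data.frame(id = id, smiles = smiles, cl_value = cl_value,
                    label = label, stringsAsFactors = FALSE)
  class(out) <- c("molecule_library", "data.frame")
  out
}

#' Dichotomize clearance values into low/high classes
#'
#' The class boundary is 1 L/h/kg (about 30% of hepatic blood flow in rat);
#' values at or above the threshold are "high" clearance.
#'
#' @param cl_value Nonnegative clearance values (L/h/kg).
#' @param threshold Class boundary, default 1 L/h/kg.
#' @return Factor with levels `low`, `high`.
#' @export
label_from_cl <- function(cl_value, threshold = 1.0) {
  if (any(is.na(cl_value))) stop("cl_value contains NA", call. = FALSE)
  if (any(cl_value < 0)) stop("cl_value must be nonnegative", call. = FALSE)
  factor(ifelse(cl_value >= threshold, "high", "low"),
         levels = c("low", "high"))
}

#' Read molecules from a SMILES or SDF file
#'
#' SMILES files hold one record per line (`smiles<TAB>id`, id optional);
#' SDF files are V2000.  The clearance endpoint is read from an SDF data
#' tag (default `CL`) or from a sidecar CSV with columns `id`, `cl_value`.
#' Invalid records are rejected with a warning giving their record numbers
#' and are listed in `attr(x, "rejects")`; they are never silently dropped.
#'
#' @param path Input file.
#' @param format `"auto"` (by extension), `"smiles"` or `"sdf"`.
#' @param cl_tag SDF data-block tag holding the clearance value.
#' @param cl_csv Optional sidecar CSV path with columns `id`, `cl_value`.
#' @param threshold Dichotomization threshold passed to [label_from_cl()].
#' @return A [molecule_library()]; SDF input also carries the conformers in
#'   `attr(x, "conformers")` when 3D coordinates are present.
#' @export
read_molecules <- function(path, format = c("auto", "smiles", "sdf"),
                           cl_tag = "CL", cl_csv = NULL, threshold = 1.0) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("sdf", "sd", "mol")) "sdf" else "smiles"
  }
  if (format == "smiles") {
    lib <- read_molecules_smiles(path)
  } else {
    lib <- read_molecules_sdf(path, cl_tag = cl_tag)
  }
  if (!is.null(cl_csv)) {
    tab <- read.csv(cl_csv, stringsAsFactors = FALSE)
    if (!all(c("id", "cl_value") %in% names(tab))) {
      stop("endpoint CSV needs columns id, cl_value", call. = FALSE)
    }
    lib$cl_value <- tab$cl_value[match(lib$id, as.character(tab$id))]
  }
  if (any(!is.na(lib$cl_value))) {
    has <- !is.na(lib$cl_value)
    lib$label[has] <- label_from_cl(lib$cl_value[has], threshold)
  }
  lib
}

read_molecules_smiles <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    warning("no molecule records in ", path, call. = FALSE)
    return(molecule_library(character(), character()))
  }
  parts <- strsplit(lines, "[\t ]+")
  smiles <- vapply(parts, `[[`, "", 1L)
  ids <- vapply(parts, function(p) if (length(p) >= 2L) p[[2L]] else "", "")
  ids[!nzchar(ids)] <- paste0("mol_", which(!nzchar(ids)))
  parsed <- parse_smiles(smiles, ids)
  bad <- !parsed$ok
  if (any(bad)) {
    warning(sum(bad), " record(s) rejected (unparsable SMILES) at line(s) ",
            paste(which(bad), collapse = ", "), call. = FALSE)
  }
  lib <- molecule_library(ids[!bad], smiles[!bad])
  attr(lib, "rejects") <- data.frame(record = which(bad),
                                     reason = parsed$error[bad],
                                     stringsAsFactors = FALSE)
  lib
}

read_molecules_sdf <- function(path, cl_tag = "CL") {
  sdfset <- suppressWarnings(ChemmineR::read.SDFset(path))
  valid <- ChemmineR::validSDF(sdfset)
  if (any(!valid)) {
    warning(sum(!valid), " SDF record(s) rejected (invalid) at record(s) ",
            paste(which(!valid), collapse = ", "), call. = FALSE)
  }
  rejects <- data.frame(record = which(!valid),
                        reason = rep("invalid SDF record", sum(!valid)),
                        stringsAsFactors = FALSE)
  sdfset <- sdfset[valid]
  n <- length(sdfset)
  if (n == 0L) {
    lib <- molecule_library(character(), character())
    attr(lib, "rejects") <- rejects
    return(lib)
  }
  ids <- vapply(ChemmineR::SDFset2SDF(sdfset), function(s) {
    h <- ChemmineR::header(s)[["Molecule_Name"]]
    if (is.null(h) || !nzchar(trimws(h))) "" else trimws(h)
  }, "")
  ids[!nzchar(ids)] <- paste0("mol_", which(!nzchar(ids)))
  smiles <- as.character(suppressWarnings(ChemmineR::sdf2smiles(sdfset)))
  cl <- rep(NA_real_, n)
  confs <- vector("list", n)
  for (i in seq_len(n)) {
    s <- sdfset[[i]]
    db <- ChemmineR::datablock(s)
    if (cl_tag %in% names(db)) cl[i] <- suppressWarnings(as.numeric(db[[cl_tag]]))
    confs[[i]] <- sdf_to_conformer(s)
  }
  lib <- molecule_library(ids, smiles, cl_value = cl)
  names(confs) <- ids
  has3d <- vapply(confs, function(cf) any(abs(cf$coords[, 3]) > 1e-8), TRUE)
  if (any(has3d)) attr(lib, "conformers") <- confs
  attr(lib, "rejects") <- rejects
  lib
}

#' Keep only the largest covalently connected fragment
#'
#' Salt/solvate stripping: counter-ions and water are dropped by retaining,
#' per molecule, the fragment with the most heavy atoms.  Ties go to the
#' larger molecular weight, then to the lexicographically smallest
#' canonical SMILES.  Single-fragment input is returned unchanged, which
#' makes the operation idempotent.
#'
#' @param smiles Character vector of SMILES (possibly multi-fragment).
#' @return Character vector of single-fragment SMILES.
#' @export
strip_salts <- function(smiles) {
  smiles <- as.character(smiles)
  pieces <- strsplit(smiles, ".", fixed = TRUE)
  multi <- lengths(pieces) > 1L
  if (!any(multi)) return(smiles)
  frags <- unique(unlist(pieces[multi]))
  info <- parse_smiles(frags, frags)
  if (any(!info$ok)) {
    stop("unparsable fragment(s): ",
         paste(frags[!info$ok], collapse = ", "), call. = FALSE)
  }
  out <- smiles
  for (k in which(multi)) {
    fr <- pieces[[k]]
    m <- info[match(fr, info$id), , drop = FALSE]
    ord <- order(-m$heavy_atoms, -m$mol_weight, m$canonical_smiles)
    out[k] <- fr[ord[1L]]
  }
  out
}

#' @export
print.molecule_library <- function(x, ...) {
  cat("molecule library:", nrow(x), "molecules")
  if (any(!is.na(x$label))) {
    tab <- table(x$label)
    cat(" (", tab[["low"]], " low / ", tab[["high"]], " high)", sep = "")
  }
  cat("\n")
  print.data.frame(head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("... and", nrow(x) - 6L, "more rows\n")
  invisible(x)
}

# ---- 3D conformers ---------------------------------------------------------

#' Construct a 3D conformer object
#'
#' @param elements Character vector of element symbols.
#' @param coords Numeric n x 3 matrix of coordinates in Angstrom.
#' @param bonds Data.frame/matrix with columns `i`, `j`, `order`
#'   (1-based atom indices).
#' @return An object of class `conformer3d`.
#' @export
conformer3d <- function(elements, coords, bonds) {
  coords <- matrix(as.numeric(coords), ncol = 3L,
                   dimnames = list(NULL, c("x", "y", "z")))
  if (length(elements) < 1L) stop("conformer needs at least one atom", call. = FALSE)
  if (nrow(coords) != length(elements)) stop("coords/elements mismatch", call. = FALSE)
  if (!all(is.finite(coords))) stop("non-finite coordinates", call. = FALSE)
  bonds <- as.data.frame(bonds)
  if (nrow(bonds) > 0L) {
    names(bonds)[1:3] <- c("i", "j", "order")
    if (any(bonds$i < 1L | bonds$i > length(elements)) ||
        any(bonds$j < 1L | bonds$j > length(elements))) {
      stop("bond indices out of range", call. = FALSE)
    }
  } else {
    bonds <- data.frame(i = integer(), j = integer(), order = integer())
  }
  structure(list(elements = as.character(elements), coords = coords,
                 bonds = bonds), class = "conformer3d")
}

#' @export
print.conformer3d <- function(x, ...) {
  cat("conformer3d:", length(x$elements), "atoms,", nrow(x$bonds), "bonds\n")
  invisible(x)
}

sdf_to_conformer <- function(sdf) {
  ab <- ChemmineR::atomblock(sdf)
  if (is.null(dim(ab)) || ncol(ab) < 3L) {
    stop("malformed atom block (single-atom records are not supported ",
         "by the SDF reader)", call. = FALSE)
  }
  bb <- ChemmineR::bondblock(sdf)
  elements <- sub("_.*$", "", rownames(ab))
  coords <- ab[, 1:3, drop = FALSE]
  bonds <- if (is.null(dim(bb)) || nrow(bb) == 0L) {
    data.frame(i = integer(), j = integer(), order = integer())
  } else {
    data.frame(i = as.integer(bb[, 1L]), j = as.integer(bb[, 2L]),
               order = as.integer(bb[, 3L]))
  }
  conformer3d(elements, coords, bonds)
}

#' Embed 3D conformers for a molecule library
#'
#' Seeded distance-geometry embedding with force-field refinement (RDKit
#' ETKDG + MMFF/UFF through the python backend); hydrogens are explicit and
#' coordinates are centred at the geometric centroid.  Deterministic given
#' (structure, seed).  Molecules that fail to embed are excluded and
#' reported via a warning and `attr(x, "failures")`.
#'
#' @param mols A [molecule_library()] or character vector of SMILES.
#' @param seed Integer seed for the embedding.
#' @return Named list of [conformer3d()] objects.
#' @export
embed_molecules <- function(mols, seed = 1L) {
  if (is.character(mols)) {
    ids <- if (!is.null(names(mols))) names(mols) else
      paste0("mol_", seq_along(mols))
    smiles <- unname(mols)
  } else {
    ids <- mols$id
    smiles <- mols$smiles
  }
  if (length(ids) == 0L) return(structure(list(), failures = character()))
  inp <- tempfile(fileext = ".tsv")
  coords <- tempfile(fileext = ".tsv")
  bonds <- tempfile(fileext = ".tsv")
  stat <- tempfile(fileext = ".tsv")
  on.exit(unlink(c(inp, coords, bonds, stat)), add = TRUE)
  write_smiles_tsv(ids, smiles, inp)
  run_chemtools(c("embed", shQuote(inp), shQuote(coords), shQuote(bonds),
                  shQuote(stat), "--seed", as.integer(seed)))
  status <- read.delim(stat, stringsAsFactors = FALSE,
                       colClasses = c(id = "character"))
  failed <- status$id[status$ok != 1L]
  if (length(failed)) {
    warning("3D embedding failed for ", length(failed), " molecule(s): ",
            paste(failed, collapse = ", "), call. = FALSE)
  }
  ct <- read.delim(coords, stringsAsFactors = FALSE,
                   colClasses = c(id = "character", element = "character"))
  bt <- read.delim(bonds, stringsAsFactors = FALSE,
                   colClasses = c(id = "character"))
  ok_ids <- setdiff(ids, failed)
  ct_by <- split(ct, factor(ct$id, levels = ok_ids))
  bt_by <- split(bt, factor(bt$id, levels = ok_ids))
  confs <- lapply(ok_ids, function(id) {
    a <- ct_by[[id]]
    b <- bt_by[[id]]
    conformer3d(a$element, cbind(a$x, a$y, a$z),
                data.frame(i = as.integer(b$i), j = as.integer(b$j),
                           order = as.integer(b$order)))
  })
  names(confs) <- ok_ids
  structure(confs, failures = failed)
}

#' Embed a single structure
#'
#' Convenience wrapper around [embed_molecules()] for one SMILES string.
#'
#' @param smiles A single SMILES string.
#' @param seed Integer seed.
#' @return A [conformer3d()].
#' @export
embed_3d <- function(smiles, seed = 1L) {
  res <- embed_molecules(c(m = smiles), seed = seed)
  if (length(res) == 0L) stop("embedding failed for: ", smiles, call. = FALSE)
  res[[1L]]
}

#' Write conformers to an SDF (V2000) file
#'
#' @param conformers Named list of [conformer3d()] objects.
#' @param path Output file.
#' @param data Optional data.frame of per-molecule tags (rownames or `id`
#'   column matched against conformer names), written to the data block.
#' @return Invisibly, `path`.
#' @export
write_conformers_sdf <- function(conformers, path, data = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  ids <- names(conformers)
  for (k in seq_along(conformers)) {
    cf <- conformers[[k]]
    na <- length(cf$elements); nb <- nrow(cf$bonds)
    lines <- c(ids[k], "  clsnap", "",
               sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nb))
    lines <- c(lines, sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                              cf$coords[, 1], cf$coords[, 2], cf$coords[, 3],
                              cf$elements))
    if (nb > 0L) {
      lines <- c(lines, sprintf("%3d%3d%3d  0  0  0  0",
                                cf$bonds$i, cf$bonds$j, cf$bonds$order))
    }
    lines <- c(lines, "M  END")
    if (!is.null(data)) {
      row <- if ("id" %in% names(data)) data[match(ids[k], data$id), , drop = FALSE]
             else data[ids[k], , drop = FALSE]
      for (cn in setdiff(names(row), "id")) {
        if (!is.na(row[[cn]])) {
          lines <- c(lines, sprintf("> <%s>", cn), as.character(row[[cn]]), "")
        }
      }
    }
    lines <- c(lines, "$$$$")
    writeLines(lines, con)
  }
  invisible(path)
}
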