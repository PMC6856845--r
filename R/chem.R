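.PARSE_ERROR <- "*PARSE_ERROR*"

.chem_python <- function() {
  py <- getOption("hitsieve.python", "")
  if (!nzchar(py)) py <- Sys.which("python")
  if (!nzchar(py)) py <- Sys.which("python3")
  if (!nzchar(py)) {
    stop("no 'python' interpreter found on PATH; the chemistry backend needs ",
         "Python with RDKit (set options(hitsieve.python = ...) to override)")
  }
  py
}

.chem_backend <- function(command, ids, smiles, extra_args = character()) {
  stopifnot(length(ids) == length(smiles))
  if (anyNA(smiles)) stop("SMILES input contains NA")
  if (any(grepl("[\t\n]", ids)) || any(grepl("[\t\n]", smiles))) {
    stop("ids and SMILES must not contain tab or newline characters")
  }
  script <- system.file("python", "chem_backend.py", package = "hitsieve")
  if (!nzchar(script)) stop("chem_backend.py not found in installed package")
  fin <- tempfile(fileext = ".tsv")
  fout <- tempfile(fileext = ".tsv")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  writeLines(paste(ids, smiles, sep = "\t"), fin)
  status <- suppressWarnings(
    system2(.chem_python(), c(shQuote(script), command, shQuote(fin), shQuote(fout), extra_args),
            stdout = TRUE, stderr = TRUE)
  )
  code <- attr(status, "status")
  if (!is.null(code) && code != 0) {
    stop("chemistry backend '", command, "' failed: ", paste(status, collapse = "\n"))
  }
  out <- read.delim(fout, header = FALSE, sep = "\t", quote = "",
                    colClasses = "character", col.names = c("id", "value"))
  if (nrow(out) != length(ids) || !identical(out$id, as.character(ids))) {
    stop("chemistry backend returned results out of register with its input")
  }
  out$value
}

#' Compute 1024-bit ECFP4 fingerprints
#'
#' Hashed Morgan circular fingerprints of radius 2 (diameter 4), folded to
#' 1024 bits, as used for all structure-based interference models in this
#' package. Fingerprinting is a pure function of the structure: the same
#' SMILES always yields the same bit vector.
#'
#' @param smiles Character vector of SMILES strings.
#' @param ids Optional identifiers used as row names (defaults to the SMILES
#'   themselves).
#' @param on_parse_failure `"error"` (default) to fail on the first
#'   unparseable structure, or `"drop"` to discard such records with a
#'   warning, mirroring standard curation practice for HTS collections.
#' @return Integer matrix with one row per (retained) structure and 1024
#'   columns; row names are `ids`. Dropped records are reported in the
#'   `"dropped"` attribute.
#' @examples
#' \dontrun{
#' fp <- fingerprint_matrix(c("c1ccccc1", "CCO"))
#' rowSums(fp)
#' }
#' @export
fingerprint_matrix <- function(smiles, ids = NULL,
                               on_parse_failure = c("error", "drop")) {
  on_parse_failure <- match.arg(on_parse_failure)
  if (length(smiles) == 0) {
    return(matrix(integer(0), nrow = 0, ncol = 1024))
  }
  if (is.null(ids)) ids <- as.character(smiles)
  if (anyDuplicated(ids)) stop("fingerprint ids must be unique")
  bits <- .chem_backend("fingerprint", ids, smiles)
  bad <- bits == .PARSE_ERROR
  if (any(bad)) {
    if (on_parse_failure == "error") {
      stop("unparseable structure(s): ",
           paste(utils::head(ids[bad], 5), collapse = ", "),
           if (sum(bad) > 5) sprintf(" (and %d more)", sum(bad) - 5) else "")
    }
    warning(sum(bad), " unparseable structure(s) discarded")
  }
  keep <- !bad
  m <- matrix(0L, nrow = sum(keep), ncol = 1024,
              dimnames = list(ids[keep], NULL))
  if (any(keep)) {
    rows <- strsplit(bits[keep], "", fixed = TRUE)
    for (i in seq_along(rows)) m[i, ] <- as.integer(rows[[i]] == "1")
  }
  attr(m, "dropped") <- ids[bad]
  m
}

#' @rdname fingerprint_matrix
#' @return For `compute_fingerprint`, a single integer vector of length 1024.
#' @export
compute_fingerprint <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1, nzchar(smiles))
  drop(fingerprint_matrix(smiles, ids = "x")[1, ])
}

#' Canonicalize SMILES (parse check)
#'
#' @param smiles Character vector of SMILES.
#' @return Character vector of canonical SMILES with `NA` where the
#'   structure could not be parsed.
#' @export
canonical_smiles <- function(smiles, ids = NULL) {
  if (length(smiles) == 0) return(character(0))
  if (is.null(ids)) ids <- sprintf("s%d", seq_along(smiles))
  out <- .chem_backend("canon", ids, smiles)
  out[out == .PARSE_ERROR] <- NA_character_
  out
}

#' Tanimoto similarity between binary fingerprints
#'
#' `tanimoto()` compares two bit vectors; `tanimoto_matrix()` computes the
#' full similarity matrix between the rows of two fingerprint matrices.
#' The similarity of two empty (all-zero) fingerprints is defined as 0;
#' empty fingerprints are pathological and worth inspecting upstream.
#'
#' @param a,b Binary vectors of equal length.
#' @return Similarity in \[0, 1\]: shared on-bits over united on-bits.
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b)) {
    stop("fingerprint length mismatch: ", length(a), " vs ", length(b))
  }
  a <- as.logical(a); b <- as.logical(b)
  un <- sum(a | b)
  if (un == 0) return(0)
  sum(a & b) / un
}

#' @rdname tanimoto
#' @param A,B Matrices with one fingerprint per row and equal column counts.
#' @return For `tanimoto_matrix`, an `nrow(A)` x `nrow(B)` matrix.
#' @export
tanimoto_matrix <- function(A, B) {
  if (ncol(A) != ncol(B)) stop("fingerprint length mismatch")
  A <- A * 1; B <- B * 1
  inter <- tcrossprod(A, B)
  un <- outer(rowSums(A), rowSums(B), "+") - inter
  out <- ifelse(un == 0, 0, inter / un)
  dimnames(out) <- list(rownames(A), rownames(B))
  out
}

#' Load a PAINS substructure catalog
#'
#' By default loads the published 480-pattern pan-assay interference
#' (PAINS) catalog as distributed with RDKit, with the conventional entry
#' names (e.g. `"quinone_A(370)"`). A user-supplied file may be given
#' instead, either as the tab-separated `smarts<TAB>name` dialect or as the
#' conventional `SMARTS name` one-pattern-per-line format.
#'
#' @param source `NULL` for the bundled catalog, or a path to a SMARTS file.
#' @return A `pains_catalog`: data frame with columns `name` and `smarts`.
#' @export
load_pains_catalog <- function(source = NULL) {
  if (is.null(source)) {
    fout <- tempfile(fileext = ".tsv")
    on.exit(unlink(fout), add = TRUE)
    script <- system.file("python", "chem_backend.py", package = "hitsieve")
    status <- suppressWarnings(
      system2(.chem_python(), c(shQuote(script), "catalog", shQuote(fout)),
              stdout = TRUE, stderr = TRUE)
    )
    code <- attr(status, "status")
    if (!is.null(code) && code != 0) {
      stop("could not load bundled PAINS catalog: ", paste(status, collapse = "\n"))
    }
    tab <- read.delim(fout, header = FALSE, sep = "\t", quote = "",
                      colClasses = "character", col.names = c("name", "smarts"))
  } else {
    if (!file.exists(source)) stop("catalog file not found: ", source)
    lines <- readLines(source)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0) stop("catalog file is empty: ", source)
    if (any(grepl("\t", lines, fixed = TRUE))) {
      parts <- strsplit(lines, "\t", fixed = TRUE)
      tab <- data.frame(smarts = vapply(parts, `[`, "", 1),
                        name = vapply(parts, `[`, "", 2))
    } else {
      sp <- regexpr("[[:space:]]", lines)
      if (any(sp < 0)) stop("catalog line without a pattern name: line ",
                            which(sp < 0)[1])
      tab <- data.frame(smarts = substr(lines, 1, sp - 1),
                        name = trimws(substring(lines, sp + 1)))
    }
    tab <- tab[, c("name", "smarts")]
  }
  if (anyDuplicated(tab$name)) {
    stop("duplicate pattern names in catalog: ",
         paste(unique(tab$name[duplicated(tab$name)])[1:3], collapse = ", "))
  }
  class(tab) <- c("pains_catalog", "data.frame")
  tab
}

#' @export
print.pains_catalog <- function(x, ...) {
  cat("PAINS substructure catalog:", nrow(x), "patterns\n")
  invisible(x)
}

#' Match PAINS substructures
#'
#' Screens structures against a PAINS catalog and reports every matching
#' pattern name. A compound is PAINS-predicted interfering iff its match
#' list is non-empty (see [pains_predict()]).
#'
#' @param smiles Character vector of SMILES.
#' @param catalog A [load_pains_catalog()] result, or `NULL` for the bundled
#'   480-pattern catalog (matched with RDKit's native PAINS FilterCatalog).
#' @param ids Optional identifiers naming the output.
#' @return Named list (one element per input) of matched pattern names,
#'   possibly empty. Unparseable structures raise an error.
#' @export
match_pains <- function(smiles, catalog = NULL, ids = NULL) {
  if (length(smiles) == 0) return(setNames(list(), character(0)))
  if (is.null(ids)) ids <- sprintf("s%d", seq_along(smiles))
  extra <- character()
  if (!is.null(catalog)) {
    stopifnot(inherits(catalog, "pains_catalog"))
    cf <- tempfile(fileext = ".tsv")
    on.exit(unlink(cf), add = TRUE)
    writeLines(paste(catalog$smarts, catalog$name, sep = "\t"), cf)
    extra <- shQuote(cf)
  }
  out <- .chem_backend("pains", ids, smiles, extra)
  if (any(out == .PARSE_ERROR)) {
    stop("unparseable structure(s): ",
         paste(utils::head(ids[out == .PARSE_ERROR], 5), collapse = ", "))
  }
  res <- strsplit(out, "|", fixed = TRUE)
  res <- lapply(res, function(x) x[nzchar(x)])
  names(res) <- ids
  res
}

#' @rdname match_pains
#' @return For `pains_predict`, a logical vector: any-match indicator.
#' @export
pains_predict <- function(smiles, catalog = NULL, ids = NULL) {
  vapply(match_pains(smiles, catalog, ids), function(m) length(m) > 0, TRUE)
}
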