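# Plain-text persistence: activity tables, campaigns, fingerprints and
# evaluation reports round-trip through CSV/JSON so every intermediate
# artifact stays inspectable.

.RESULT_COLS <- c("compound_id", "assay_id", "technology", "assay_kind",
                  "activity_flag", "flag_source")

#' Read a compound-activity table
#'
#' Validates the result-table schema: required columns, closed flag and
#' assay-kind vocabularies. Offending rows are named in errors.
#'
#' @param path CSV path with columns `compound_id`, `assay_id`,
#'   `technology`, `assay_kind` (primary/artefact), `activity_flag`
#'   (active/inactive/inconclusive), `flag_source` (zscore/percent_effect,
#'   empty for artefact rows).
#' @return Validated data frame of assay results.
#' @export
read_activity_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  missing <- setdiff(.RESULT_COLS, names(tab))
  if (length(missing)) {
    stop("missing column(s) in ", path, ": ", paste(missing, collapse = ", "))
  }
  tab$flag_source[!nzchar(tab$flag_source) | is.na(tab$flag_source)] <- NA_character_
  bad <- which(!(tab$activity_flag %in% .FLAG_LEVELS))
  if (length(bad)) {
    stop("unknown activity_flag '", tab$activity_flag[bad[1]],
         "' at row ", bad[1], if (length(bad) > 1)
           sprintf(" (and %d more rows)", length(bad) - 1) else "")
  }
  bad <- which(!(tab$assay_kind %in% c("primary", "artefact")))
  if (length(bad)) {
    stop("unknown assay_kind '", tab$assay_kind[bad[1]], "' at row ", bad[1])
  }
  bad <- which(!is.na(tab$flag_source) &
                 !(tab$flag_source %in% c("zscore", "percent_effect")))
  if (length(bad)) {
    stop("unknown flag_source '", tab$flag_source[bad[1]], "' at row ", bad[1])
  }
  tab[, .RESULT_COLS]
}

#' Write / read a synthetic campaign
#'
#' A campaign is stored as plain text: `compounds.csv`, `assays.csv`,
#' `results.csv` and `ground_truth.json` in a directory.
#'
#' @param campaign A `synthetic_campaign`.
#' @param dir Output directory (created if needed).
#' @return `write_campaign` returns `dir` invisibly; `read_campaign`
#'   returns the campaign (without the generator config).
#' @export
write_campaign <- function(campaign, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(campaign$compounds, file.path(dir, "compounds.csv"),
                   row.names = FALSE)
  utils::write.csv(campaign$assays, file.path(dir, "assays.csv"),
                   row.names = FALSE)
  utils::write.csv(campaign$results, file.path(dir, "results.csv"),
                   row.names = FALSE)
  gt <- campaign$ground_truth
  techs <- setdiff(names(gt), "compound_id")
  gt_list <- lapply(seq_len(nrow(gt)), function(i) {
    setNames(lapply(techs, function(t) if (gt[[t]][i]) "CIAT" else "NCIAT"),
             techs)
  })
  names(gt_list) <- gt$compound_id
  jsonlite::write_json(gt_list, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, pretty = FALSE)
  invisible(dir)
}

#' @rdname write_campaign
#' @export
read_campaign <- function(dir) {
  compounds <- utils::read.csv(file.path(dir, "compounds.csv"),
                               stringsAsFactors = FALSE,
                               colClasses = "character")
  assays <- utils::read.csv(file.path(dir, "assays.csv"),
                            stringsAsFactors = FALSE,
                            colClasses = "character")
  assays$linked_artefact[assays$linked_artefact == ""] <- NA_character_
  results <- read_activity_table(file.path(dir, "results.csv"))
  gt_list <- jsonlite::read_json(file.path(dir, "ground_truth.json"))
  techs <- unique(assays$technology)
  gt <- data.frame(compound_id = names(gt_list), stringsAsFactors = FALSE)
  for (t in techs) {
    gt[[t]] <- vapply(gt_list, function(x) identical(x[[t]], "CIAT"), TRUE)
  }
  rownames(gt) <- NULL
  structure(list(compounds = compounds, assays = assays, results = results,
                 ground_truth = gt),
            class = "synthetic_campaign")
}

#' Write / read an evaluation report
#'
#' Lossless CSV round-trip of the report schema.
#'
#' @param report An `evaluation_report` data frame.
#' @param path CSV path.
#' @export
write_report <- function(report, path) {
  utils::write.csv(as.data.frame(report), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(technology = "character",
                                        holdout_assay = "character",
                                        method = "character",
                                        subset = "character",
                                        excluded_reason = "character"))
  expected <- c("technology", "holdout_assay", "method", "subset", "n",
                "TP", "FP", "TN", "FN", "mcc", "recall", "precision",
                "auc", "excluded_reason")
  if (!identical(names(tab), expected)) {
    stop("report schema mismatch in ", path, "; expected columns: ",
         paste(expected, collapse = ", "))
  }
  for (cc in c("method", "excluded_reason")) {
    tab[[cc]][!nzchar(tab[[cc]]) | is.na(tab[[cc]])] <- NA_character_
  }
  class(tab) <- c("evaluation_report", "data.frame")
  tab
}

#' Serialize fingerprints as bit strings
#'
#' @param fp Fingerprint matrix (rownames = compound ids).
#' @param path CSV path with columns `compound_id`, `bits`.
#' @export
write_fingerprints <- function(fp, path) {
  bits <- apply(fp, 1, paste, collapse = "")
  utils::write.csv(data.frame(compound_id = rownames(fp), bits = bits,
                              stringsAsFactors = FALSE),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fingerprints
#' @export
read_fingerprints <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  n <- nchar(tab$bits[1])
  m <- matrix(0L, nrow(tab), n, dimnames = list(tab$compound_id, NULL))
  rows <- strsplit(tab$bits, "", fixed = TRUE)
  for (i in seq_along(rows)) m[i, ] <- as.integer(rows[[i]] == "1")
  m
}
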