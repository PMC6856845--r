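# CIAT/NCIAT curation: reconcile raw activity flags and derive
# per-technology interference labels from artefact (counter-screen) assays.

.FLAG_LEVELS <- c("active", "inactive", "inconclusive")

.check_flags <- function(flags) {
  bad <- !(flags %in% .FLAG_LEVELS)
  if (any(bad)) {
    stop("unknown activity flag value(s): ",
         paste(unique(flags[bad]), collapse = ", "))
  }
}

#' Reconcile primary activity flags
#'
#' Collapses multiple datapoints per (compound, assay) to one flag:
#' Z-score-sourced flags take precedence over percent-effect flags
#' whenever any are present; within the considered flags a compound found
#' both active and inactive under the same conditions (same assay) is
#' classified active; compounds left with only inconclusive readouts are
#' dropped.
#'
#' @param results Data frame of primary assay results with columns
#'   `compound_id`, `assay_id`, `activity_flag`, `flag_source`.
#' @return Data frame with one row per (compound, assay):
#'   `compound_id`, `assay_id`, `activity_flag` (active/inactive).
#' @export
reconcile_primary_flags <- function(results) {
  req <- c("compound_id", "assay_id", "activity_flag", "flag_source")
  if (!all(req %in% names(results))) {
    stop("missing column(s): ", paste(setdiff(req, names(results)), collapse = ", "))
  }
  .check_flags(results$activity_flag)
  if (nrow(results) == 0) {
    return(data.frame(compound_id = character(0), assay_id = character(0),
                      activity_flag = character(0), stringsAsFactors = FALSE))
  }
  key <- paste(results$compound_id, results$assay_id, sep = "\r")
  is_z <- !is.na(results$flag_source) & results$flag_source == "zscore"
  # order-independent aggregation per (compound, assay)
  flag <- tapply(seq_len(nrow(results)), key, function(i) {
    use <- if (any(is_z[i])) i[is_z[i]] else i
    fl <- results$activity_flag[use]
    fl <- fl[fl != "inconclusive"]
    if (!length(fl)) return(NA_character_)
    if (any(fl == "active")) "active" else "inactive"
  })
  keys <- names(flag)
  keep <- !is.na(flag)
  parts <- strsplit(keys[keep], "\r", fixed = TRUE)
  out <- data.frame(
    compound_id = vapply(parts, `[`, "", 1),
    assay_id = vapply(parts, `[`, "", 2),
    activity_flag = unname(flag[keep]),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out[order(out$compound_id, out$assay_id), , drop = FALSE]
}

#' Derive per-technology CIAT/NCIAT labels
#'
#' A compound active in at least one reconciled artefact-linked primary
#' assay of a technology is labeled CIAT when active in any artefact assay
#' of that technology, NCIAT when inactive in all of them, and excluded
#' when it has no conclusive artefact result.
#'
#' @param primary_flags Reconciled flags from [reconcile_primary_flags()]
#'   (artefact-linked primary assays of one technology).
#' @param artefact_results Raw artefact results of the same technology
#'   (`compound_id`, `activity_flag`).
#' @return Data frame `compound_id`, `label` ("CIAT"/"NCIAT"),
#'   `active_assays` (comma-separated primary assay ids where active).
#' @export
derive_technology_labels <- function(primary_flags, artefact_results) {
  .check_flags(artefact_results$activity_flag)
  act <- primary_flags[primary_flags$activity_flag == "active", , drop = FALSE]
  if (nrow(act) == 0) {
    return(data.frame(compound_id = character(0), label = character(0),
                      active_assays = character(0), stringsAsFactors = FALSE))
  }
  active_assays <- tapply(act$assay_id, act$compound_id,
                          function(a) paste(sort(unique(a)), collapse = ","))
  ids <- names(active_assays)
  art <- artefact_results[artefact_results$compound_id %in% ids &
                            artefact_results$activity_flag != "inconclusive", ,
                          drop = FALSE]
  art_active <- tapply(art$activity_flag == "active", art$compound_id, any)
  label <- ifelse(art_active[ids], "CIAT", "NCIAT")  # NA where no artefact data
  keep <- !is.na(label)
  out <- data.frame(compound_id = ids[keep], label = unname(label[keep]),
                    active_assays = unname(active_assays[keep]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$compound_id), , drop = FALSE]
}

#' Build a per-technology training dataset
#'
#' Joins curated labels with structures and 1024-bit ECFP4 fingerprints.
#' Structures that cannot be parsed are discarded. The result carries
#' class counts and CIAT prevalence, the composition line reported for
#' every curated training set.
#'
#' @param labels Output of [derive_technology_labels()].
#' @param compounds Data frame with `compound_id` and `smiles`.
#' @param technology Technology name recorded on the dataset.
#' @param fingerprints Optional precomputed fingerprint matrix (rownames =
#'   compound ids); computed on demand otherwise.
#' @return A `technology_dataset`: list with `technology`, `table`
#'   (compound_id, smiles, label, active_assays), `fingerprints`, `counts`.
#' @export
build_dataset <- function(labels, compounds, technology = "unknown",
                          fingerprints = NULL) {
  if (nrow(labels) == 0) stop("empty dataset: no labeled compounds")
  tab <- merge(labels, compounds[, c("compound_id", "smiles")],
               by = "compound_id", sort = TRUE)
  if (is.null(fingerprints)) {
    fingerprints <- fingerprint_matrix(tab$smiles, ids = tab$compound_id,
                                       on_parse_failure = "drop")
  }
  keep <- tab$compound_id %in% rownames(fingerprints)
  if (any(!keep)) {
    message(sum(!keep), " labeled compound(s) dropped (unparseable structure)")
  }
  tab <- tab[keep, , drop = FALSE]
  if (nrow(tab) == 0) stop("empty dataset: all structures unparseable")
  fp <- fingerprints[tab$compound_id, , drop = FALSE]
  counts <- c(CIAT = sum(tab$label == "CIAT"),
              NCIAT = sum(tab$label == "NCIAT"))
  structure(list(
    technology = technology,
    table = tab,
    fingerprints = fp,
    counts = counts,
    prevalence = unname(counts["CIAT"] / sum(counts))
  ), class = "technology_dataset")
}

#' @export
print.technology_dataset <- function(x, ...) {
  cat("Technology dataset:", x$technology, "\n")
  cat(sprintf("  %d compounds: %d CIAT (%.1f %%), %d NCIAT (%.1f %%)\n",
              sum(x$counts), x$counts["CIAT"], 100 * x$prevalence,
              x$counts["NCIAT"], 100 * (1 - x$prevalence)))
  invisible(x)
}

#' Curate a campaign into per-technology datasets
#'
#' Convenience wrapper running flag reconciliation, artefact labeling and
#' dataset assembly for each technology of a campaign. Only primary assays
#' with a linked artefact assay contribute datapoints.
#'
#' @param campaign A `synthetic_campaign` or an equivalent list with
#'   `results`, `assays`, `compounds`.
#' @param technologies Subset of technologies (default: all in the campaign).
#' @param fingerprints Optional precomputed fingerprint matrix.
#' @param exclude_assays Assay ids whose datapoints are ignored (used by
#'   leave-one-assay-out evaluation).
#' @return Named list of `technology_dataset` objects.
#' @export
curate_campaign <- function(campaign, technologies = NULL, fingerprints = NULL,
                            exclude_assays = character(0)) {
  assays <- campaign$assays
  results <- campaign$results[!(campaign$results$assay_id %in% exclude_assays), ,
                              drop = FALSE]
  if (is.null(technologies)) technologies <- unique(assays$technology)
  out <- list()
  for (tech in technologies) {
    linked <- assays$assay_id[assays$technology == tech &
                                assays$assay_kind == "primary" &
                                !is.na(assays$linked_artefact)]
    prim <- results[results$assay_id %in% linked, , drop = FALSE]
    art <- results[results$technology == tech &
                     results$assay_kind == "artefact", , drop = FALSE]
    rec <- reconcile_primary_flags(prim)
    lab <- derive_technology_labels(rec, art)
    out[[tech]] <- build_dataset(lab, campaign$compounds, technology = tech,
                                 fingerprints = fingerprints)
  }
  out
}

#' Ingest PubChem BioAssay counter-screen exports
#'
#' Reads one or more PubChem BioAssay CSV exports (artefact assays of one
#' technology) and curates CIAT/NCIAT labels: active outcomes map to CIAT,
#' inactive to NCIAT, inconclusive (and unspecified) outcomes are not
#' considered, and compounds whose label depends on the assay are
#' discarded.
#'
#' @param paths Character vector of CSV paths (one per AID).
#' @param technology Technology name for the resulting labels.
#' @param id_column Identifier column (default `PUBCHEM_CID`, falling back
#'   to `PUBCHEM_SID`).
#' @return Data frame `compound_id`, `label`, plus `smiles` when the export
#'   carries a structure column.
#' @export
ingest_pubchem <- function(paths, technology,
                           id_column = c("PUBCHEM_CID", "PUBCHEM_SID")) {
  rows <- lapply(paths, function(p) {
    tab <- utils::read.csv(p, stringsAsFactors = FALSE, check.names = FALSE)
    if (!"PUBCHEM_ACTIVITY_OUTCOME" %in% names(tab)) {
      stop("missing PUBCHEM_ACTIVITY_OUTCOME column in ", p)
    }
    idc <- intersect(id_column, names(tab))
    if (!length(idc)) {
      stop("no identifier column (", paste(id_column, collapse = "/"),
           ") in ", p)
    }
    smi <- intersect(c("PUBCHEM_EXT_DATASOURCE_SMILES", "SMILES"), names(tab))
    data.frame(
      compound_id = as.character(tab[[idc[1]]]),
      outcome = tolower(tab$PUBCHEM_ACTIVITY_OUTCOME),
      smiles = if (length(smi)) as.character(tab[[smi[1]]]) else NA_character_,
      stringsAsFactors = FALSE)
  })
  all <- do.call(rbind, rows)
  all <- all[all$outcome %in% c("active", "inactive"), , drop = FALSE]
  lab <- tapply(all$outcome, all$compound_id, function(o) {
    u <- unique(o)
    if (length(u) > 1) NA_character_ else if (u == "active") "CIAT" else "NCIAT"
  })
  keep <- !is.na(lab)
  out <- data.frame(compound_id = names(lab)[keep], label = unname(lab[keep]),
                    stringsAsFactors = FALSE)
  smi <- all$smiles[match(out$compound_id, all$compound_id)]
  if (!all(is.na(smi))) out$smiles <- smi
  attr(out, "technology") <- technology
  rownames(out) <- NULL
  out[order(out$compound_id), , drop = FALSE]
}
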