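# Leave-one-assay-out comparison protocol: Set A/Set B splits, the
# >5-CIAT assay filter, per-method metric rows, cross-validation and
# label-randomization controls, nearest-neighbor error analysis, and the
# BSF assay-subsampling experiment.

#' Split held-out compounds into Set A and Set B
#'
#' Set A are held-out compounds that also occur in at least one training
#' (non-held-out) primary assay of the technology — previously seen
#' chemical matter; Set B are compounds found only in the held-out assay,
#' i.e. novel structures from the model's point of view. The two sets
#' partition the held-out compounds. The LOAO protocol passes
#' active-membership here (assays where the compound was *found*, the
#' screening sense of occurrence), so Set A coincides with the compounds
#' the training table can contain.
#'
#' @param compound_ids Held-out compounds (typically its primary actives).
#' @param held_out_assay The held-out assay id.
#' @param membership Data frame `compound_id`, `assay_id` defining assay
#'   occurrence per compound.
#' @return List with `set_a`, `set_b` (character vectors).
#' @export
split_sets <- function(compound_ids, held_out_assay, membership) {
  other <- membership[membership$assay_id != held_out_assay, , drop = FALSE]
  seen <- compound_ids %in% other$compound_id
  list(set_a = compound_ids[seen], set_b = compound_ids[!seen])
}

#' Assay inclusion filter on CIAT count
#'
#' Performance is only meaningful for assays with more than `minimum`
#' (strictly) CIATs among their actives.
#'
#' @param labels Character vector of labels for the assay's compounds.
#' @param minimum Strict lower bound (default 5).
#' @return TRUE to include the assay.
#' @export
ciat_count_filter <- function(labels, minimum = 5) {
  sum(labels == "CIAT") > minimum
}

.metric_row <- function(technology, holdout, method, subset, m,
                        excluded = NA_character_) {
  data.frame(technology = technology, holdout_assay = holdout,
             method = method, subset = subset,
             n = m$n, TP = m$tp, FP = m$fp, TN = m$tn, FN = m$fn,
             mcc = m$mcc, recall = m$recall, precision = m$precision,
             auc = m$auc, excluded_reason = excluded,
             stringsAsFactors = FALSE)
}

.empty_metrics <- list(n = 0L, tp = NA_integer_, fp = NA_integer_,
                       tn = NA_integer_, fn = NA_integer_, mcc = NA_real_,
                       recall = NA_real_, precision = NA_real_, auc = NA_real_)

#' Leave-one-assay-out evaluation of the three triage methods
#'
#' For every artefact-linked primary assay of a technology: rebuild the
#' training set from the remaining assays, score the held-out actives with
#' the requested methods (random forest on fingerprints, Binomial Survivor
#' Function on screening histories, PAINS any-match), split them into Set
#' A/Set B, and report MCC, recall, precision and ROC AUC per subset.
#' Comparison rows are restricted to the compounds predictable by every
#' requested method, so all methods are measured on the identical set.
#' Assays failing the >5-CIAT filter or with an empty Set B are reported
#' flagged, never silently dropped.
#'
#' @param campaign A `synthetic_campaign` (or compatible list).
#' @param technology Technology to evaluate.
#' @param methods Subset of `c("rfc", "bsf", "pains")`.
#' @param hyperparameters Forest hyperparameters (`NULL` for defaults, or
#'   `"tune"` to run the random search per holdout).
#' @param min_ciat Strict CIAT-count filter (default 5).
#' @param bsf_cutoff pBSF classification cutoff (default 2).
#' @param pains_catalog Optional custom catalog for [pains_predict()].
#' @param fingerprints Optional precomputed fingerprint matrix.
#' @param seed Seed for model fits.
#' @return An `evaluation_report` data frame (one row per assay, method,
#'   subset), with the fingerprint matrix in attribute `"fingerprints"`.
#' @export
loao_run <- function(campaign, technology,
                     methods = c("rfc", "bsf", "pains"),
                     hyperparameters = NULL, min_ciat = 5, bsf_cutoff = 2,
                     pains_catalog = NULL, fingerprints = NULL, seed = 1L) {
  methods <- match.arg(methods, several.ok = TRUE)
  assays <- campaign$assays
  linked <- assays$assay_id[assays$technology == technology &
                              assays$assay_kind == "primary" &
                              !is.na(assays$linked_artefact)]
  if (length(linked) < 2) stop("need at least 2 artefact-linked primary assays")
  # BSF scope: the technology's own screening record (linked + historic
  # screens of that technology), matching the per-technology protocol.
  primary_ids <- assays$assay_id[assays$assay_kind == "primary" &
                                   assays$technology == technology]
  primary_res <- campaign$results[campaign$results$assay_id %in% primary_ids, ,
                                  drop = FALSE]
  tech_prim <- campaign$results[campaign$results$assay_id %in% linked, ,
                                drop = FALSE]
  art <- campaign$results[campaign$results$technology == technology &
                            campaign$results$assay_kind == "artefact", ,
                          drop = FALSE]
  rec_all <- reconcile_primary_flags(tech_prim)
  labels_all <- derive_technology_labels(rec_all, art)
  label_of <- setNames(labels_all$label, labels_all$compound_id)

  if (is.null(fingerprints)) {
    fingerprints <- fingerprint_matrix(campaign$compounds$smiles,
                                       ids = campaign$compounds$compound_id,
                                       on_parse_failure = "drop")
  }

  pains_hit <- NULL
  if ("pains" %in% methods) {
    labeled <- campaign$compounds[campaign$compounds$compound_id %in%
                                    labels_all$compound_id, , drop = FALSE]
    pains_hit <- pains_predict(labeled$smiles, catalog = pains_catalog,
                               ids = labeled$compound_id)
  }

  act_all <- rec_all[rec_all$activity_flag == "active", , drop = FALSE]
  membership <- unique(act_all[, c("compound_id", "assay_id")])
  rows <- list()
  for (holdout in linked) {
    rec_hold <- rec_all[rec_all$assay_id == holdout, , drop = FALSE]
    test_ids <- rec_hold$compound_id[rec_hold$activity_flag == "active"]
    test_ids <- test_ids[test_ids %in% names(label_of) &
                           test_ids %in% rownames(fingerprints)]
    test_lab <- label_of[test_ids] == "CIAT"
    excluded <- NA_character_
    if (!ciat_count_filter(label_of[test_ids], min_ciat)) {
      excluded <- sprintf("<=%d CIATs in held-out assay", min_ciat)
    }
    sets <- split_sets(test_ids, holdout, membership)
    if (length(sets$set_b) == 0 && is.na(excluded)) excluded <- "no Set B compounds"

    if (!is.na(excluded)) {
      rows[[holdout]] <- .metric_row(technology, holdout, NA_character_,
                                     "all", .empty_metrics, excluded)
      next
    }

    # training table: labeled compounds active in >=1 remaining assay
    rec_rest <- rec_all[rec_all$assay_id != holdout, , drop = FALSE]
    train_lab <- derive_technology_labels(rec_rest, art)
    train_lab <- train_lab[train_lab$compound_id %in% rownames(fingerprints), ,
                           drop = FALSE]

    scores <- list(); preds <- list(); predictable <- list()
    if ("rfc" %in% methods) {
      ds <- build_dataset(train_lab, campaign$compounds, technology,
                          fingerprints = fingerprints)
      hp <- hyperparameters
      if (identical(hp, "tune")) {
        hp <- tune_hyperparameters(ds, model_config(seed = seed))
      }
      model <- train_rfc(ds, hp, seed = seed)
      p <- predict(model, fingerprints[test_ids, , drop = FALSE])
      scores$rfc <- p; preds$rfc <- p >= 0.5
      predictable$rfc <- rep(TRUE, length(test_ids))
    }
    if ("bsf" %in% methods) {
      bsf <- bsf_loao(primary_res, holdout, compound_ids = test_ids,
                      cutoff = bsf_cutoff)
      scores$bsf <- setNames(bsf$pbsf, bsf$compound_id)
      preds$bsf <- setNames(!is.na(bsf$class) & bsf$class == "CIAT",
                            bsf$compound_id)
      predictable$bsf <- bsf$predictable
    }
    if ("pains" %in% methods) {
      ph <- pains_hit[test_ids]
      scores$pains <- setNames(as.numeric(ph), test_ids); preds$pains <- ph
      predictable$pains <- rep(TRUE, length(test_ids))
    }
    common <- Reduce(`&`, predictable)
    for (subset in c("all", "set_a", "set_b")) {
      in_sub <- switch(subset, all = rep(TRUE, length(test_ids)),
                       set_a = test_ids %in% sets$set_a,
                       set_b = test_ids %in% sets$set_b)
      use <- in_sub & common
      for (m in methods) {
        met <- if (sum(use) == 0) {
          .empty_metrics
        } else {
          compute_metrics(test_lab[use], scores[[m]][test_ids][use],
                          preds[[m]][test_ids][use])
        }
        rows[[paste(holdout, m, subset)]] <-
          .metric_row(technology, holdout, m, subset, met)
      }
    }
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  class(report) <- c("evaluation_report", "data.frame")
  attr(report, "fingerprints") <- fingerprints
  report
}

#' Stratified k-fold cross-validation of the forest classifier
#'
#' @param dataset A `technology_dataset`.
#' @param seed Fold and fit seed.
#' @param folds Number of folds (default 10).
#' @param hyperparameters Forest hyperparameters (defaults of
#'   [train_rfc()] when `NULL`).
#' @return List with `mean_auc`, `sd_auc`, `mean_mcc`, and the per-fold
#'   table `folds`.
#' @export
crossval_10fold <- function(dataset, seed = 1L, folds = 10L,
                            hyperparameters = NULL) {
  xy <- .dataset_xy(dataset)
  set.seed(as.integer(seed))
  fold <- .stratified_folds(xy$y, folds)
  if (is.null(hyperparameters)) {
    hyperparameters <- list(num_trees = 300L, max_depth = 0L,
                            min_node_size = 1L, mtry = "sqrt")
  }
  res <- lapply(seq_len(folds), function(f) {
    tr <- fold != f
    fit <- .fit_forest(xy$x[tr, , drop = FALSE], xy$y[tr], hyperparameters,
                       seed = as.integer(seed) + f)
    prob <- .forest_prob(fit, xy$x[!tr, , drop = FALSE])
    m <- compute_metrics(xy$y[!tr] == "CIAT", prob, prob >= 0.5)
    data.frame(fold = f, auc = m$auc, mcc = m$mcc, recall = m$recall,
               precision = m$precision)
  })
  tab <- do.call(rbind, res)
  list(mean_auc = mean(tab$auc), sd_auc = stats::sd(tab$auc),
       mean_mcc = mean(tab$mcc), folds = tab)
}

#' Nearest-neighbor similarity analysis of classifier errors
#'
#' For every true-positive and false-negative CIAT of a prediction run,
#' computes the mean Tanimoto similarity to its k nearest neighbors among
#' the training CIATs and, separately, among the training NCIATs. The raw
#' per-compound values are suitable for density plots; ties at equal
#' similarity are broken by compound id for determinism.
#'
#' @param test_fp Fingerprints of the evaluated CIAT compounds (rownames =
#'   ids).
#' @param predicted Logical: was each compound predicted CIAT?
#' @param train_fp Training fingerprints.
#' @param train_labels Training labels ("CIAT"/"NCIAT"), aligned with
#'   `train_fp` rows.
#' @param k Neighbors per class (default 5); reduced with a warning when a
#'   class is smaller.
#' @return Data frame `compound_id`, `group` ("TP"/"FN"), `mean_tc_ciat`,
#'   `mean_tc_nciat`.
#' @export
nn_analysis <- function(test_fp, predicted, train_fp, train_labels, k = 5L) {
  stopifnot(nrow(test_fp) == length(predicted),
            nrow(train_fp) == length(train_labels))
  out <- NULL
  for (cls in c("CIAT", "NCIAT")) {
    sub <- train_fp[train_labels == cls, , drop = FALSE]
    kk <- k
    if (nrow(sub) < k) {
      warning("training class ", cls, " smaller than k=", k,
              "; using k=", nrow(sub))
      kk <- nrow(sub)
    }
    if (kk == 0) stop("training class ", cls, " is empty")
    sim <- tanimoto_matrix(test_fp, sub)
    sub_ord <- order(colnames(sim) %||% seq_len(ncol(sim)))
    vals <- apply(sim, 1, function(s) {
      ord <- order(-s, sub_ord)
      mean(s[ord[seq_len(kk)]])
    })
    col <- if (cls == "CIAT") "mean_tc_ciat" else "mean_tc_nciat"
    if (is.null(out)) {
      out <- data.frame(compound_id = rownames(test_fp),
                        group = ifelse(predicted, "TP", "FN"),
                        stringsAsFactors = FALSE)
    }
    out[[col]] <- unname(vals)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' BSF assay-subsampling experiment
#'
#' Measures how the Binomial Survivor Function's leave-one-assay-out
#' performance grows with the size of the screening record: the base panel
#' is the artefact-linked assays, and increasing fractions of the
#' remaining primary screens are added (seeded draws, several seeds). The
#' forest classifier's LOAO performance on the same compounds is the
#' constant baseline; the mean number of screens per scored compound is
#' recorded so statements like "the BSF needs compounds tested ~10 times"
#' can be read off.
#'
#' @param campaign A `synthetic_campaign`.
#' @param technology Technology to evaluate.
#' @param fractions Fractions of the unlinked assays to add (default
#'   0.2...1.0).
#' @param seeds Seeds for the assay draws (>= 2 recommended).
#' @param rfc_report Optional precomputed [loao_run()] report providing the
#'   RFC baseline (computed here when `NULL`).
#' @param bsf_cutoff pBSF cutoff.
#' @param fingerprints Optional precomputed fingerprints.
#' @return A list: `curve` (fraction x seed table of BSF metrics),
#'   `rfc_auc` baseline, and `crossover` (smallest fraction whose mean BSF
#'   AUC reaches the RFC baseline, or `"none"`).
#' @export
bsf_scaling_experiment <- function(campaign, technology,
                                   fractions = c(0.2, 0.4, 0.6, 0.8, 1.0),
                                   seeds = 1:10, rfc_report = NULL,
                                   bsf_cutoff = 2, fingerprints = NULL) {
  assays <- campaign$assays
  linked <- assays$assay_id[assays$technology == technology &
                              assays$assay_kind == "primary" &
                              !is.na(assays$linked_artefact)]
  primary_ids <- assays$assay_id[assays$assay_kind == "primary" &
                                   assays$technology == technology]
  primary_res <- campaign$results[campaign$results$assay_id %in% primary_ids, ,
                                  drop = FALSE]
  if (is.null(rfc_report)) {
    rfc_report <- loao_run(campaign, technology, methods = "rfc",
                           fingerprints = fingerprints)
  }
  ok <- rfc_report$method == "rfc" & rfc_report$subset == "all" &
    is.na(rfc_report$excluded_reason)
  rfc_auc <- mean(rfc_report$auc[ok], na.rm = TRUE)

  tech_prim <- campaign$results[campaign$results$assay_id %in% linked, ,
                                drop = FALSE]
  art <- campaign$results[campaign$results$technology == technology &
                            campaign$results$assay_kind == "artefact", ,
                          drop = FALSE]
  rec_all <- reconcile_primary_flags(tech_prim)
  labels_all <- derive_technology_labels(rec_all, art)
  label_of <- setNames(labels_all$label, labels_all$compound_id)

  rows <- list()
  for (seed in seeds) {
    for (fr in fractions) {
      panel_res <- subsample_assay_fraction(primary_res, assays, fr,
                                            seed = seed)
      labs <- logical(0); scores <- numeric(0); preds <- logical(0)
      ntests <- integer(0)
      for (holdout in linked) {
        rec_hold <- rec_all[rec_all$assay_id == holdout, , drop = FALSE]
        test_ids <- rec_hold$compound_id[rec_hold$activity_flag == "active"]
        test_ids <- test_ids[test_ids %in% names(label_of)]
        if (!length(test_ids)) next
        bsf <- bsf_loao(panel_res, holdout, compound_ids = test_ids,
                        cutoff = bsf_cutoff)
        use <- bsf$predictable
        labs <- c(labs, label_of[test_ids][use] == "CIAT")
        scores <- c(scores, bsf$pbsf[use])
        preds <- c(preds, bsf$class[use] == "CIAT")
        ntests <- c(ntests, bsf$N[use])
      }
      m <- compute_metrics(labs, scores, preds)
      rows[[paste(seed, fr)]] <- data.frame(
        fraction = fr, seed = seed, auc = m$auc, mcc = m$mcc,
        recall = m$recall, precision = m$precision,
        mean_tests = mean(ntests), n = m$n)
    }
  }
  curve <- do.call(rbind, rows)
  rownames(curve) <- NULL
  mean_auc <- tapply(curve$auc, curve$fraction, mean)
  over <- as.numeric(names(mean_auc))[mean_auc >= rfc_auc]
  list(curve = curve, rfc_auc = rfc_auc,
       crossover = if (length(over)) min(over) else "none")
}

#' Consolidate evaluation reports
#'
#' Binds per-technology reports and summarizes each (technology, method,
#' subset) by its unweighted per-assay mean, the convention used for all
#' headline comparisons.
#'
#' @param ... `evaluation_report` objects (or a single list of them).
#' @return List with `report` (all rows) and `summary` (per-assay means).
#' @export
compare_report <- function(...) {
  reports <- list(...)
  if (length(reports) == 1 && !inherits(reports[[1]], "data.frame")) {
    reports <- reports[[1]]
  }
  all <- do.call(rbind, lapply(reports, as.data.frame))
  ok <- all[!is.na(all$method), , drop = FALSE]
  key <- interaction(ok$technology, ok$method, ok$subset, drop = TRUE)
  summary <- do.call(rbind, lapply(split(ok, key), function(g) {
    data.frame(technology = g$technology[1], method = g$method[1],
               subset = g$subset[1], n_assays = nrow(g),
               mcc = mean(g$mcc, na.rm = TRUE),
               recall = mean(g$recall, na.rm = TRUE),
               precision = mean(g$precision, na.rm = TRUE),
               auc = mean(g$auc, na.rm = TRUE), stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  list(report = all, summary = summary)
}

#' Plot the three-method comparison
#'
#' One panel per subset, per-assay metric distributions by method.
#'
#' @param report An `evaluation_report` (or the `report` element of
#'   [compare_report()]).
#' @param metric Which metric column to plot.
#' @return A ggplot object.
#' @export
plot_method_comparison <- function(report, metric = "auc") {
  df <- as.data.frame(report)
  df <- df[!is.na(df$method) & df$subset != "all", , drop = FALSE]
  df$.metric <- df[[metric]]
  ggplot2::ggplot(df, ggplot2::aes(x = method, y = .metric, fill = method)) +
    ggplot2::geom_boxplot(outlier.size = 0.8) +
    ggplot2::facet_grid(stats::reformulate("subset", "technology")) +
    ggplot2::labs(x = NULL, y = toupper(metric)) +
    ggplot2::theme_bw() +
    ggplot2::theme(legend.position = "none")
}
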