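# Random-forest interference classifier over 1024-bit ECFP4 fingerprints.
# Hyperparameters come from a seeded random search scored by mean MCC over
# a 3-fold cross-validation; class assignment uses the 0.5 probability
# threshold.

#' Model configuration for the interference classifier
#'
#' @param search_space Named list of hyperparameter ranges for the random
#'   search: `num_trees` (range), `max_depth` (candidates; 0 = unlimited),
#'   `min_node_size` (range), `mtry` (`"sqrt"`/`"log2"` of the feature
#'   count).
#' @param n_search_iters Random-search draws.
#' @param cv_folds Folds for the tuning cross-validation (3, per protocol).
#' @param seed Integer seed making search and fits reproducible.
#' @return A `model_config` list.
#' @export
model_config <- function(search_space = list(num_trees = c(100L, 1000L),
                                             max_depth = c(0L, 10L, 20L),
                                             min_node_size = c(1L, 10L),
                                             mtry = c("sqrt", "log2")),
                         n_search_iters = 20L,
                         cv_folds = 3L,
                         seed = 1L) {
  stopifnot(n_search_iters >= 1, cv_folds >= 2)
  structure(list(search_space = search_space,
                 n_search_iters = as.integer(n_search_iters),
                 cv_folds = as.integer(cv_folds),
                 selection_metric = "MCC",
                 seed = as.integer(seed)),
            class = "model_config")
}

.resolve_mtry <- function(mtry, p) {
  switch(mtry, sqrt = max(1L, floor(sqrt(p))), log2 = max(1L, floor(log2(p))),
         stop("unknown mtry rule: ", mtry))
}

.sample_hyperparameters <- function(space) {
  list(
    num_trees = sample(seq(space$num_trees[1], space$num_trees[2], by = 50L), 1),
    max_depth = sample(space$max_depth, 1),
    min_node_size = sample(seq(space$min_node_size[1], space$min_node_size[2]), 1),
    mtry = sample(space$mtry, 1)
  )
}

.dataset_xy <- function(dataset) {
  x <- dataset$fingerprints * 1
  colnames(x) <- sprintf("b%04d", seq_len(ncol(x)))
  y <- factor(dataset$table$label, levels = c("NCIAT", "CIAT"))
  list(x = x, y = y)
}

.fit_forest <- function(x, y, hp, seed) {
  ranger::ranger(
    x = x, y = y, probability = TRUE,
    num.trees = hp$num_trees,
    mtry = .resolve_mtry(hp$mtry, ncol(x)),
    min.node.size = hp$min_node_size,
    max.depth = hp$max_depth,
    num.threads = 1, seed = seed, verbose = FALSE)
}

.forest_prob <- function(fit, x) {
  p <- stats::predict(fit, data = x, num.threads = 1)$predictions
  p[, "CIAT"]
}

.stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    if (length(idx) < k) {
      stop("class ", cl, " has fewer members (", length(idx),
           ") than folds (", k, ")")
    }
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

#' Tune forest hyperparameters by seeded random search
#'
#' Draws `n_search_iters` settings from the search space and scores each
#' by the mean Matthews correlation coefficient over a stratified
#' `cv_folds`-fold cross-validation of the training table.
#'
#' @param dataset A `technology_dataset` with both classes present.
#' @param config A [model_config()].
#' @return The winning hyperparameter list; the full search table is in
#'   the `"search"` attribute.
#' @export
tune_hyperparameters <- function(dataset, config = model_config()) {
  xy <- .dataset_xy(dataset)
  if (nlevels(droplevels(xy$y)) < 2) {
    stop("dataset has a single class; cannot tune a classifier")
  }
  set.seed(config$seed)
  fold <- .stratified_folds(xy$y, config$cv_folds)
  trials <- vector("list", config$n_search_iters)
  score <- numeric(config$n_search_iters)
  for (i in seq_len(config$n_search_iters)) {
    hp <- .sample_hyperparameters(config$search_space)
    mccs <- vapply(seq_len(config$cv_folds), function(f) {
      tr <- fold != f
      fit <- .fit_forest(xy$x[tr, , drop = FALSE], xy$y[tr], hp,
                         seed = config$seed + i)
      prob <- .forest_prob(fit, xy$x[!tr, , drop = FALSE])
      m <- compute_metrics(xy$y[!tr] == "CIAT", prob, prob >= 0.5)
      m$mcc
    }, 0)
    trials[[i]] <- hp
    score[i] <- mean(mccs)
  }
  best <- trials[[which.max(score)]]
  attr(best, "search") <- data.frame(
    do.call(rbind, lapply(trials, as.data.frame)), mean_mcc = score)
  best
}

#' Train the interference classifier
#'
#' @param dataset A `technology_dataset`.
#' @param hyperparameters A hyperparameter list (e.g. from
#'   [tune_hyperparameters()]); sensible defaults otherwise.
#' @param seed Fit seed.
#' @return A `trained_rfc` carrying the fitted forest and its training
#'   provenance (technology, assay ids, hyperparameters, seed).
#' @export
train_rfc <- function(dataset, hyperparameters = NULL, seed = 1L) {
  xy <- .dataset_xy(dataset)
  if (nlevels(droplevels(xy$y)) < 2) {
    stop("dataset has a single class; cannot train a classifier")
  }
  if (is.null(hyperparameters)) {
    hyperparameters <- list(num_trees = 300L, max_depth = 0L,
                            min_node_size = 1L, mtry = "sqrt")
  }
  fit <- .fit_forest(xy$x, xy$y, hyperparameters, seed = seed)
  structure(list(
    forest = fit,
    hyperparameters = hyperparameters,
    technology = dataset$technology,
    training_assays = sort(unique(unlist(
      strsplit(dataset$table$active_assays, ",", fixed = TRUE)))),
    training_ids = dataset$table$compound_id,
    n_features = ncol(xy$x),
    seed = as.integer(seed)
  ), class = "trained_rfc")
}

#' Predict interference probabilities
#'
#' @param object A `trained_rfc`.
#' @param fingerprints Fingerprint matrix with the training bit length.
#' @param ... Unused.
#' @return Named numeric vector: probability of CIAT per compound; the
#'   predicted class is CIAT at probability >= 0.5.
#' @export
predict.trained_rfc <- function(object, fingerprints, ...) {
  if (is.null(dim(fingerprints))) fingerprints <- matrix(fingerprints, nrow = 1)
  if (ncol(fingerprints) != object$n_features) {
    stop("fingerprint length ", ncol(fingerprints),
         " does not match training length ", object$n_features)
  }
  x <- fingerprints * 1
  colnames(x) <- sprintf("b%04d", seq_len(ncol(x)))
  p <- .forest_prob(object$forest, x)
  names(p) <- rownames(fingerprints)
  p
}

#' @export
print.trained_rfc <- function(x, ...) {
  cat("Random-forest interference classifier (", x$technology, ")\n", sep = "")
  cat("  training compounds:", length(x$training_ids), "\n")
  cat("  hyperparameters: trees=", x$hyperparameters$num_trees,
      " depth=", x$hyperparameters$max_depth,
      " min.node=", x$hyperparameters$min_node_size,
      " mtry=", x$hyperparameters$mtry, "\n", sep = "")
  invisible(x)
}

#' Shuffle class labels (overfitting control)
#'
#' Permutes the CIAT/NCIAT labels of a dataset with a seeded draw,
#' preserving the label multiset; repeating cross-validation on the
#' shuffled dataset should drive the ROC AUC to chance.
#'
#' @param dataset A `technology_dataset`.
#' @param seed Permutation seed.
#' @return The dataset with permuted labels.
#' @export
randomize_labels <- function(dataset, seed = 1L) {
  set.seed(as.integer(seed))
  perm <- sample.int(nrow(dataset$table))
  dataset$table$label <- dataset$table$label[perm]
  dataset$counts <- c(CIAT = sum(dataset$table$label == "CIAT"),
                      NCIAT = sum(dataset$table$label == "NCIAT"))
  dataset
}
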