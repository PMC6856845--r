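# Binomial Survivor Function promiscuity score.
#
# pBSF = -log10 P(X >= A | N, h): the chance that a compound tested in N
# screens, under hit rate h, would show at least its observed A activities
# by randomness alone. Scores >= 2 (a 1 % chance) flag promiscuous,
# technology-interfering behavior.

#' Pooled hit rate over a set of primary screens
#'
#' @param results Data frame of primary results (`compound_id`, `assay_id`,
#'   `activity_flag`); replicates within an assay are collapsed to one
#'   tested/active pair before counting.
#' @return Fraction of (compound, assay) pairs that are active.
#' @export
pooled_hit_rate <- function(results) {
  h <- .screening_counts(results)
  tot <- sum(h$N)
  if (tot == 0) stop("cannot compute a hit rate from zero results")
  sum(h$A) / tot
}

# per-compound (N tested, A active) over distinct assays
.screening_counts <- function(results) {
  if (nrow(results) == 0) {
    return(data.frame(compound_id = character(0), N = integer(0),
                      A = integer(0), stringsAsFactors = FALSE))
  }
  key <- paste(results$compound_id, results$assay_id, sep = "\r")
  active <- tapply(results$activity_flag == "active", key, any)
  cid <- vapply(strsplit(names(active), "\r", fixed = TRUE), `[`, "", 1)
  N <- tapply(rep(1L, length(cid)), cid, sum)
  A <- tapply(as.integer(active), cid, sum)
  data.frame(compound_id = names(N), N = as.integer(N),
             A = as.integer(A[names(N)]), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Per-compound screening history
#'
#' Counts, for every compound, the number of distinct primary screens it
#' was tested in (N) and found active in (A), optionally excluding assays
#' (the leave-one-assay-out holdout).
#'
#' @param results Primary assay results.
#' @param exclude_assays Assay ids to leave out of the history.
#' @return Data frame `compound_id`, `N`, `A`.
#' @export
screening_history <- function(results, exclude_assays = character(0)) {
  .screening_counts(results[!(results$assay_id %in% exclude_assays), ,
                            drop = FALSE])
}

#' Binomial Survivor Function score
#'
#' `pbsf(A, N, h)` is the negative log of the binomial upper-tail
#' probability `P(X >= A | N, h)`, computed in log space so small h and
#' large N never underflow. With `scale = "log10"` (the default) a score
#' of 2 corresponds to a 1 % chance that the observed activity is random;
#' `scale = "ten_log10"` gives the literal ten-fold variant.
#'
#' @param A Number of screens active (vectorized).
#' @param N Number of screens tested.
#' @param h Hit rate in (0, 1); h in {0, 1} is accepted only where the
#'   score is well defined (A = 0).
#' @param scale `"log10"` or `"ten_log10"`.
#' @return Non-negative scores; 0 whenever A = 0.
#' @export
pbsf <- function(A, N, h, scale = c("log10", "ten_log10")) {
  scale <- match.arg(scale)
  k <- max(length(A), length(N), length(h))
  A <- rep_len(A, k); N <- rep_len(N, k); h <- rep_len(h, k)
  if (any(A < 0 | N < 0 | A > N)) stop("need 0 <= A <= N")
  if (any(h < 0 | h > 1)) stop("hit rate must lie in [0, 1]")
  if (any(A > 0 & (h == 0 | h == 1))) {
    stop("hit rate must lie strictly in (0, 1) when A > 0")
  }
  out <- numeric(k)
  pos <- A > 0
  if (any(pos)) {
    # upper tail P(X >= A) = P(X > A - 1), exact in log space
    logtail <- stats::pbinom(A[pos] - 1, N[pos], h[pos],
                             lower.tail = FALSE, log.p = TRUE)
    out[pos] <- -logtail / log(10)
  }
  if (scale == "ten_log10") out <- 10 * out
  out
}

#' Classify a compound from its BSF score
#'
#' @param score pBSF scores.
#' @param cutoff Classification cutoff (default 2, i.e. a 1 % chance).
#' @return `"CIAT"` where `score >= cutoff`, else `"NCIAT"`.
#' @export
classify_bsf <- function(score, cutoff = 2) {
  ifelse(score >= cutoff, "CIAT", "NCIAT")
}

#' Leave-one-assay-out BSF prediction
#'
#' Scores every compound of a held-out assay from its screening history in
#' all remaining primary assays, with the hit rate pooled over those same
#' assays. Compounds never tested outside the held-out assay have no
#' history and are marked unpredictable.
#'
#' @param results Primary assay results (all technologies; the BSF uses
#'   the full screening record, not just one technology's assays).
#' @param held_out_assay Assay id to predict.
#' @param compound_ids Compounds to score (default: all compounds with a
#'   result in the held-out assay).
#' @param cutoff Classification cutoff.
#' @param scale Score scale, see [pbsf()].
#' @return Data frame `compound_id`, `N`, `A`, `pbsf`, `class`,
#'   `predictable`.
#' @export
bsf_loao <- function(results, held_out_assay, compound_ids = NULL,
                     cutoff = 2, scale = "log10") {
  if (is.null(compound_ids)) {
    compound_ids <- unique(results$compound_id[results$assay_id == held_out_assay])
  }
  rest <- results[results$assay_id != held_out_assay, , drop = FALSE]
  hist <- screening_history(rest)
  h <- pooled_hit_rate(rest)
  idx <- match(compound_ids, hist$compound_id)
  N <- ifelse(is.na(idx), 0L, hist$N[idx])
  A <- ifelse(is.na(idx), 0L, hist$A[idx])
  score <- pbsf(A, N, h, scale = scale)
  out <- data.frame(
    compound_id = compound_ids, N = N, A = A, pbsf = score,
    class = classify_bsf(score, cutoff),
    predictable = N > 0, stringsAsFactors = FALSE)
  out$class[!out$predictable] <- NA_character_
  attr(out, "hit_rate") <- h
  out
}

#' Subsample the assay panel for the BSF scaling experiment
#'
#' Keeps the artefact-linked primary assays as the base panel and adds a
#' seeded random fraction of the remaining (unlinked) primary assays;
#' `round()` determines the count, so fraction 0.2 of 10 extra assays adds
#' 2.
#'
#' @param results Primary assay results.
#' @param assays Assay descriptor table (`assay_id`, `assay_kind`,
#'   `linked_artefact`).
#' @param fraction Fraction of the unlinked assays to add, in (0, 1\].
#' @param seed Integer seed for the assay draw.
#' @return The filtered results (attribute `"assays_used"` lists the panel).
#' @export
subsample_assay_fraction <- function(results, assays, fraction, seed = 1L) {
  if (length(fraction) != 1 || is.na(fraction) || fraction <= 0 || fraction > 1) {
    stop("fraction must lie in (0, 1]")
  }
  present <- unique(results$assay_id)
  base <- intersect(assays$assay_id[assays$assay_kind == "primary" &
                                      !is.na(assays$linked_artefact)], present)
  extra <- intersect(assays$assay_id[assays$assay_kind == "primary" &
                                       is.na(assays$linked_artefact)], present)
  n_add <- round(fraction * length(extra))
  set.seed(as.integer(seed))
  add <- if (n_add > 0) sample(extra, n_add) else character(0)
  panel <- c(base, sort(add))
  out <- results[results$assay_id %in% panel, , drop = FALSE]
  attr(out, "assays_used") <- panel
  out
}
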