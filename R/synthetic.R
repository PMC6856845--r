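# Synthetic HTS campaigns with planted interference chemotypes.
#
# Structures are built by combinatorial enumeration of hand-written
# scaffold templates and substituent fragments, which guarantees
# parseability and exact control over which compounds carry a
# technology's interference motif.

.SCAFFOLD_TEMPLATES <- c(
  "CC(%s)Nc1ccc(%s)cc1",
  "O=C(%s)Nc1cccc(%s)c1",
  "CN(C(=O)%s)c1ccc(%s)cc1",
  "CC(C)(%s)c1ccc(OC%s)cc1",
  "O=S(=O)(%s)Nc1ccc(%s)cc1",
  "C(%s)C(=O)N1CCN(CC1)%s",
  "CC(NC(=O)%s)c1cccc(C%s)c1",
  "O=C(N(C)%s)c1ccc(N%s)cc1",
  "CC(O)(C%s)c1cccc(%s)c1",
  "C(%s)Oc1ccc(CN%s)cc1",
  "CC(C%s)NC(=O)c1ccc(%s)cc1",
  "N(C%s)c1ncccc1C(=O)%s"
)

.SUBSTITUENTS <- c(
  "C", "CC", "CCC", "CCCC", "C(C)C", "C(C)(C)C", "CCO", "CCN", "CCl",
  "CF", "C(F)(F)F", "CO", "COC", "CCOC", "CN(C)C", "CCNC", "CC#N", "C#N",
  "C(=O)C", "C(=O)OC", "C(=O)NC", "CS(C)(=O)=O", "CSC",
  "c2ccccc2", "c2ccc(C)cc2", "c2ccc(F)cc2", "c2ccc(Cl)cc2",
  "c2ccc(OC)cc2", "c2ccc(C#N)cc2", "c2ccncc2", "c2cccnc2", "c2ccco2",
  "c2cccs2", "c2cnccn2", "Cc2ccccc2", "CCc2ccccc2", "COc2ccccc2",
  "Cc2ccco2", "CN2CCCC2",
  "C2CC2", "C2CCC2", "C2CCCC2", "C2CCCCC2", "C2CCOCC2", "C2CCNCC2",
  "N2CCCC2", "N2CCCCC2", "N2CCOCC2"
)

#' Default interference-motif table
#'
#' Two planted chemotypes per detection technology: one that overlaps the
#' published PAINS alerts (quinones for AlphaScreen, rhodanines for FRET,
#' catechols for TR-FRET — all documented interference chemotypes for
#' luminescence/fluorescence readouts) and one deliberately outside the
#' PAINS chemical space, so a structure-based model has signal that
#' substructure alerts alone cannot capture.
#'
#' @return Data frame with columns `technology`, `name`, `fragment`
#'   (attachable SMILES used during library enumeration) and `smarts`
#'   (the pattern designating the motif).
#' @export
default_interference_motifs <- function() {
  data.frame(
    technology = c("AlphaScreen", "AlphaScreen", "FRET", "FRET",
                   "TR-FRET", "TR-FRET"),
    name = c("quinone", "sulfonyl_piperidine",
             "rhodanine", "quinoxaline",
             "catechol", "benzothiazole"),
    fragment = c("C2=CC(=O)C=CC2=O", "C2CCN(CC2)S(C)(=O)=O",
                 "N2C(=O)CSC2=S", "c2ccc3nccnc3c2",
                 "c2ccc(O)c(O)c2", "c2nc3ccccc3s2"),
    smarts = c("O=C1C=CC(=O)C=C1", "O=S(=O)(C)N1CCCCC1",
               "O=C1CSC(=S)N1", "c1ccc2nccnc2c1",
               "Oc1ccccc1O", "c1nc2ccccc2s1"),
    stringsAsFactors = FALSE
  )
}

# Deterministic per-stage seeds: one user seed fans out into named
# substreams so library, truth, assignment and noise draws are
# independently reproducible.
.substream_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483629)
}

#' Configuration for the synthetic campaign generator
#'
#' The defaults define the study conditions the package's evaluation
#' protocol is exercised under: a three-technology screening deck in which
#' a fixed fraction of the library carries a technology-specific
#' interference chemotype, interference among primary actives sits at the
#' 22.4 % prevalence typical of curated AlphaScreen collections, and each
#' compound is screened in one to four primary assays per technology so
#' that both previously-tested (Set A) and novel (Set B) compounds arise
#' under leave-one-assay-out evaluation.
#'
#' @param n_compounds Library size.
#' @param technologies Detection technology names.
#' @param n_primary_assays Artefact-linked primary assays per technology.
#' @param n_unlinked_assays Additional primary screens per technology with
#'   no linked artefact assay. They contribute screening history for the
#'   Binomial Survivor Function (and its assay-subsampling experiment) but
#'   never to CIAT/NCIAT labels.
#' @param motifs Motif table as in [default_interference_motifs()].
#' @param motif_fraction Fraction of the library carrying each technology's
#'   motif set (carrier sets are disjoint across technologies).
#' @param p_ciat_given_motif,p_ciat_no_motif Probability that a compound is
#'   a true interferer with a technology given that it does / does not
#'   carry that technology's motif.
#' @param base_hit_rate Probability of genuine (target-driven) activity per
#'   primary assay; recalibrated when `target_ciat_prevalence` is set.
#' @param interference_penetrance Probability that a true interferer's
#'   interference actually manifests as an active readout in any given
#'   primary screen. Interference depends on assay conditions and is far
#'   from perfectly reproducible — one historic observation is evidence,
#'   not proof, which is exactly why promiscuity scores need compounds
#'   tested many times before they rival a structural model.
#' @param artefact_flip_noise Probability that an artefact readout
#'   contradicts the true interference status.
#' @param multiplicity_dist Named probability vector over the number of
#'   linked primary assays a compound is tested in per technology; must
#'   give mass to 1 and to >1.
#' @param unlinked_test_rate Probability a compound is tested in each
#'   unlinked assay.
#' @param target_ciat_prevalence Desired fraction of true interferers among
#'   primary-active compounds (`NA` to disable calibration and use
#'   `base_hit_rate` as given). Default 0.224.
#' @param pct_effect_dup_rate Probability a primary datapoint carries an
#'   additional percent-effect flag beside its main one.
#' @param inconclusive_rate Probability a flag is recorded inconclusive.
#' @param seed Integer master seed; identical configurations produce
#'   byte-identical campaigns.
#' @return A validated `generator_config` object.
#' @export
generator_config <- function(n_compounds = 20000,
                             technologies = c("AlphaScreen", "FRET", "TR-FRET"),
                             n_primary_assays = 8,
                             n_unlinked_assays = 6,
                             motifs = default_interference_motifs(),
                             motif_fraction = 0.08,
                             p_ciat_given_motif = 0.8,
                             p_ciat_no_motif = 0.015,
                             base_hit_rate = 0.1,
                             interference_penetrance = 0.5,
                             artefact_flip_noise = 0.05,
                             multiplicity_dist = c("1" = 0.5, "2" = 0.25,
                                                   "3" = 0.15, "4" = 0.10),
                             unlinked_test_rate = 0.15,
                             target_ciat_prevalence = 0.224,
                             pct_effect_dup_rate = 0.08,
                             inconclusive_rate = 0.01,
                             seed = 1L) {
  probs <- c(motif_fraction = motif_fraction,
             p_ciat_given_motif = p_ciat_given_motif,
             p_ciat_no_motif = p_ciat_no_motif,
             base_hit_rate = base_hit_rate,
             interference_penetrance = interference_penetrance,
             artefact_flip_noise = artefact_flip_noise,
             unlinked_test_rate = unlinked_test_rate,
             pct_effect_dup_rate = pct_effect_dup_rate,
             inconclusive_rate = inconclusive_rate)
  bad <- probs < 0 | probs > 1
  if (any(bad)) stop("probabilities outside [0,1]: ",
                     paste(names(probs)[bad], collapse = ", "))
  if (!is.na(target_ciat_prevalence) &&
      (target_ciat_prevalence <= 0 || target_ciat_prevalence >= 1)) {
    stop("target_ciat_prevalence must be in (0,1) or NA")
  }
  if (n_compounds <= 0) stop("n_compounds must be positive")
  if (n_primary_assays < 2) stop("need at least 2 primary assays per technology")
  stopifnot(is.data.frame(motifs),
            all(c("technology", "name", "fragment", "smarts") %in% names(motifs)))
  if (!all(technologies %in% motifs$technology)) {
    stop("no motifs defined for technology: ",
         paste(setdiff(technologies, motifs$technology), collapse = ", "))
  }
  m <- as.numeric(names(multiplicity_dist))
  if (anyNA(m) || any(m < 1) || any(m > n_primary_assays)) {
    stop("multiplicity_dist support must lie in [1, n_primary_assays]")
  }
  if (abs(sum(multiplicity_dist) - 1) > 1e-8 || any(multiplicity_dist < 0)) {
    stop("multiplicity_dist must be a probability vector")
  }
  if (!any(m == 1 & multiplicity_dist > 0)) {
    stop("multiplicity_dist must give mass to multiplicity 1")
  }
  if (!any(m > 1 & multiplicity_dist > 0)) {
    warning("multiplicity_dist gives no mass to multiplicities >1; ",
            "Set A will be empty for every held-out assay")
  }
  structure(list(
    n_compounds = as.integer(n_compounds), technologies = technologies,
    n_primary_assays = as.integer(n_primary_assays),
    n_unlinked_assays = as.integer(n_unlinked_assays),
    motifs = motifs[motifs$technology %in% technologies, , drop = FALSE],
    motif_fraction = motif_fraction,
    p_ciat_given_motif = p_ciat_given_motif,
    p_ciat_no_motif = p_ciat_no_motif,
    base_hit_rate = base_hit_rate,
    interference_penetrance = interference_penetrance,
    artefact_flip_noise = artefact_flip_noise,
    multiplicity_dist = multiplicity_dist,
    unlinked_test_rate = unlinked_test_rate,
    target_ciat_prevalence = target_ciat_prevalence,
    pct_effect_dup_rate = pct_effect_dup_rate,
    inconclusive_rate = inconclusive_rate,
    seed = as.integer(seed)
  ), class = "generator_config")
}

#' Generate the synthetic compound library
#'
#' Enumerates unique, parseable structures from scaffold/substituent
#' combinations. A `motif_fraction` of the library per technology carries
#' one of that technology's interference motifs; carrier sets are disjoint
#' across technologies and non-carriers match no motif pattern.
#'
#' @param config A [generator_config()].
#' @return Data frame: `compound_id`, `smiles`, `motif_technology` (`NA`
#'   for non-carriers), `motif_name`.
#' @export
generate_library <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(.substream_seed(config$seed, "library"))
  n <- config$n_compounds
  ntech <- length(config$technologies)
  n_carrier <- round(config$motif_fraction * n)
  n_plain <- n - n_carrier * ntech
  if (n_plain < 0) stop("motif_fraction too large for ", ntech, " technologies")

  templ <- .SCAFFOLD_TEMPLATES
  subs <- .SUBSTITUENTS

  build <- function(t, a, b) sprintf(templ[t], subs[a], subs[b])

  # Plain grid: (template, subA, subB)
  plain_grid <- expand.grid(t = seq_along(templ), a = seq_along(subs),
                            b = seq_along(subs))
  if (nrow(plain_grid) < n_plain * 1.05) {
    stop("scaffold/substituent grid too small for ", n_plain,
         " motif-free compounds")
  }
  plain_order <- sample.int(nrow(plain_grid))

  carrier_pool <- list()
  for (tech in config$technologies) {
    mt <- config$motifs[config$motifs$technology == tech, , drop = FALSE]
    g <- expand.grid(t = seq_along(templ), m = seq_len(nrow(mt)),
                     slot = 1:2, s = seq_along(subs))
    if (nrow(g) < n_carrier) {
      stop("unsatisfiable motif fraction for technology ", tech,
           " (motifs: ", paste(mt$name, collapse = ", "), "): ",
           nrow(g), " combinations < ", n_carrier, " carriers requested")
    }
    g <- g[sample.int(nrow(g)), , drop = FALSE]
    smi <- ifelse(g$slot == 1,
                  sprintf(templ[g$t], mt$fragment[g$m], subs[g$s]),
                  sprintf(templ[g$t], subs[g$s], mt$fragment[g$m]))
    carrier_pool[[tech]] <- data.frame(smiles = smi,
                                       motif_technology = tech,
                                       motif_name = mt$name[g$m],
                                       stringsAsFactors = FALSE)
  }

  plain_smi <- build(plain_grid$t[plain_order], plain_grid$a[plain_order],
                     plain_grid$b[plain_order])
  pool <- rbind(
    data.frame(smiles = plain_smi, motif_technology = NA_character_,
               motif_name = NA_character_, stringsAsFactors = FALSE),
    do.call(rbind, carrier_pool)
  )
  want <- c(n_plain, rep(n_carrier, ntech))
  names(want) <- c(".plain", config$technologies)

  # Deduplicate on canonical structure, then take the first `want` of each
  # stratum in sampled order.
  key <- ifelse(is.na(pool$motif_technology), ".plain", pool$motif_technology)
  canon <- canonical_smiles(pool$smiles)
  if (anyNA(canon)) {
    stop("internal: enumerated structure failed to parse: ",
         pool$smiles[which(is.na(canon))[1]])
  }
  keep <- !duplicated(canon)
  pool <- pool[keep, , drop = FALSE]
  key <- key[keep]
  sel <- unlist(lapply(names(want), function(k) {
    idx <- which(key == k)
    if (length(idx) < want[[k]]) {
      stop("could not enumerate ", want[[k]], " unique structures for ",
           if (k == ".plain") "the motif-free stratum" else paste("technology", k))
    }
    idx[seq_len(want[[k]])]
  }), use.names = FALSE)
  out <- pool[sel, , drop = FALSE]
  out <- out[sample.int(nrow(out)), , drop = FALSE]  # interleave strata
  out$compound_id <- sprintf("C%06d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out[, c("compound_id", "smiles", "motif_technology", "motif_name")]
}

#' Assign ground-truth interference status
#'
#' Per technology, a compound is a true interferer (CIAT) with probability
#' `p_ciat_given_motif` when it carries that technology's motif and
#' `p_ciat_no_motif` otherwise; draws come from the seeded `truth`
#' substream.
#'
#' @param library Output of [generate_library()].
#' @param config The [generator_config()].
#' @param p_override Optional named list overriding the two probabilities
#'   (used internally by prevalence calibration).
#' @return Data frame `compound_id` plus one logical column per technology.
#' @export
assign_ground_truth <- function(library, config, p_override = NULL) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(.substream_seed(config$seed, "truth"))
  pg <- if (is.null(p_override)) config$p_ciat_given_motif else p_override$p_ciat_given_motif
  pn <- if (is.null(p_override)) config$p_ciat_no_motif else p_override$p_ciat_no_motif
  out <- data.frame(compound_id = library$compound_id, stringsAsFactors = FALSE)
  for (tech in config$technologies) {
    p <- ifelse(!is.na(library$motif_technology) &
                  library$motif_technology == tech, pg, pn)
    out[[tech]] <- stats::runif(nrow(library)) < p
  }
  out
}

# Expected fraction of true interferers among primary-active compounds at
# base hit rate b: an interferer reads active per assay with probability
# 1-(1-q)(1-b) (q = penetrance), a clean compound with probability b.
.expected_prevalence <- function(b, q, is_ciat, k) {
  n_active_c <- sum(1 - ((1 - q) * (1 - b))^k[is_ciat])
  n_active_nc <- sum(1 - (1 - b)^k[!is_ciat])
  n_active_c / (n_active_c + n_active_nc)
}

.calibrate_hit_rate <- function(truth, mult, technologies, target, q) {
  f <- function(b) {
    mean(vapply(technologies, function(tech) {
      .expected_prevalence(b, q, truth[[tech]], mult[[tech]]$k)
    }, 0)) - target
  }
  lo <- 1e-6; hi <- 0.999
  if (f(hi) > 0) {
    stop("prevalence calibration failure: even at hit rate ~1 the expected ",
         "CIAT prevalence among actives is ", round(f(hi) + target, 3),
         " > target ", target)
  }
  if (f(lo) < 0) {
    stop("prevalence calibration failure: even at hit rate ~0 the expected ",
         "CIAT prevalence among actives is ", round(f(lo) + target, 3),
         " < target ", target)
  }
  stats::uniroot(f, c(lo, hi), tol = 1e-8)$root
}

.draw_flag <- function(active, inconclusive_rate) {
  f <- ifelse(active, "active", "inactive")
  inc <- stats::runif(length(f)) < inconclusive_rate
  f[inc] <- "inconclusive"
  f
}

#' Simulate a full screening campaign
#'
#' Assigns each compound to `k ~ multiplicity_dist` artefact-linked primary
#' assays per technology (plus unlinked historic screens), draws primary
#' activity flags — a true interferer always reads active, since
#' interference produces false positive readouts; genuine activity occurs
#' at the (possibly calibrated) base hit rate — and generates one artefact
#' readout per technology for every primary-active compound, flipped
#' against ground truth with probability `artefact_flip_noise`.
#'
#' When `target_ciat_prevalence` is set, the base hit rate is first
#' calibrated so the expected interferer fraction among primary actives
#' matches it; the realized fraction must land within ±0.05 or the flag
#' draws are retried (bounded), then an error reports the achieved value.
#'
#' @param config A [generator_config()].
#' @return A `synthetic_campaign`: list with `compounds`, `assays`,
#'   `results`, `ground_truth`, `config`, and `realized` diagnostics.
#' @export
simulate_campaign <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  lib <- generate_library(config)
  truth <- assign_ground_truth(lib, config)
  n <- nrow(lib)

  assays <- do.call(rbind, lapply(config$technologies, function(tech) {
    primary <- sprintf("%s_P%d", tech, seq_len(config$n_primary_assays))
    artefact <- sprintf("%s_CR%d", tech, seq_len(config$n_primary_assays))
    unlinked <- if (config$n_unlinked_assays > 0)
      sprintf("%s_X%d", tech, seq_len(config$n_unlinked_assays)) else character(0)
    rbind(
      data.frame(assay_id = primary, technology = tech, assay_kind = "primary",
                 linked_artefact = artefact, stringsAsFactors = FALSE),
      data.frame(assay_id = artefact, technology = tech, assay_kind = "artefact",
                 linked_artefact = NA_character_, stringsAsFactors = FALSE),
      if (length(unlinked))
        data.frame(assay_id = unlinked, technology = tech, assay_kind = "primary",
                   linked_artefact = NA_character_, stringsAsFactors = FALSE)
    )
  }))
  rownames(assays) <- NULL

  # Assay membership: which linked primaries each compound is tested in.
  set.seed(.substream_seed(config$seed, "assignment"))
  mult <- list()
  for (tech in config$technologies) {
    supp <- as.integer(names(config$multiplicity_dist))
    k <- if (length(supp) == 1) rep(supp, n) else
      sample(supp, n, replace = TRUE, prob = config$multiplicity_dist)
    # top-k of a random permutation per compound = k distinct assays
    u <- matrix(stats::runif(n * config$n_primary_assays), nrow = n)
    ord <- t(apply(u, 1, order))
    idx <- rep(seq_len(n), k)
    pick <- unlist(lapply(seq_len(n), function(i) ord[i, seq_len(k[i])]))
    mult[[tech]] <- list(
      k = k,
      membership = data.frame(
        compound_id = lib$compound_id[idx],
        assay_id = sprintf("%s_P%d", tech, pick),
        stringsAsFactors = FALSE)
    )
    if (config$n_unlinked_assays > 0) {
      tested <- matrix(stats::runif(n * config$n_unlinked_assays) <
                         config$unlinked_test_rate, nrow = n)
      w <- which(tested, arr.ind = TRUE)
      mult[[tech]]$unlinked <- data.frame(
        compound_id = lib$compound_id[w[, 1]],
        assay_id = sprintf("%s_X%d", tech, w[, 2]),
        stringsAsFactors = FALSE)
    }
  }

  b <- config$base_hit_rate
  if (!is.na(config$target_ciat_prevalence)) {
    b <- .calibrate_hit_rate(truth, mult, config$technologies,
                             config$target_ciat_prevalence,
                             config$interference_penetrance)
  }

  draw_results <- function(attempt, b) {
    set.seed(.substream_seed(config$seed, sprintf("noise%d", attempt)))
    res <- list()
    for (tech in config$technologies) {
      is_ciat <- truth[[tech]][match(mult[[tech]]$membership$compound_id,
                                     lib$compound_id)]
      genuine <- stats::runif(nrow(mult[[tech]]$membership)) < b
      manifests <- stats::runif(nrow(mult[[tech]]$membership)) <
        config$interference_penetrance
      active <- (is_ciat & manifests) | genuine
      flag <- .draw_flag(active, config$inconclusive_rate)
      src <- ifelse(stats::runif(length(flag)) < 0.9, "zscore", "percent_effect")
      prim <- data.frame(mult[[tech]]$membership,
                         technology = tech, assay_kind = "primary",
                         activity_flag = flag, flag_source = src,
                         stringsAsFactors = FALSE)
      # occasional second flag from the percent-effect pipeline
      dup <- stats::runif(nrow(prim)) < config$pct_effect_dup_rate
      if (any(dup)) {
        agree <- stats::runif(sum(dup)) < 0.7
        dupflag <- ifelse(agree, prim$activity_flag[dup],
                          ifelse(prim$activity_flag[dup] == "active",
                                 "inactive", "active"))
        dups <- prim[dup, ]
        dups$activity_flag <- dupflag
        dups$flag_source <- "percent_effect"
        prim <- rbind(prim, dups)
      }
      res[[paste0(tech, "_prim")]] <- prim

      if (!is.null(mult[[tech]]$unlinked) && nrow(mult[[tech]]$unlinked)) {
        uc <- truth[[tech]][match(mult[[tech]]$unlinked$compound_id,
                                  lib$compound_id)]
        um <- stats::runif(nrow(mult[[tech]]$unlinked)) <
          config$interference_penetrance
        uact <- (uc & um) | (stats::runif(nrow(mult[[tech]]$unlinked)) < b)
        res[[paste0(tech, "_unl")]] <- data.frame(
          mult[[tech]]$unlinked, technology = tech, assay_kind = "primary",
          activity_flag = .draw_flag(uact, config$inconclusive_rate),
          flag_source = "zscore", stringsAsFactors = FALSE)
      }

      # artefact readout for every compound with an active linked-primary flag
      active_ids <- unique(prim$compound_id[prim$activity_flag == "active"])
      if (length(active_ids)) {
        tc <- truth[[tech]][match(active_ids, lib$compound_id)]
        flipped <- xor(tc, stats::runif(length(tc)) < config$artefact_flip_noise)
        res[[paste0(tech, "_art")]] <- data.frame(
          compound_id = active_ids,
          assay_id = sprintf("%s_CR%d", tech,
                             sample.int(config$n_primary_assays,
                                        length(active_ids), replace = TRUE)),
          technology = tech, assay_kind = "artefact",
          activity_flag = .draw_flag(flipped, config$inconclusive_rate),
          flag_source = NA_character_, stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, res)
    rownames(out) <- NULL
    out
  }

  realized_prev <- function(results) {
    vapply(config$technologies, function(tech) {
      linked <- assays$assay_id[assays$technology == tech &
                                  assays$assay_kind == "primary" &
                                  !is.na(assays$linked_artefact)]
      r <- results[results$assay_id %in% linked &
                     results$activity_flag == "active", ]
      ids <- unique(r$compound_id)
      if (!length(ids)) return(NA_real_)
      mean(truth[[tech]][match(ids, lib$compound_id)])
    }, 0)
  }

  max_tries <- 5L
  for (attempt in seq_len(max_tries)) {
    results <- draw_results(attempt, b)
    prev <- realized_prev(results)
    ok <- is.na(config$target_ciat_prevalence) ||
      all(abs(prev - config$target_ciat_prevalence) <= 0.05, na.rm = TRUE)
    if (ok) break
    if (attempt == max_tries) {
      stop("prevalence calibration failure after ", max_tries,
           " retries: achieved ", paste(round(prev, 3), collapse = "/"),
           " vs target ", config$target_ciat_prevalence)
    }
  }

  structure(list(
    compounds = lib,
    assays = assays,
    results = results,
    ground_truth = truth,
    config = config,
    realized = list(base_hit_rate = b, ciat_prevalence_among_actives = prev,
                    draw_attempts = attempt)
  ), class = "synthetic_campaign")
}

#' @export
print.synthetic_campaign <- function(x, ...) {
  cat("Synthetic HTS campaign\n")
  cat("  compounds: ", nrow(x$compounds), "\n")
  cat("  technologies: ", paste(x$config$technologies, collapse = ", "), "\n")
  cat("  assays: ", nrow(x$assays), " (",
      sum(x$assays$assay_kind == "primary"), " primary, ",
      sum(x$assays$assay_kind == "artefact"), " artefact)\n", sep = "")
  cat("  results: ", nrow(x$results), "\n")
  cat("  base hit rate used: ", signif(x$realized$base_hit_rate, 3), "\n")
  prev <- x$realized$ciat_prevalence_among_actives
  cat("  CIAT prevalence among primary actives: ",
      paste(sprintf("%s %.1f%%", names(prev), 100 * prev), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}
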