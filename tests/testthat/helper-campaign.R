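# Shared fixtures: a small three-technology campaign (built once per test
# run) and hand-rolled helpers used across test files.

.fixture_env <- new.env(parent = emptyenv())

small_campaign_config <- function(seed = 11) {
  generator_config(n_compounds = 2500, n_primary_assays = 4,
                   n_unlinked_assays = 6,
                   multiplicity_dist = c("1" = 0.5, "2" = 0.25,
                                         "3" = 0.15, "4" = 0.10),
                   seed = seed)
}

get_small_campaign <- function() {
  if (is.null(.fixture_env$campaign)) {
    .fixture_env$campaign <- simulate_campaign(small_campaign_config())
  }
  .fixture_env$campaign
}

get_small_fingerprints <- function() {
  if (is.null(.fixture_env$fp)) {
    cmp <- get_small_campaign()
    .fixture_env$fp <- fingerprint_matrix(cmp$compounds$smiles,
                                          ids = cmp$compounds$compound_id)
  }
  .fixture_env$fp
}

get_small_dataset <- function(technology = "AlphaScreen") {
  key <- paste0("ds_", technology)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- curate_campaign(
      get_small_campaign(), technologies = technology,
      fingerprints = get_small_fingerprints())[[technology]]
  }
  .fixture_env[[key]]
}

# independent exact binomial upper tail, summed term by term
brute_binom_tail <- function(A, N, h) {
  if (A == 0) return(1)
  sum(vapply(A:N, function(a) choose(N, a) * h^a * (1 - h)^(N - a), 0))
}

# independent confusion-matrix metrics written as explicit loops
brute_metrics <- function(labels, predictions) {
  tp <- fp <- tn <- fn <- 0
  for (i in seq_along(labels)) {
    if (predictions[i] && labels[i]) tp <- tp + 1
    else if (predictions[i] && !labels[i]) fp <- fp + 1
    else if (!predictions[i] && !labels[i]) tn <- tn + 1
    else fn <- fn + 1
  }
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       mcc = if (den == 0) 0 else (tp * tn - fp * fn) / den,
       recall = if (tp + fn == 0) NA_real_ else tp / (tp + fn),
       precision = if (tp + fp == 0) NA_real_ else tp / (tp + fp))
}

# PubChem BioAssay export mimic (synthetic fixture, written on the fly)
write_pubchem_fixture <- function(dir) {
  aid1 <- file.path(dir, "AID_900001.csv")
  aid2 <- file.path(dir, "AID_900002.csv")
  write.csv(data.frame(
    PUBCHEM_CID = c(101, 102, 103, 104, 105, 106),
    PUBCHEM_ACTIVITY_OUTCOME = c("Active", "Inactive", "Inconclusive",
                                 "Active", "Inactive", "Active")
  ), aid1, row.names = FALSE)
  write.csv(data.frame(
    PUBCHEM_CID = c(101, 104, 105, 107),
    PUBCHEM_ACTIVITY_OUTCOME = c("Active", "Inactive", "Inactive", "Active")
  ), aid2, row.names = FALSE)
  c(aid1, aid2)
}
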