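test_that("pbsf matches its closed forms and the cutoff correspondence", {
  for (N in c(1, 5, 20)) for (h in c(0.01, 0.3, 0.9)) {
    expect_equal(pbsf(0, N, h), 0)
    expect_equal(pbsf(N, N, h), -N * log10(h))
  }
  # a score of 2 is a 1 % chance: single test at hit rate 1 %
  expect_equal(pbsf(1, 1, 0.01), 2)
  expect_equal(pbsf(1, 1, 0.01, scale = "ten_log10"), 20)
  expect_equal(round(pbsf(5, 20, 0.02), 1), 4.4)
})

test_that("pbsf agrees with exact tail summation to 1e-9 relative", {
  set.seed(31)
  for (i in 1:200) {
    N <- sample(1:50, 1)
    A <- sample(1:N, 1)
    h <- runif(1, 0.005, 0.6)
    expected <- -log10(brute_binom_tail(A, N, h))
    # relative agreement; absolute floor where the score vanishes and the
    # term-by-term oracle loses digits to cancellation (tail ~ 1)
    expect_lte(abs(pbsf(A, N, h) - expected),
               1e-9 * max(abs(expected), 1))
  }
})

test_that("pbsf is monotone in A and in h", {
  h <- 0.07
  for (N in c(3, 10, 40)) {
    scores <- pbsf(0:N, N, h)
    expect_true(all(diff(scores) >= 0))
  }
  hs <- seq(0.01, 0.95, by = 0.02)
  for (A in c(1, 3, 7)) {
    scores <- vapply(hs, function(x) pbsf(A, 10, x), 0)
    expect_true(all(diff(scores) <= 1e-12))
  }
})

test_that("pbsf rejects invalid inputs", {
  expect_error(pbsf(5, 3, 0.1), "A <= N")
  expect_error(pbsf(1, 2, -0.1), "\\[0, 1\\]")
  expect_error(pbsf(1, 2, 1.2), "\\[0, 1\\]")
  expect_error(pbsf(1, 2, 0), "strictly")
  expect_equal(pbsf(0, 2, 0), 0)
})

test_that("classification applies the pBSF >= 2 cutoff strictly", {
  expect_equal(classify_bsf(1.99), "NCIAT")
  expect_equal(classify_bsf(2.0), "CIAT")
  expect_equal(classify_bsf(pbsf(0, 30, 0.05)), "NCIAT")
})

test_that("pooled hit rate is the active fraction and a weighted mean", {
  r <- data.frame(
    compound_id = rep(sprintf("c%d", 1:50), 2),
    assay_id = rep(c("a1", "a2"), each = 50),
    activity_flag = "inactive", stringsAsFactors = FALSE)
  expect_equal(pooled_hit_rate(r), 0)
  r$activity_flag[c(1:3, 51:52)] <- "active"
  expect_equal(pooled_hit_rate(r), 0.05)
  # identity: pooled rate = size-weighted mean of per-assay rates
  per <- tapply(r$activity_flag == "active", r$assay_id, mean)
  size <- table(r$assay_id)
  expect_equal(pooled_hit_rate(r),
               sum(per * size) / sum(size))
  expect_error(pooled_hit_rate(r[0, ]), "zero results")
})

test_that("screening history collapses replicates within an assay", {
  r <- data.frame(
    compound_id = c("c1", "c1", "c1", "c2"),
    assay_id = c("a1", "a1", "a2", "a1"),
    activity_flag = c("active", "inactive", "inactive", "inactive"),
    stringsAsFactors = FALSE)
  h <- screening_history(r)
  expect_equal(h$N[h$compound_id == "c1"], 2)  # two distinct assays
  expect_equal(h$A[h$compound_id == "c1"], 1)  # a1 counts once, active
  expect_equal(h$N[h$compound_id == "c2"], 1)
  h2 <- screening_history(r, exclude_assays = "a1")
  expect_equal(h2$N[h2$compound_id == "c1"], 1)
  expect_false("c2" %in% h2$compound_id)
})

test_that("LOAO scoring marks never-tested compounds unpredictable", {
  cmp <- get_small_campaign()
  linked <- cmp$assays[cmp$assays$technology == "AlphaScreen" &
                         cmp$assays$assay_kind == "primary" &
                         !is.na(cmp$assays$linked_artefact), ]
  prim <- cmp$results[cmp$results$assay_id %in% linked$assay_id, ]
  holdout <- linked$assay_id[1]
  out <- bsf_loao(prim, holdout)
  tested_elsewhere <- unique(prim$compound_id[prim$assay_id != holdout])
  expect_identical(out$predictable, out$compound_id %in% tested_elsewhere)
  expect_true(all(is.na(out$class[!out$predictable])))
  expect_true(all(out$pbsf[!out$predictable] == 0))
  # fraction unpredictable = fraction tested only in the held-out assay
  membership <- unique(prim[, c("compound_id", "assay_id")])
  k <- table(membership$compound_id)
  only_here <- names(k)[k == 1]
  expect_equal(mean(!out$predictable),
               mean(out$compound_id %in% only_here))
  # a compound tested in two other assays is scored from N = 2
  two <- out$compound_id[out$N == 2][1]
  if (!is.na(two)) {
    expect_equal(sum(membership$compound_id == two &
                       membership$assay_id != holdout), 2)
  }
})

test_that("assay subsampling keeps the artefact-linked base panel", {
  cmp <- get_small_campaign()
  primary <- cmp$results[cmp$results$assay_kind == "primary" &
                           cmp$results$technology == "FRET", ]
  expect_error(subsample_assay_fraction(primary, cmp$assays, 0), "\\(0, 1\\]")
  expect_error(subsample_assay_fraction(primary, cmp$assays, 1.2), "\\(0, 1\\]")

  full <- subsample_assay_fraction(primary, cmp$assays, 1, seed = 4)
  expect_setequal(unique(full$assay_id), unique(primary$assay_id))

  half <- subsample_assay_fraction(primary, cmp$assays, 0.5, seed = 4)
  panel <- attr(half, "assays_used")
  base <- cmp$assays$assay_id[cmp$assays$assay_kind == "primary" &
                                !is.na(cmp$assays$linked_artefact)]
  n_unl <- sum(cmp$assays$assay_kind == "primary" &
                 is.na(cmp$assays$linked_artefact) &
                 cmp$assays$technology == "FRET")
  expect_true(all(intersect(base, unique(primary$assay_id)) %in% panel))
  # round(0.5 * 6 unlinked FRET assays) = 3 extras
  expect_equal(sum(grepl("_X", panel)), round(0.5 * n_unl))
  # same seed, same draw
  half2 <- subsample_assay_fraction(primary, cmp$assays, 0.5, seed = 4)
  expect_identical(attr(half2, "assays_used"), panel)
})
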