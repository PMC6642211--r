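test_that("generators are deterministic under a fixed seed", {
  a <- simulate_structure_profiles(n_transcripts = 10, seed = 91)
  b <- simulate_structure_profiles(n_transcripts = 10, seed = 91)
  expect_identical(a, b)

  tx <- tibble::tibble(transcript_id = sprintf("t%02d", 1:20), content = runif(20))
  expect_identical(
    simulate_clip_peaks(tx, seed = 92), simulate_clip_peaks(tx, seed = 92)
  )
  expect_identical(
    simulate_complexes(5, seed = 93), simulate_complexes(5, seed = 93)
  )
  expect_identical(
    simulate_lfq_experiment(n_proteins = 30, seed = 94),
    simulate_lfq_experiment(n_proteins = 30, seed = 94)
  )
  expect_identical(
    simulate_paralog_clusters(n_clusters = 5, seed = 95),
    simulate_paralog_clusters(n_clusters = 5, seed = 95)
  )
})

test_that("invalid generator configurations are rejected", {
  expect_error(simulate_structure_profiles(n_transcripts = 0), ">= 1")
  expect_error(simulate_structure_profiles(read_depth = 0), "> 0")
  expect_error(simulate_structure_profiles(ds_fraction = 1.2), "\\[0, 1]")
  expect_error(simulate_lfq_experiment(planted_auc = 0.4), "\\(0.5, 1]")
  expect_error(simulate_lfq_experiment(planted_auc = 1.2), "\\(0.5, 1]")
  expect_error(
    simulate_lfq_experiment(frac_released = 0.8, frac_kept = 0.5),
    "at most 1"
  )
  expect_error(simulate_complexes(0), ">= 1")
  expect_error(simulate_paralog_clusters(frac_negative = 2), "\\[0, 1]")
})

test_that("planted double-stranded fractions drive the recovered content", {
  high <- simulate_structure_profiles(
    n_transcripts = 40, read_depth = 50, ds_fraction = 0.9,
    length_range = c(100, 200), seed = 96
  )
  low <- simulate_structure_profiles(
    n_transcripts = 40, read_depth = 50, ds_fraction = 0.1,
    length_range = c(100, 200), seed = 97
  )
  gap <- mean(pars_content(high$pars)$content) - mean(pars_content(low$pars)$content)
  expect_gt(gap, 0.5)

  # per-transcript state fractions stay within binomial error of the target
  states <- high$transcripts
  phat <- vapply(states$per_nt_state, mean, numeric(1))
  se <- sqrt(0.9 * 0.1 / states$length)
  expect_true(all(abs(phat - 0.9) < 5 * se))
})

test_that("a flat binder law gives unit-mean counts and decoys never pass", {
  set.seed(98)
  tx <- tibble::tibble(transcript_id = sprintf("t%03d", 1:400), content = runif(400))
  peaks <- simulate_clip_peaks(tx, alpha = 0, beta = 0, seed = 99)
  counts <- filter_peaks(peaks) |>
    count_binders(transcript_ids = tx$transcript_id)
  expect_equal(mean(counts$n_binders), 1, tolerance = 0.15) # Poisson(e^0)

  # filtering retains exactly the planted (above-threshold) peaks
  kept <- filter_peaks(peaks)
  expect_true(all(kept$planted))
  expect_equal(nrow(kept), sum(peaks$planted))
})

test_that("binned binder counts track the planted exponential law", {
  tx <- tibble::tibble(
    transcript_id = sprintf("t%04d", 1:3000), content = runif(3000)
  )
  peaks <- simulate_clip_peaks(tx, alpha = -0.75, beta = 0.67, seed = 100)
  counts <- filter_peaks(peaks) |>
    count_binders(transcript_ids = tx$transcript_id) |>
    dplyr::inner_join(tx, by = "transcript_id")
  binned <- counts |>
    dplyr::mutate(bin = cut(content, seq(0, 1, 0.2))) |>
    dplyr::group_by(bin) |>
    dplyr::summarise(
      mean_count = mean(n_binders), mid = mean(content), n = dplyr::n()
    )
  expected <- exp(-0.75 + 0.67 * binned$mid)
  # each binned mean within a generous Poisson standard-error envelope
  expect_true(all(
    abs(binned$mean_count - expected) < 4 * sqrt(expected / binned$n)
  ))
})

test_that("binder draws larger than the RBP universe fail loudly", {
  tx <- tibble::tibble(transcript_id = "t1", content = 1)
  expect_error(
    simulate_clip_peaks(tx, alpha = 4, beta = 0, n_rbps = 10, seed = 101),
    "universe"
  )
})

test_that("zero contact level produces contact-free complexes", {
  sim <- simulate_complexes(10, contact_level = 0, seed = 102)
  sc <- contact_scores(sim$coordinates)
  expect_true(all(sc$internal_count == 0))
  expect_true(all(sc$external_count == 0))
})

test_that("planted AUC is realized by the simulated interaction scores", {
  perfect <- simulate_lfq_experiment(n_proteins = 200, planted_auc = 1, seed = 103)
  pos <- perfect$truth$protein_id[perfect$truth$label == "released"]
  neg <- setdiff(perfect$truth$protein_id, pos)
  expect_equal(roc_auc(perfect$scores, pos, neg), 1)

  mid <- simulate_lfq_experiment(n_proteins = 500, planted_auc = 0.8, seed = 104)
  pos <- mid$truth$protein_id[mid$truth$label == "released"]
  neg <- setdiff(mid$truth$protein_id, pos)
  expect_equal(roc_auc(mid$scores, pos, neg), 0.8, tolerance = 0.05)
})

test_that("paralog clusters respect identity structure and planted sign", {
  sim <- simulate_paralog_clusters(n_clusters = 8, frac_negative = 1, seed = 105)
  # within-cluster identity above threshold, across-cluster below
  truth <- sim$truth
  one <- truth$transcript_id[truth$cluster_id == truth$cluster_id[1]]
  expect_gte(pairwise_identity(sim$sequences[[one[1]]], sim$sequences[[one[2]]]), 0.85)
  other <- truth$transcript_id[truth$cluster_id != truth$cluster_id[1]][1]
  expect_lt(pairwise_identity(sim$sequences[[one[1]]], sim$sequences[[other]]), 0.85)

  rep <- paralog_correlation(truth, sim$structure_scores, sim$binder_counts)
  expect_equal(fraction_negative(rep), 1)
})

test_that("tabular and sequence artifacts round-trip through the readers", {
  dir <- withr::local_tempdir()
  sim <- simulate_structure_profiles(n_transcripts = 5, seed = 106)
  p <- write_tsv_file(sim$pars, file.path(dir, "pars.tsv"))
  expect_equal(read_tsv_file(p), sim$pars)

  lfq <- simulate_lfq_experiment(n_proteins = 20, seed = 107)$lfq
  p2 <- write_tsv_file(lfq, file.path(dir, "lfq.tsv"))
  expect_equal(read_tsv_file(p2), lfq)

  seqs <- simulate_paralog_clusters(n_clusters = 3, seed = 108)$sequences
  p3 <- write_fasta(seqs, file.path(dir, "seqs.fa"))
  expect_equal(read_fasta(p3), seqs)
})
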