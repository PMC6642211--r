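test_that("pars content counts strictly double-stranded nucleotides", {
  prof <- tibble::tibble(
    transcript_id = "tx1", position = 0:3,
    ds_reads = c(10L, 1L, 5L, 0L), ss_reads = c(1L, 10L, 5L, 2L)
  )
  res <- pars_content(prof)
  expect_equal(res$content, 0.25)
  expect_equal(res$n_determined, 4L)

  all_ds <- tibble::tibble(
    transcript_id = "t", position = 0:4,
    ds_reads = c(3L, 1L, 9L, 2L, 4L), ss_reads = 0L
  )
  expect_equal(pars_content(all_ds)$content, 1)

  balanced <- tibble::tibble(
    transcript_id = "t", position = 0:4,
    ds_reads = 5L, ss_reads = 5L
  )
  res <- pars_content(balanced)
  expect_equal(res$content, 0)
  expect_true(is.na(res$log_content))
})

test_that("pars content equals the literal stepwise oracle on random profiles", {
  set.seed(11)
  for (i in 1:1000) {
    prof <- random_pars_profile("tx", sample(5:50, 1))
    expected <- oracle_pars_content(prof$ds_reads, prof$ss_reads)
    if (is.na(expected)) {
      expect_warning(expect_error(pars_content(prof), "determined"))
    } else {
      expect_equal(pars_content(prof)$content, expected)
    }
  }
})

test_that("pars content is invariant to a common read-count scale factor", {
  set.seed(12)
  for (i in 1:50) {
    prof <- random_pars_profile("tx", 40)
    scaled <- dplyr::mutate(prof,
      ds_reads = ds_reads * 13L, ss_reads = ss_reads * 13L
    )
    expect_equal(pars_content(scaled)$content, pars_content(prof)$content)
  }
})

test_that("full-length denominator and undetermined handling behave", {
  prof <- tibble::tibble(
    transcript_id = "tx1", position = 0:4,
    ds_reads = c(10L, 0L, 3L, 0L, 0L), ss_reads = c(1L, 0L, 1L, 0L, 0L)
  )
  # 2 double-stranded calls; 2 determined of 5 positions
  expect_equal(pars_content(prof)$content, 1)
  expect_equal(pars_content(prof, denominator = "full")$content, 2 / 5)

  dead <- tibble::tibble(
    transcript_id = c("ok", "ok", "dead", "dead"), position = c(0:1, 0:1),
    ds_reads = c(5L, 1L, 0L, 0L), ss_reads = c(0L, 3L, 0L, 0L)
  )
  expect_warning(res <- pars_content(dead), "discarding")
  expect_equal(res$transcript_id, "ok")
})

test_that("dms content normalizes to the maximum and averages covered rows", {
  prof <- tibble::tibble(
    transcript_id = "tx1", position = 0:3, reads = c(0L, 5L, 10L, 5L)
  )
  expect_equal(dms_content(prof)$content, 0.5)

  flat <- tibble::tibble(transcript_id = "t", position = 0:9, reads = 7L)
  expect_equal(dms_content(flat)$content, 1)
})

test_that("dms transcripts under 10% coverage or without reads are excluded", {
  lens <- tibble::tibble(transcript_id = c("thin", "ok"), length = c(100L, 40L))
  prof <- dplyr::bind_rows(
    tibble::tibble(transcript_id = "thin", position = 0:4, reads = 5L),
    tibble::tibble(transcript_id = "ok", position = 0:19, reads = rpois(20, 8) + 1L)
  )
  expect_warning(res <- dms_content(prof, lengths = lens), "excluding")
  expect_equal(res$transcript_id, "ok")

  silent <- tibble::tibble(transcript_id = "z", position = 0:19, reads = 0L)
  expect_warning(res0 <- dms_content(silent), "excluding")
  expect_equal(nrow(res0), 0)
})

test_that("predicted content is the fraction of strictly positive scores", {
  prof <- tibble::tibble(
    transcript_id = "tx1", position = 0:3, score = c(1.2, -0.5, 0.0, 3.1)
  )
  expect_equal(predicted_content(prof)$content, 0.5)
  expect_equal(
    predicted_content(dplyr::mutate(prof, score = -abs(score) - 1))$content, 0
  )
  expect_equal(
    predicted_content(dplyr::mutate(prof, score = abs(score) + 1))$content, 1
  )
  expect_error(predicted_content(prof[0, ]), "empty")
})

test_that("log score matches the printed score/content conversions", {
  # ln(0.26) = -1.347, ln(0.06) = -2.813: the -1.3 / 26% and -2.8 / 6% pairs
  expect_equal(log_content(0.26), -1.35, tolerance = 0.01)
  expect_equal(log_content(0.06), -2.81, tolerance = 0.01)
  expect_equal(round(exp(-1.3), 2), 0.27)
  expect_equal(round(exp(-2.8), 2), 0.06)
  expect_equal(log_content(1), 0)
  expect_warning(out <- log_content(0), "undefined")
  expect_true(is.na(out))
  expect_error(log_content(1.2), "0, 1")
})

test_that("UTR masking retains the coding span", {
  prof <- tibble::tibble(
    transcript_id = "tx1", position = 0:99,
    ds_reads = rpois(100, 5), ss_reads = rpois(100, 5)
  )
  ann <- tibble::tibble(
    transcript_id = "tx1",
    utr5_start = 0L, utr5_end = 10L, utr3_start = 90L, utr3_end = 100L
  )
  kept <- exclude_regions(prof, ann)
  expect_equal(nrow(kept), 80)
  expect_equal(range(kept$position), c(10, 89))

  empty_ann <- tibble::tibble(
    transcript_id = "tx1",
    utr5_start = 0L, utr5_end = 0L, utr3_start = 0L, utr3_end = 0L
  )
  expect_equal(exclude_regions(prof, empty_ann), prof)

  all_utr <- tibble::tibble(
    transcript_id = "tx1",
    utr5_start = 0L, utr5_end = 50L, utr3_start = 50L, utr3_end = 100L
  )
  expect_error(exclude_regions(prof, all_utr), "every position")
})

test_that("masking then scoring equals scoring manually sliced reads", {
  set.seed(21)
  prof <- random_pars_profile("tx1", 120)
  ann <- tibble::tibble(
    transcript_id = "tx1",
    utr5_start = 0L, utr5_end = 15L, utr3_start = 100L, utr3_end = 120L
  )
  masked <- exclude_regions(prof, ann)
  manual <- prof[prof$position >= 15 & prof$position < 100, ]
  expect_equal(pars_content(masked)$content, pars_content(manual)$content)
})

test_that("pars and dms scores anti-correlate on a shared planted cohort", {
  sim <- simulate_structure_profiles(
    n_transcripts = 60, read_depth = 40,
    length_range = c(100, 200), seed = 31
  )
  pars <- pars_content(sim$pars)
  dms <- dms_content(sim$dms)
  both <- dplyr::inner_join(pars, dms,
    by = "transcript_id", suffix = c("_pars", "_dms")
  )
  expect_lt(cor(both$content_pars, both$content_dms), -0.8)
})
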