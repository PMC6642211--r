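test_that("stratification takes equal-size disjoint extremes", {
  set.seed(51)
  scores <- tibble::tibble(
    transcript_id = sprintf("t%02d", 1:10), score = runif(10)
  )
  sets <- stratify(scores, 0.2)
  expect_equal(sum(sets$set == "hs"), 2)
  expect_equal(sum(sets$set == "ls"), 2)
  expect_length(intersect(
    sets$transcript_id[sets$set == "hs"], sets$transcript_id[sets$set == "ls"]
  ), 0)
  expect_gte(
    min(sets$score[sets$set == "hs"]), max(sets$score[sets$set == "ls"])
  )

  half <- stratify(scores, 0.5)
  expect_setequal(half$transcript_id, scores$transcript_id)

  expect_error(stratify(scores, 0.6), "\\(0, 0.5]")
})

test_that("stratification breaks ties lexicographically and ignores row order", {
  scores <- tibble::tibble(
    transcript_id = c("b", "a", "c", "d"), score = c(1, 1, 0, 0.5)
  )
  sets <- stratify(scores, 0.25)
  expect_equal(sets$transcript_id[sets$set == "hs"], "a")

  set.seed(52)
  big <- tibble::tibble(transcript_id = sprintf("t%03d", 1:40), score = runif(40))
  shuffled <- big[sample(nrow(big)), ]
  expect_equal(
    dplyr::arrange(stratify(big, 0.3), set, transcript_id),
    dplyr::arrange(stratify(shuffled, 0.3), set, transcript_id)
  )
})

test_that("ks comparison matches hand values and the ECDF-sweep oracle", {
  same <- ks_compare(1:20, 1:20)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  set.seed(53)
  expect_equal(ks_compare(rnorm(1000), rnorm(1000) + 100)$statistic, 1)

  expect_equal(ks_compare(c(1, 2, 3), c(2, 3, 4))$statistic, 1 / 3)

  for (i in 1:25) {
    a <- sample(1:30, sample(3:50, 1), replace = TRUE)
    b <- sample(1:30, sample(3:50, 1), replace = TRUE)
    expect_equal(ks_compare(a, b)$statistic, oracle_ks_d(a, b))
  }

  expect_error(ks_compare(numeric(), 1:3), "non-empty")
})

test_that("noiseless exponential data is recovered to numerical precision", {
  d <- tibble::tibble(x = seq(0, 1, length.out = 50))
  d$y <- exp(-0.75 + 0.67 * d$x)
  fit <- fit_binder_model(d, model = "exponential")
  expect_equal(fit$alpha, -0.75, tolerance = 1e-6)
  expect_equal(fit$beta, 0.67, tolerance = 1e-6)
  expect_lt(fit$rss, 1e-10)

  flat <- tibble::tibble(x = seq(0, 1, length.out = 20), y = 3)
  ffit <- fit_binder_model(flat, model = "exponential")
  expect_equal(ffit$alpha, log(3), tolerance = 1e-6)
  expect_equal(ffit$beta, 0, tolerance = 1e-6)
})

test_that("noiseless reciprocal data is recovered to numerical precision", {
  d <- tibble::tibble(x = seq(0, 0.1, length.out = 50))
  d$y <- 1 / (2.60 + 87.36 * d$x)
  fit <- fit_binder_model(d, model = "reciprocal")
  expect_equal(fit$alpha, 2.60, tolerance = 1e-4)
  expect_equal(fit$beta, 87.36, tolerance = 1e-2)

  flat <- tibble::tibble(x = seq(0, 1, length.out = 20), y = 1 / 4)
  ffit <- fit_binder_model(flat, model = "reciprocal")
  expect_equal(ffit$alpha, 4, tolerance = 1e-6)
  expect_equal(ffit$beta, 0, tolerance = 1e-4)
})

test_that("refined fits never sit above their linearized initializer", {
  set.seed(54)
  for (i in 1:10) {
    d <- tibble::tibble(x = runif(200))
    d$y <- rpois(200, exp(0.5 + 1.2 * d$x))
    fit <- fit_binder_model(d, model = "exponential")
    init <- unname(coef(lm(log(y + 1) ~ x, data = d)))
    rss_init <- sum((d$y - exp(init[1] + init[2] * d$x))^2)
    expect_lte(fit$rss, rss_init + 1e-8)
  }
})

test_that("poisson-loss exponential fit matches a log-link GLM", {
  set.seed(55)
  d <- tibble::tibble(x = runif(500))
  d$y <- rpois(500, exp(0.2 + 1.5 * d$x))
  fit <- fit_binder_model(d, model = "exponential", loss = "poisson")
  ref <- glm(y ~ x, family = poisson(), data = d)
  expect_equal(fit$alpha, unname(coef(ref))[1])
  expect_equal(fit$beta, unname(coef(ref))[2])
  expect_error(
    fit_binder_model(d, model = "reciprocal", loss = "poisson"),
    "exponential"
  )
})

test_that("binder fits expose broom-style methods and predictions", {
  d <- tibble::tibble(x = seq(0, 1, length.out = 30))
  d$y <- exp(0.1 + 0.9 * d$x)
  fit <- fit_binder_model(d, model = "exponential")
  td <- tidy(fit)
  expect_equal(td$term, c("alpha", "beta"))
  expect_equal(td$estimate, c(0.1, 0.9), tolerance = 1e-5)
  gl <- glance(fit)
  expect_equal(gl$n, 30L)
  expect_equal(gl$model, "exponential")
  expect_equal(predict(fit, tibble::tibble(x = 0)), exp(0.1), tolerance = 1e-5)
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
})

test_that("greedy clustering groups by global-alignment identity", {
  s <- paste(rep("ACGUACGUGG", 12), collapse = "")
  two_same <- c(a = s, b = s)
  cl <- cluster_sequences(two_same)
  expect_equal(dplyr::n_distinct(cl$cluster_id), 1)

  # mutate 20% of positions: identity ~0.8, below the 0.85 threshold
  set.seed(56)
  chars <- strsplit(s, "")[[1]]
  idx <- sample(length(chars), round(0.2 * length(chars)))
  chars[idx] <- vapply(
    chars[idx],
    function(b) sample(setdiff(c("A", "C", "G", "U"), b), 1), character(1)
  )
  far <- paste(chars, collapse = "")
  expect_lt(pairwise_identity(s, far), 0.85)
  expect_equal(dplyr::n_distinct(cluster_sequences(c(a = s, b = far))$cluster_id), 2)

  # a single substitution in 120 nt: ~99% identity, clusters together
  near <- sub("^A", "G", s)
  expect_gt(pairwise_identity(s, near), 0.99)
  expect_equal(dplyr::n_distinct(cluster_sequences(c(a = s, b = near))$cluster_id), 1)
})

test_that("every cluster member matches its representative at threshold", {
  sim <- simulate_paralog_clusters(n_clusters = 12, seed = 57)
  cl <- cluster_sequences(sim$sequences)
  reps <- cl[cl$representative, c("cluster_id", "transcript_id")]
  for (i in seq_len(nrow(cl))) {
    rep_id <- reps$transcript_id[reps$cluster_id == cl$cluster_id[i]]
    expect_gte(
      pairwise_identity(sim$sequences[[rep_id]], sim$sequences[[cl$transcript_id[i]]]),
      0.85
    )
  }
})

test_that("paralog correlations flag structure-favoured family members", {
  # two-member family: more structure (lower DMS), more binders -> r = -1
  clusters <- tibble::tibble(
    cluster_id = "globin", transcript_id = c("HBG1like", "HBG2like")
  )
  scores <- tibble::tibble(
    transcript_id = c("HBG1like", "HBG2like"), score = c(0.04, 0.07)
  )
  counts <- tibble::tibble(
    transcript_id = c("HBG1like", "HBG2like"), n_binders = c(29, 14)
  )
  rep <- paralog_correlation(clusters, scores, counts)
  expect_equal(rep$pearson_r, -1)
  expect_equal(fraction_negative(rep), 1)

  # members without data are dropped; clusters falling under 2 are excluded
  clusters2 <- dplyr::bind_rows(
    clusters,
    tibble::tibble(cluster_id = "partial", transcript_id = c("u1", "u2"))
  )
  scores2 <- dplyr::bind_rows(scores, tibble::tibble(transcript_id = "u1", score = 0.1))
  rep2 <- paralog_correlation(clusters2, scores2, counts)
  expect_equal(rep2$cluster_id, "globin")
})

test_that("planted negative-correlation fractions are recovered", {
  sim <- simulate_paralog_clusters(n_clusters = 40, frac_negative = 1, seed = 58)
  rep <- paralog_correlation(
    dplyr::rename(sim$truth, cluster = cluster_id) |>
      dplyr::select(cluster_id = cluster, transcript_id),
    sim$structure_scores, sim$binder_counts
  )
  expect_equal(fraction_negative(rep), 1)
})
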