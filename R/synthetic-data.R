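# run expr under a temporary RNG state when a seed is given
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
      abort("seed must be a single integer")
    }
    old <- globalenv()$.Random.seed
    on.exit(restore_seed(old), add = TRUE)
    set.seed(seed)
  }
  expr
}

#' Simulate per-nucleotide structure-probing profiles
#'
#' Generates a cohort of transcripts with known per-nucleotide pairing states
#' and emits matched PARS-type (paired double-/single-strand nuclease read
#' counts) and DMS-type (reactivity read counts) profiles, so that
#' transcript-level content scores can be checked against the planted
#' double-stranded fractions.
#'
#' Each nucleotide is double-stranded with the transcript's
#' `true_ds_fraction`. Reads are Poisson with a state-dependent rate split:
#' a double-stranded nucleotide draws `ds_reads ~ Pois(depth * 0.9)` and
#' `ss_reads ~ Pois(depth * 0.1)` (and vice versa), while DMS reads are high
#' on *single*-stranded nucleotides (`Pois(depth * 0.9)`), matching the
#' inverted DMS convention.
#'
#' @param n_transcripts Number of transcripts (>= 1).
#' @param read_depth Mean reads per nucleotide (> 0).
#' @param length_range Transcript length range (nt), inclusive.
#' @param ds_fraction Either `NULL` (per-transcript fractions drawn uniformly
#'   on `[0.05, 0.95]`), a single value, or a vector of length
#'   `n_transcripts`.
#' @param utr_fraction Fraction of the length annotated as 5'- and as 3'-UTR.
#' @param rate_split Read-rate fraction directed to the state-concordant
#'   channel (default 0.9).
#' @param seed Optional integer seed; identical seeds give identical output.
#' @return A list of tibbles: `transcripts` (id, length, true_ds_fraction,
#'   utr5_end, cds_end, and the per-nucleotide state as a list-column),
#'   `pars` (transcript_id, position, ds_reads, ss_reads), `dms`
#'   (transcript_id, position, reads), and `annotations` (UTR intervals as
#'   consumed by [exclude_regions()]).
#' @export
simulate_structure_profiles <- function(n_transcripts = 100, read_depth = 50,
                                        length_range = c(200, 1000),
                                        ds_fraction = NULL, utr_fraction = 0.1,
                                        rate_split = 0.9, seed = NULL) {
  if (n_transcripts < 1) abort("n_transcripts must be >= 1")
  if (read_depth <= 0) abort("read_depth must be > 0")
  if (utr_fraction < 0 || utr_fraction > 0.5) abort("utr_fraction must be in [0, 0.5]")
  if (rate_split <= 0.5 || rate_split > 1) abort("rate_split must be in (0.5, 1]")
  if (!is.null(ds_fraction)) {
    if (any(ds_fraction < 0 | ds_fraction > 1)) abort("ds_fraction must lie in [0, 1]")
    if (!length(ds_fraction) %in% c(1, n_transcripts)) {
      abort("ds_fraction must have length 1 or n_transcripts")
    }
  }

  with_seed(seed, {
    lens <- sample(length_range[1]:length_range[2], n_transcripts, replace = TRUE)
    fracs <- if (is.null(ds_fraction)) {
      runif(n_transcripts, 0.05, 0.95)
    } else {
      rep_len(ds_fraction, n_transcripts)
    }
    ids <- sprintf("tx%04d", seq_len(n_transcripts))

    states <- purrr::map2(lens, fracs, \(l, f) rbinom(l, 1, f))
    transcripts <- tibble::tibble(
      transcript_id = ids,
      length = lens,
      true_ds_fraction = fracs,
      utr5_end = floor(utr_fraction * lens),
      cds_end = lens - floor(utr_fraction * lens),
      per_nt_state = states
    )

    per_nt <- tibble::tibble(
      transcript_id = rep(ids, lens),
      position = unlist(purrr::map(lens, \(l) seq_len(l) - 1L)),
      state = unlist(states)
    )
    w <- ifelse(per_nt$state == 1, rate_split, 1 - rate_split)
    pars <- tibble::tibble(
      transcript_id = per_nt$transcript_id,
      position = per_nt$position,
      ds_reads = rpois(nrow(per_nt), read_depth * w),
      ss_reads = rpois(nrow(per_nt), read_depth * (1 - w))
    )
    dms <- tibble::tibble(
      transcript_id = per_nt$transcript_id,
      position = per_nt$position,
      reads = rpois(nrow(per_nt), read_depth * (1 - w))
    )
    annotations <- tibble::tibble(
      transcript_id = ids,
      utr5_start = 0L, utr5_end = transcripts$utr5_end,
      utr3_start = transcripts$cds_end, utr3_end = lens
    )
    list(
      transcripts = transcripts, pars = pars, dms = dms,
      annotations = annotations
    )
  })
}

#' Simulate a CLIP peak table with a planted binder-count law
#'
#' Plants the structure-to-binders relationship: each transcript's number of
#' distinct above-threshold binders is Poisson with mean `f(x)` where `x` is
#' its structural content and `f` is `exp(alpha + beta x)` or
#' `1/(alpha + beta x)`. Distinct RBP identities are sampled without
#' replacement per transcript. Sub-threshold decoy peaks (both significance
#' and enrichment below the standard cut-offs) are added so that peak
#' filtering is exercised, and a fraction of planted peaks is duplicated in a
#' second cell line to exercise unique-binder counting.
#'
#' @param transcripts A data frame with `transcript_id` and `content` (the
#'   structural content `x`), e.g. a [structure_content()] result.
#' @param alpha,beta Coefficients of the planted law.
#' @param model `"exponential"` or `"reciprocal"`.
#' @param n_rbps Size of the RBP universe; must exceed every drawn binder
#'   count, otherwise generation fails.
#' @param decoy_rate Mean number of decoy (sub-threshold) peaks per
#'   transcript.
#' @param duplicate_prob Probability that a planted peak is repeated in the
#'   second cell line.
#' @param seed Optional integer seed.
#' @return A peak tibble: `transcript_id`, `rbp_id`, `cell_line`,
#'   `neglog10_p`, `log2_fe`, and a `planted` flag (`TRUE` for the
#'   above-threshold peaks encoding the law).
#' @export
simulate_clip_peaks <- function(transcripts, alpha = -0.75, beta = 0.67,
                                model = c("exponential", "reciprocal"),
                                n_rbps = 200, decoy_rate = 2,
                                duplicate_prob = 0.3, seed = NULL) {
  model <- match.arg(model)
  check_profile_cols(transcripts, c("transcript_id", "content"))
  if (n_rbps < 1) abort("n_rbps must be >= 1")

  x <- transcripts$content
  mu <- if (model == "exponential") {
    exp(alpha + beta * x)
  } else {
    denom <- alpha + beta * x
    if (any(denom <= 0)) abort("reciprocal law non-positive over the contents supplied")
    1 / denom
  }

  with_seed(seed, {
    rbp_universe <- sprintf("RBP%03d", seq_len(n_rbps))
    counts <- rpois(length(mu), mu)
    if (any(counts > n_rbps)) {
      abort("drawn binder count exceeds n_rbps; enlarge the RBP universe")
    }
    peaks <- purrr::map2(transcripts$transcript_id, counts, function(id, k) {
      if (k == 0) {
        return(NULL)
      }
      tibble::tibble(
        transcript_id = id,
        rbp_id = sample(rbp_universe, k),
        cell_line = "K562",
        neglog10_p = runif(k, 6, 12),
        log2_fe = runif(k, 3.5, 8),
        planted = TRUE
      )
    }) |>
      dplyr::bind_rows()

    if (nrow(peaks) > 0) {
      dup <- peaks[runif(nrow(peaks)) < duplicate_prob, , drop = FALSE]
      dup$cell_line <- "HepG2"
      peaks <- dplyr::bind_rows(peaks, dup)
    }

    n_decoys <- rpois(length(mu), decoy_rate)
    decoys <- purrr::map2(transcripts$transcript_id, n_decoys, function(id, k) {
      if (k == 0) {
        return(NULL)
      }
      tibble::tibble(
        transcript_id = id,
        rbp_id = sample(rbp_universe, k, replace = TRUE),
        cell_line = sample(c("K562", "HepG2"), k, replace = TRUE),
        neglog10_p = runif(k, 0, 5),
        log2_fe = runif(k, -2, 3),
        planted = FALSE
      )
    }) |>
      dplyr::bind_rows()

    dplyr::bind_rows(peaks, decoys)
  })
}

#' Simulate toy protein-RNA complex geometries
#'
#' Generates 3D complexes whose intra-RNA and RNA-protein contact densities
#' are positively coupled: each complex draws a latent compaction factor and
#' both chains are placed uniformly in a box whose volume shrinks with it, so
#' denser RNA packing (more internal contacts) comes with a denser interface
#' (more external contacts). With `contact_level = 0` the atoms are placed on
#' a sparse grid with every pairwise distance above the contact cutoff, so
#' all counts are zero.
#'
#' @param n Number of complexes (>= 1).
#' @param contact_level Non-negative overall contact density multiplier.
#' @param rna_length_range,protein_length_range Chain length ranges.
#' @param seed Optional integer seed.
#' @return A list: `coordinates` (tibble `complex_id`, `chain`,
#'   `residue_index`, `x`, `y`, `z`) and `truth` (tibble `complex_id`,
#'   `compaction`).
#' @export
simulate_complexes <- function(n, contact_level = 1,
                               rna_length_range = c(10, 30),
                               protein_length_range = c(15, 45),
                               seed = NULL) {
  if (n < 1) abort("n must be >= 1")
  if (contact_level < 0) abort("contact_level must be non-negative")

  with_seed(seed, {
    out <- purrr::map(seq_len(n), function(i) {
      cid <- sprintf("cplx%04d", i)
      l_rna <- sample(rna_length_range[1]:rna_length_range[2], 1)
      l_prot <- sample(protein_length_range[1]:protein_length_range[2], 1)

      if (contact_level == 0) {
        # all atoms on one line, 20 A apart: no pair under any sane cutoff
        idx <- seq_len(l_rna + l_prot)
        coords <- tibble::tibble(
          complex_id = cid,
          chain = rep(c("rna", "protein"), c(l_rna, l_prot)),
          residue_index = c(seq_len(l_rna), seq_len(l_prot)),
          x = 20 * idx, y = 0, z = 0
        )
        return(list(coords = coords, compaction = 0))
      }

      u <- runif(1, 0.3, 3) # latent compaction shared by both chains
      # box volume chosen so expected internal contacts ~ contact_level * u * l_rna
      v_sphere <- 4 / 3 * pi * 7^3
      target_internal <- contact_level * u * l_rna
      volume <- choose(l_rna, 2) * v_sphere / target_internal
      side <- volume^(1 / 3)
      coords <- tibble::tibble(
        complex_id = cid,
        chain = rep(c("rna", "protein"), c(l_rna, l_prot)),
        residue_index = c(seq_len(l_rna), seq_len(l_prot)),
        x = runif(l_rna + l_prot, 0, side),
        y = runif(l_rna + l_prot, 0, side),
        z = runif(l_rna + l_prot, 0, side)
      )
      list(coords = coords, compaction = u)
    })
    list(
      coordinates = dplyr::bind_rows(purrr::map(out, "coords")),
      truth = tibble::tibble(
        complex_id = sprintf("cplx%04d", seq_len(n)),
        compaction = purrr::map_dbl(out, "compaction")
      )
    )
  })
}

#' Simulate a label-free-quantification condensate experiment
#'
#' Emulates the RNA-driven remodelling of a precipitated protein assembly:
#' a 3-condition (background, HS-RNA, LS-RNA) x `n_replicates` LFQ intensity
#' matrix with planted `released` (HS intensity lowered), `kept` (raised) and
#' `static` proteins, random missing values, and a per-protein interaction
#' score drawn so that the score separates released from non-released
#' proteins with a planted ROC AUC.
#'
#' Scores for non-released proteins are standard normal; released proteins
#' are shifted by `sqrt(2) * qnorm(planted_auc)`, the shift giving that exact
#' expected AUC for two unit-variance normals. `planted_auc = 1` places the
#' two groups on disjoint ranges.
#'
#' @param n_proteins Number of proteins.
#' @param frac_released,frac_kept Fractions of released/kept proteins
#'   (non-negative, summing to at most 1).
#' @param effect_size Planted intensity shift, in log2 units (1 = 2-fold).
#' @param noise_sd Replicate noise standard deviation on the log2 scale.
#' @param planted_auc Target AUC of the interaction score, in `(0.5, 1]`.
#' @param missing_rate Probability that any cell is missing.
#' @param n_replicates Replicates per condition.
#' @param seed Optional integer seed.
#' @return A list: `lfq` (wide intensity tibble on the raw scale),
#'   `scores` (tibble `protein_id`, `score`), `truth` (tibble `protein_id`,
#'   `label`).
#' @export
simulate_lfq_experiment <- function(n_proteins = 500, frac_released = 0.15,
                                    frac_kept = 0.05, effect_size = 1,
                                    noise_sd = 0.05, planted_auc = 0.8,
                                    missing_rate = 0.1, n_replicates = 4,
                                    seed = NULL) {
  if (n_proteins < 1 || n_replicates < 2) abort("need proteins and >= 2 replicates")
  if (frac_released < 0 || frac_kept < 0 || frac_released + frac_kept > 1) {
    abort("released/kept fractions must be non-negative and sum to at most 1")
  }
  if (planted_auc <= 0.5 || planted_auc > 1) abort("planted_auc must lie in (0.5, 1]")
  if (missing_rate < 0 || missing_rate >= 1) abort("missing_rate must lie in [0, 1)")

  with_seed(seed, {
    ids <- sprintf("prot%04d", seq_len(n_proteins))
    n_rel <- round(frac_released * n_proteins)
    n_kept <- round(frac_kept * n_proteins)
    label <- rep("static", n_proteins)
    label[seq_len(n_rel)] <- "released"
    label[n_rel + seq_len(n_kept)] <- "kept"
    label <- sample(label) # shuffle so labels are not positional

    base <- runif(n_proteins, 22, 30) # log2 baseline intensity
    shift <- dplyr::case_when(
      label == "released" ~ -effect_size,
      label == "kept" ~ effect_size,
      .default = 0
    )

    cols <- tidyr::expand_grid(
      condition = LFQ_CONDITIONS,
      replicate = seq_len(n_replicates)
    )
    mat <- purrr::pmap(cols, function(condition, replicate) {
      mu <- base + if (condition == "hs_rna") shift else 0
      vals <- 2^(mu + rnorm(n_proteins, 0, noise_sd))
      vals[runif(n_proteins) < missing_rate] <- NA_real_
      vals
    })
    names(mat) <- paste0(cols$condition, "_", cols$replicate)
    lfq <- dplyr::bind_cols(tibble::tibble(protein_id = ids), tibble::as_tibble(mat))

    released <- label == "released"
    score <- if (planted_auc == 1) {
      ifelse(released, runif(n_proteins, 10, 11), runif(n_proteins, 0, 1))
    } else {
      rnorm(n_proteins) + ifelse(released, sqrt(2) * qnorm(planted_auc), 0)
    }

    list(
      lfq = lfq,
      scores = tibble::tibble(protein_id = ids, score = score),
      truth = tibble::tibble(protein_id = ids, label = label)
    )
  })
}

#' Simulate paralog sequence clusters with planted correlations
#'
#' Builds families of near-identical transcript sequences (each member a
#' point-mutated copy of a cluster seed sequence, so within-cluster identity
#' stays above the clustering threshold while unrelated clusters stay well
#' below it) and assigns structure scores and binder counts so that a chosen
#' fraction of clusters has a strictly negative structure/binder-count
#' correlation and the rest a strictly positive one.
#'
#' @param n_clusters Number of clusters (>= 1).
#' @param frac_negative Fraction of clusters planted with negative
#'   correlation, in `[0, 1]`.
#' @param members_range Number of member sequences per cluster.
#' @param seq_length_range Seed sequence length range (nt).
#' @param mutation_rate Per-position substitution probability for members.
#' @param seed Optional integer seed.
#' @return A list: `sequences` (named character vector),
#'   `structure_scores` (tibble `transcript_id`, `score`; DMS-like, higher =
#'   less structured), `binder_counts` (tibble `transcript_id`,
#'   `n_binders`), and `truth` (tibble `cluster_id`, `transcript_id`,
#'   `planted_negative`).
#' @export
simulate_paralog_clusters <- function(n_clusters = 100, frac_negative = 0.64,
                                      members_range = c(2, 4),
                                      seq_length_range = c(200, 400),
                                      mutation_rate = 0.05, seed = NULL) {
  if (n_clusters < 1) abort("n_clusters must be >= 1")
  if (frac_negative < 0 || frac_negative > 1) abort("frac_negative must lie in [0, 1]")
  if (mutation_rate < 0 || mutation_rate > 0.5) abort("mutation_rate must lie in [0, 0.5]")

  alphabet <- c("A", "C", "G", "U")
  with_seed(seed, {
    n_neg <- round(frac_negative * n_clusters)
    negative <- sample(rep(c(TRUE, FALSE), c(n_neg, n_clusters - n_neg)))

    out <- purrr::map(seq_len(n_clusters), function(ci) {
      m <- sample(members_range[1]:members_range[2], 1)
      len <- sample(seq_length_range[1]:seq_length_range[2], 1)
      seed_seq <- sample(alphabet, len, replace = TRUE)
      members <- purrr::map_chr(seq_len(m), function(j) {
        mutate_at <- runif(len) < mutation_rate
        s <- seed_seq
        if (any(mutate_at)) {
          s[mutate_at] <- vapply(
            s[mutate_at],
            function(b) sample(setdiff(alphabet, b), 1),
            character(1)
          )
        }
        paste(s, collapse = "")
      })
      ids <- sprintf("cl%03d_tx%d", ci, seq_len(m))

      # distinct DMS-like scores; counts strictly monotone in score,
      # decreasing for planted-negative clusters, so the correlation sign
      # is guaranteed
      scores <- sort(runif(m, 0.02, 0.2))
      counts <- sort(sample(5:60, m))
      if (negative[ci]) counts <- rev(counts)

      list(
        sequences = setNames(members, ids),
        scores = tibble::tibble(transcript_id = ids, score = scores),
        counts = tibble::tibble(transcript_id = ids, n_binders = counts),
        truth = tibble::tibble(
          cluster_id = sprintf("planted_%03d", ci),
          transcript_id = ids, planted_negative = negative[ci]
        )
      )
    })

    list(
      sequences = purrr::reduce(purrr::map(out, "sequences"), c),
      structure_scores = dplyr::bind_rows(purrr::map(out, "scores")),
      binder_counts = dplyr::bind_rows(purrr::map(out, "counts")),
      truth = dplyr::bind_rows(purrr::map(out, "truth"))
    )
  })
}
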