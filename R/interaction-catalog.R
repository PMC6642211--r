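#' Filter CLIP peaks at significance and enrichment cut-offs
#'
#' Retains input-normalized CLIP peaks passing stringent cut-offs on both
#' significance and fold enrichment over the size-matched input:
#' `-log10(p) > 5` and `log2(fold enrichment) > 3` by default, which selects
#' roughly the top tier of reproducible protein-RNA contacts. Both
#' comparisons are strict.
#'
#' @param peaks A data frame with at least `transcript_id`, `rbp_id`,
#'   `neglog10_p` and `log2_fe` columns. Extra columns (e.g. `cell_line`) are
#'   carried through.
#' @param min_neglog10_p,min_log2_fe Strict lower thresholds.
#' @return The retained rows, original order preserved.
#' @examples
#' peaks <- tibble::tibble(
#'   transcript_id = "tx1", rbp_id = letters[1:5],
#'   neglog10_p = c(6, 6, 4, 5, 7), log2_fe = c(4, 2, 4, 3, 3.01)
#' )
#' filter_peaks(peaks) # retains rows 1 and 5
#' @export
filter_peaks <- function(peaks, min_neglog10_p = 5, min_log2_fe = 3) {
  check_profile_cols(peaks, c("transcript_id", "rbp_id", "neglog10_p", "log2_fe"))
  if (anyNA(c(min_neglog10_p, min_log2_fe)) ||
    max(min_neglog10_p, min_log2_fe) == Inf) {
    abort("thresholds must be finite or -Inf")
  }
  dplyr::filter(
    peaks,
    .data$neglog10_p > min_neglog10_p, .data$log2_fe > min_log2_fe
  )
}

#' Count distinct protein binders per transcript
#'
#' Tallies the number of distinct RNA-binding proteins with at least one
#' (already filtered) peak on each transcript. Peaks for the same RBP in
#' different cell lines or replicates count once: the tally is a unique-RBP
#' count, merged across cell lines by union.
#'
#' @param peaks A filtered peak table with `transcript_id` and `rbp_id`.
#' @param transcript_ids Optional character vector of transcripts that must
#'   appear in the output; transcripts with no peaks get `n_binders = 0`.
#' @return A tibble with `transcript_id`, `n_binders`, and `rbp_ids`
#'   (list-column of the distinct binder identifiers).
#' @export
count_binders <- function(peaks, transcript_ids = NULL) {
  check_profile_cols(peaks, c("transcript_id", "rbp_id"))
  counts <- peaks |>
    dplyr::distinct(.data$transcript_id, .data$rbp_id) |>
    dplyr::group_by(.data$transcript_id) |>
    dplyr::summarise(
      n_binders = dplyr::n(),
      rbp_ids = list(sort(.data$rbp_id)),
      .groups = "drop"
    )
  if (!is.null(transcript_ids)) {
    counts <- tibble::tibble(transcript_id = unique(transcript_ids)) |>
      dplyr::left_join(counts, by = "transcript_id") |>
      dplyr::mutate(
        n_binders = dplyr::coalesce(.data$n_binders, 0L),
        rbp_ids = purrr::map(.data$rbp_ids, \(x) x %||% character())
      )
  }
  counts
}

#' Classify an RNA-binding protein's structure preference
#'
#' Compares the structural-content scores of an RBP's target transcripts with
#' a background transcriptome. The RBP is called `high_structured` when the
#' median target score exceeds the background median with p <= `alpha`,
#' `low_structured` for the symmetric case, and `no_preference` otherwise.
#' Scores must be on a scale where higher means more structured; negate DMS
#' scores before calling (high DMS reactivity marks single-stranded regions).
#'
#' @param target_scores,background_scores Numeric score vectors. At least 3
#'   targets are required.
#' @param rbp_id Identifier carried into the output.
#' @param alpha Significance level for the preference call.
#' @param test `"wilcox"` (two-sided Mann-Whitney U, default) or `"ks"`.
#' @return A one-row tibble: `rbp_id`, `label`, `p_value`, `median_targets`,
#'   `median_background`.
#' @export
classify_preference <- function(target_scores, background_scores,
                                rbp_id = NA_character_, alpha = 0.01,
                                test = c("wilcox", "ks")) {
  test <- match.arg(test)
  target_scores <- target_scores[!is.na(target_scores)]
  background_scores <- background_scores[!is.na(background_scores)]
  if (length(target_scores) < 3) abort("need at least 3 target scores")
  if (length(background_scores) == 0) abort("empty background")

  p <- if (test == "wilcox") {
    suppressWarnings(wilcox.test(target_scores, background_scores)$p.value)
  } else {
    suppressWarnings(ks.test(target_scores, background_scores)$p.value)
  }
  m_t <- median(target_scores)
  m_b <- median(background_scores)
  label <- if (p <= alpha && m_t > m_b) {
    "high_structured"
  } else if (p <= alpha && m_t < m_b) {
    "low_structured"
  } else {
    "no_preference"
  }
  tibble::tibble(
    rbp_id = rbp_id, label = label, p_value = p,
    median_targets = m_t, median_background = m_b
  )
}

#' Empirical significance of the overlap between two binder sets
#'
#' Tests whether the observed overlap between two sets of proteins (e.g. the
#' eCLIP binders of two transcripts) is larger than expected by chance, by
#' drawing `n_samples` random subsets of size `|set_b|` from the binder
#' universe and counting how often the random overlap with `set_a` reaches
#' the observed one. The add-one estimator
#' `p = (1 + #{draws >= observed}) / (n_samples + 1)` avoids a literal zero
#' from finite sampling.
#'
#' @param set_a,set_b Character vectors, both subsets of `universe`.
#' @param universe Character vector of all candidate binders.
#' @param n_samples Number of random draws.
#' @param seed Optional integer seed for reproducible draws.
#' @return A single empirical p-value in `[1/(n_samples+1), 1]`.
#' @export
empirical_overlap_p <- function(set_a, set_b, universe, n_samples = 1000,
                                seed = NULL) {
  set_a <- unique(set_a)
  set_b <- unique(set_b)
  universe <- unique(universe)
  if (!all(set_a %in% universe) || !all(set_b %in% universe)) {
    abort("set_a and set_b must be subsets of the universe")
  }
  if (length(set_b) > length(universe)) {
    abort("set_b larger than the universe")
  }
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restore_seed(old), add = TRUE)
    set.seed(seed)
  }
  observed <- length(intersect(set_a, set_b))
  hits <- sum(vapply(
    seq_len(n_samples),
    function(i) {
      draw <- sample(universe, length(set_b))
      length(intersect(set_a, draw)) >= observed
    },
    logical(1)
  ))
  (1 + hits) / (n_samples + 1)
}

# put the RNG state back so seeded helpers do not perturb callers
restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
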