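LFQ_CONDITIONS <- c("background", "hs_rna", "ls_rna")

# wide LFQ table -> long (protein_id, condition, replicate, intensity)
lfq_long <- function(lfq) {
  check_profile_cols(lfq, "protein_id")
  value_cols <- setdiff(names(lfq), "protein_id")
  cond <- sub("_[0-9]+$", "", value_cols)
  bad <- value_cols[!cond %in% LFQ_CONDITIONS]
  if (length(bad) > 0) {
    abort(paste0(
      "intensity columns must be named <condition>_<replicate> with condition ",
      "one of ", paste(LFQ_CONDITIONS, collapse = "/"), "; offending: ",
      paste(head(bad, 5), collapse = ", ")
    ))
  }
  lfq |>
    tidyr::pivot_longer(-"protein_id",
      names_to = c("condition", "replicate"),
      names_pattern = "(.*)_([0-9]+)$", values_to = "intensity"
    )
}

#' Filter proteins quantifiable in at least one condition
#'
#' Keeps proteins with at least `min_valid` non-missing label-free
#' quantification (LFQ) intensities in at least one condition group — the
#' standard quantifiability rule for a 3-condition, 4-replicate design.
#'
#' @param lfq A wide LFQ table: a `protein_id` column plus intensity columns
#'   named `<condition>_<replicate>` with conditions `background`, `hs_rna`,
#'   `ls_rna` (e.g. `background_1` ... `ls_rna_4`). Missing values are `NA`.
#' @param min_valid Minimum number of valid values in some condition.
#' @return The retained rows of `lfq`.
#' @export
quantifiable_filter <- function(lfq, min_valid = 3) {
  keep <- lfq_long(lfq) |>
    dplyr::group_by(.data$protein_id, .data$condition) |>
    dplyr::summarise(n_valid = sum(!is.na(.data$intensity)), .groups = "drop_last") |>
    dplyr::summarise(ok = max(.data$n_valid) >= min_valid, .groups = "drop")
  lfq[lfq$protein_id %in% keep$protein_id[keep$ok], , drop = FALSE]
}

#' Per-protein differential intensity between an RNA condition and background
#'
#' For each protein, compares intensities in the chosen RNA condition with the
#' background (no RNA) condition by a two-sample t-test on log-transformed
#' intensities (Welch's unequal-variance variant by default), and reports the
#' mean log-ratio `mean(log RNA) - mean(log background)`. Proteins with fewer
#' than two valid values on either side — or with zero variance on both
#' sides, where the t statistic is undefined — are flagged untestable
#' (`p_value = NA`).
#'
#' @param lfq A wide LFQ table (see [quantifiable_filter()]), normally
#'   already filtered.
#' @param rna_condition `"hs_rna"` or `"ls_rna"`.
#' @param log_base Base of the log transform and the reported ratio
#'   (default 2).
#' @param log_transform Set `FALSE` to test raw intensities.
#' @param test `"welch"` (default) or `"student"`.
#' @return A tibble per protein: `protein_id`, `condition`, `log_ratio`,
#'   `p_value`, `neglog_p` (`-log10 p`), `testable`.
#' @export
lfq_differential <- function(lfq, rna_condition = c("hs_rna", "ls_rna"),
                             log_base = 2, log_transform = TRUE,
                             test = c("welch", "student")) {
  rna_condition <- match.arg(rna_condition)
  test <- match.arg(test)
  long <- lfq_long(lfq) |>
    dplyr::filter(.data$condition %in% c("background", rna_condition), !is.na(.data$intensity))
  if (log_transform && any(long$intensity <= 0)) {
    abort("intensities must be positive for the log transform")
  }
  if (log_transform) long$intensity <- log(long$intensity, base = log_base)

  long |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::group_map(function(g, key) {
      rna <- g$intensity[g$condition == rna_condition]
      bg <- g$intensity[g$condition == "background"]
      testable <- length(rna) >= 2 && length(bg) >= 2
      log_ratio <- if (length(rna) > 0 && length(bg) > 0) mean(rna) - mean(bg) else NA_real_
      p <- NA_real_
      if (testable) {
        p <- tryCatch(
          t.test(rna, bg, var.equal = (test == "student"))$p.value,
          error = function(e) NA_real_ # zero variance on both sides
        )
        testable <- !is.na(p)
      }
      tibble::tibble(
        protein_id = key$protein_id, condition = rna_condition,
        log_ratio = log_ratio, p_value = p,
        neglog_p = -log10(p), testable = testable
      )
    }) |>
    dplyr::bind_rows()
}

#' Classify proteins as released, kept or static
#'
#' Applies the release rule to a differential result for one RNA condition:
#' a protein is `released` when its intensity in the RNA-containing
#' precipitate drops significantly (`-log10 p > 1.3`, i.e. p < 0.05, and
#' negative log-ratio), `kept` when it rises significantly, `static`
#' otherwise, and `unquantified` when the test was not possible.
#'
#' @param diff An [lfq_differential()] result.
#' @param sig_neglog_p Significance threshold on `-log10 p` (1.3 = p 0.05).
#' @return `diff` with a `label` column appended.
#' @export
classify_release <- function(diff, sig_neglog_p = 1.3) {
  check_profile_cols(diff, c("protein_id", "log_ratio", "neglog_p", "testable"))
  dplyr::mutate(
    diff,
    label = dplyr::case_when(
      !.data$testable ~ "unquantified",
      .data$neglog_p > sig_neglog_p & .data$log_ratio < 0 ~ "released",
      .data$neglog_p > sig_neglog_p & .data$log_ratio > 0 ~ "kept",
      .default = "static"
    )
  )
}

#' Stringency tiers of unaffected proteins
#'
#' Buckets the proteins that were *not* significantly changed by either RNA
#' into nested stringency tiers by how flat their response was: `high`
#' requires `|log_ratio| < 0.15` for both RNA conditions, `medium` `< 0.30`,
#' `low` `< 1`. Tiers are nested (`high` implies `medium` implies `low`) and
#' exclude proteins significant (`-log10 p > 1.3`) or untestable in either
#' condition.
#'
#' @param diff An [lfq_differential()] result covering both RNA conditions
#'   (bind the `hs_rna` and `ls_rna` results together).
#' @param sig_neglog_p Significance threshold on `-log10 p`.
#' @param bounds Named numeric vector of tier half-widths on `|log_ratio|`.
#' @return A tibble per protein: `protein_id`, logical `high`, `medium`,
#'   `low`.
#' @export
stringency_tiers <- function(diff, sig_neglog_p = 1.3,
                             bounds = c(high = 0.15, medium = 0.30, low = 1)) {
  check_profile_cols(diff, c("protein_id", "condition", "log_ratio", "neglog_p", "testable"))
  if (!all(c("high", "medium", "low") %in% names(bounds))) {
    abort("bounds must name high, medium and low")
  }
  diff |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::summarise(
      eligible = all(.data$testable) && all(.data$neglog_p < sig_neglog_p),
      max_abs_ratio = max(abs(.data$log_ratio)),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      high = .data$eligible & .data$max_abs_ratio < bounds[["high"]],
      medium = .data$eligible & .data$max_abs_ratio < bounds[["medium"]],
      low = .data$eligible & .data$max_abs_ratio < bounds[["low"]]
    ) |>
    dplyr::select("protein_id", "high", "medium", "low")
}

#' ROC area under the curve by the rank-sum formulation
#'
#' Computes the probability that a randomly chosen positive outscores a
#' randomly chosen negative (ties credited 1/2) — the Mann-Whitney
#' formulation of the ROC AUC. Used to evaluate how well predicted
#' interaction scores separate released from unaffected proteins.
#'
#' @param scores Named numeric vector, or data frame with `protein_id` and
#'   `score` columns.
#' @param positives,negatives Disjoint character vectors of ids; every member
#'   must have a score.
#' @return The AUC, in `[0, 1]`.
#' @examples
#' roc_auc(c(a = 3, b = 1, c = 2, d = 0), positives = c("a", "b"), negatives = c("c", "d"))
#' @export
roc_auc <- function(scores, positives, negatives) {
  if (is.data.frame(scores)) {
    check_profile_cols(scores, c("protein_id", "score"))
    scores <- setNames(scores$score, scores$protein_id)
  }
  positives <- unique(positives)
  negatives <- unique(negatives)
  if (length(positives) == 0 || length(negatives) == 0) {
    abort("both sets must be non-empty")
  }
  if (length(intersect(positives, negatives)) > 0) {
    abort("positive and negative sets overlap")
  }
  missing <- setdiff(c(positives, negatives), names(scores))
  if (length(missing) > 0) {
    abort(paste0(
      "no score for: ", paste(head(missing, 5), collapse = ", ")
    ))
  }
  s <- c(scores[positives], scores[negatives])
  r <- rank(s) # average ranks credit ties 0.5
  np <- length(positives)
  nn <- length(negatives)
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}
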