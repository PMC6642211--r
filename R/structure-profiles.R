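#' Transcript-level structural content from per-nucleotide probing data
#'
#' Aggregates per-nucleotide structure-probing evidence into one structural
#' content score per transcript, the fraction of nucleotides in double-stranded
#' conformation.
#'
#' Three kinds of evidence are supported:
#'
#' * **pars** — paired nuclease read counts per nucleotide: `ds_reads` (V1-type,
#'   double-strand-specific) and `ss_reads` (S1-type, single-strand-specific).
#'   A nucleotide counts as double-stranded when `log10(V/S) > 0`, i.e. strictly
#'   more double- than single-stranded reads; the content is the fraction of
#'   such nucleotides. Nucleotides with `V = S` (including the `0/0`
#'   undetermined case) contribute 0; `V > 0, S = 0` is the infinite-ratio
#'   limit and contributes 1. Transcripts where every nucleotide is
#'   undetermined (`V + S = 0` everywhere) are discarded with a warning.
#' * **dms** — dimethyl-sulfate reactivity read counts. Reads are normalized
#'   to the transcript's maximum and averaged over the positions present in
#'   the input (a reported zero-read position counts as covered and pulls the
#'   mean down). Note the inverted convention: high DMS signal marks
#'   *single*-stranded nucleotides, so this score *decreases* with structure.
#'   Transcripts covered on fewer than `min_coverage` of their length (default
#'   10%) are excluded with a warning, as are transcripts with no reads.
#' * **predicted** — precomputed per-nucleotide propensity scores where
#'   positive values indicate double-stranded tendency. The content is the
#'   fraction of positions with a strictly positive score.
#'
#' @param profiles A data frame of per-nucleotide values with columns
#'   `transcript_id`, `position` (0-based), and, depending on `kind`,
#'   `ds_reads` + `ss_reads` (pars), `reads` (dms), or `score` (predicted).
#' @param kind One of `"pars"`, `"dms"`, `"predicted"`.
#' @param lengths Optional data frame with columns `transcript_id` and
#'   `length` (nt). When `NULL`, the transcript length is inferred as
#'   `max(position) + 1`.
#' @param denominator For `kind = "pars"`: `"determined"` (default) divides by
#'   the number of nucleotides with at least one read (`V + S > 0`);
#'   `"full"` divides by the transcript length.
#' @param pseudocount For `kind = "pars"`: a constant added to both read
#'   counts before comparison. The default 0 uses the raw counts.
#' @param min_coverage For `kind = "dms"`: minimum fraction of the transcript
#'   length that must be covered for the transcript to be scored.
#'
#' @return A tibble with one row per scored transcript: `transcript_id`,
#'   `content` (in `[0, 1]`), `log_content` (natural log of `content`; `NA`
#'   when the content is 0), and `n_determined` (number of nucleotides that
#'   entered the score).
#'
#' @examples
#' profs <- tibble::tibble(
#'   transcript_id = "tx1", position = 0:3,
#'   ds_reads = c(10L, 1L, 5L, 0L), ss_reads = c(1L, 10L, 5L, 2L)
#' )
#' structure_content(profs, kind = "pars")
#' @export
structure_content <- function(profiles, kind = c("pars", "dms", "predicted"),
                              lengths = NULL,
                              denominator = c("determined", "full"),
                              pseudocount = 0, min_coverage = 0.1) {
  kind <- match.arg(kind)
  switch(kind,
    pars = pars_content(profiles,
      lengths = lengths,
      denominator = denominator, pseudocount = pseudocount
    ),
    dms = dms_content(profiles, lengths = lengths, min_coverage = min_coverage),
    predicted = predicted_content(profiles)
  )
}

#' @rdname structure_content
#' @export
pars_content <- function(profiles, lengths = NULL,
                         denominator = c("determined", "full"),
                         pseudocount = 0) {
  denominator <- match.arg(denominator)
  check_profile_cols(profiles, c("transcript_id", "position", "ds_reads", "ss_reads"))
  if (any(profiles$ds_reads < 0) || any(profiles$ss_reads < 0)) {
    abort("read counts must be non-negative")
  }
  lens <- resolve_lengths(profiles, lengths)

  scored <- profiles |>
    dplyr::mutate(
      determined = .data$ds_reads + .data$ss_reads > 0,
      ds_call = .data$ds_reads + pseudocount > .data$ss_reads + pseudocount
    ) |>
    dplyr::group_by(.data$transcript_id) |>
    dplyr::summarise(
      n_ds = sum(.data$ds_call),
      n_determined = sum(.data$determined),
      .groups = "drop"
    ) |>
    dplyr::left_join(lens, by = "transcript_id")

  discarded <- scored$transcript_id[scored$n_determined == 0]
  if (length(discarded) > 0) {
    warn(paste0(
      "discarding ", length(discarded),
      " transcript(s) with all nucleotides undetermined: ",
      paste(head(discarded, 5), collapse = ", ")
    ))
    scored <- scored[scored$n_determined > 0, , drop = FALSE]
  }
  if (nrow(scored) == 0) {
    abort("no transcript has any determined nucleotide")
  }

  denom <- if (denominator == "determined") scored$n_determined else scored$length
  content <- scored$n_ds / denom
  tibble::tibble(
    transcript_id = scored$transcript_id,
    content = content,
    log_content = log_content(content, quiet = TRUE),
    n_determined = scored$n_determined
  )
}

#' @rdname structure_content
#' @export
dms_content <- function(profiles, lengths = NULL, min_coverage = 0.1) {
  check_profile_cols(profiles, c("transcript_id", "position", "reads"))
  if (any(profiles$reads < 0)) abort("read counts must be non-negative")
  lens <- resolve_lengths(profiles, lengths)

  scored <- profiles |>
    dplyr::group_by(.data$transcript_id) |>
    dplyr::summarise(
      content = if (max(.data$reads) > 0) mean(.data$reads / max(.data$reads)) else NA_real_,
      n_determined = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::right_join(lens, by = "transcript_id") |>
    dplyr::mutate(n_determined = dplyr::coalesce(.data$n_determined, 0L))

  excluded <- scored$transcript_id[
    scored$n_determined < min_coverage * scored$length | is.na(scored$content)
  ]
  if (length(excluded) > 0) {
    warn(paste0(
      "excluding ", length(excluded), " transcript(s) covered on < ",
      format(100 * min_coverage), "% of their length: ",
      paste(head(excluded, 5), collapse = ", ")
    ))
  }
  scored <- scored[!scored$transcript_id %in% excluded, , drop = FALSE]
  tibble::tibble(
    transcript_id = scored$transcript_id,
    content = scored$content,
    log_content = log_content(scored$content, quiet = TRUE),
    n_determined = scored$n_determined
  )
}

#' @rdname structure_content
#' @export
predicted_content <- function(profiles) {
  check_profile_cols(profiles, c("transcript_id", "position", "score"))
  if (nrow(profiles) == 0) abort("empty profile table")
  profiles |>
    dplyr::group_by(.data$transcript_id) |>
    dplyr::summarise(
      content = mean(.data$score > 0),
      n_determined = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      log_content = log_content(.data$content, quiet = TRUE),
      .after = "content"
    )
}

#' Natural-log transform of structural content
#'
#' The transcript-level log score used to rank transcripts by structure: a
#' score of -1.3 corresponds to ~27% double-stranded content and -2.8 to ~6%.
#'
#' @param content Numeric vector of structural contents in `[0, 1]`.
#' @param quiet Suppress the warning emitted for zero contents.
#' @return `log(content)`; `NA` where the content is 0 (the log score is
#'   undefined there), with a warning unless `quiet = TRUE`.
#' @examples
#' log_content(c(0.26, 0.06, 1))
#' @export
log_content <- function(content, quiet = FALSE) {
  if (any(content < 0 | content > 1, na.rm = TRUE)) {
    abort("content must lie in [0, 1]")
  }
  out <- ifelse(content > 0, log(content), NA_real_)
  if (!quiet && any(content == 0, na.rm = TRUE)) {
    warn("log score undefined for zero structural content; returning NA")
  }
  out
}

#' Mask untranslated regions out of structure profiles
#'
#' Removes the per-nucleotide rows falling in the annotated 5'- and 3'-UTRs so
#' that downstream content scores reflect the coding region only. Intervals
#' are 0-based, half-open.
#'
#' @param profiles A per-nucleotide profile table (any kind) with
#'   `transcript_id` and `position` columns.
#' @param annotations A data frame with columns `transcript_id`,
#'   `utr5_start`, `utr5_end`, `utr3_start`, `utr3_end`. Zero-width intervals
#'   (`start == end`) mask nothing. Transcripts absent from `annotations` are
#'   passed through unchanged.
#' @return The profile table restricted to positions outside both UTRs.
#'   Errors if masking removes every position of some annotated transcript.
#' @export
exclude_regions <- function(profiles, annotations) {
  check_profile_cols(profiles, c("transcript_id", "position"))
  check_profile_cols(
    annotations,
    c("transcript_id", "utr5_start", "utr5_end", "utr3_start", "utr3_end")
  )
  bad <- annotations$utr5_start > annotations$utr5_end |
    annotations$utr3_start > annotations$utr3_end
  if (any(bad)) abort("malformed UTR intervals (start > end)")

  out <- profiles |>
    dplyr::left_join(annotations, by = "transcript_id") |>
    dplyr::filter(
      is.na(.data$utr5_start) |
        !(
          (.data$position >= .data$utr5_start & .data$position < .data$utr5_end) |
            (.data$position >= .data$utr3_start & .data$position < .data$utr3_end)
        )
    ) |>
    dplyr::select(dplyr::all_of(names(profiles)))

  emptied <- setdiff(
    intersect(unique(profiles$transcript_id), annotations$transcript_id),
    unique(out$transcript_id)
  )
  if (length(emptied) > 0) {
    abort(paste0(
      "UTR masking removed every position of: ",
      paste(head(emptied, 5), collapse = ", ")
    ))
  }
  out
}

# shared column validation for tabular inputs
check_profile_cols <- function(x, cols) {
  if (!is.data.frame(x)) abort("expected a data frame")
  missing <- setdiff(cols, names(x))
  if (length(missing) > 0) {
    abort(paste0("missing required column(s): ", paste(missing, collapse = ", ")))
  }
  invisible(x)
}

# length lookup: explicit table or inferred from the largest observed position
resolve_lengths <- function(profiles, lengths) {
  if (is.null(lengths)) {
    profiles |>
      dplyr::group_by(.data$transcript_id) |>
      dplyr::summarise(length = max(.data$position) + 1, .groups = "drop")
  } else {
    check_profile_cols(lengths, c("transcript_id", "length"))
    missing <- setdiff(unique(profiles$transcript_id), lengths$transcript_id)
    if (length(missing) > 0) {
      abort(paste0(
        "no length for transcript(s): ",
        paste(head(missing, 5), collapse = ", ")
      ))
    }
    dplyr::distinct(
      lengths[, c("transcript_id", "length")],
      .data$transcript_id,
      .keep_all = TRUE
    )
  }
}
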