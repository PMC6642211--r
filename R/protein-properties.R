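STANDARD_AA <- c(
  "A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"
)

# md5 of the shipped scale tables; load refuses a tampered file
PROPERTY_SCALE_MD5 <- c(
  grantham_polarity = "de8b825e034581fca69a21fee1885296",
  chou_fasman_helix = "fbf8ab36a0fbc704f7580f6ebdf138ef",
  kyte_doolittle = "d92b00299810293a6a98ac519000678f"
)

#' Amino-acid property scales
#'
#' Loads one of the packaged residue-level property tables: Grantham's
#' polarity, the Chou-Fasman alpha-helix propensity, or the Kyte-Doolittle
#' hydropathy index. Polarity and helix propensity are the protein features
#' that best distinguish binders of double-stranded from binders of
#' single-stranded RNA; hydropathy is shipped as the standard complementary
#' scale. Tables are read from versioned files in the installed package and
#' checksum-verified on load.
#'
#' @param name One of `"grantham_polarity"`, `"chou_fasman_helix"`,
#'   `"kyte_doolittle"`.
#' @return A tibble with columns `residue` (the 20 standard amino acids) and
#'   `value`, with the scale name in attribute `"scale"`.
#' @examples
#' property_scale("grantham_polarity")
#' @export
property_scale <- function(name = c("grantham_polarity", "chou_fasman_helix", "kyte_doolittle")) {
  name <- match.arg(name)
  path <- system.file("extdata", "property_scales", paste0(name, ".tsv"),
    package = "structint", mustWork = TRUE
  )
  if (unname(tools::md5sum(path)) != PROPERTY_SCALE_MD5[[name]]) {
    abort(paste0("checksum mismatch for scale table ", name))
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!setequal(tab$residue, STANDARD_AA) || any(!is.finite(tab$value))) {
    abort(paste0("malformed scale table ", name))
  }
  out <- tibble::as_tibble(tab)
  attr(out, "scale") <- name
  out
}

#' @rdname property_scale
#' @export
list_property_scales <- function() names(PROPERTY_SCALE_MD5)

#' Score protein sequences on a property scale
#'
#' Computes the unweighted mean property value over the residues of each
#' sequence. Non-standard residues (X, B, Z, U, O, gaps, ...) are skipped and
#' counted; a sequence with no scorable residue is an error.
#'
#' @param sequences Named character vector of amino-acid sequences, or a
#'   `Biostrings::AAStringSet`.
#' @param scale A scale name accepted by [property_scale()], or a data frame
#'   with `residue` and `value` columns (e.g. a custom scale).
#' @return A tibble per sequence: `protein_id`, `scale`, `mean_value`,
#'   `n_scored`, `n_skipped`.
#' @examples
#' score_sequences(c(p1 = "ARN", p2 = "GGG"), scale = "grantham_polarity")
#' @export
score_sequences <- function(sequences, scale = "grantham_polarity") {
  seqs <- as_named_sequences(sequences)
  if (is.character(scale)) scale <- property_scale(scale)
  check_profile_cols(scale, c("residue", "value"))
  scale_name <- attr(scale, "scale") %||% "custom"
  values <- setNames(scale$value, scale$residue)

  purrr::imap(seqs, function(s, id) {
    residues <- strsplit(s, "")[[1]]
    scorable <- residues %in% names(values)
    if (!any(scorable)) {
      abort(paste0("no scorable residue in sequence ", id))
    }
    tibble::tibble(
      protein_id = id, scale = scale_name,
      mean_value = mean(values[residues[scorable]]),
      n_scored = sum(scorable), n_skipped = sum(!scorable)
    )
  }) |>
    dplyr::bind_rows()
}

#' Compare the property distributions of two protein sets
#'
#' Two-sample Kolmogorov-Smirnov comparison of per-protein property scores,
#' e.g. the polarity of proteins released from a condensate by a structured
#' RNA versus the proteins that stayed.
#'
#' @param scores_a,scores_b [score_sequences()] results (their `mean_value`
#'   columns are compared) or plain numeric vectors; at least 3 values each.
#' @return A one-row tibble with `statistic` and `p_value` (see
#'   [ks_compare()]).
#' @export
compare_property_sets <- function(scores_a, scores_b) {
  pull_values <- function(x) {
    if (is.data.frame(x)) {
      check_profile_cols(x, "mean_value")
      x$mean_value
    } else {
      as.numeric(x)
    }
  }
  a <- pull_values(scores_a)
  b <- pull_values(scores_b)
  if (length(a) < 3 || length(b) < 3) abort("need at least 3 scores per set")
  ks_compare(a, b)
}
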