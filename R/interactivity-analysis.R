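#' Split transcripts into high- and low-structure sets
#'
#' Ranks transcripts by structural-content score and labels the top
#' `round(fraction * N)` as the HS (high structural content) set and the
#' bottom as many as the LS set. The two sets always have equal size and are
#' disjoint; ties at a boundary are broken towards the lexicographically
#' smaller transcript id, so the split is deterministic and invariant to the
#' input row order.
#'
#' @param scores A data frame with `transcript_id` and `score` columns, or a
#'   named numeric vector.
#' @param fraction Fraction of the cohort in each set, in `(0, 0.5]`.
#' @return A tibble of the selected transcripts: `transcript_id`, `score`,
#'   `set` (`"hs"` or `"ls"`).
#' @export
stratify <- function(scores, fraction) {
  scores <- as_score_table(scores)
  n <- nrow(scores)
  if (n < 2) abort("need at least 2 scored transcripts")
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 0.5) {
    abort("fraction must lie in (0, 0.5]")
  }
  k <- round(fraction * n)
  if (k < 1) abort("fraction too small: selects no transcript")
  if (2 * k > n) abort("HS and LS sets would overlap")

  hs <- scores |>
    dplyr::arrange(dplyr::desc(.data$score), .data$transcript_id) |>
    head(k) |>
    dplyr::mutate(set = "hs")
  ls <- scores |>
    dplyr::arrange(.data$score, .data$transcript_id) |>
    head(k) |>
    dplyr::mutate(set = "ls")
  dplyr::bind_rows(hs, ls)
}

as_score_table <- function(scores, value = "score") {
  if (is.data.frame(scores)) {
    check_profile_cols(scores, c("transcript_id", value))
    tibble::as_tibble(scores)
  } else if (is.numeric(scores) && !is.null(names(scores))) {
    tibble::tibble(transcript_id = names(scores), "{value}" := unname(scores))
  } else {
    abort("scores must be a data frame or a named numeric vector")
  }
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' Compares two samples with the two-sample KS test (asymptotic p-value), the
#' test used throughout this package to compare score distributions, e.g.
#' interaction scores of HS vs LS transcript sets.
#'
#' @param sample_a,sample_b Non-empty numeric vectors.
#' @return A one-row tibble with `statistic` (the KS D in `[0, 1]`) and
#'   `p_value`.
#' @export
ks_compare <- function(sample_a, sample_b) {
  sample_a <- sample_a[!is.na(sample_a)]
  sample_b <- sample_b[!is.na(sample_b)]
  if (length(sample_a) == 0 || length(sample_b) == 0) {
    abort("both samples must be non-empty")
  }
  res <- suppressWarnings(ks.test(sample_a, sample_b, exact = FALSE))
  tibble::tibble(
    statistic = unname(res$statistic),
    p_value = res$p.value
  )
}

#' Fit the structure-to-binders relationship
#'
#' Fits the number of protein binders `y` as a function of structural content
#' `x` under one of two functional forms:
#'
#' * `model = "exponential"`: `y = exp(alpha + beta * x)`
#' * `model = "reciprocal"`: `y = 1 / (alpha + beta * x)`
#'
#' The default loss is unweighted least squares on the original `y` scale,
#' initialized from an ordinary linear regression of the linearized model
#' (`log(y + 1)` or `1/y` on `x`) and refined by Levenberg-Marquardt
#' iteration. For count data, `loss = "poisson"` fits the exponential form by
#' Poisson maximum likelihood (a log-link GLM) instead.
#'
#' For the reciprocal form the fitted denominator `alpha + beta * x` must stay
#' positive over the observed `x` range; a sign change at the solution raises
#' an error reporting the offending estimates.
#'
#' @param data A data frame containing the predictor and response columns.
#' @param x,y Column names (strings) of structural content and binder count.
#' @param model Functional form, `"exponential"` or `"reciprocal"`.
#' @param loss `"ls"` (default) or `"poisson"` (exponential form only).
#' @return An object of class `binder_fit` with coefficient table, residual
#'   sum of squares and the training data; see [tidy.binder_fit()],
#'   [glance.binder_fit()], [predict.binder_fit()], [autoplot.binder_fit()].
#' @examples
#' d <- tibble::tibble(x = seq(0, 1, length.out = 50))
#' d$y <- exp(-0.75 + 0.67 * d$x)
#' fit <- fit_binder_model(d, model = "exponential")
#' tidy(fit)
#' @export
fit_binder_model <- function(data, x = "x", y = "y",
                             model = c("exponential", "reciprocal"),
                             loss = c("ls", "poisson")) {
  model <- match.arg(model)
  loss <- match.arg(loss)
  check_profile_cols(data, c(x, y))
  d <- tibble::tibble(x = as.numeric(data[[x]]), y = as.numeric(data[[y]]))
  d <- d[stats::complete.cases(d), , drop = FALSE]
  if (nrow(d) < 3) abort("need at least 3 complete observations")
  if (length(unique(d$x)) < 2) abort("x must not be constant")
  if (any(d$y < 0)) abort("binder counts must be non-negative")

  if (model == "exponential") {
    fit_exponential_impl(d, loss)
  } else {
    if (loss == "poisson") abort("poisson loss is only defined for the exponential form")
    if (any(d$y <= 0)) abort("reciprocal form requires strictly positive y")
    fit_reciprocal_impl(d)
  }
}

fit_exponential_impl <- function(d, loss) {
  if (loss == "poisson") {
    g <- glm(y ~ x, family = poisson(), data = d)
    est <- unname(coef(g))
    se <- unname(summary(g)$coefficients[, "Std. Error"])
    fitted <- exp(est[1] + est[2] * d$x)
    return(new_binder_fit("exponential", est, se, d, fitted, loss))
  }
  init <- unname(coef(lm(log(y + 1) ~ x, data = d)))
  lm_fit <- refine_lm(
    init,
    residual = function(p) d$y - exp(p[1] + p[2] * d$x),
    jacobian = function(p) {
      mu <- exp(p[1] + p[2] * d$x)
      cbind(-mu, -mu * d$x)
    }
  )
  est <- lm_fit$par
  new_binder_fit("exponential", est, lm_fit$se, d, exp(est[1] + est[2] * d$x), loss)
}

# Levenberg-Marquardt refinement of a 2-parameter residual model, with
# standard errors from the Jacobian at the solution (NA when the normal
# matrix is singular, e.g. an exact fit of a degenerate model)
refine_lm <- function(init, residual, jacobian) {
  out <- minpack.lm::nls.lm(
    par = init, fn = residual, jac = jacobian,
    control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14, ptol = 1e-14)
  )
  if (out$info == 0 || out$info > 4) {
    abort(paste0(
      "fit did not converge (", out$message, "); last iterate: ",
      paste(format(out$par), collapse = ", ")
    ))
  }
  p <- unname(out$par)
  r <- residual(p)
  n <- length(r)
  se <- tryCatch(
    {
      j <- jacobian(p)
      sigma2 <- sum(r^2) / max(n - length(p), 1)
      sqrt(diag(sigma2 * solve(crossprod(j))))
    },
    error = function(e) rep(NA_real_, length(p))
  )
  list(par = p, se = se)
}

fit_reciprocal_impl <- function(d) {
  init <- unname(coef(lm(I(1 / y) ~ x, data = d)))
  lm_fit <- refine_lm(
    init,
    residual = function(p) d$y - 1 / (p[1] + p[2] * d$x),
    jacobian = function(p) {
      den <- (p[1] + p[2] * d$x)^2
      cbind(1 / den, d$x / den)
    }
  )
  est <- lm_fit$par
  denom <- est[1] + est[2] * range(d$x)
  if (any(denom <= 0)) {
    abort(paste0(
      "fitted denominator changes sign over the data range ",
      "(alpha = ", format(est[1]), ", beta = ", format(est[2]), ")"
    ))
  }
  new_binder_fit("reciprocal", est, lm_fit$se, d, 1 / (est[1] + est[2] * d$x), "ls")
}

new_binder_fit <- function(model, est, se, d, fitted, loss) {
  structure(
    list(
      model = model,
      alpha = est[1], beta = est[2],
      se_alpha = se[1], se_beta = se[2],
      rss = sum((d$y - fitted)^2),
      n = nrow(d),
      loss = loss,
      data = d
    ),
    class = "binder_fit"
  )
}

#' @export
print.binder_fit <- function(x, ...) {
  cat(
    "Binder-count fit: y =",
    if (x$model == "exponential") "exp(alpha + beta * x)" else "1 / (alpha + beta * x)",
    "\n"
  )
  cat(sprintf(
    "  alpha = %.4f (se %.4f), beta = %.4f (se %.4f)\n",
    x$alpha, x$se_alpha, x$beta, x$se_beta
  ))
  cat(sprintf("  n = %d, rss = %.4g, loss = %s\n", x$n, x$rss, x$loss))
  invisible(x)
}

#' Tidy a binder-count fit
#'
#' @param x A [fit_binder_model()] result.
#' @param ... Unused.
#' @return A tibble with one row per coefficient: `term`, `estimate`,
#'   `std.error`.
#' @method tidy binder_fit
#' @export
tidy.binder_fit <- function(x, ...) {
  tibble::tibble(
    term = c("alpha", "beta"),
    estimate = c(x$alpha, x$beta),
    std.error = c(x$se_alpha, x$se_beta)
  )
}

#' One-row summary of a binder-count fit
#'
#' @param x A [fit_binder_model()] result.
#' @param ... Unused.
#' @return A one-row tibble: `model`, `alpha`, `beta`, `rss`, `n`, `loss`.
#' @method glance binder_fit
#' @export
glance.binder_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model, alpha = x$alpha, beta = x$beta,
    rss = x$rss, n = x$n, loss = x$loss
  )
}

#' Predict binder counts from a fitted model
#'
#' @param object A [fit_binder_model()] result.
#' @param newdata Optional data frame with an `x` column (defaults to the
#'   training data).
#' @param ... Unused.
#' @return Numeric vector of predicted binder counts.
#' @export
predict.binder_fit <- function(object, newdata = NULL, ...) {
  xs <- if (is.null(newdata)) object$data$x else newdata$x
  if (object$model == "exponential") {
    exp(object$alpha + object$beta * xs)
  } else {
    1 / (object$alpha + object$beta * xs)
  }
}

#' Greedy sequence-identity clustering
#'
#' Groups sequences by pairwise identity with a greedy incremental scheme:
#' sequences are sorted by length (longest first, ties by id), and each
#' sequence joins the first existing cluster whose representative (founding
#' sequence) it matches at or above the identity threshold, otherwise it
#' founds a new cluster. Identity is computed from a global (end-to-end)
#' alignment as matches over alignment length.
#'
#' @param sequences Named character vector of nucleotide sequences, or a
#'   `Biostrings::XStringSet`.
#' @param identity_threshold Minimum identity for cluster membership
#'   (default 0.85).
#' @return A tibble with `cluster_id`, `transcript_id`, `representative`
#'   (logical) and `identity` (identity to the representative; 1 for the
#'   representative itself).
#' @export
cluster_sequences <- function(sequences, identity_threshold = 0.85) {
  seqs <- as_named_sequences(sequences)
  if (length(seqs) == 0) abort("no sequences supplied")

  ord <- order(-nchar(seqs), names(seqs))
  seqs <- seqs[ord]
  rep_idx <- integer(0) # indices (into seqs) of cluster representatives
  assignment <- integer(length(seqs))
  identity <- numeric(length(seqs))

  for (i in seq_along(seqs)) {
    placed <- FALSE
    for (ci in seq_along(rep_idx)) {
      id <- pairwise_identity(seqs[[rep_idx[ci]]], seqs[[i]])
      if (id >= identity_threshold) {
        assignment[i] <- ci
        identity[i] <- id
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      rep_idx <- c(rep_idx, i)
      assignment[i] <- length(rep_idx)
      identity[i] <- 1
    }
  }

  tibble::tibble(
    cluster_id = paste0("cluster_", assignment),
    transcript_id = names(seqs),
    representative = seq_along(seqs) %in% rep_idx,
    identity = identity
  ) |>
    dplyr::arrange(.data$cluster_id, dplyr::desc(.data$representative), .data$transcript_id)
}

as_named_sequences <- function(sequences) {
  if (inherits(sequences, "XStringSet")) {
    sequences <- setNames(as.character(sequences), names(sequences))
  }
  if (!is.character(sequences)) {
    abort("sequences must be a named character vector or an XStringSet")
  }
  if (is.null(names(sequences)) || anyDuplicated(names(sequences)) > 0) {
    abort("sequences must carry unique names")
  }
  toupper(sequences)
}

#' Global-alignment identity between two nucleotide sequences
#'
#' Needleman-Wunsch global alignment (match 1, mismatch 0, affine gaps
#' -1/-0.5), identity counted as matching positions over the full alignment
#' length including gaps.
#'
#' @param seq_a,seq_b Nucleotide sequence strings (T and U are equivalent).
#' @return Identity in `[0, 1]`.
#' @export
pairwise_identity <- function(seq_a, seq_b) {
  seq_a <- chartr("Uu", "Tt", seq_a)
  seq_b <- chartr("Uu", "Tt", seq_b)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = 0)
  aln <- Biostrings::pairwiseAlignment(
    seq_a, seq_b,
    type = "global", substitutionMatrix = mat,
    gapOpening = 1, gapExtension = 0.5
  )
  Biostrings::pid(aln, type = "PID1") / 100
}

#' Per-cluster correlation between structure and binder count
#'
#' For each sequence-similarity cluster, computes the Pearson correlation
#' between a structural score and the number of protein binders across the
#' cluster members. With DMS-scale scores (higher = less structure) a
#' negative correlation means the more structured paralog binds more
#' proteins. Members missing either value are dropped; clusters left with
#' fewer than two members (or with a constant score or count, where the
#' correlation is undefined) are excluded.
#'
#' @param clusters A data frame with `cluster_id` and `transcript_id`
#'   (e.g. from [cluster_sequences()]).
#' @param structure_scores Data frame `transcript_id`, `score`, or named
#'   numeric vector.
#' @param binder_counts Data frame `transcript_id`, `n_binders`, or named
#'   numeric vector.
#' @return A tibble with `cluster_id`, `n_members`, `pearson_r`. The summary
#'   fraction of clusters with negative correlation is available via
#'   [fraction_negative()].
#' @export
paralog_correlation <- function(clusters, structure_scores, binder_counts) {
  check_profile_cols(clusters, c("cluster_id", "transcript_id"))
  structure_scores <- as_score_table(structure_scores)
  binder_counts <- as_score_table(binder_counts, value = "n_binders")

  clusters |>
    dplyr::inner_join(structure_scores, by = "transcript_id") |>
    dplyr::inner_join(binder_counts, by = "transcript_id") |>
    dplyr::filter(!is.na(.data$score), !is.na(.data$n_binders)) |>
    dplyr::group_by(.data$cluster_id) |>
    dplyr::filter(dplyr::n() >= 2) |>
    dplyr::summarise(
      n_members = dplyr::n(),
      pearson_r = if (sd(.data$score) == 0 || sd(.data$n_binders) == 0) {
        NA_real_
      } else {
        cor(.data$score, .data$n_binders)
      },
      .groups = "drop"
    ) |>
    dplyr::filter(!is.na(.data$pearson_r))
}

#' Fraction of clusters with negative structure/binder correlation
#'
#' @param cluster_report A [paralog_correlation()] result.
#' @return The fraction of clusters with `pearson_r < 0`.
#' @export
fraction_negative <- function(cluster_report) {
  check_profile_cols(cluster_report, "pearson_r")
  if (nrow(cluster_report) == 0) abort("empty cluster report")
  mean(cluster_report$pearson_r < 0)
}
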