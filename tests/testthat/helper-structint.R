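# Independent brute-force oracles and tiny fixture builders.
# The oracles deliberately re-derive every quantity with literal loops so the
# vectorized implementations are checked against something they do not share
# code with.

# literal per-nucleotide stepwise sum: theta(log10(V/S)) with the 0-read
# limits handled explicitly; denominator = determined nucleotides
oracle_pars_content <- function(v, s) {
  n_ds <- 0L
  n_det <- 0L
  for (i in seq_along(v)) {
    if (v[i] + s[i] == 0) next
    n_det <- n_det + 1L
    ratio <- if (s[i] == 0) Inf else v[i] / s[i]
    if (is.infinite(ratio) || log10(ratio) > 0) n_ds <- n_ds + 1L
  }
  if (n_det == 0L) {
    return(NA_real_)
  }
  n_ds / n_det
}

random_pars_profile <- function(id, len) {
  tibble::tibble(
    transcript_id = id,
    position = seq_len(len) - 1L,
    ds_reads = rpois(len, sample(c(0, 2, 10), len, replace = TRUE)),
    ss_reads = rpois(len, sample(c(0, 2, 10), len, replace = TRUE))
  )
}

# O(n^2) double-loop contact counters
oracle_count_internal <- function(geometry, cutoff = 7) {
  p <- geometry[geometry$chain == "rna", , drop = FALSE]
  n <- 0L
  if (nrow(p) < 2) {
    return(0L)
  }
  for (i in seq_len(nrow(p) - 1)) {
    for (j in (i + 1):nrow(p)) {
      d <- sqrt((p$x[i] - p$x[j])^2 + (p$y[i] - p$y[j])^2 + (p$z[i] - p$z[j])^2)
      if (d < cutoff) n <- n + 1L
    }
  }
  n
}

oracle_count_external <- function(geometry, cutoff = 7) {
  p <- geometry[geometry$chain == "rna", , drop = FALSE]
  q <- geometry[geometry$chain == "protein", , drop = FALSE]
  n <- 0L
  for (i in seq_len(nrow(p))) {
    for (j in seq_len(nrow(q))) {
      d <- sqrt((p$x[i] - q$x[j])^2 + (p$y[i] - q$y[j])^2 + (p$z[i] - q$z[j])^2)
      if (d < cutoff) n <- n + 1L
    }
  }
  n
}

random_geometry <- function(id, n_rna = 8, n_prot = 10, spread = 12) {
  tibble::tibble(
    complex_id = id,
    chain = rep(c("rna", "protein"), c(n_rna, n_prot)),
    residue_index = c(seq_len(n_rna), seq_len(n_prot)),
    x = runif(n_rna + n_prot, 0, spread),
    y = runif(n_rna + n_prot, 0, spread),
    z = runif(n_rna + n_prot, 0, spread)
  )
}

# brute-force two-sample KS statistic: maximize |ECDF_a - ECDF_b| over all
# observed points
oracle_ks_d <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(vapply(
    pts,
    function(t) abs(mean(a <= t) - mean(b <= t)),
    numeric(1)
  ))
}

# random-rotation matrix via QR of a gaussian matrix
random_rotation <- function() {
  qr_d <- qr(matrix(rnorm(9), 3, 3))
  q <- qr.Q(qr_d)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

apply_rigid <- function(geometry, rotation, translation) {
  m <- as.matrix(geometry[, c("x", "y", "z")]) %*% t(rotation)
  geometry$x <- m[, 1] + translation[1]
  geometry$y <- m[, 2] + translation[2]
  geometry$z <- m[, 3] + translation[3]
  geometry
}

# wide LFQ row builder: values in condition order bg / hs / ls
lfq_row <- function(protein_id, bg, hs, ls) {
  stopifnot(length(bg) == 4, length(hs) == 4, length(ls) == 4)
  vals <- as.list(c(bg, hs, ls))
  names(vals) <- c(
    paste0("background_", 1:4), paste0("hs_rna_", 1:4), paste0("ls_rna_", 1:4)
  )
  dplyr::bind_cols(tibble::tibble(protein_id = protein_id), tibble::as_tibble(vals))
}
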