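#' Count intra-RNA phosphate contacts
#'
#' Counts unordered pairs of phosphate atoms from two distinct nucleotides
#' lying strictly closer than `cutoff` angstroms — a proxy for the amount of
#' intramolecular RNA structure in a 3D complex. Sequence-adjacent
#' nucleotides are included.
#'
#' @param geometry Coordinates of one complex: a data frame with columns
#'   `chain` (`"rna"` / `"protein"`), `residue_index`, `x`, `y`, `z`.
#' @param cutoff Distance cutoff in angstroms (strict `<`).
#' @return Number of contacting phosphate pairs (each pair counted once).
#' @export
count_internal <- function(geometry, cutoff = 7.0) {
  p <- chain_coords(geometry, "rna")
  if (nrow(p) == 0) abort("no phosphate coordinates")
  if (nrow(p) == 1) {
    return(0L)
  }
  d <- stats::dist(as.matrix(p[, c("x", "y", "z")]))
  sum(d < cutoff)
}

#' Count RNA-protein phosphate/C-alpha contacts
#'
#' Counts (phosphate, C-alpha) cross-pairs strictly closer than `cutoff`
#' angstroms — the intermolecular contact surface between the RNA and the
#' protein chain.
#'
#' @inheritParams count_internal
#' @return Number of contacting cross-pairs.
#' @export
count_external <- function(geometry, cutoff = 7.0) {
  p <- chain_coords(geometry, "rna")
  ca <- chain_coords(geometry, "protein")
  if (nrow(p) == 0 || nrow(ca) == 0) {
    abort("need at least one phosphate and one C-alpha coordinate")
  }
  pm <- as.matrix(p[, c("x", "y", "z")])
  cm <- as.matrix(ca[, c("x", "y", "z")])
  # squared cross-distance matrix, no loops
  d2 <- outer(rowSums(pm^2), rowSums(cm^2), "+") - 2 * pm %*% t(cm)
  sum(d2 < cutoff^2)
}

chain_coords <- function(geometry, which_chain) {
  check_profile_cols(geometry, c("chain", "residue_index", "x", "y", "z"))
  sub <- geometry[geometry$chain == which_chain, , drop = FALSE]
  if (anyDuplicated(sub$residue_index) > 0) {
    abort(paste0("multiple coordinates for one ", which_chain, " residue"))
  }
  if (any(!is.finite(as.matrix(sub[, c("x", "y", "z")])))) {
    abort("coordinates must be finite")
  }
  sub
}

#' Length-normalized contact scores
#'
#' Normalizes raw contact counts by chain length so complexes of different
#' sizes are comparable:
#' `internal_score = log2((1 + internal_count) / length_rna^2)` and
#' `external_score = log2((1 + external_count) / (length_rna * length_protein))`.
#'
#' @param internal_count,external_count Non-negative contact counts.
#' @param length_rna,length_protein Chain lengths (residues observed), >= 1.
#' @return A tibble with the counts, lengths and both scores. Vectorized.
#' @examples
#' score_contacts(3, 7, length_rna = 4, length_protein = 2)
#' @export
score_contacts <- function(internal_count, external_count,
                           length_rna, length_protein) {
  if (any(internal_count < 0) || any(external_count < 0)) {
    abort("contact counts must be non-negative")
  }
  if (any(length_rna < 1) || any(length_protein < 1)) {
    abort("chain lengths must be >= 1")
  }
  tibble::tibble(
    internal_count = as.integer(internal_count),
    external_count = as.integer(external_count),
    length_rna = length_rna,
    length_protein = length_protein,
    internal_score = log2((1 + internal_count) / length_rna^2),
    external_score = log2((1 + external_count) / (length_rna * length_protein))
  )
}

#' Contact statistics for a set of complexes
#'
#' Computes, per complex, the intra-RNA and RNA-protein contact counts and
#' their length-normalized scores. Chain lengths are the numbers of residues
#' observed per chain (residues with a missing phosphate or C-alpha still
#' count towards the length when present in the input).
#'
#' @param complexes A data frame of coordinates for one or more complexes:
#'   `complex_id`, `chain`, `residue_index`, `x`, `y`, `z`. An optional
#'   `chain_length` column overrides the observed residue count.
#' @param cutoff Contact distance cutoff in angstroms.
#' @return One row per complex with counts, lengths and scores.
#' @export
contact_scores <- function(complexes, cutoff = 7.0) {
  check_profile_cols(complexes, c("complex_id", "chain", "residue_index", "x", "y", "z"))
  complexes |>
    dplyr::group_by(.data$complex_id) |>
    dplyr::group_map(function(g, key) {
      len <- function(ch) {
        sub <- g[g$chain == ch, , drop = FALSE]
        if ("chain_length" %in% names(sub) && nrow(sub) > 0) {
          sub$chain_length[1]
        } else {
          dplyr::n_distinct(sub$residue_index)
        }
      }
      dplyr::bind_cols(
        key,
        score_contacts(
          count_internal(g, cutoff), count_external(g, cutoff),
          len("rna"), len("protein")
        )
      )
    }) |>
    dplyr::bind_rows()
}

#' Dataset-level correlation between intra- and inter-molecular contacts
#'
#' Pearson correlation between the internal (RNA structure) and external
#' (protein contact) scores across complexes: a positive value means more
#' structured RNAs make more protein contacts in 3D.
#'
#' @param scores A [contact_scores()] result (needs `internal_score` and
#'   `external_score`; at least 3 complexes).
#' @return Pearson correlation coefficient.
#' @export
dataset_correlation <- function(scores) {
  check_profile_cols(scores, c("internal_score", "external_score"))
  if (nrow(scores) < 3) abort("need at least 3 complexes")
  if (sd(scores$internal_score) == 0 || sd(scores$external_score) == 0) {
    abort("correlation undefined: zero variance in a score")
  }
  cor(scores$internal_score, scores$external_score)
}

# residue names recognised as RNA / amino acids in structure files
RNA_RESIDUES <- c("A", "C", "G", "U", "RA", "RC", "RG", "RU", "ADE", "CYT", "GUA", "URA", "URI")
AA_RESIDUES <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL"
)

#' Read protein-RNA complex geometries from a PDB file
#'
#' Extracts phosphate (P) coordinates of RNA chains and C-alpha (CA)
#' coordinates of protein chains from a standard PDB file, and emits one
#' complex per (RNA chain, protein chain) pair. Only the first model of
#' multi-model files is used; for alternate locations the highest-occupancy
#' conformer is kept (first on ties); HETATM/solvent records are skipped.
#' Chain lengths are the numbers of RNA / amino-acid residues observed in the
#' ATOM records of each chain, so residues without a phosphate (e.g. a
#' 5'-terminal nucleotide) still count towards the length.
#'
#' @param file Path to a PDB file.
#' @param complex_prefix Prefix for complex ids; defaults to the file name.
#' @return A coordinate tibble as consumed by [contact_scores()], with
#'   columns `complex_id`, `chain`, `residue_index`, `x`, `y`, `z`,
#'   `chain_length`. Empty (with a warning) when the file holds no
#'   protein-RNA chain pair.
#' @export
read_complexes <- function(file, complex_prefix = NULL) {
  if (!file.exists(file)) abort(paste0("no such file: ", file))
  prefix <- complex_prefix %||% sub("\\.(pdb|ent)$", "", basename(file))
  pdb <- tryCatch(
    suppressWarnings(
      bio3d::read.pdb(file, multi = FALSE, rm.alt = FALSE, verbose = FALSE)
    ),
    error = function(e) abort(paste0("malformed structure file: ", conditionMessage(e)))
  )
  atoms <- tibble::as_tibble(pdb$atom) |>
    dplyr::filter(.data$type == "ATOM")

  pick_atoms <- function(residues, atom_name) {
    atoms |>
      dplyr::filter(.data$resid %in% residues, .data$elety == atom_name) |>
      dplyr::group_by(.data$chain, .data$resno) |>
      dplyr::slice_max(dplyr::coalesce(.data$o, 1), n = 1, with_ties = FALSE) |>
      dplyr::ungroup()
  }
  chain_len <- function(residues) {
    atoms |>
      dplyr::filter(.data$resid %in% residues) |>
      dplyr::distinct(.data$chain, .data$resno) |>
      dplyr::count(.data$chain, name = "chain_length")
  }

  p_atoms <- pick_atoms(RNA_RESIDUES, "P")
  ca_atoms <- pick_atoms(AA_RESIDUES, "CA")
  rna_lens <- chain_len(RNA_RESIDUES)
  prot_lens <- chain_len(AA_RESIDUES)

  rna_chains <- intersect(unique(p_atoms$chain), rna_lens$chain)
  prot_chains <- intersect(unique(ca_atoms$chain), prot_lens$chain)
  if (length(rna_chains) == 0 || length(prot_chains) == 0) {
    warn(paste0("no protein-RNA chain pair in ", basename(file)))
    return(tibble::tibble(
      complex_id = character(), chain = character(),
      residue_index = integer(), x = numeric(), y = numeric(), z = numeric(),
      chain_length = integer()
    ))
  }

  pairs <- tidyr::expand_grid(rna_chain = rna_chains, prot_chain = prot_chains)
  purrr::pmap(pairs, function(rna_chain, prot_chain) {
    rna <- p_atoms[p_atoms$chain == rna_chain, , drop = FALSE]
    prot <- ca_atoms[ca_atoms$chain == prot_chain, , drop = FALSE]
    cid <- paste(prefix, rna_chain, prot_chain, sep = "_")
    dplyr::bind_rows(
      tibble::tibble(
        complex_id = cid, chain = "rna", residue_index = rna$resno,
        x = rna$x, y = rna$y, z = rna$z,
        chain_length = rna_lens$chain_length[rna_lens$chain == rna_chain]
      ),
      tibble::tibble(
        complex_id = cid, chain = "protein", residue_index = prot$resno,
        x = prot$x, y = prot$y, z = prot$z,
        chain_length = prot_lens$chain_length[prot_lens$chain == prot_chain]
      )
    )
  }) |>
    dplyr::bind_rows()
}

#' Write complex geometries to PDB files
#'
#' Serializes coordinate tibbles (one file per complex) as minimal standard
#' PDB: RNA phosphates as `P` atoms of chain R, protein C-alphas as `CA`
#' atoms of chain P. Round-trips through [read_complexes()].
#'
#' @param complexes A coordinate tibble (`complex_id`, `chain`,
#'   `residue_index`, `x`, `y`, `z`).
#' @param dir Output directory (created if missing).
#' @return Invisibly, the written file paths.
#' @export
write_complexes_pdb <- function(complexes, dir) {
  check_profile_cols(complexes, c("complex_id", "chain", "residue_index", "x", "y", "z"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ids <- unique(complexes$complex_id)
  paths <- vapply(ids, function(cid) {
    g <- complexes[complexes$complex_id == cid, , drop = FALSE]
    rna <- g[g$chain == "rna", , drop = FALSE]
    prot <- g[g$chain == "protein", , drop = FALSE]
    lines <- c(
      sprintf(
        "ATOM  %5d  P     U R%4d    %8.3f%8.3f%8.3f  1.00  0.00           P",
        seq_len(nrow(rna)), rna$residue_index, rna$x, rna$y, rna$z
      ),
      "TER",
      sprintf(
        "ATOM  %5d  CA  GLY P%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
        nrow(rna) + seq_len(nrow(prot)), prot$residue_index, prot$x, prot$y, prot$z
      ),
      "TER",
      "END"
    )
    path <- file.path(dir, paste0(cid, ".pdb"))
    writeLines(lines, path)
    path
  }, character(1))
  invisible(unname(paths))
}
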