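## Protein composition, CXC accounting, MT-likeness and average mass.

AA20 <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

## Pinned standard atomic weights (IUPAC 2005 table, Da). All average-mass
## arithmetic in the package goes through this single table.
ATOMIC_WEIGHTS <- c(H = 1.00794, C = 12.0107, N = 14.0067, O = 15.9994,
                    S = 32.065)

## Residue (i.e. water-loss) elemental compositions of the 20 canonical
## amino acids; rows H, C, N, O, S.
RESIDUE_FORMULAS <- matrix(c(
  ## H   C  N  O  S
     5,  3, 1, 1, 0,  # A
    12,  6, 4, 1, 0,  # R
     6,  4, 2, 2, 0,  # N
     5,  4, 1, 3, 0,  # D
     5,  3, 1, 1, 1,  # C
     7,  5, 1, 3, 0,  # E
     8,  5, 2, 2, 0,  # Q
     3,  2, 1, 1, 0,  # G
     7,  6, 3, 1, 0,  # H
    11,  6, 1, 1, 0,  # I
    11,  6, 1, 1, 0,  # L
    12,  6, 2, 1, 0,  # K
     9,  5, 1, 1, 1,  # M
     9,  9, 1, 1, 0,  # F
     7,  5, 1, 1, 0,  # P
     5,  3, 1, 2, 0,  # S
     7,  4, 1, 2, 0,  # T
    10, 11, 2, 1, 0,  # W
     9,  9, 1, 2, 0,  # Y
     9,  5, 1, 1, 0   # V
), nrow = 20, byrow = TRUE,
  dimnames = list(AA20, c("H", "C", "N", "O", "S")))

## Residue average masses derived once from the formulas + weights above.
RESIDUE_MASSES <- drop(RESIDUE_FORMULAS %*% ATOMIC_WEIGHTS[colnames(RESIDUE_FORMULAS)])

WATER_MASS <- 2 * ATOMIC_WEIGHTS[["H"]] + ATOMIC_WEIGHTS[["O"]]
PROTON_MASS <- ATOMIC_WEIGHTS[["H"]]

#' Create a protein record
#'
#' Light container for an amino-acid sequence with provenance. The sequence
#' is upper-cased and validated against the 20-letter canonical alphabet.
#'
#' @param id Record identifier.
#' @param sequence Amino-acid string (canonical 20-letter alphabet).
#' @param source Provenance: `"in_paper"` for sequences transcribed from a
#'   printed table, `"accession"` for database records, `"synthetic"` for
#'   generator output.
#' @return An object of class `protein_record` with fields `id`, `sequence`,
#'   `source`.
#' @export
protein_record <- function(id, sequence, source = c("synthetic", "in_paper", "accession")) {
  source <- match.arg(source)
  sequence <- toupper(as.character(sequence))
  check_protein_sequence(sequence)
  structure(list(id = as.character(id), sequence = sequence, source = source),
            class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf("<protein_record> %s (%s), %d aa\n", x$id, x$source, nchar(x$sequence)))
  invisible(x)
}

check_protein_sequence <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence) ||
      nchar(sequence) == 0L) {
    stop("invalid protein sequence: must be one non-empty string", call. = FALSE)
  }
  chars <- strsplit(sequence, "")[[1]]
  bad <- which(!chars %in% AA20)
  if (length(bad) > 0L) {
    stop(sprintf("invalid alphabet: character '%s' at position %d is not a canonical residue",
                 chars[bad[1]], bad[1]), call. = FALSE)
  }
  invisible(TRUE)
}

as_protein_record <- function(x) {
  if (inherits(x, "protein_record")) return(x)
  if (is.character(x) && length(x) == 1L) return(protein_record("seq", x))
  stop("expected a protein_record or a single sequence string", call. = FALSE)
}

#' Read protein records from a FASTA file
#'
#' @param path FASTA file with one or more protein sequences.
#' @param source Provenance tag applied to every record (see
#'   [protein_record()]).
#' @return List of `protein_record` objects, named by FASTA id (first word of
#'   the header).
#' @export
read_protein_fasta <- function(path, source = "accession") {
  aas <- Biostrings::readAAStringSet(path)
  ids <- vapply(strsplit(names(aas), "\\s+"), `[`, "", 1L)
  recs <- lapply(seq_along(aas), function(i) {
    protein_record(ids[i], as.character(aas[[i]]), source = source)
  })
  names(recs) <- ids
  recs
}

#' Summarize amino-acid composition of a protein
#'
#' Reports length, per-residue counts, cysteine count and fraction,
#' histidine/methionine counts, aromatic (F/W/Y) count, the number of Cys
#' residues participating in CXC motifs, and the average molecular mass.
#'
#' @param record A [protein_record()] (or a plain sequence string).
#' @return A list of class `composition_summary` with fields `id`, `length`,
#'   `residue_counts`, `cys_count`, `cys_fraction`, `his_count`, `met_count`,
#'   `aromatic_count`, `cys_in_cxc`, `average_mass_da`.
#' @examples
#' summarize_composition(protein_record("NcMT", "MGDCGCSGASSCNCGSGCSCSNCGSK"))
#' @export
summarize_composition <- function(record) {
  record <- as_protein_record(record)
  chars <- strsplit(record$sequence, "")[[1]]
  counts <- table(factor(chars, levels = AA20))
  counts <- setNames(as.integer(counts), AA20)
  len <- length(chars)
  cys <- counts[["C"]]
  structure(list(
    id = record$id,
    length = len,
    residue_counts = counts,
    cys_count = cys,
    cys_fraction = cys / len,
    his_count = counts[["H"]],
    met_count = counts[["M"]],
    aromatic_count = counts[["F"]] + counts[["W"]] + counts[["Y"]],
    cys_in_cxc = count_cys_in_cxc(record),
    average_mass_da = average_mass(record)
  ), class = "composition_summary")
}

#' @export
print.composition_summary <- function(x, ...) {
  cat(sprintf("<composition_summary> %s\n", x$id))
  cat(sprintf("  length       : %d aa\n", x$length))
  cat(sprintf("  Cys          : %d (%.1f%%), %d in CXC motifs\n",
              x$cys_count, 100 * x$cys_fraction, x$cys_in_cxc))
  cat(sprintf("  His/Met      : %d / %d\n", x$his_count, x$met_count))
  cat(sprintf("  aromatics    : %d (F/W/Y)\n", x$aromatic_count))
  cat(sprintf("  average mass : %.2f Da\n", x$average_mass_da))
  invisible(x)
}

#' Count cysteines participating in CXC motifs
#'
#' A Cys at position i participates if position i-2 or i+2 is also Cys
#' ("X" is any residue, Cys included). Each Cys is counted once even when it
#' belongs to two overlapping windows.
#'
#' @inheritParams summarize_composition
#' @return Integer count of distinct CXC-participating Cys positions.
#' @examples
#' count_cys_in_cxc("CAC")  # 2
#' count_cys_in_cxc("CC")   # 0: adjacency is not CXC
#' @export
count_cys_in_cxc <- function(record) {
  record <- as_protein_record(record)
  chars <- strsplit(record$sequence, "")[[1]]
  n <- length(chars)
  is_c <- chars == "C"
  left <- c(rep(FALSE, 2L), is_c[seq_len(max(n - 2L, 0L))])
  right <- c(is_c[-seq_len(min(2L, n))], rep(FALSE, min(2L, n)))
  sum(is_c & (left | right))
}

#' Default thresholds for the MT-likeness screen
#'
#' @param min_cys_fraction Minimum Cys fraction (default 0.15).
#' @return Named list of cutoffs.
#' @export
mt_thresholds <- function(min_cys_fraction = 0.15) {
  stopifnot(is.numeric(min_cys_fraction), min_cys_fraction >= 0, min_cys_fraction <= 1)
  list(min_cys_fraction = min_cys_fraction)
}

#' Screen a composition summary for metallothionein likeness
#'
#' A sequence is MT-like when its Cys fraction reaches the threshold and it
#' contains no aromatic residues (F/W/Y). Histidine is tracked separately and
#' never disqualifies: it is a potential metal ligand, not an aromatic in the
#' screening sense used for MTs.
#'
#' @param summary A `composition_summary` from [summarize_composition()].
#' @param thresholds Cutoffs from [mt_thresholds()].
#' @return List of class `mt_verdict` with `is_mt_like`, `reasons` (one entry
#'   per rule, `"pass"`/`"fail"` annotated), and `thresholds_used`.
#' @export
is_mt_like <- function(summary, thresholds = mt_thresholds()) {
  stopifnot(inherits(summary, "composition_summary"))
  cys_ok <- summary$cys_fraction >= thresholds$min_cys_fraction
  aro_ok <- summary$aromatic_count == 0L
  reasons <- c(
    sprintf("cys_fraction %.3f %s threshold %.3f [%s]",
            summary$cys_fraction, if (cys_ok) ">=" else "<",
            thresholds$min_cys_fraction, if (cys_ok) "pass" else "fail"),
    sprintf("aromatic_count %d %s [%s]", summary$aromatic_count,
            if (aro_ok) "== 0" else "> 0", if (aro_ok) "pass" else "fail")
  )
  structure(list(is_mt_like = cys_ok && aro_ok, reasons = reasons,
                 thresholds_used = thresholds),
            class = "mt_verdict")
}

#' @export
print.mt_verdict <- function(x, ...) {
  cat(sprintf("<mt_verdict> %s\n", if (x$is_mt_like) "MT-like" else "not MT-like"))
  for (r in x$reasons) cat("  -", r, "\n")
  invisible(x)
}

#' Average molecular mass of a polypeptide
#'
#' Average (not monoisotopic) mass: sum of residue masses plus one water,
#' under the package's pinned standard-atomic-weight table. Two computation
#' routes are provided; they share only the atomic weights, so their
#' agreement checks the residue table against the elemental bookkeeping.
#'
#' @inheritParams summarize_composition
#' @param n_term_extension Optional residue string prepended before the
#'   computation (e.g. `"GS"` for the Gly-Ser pair left by thrombin-cleaved
#'   GST-fusion constructs).
#' @param method `"residue"` sums a precomputed residue-mass table;
#'   `"formula"` accumulates the full elemental composition and dots it with
#'   the atomic weights.
#' @return Mass in Daltons. An empty body with empty extension returns the
#'   mass of water.
#' @examples
#' average_mass(protein_record("G", "G"))  # 75.07
#' @export
average_mass <- function(record, n_term_extension = "", method = c("residue", "formula")) {
  method <- match.arg(method)
  seq <- if (inherits(record, "protein_record")) record$sequence
         else as.character(record)
  if (length(seq) != 1L || is.na(seq)) stop("invalid protein sequence", call. = FALSE)
  full <- paste0(toupper(n_term_extension), toupper(seq))
  if (nchar(full) == 0L) return(unname(WATER_MASS))
  chars <- strsplit(full, "")[[1]]
  bad <- which(!chars %in% AA20)
  if (length(bad) > 0L) {
    stop(sprintf("invalid alphabet: character '%s' at position %d is not a canonical residue",
                 chars[bad[1]], bad[1]), call. = FALSE)
  }
  if (method == "residue") {
    sum(RESIDUE_MASSES[chars]) + WATER_MASS
  } else {
    counts <- table(factor(chars, levels = AA20))
    elements <- drop(as.integer(counts) %*% RESIDUE_FORMULAS)
    elements["H"] <- elements["H"] + 2
    elements["O"] <- elements["O"] + 1
    sum(elements * ATOMIC_WEIGHTS[names(elements)])
  }
}
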