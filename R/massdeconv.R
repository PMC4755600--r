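## Theoretical holo-species masses, stoichiometry assignment of deconvoluted
## ESI-MS peaks, and ICP-AES metal-per-protein ratios.
##
## Neutral-mass bookkeeping: each bound metal ion displaces as many protons
## as its charge (Zn2+/Cd2+ -> 2 H, Cu+ -> 1 H), so the mass increment per
## ion is (average atomic mass - charge * 1.00794) Da. Sulfide (S2-) is
## treated as a zero-proton-displacement ligand of mass 32.065 Da.

METAL_TABLE <- list(
  Zn = list(avg_atomic_mass = 65.38,   bound_charge = 2L),
  Cd = list(avg_atomic_mass = 112.411, bound_charge = 2L),
  Cu = list(avg_atomic_mass = 63.546,  bound_charge = 1L),
  S2 = list(avg_atomic_mass = 32.065,  bound_charge = 0L)
)

#' Describe a metal (or sulfide) for holo-mass arithmetic
#'
#' @param element `"Zn"`, `"Cd"`, `"Cu"`, `"S2"` (sulfide), or a custom
#'   element name with explicit mass and charge.
#' @param avg_atomic_mass Average atomic mass (Da); defaults from the
#'   built-in table for known elements.
#' @param bound_charge Charge of the bound ion (protons displaced).
#' @return List of class `metal_spec` with `element`, `bound_charge`,
#'   `avg_atomic_mass`, `mass_increment`.
#' @export
metal_spec <- function(element, avg_atomic_mass = NULL, bound_charge = NULL) {
  if (is.null(avg_atomic_mass) || is.null(bound_charge)) {
    known <- METAL_TABLE[[element]]
    if (is.null(known)) {
      stop(sprintf("unknown metal '%s': supply avg_atomic_mass and bound_charge", element),
           call. = FALSE)
    }
    if (is.null(avg_atomic_mass)) avg_atomic_mass <- known$avg_atomic_mass
    if (is.null(bound_charge)) bound_charge <- known$bound_charge
  }
  stopifnot(avg_atomic_mass > 0, bound_charge >= 0)
  structure(list(element = element, bound_charge = as.integer(bound_charge),
                 avg_atomic_mass = avg_atomic_mass,
                 mass_increment = avg_atomic_mass - bound_charge * PROTON_MASS),
            class = "metal_spec")
}

#' Default metal specs
#'
#' @param elements Character vector of element names.
#' @return Named list of [metal_spec()] objects.
#' @export
default_metals <- function(elements = c("Zn", "Cd", "Cu")) {
  setNames(lapply(elements, metal_spec), elements)
}

#' Theoretical mass of a metalated holo-species
#'
#' `apo + sum(n_i * (atomic mass_i - charge_i * 1.00794))`; sulfide counts
#' add 32.065 Da each with no proton displacement.
#'
#' @param apo_mass Apo-protein average mass (Da), > 0.
#' @param stoichiometry Named integer vector of element counts, e.g.
#'   `c(Zn = 20)` or `c(Cu = 5, S2 = 2)`.
#' @param metals Named list of [metal_spec()] objects covering every element
#'   in `stoichiometry` (defaults cover Zn/Cd/Cu/S2).
#' @return Mass in Daltons.
#' @examples
#' holo_mass(25377.62, c(Zn = 20))
#' @export
holo_mass <- function(apo_mass, stoichiometry, metals = default_metals(c("Zn", "Cd", "Cu", "S2"))) {
  stopifnot(is.numeric(apo_mass), length(apo_mass) == 1L, apo_mass > 0)
  if (length(stoichiometry) == 0L) return(apo_mass)
  if (is.null(names(stoichiometry)) || any(names(stoichiometry) == "")) {
    stop("stoichiometry must be a named count vector", call. = FALSE)
  }
  if (any(stoichiometry < 0)) stop("stoichiometry counts must be >= 0", call. = FALSE)
  inc <- vapply(names(stoichiometry), function(el) {
    spec <- metals[[el]]
    if (is.null(spec)) stop(sprintf("unknown metal '%s': no metal_spec supplied", el),
                            call. = FALSE)
    spec$mass_increment
  }, 0)
  apo_mass + sum(stoichiometry * inc)
}

species_label <- function(counts) {
  counts <- counts[counts > 0]
  if (length(counts) == 0L) return("apo")
  paste0(names(counts), counts, collapse = "")
}

#' Assign deconvoluted peaks to metal/sulfide stoichiometries
#'
#' Exhaustively enumerates stoichiometries within bounds, keeps candidates
#' whose theoretical mass lies within a relative tolerance of the peak, and
#' ranks them by absolute mass error. When the best Zn-containing and best
#' Cu-containing candidates are mutually indistinguishable at the tolerance,
#' the assignment is flagged `ambiguous_ZnCu` and the best label is reported
#' as the composite `"M<n>"` (n total metals), mirroring the convention used
#' when Zn and Cu cannot be discerned by ESI-MS.
#'
#' @param peaks Numeric vector of deconvoluted neutral masses (Da).
#' @param apo_mass Apo-protein mass (Da), > 0.
#' @param metals Named list of [metal_spec()] objects to enumerate over.
#' @param max_total Cap on total metal ions per species. Default
#'   `ceiling(cys_count * 5/7) + 10` when `cys_count` is given (the per-box
#'   Cu capacity bound plus slack), else 50.
#' @param cys_count Optional Cys count of the construct, used for the
#'   default `max_total`.
#' @param sulfide Also enumerate sulfide (S2-) ligands, 0..`max_sulfide`.
#' @param max_sulfide Cap on sulfide count (default 10).
#' @param tolerance_rel Relative mass tolerance (default 0.001, i.e. the
#'   0.1% instrument-level mass accuracy of deconvoluted ESI-MS).
#' @return List of class `stoich_assignment_set`; one element per peak with
#'   `peak_mass`, `candidates` (data frame: `label`, per-element counts,
#'   `theoretical_mass`, `mass_error_da`, `mass_error_rel`, sorted by
#'   |error|), `best_label`, `ambiguous_ZnCu`.
#' @export
assign_peaks <- function(peaks, apo_mass, metals = default_metals(c("Zn", "Cu")),
                         max_total = NULL, cys_count = NULL, sulfide = FALSE,
                         max_sulfide = 10L, tolerance_rel = 0.001) {
  if (!is.numeric(apo_mass) || length(apo_mass) != 1L || is.na(apo_mass) || apo_mass <= 0) {
    stop("invalid input: apo_mass must be a positive number", call. = FALSE)
  }
  peaks <- as.numeric(peaks)
  if (length(peaks) == 0L) {
    return(structure(list(), class = "stoich_assignment_set"))
  }
  if (is.null(max_total)) {
    max_total <- if (!is.null(cys_count)) as.integer(ceiling(cys_count * 5 / 7) + 10L) else 50L
  }
  elements <- names(metals)
  grids <- lapply(elements, function(e) 0:max_total)
  names(grids) <- elements
  if (sulfide) grids$S2 <- 0:max_sulfide
  grid <- do.call(expand.grid, c(grids, KEEP.OUT.ATTRS = FALSE))
  metal_cols <- elements
  total_metal <- if (length(metal_cols) == 1L) grid[[metal_cols]] else
    rowSums(grid[, metal_cols, drop = FALSE])
  grid <- grid[total_metal <= max_total, , drop = FALSE]
  specs <- c(metals, if (sulfide) list(S2 = metal_spec("S2")) else NULL)
  incs <- vapply(names(grid), function(e) specs[[e]]$mass_increment, 0)
  masses <- apo_mass + as.numeric(as.matrix(grid) %*% incs)
  totals <- if (length(metal_cols) == 1L) grid[[metal_cols]] else
    rowSums(grid[, metal_cols, drop = FALSE])

  out <- lapply(peaks, function(pk) {
    tol <- tolerance_rel * pk
    err <- masses - pk
    keep <- which(abs(err) <= tol)
    if (length(keep) == 0L) {
      return(list(peak_mass = pk,
                  candidates = data.frame(),
                  best_label = NA_character_, ambiguous_ZnCu = FALSE))
    }
    keep <- keep[order(abs(err[keep]), totals[keep])]
    cand <- grid[keep, , drop = FALSE]
    cdf <- data.frame(
      label = apply(cand, 1L, function(r) species_label(setNames(as.integer(r), names(cand)))),
      cand,
      theoretical_mass = masses[keep],
      mass_error_da = err[keep],
      mass_error_rel = err[keep] / pk,
      row.names = NULL
    )
    ambiguous <- FALSE
    best_label <- cdf$label[1L]
    if (all(c("Zn", "Cu") %in% names(cand))) {
      ## best Zn-route vs best Cu-route species: indistinguishable at the
      ## tolerance -> composite M_n
      i_zn <- which(cdf$Zn > 0 & cdf$Cu == 0)[1]
      i_cu <- which(cdf$Cu > 0 & cdf$Zn == 0)[1]
      if (!is.na(i_zn) && !is.na(i_cu) &&
          abs(cdf$theoretical_mass[i_zn] - cdf$theoretical_mass[i_cu]) <= tol &&
          totals[keep][1L] > 0) {
        ambiguous <- TRUE
        best_label <- sprintf("M%d", as.integer(totals[keep][1L]))
      }
    }
    list(peak_mass = pk, candidates = cdf, best_label = best_label,
         ambiguous_ZnCu = ambiguous)
  })
  structure(out, class = "stoich_assignment_set")
}

#' @export
print.stoich_assignment_set <- function(x, ...) {
  cat(sprintf("<stoich_assignment_set> %d peak(s)\n", length(x)))
  for (a in x) {
    flag <- if (a$ambiguous_ZnCu) " [Zn/Cu ambiguous]" else ""
    cat(sprintf("  %.2f Da -> %s%s (%d candidate(s))\n", a$peak_mass,
                a$best_label, flag, nrow(a$candidates)))
  }
  invisible(x)
}

#' Best stoichiometry per peak, as a data frame
#'
#' @param x A `stoich_assignment_set` from [assign_peaks()].
#' @return Data frame with one row per peak: `peak_mass`, `best_label`,
#'   `ambiguous_ZnCu`, `mass_error_da`, plus the best candidate's counts.
#' @export
best_assignments <- function(x) {
  stopifnot(inherits(x, "stoich_assignment_set"))
  rows <- lapply(x, function(a) {
    if (nrow(a$candidates) == 0L) {
      return(data.frame(peak_mass = a$peak_mass, best_label = NA_character_,
                        ambiguous_ZnCu = FALSE, mass_error_da = NA_real_))
    }
    cbind(data.frame(peak_mass = a$peak_mass, best_label = a$best_label,
                     ambiguous_ZnCu = a$ambiguous_ZnCu,
                     mass_error_da = a$candidates$mass_error_da[1L]),
          a$candidates[1L, setdiff(names(a$candidates),
                                   c("label", "theoretical_mass", "mass_error_da",
                                     "mass_error_rel")), drop = FALSE])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read a deconvoluted peak list from CSV
#'
#' @param path CSV with columns `mass_da` and optionally `intensity`.
#' @return Data frame with `mass_da` and `intensity` (1 when absent).
#' @export
read_peaklist <- function(path) {
  df <- read.csv(path)
  if (!"mass_da" %in% names(df)) stop("peak CSV needs a mass_da column", call. = FALSE)
  if (!"intensity" %in% names(df)) df$intensity <- 1
  df[, c("mass_da", "intensity")]
}

#' Metal-per-protein ratios from ICP-AES element concentrations
#'
#' Protein concentration is obtained from the sulfur signal, assuming every
#' measured S atom belongs to the MT construct (Cys + Met, plus any
#' tag-derived residues): `[protein] = [S] / s_atoms_per_protein`. Ratios
#' are then `[metal] / [protein]`.
#'
#' @param element_concentrations Named numeric vector of molar
#'   concentrations; must include `S`.
#' @param s_atoms_per_protein Number of sulfur atoms per polypeptide
#'   (Cys + Met of the construct), >= 1.
#' @return List of class `icp_measurement`: `element_concentrations`,
#'   `s_atoms_per_protein`, `protein_concentration`, `metal_per_protein`.
#' @examples
#' metal_per_protein(c(S = 114e-6, Zn = 40e-6), 57)
#' @export
metal_per_protein <- function(element_concentrations, s_atoms_per_protein) {
  stopifnot(is.numeric(element_concentrations), s_atoms_per_protein >= 1)
  if (!"S" %in% names(element_concentrations)) {
    stop("element_concentrations must include S", call. = FALSE)
  }
  s_conc <- element_concentrations[["S"]]
  if (is.na(s_conc) || s_conc <= 0) {
    stop("division undefined: sulfur concentration must be > 0", call. = FALSE)
  }
  protein <- s_conc / s_atoms_per_protein
  others <- element_concentrations[setdiff(names(element_concentrations), "S")]
  ratios <- others / protein
  structure(list(element_concentrations = element_concentrations,
                 s_atoms_per_protein = s_atoms_per_protein,
                 protein_concentration = protein,
                 metal_per_protein = ratios),
            class = "icp_measurement")
}

#' @export
print.icp_measurement <- function(x, ...) {
  cat(sprintf("<icp_measurement> protein %.3g M (S/%d)\n",
              x$protein_concentration, x$s_atoms_per_protein))
  for (el in names(x$metal_per_protein)) {
    cat(sprintf("  %s/protein = %.2f\n", el, x$metal_per_protein[[el]]))
  }
  invisible(x)
}
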