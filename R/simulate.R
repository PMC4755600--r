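## Seeded generators for modular MT proteins, intron-bearing genes with
## promoter plants, deconvoluted peak lists, and growth tables. Every
## generator returns machine-readable ground truth so each analysis stage
## can be tested by parameter recovery.

## run code under a fixed seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

## inter-Cys "X" residues: small residues dominate (Gly/Ala), with the
## other residues seen between the coordinating Cys of fungal MT boxes
X_POOL <- c("G", "A", "S", "T", "K", "Q", "E", "P")
X_WEIGHTS <- c(4, 3, 2, 1, 1, 1, 1, 1)

draw_x <- function(n) {
  sample(X_POOL, n, replace = TRUE, prob = X_WEIGHTS)
}

#' Specification for a synthetic modular MT protein
#'
#' @param n_seven_cys_boxes,n_six_cys_boxes Counts of full and degenerate
#'   boxes.
#' @param n_prefix_cys Cys in the N-terminal segment outside any box.
#' @param linker_length_range Cys-free inter-box linker length range
#'   (residues).
#' @param seed Integer seed; same spec + seed gives byte-identical output.
#' @return List of class `architecture_spec`.
#' @export
architecture_spec <- function(n_seven_cys_boxes = 6L, n_six_cys_boxes = 2L,
                              n_prefix_cys = 3L, linker_length_range = c(3L, 8L),
                              seed = 1L) {
  stopifnot(n_seven_cys_boxes >= 0, n_six_cys_boxes >= 0, n_prefix_cys >= 0,
            length(linker_length_range) == 2L,
            linker_length_range[1] >= 1, diff(linker_length_range) >= 0)
  structure(list(n_seven_cys_boxes = as.integer(n_seven_cys_boxes),
                 n_six_cys_boxes = as.integer(n_six_cys_boxes),
                 n_prefix_cys = as.integer(n_prefix_cys),
                 linker_length_range = as.integer(linker_length_range),
                 seed = as.integer(seed)),
            class = "architecture_spec")
}

## one 7-Cys box instance as a character vector; consensus CXCX3CSCPPGXCXCAXCP
instantiate_box <- function() {
  c("C", draw_x(1), "C", draw_x(3), "C", "S", "C", "P", "P", "G", draw_x(1),
    "C", draw_x(1), "C", "A", draw_x(1), "C", "P")
}

#' Generate a synthetic modular MT protein with ground truth
#'
#' Builds an N-terminal segment carrying the prefix Cys, then the 6-Cys
#' boxes (a 7-Cys box instance with one mandatory Cys replaced at a seeded
#' position), then the 7-Cys boxes, separated by Cys-free linkers. Prefix
#' Cys are spaced four residues apart so they cannot be absorbed into a box
#' match under the default +/-2 gap tolerance.
#'
#' @param spec An [architecture_spec()].
#' @param id Record id.
#' @return List with `record` (a [protein_record()], source `"synthetic"`)
#'   and `truth` (box kinds, 1-based start/end coordinates, matched Cys
#'   positions, prefix Cys positions, totals).
#' @export
make_protein <- function(spec, id = "synthetic_mt") {
  stopifnot(inherits(spec, "architecture_spec"))
  with_seed(spec$seed, {
    chars <- character(0)
    ## prefix: Met + spacer, then prefix Cys each followed by 4 X residues
    chars <- c(chars, "M", draw_x(2))
    prefix_cys <- integer(0)
    for (i in seq_len(spec$n_prefix_cys)) {
      chars <- c(chars, "C")
      prefix_cys <- c(prefix_cys, length(chars))
      chars <- c(chars, draw_x(4))
    }
    boxes <- list()
    kinds <- c(rep("six_cys", spec$n_six_cys_boxes),
               rep("seven_cys", spec$n_seven_cys_boxes))
    for (b in seq_along(kinds)) {
      lo <- spec$linker_length_range[1]; hi <- spec$linker_length_range[2]
      chars <- c(chars, draw_x(lo + sample.int(hi - lo + 1L, 1L) - 1L))
      box <- instantiate_box()
      cys_in_box <- which(box == "C")   # template offsets of the 7 mandatory Cys
      dropped <- NA_integer_
      if (kinds[b] == "six_cys") {
        dropped <- sample(7L, 1L)
        box[cys_in_box[dropped]] <- draw_x(1)
        cys_in_box <- cys_in_box[-dropped]
      }
      offset <- length(chars)
      chars <- c(chars, box)
      cys_pos <- offset + cys_in_box
      last_cys <- cys_pos[length(cys_pos)]
      end <- if (last_cys < length(chars) && chars[last_cys + 1L] == "P") {
        last_cys + 1L
      } else {
        last_cys
      }
      boxes[[b]] <- list(kind = kinds[b], start = cys_pos[1L], end = end,
                         cys_positions = cys_pos, dropped_cys = dropped)
    }
    seqstr <- paste(chars, collapse = "")
    truth <- list(
      boxes = data.frame(
        kind = vapply(boxes, `[[`, "", "kind"),
        start = vapply(boxes, `[[`, 0L, "start"),
        end = vapply(boxes, `[[`, 0L, "end"),
        cys_positions = I(lapply(boxes, `[[`, "cys_positions"))
      ),
      prefix_cys = prefix_cys,
      totals = c(seven_cys = spec$n_seven_cys_boxes,
                 six_cys = spec$n_six_cys_boxes),
      n_cys = 7L * spec$n_seven_cys_boxes + 6L * spec$n_six_cys_boxes +
        spec$n_prefix_cys
    )
    list(record = protein_record(id, seqstr, source = "synthetic"), truth = truth)
  })
}

#' Specification for a synthetic intron-bearing gene
#'
#' Defaults mirror the architecture of long modular fungal MT genes: short
#' coding exons (63-105 bp), introns of 48-204 bp bounded by GT/AG, a 69-bp
#' 5' UTR, and promoter elements planted upstream of the start codon (TATA
#' at -38, an MRE core at -1457).
#'
#' @param n_introns Introns to insert (all within the coding span).
#' @param intron_length_range,exon_length_range Length bounds (bp); the
#'   exon range constrains the coding pieces.
#' @param utr5_length 5' UTR length (bp), prepended to the first exon.
#' @param promoter_plants Data frame `name`, `seq`, `offset` (offset of the
#'   motif's 5'-most base relative to the A of ATG = +1; upstream negative).
#' @param upstream_flank,downstream_flank Scaffold flank lengths (bp).
#' @param seed Integer seed.
#' @return List of class `gene_spec`.
#' @export
gene_spec <- function(n_introns = 9L, intron_length_range = c(48L, 204L),
                      exon_length_range = c(63L, 105L), utr5_length = 69L,
                      promoter_plants = data.frame(
                        name = c("TATA", "MRE"),
                        seq = c("TATAAAT", "TGCACAC"),
                        offset = c(-38L, -1457L)),
                      upstream_flank = 1500L, downstream_flank = 200L,
                      seed = 1L) {
  stopifnot(n_introns >= 0, intron_length_range[1] >= 5,
            diff(intron_length_range) >= 0, exon_length_range[1] >= 1,
            utr5_length >= 0, upstream_flank >= 0, downstream_flank >= 0)
  structure(list(n_introns = as.integer(n_introns),
                 intron_length_range = as.integer(intron_length_range),
                 exon_length_range = as.integer(exon_length_range),
                 utr5_length = as.integer(utr5_length),
                 promoter_plants = promoter_plants,
                 upstream_flank = as.integer(upstream_flank),
                 downstream_flank = as.integer(downstream_flank),
                 seed = as.integer(seed)),
            class = "gene_spec")
}

random_dna <- function(n) {
  if (n == 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## random DNA with no ATG (so the annotated start codon stays the first one)
random_utr <- function(n) {
  s <- random_dna(n)
  while (grepl("ATG", s, fixed = TRUE)) s <- sub("ATG", "ATC", s, fixed = TRUE)
  s
}

## codons per amino acid, from the standard genetic code
codons_by_aa <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
}

reverse_translate <- function(protein_seq) {
  tab <- codons_by_aa()
  aa <- strsplit(protein_seq, "")[[1]]
  codons <- vapply(aa, function(a) {
    opts <- tab[[a]]
    opts[sample.int(length(opts), 1L)]
  }, "")
  paste(codons, collapse = "")
}

## lengths of m parts summing to total, each within [lo, hi] (uniform
## sequential composition sampling); NULL when infeasible
composition_sample <- function(total, m, lo, hi) {
  if (total < m * lo || total > m * hi) return(NULL)
  out <- integer(m)
  remaining <- total
  for (i in seq_len(m)) {
    left <- m - i
    a <- max(lo, remaining - left * hi)
    b <- min(hi, remaining - left * lo)
    if (a > b) return(NULL)
    out[i] <- if (i == m) remaining else a + sample.int(b - a + 1L, 1L) - 1L
    remaining <- remaining - out[i]
  }
  out
}

## TRUE when the intron placed at cdna split position s (last base of the
## left exon) admits no alternative sequence-compatible GT/AG placement
## within +/- window
splice_unambiguous <- function(gene, cdna, s, g_intron_start, intron_len, window = 8L) {
  nc <- nchar(cdna); ngn <- nchar(gene)
  for (t in setdiff(-window:window, 0L)) {
    s2 <- s + t
    if (s2 < 1L || s2 >= nc) next
    ## sequence compatibility: shifting the boundary by t keeps both exon
    ## sides identical between cDNA and genome
    compat <- TRUE
    if (t > 0L) {
      for (p in (s + 1L):s2) {           # bases move into the left exon
        if (substr(cdna, p, p) != substr(gene, g_intron_start + (p - s - 1L),
                                         g_intron_start + (p - s - 1L))) {
          compat <- FALSE; break
        }
      }
    } else {
      g_after <- g_intron_start + intron_len   # genome pos of first base after intron
      for (p in (s2 + 1L):s) {           # bases move into the right exon
        if (substr(cdna, p, p) != substr(gene, g_after - (s - p) - 1L,
                                         g_after - (s - p) - 1L)) {
          compat <- FALSE; break
        }
      }
    }
    if (!compat) next
    d_start <- g_intron_start + t
    d_end <- d_start + intron_len - 1L
    if (d_start < 1L || d_end > ngn) next
    if (substr(gene, d_start, d_start + 1L) == "GT" &&
        substr(gene, d_end - 1L, d_end) == "AG") {
      return(FALSE)
    }
  }
  TRUE
}

#' Generate a synthetic gene (cDNA + scaffold) with ground truth
#'
#' Reverse-translates the protein with seeded-uniform synonymous codons,
#' appends a stop codon, prepends an ATG-free 5' UTR, inserts GT..AG
#' introns at seeded positions within the coding span (re-drawing intron
#' interiors until every boundary admits a unique GT/AG placement), embeds
#' the gene in random scaffold flanks, and plants promoter motifs at the
#' requested offsets from the start codon (edits inside the UTR are
#' propagated to the cDNA so transcript and genome stay consistent).
#'
#' @param protein A [protein_record()] (or plain sequence) to encode.
#' @param spec A [gene_spec()].
#' @return List with `cdna`, `scaffold` (named character), and `truth`:
#'   exon/intron coordinates (0-based half-open on the scaffold, forward
#'   strand), `atg_pos` (1-based), `utr5_length`, `coding_length`,
#'   `strand`.
#' @export
make_gene <- function(protein, spec = gene_spec()) {
  record <- as_protein_record(protein)
  stopifnot(inherits(spec, "gene_spec"))
  with_seed(spec$seed, {
    aa_seq <- record$sequence
    if (substr(aa_seq, 1L, 1L) != "M") aa_seq <- paste0("M", aa_seq)  # initiator
    cds <- reverse_translate(aa_seq)
    cds <- paste0(cds, sample(c("TAA", "TAG", "TGA"), 1L))
    utr5 <- random_utr(spec$utr5_length)
    cdna <- paste0(utr5, cds)
    nc <- nchar(cdna)
    coding_len <- nchar(cds)

    ## coding-piece lengths within the exon range
    pieces <- composition_sample(coding_len, spec$n_introns + 1L,
                                 spec$exon_length_range[1], spec$exon_length_range[2])
    if (is.null(pieces)) {
      stop(sprintf("infeasible spec: %d bp of coding sequence cannot be split into %d exons of %d-%d bp",
                   coding_len, spec$n_introns + 1L,
                   spec$exon_length_range[1], spec$exon_length_range[2]),
           call. = FALSE)
    }
    ## cdna split positions (last base of each exon-but-last, 1-based)
    splits <- spec$utr5_length + cumsum(pieces[-length(pieces)])
    intron_lens <- if (spec$n_introns > 0L) {
      spec$intron_length_range[1] +
        sample.int(diff(spec$intron_length_range) + 1L, spec$n_introns,
                   replace = TRUE) - 1L
    } else integer(0)

    ## assemble gene left to right, re-drawing intron interiors until the
    ## boundary placement is unique
    gene <- ""
    prev <- 0L
    intron_g <- list()
    for (i in seq_along(splits)) {
      gene <- paste0(gene, substr(cdna, prev + 1L, splits[i]))
      g_start <- nchar(gene) + 1L
      len <- intron_lens[i]
      ok <- FALSE
      for (try in 1:100) {
        intr <- paste0("GT", random_dna(len - 4L), "AG")
        cand <- paste0(gene, intr, substr(cdna, splits[i] + 1L, nc))
        if (splice_unambiguous(cand, cdna, splits[i], g_start, len)) {
          ok <- TRUE
          break
        }
      }
      if (!ok) stop("infeasible spec: could not realize an unambiguous GT/AG intron",
                    call. = FALSE)
      gene <- paste0(gene, intr)
      intron_g[[i]] <- c(g_start, g_start + len - 1L)
      prev <- splits[i]
    }
    gene <- paste0(gene, substr(cdna, prev + 1L, nc))

    up <- random_dna(spec$upstream_flank)
    down <- random_dna(spec$downstream_flank)
    scaffold <- paste0(up, gene, down)
    offset0 <- nchar(up)                      # gene starts at offset0 + 1
    atg_pos <- offset0 + spec$utr5_length + 1L

    ## promoter plants: overwrite scaffold bases; propagate UTR edits to cdna
    plants <- spec$promoter_plants
    planted_c <- integer(0)                   # cdna positions covered by plants
    if (!is.null(plants) && nrow(plants) > 0L) {
      for (r in seq_len(nrow(plants))) {
        pseq <- toupper(plants$seq[r])
        plen <- nchar(pseq)
        gpos <- atg_pos + plants$offset[r]    # offset -n: 5'-most base n bp before ATG
        if (gpos < 1L || gpos + plen - 1L >= atg_pos) {
          stop(sprintf("infeasible spec: plant '%s' at offset %d does not fit upstream",
                       plants$name[r], plants$offset[r]), call. = FALSE)
        }
        substr(scaffold, gpos, gpos + plen - 1L) <- pseq
        utr_start_g <- offset0 + 1L
        if (gpos + plen - 1L >= utr_start_g) {  # plant reaches into the transcribed UTR
          ov_from <- max(gpos, utr_start_g)
          c_from <- ov_from - utr_start_g + 1L
          piece <- substr(pseq, ov_from - gpos + 1L, plen)
          substr(cdna, c_from, c_from + nchar(piece) - 1L) <- piece
          planted_c <- c(planted_c, c_from:(c_from + nchar(piece) - 1L))
        }
      }
    }
    ## keep the 5' UTR ATG-free after planting, so the annotated start codon
    ## remains the first ATG of the transcript (edits mirrored to scaffold)
    if (spec$utr5_length >= 3L) {
      repeat {
        hit <- regexpr("ATG", substr(cdna, 1L, spec$utr5_length), fixed = TRUE)
        if (hit < 0L) break
        span <- hit:(hit + 2L)
        free <- setdiff(span, planted_c)
        if (length(free) == 0L) {
          stop("infeasible spec: promoter plants spell an upstream ATG in the UTR",
               call. = FALSE)
        }
        fix_at <- free[length(free)]          # prefer the G
        substr(cdna, fix_at, fix_at) <- "C"
        gfix <- offset0 + fix_at
        substr(scaffold, gfix, gfix) <- "C"
      }
    }

    exon_c <- c(0L, splits, nc)               # cdna boundaries
    exon_g0 <- integer(0); exon_g1 <- integer(0)
    shift <- offset0
    for (i in seq_len(length(exon_c) - 1L)) {
      c1 <- exon_c[i] + 1L; c2 <- exon_c[i + 1L]
      exon_g0 <- c(exon_g0, shift + c1 - 1L)  # 0-based start
      exon_g1 <- c(exon_g1, shift + c2)       # half-open end
      if (i <= length(intron_lens)) shift <- shift + intron_lens[i]
    }
    exons_df <- data.frame(start0 = exon_g0, end0 = exon_g1)
    introns_df <- if (nrow(exons_df) > 1L) {
      data.frame(start0 = exons_df$end0[-nrow(exons_df)],
                 end0 = exons_df$start0[-1L])
    } else {
      data.frame(start0 = integer(), end0 = integer())
    }
    truth <- list(
      exons = exons_df,
      introns = introns_df,
      atg_pos = atg_pos,
      utr5_length = spec$utr5_length,
      coding_length = coding_len,
      strand = "+"
    )
    list(cdna = setNames(cdna, paste0(record$id, "_cdna")),
         scaffold = setNames(scaffold, paste0(record$id, "_scaffold")),
         truth = truth)
  })
}

#' Specification for a synthetic deconvoluted peak list
#'
#' @param apo_mass Apo-protein mass (Da).
#' @param species List of `list(stoich = c(El = n, ...), abundance = a)`.
#' @param mass_error_rel Relative Gaussian mass error SD (default 2e-4,
#'   i.e. 0.02%, below the 0.1% assignment tolerance).
#' @param seed Integer seed.
#' @return List of class `spectrum_spec`.
#' @export
spectrum_spec <- function(apo_mass, species, mass_error_rel = 2e-4, seed = 1L) {
  stopifnot(apo_mass > 0, length(species) > 0)
  ab <- vapply(species, function(s) s$abundance, 0)
  stopifnot(all(ab >= 0))
  structure(list(apo_mass = apo_mass, species = species,
                 mass_error_rel = mass_error_rel, seed = as.integer(seed)),
            class = "spectrum_spec")
}

#' Generate a synthetic deconvoluted peak list with ground truth
#'
#' One peak per species at its theoretical holo mass perturbed by Gaussian
#' relative error, intensity equal to the requested abundance.
#'
#' @param spec A [spectrum_spec()].
#' @return List with `peaks` (data frame `mass_da`, `intensity`) and
#'   `truth` (data frame `label`, `theoretical_mass`, plus one column per
#'   element).
#' @export
make_peaklist <- function(spec) {
  stopifnot(inherits(spec, "spectrum_spec"))
  with_seed(spec$seed, {
    masses <- vapply(spec$species, function(s) holo_mass(spec$apo_mass, s$stoich), 0)
    obs <- masses * (1 + rnorm(length(masses), 0, spec$mass_error_rel))
    elements <- unique(unlist(lapply(spec$species, function(s) names(s$stoich))))
    truth <- data.frame(
      label = vapply(spec$species, function(s) species_label(s$stoich), ""),
      theoretical_mass = masses
    )
    for (el in elements) {
      truth[[el]] <- vapply(spec$species, function(s) {
        n <- s$stoich[el]
        if (is.na(n)) 0L else as.integer(n)
      }, 0L)
    }
    list(peaks = data.frame(mass_da = obs,
                            intensity = vapply(spec$species, function(s) s$abundance, 0)),
         truth = truth)
  })
}

#' Generate a synthetic Cu-tolerance growth table
#'
#' Endpoint OD600 is a saturating control level scaled by a
#' monotone-decreasing Hill-type dose factor `1 / (1 + (dose/ic50)^hill)`
#' plus Gaussian noise (truncated at zero); triplicates by default.
#'
#' @param doses Cu concentrations (one must be 0, the control).
#' @param strain Strain/construct id.
#' @param unit Concentration unit label, carried through unchanged.
#' @param n_replicates Replicates per dose.
#' @param od_control Endpoint OD600 of the unsupplemented culture.
#' @param ic50,hill Dose-response parameters of the inhibition factor.
#' @param noise_sd Gaussian OD noise SD.
#' @param seed Integer seed.
#' @return List with `table` (rows `strain`, `cu_conc`, `unit`, `replicate`,
#'   `od600`) and `truth` (`dose_factor`, `expected_percent` per dose).
#' @export
make_growth <- function(doses = c(0, 2, 4, 7, 10, 15, 20, 30),
                        strain = "construct", unit = "uM", n_replicates = 3L,
                        od_control = 2.0, ic50 = 10, hill = 2,
                        noise_sd = 0.05, seed = 1L) {
  stopifnot(0 %in% doses, n_replicates >= 1, od_control > 0)
  with_seed(seed, {
    factor <- 1 / (1 + (doses / ic50)^hill)
    rows <- list()
    for (i in seq_along(doses)) {
      od <- pmax(od_control * factor[i] + rnorm(n_replicates, 0, noise_sd), 0)
      rows[[i]] <- data.frame(strain = strain, cu_conc = doses[i], unit = unit,
                              replicate = seq_len(n_replicates), od600 = od)
    }
    list(table = do.call(rbind, rows),
         truth = data.frame(cu_conc = doses, dose_factor = factor,
                            expected_percent = 100 * factor))
  })
}
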