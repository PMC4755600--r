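## Splice-aware gene-model reconstruction: exact-seed anchoring, collinear
## chaining, mismatch-tolerant exon extension, GT/AG-constrained intron
## boundary placement, ORF validation, promoter motif scanning and GFF3
## export. Coordinates are 0-based half-open internally (and in the model),
## 1-based inclusive in GFF3.

check_dna <- function(x, what = "sequence") {
  if (!is.character(x) || length(x) != 1L || is.na(x) || nchar(x) == 0L) {
    stop(sprintf("invalid %s: must be one non-empty string", what), call. = FALSE)
  }
  chars <- strsplit(x, "")[[1]]
  bad <- which(!chars %in% c("A", "C", "G", "T", "N"))
  if (length(bad) > 0L) {
    stop(sprintf("invalid %s: character '%s' at position %d (alphabet is A/C/G/T/N)",
                 what, chars[bad[1]], bad[1]), call. = FALSE)
  }
  invisible(TRUE)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Read DNA sequences from a FASTA file
#'
#' @param path FASTA file.
#' @return Named character vector of upper-case sequences.
#' @export
read_dna_fasta <- function(path) {
  dss <- Biostrings::readDNAStringSet(path)
  ids <- vapply(strsplit(names(dss), "\\s+"), `[`, "", 1L)
  setNames(toupper(as.character(dss)), ids)
}

#' Parameters for spliced alignment
#'
#' @param seed_kmer Exact-seed length (1-32).
#' @param max_mismatch_rate Maximum tolerated substitution rate within exons
#'   (fraction of cDNA length). Default 0.02, comfortably above the ~1%
#'   strain-polymorphism level typical of cDNA-vs-reference comparisons.
#' @param min_intron,max_intron Intron length bounds (bases).
#' @param enforce_gt_ag Require every intron to start `GT` and end `AG`
#'   (canonical splice donors/acceptors), sliding ambiguous boundaries to
#'   the first satisfying placement.
#' @param min_coverage Minimum fraction of the cDNA that must be covered by
#'   exact seed chains before extension.
#' @return List of class `splice_params`.
#' @export
splice_params <- function(seed_kmer = 12L, max_mismatch_rate = 0.02,
                          min_intron = 40L, max_intron = 5000L,
                          enforce_gt_ag = TRUE, min_coverage = 0.5) {
  stopifnot(seed_kmer > 0, seed_kmer <= 32, min_intron < max_intron,
            max_mismatch_rate >= 0, min_coverage > 0, min_coverage <= 1)
  structure(list(seed_kmer = as.integer(seed_kmer),
                 max_mismatch_rate = max_mismatch_rate,
                 min_intron = as.integer(min_intron),
                 max_intron = as.integer(max_intron),
                 enforce_gt_ag = isTRUE(enforce_gt_ag),
                 min_coverage = min_coverage),
            class = "splice_params")
}

## All exact k-mer matches between cdna and genome, merged into maximal
## same-diagonal runs. Returns data.frame(cs, ce, d) in 1-based cDNA coords
## (genome pos = cdna pos + d).
seed_runs <- function(cdna, genome, k) {
  nc <- nchar(cdna)
  ng <- nchar(genome)
  if (nc < k || ng < k) return(NULL)
  cpos <- seq_len(nc - k + 1L)
  gpos <- seq_len(ng - k + 1L)
  ckmer <- substring(cdna, cpos, cpos + k - 1L)
  gkmer <- substring(genome, gpos, gpos + k - 1L)
  keep_c <- !grepl("N", ckmer, fixed = TRUE)
  keep_g <- !grepl("N", gkmer, fixed = TRUE)
  gmap <- split(gpos[keep_g], gkmer[keep_g])
  hits_c <- integer(0); hits_g <- integer(0)
  for (i in cpos[keep_c]) {
    gs <- gmap[[ckmer[i]]]
    if (!is.null(gs)) {
      hits_c <- c(hits_c, rep.int(i, length(gs)))
      hits_g <- c(hits_g, gs)
    }
  }
  if (length(hits_c) == 0L) return(NULL)
  d <- hits_g - hits_c
  ord <- order(d, hits_c)
  hc <- hits_c[ord]; hd <- d[ord]
  new_run <- c(TRUE, diff(hc) > k | diff(hd) != 0L)
  run_id <- cumsum(new_run)
  cs <- tapply(hc, run_id, min)
  ce <- tapply(hc, run_id, max) + k - 1L
  dd <- tapply(hd, run_id, `[`, 1L)
  data.frame(cs = as.integer(cs), ce = as.integer(ce), d = as.integer(dd))
}

count_mismatches <- function(cchars, gchars, cfrom, cto, d) {
  if (cto < cfrom) return(0L)
  cseg <- cchars[cfrom:cto]
  gseg <- gchars[(cfrom + d):(cto + d)]
  ## N is mismatch-neutral during extension
  sum(cseg != gseg & cseg != "N" & gseg != "N")
}

## Chain and extend on one strand. Returns NULL on failure, else a list with
## exon cDNA segments, diagonals, mismatches, intron boundary records.
align_one_strand <- function(cdna, genome, params) {
  k <- params$seed_kmer
  nc <- nchar(cdna); ng <- nchar(genome)
  runs <- seed_runs(cdna, genome, k)
  if (is.null(runs) || nrow(runs) == 0L) return(NULL)
  cchars <- strsplit(cdna, "")[[1]]
  gchars <- strsplit(genome, "")[[1]]
  runs <- runs[order(runs$cs, runs$ce), , drop = FALSE]
  rownames(runs) <- NULL
  n <- nrow(runs)
  len <- runs$ce - runs$cs + 1L
  dp <- as.numeric(len)
  parent <- rep(0L, n)
  intron_open_pen <- 4
  mism_pen <- 2
  for (i in seq_len(n)) {
    for (j in seq_len(max(i - 1L, 0L))) {
      if (runs$cs[j] >= runs$cs[i] || runs$ce[j] >= runs$ce[i]) next
      delta <- runs$d[i] - runs$d[j]
      gap_c <- runs$cs[i] - runs$ce[j] - 1L
      if (delta == 0L) {
        if (gap_c < 0L) next
        mm <- count_mismatches(cchars, gchars, runs$ce[j] + 1L, runs$cs[i] - 1L, runs$d[i])
        pen <- mism_pen * mm
      } else if (delta >= params$min_intron && delta <= params$max_intron) {
        pen <- intron_open_pen + mism_pen * max(gap_c, 0L)
      } else {
        next
      }
      cand <- dp[j] + len[i] - pen
      if (cand > dp[i]) { dp[i] <- cand; parent[i] <- j }
    }
  }
  end_i <- which.max(dp)
  chain <- integer(0)
  i <- end_i
  while (i != 0L) { chain <- c(i, chain); i <- parent[i] }
  runs <- runs[chain, , drop = FALSE]
  cov <- sum(runs$ce - runs$cs + 1L)
  if (cov / nc < params$min_coverage) return(NULL)

  ## head/tail extension must stay inside the genome
  if (1L + runs$d[1L] < 1L) return(NULL)
  if (nc + runs$d[nrow(runs)] > ng) return(NULL)

  total_mm <- 0L
  total_mm <- total_mm + count_mismatches(cchars, gchars, 1L, runs$cs[1L] - 1L, runs$d[1L])
  total_mm <- total_mm + count_mismatches(cchars, gchars, runs$ce[nrow(runs)] + 1L, nc,
                                          runs$d[nrow(runs)])

  ## walk the chain: exon segments in cDNA coords + introns
  exon_c_start <- 1L
  cur_d <- runs$d[1L]
  exons <- list()     # (c_start, c_end, d)
  introns <- list()   # (g_start, g_end, donor, acceptor)  1-based on this strand
  noncanon <- character(0)
  if (nrow(runs) > 1L) {
    for (i in 2L:nrow(runs)) {
      delta <- runs$d[i] - runs$d[i - 1L]
      if (delta == 0L) {
        total_mm <- total_mm + count_mismatches(cchars, gchars, runs$ce[i - 1L] + 1L,
                                                runs$cs[i] - 1L, cur_d)
        next
      }
      L <- runs$ce[i - 1L]; R <- runs$cs[i]
      dL <- runs$d[i - 1L]; dR <- runs$d[i]
      s_lo <- min(L, R - 1L); s_hi <- max(L, R - 1L)
      s_cand <- s_lo:s_hi
      mm_of <- function(s) {
        count_mismatches(cchars, gchars, L + 1L, s, dL) +
          count_mismatches(cchars, gchars, s + 1L, R - 1L, dR)
      }
      gtag_of <- function(s) {
        don <- s + dL + 1L
        acc <- s + dR
        don >= 1L && acc <= ng &&
          gchars[don] == "G" && gchars[don + 1L] == "T" &&
          gchars[acc - 1L] == "A" && gchars[acc] == "G"
      }
      ok <- vapply(s_cand, gtag_of, TRUE)
      if (any(ok)) {
        s <- s_cand[which(ok)[1L]]           # first GT/AG placement, left to right
      } else if (params$enforce_gt_ag) {
        noncanon <- c(noncanon, sprintf("gap after cDNA position %d", L))
        s <- s_cand[1L]
      } else {
        mms <- vapply(s_cand, mm_of, 0L)
        s <- s_cand[which.min(mms)]          # leftmost minimal-mismatch split
      }
      total_mm <- total_mm + mm_of(s)
      exons[[length(exons) + 1L]] <- c(exon_c_start, s, cur_d)
      introns[[length(introns) + 1L]] <- list(
        g_start = s + dL + 1L, g_end = s + dR,
        donor = paste0(gchars[s + dL + 1L], gchars[s + dL + 2L]),
        acceptor = paste0(gchars[s + dR - 1L], gchars[s + dR]))
      exon_c_start <- s + 1L
      cur_d <- dR
    }
  }
  exons[[length(exons) + 1L]] <- c(exon_c_start, nc, cur_d)
  if (length(noncanon) > 0L) {
    stop(sprintf("non-canonical splice: no GT..AG placement in %s",
                 paste(noncanon, collapse = "; ")), call. = FALSE)
  }
  list(exons = do.call(rbind, exons), introns = introns, mismatches = total_mm,
       score = (nc - total_mm) - 2 * total_mm - 4 * length(introns))
}

#' Spliced alignment of a cDNA against a genomic scaffold
#'
#' Anchors exact seed k-mers, chains them collinearly, extends to
#' mismatch-tolerant exon blocks, turns genomic gaps between consecutive
#' blocks into introns, and slides ambiguous intron boundaries to the first
#' (left-to-right) placement satisfying the canonical GT/AG rule. Both
#' strands are searched and the better-scoring one is returned.
#'
#' @param cdna,genome Nucleotide strings over A/C/G/T/N (or length-1 named
#'   vectors from [read_dna_fasta()]).
#' @param params A [splice_params()] object.
#' @param cdna_id,scaffold_id Identifiers stored in the model (default from
#'   sequence names, if any).
#' @return Object of class `gene_model`: `scaffold_id`, `cdna_id`, `strand`,
#'   `exons` (data frame `start0`/`end0`, 0-based half-open, ascending on
#'   the forward scaffold axis), `introns` (`start0`, `end0`, `donor`,
#'   `acceptor`; dinucleotides read in transcription direction),
#'   `mismatches`, `cdna_length`, `coding` (in-frame ORF location from
#'   [check_coding()] logic), `score`.
#' @export
spliced_align <- function(cdna, genome, params = splice_params(),
                          cdna_id = NULL, scaffold_id = NULL) {
  if (is.null(cdna_id)) cdna_id <- if (!is.null(names(cdna))) names(cdna)[1] else "cdna"
  if (is.null(scaffold_id)) scaffold_id <- if (!is.null(names(genome))) names(genome)[1] else "scaffold"
  cdna <- toupper(as.character(cdna)[1])
  genome <- toupper(as.character(genome)[1])
  check_dna(cdna, "cdna")
  check_dna(genome, "genome")
  if (nchar(cdna) < 2L * params$seed_kmer) {
    stop("invalid input: cdna shorter than two seed k-mers", call. = FALSE)
  }
  ng <- nchar(genome)
  res_plus <- tryCatch(align_one_strand(cdna, genome, params), error = function(e) e)
  res_minus <- tryCatch(align_one_strand(cdna, revcomp(genome), params), error = function(e) e)
  rate_ok <- function(r) {
    !is.null(r) && !inherits(r, "error") &&
      r$mismatches / nchar(cdna) <= params$max_mismatch_rate
  }
  pick <- function(r) if (rate_ok(r)) r$score else -Inf
  if (pick(res_plus) == -Inf && pick(res_minus) == -Inf) {
    ## surface the most informative diagnosis
    for (r in list(res_plus, res_minus)) {
      if (inherits(r, "error") && grepl("non-canonical splice", conditionMessage(r))) stop(r)
    }
    for (r in list(res_plus, res_minus)) {
      if (!is.null(r) && !inherits(r, "error")) {
        stop(sprintf("no alignment: mismatch rate %.4f exceeds max_mismatch_rate %.4f",
                     r$mismatches / nchar(cdna), params$max_mismatch_rate), call. = FALSE)
      }
    }
    stop("no alignment: no collinear seed chain above minimum coverage", call. = FALSE)
  }
  strand <- if (pick(res_plus) >= pick(res_minus)) "+" else "-"
  res <- if (strand == "+") res_plus else res_minus

  ex <- res$exons  # columns: c_start, c_end, d (strand-local 1-based)
  g1 <- ex[, 1L] + ex[, 3L]          # genomic 1-based start on aligned strand
  g2 <- ex[, 2L] + ex[, 3L]
  if (strand == "+") {
    exons <- data.frame(start0 = g1 - 1L, end0 = g2)
    introns <- lapply(res$introns, function(i) {
      data.frame(start0 = i$g_start - 1L, end0 = i$g_end,
                 donor = i$donor, acceptor = i$acceptor)
    })
  } else {
    exons <- data.frame(start0 = ng - g2, end0 = ng - g1 + 1L)
    introns <- lapply(res$introns, function(i) {
      data.frame(start0 = ng - i$g_end, end0 = ng - i$g_start + 1L,
                 donor = i$donor, acceptor = i$acceptor)
    })
  }
  exons <- exons[order(exons$start0), , drop = FALSE]
  rownames(exons) <- NULL
  introns <- if (length(introns) > 0L) {
    ii <- do.call(rbind, introns)
    ii <- ii[order(ii$start0), , drop = FALSE]
    rownames(ii) <- NULL
    ii
  } else {
    data.frame(start0 = integer(), end0 = integer(),
               donor = character(), acceptor = character())
  }
  model <- structure(list(
    scaffold_id = scaffold_id, cdna_id = cdna_id, strand = strand,
    exons = exons, introns = introns, mismatches = res$mismatches,
    cdna_length = nchar(cdna), coding = find_orf(cdna), score = res$score
  ), class = "gene_model")
  model
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s on %s (%s): %d exon(s), %d intron(s), %d mismatch(es)\n",
              x$cdna_id, x$scaffold_id, x$strand, nrow(x$exons), nrow(x$introns),
              x$mismatches))
  if (!is.na(x$coding$coding_start)) {
    cat(sprintf("  coding: cDNA %d..%d (%d bp, %d aa), 5'UTR %d bp\n",
                x$coding$coding_start, x$coding$coding_end,
                x$coding$coding_length, x$coding$protein_length,
                x$coding$utr5_length))
  }
  invisible(x)
}

## First in-frame ORF: earliest ATG with an in-frame stop codon.
find_orf <- function(cdna) {
  nc <- nchar(cdna)
  stops <- c("TAA", "TAG", "TGA")
  atg <- gregexpr("ATG", cdna, fixed = TRUE)[[1]]
  atg <- atg[atg > 0]
  for (p in atg) {
    q <- p
    while (q + 2L <= nc) {
      codon <- substr(cdna, q, q + 2L)
      if (q > p && codon %in% stops) {
        return(list(coding_start = p, coding_end = q + 2L,
                    coding_length = q + 2L - p + 1L,
                    protein_length = (q + 2L - p + 1L) %/% 3L - 1L,
                    utr5_length = p - 1L,
                    start_codon = "ATG", stop_codon = codon))
      }
      q <- q + 3L
    }
  }
  list(coding_start = NA_integer_, coding_end = NA_integer_,
       coding_length = NA_integer_, protein_length = NA_integer_,
       utr5_length = NA_integer_, start_codon = NA_character_,
       stop_codon = NA_character_)
}

#' Validate the coding structure of a gene model
#'
#' Checks that exon lengths sum to the cDNA length, that the cDNA carries an
#' in-frame ATG..stop open reading frame, and that the coding length equals
#' `3 * (protein length + 1)` (the stop codon included). The symptoms
#' reported on failure (missing in-frame ATG, missing stop) are exactly the
#' ones that betray a 5'-truncated gene annotation.
#'
#' @param model A `gene_model` from [spliced_align()], or `NULL` to check a
#'   bare cDNA.
#' @param cdna The cDNA sequence the model was built from.
#' @return List of class `coding_report`: `ok`, `coding_length`,
#'   `protein_length`, `utr5_length`, `start_codon`, `stop_codon`,
#'   `diagnostics` (character vector, empty when ok).
#' @export
check_coding <- function(model = NULL, cdna) {
  cdna <- toupper(as.character(cdna)[1])
  check_dna(cdna, "cdna")
  diags <- character(0)
  if (!is.null(model)) {
    stopifnot(inherits(model, "gene_model"))
    if (sum(model$exons$end0 - model$exons$start0) != nchar(cdna)) {
      diags <- c(diags, "exon lengths do not sum to the cDNA length")
    }
  }
  orf <- find_orf(cdna)
  if (is.na(orf$coding_start)) {
    has_atg <- grepl("ATG", cdna, fixed = TRUE)
    diags <- c(diags, if (!has_atg) "no ATG start codon" else
      "no in-frame stop codon downstream of any ATG")
  } else if (orf$coding_length %% 3L != 0L) {
    diags <- c(diags, "coding length not divisible by 3")  # unreachable by construction
  }
  structure(c(orf, list(ok = length(diags) == 0L, diagnostics = diags)),
            class = "coding_report")
}

#' @export
print.coding_report <- function(x, ...) {
  if (x$ok) {
    cat(sprintf("<coding_report> OK: %d bp coding (%d aa + stop), 5'UTR %d bp\n",
                x$coding_length, x$protein_length, x$utr5_length))
  } else {
    cat("<coding_report> PROBLEMS:\n")
    for (d in x$diagnostics) cat("  -", d, "\n")
  }
  invisible(x)
}

#' Default promoter motifs
#'
#' `TATA` = `TATAWAW` (canonical TATA box) and `MRE` = `TGCRCNC` (standard
#' metal-response-element core). IUPAC-degenerate; override freely.
#'
#' @return Named character vector of IUPAC motifs.
#' @export
default_motifs <- function() {
  c(TATA = "TATAWAW", MRE = "TGCRCNC")
}

#' Scan an upstream region for promoter motifs
#'
#' Matches IUPAC-degenerate motifs on both strands of the region upstream of
#' a translation start. Offsets use the convention A of ATG = +1 with no
#' position 0, so a motif whose 5'-most base sits n bases before the ATG has
#' offset -n. For minus-strand hits the offset refers to the leftmost base
#' on the coding strand and `matched_seq` is the motif as read on the minus
#' strand.
#'
#' @param upstream Sequence 5'->3' on the coding strand, ending immediately
#'   before the ATG (see `atg_gap`).
#' @param motifs Named character vector of IUPAC motifs
#'   (default [default_motifs()]).
#' @param atg_gap Bases between the end of `upstream` and the A of the ATG
#'   (0 when the region ends immediately before the start codon).
#' @return Data frame with `motif_name`, `offset`, `matched_seq`, `strand`.
#' @export
scan_promoter <- function(upstream, motifs = default_motifs(), atg_gap = 0L) {
  upstream <- toupper(as.character(upstream)[1])
  check_dna(upstream, "upstream")
  iupac <- names(Biostrings::IUPAC_CODE_MAP)
  L <- nchar(upstream)
  subj <- Biostrings::DNAString(upstream)
  out <- list()
  if (is.null(names(motifs)) || any(names(motifs) == "")) {
    stop("invalid motif: motifs must be a named character vector", call. = FALSE)
  }
  for (nm in names(motifs)) {
    motif <- toupper(motifs[[nm]])
    chars <- strsplit(motif, "")[[1]]
    if (length(chars) == 0L || any(!chars %in% iupac)) {
      stop(sprintf("invalid motif '%s': not an IUPAC nucleotide string", nm),
           call. = FALSE)
    }
    pat <- Biostrings::DNAString(motif)
    for (strand in c("+", "-")) {
      p <- if (strand == "+") pat else Biostrings::reverseComplement(pat)
      m <- Biostrings::matchPattern(p, subj, fixed = FALSE)
      starts <- Biostrings::start(m)
      for (s in starts) {
        seg <- substr(upstream, s, s + length(p) - 1L)
        out[[length(out) + 1L]] <- data.frame(
          motif_name = nm,
          offset = s - L - 1L - as.integer(atg_gap),
          matched_seq = if (strand == "+") seg else revcomp(seg),
          strand = strand
        )
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(motif_name = character(), offset = integer(),
                      matched_seq = character(), strand = character()))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$offset, res$motif_name), , drop = FALSE]
  rownames(res) <- NULL
  res
}

## Map a cDNA interval (1-based inclusive) to genomic pieces (0-based
## half-open) through the model's exons, respecting strand.
map_cdna_to_genome <- function(model, from, to) {
  ex <- model$exons
  n <- nrow(ex)
  ord <- if (model$strand == "+") seq_len(n) else rev(seq_len(n))
  lens <- ex$end0 - ex$start0
  pieces <- list()
  cpos <- 0L
  for (i in ord) {
    clen <- lens[i]
    c1 <- cpos + 1L; c2 <- cpos + clen
    a <- max(from, c1); b <- min(to, c2)
    if (a <= b) {
      if (model$strand == "+") {
        pieces[[length(pieces) + 1L]] <- data.frame(
          start0 = ex$start0[i] + (a - c1), end0 = ex$start0[i] + (b - c1) + 1L)
      } else {
        pieces[[length(pieces) + 1L]] <- data.frame(
          start0 = ex$end0[i] - (b - c1) - 1L, end0 = ex$end0[i] - (a - c1))
      }
    }
    cpos <- c2
  }
  if (length(pieces) == 0L) return(data.frame(start0 = integer(), end0 = integer()))
  out <- do.call(rbind, pieces)
  out <- out[order(out$start0), , drop = FALSE]
  rownames(out) <- NULL
  out
}

gff3_attr <- function(...) {
  kv <- list(...)
  paste(sprintf("%s=%s", names(kv), unlist(kv)), collapse = ";")
}

#' Export a gene model as GFF3
#'
#' Writes gene, mRNA, exon, CDS and five_prime_UTR features with 1-based
#' inclusive coordinates (GFF3 standard); the model's internal 0-based
#' half-open exons convert as `start0 + 1 .. end0`. CDS and UTR features are
#' emitted when the model carries an in-frame ORF.
#'
#' @param model A `gene_model`.
#' @param file Output path; when `NULL` the GFF3 text lines are returned.
#' @param gene_id Feature ID stem.
#' @return Invisibly (or visibly, when `file` is `NULL`) the GFF3 lines.
#' @export
export_gff3 <- function(model, file = NULL, gene_id = NULL) {
  stopifnot(inherits(model, "gene_model"))
  if (is.null(gene_id)) gene_id <- model$cdna_id
  ex <- model$exons
  src <- "modmt"
  seqid <- model$scaffold_id
  strand <- model$strand
  g1 <- min(ex$start0) + 1L
  g2 <- max(ex$end0)
  lines <- c("##gff-version 3",
             sprintf("##sequence-region %s %d %d", seqid, 1L, g2))
  row <- function(type, s0, e0, phase = ".", attrs) {
    sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t%s\t%s",
            seqid, src, type, s0 + 1L, e0, strand, phase, attrs)
  }
  lines <- c(lines, row("gene", g1 - 1L, g2, ".", gff3_attr(ID = gene_id)))
  mrna_id <- paste0(gene_id, ".t1")
  lines <- c(lines, row("mRNA", g1 - 1L, g2, ".",
                        gff3_attr(ID = mrna_id, Parent = gene_id)))
  for (i in seq_len(nrow(ex))) {
    lines <- c(lines, row("exon", ex$start0[i], ex$end0[i], ".",
                          gff3_attr(ID = sprintf("%s.exon%d", mrna_id, i),
                                    Parent = mrna_id)))
  }
  cs <- model$coding
  if (!is.null(cs) && !is.na(cs$coding_start)) {
    if (cs$utr5_length > 0L) {
      utr <- map_cdna_to_genome(model, 1L, cs$utr5_length)
      for (i in seq_len(nrow(utr))) {
        lines <- c(lines, row("five_prime_UTR", utr$start0[i], utr$end0[i], ".",
                              gff3_attr(ID = sprintf("%s.utr5.%d", mrna_id, i),
                                        Parent = mrna_id)))
      }
    }
    cds <- map_cdna_to_genome(model, cs$coding_start, cs$coding_end)
    ## phase: pieces in transcription order
    ord <- if (strand == "+") order(cds$start0) else order(-cds$start0)
    cdslen <- cds$end0 - cds$start0
    before <- c(0L, cumsum(cdslen[ord]))[seq_along(ord)]
    phase <- (3L - (before %% 3L)) %% 3L
    for (idx in seq_along(ord)) {
      i <- ord[idx]
      lines <- c(lines, row("CDS", cds$start0[i], cds$end0[i],
                            as.character(phase[idx]),
                            gff3_attr(ID = paste0(mrna_id, ".cds"), Parent = mrna_id)))
    }
  }
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}
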