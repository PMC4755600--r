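# n_aa defaults to a size whose coding length fits the exon-length range
make_test_gene <- function(n_aa = 28L * (n_introns + 1L), n_introns = 3, seed = 1,
                           upstream = 300L, ...) {
  prot <- random_protein(n_aa, cys_prob = 0.1)
  make_gene(protein_record("p", prot),
            gene_spec(n_introns = n_introns, seed = seed,
                      upstream_flank = upstream, downstream_flank = 100L,
                      promoter_plants = NULL, ...))
}

test_that("planted introns are recovered exactly, including boundaries", {
  g <- make_test_gene(n_aa = 90, n_introns = 3, seed = 12)
  m <- spliced_align(g$cdna, g$scaffold)
  expect_equal(m$exons$start0, g$truth$exons$start0)
  expect_equal(m$exons$end0, g$truth$exons$end0)
  expect_equal(m$introns$start0, g$truth$introns$start0)
  expect_equal(m$introns$end0, g$truth$introns$end0)
  expect_equal(m$mismatches, 0L)
  expect_equal(m$strand, "+")
  expect_true(all(m$introns$donor == "GT"))
  expect_true(all(m$introns$acceptor == "AG"))
})

test_that("a cDNA identical to a genome segment maps to one clean exon", {
  cdna <- g <- NULL
  set.seed(4)
  cdna <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE), collapse = "")
  genome <- paste0(strrep("T", 150), cdna, strrep("A", 150))
  m <- spliced_align(cdna, genome)
  expect_equal(nrow(m$exons), 1L)
  expect_equal(nrow(m$introns), 0L)
  expect_equal(m$mismatches, 0L)
  expect_equal(m$exons$start0, 150L)
  expect_equal(m$exons$end0, 550L)
})

test_that("exon-internal substitutions are tolerated and counted", {
  g <- make_test_gene(n_aa = 90, n_introns = 2, seed = 31)
  cdna <- g$cdna[[1]]
  # mutate three bases well inside the first exon, away from splice junctions
  for (p in c(20L, 30L, 40L)) {
    old <- substr(cdna, p, p)
    substr(cdna, p, p) <- setdiff(c("A", "C", "G", "T"), old)[1]
  }
  m <- spliced_align(cdna, g$scaffold)
  expect_equal(m$exons$start0, g$truth$exons$start0)
  expect_equal(m$exons$end0, g$truth$exons$end0)
  expect_equal(m$mismatches, 3L)
  # beyond the mismatch budget the alignment is refused
  expect_error(spliced_align(cdna, g$scaffold,
                             splice_params(max_mismatch_rate = 0.002)),
               "mismatch rate")
})

test_that("exon lengths always sum to the cDNA length", {
  for (seed in 1:8) {
    g <- make_test_gene(n_introns = (seed %% 4) + 1, seed = seed + 100)
    m <- spliced_align(g$cdna, g$scaffold)
    expect_equal(sum(m$exons$end0 - m$exons$start0), nchar(g$cdna[[1]]))
  }
})

test_that("aligning the reverse-complemented genome mirrors the model", {
  g <- make_test_gene(n_aa = 90, n_introns = 3, seed = 77)
  m_fwd <- spliced_align(g$cdna, g$scaffold)
  L <- nchar(g$scaffold[[1]])
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(g$scaffold[[1]])))
  m_rev <- spliced_align(g$cdna, rc)
  expect_equal(m_rev$strand, "-")
  expect_equal(sort(L - m_fwd$exons$end0), sort(m_rev$exons$start0))
  expect_equal(sort(L - m_fwd$exons$start0), sort(m_rev$exons$end0))
  expect_true(all(m_rev$introns$donor == "GT"))
  expect_true(all(m_rev$introns$acceptor == "AG"))
})

test_that("non-canonical introns trigger the splice signal unless relaxed", {
  g <- make_test_gene(n_aa = 60, n_introns = 1, seed = 55)
  scaf <- g$scaffold[[1]]
  i0 <- g$truth$introns$start0[1]
  i1 <- g$truth$introns$end0[1]
  substr(scaf, i0 + 1L, i0 + 2L) <- "CT"      # break the donor
  substr(scaf, i1 - 1L, i1) <- "AC"           # break the acceptor
  expect_error(spliced_align(g$cdna, scaf), "non-canonical splice")
  m <- spliced_align(g$cdna, scaf, splice_params(enforce_gt_ag = FALSE))
  expect_equal(nrow(m$introns), 1L)
  expect_equal(sum(m$exons$end0 - m$exons$start0), nchar(g$cdna[[1]]))
})

test_that("unalignable input raises the no-alignment signal", {
  set.seed(9)
  cdna <- paste(sample(c("A", "C"), 200, replace = TRUE), collapse = "")
  genome <- strrep("GT", 500)
  expect_error(spliced_align(cdna, genome), "no alignment")
  expect_error(spliced_align("ACGT", genome), "shorter than two seed k-mers")
})

test_that("coding checks report ORF arithmetic and truncation symptoms", {
  r <- check_coding(NULL, "ATGTGA")
  expect_true(r$ok)
  expect_equal(r$coding_length, 6L)
  expect_equal(r$utr5_length, 0L)
  expect_equal(r$coding_length, 3L * (r$protein_length + 1L))

  # a 26-aa ORF spans 81 bp = 3 * (26 + 1)
  g26 <- make_gene(protein_record("nc", short_mt_seq),
                   gene_spec(n_introns = 0, utr5_length = 20,
                             promoter_plants = NULL, upstream_flank = 60,
                             seed = 3))
  r26 <- check_coding(NULL, g26$cdna[[1]])
  expect_equal(r26$coding_length, 81L)
  expect_equal(r26$protein_length, 26L)
  expect_equal(r26$utr5_length, 20L)

  # 5'-truncated gene symptom: no in-frame start codon
  bad <- check_coding(NULL, "CCCTGACCCTTTGGG")
  expect_false(bad$ok)
  expect_match(paste(bad$diagnostics, collapse = " "), "ATG")
})

test_that("promoter plants are found at their planted offsets", {
  up <- strrep("C", 1500)
  substr(up, 1500 - 37, 1500 - 31) <- "TATAAAT"    # first base 38 bp upstream
  substr(up, 1500 - 1456, 1500 - 1450) <- "TGCACAC"
  hits <- scan_promoter(up)
  tata <- hits[hits$motif_name == "TATA" & hits$strand == "+", ]
  mre <- hits[hits$motif_name == "MRE" & hits$strand == "+", ]
  expect_equal(tata$offset, -38L)
  expect_equal(tata$matched_seq, "TATAAAT")
  expect_equal(mre$offset, -1457L)
  # an all-C region holds no TATA hit at all
  none <- scan_promoter(strrep("C", 400), motifs = c(TATA = "TATAWAW"))
  expect_equal(nrow(none), 0L)
  expect_error(scan_promoter(up, motifs = c(bad = "TAZA")), "invalid motif")
})

test_that("GFF3 export round-trips through an independent parser", {
  skip_if_not_installed("rtracklayer")
  g <- make_test_gene(n_aa = 100, n_introns = 9, seed = 202,
                      exon_length_range = c(25L, 45L))
  m <- spliced_align(g$cdna, g$scaffold)
  expect_equal(nrow(m$exons), 10L)
  gff <- tempfile(fileext = ".gff3")
  export_gff3(m, gff)
  imported <- rtracklayer::import(gff)
  ex <- imported[imported$type == "exon"]
  expect_equal(length(ex), 10L)
  expect_equal(GenomicRanges::start(ex) - 1L, m$exons$start0)
  expect_equal(GenomicRanges::end(ex), m$exons$end0)
  expect_true(all(as.character(GenomicRanges::strand(ex)) == m$strand))
  cds <- imported[imported$type == "CDS"]
  expect_equal(sum(GenomicRanges::width(cds)), m$coding$coding_length)

  # minus-strand model: coordinates stay on the forward axis, strand flips
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(g$scaffold[[1]])))
  m2 <- spliced_align(g$cdna, rc)
  gff2 <- tempfile(fileext = ".gff3")
  export_gff3(m2, gff2)
  imported2 <- rtracklayer::import(gff2)
  ex2 <- imported2[imported2$type == "exon"]
  expect_equal(GenomicRanges::start(ex2) - 1L, m2$exons$start0)
  expect_true(all(as.character(GenomicRanges::strand(ex2)) == "-"))

  # single-exon model: one exon feature with matching coordinates
  set.seed(14)
  cd <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE), collapse = "")
  gn <- paste0(strrep("A", 100), cd, strrep("C", 100))
  m1 <- spliced_align(cd, gn)
  gff1 <- tempfile(fileext = ".gff3")
  export_gff3(m1, gff1)
  ex1 <- rtracklayer::import(gff1)
  ex1 <- ex1[ex1$type == "exon"]
  expect_equal(length(ex1), 1L)
  expect_equal(GenomicRanges::start(ex1), 101L)
  expect_equal(GenomicRanges::end(ex1), 400L)
})
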