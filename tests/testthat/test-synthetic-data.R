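test_that("generators are deterministic given spec + seed", {
  a <- make_protein(architecture_spec(3, 1, 2, seed = 5))
  b <- make_protein(architecture_spec(3, 1, 2, seed = 5))
  expect_identical(a, b)
  c <- make_protein(architecture_spec(3, 1, 2, seed = 6))
  expect_false(identical(a$record$sequence, c$record$sequence))

  p <- protein_record("p", random_protein(70, 0.1))
  g1 <- make_gene(p, gene_spec(n_introns = 2, seed = 3, promoter_plants = NULL))
  g2 <- make_gene(p, gene_spec(n_introns = 2, seed = 3, promoter_plants = NULL))
  expect_identical(g1, g2)

  s <- spectrum_spec(25377.62, list(list(stoich = c(Zn = 18), abundance = 1)),
                     seed = 4)
  expect_identical(make_peaklist(s), make_peaklist(s))
  expect_identical(make_growth(seed = 2), make_growth(seed = 2))
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  invisible(make_protein(architecture_spec(2, 1, 1, seed = 7)))
  after <- runif(1)
  expect_identical(before, after)
})

test_that("synthetic proteins carry the requested Cys budget", {
  mp <- make_protein(architecture_spec(6, 2, 3, seed = 1))
  expect_equal(summarize_composition(mp$record)$cys_count, 57L)  # 6*7 + 2*6 + 3
  expect_equal(mp$truth$n_cys, 57L)
  none <- make_protein(architecture_spec(0, 0, 0, seed = 1))
  expect_equal(summarize_composition(none$record)$cys_count, 0L)
  one <- make_protein(architecture_spec(1, 0, 0, seed = 2))
  arch <- decompose(one$record)
  expect_equal(nrow(arch$boxes), 1L)
  expect_equal(arch$boxes$kind, "seven_cys")
  expect_equal(arch$boxes$start, one$truth$boxes$start)
})

test_that("intron-free genes transcribe to their genomic span", {
  p <- protein_record("p", random_protein(30, 0.1))
  g <- make_gene(p, gene_spec(n_introns = 0, promoter_plants = NULL,
                              upstream_flank = 120, seed = 9))
  truth <- g$truth
  expect_equal(nrow(truth$exons), 1L)
  span <- substr(g$scaffold[[1]], truth$exons$start0 + 1L, truth$exons$end0)
  expect_equal(span, g$cdna[[1]])
})

test_that("gene ground truth has n_introns + 1 exons and GT/AG introns", {
  p <- protein_record("p", random_protein(120, 0.1))
  g <- make_gene(p, gene_spec(n_introns = 4, seed = 21, promoter_plants = NULL))
  expect_equal(nrow(g$truth$exons), 5L)
  scaf <- g$scaffold[[1]]
  for (i in seq_len(nrow(g$truth$introns))) {
    i0 <- g$truth$introns$start0[i]; i1 <- g$truth$introns$end0[i]
    expect_equal(substr(scaf, i0 + 1L, i0 + 2L), "GT")
    expect_equal(substr(scaf, i1 - 1L, i1), "AG")
    len <- i1 - i0
    expect_gte(len, 48L); expect_lte(len, 204L)
  }
  # the generator supplies the initiator Met, hence 121 encoded residues
  expect_equal(g$truth$coding_length, 3L * (121L + 1L))
})

test_that("infeasible gene specs are refused", {
  p <- protein_record("tiny", random_protein(20, 0.1))  # 63 bp of coding
  expect_error(make_gene(p, gene_spec(n_introns = 9, promoter_plants = NULL)),
               "infeasible spec")
  q <- protein_record("q", random_protein(200, 0.1))
  expect_error(make_gene(q, gene_spec(
    n_introns = 0, upstream_flank = 10,
    promoter_plants = data.frame(name = "MRE", seq = "TGCACAC", offset = -1457L),
    seed = 1)), "infeasible spec")
})

test_that("planted promoter motifs round-trip through the scanner", {
  p <- protein_record("p", random_protein(60, 0.1))
  g <- make_gene(p, gene_spec(n_introns = 1, seed = 13))   # default plants
  atg <- g$truth$atg_pos
  up <- substr(g$scaffold[[1]], atg - 1500L, atg - 1L)
  hits <- scan_promoter(up)
  expect_true(any(hits$motif_name == "TATA" & hits$offset == -38L & hits$strand == "+"))
  expect_true(any(hits$motif_name == "MRE" & hits$offset == -1457L & hits$strand == "+"))
  # plants never corrupt the annotated start: the first transcript ATG is the real one
  cc <- check_coding(NULL, g$cdna[[1]])
  expect_equal(cc$utr5_length, g$truth$utr5_length)
})

test_that("synthetic peak lists sit at their theoretical masses", {
  apo <- 25377.62
  exact <- spectrum_spec(apo, list(list(stoich = c(Zn = 20), abundance = 7)),
                         mass_error_rel = 0, seed = 1)
  pk <- make_peaklist(exact)
  expect_equal(pk$peaks$mass_da, pk$truth$theoretical_mass)
  expect_equal(pk$peaks$intensity, 7)

  ladder <- spectrum_spec(apo, lapply(17:21, function(n)
    list(stoich = c(Zn = n), abundance = 1)), mass_error_rel = 0, seed = 1)
  lp <- make_peaklist(ladder)
  expect_equal(diff(lp$peaks$mass_da), rep(ZN_INC, 4), tolerance = 1e-12)

  series <- loading_series(3)$doublets
  cu <- spectrum_spec(apo, lapply(c(rbind(series$lower, series$upper)), function(n)
    list(stoich = c(Cu = n), abundance = 1)), mass_error_rel = 0, seed = 1)
  cp <- make_peaklist(cu)
  expect_equal(cp$truth$Cu, c(4L, 5L, 8L, 9L, 12L, 13L))
  expect_equal(cp$peaks$mass_da, apo + cp$truth$Cu * CU_INC, tolerance = 1e-12)
})

test_that("growth tables carry triplicates and a zero-dose control", {
  g <- make_growth(seed = 1)
  expect_true(all(table(g$table$cu_conc) == 3))
  expect_true(0 %in% g$table$cu_conc)
  expect_true(all(g$table$od600 >= 0))
  expect_equal(g$truth$expected_percent[g$truth$cu_conc == 0], 100)
  # full inhibition drives growth to about zero percent
  hard <- make_growth(doses = c(0, 1000), ic50 = 5, hill = 4, noise_sd = 0.01,
                      seed = 2)
  out <- normalize_growth(hard$table)
  expect_lt(out$percent_of_control[out$cu_conc == 1000], 5)
})
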