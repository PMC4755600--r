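test_that("a perfect consensus instance in a Gly background is found exactly", {
  consensus <- gsub("X", "G", profile_consensus(seven_cys_profile()))
  seqstr <- paste0(strrep("G", 10), consensus, strrep("G", 10))
  hits <- scan_boxes(seqstr, seven_cys_profile())
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 11L)                         # first mandatory Cys
  expect_equal(hits$end, 10L + nchar(consensus))        # trailing Pro included
  # maximal score: 7 mandatory Cys + 6 conserved-residue bonuses, no flanks
  expect_equal(hits$score, 13)
})

test_that("Cys-free sequences yield no boxes and empty architectures", {
  expect_equal(nrow(scan_boxes(strrep("GAS", 20), seven_cys_profile())), 0L)
  arch <- decompose(strrep("GAS", 20))
  expect_equal(nrow(arch$boxes), 0L)
  expect_equal(sum(arch$totals), 0L)
  rep <- architecture_report(arch)
  expect_equal(rep$n_boxes, 0L)
})

test_that("the short-MT gap arrangement matches the 7-Cys profile at +/-2", {
  hits <- scan_boxes(short_mt_seq, seven_cys_profile())
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$cys_positions[[1]], c(4L, 6L, 12L, 14L, 18L, 20L, 23L))
  expect_equal(hits$start, 4L)
  # at zero tolerance the (1,5,1,3,1,2) gaps no longer fit (1,3,1,4,1,2)
  strict <- scan_boxes(short_mt_seq, seven_cys_profile(gap_tolerance = 0L))
  expect_equal(nrow(strict), 0L)
})

test_that("an empty gap signature is an invalid profile", {
  expect_error(box_profile("bad", integer(0)), "invalid profile")
  expect_error(box_profile("bad", c(1, 2), gap_tolerance = -1), "invalid profile")
})

test_that("decompose recovers the synthetic architecture and its coordinates", {
  mp <- make_protein(architecture_spec(6, 2, 3, seed = 101))
  arch <- decompose(mp$record)
  expect_equal(unname(arch$totals[c("seven_cys", "six_cys")]),
               unname(mp$truth$totals))
  expect_equal(length(arch$unassigned_cys), 3L)
  expect_equal(arch$unassigned_cys, mp$truth$prefix_cys)
  expect_equal(arch$boxes$start, mp$truth$boxes$start)
  expect_equal(arch$boxes$end, mp$truth$boxes$end)
  expect_equal(arch$boxes$kind, mp$truth$boxes$kind)
})

test_that("two disjoint perfect boxes are both reported", {
  consensus <- gsub("X", "A", profile_consensus(seven_cys_profile()))
  seqstr <- paste0("M", consensus, strrep("G", 6), consensus, "G")
  arch <- decompose(seqstr, allow_degenerate = FALSE)
  expect_equal(nrow(arch$boxes), 2L)
  expect_equal(unname(arch$totals[["seven_cys"]]), 2L)
  expect_equal(length(arch$unassigned_cys), 0L)
})

test_that("Cys conservation holds on arbitrary inputs", {
  set.seed(21)
  for (i in 1:20) {
    s <- random_protein(sample(30:120, 1), cys_prob = runif(1, 0.1, 0.4))
    arch <- decompose(s)
    matched <- sum(vapply(arch$boxes$cys_positions, length, 0L))
    expect_equal(matched + length(arch$unassigned_cys),
                 sum(strsplit(s, "")[[1]] == "C"))
  }
})

test_that("the DP segmentation score equals the brute-force optimum", {
  set.seed(33)
  checked <- 0L
  for (i in 1:40) {
    s <- random_protein(sample(30:80, 1), cys_prob = runif(1, 0.2, 0.5))
    profiles <- c(list(seven_cys_profile()),
                  modmt:::degenerate_profiles(seven_cys_profile()))
    cands <- scan_boxes(s, profiles)
    if (nrow(cands) > 12L) next                   # keep subset enumeration cheap
    arch <- decompose(s)
    expect_equal(arch$total_score,
                 brute_best_score(cands$start, cands$end, cands$score))
    checked <- checked + 1L
  }
  expect_gt(checked, 10L)
})

test_that("decomposition is additive over box concatenations with clean linkers", {
  a <- make_protein(architecture_spec(2, 1, 0, seed = 7))
  b <- make_protein(architecture_spec(3, 0, 0, seed = 8))
  joined <- paste0(a$record$sequence, strrep("G", 6), b$record$sequence)
  arch_a <- decompose(a$record)
  arch_b <- decompose(b$record)
  arch_j <- decompose(joined)
  expect_equal(unname(arch_j$totals), unname(arch_a$totals + arch_b$totals))
})

test_that("architecture reports serialize stably", {
  mp <- make_protein(architecture_spec(6, 2, 3, seed = 55))
  rep <- architecture_report(decompose(mp$record))
  expect_equal(rep$totals_line, "7-Cys: 6, 6-Cys: 2, unassigned Cys: 3")
  expect_equal(rep$n_boxes, 8L)
  expect_equal(names(rep)[1:4], c("id", "length", "n_boxes", "totals"))
  js <- architecture_report(decompose(mp$record), json = TRUE)
  parsed <- jsonlite::fromJSON(js)
  expect_equal(parsed$n_boxes, 8L)
  # single-box report carries coordinates
  one <- architecture_report(decompose(short_mt_seq))
  expect_equal(one$boxes[[1]]$start, 4L)
  expect_equal(one$boxes[[1]]$kind, "seven_cys")
})

test_that("profiles round-trip through a JSON config file", {
  cfg <- tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(list(list(name = "seven_cys",
                                        gap_signature = c(1, 3, 1, 4, 1, 2),
                                        gap_tolerance = 2)),
                              auto_unbox = TRUE), cfg)
  prof <- read_box_profiles(cfg)[[1]]
  expect_equal(prof$gap_signature, c(1L, 3L, 1L, 4L, 1L, 2L))
  expect_equal(prof$n_cys, 7L)
})

test_that("1-based inclusive coordinates convert to 0-based half-open", {
  hc <- to_half_open(4L, 23L)
  expect_equal(hc$start0, 3L)
  expect_equal(hc$end0, 23L)
})
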