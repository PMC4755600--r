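# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# brute-force CXC count: scan every (i, i+2) window directly
brute_cxc <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  cnt <- 0L
  for (i in seq_len(n)) {
    if (ch[i] == "C" &&
        ((i > 2 && ch[i - 2] == "C") || (i + 2 <= n && ch[i + 2] == "C"))) {
      cnt <- cnt + 1L
    }
  }
  cnt
}

# brute-force optimal non-overlapping selection over candidate boxes:
# enumerate every subset (feasible for small candidate sets)
brute_best_score <- function(starts, ends, scores) {
  n <- length(starts)
  best <- 0
  if (n == 0L) return(best)
  for (mask in 0:(2^n - 1)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0)
    if (length(sel) > 1L) {
      o <- order(starts[sel])
      s <- sel[o]
      if (any(starts[s][-1] <= ends[s][-length(s)])) next
    }
    best <- max(best, sum(scores[sel]))
  }
  best
}

# random protein sequence with given Cys density
random_protein <- function(n, cys_prob = 0.2) {
  pool <- c("A", "G", "S", "T", "K", "P", "E", "Q", "V", "L")
  ch <- sample(pool, n, replace = TRUE)
  ch[runif(n) < cys_prob] <- "C"
  paste(ch, collapse = "")
}

# theoretical holo masses by direct arithmetic (independent of metal_spec)
ZN_INC <- 65.38 - 2 * 1.00794
CU_INC <- 63.546 - 1.00794
CD_INC <- 112.411 - 2 * 1.00794

short_mt_seq <- "MGDCGCSGASSCNCGSGCSCSNCGSK"  # 26-aa fungal Cu-thionein
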