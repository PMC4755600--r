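## Percent-of-control normalization of Cu-tolerance growth assays.

#' Normalize growth readings to percent of the no-Cu control
#'
#' Each strain must have exactly one zero-Cu control condition; every
#' condition's percent-of-control is `100 * mean(OD_c) / mean(OD_0)`, and
#' the percent SD propagates the replicate spread of the treated condition
#' against the control mean (the convention used for error bars in
#' endpoint-OD tolerance plots, without a ratio-distribution correction).
#'
#' @param table Data frame with columns `strain`, `cu_conc`, `od600` and
#'   optionally `unit` (carried through unchanged, no conversion) and
#'   `replicate`; one row per replicate reading. OD600 must be >= 0.
#' @return Data frame of class `tolerance_summary`: one row per
#'   (strain, cu_conc) with `n`, `mean_od`, `sd_od`, `percent_of_control`,
#'   `percent_sd`. The control row is exactly 100%.
#' @examples
#' tab <- data.frame(strain = "s", cu_conc = c(0, 0, 0, 10, 10, 10),
#'                   od600 = c(0.9, 1.0, 1.1, 0.45, 0.5, 0.55))
#' normalize_growth(tab)
#' @export
normalize_growth <- function(table) {
  stopifnot(is.data.frame(table),
            all(c("strain", "cu_conc", "od600") %in% names(table)))
  if (any(table$od600 < 0, na.rm = TRUE)) {
    stop("od600 readings must be >= 0", call. = FALSE)
  }
  has_unit <- "unit" %in% names(table)
  out <- list()
  for (st in unique(table$strain)) {
    sub <- table[table$strain == st, , drop = FALSE]
    ctrl <- sub[sub$cu_conc == 0, , drop = FALSE]
    if (nrow(ctrl) == 0L) {
      stop(sprintf("no control: strain '%s' has no zero-Cu condition", st),
           call. = FALSE)
    }
    ctrl_mean <- mean(ctrl$od600)
    if (ctrl_mean <= 0) {
      stop(sprintf("no control: strain '%s' control mean OD is not > 0", st),
           call. = FALSE)
    }
    for (conc in sort(unique(sub$cu_conc))) {
      reps <- sub$od600[sub$cu_conc == conc]
      m <- mean(reps)
      s <- if (length(reps) > 1L) sd(reps) else NA_real_
      out[[length(out) + 1L]] <- data.frame(
        strain = st, cu_conc = conc,
        unit = if (has_unit) sub$unit[sub$cu_conc == conc][1] else NA_character_,
        n = length(reps), mean_od = m, sd_od = s,
        percent_of_control = 100 * m / ctrl_mean,
        percent_sd = if (is.na(s)) NA_real_ else 100 * s / ctrl_mean
      )
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("tolerance_summary", class(res))
  res
}
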