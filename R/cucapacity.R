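## Additive per-box Cu(I) cluster capacity model and the predominant-species
## loading series.
##
## Each 7-Cys box hosts a Cu5 cluster and each 6-Cys box a Cu4 cluster, in
## line with the Cu4S6/Cu5S7 model cores of Cu(I)-thiolate chemistry; the
## base capacity of a modular MT is the sum over its boxes, and
## box-unassigned Cys can each take up to one extra Cu(I) (the loosest bound
## consistent with Cu:S <= 1 in those cores).

BOX_CU_CAPACITY <- c(seven_cys = 5L, six_cys = 4L)

#' Predict Cu(I)-binding capacity from a module architecture
#'
#' @param arch A `module_architecture` from [decompose()] (or any list with
#'   a `boxes` data frame carrying a `kind` column and an `unassigned_cys`
#'   vector).
#' @return List of class `capacity_prediction`: `per_box` (data frame `kind`,
#'   `cu_capacity`), `base_total` (sum over boxes), `extra_cys`, `max_total`
#'   (= base + extra Cys at one Cu each), `predicted_major_range`.
#' @examples
#' # six 7-Cys + two 6-Cys boxes + 3 spare Cys -> base 38, max 41
#' @export
cu_capacity <- function(arch) {
  stopifnot(is.list(arch), !is.null(arch$boxes))
  kinds <- arch$boxes$kind
  unknown <- setdiff(unique(kinds), names(BOX_CU_CAPACITY))
  if (length(unknown) > 0L) {
    stop(sprintf("unknown box kind '%s': no Cu capacity defined", unknown[1]),
         call. = FALSE)
  }
  per_box <- data.frame(kind = kinds,
                        cu_capacity = unname(BOX_CU_CAPACITY[kinds]))
  base_total <- sum(per_box$cu_capacity)
  extra <- length(arch$unassigned_cys)
  structure(list(per_box = per_box, base_total = base_total,
                 extra_cys = extra, max_total = base_total + extra,
                 predicted_major_range = c(base_total, base_total + extra)),
            class = "capacity_prediction")
}

#' @export
print.capacity_prediction <- function(x, ...) {
  cat(sprintf("<capacity_prediction> base %d Cu(I) (%s), +%d spare Cys -> max %d\n",
              x$base_total,
              paste(sprintf("%dx%s", table(x$per_box$kind),
                            names(table(x$per_box$kind))), collapse = " + "),
              x$extra_cys, x$max_total))
  invisible(x)
}

#' Predominant Cu(I) loading series
#'
#' The stepwise Cu(I) titration of the Zn-protein produces predominant
#' species in doublets `(lower, lower + 1)`: the first three doublets are
#' multiples of four, (4,5), (8,9), (12,13); thereafter each doublet adds 5
#' Cu(I) to the previous one: (17,18), (22,23), (27,28), (32,33), ...
#'
#' @param n_doublets Number of doublets to generate (>= 1).
#' @return List of class `loading_series`: `doublets` (data frame `lower`,
#'   `upper`), `rule` (text descriptor).
#' @examples
#' loading_series(6)$doublets
#' @export
loading_series <- function(n_doublets) {
  if (!is.numeric(n_doublets) || length(n_doublets) != 1L || is.na(n_doublets) ||
      n_doublets < 1) {
    stop("invalid input: n_doublets must be >= 1", call. = FALSE)
  }
  n_doublets <- as.integer(n_doublets)
  lower <- integer(n_doublets)
  for (k in seq_len(n_doublets)) {
    lower[k] <- if (k <= 3L) 4L * k else lower[k - 1L] + 5L
  }
  structure(list(
    doublets = data.frame(lower = lower, upper = lower + 1L),
    rule = paste("doublets (4k, 4k+1) for k = 1..3, then +5 per step;",
                 "4 matches a 6-Cys box filling, 5 a 7-Cys box filling")
  ), class = "loading_series")
}

#' @export
print.loading_series <- function(x, ...) {
  cat("<loading_series>",
      paste(sprintf("(%d,%d)", x$doublets$lower, x$doublets$upper), collapse = " "),
      "\n")
  invisible(x)
}

#' Compare observed major stoichiometries against a capacity prediction
#'
#' For each observed major Cu(I) count, reports whether it falls inside
#' `[base_total, max_total + 1]` (one extra Cu beyond the maximum is still
#' counted as compatible, covering a loosely bound ion) and its offset from
#' the base capacity.
#'
#' @param prediction A `capacity_prediction` from [cu_capacity()].
#' @param observed_majors Non-empty integer vector of observed major Cu(I)
#'   stoichiometries.
#' @return Data frame with `observed`, `inside`, `offset_from_base`.
#' @export
capacity_consistency <- function(prediction, observed_majors) {
  stopifnot(inherits(prediction, "capacity_prediction"))
  if (length(observed_majors) == 0L) {
    stop("observed_majors must be non-empty", call. = FALSE)
  }
  lo <- prediction$base_total
  hi <- prediction$max_total + 1L
  data.frame(observed = as.integer(observed_majors),
             inside = observed_majors >= lo & observed_majors <= hi,
             offset_from_base = as.integer(observed_majors) - lo,
             offset_from_max = as.integer(observed_majors) - prediction$max_total)
}
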