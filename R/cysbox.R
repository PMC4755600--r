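## Cys-box detection and tandem-module decomposition.
##
## A "box profile" is a gap signature: the number of residues between each
## pair of consecutive mandatory cysteines, matched with a per-gap tolerance,
## plus conserved-residue bonuses at fixed offsets inside specific gaps.
## Decomposition picks the score-maximal set of non-overlapping box
## placements by dynamic programming (weighted interval scheduling).

#' Construct a Cys-box profile
#'
#' @param name Profile name.
#' @param gap_signature Integer vector: residues between consecutive
#'   mandatory Cys. A profile with k gaps has k+1 mandatory Cys.
#' @param gap_tolerance Allowed deviation (residues, +/-) per gap.
#' @param min_score Minimum score for [scan_boxes()] to report a placement;
#'   defaults to the base score (number of mandatory Cys).
#' @param conserved Data frame of conserved-residue bonuses with columns
#'   `gap` (gap index; `NA` = position after the last Cys), `pos` (1-based
#'   offset after the gap's left Cys), `residue`, `weight`.
#' @param charged_flank_weight Bonus for K/R/E/D immediately flanking the
#'   box (each side), reflecting conserved charged residues at linker
#'   boundaries.
#' @param score_penalty Subtracted from the base score (used by degenerate
#'   variants).
#' @return Object of class `box_profile`.
#' @export
box_profile <- function(name, gap_signature, gap_tolerance = 2L,
                        min_score = NULL, conserved = NULL,
                        charged_flank_weight = 0.5, score_penalty = 0) {
  gap_signature <- as.integer(gap_signature)
  if (length(gap_signature) == 0L || any(gap_signature < 0L)) {
    stop("invalid profile: gap_signature must be a non-empty vector of gaps >= 0",
         call. = FALSE)
  }
  if (gap_tolerance < 0) stop("invalid profile: gap_tolerance must be >= 0", call. = FALSE)
  n_cys <- length(gap_signature) + 1L
  if (is.null(min_score)) min_score <- n_cys - score_penalty
  if (is.null(conserved)) {
    conserved <- data.frame(gap = integer(), pos = integer(),
                            residue = character(), weight = numeric())
  }
  structure(list(name = name, gap_signature = gap_signature, n_cys = n_cys,
                 gap_tolerance = as.integer(gap_tolerance),
                 min_score = min_score, conserved = conserved,
                 charged_flank_weight = charged_flank_weight,
                 score_penalty = score_penalty),
            class = "box_profile")
}

#' The 7-Cys box profile of long modular fungal metallothioneins
#'
#' Consensus `CXCX3CSCPPGXCXCAXCP`: mandatory Cys with gap signature
#' (1,3,1,4,1,2), conserved Ser after the third Cys, Pro-Pro-Gly in the
#' four-residue gap, Ala after the sixth Cys, and a Pro closing the box.
#' The default +/-2 gap tolerance admits the short-MT arrangement with gaps
#' (1,5,1,3,1,2) while rejecting unrelated Cys runs.
#'
#' @inheritParams box_profile
#' @return A `box_profile`.
#' @export
seven_cys_profile <- function(gap_tolerance = 2L, min_score = NULL) {
  conserved <- data.frame(
    gap = c(3L, 4L, 4L, 4L, 6L, NA),
    pos = c(1L, 1L, 2L, 3L, 1L, 1L),
    residue = c("S", "P", "P", "G", "A", "P"),
    weight = 1
  )
  box_profile("seven_cys", c(1L, 3L, 1L, 4L, 1L, 2L),
              gap_tolerance = gap_tolerance, min_score = min_score,
              conserved = conserved)
}

#' @export
print.box_profile <- function(x, ...) {
  cat(sprintf("<box_profile> %s: %d Cys, gaps [%s] +/- %d, min score %.1f\n",
              x$name, x$n_cys, paste(x$gap_signature, collapse = ","),
              x$gap_tolerance, x$min_score))
  invisible(x)
}

#' Consensus string of a box profile
#'
#' @param profile A [box_profile()].
#' @return Character string with mandatory `C`s, conserved residues, and `X`
#'   elsewhere.
#' @export
profile_consensus <- function(profile) {
  gaps <- profile$gap_signature
  chars <- character(0)
  for (i in seq_along(gaps)) chars <- c(chars, "C", rep("X", gaps[i]))
  chars <- c(chars, "C")
  cys_at <- cumsum(c(1L, gaps + 1L))
  cons <- profile$conserved
  for (r in seq_len(nrow(cons))) {
    gi <- cons$gap[r]
    if (is.na(gi)) {
      chars <- c(chars, cons$residue[r])
    } else {
      chars[cys_at[gi] + cons$pos[r]] <- cons$residue[r]
    }
  }
  paste(chars, collapse = "")
}

## Degenerate variants: the parent profile with exactly one mandatory Cys
## dropped (penalty one base unit). Dropping an interior Cys k merges gaps
## k-1 and k (plus the replaced Cys itself); bonuses from gap k shift into
## the merged gap at their nominal offset past the dropped position, so a
## 6-Cys box still earns credit for its conserved residues. Bonuses in the
## first/last gap are lost when the terminal Cys is the one dropped (the
## residues fall outside the Cys-anchored box).
degenerate_profiles <- function(profile) {
  gaps <- profile$gap_signature
  k_all <- seq_len(profile$n_cys)
  lapply(k_all, function(k) {
    cons <- profile$conserved
    if (k == 1L) {
      new_gaps <- gaps[-1L]
      cons <- cons[is.na(cons$gap) | cons$gap > 1L, , drop = FALSE]
      cons$gap <- cons$gap - 1L
    } else if (k == profile$n_cys) {
      new_gaps <- gaps[-length(gaps)]
      cons <- cons[!is.na(cons$gap) & cons$gap < length(gaps), , drop = FALSE]
    } else {
      new_gaps <- c(gaps[seq_len(k - 2L)], gaps[k - 1L] + gaps[k] + 1L,
                    if (k < length(gaps)) gaps[(k + 1L):length(gaps)] else integer(0))
      shift <- !is.na(cons$gap) & cons$gap == k
      cons$pos[shift] <- cons$pos[shift] + gaps[k - 1L] + 1L
      cons$gap <- ifelse(is.na(cons$gap), NA_integer_,
                         ifelse(cons$gap < k, cons$gap, cons$gap - 1L))
    }
    box_profile(paste0(profile$name, "_deg", k), new_gaps,
                gap_tolerance = profile$gap_tolerance,
                min_score = profile$n_cys - 2L,
                conserved = cons,
                charged_flank_weight = profile$charged_flank_weight,
                score_penalty = 1)
  })
}

## Score a concrete placement (matched Cys positions) of a profile.
## Returns list(score, start, end).
score_placement <- function(chars, positions, profile) {
  n <- length(chars)
  score <- length(positions) - profile$score_penalty
  cons <- profile$conserved
  end <- positions[length(positions)]
  for (r in seq_len(nrow(cons))) {
    gi <- cons$gap[r]
    if (is.na(gi)) {
      p <- positions[length(positions)] + cons$pos[r]
      if (p <= n && chars[p] == cons$residue[r]) {
        score <- score + cons$weight[r]
        end <- max(end, p)
      }
    } else {
      left <- positions[gi]
      right <- positions[gi + 1L]
      p <- left + cons$pos[r]
      if (p < right && chars[p] == cons$residue[r]) score <- score + cons$weight[r]
    }
  }
  start <- positions[1L]
  charged <- c("K", "R", "E", "D")
  if (start > 1L && chars[start - 1L] %in% charged) {
    score <- score + profile$charged_flank_weight
  }
  if (end < n && chars[end + 1L] %in% charged) {
    score <- score + profile$charged_flank_weight
  }
  list(score = score, start = start, end = end)
}

## Enumerate all gap-compatible Cys assignments starting at anchor index a.
## cys: sorted Cys positions. Returns list of integer vectors (positions).
enumerate_matches <- function(cys, a, gaps, tol) {
  partial <- list(cys[a])
  for (g in gaps) {
    nxt <- list()
    for (p in partial) {
      last <- p[length(p)]
      lo <- last + max(g - tol, 0L) + 1L
      hi <- last + g + tol + 1L
      cand <- cys[cys >= lo & cys <= hi]
      for (q in cand) nxt[[length(nxt) + 1L]] <- c(p, q)
    }
    if (length(nxt) == 0L) return(list())
    partial <- nxt
  }
  partial
}

#' Scan a protein for Cys-box placements
#'
#' Reports, for every profile and every anchor Cys, the maximal-scoring
#' gap-compatible placement with score at or above the profile's
#' `min_score`. Placements from different anchors may overlap; use
#' [decompose()] for a non-overlapping segmentation.
#'
#' @inheritParams summarize_composition
#' @param profiles A `box_profile` or list of them.
#' @return Data frame with columns `profile_name`, `start`, `end` (1-based
#'   inclusive protein coordinates), `kind` (`seven_cys`/`six_cys`/`other`),
#'   `n_cys`, `score`, and list-column `cys_positions`; ordered by
#'   `(start, -score)`.
#' @export
scan_boxes <- function(record, profiles) {
  record <- as_protein_record(record)
  if (inherits(profiles, "box_profile")) profiles <- list(profiles)
  if (length(profiles) == 0L) stop("invalid profile: need at least one", call. = FALSE)
  chars <- strsplit(record$sequence, "")[[1]]
  cys <- which(chars == "C")
  rows <- list()
  for (profile in profiles) {
    if (length(cys) < profile$n_cys) next
    for (a in seq_len(length(cys) - profile$n_cys + 1L)) {
      matches <- enumerate_matches(cys, a, profile$gap_signature, profile$gap_tolerance)
      if (length(matches) == 0L) next
      scored <- lapply(matches, function(m) c(score_placement(chars, m, profile),
                                              list(positions = m)))
      ## best per anchor: highest score, then shortest box, then leftmost end
      ord <- order(-vapply(scored, `[[`, 0, "score"),
                   vapply(scored, function(s) s$end - s$start, 0),
                   vapply(scored, `[[`, 0, "end"))
      best <- scored[[ord[1L]]]
      if (best$score < profile$min_score) next
      kind <- if (profile$n_cys == 7L) "seven_cys"
              else if (profile$n_cys == 6L) "six_cys" else "other"
      rows[[length(rows) + 1L]] <- list(profile_name = profile$name,
                                        start = best$start, end = best$end,
                                        kind = kind, n_cys = profile$n_cys,
                                        score = best$score,
                                        cys_positions = best$positions)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(profile_name = character(), start = integer(),
                      end = integer(), kind = character(), n_cys = integer(),
                      score = numeric(), cys_positions = I(list())))
  }
  df <- data.frame(
    profile_name = vapply(rows, `[[`, "", "profile_name"),
    start = vapply(rows, `[[`, 0L, "start"),
    end = vapply(rows, `[[`, 0L, "end"),
    kind = vapply(rows, `[[`, "", "kind"),
    n_cys = vapply(rows, `[[`, 0L, "n_cys"),
    score = vapply(rows, `[[`, 0, "score"),
    cys_positions = I(lapply(rows, `[[`, "cys_positions"))
  )
  df <- df[order(df$start, -df$score, df$end), , drop = FALSE]
  rownames(df) <- NULL
  df
}

## Lexicographic tie key for a selection of candidate rows: prefer leftmost
## start, then higher score, then shorter box, element by element.
selection_key <- function(cands, sel) {
  if (length(sel) == 0L) return(numeric(0))
  sel <- sel[order(cands$start[sel])]
  as.numeric(rbind(cands$start[sel], -cands$score[sel],
                   cands$end[sel] - cands$start[sel]))
}

key_less <- function(a, b) {
  n <- min(length(a), length(b))
  if (n > 0L) {
    for (i in seq_len(n)) {
      if (a[i] < b[i]) return(TRUE)
      if (a[i] > b[i]) return(FALSE)
    }
  }
  length(a) < length(b)
}

#' Decompose a protein into non-overlapping Cys-box modules
#'
#' Segments the sequence into the score-maximal set of non-overlapping box
#' placements (dynamic programming over all candidate placements from
#' [scan_boxes()]). With `allow_degenerate`, six-Cys variants of each
#' profile (one mandatory Cys absent, one base unit of score penalty) are
#' admitted as candidates. Ties between equal-score segmentations are broken
#' leftmost-start first, then higher score, then shorter box.
#'
#' @inheritParams scan_boxes
#' @param allow_degenerate Admit one-Cys-dropped variants of each profile.
#' @return Object of class `module_architecture`: `boxes` (as in
#'   [scan_boxes()], non-overlapping, sorted), `linkers` (inter-box
#'   segments), `unassigned_cys` (Cys positions not matched by any chosen
#'   box), `totals` (named counts per box kind), `total_score`, `id`,
#'   `length`.
#' @export
decompose <- function(record, profiles = list(seven_cys_profile()),
                      allow_degenerate = TRUE) {
  record <- as_protein_record(record)
  if (inherits(profiles, "box_profile")) profiles <- list(profiles)
  all_profiles <- profiles
  if (allow_degenerate) {
    for (p in profiles) all_profiles <- c(all_profiles, degenerate_profiles(p))
  }
  cands <- scan_boxes(record, all_profiles)
  chars <- strsplit(record$sequence, "")[[1]]
  all_cys <- which(chars == "C")

  chosen <- integer(0)
  if (nrow(cands) > 0L) {
    ord <- order(cands$end, cands$start)
    cands <- cands[ord, , drop = FALSE]
    rownames(cands) <- NULL
    n <- nrow(cands)
    ## pred[i]: latest candidate ending before cands$start[i]
    pred <- vapply(seq_len(n), function(i) {
      ok <- which(cands$end < cands$start[i])
      if (length(ok) == 0L) 0L else max(ok)
    }, 0L)
    best_score <- numeric(n + 1L)
    best_sel <- vector("list", n + 1L)
    best_sel[[1L]] <- integer(0)
    for (i in seq_len(n)) {
      excl_score <- best_score[i]
      excl_sel <- best_sel[[i]]
      incl_score <- cands$score[i] + best_score[pred[i] + 1L]
      incl_sel <- c(best_sel[[pred[i] + 1L]], i)
      if (incl_score > excl_score ||
          (incl_score == excl_score &&
           key_less(selection_key(cands, incl_sel), selection_key(cands, excl_sel)))) {
        best_score[i + 1L] <- incl_score
        best_sel[[i + 1L]] <- incl_sel
      } else {
        best_score[i + 1L] <- excl_score
        best_sel[[i + 1L]] <- excl_sel
      }
    }
    chosen <- best_sel[[n + 1L]]
  }

  boxes <- cands[chosen, , drop = FALSE]
  boxes <- boxes[order(boxes$start), , drop = FALSE]
  rownames(boxes) <- NULL
  matched_cys <- sort(unlist(boxes$cys_positions))
  unassigned <- setdiff(all_cys, matched_cys)
  totals <- c(seven_cys = sum(boxes$kind == "seven_cys"),
              six_cys = sum(boxes$kind == "six_cys"),
              other = sum(boxes$kind == "other"))
  linkers <- NULL
  if (nrow(boxes) > 1L) {
    ls <- boxes$end[-nrow(boxes)] + 1L
    le <- boxes$start[-1L] - 1L
    keep <- le >= ls
    linkers <- data.frame(start = ls[keep], end = le[keep])
  } else {
    linkers <- data.frame(start = integer(), end = integer())
  }
  structure(list(id = record$id, length = length(chars), boxes = boxes,
                 linkers = linkers, unassigned_cys = unassigned,
                 totals = totals, total_score = sum(boxes$score)),
            class = "module_architecture")
}

#' @export
print.module_architecture <- function(x, ...) {
  cat(sprintf("<module_architecture> %s (%d aa)\n", x$id, x$length))
  cat(sprintf("  boxes: 7-Cys: %d, 6-Cys: %d, other: %d; unassigned Cys: %d\n",
              x$totals[["seven_cys"]], x$totals[["six_cys"]], x$totals[["other"]],
              length(x$unassigned_cys)))
  if (nrow(x$boxes) > 0L) {
    for (i in seq_len(nrow(x$boxes))) {
      cat(sprintf("  [%d] %s %d-%d (score %.1f)\n", i, x$boxes$kind[i],
                  x$boxes$start[i], x$boxes$end[i], x$boxes$score[i]))
    }
  }
  invisible(x)
}

#' Serialize a module architecture to a report
#'
#' @param arch A `module_architecture` from [decompose()].
#' @param json Return a JSON string instead of a list.
#' @return List (or JSON string) with per-box coordinates, kinds, matched
#'   Cys positions, a totals line, linkers and unassigned Cys. Field order
#'   is stable.
#' @export
architecture_report <- function(arch, json = FALSE) {
  stopifnot(inherits(arch, "module_architecture"))
  boxes <- lapply(seq_len(nrow(arch$boxes)), function(i) {
    list(index = i,
         profile = arch$boxes$profile_name[i],
         kind = arch$boxes$kind[i],
         start = arch$boxes$start[i],
         end = arch$boxes$end[i],
         score = arch$boxes$score[i],
         cys_positions = arch$boxes$cys_positions[[i]])
  })
  rep <- list(
    id = arch$id,
    length = arch$length,
    n_boxes = nrow(arch$boxes),
    totals = as.list(arch$totals),
    totals_line = sprintf("7-Cys: %d, 6-Cys: %d, unassigned Cys: %d",
                          arch$totals[["seven_cys"]], arch$totals[["six_cys"]],
                          length(arch$unassigned_cys)),
    boxes = boxes,
    linkers = arch$linkers,
    unassigned_cys = arch$unassigned_cys,
    total_score = arch$total_score
  )
  if (json) jsonlite::toJSON(rep, auto_unbox = TRUE, digits = NA) else rep
}

#' Convert 1-based inclusive box coordinates to 0-based half-open
#'
#' @param start,end 1-based inclusive coordinates.
#' @return Data frame with `start0` and `end0` (0-based half-open).
#' @export
to_half_open <- function(start, end) {
  data.frame(start0 = as.integer(start) - 1L, end0 = as.integer(end))
}

#' Read box profiles from a JSON config file
#'
#' The file holds an array of objects with fields `name`, `gap_signature`
#' and optionally `gap_tolerance`, `min_score`.
#'
#' @param path JSON file path.
#' @return List of [box_profile()] objects.
#' @export
read_box_profiles <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(cfg, function(p) {
    box_profile(p$name, unlist(p$gap_signature),
                gap_tolerance = if (!is.null(p$gap_tolerance)) p$gap_tolerance else 2L,
                min_score = p$min_score)
  })
}
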