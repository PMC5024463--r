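# Primary-sequence context of an indel: homopolymer runs (HR) and
# tandem repeats (TR), the two slippage-prone contexts in which most
# small indels arise.

# Genomic interval of the reference bases an indel alters, plus the
# insertion point (for insertions both flanking bases are returned).
context_target <- function(v) {
  span <- altered_span(v)
  list(type = span$type,
       lo = span$del_start, hi = span$del_end,
       inserted = span$inserted,
       net = net_length_change(v))
}

check_flank <- function(v, flank, flank_start, need = 30L) {
  tgt <- context_target(v)
  n <- nchar(flank)
  if (tgt$lo - flank_start < need ||
      (flank_start + n - 1L) - tgt$hi < need) {
    stop(sprintf("flank must cover the variant plus %d nt on each side", need))
  }
  invisible(tgt)
}

# Maximal runs of identical bases in a string; data frame of
# (start, end, base, length) in local 1-based coordinates.
maximal_runs <- function(s) {
  ch <- strsplit(s, "")[[1]]
  r <- rle(ch)
  end <- cumsum(r$lengths)
  data.frame(start = end - r$lengths + 1L, end = end,
             base = r$values, length = r$lengths,
             stringsAsFactors = FALSE)
}

#' Detect a homopolymer-run context
#'
#' True when the indel's altered bases lie within -- or, for
#' insertions of the run base, immediately extend -- a maximal run of
#' `min_run` or more identical reference bases. Run length is measured
#' on the reference.
#'
#' @param v A normalized [raw_variant()].
#' @param flank Reference sequence covering the variant plus at least
#'   30 nt on each side.
#' @param flank_start 1-based genomic position of `flank[1]`.
#' @param min_run Minimum run length (default 6).
#' @return List with `is_homopolymer`, `base` (`NA` when negative) and
#'   `run_length` (0 when negative).
#' @export
detect_homopolymer_context <- function(v, flank, flank_start, min_run = 6L) {
  flank <- toupper(as.character(flank))
  tgt <- check_flank(v, flank, flank_start)
  runs <- maximal_runs(flank)
  runs <- runs[runs$length >= min_run, , drop = FALSE]
  best <- NULL
  loc <- function(g) g - flank_start + 1L  # genomic -> local
  for (k in seq_len(nrow(runs))) {
    rs <- runs$start[k]; re <- runs$end[k]
    hit <- if (tgt$type == "ins") {
      inside <- loc(tgt$lo) >= rs && loc(tgt$hi) <= re
      at_edge <- (loc(tgt$lo) >= rs && loc(tgt$lo) <= re) ||
        (loc(tgt$hi) >= rs && loc(tgt$hi) <= re)
      extends <- all(strsplit(tgt$inserted, "")[[1]] == runs$base[k])
      inside || (at_edge && extends)
    } else {
      loc(tgt$lo) >= rs && loc(tgt$hi) <= re
    }
    if (hit && (is.null(best) || runs$length[k] > best$run_length)) {
      best <- list(is_homopolymer = TRUE, base = runs$base[k],
                   run_length = runs$length[k])
    }
  }
  best %||% list(is_homopolymer = FALSE, base = NA_character_,
                 run_length = 0L)
}

#' Detect a tandem-repeat context
#'
#' True when the reference around the variant contains at least two
#' consecutive copies of some unit `u` (1 <= |u| <= `max_unit`), the
#' indel's altered bases lie within that segment (insertions may sit at
#' its edge when they extend the array), and the net length change is a
#' multiple of |u| or the inserted/deleted sequence is itself a
#' rotation of whole copies of `u`. The smallest qualifying unit is
#' reported with its reference copy count.
#'
#' @inheritParams detect_homopolymer_context
#' @param max_unit Largest repeat unit length searched (default 21).
#' @return List with `is_tandem_repeat`, `unit` (`NA` when negative)
#'   and `copy_count` (0 when negative).
#' @export
detect_tandem_repeat_context <- function(v, flank, flank_start,
                                         max_unit = 21L) {
  flank <- toupper(as.character(flank))
  tgt <- check_flank(v, flank, flank_start)
  n <- nchar(flank)
  ch <- strsplit(flank, "")[[1]]
  loc_lo <- tgt$lo - flank_start + 1L
  loc_hi <- tgt$hi - flank_start + 1L
  indel_seq <- if (tgt$type == "ins") tgt$inserted else
    substr(flank, loc_lo, loc_hi)

  for (L in seq_len(max_unit)) {
    best <- NULL
    # candidate array anchors near the variant
    s_min <- max(1L, loc_lo - 30L)
    s_max <- min(n - 2L * L + 1L, loc_hi + 1L)
    if (s_max < s_min) next
    for (s in s_min:s_max) {
      # extend the maximal array of period L starting at s
      e <- s + L - 1L
      while (e + 1L <= n && ch[e + 1L] == ch[e + 1L - L]) e <- e + 1L
      copies <- (e - s + 1L) %/% L
      if (copies < 2L) next
      seg_end <- s + copies * L - 1L
      unit <- substr(flank, s, s + L - 1L)
      hit <- if (tgt$type == "ins") {
        inside <- loc_lo >= s && loc_hi <= seg_end
        at_edge <- (loc_lo >= s && loc_lo <= seg_end) ||
          (loc_hi >= s && loc_hi <= seg_end)
        inside || (at_edge && is_rotated_copies(indel_seq, unit))
      } else {
        loc_lo >= s && loc_hi <= seg_end
      }
      if (!hit) next
      if (!(abs(tgt$net) %% L == 0L ||
            is_rotated_copies(indel_seq, unit))) next
      if (is.null(best) || copies > best$copy_count) {
        best <- list(is_tandem_repeat = TRUE, unit = unit,
                     copy_count = copies)
      }
    }
    if (!is.null(best)) return(best)
  }
  list(is_tandem_repeat = FALSE, unit = NA_character_, copy_count = 0L)
}

# Is s a whole number of copies of some rotation of unit?
is_rotated_copies <- function(s, unit) {
  L <- nchar(unit)
  if (!nzchar(s) || nchar(s) %% L != 0L) return(FALSE)
  doubled <- paste0(unit, unit)
  for (r in 0:(L - 1L)) {
    rot <- substr(doubled, r + 1L, r + L)
    k <- nchar(s) %/% L
    if (identical(s, strrep(rot, k))) return(TRUE)
  }
  FALSE
}

#' Combine HR and TR flags into a context label
#'
#' @param hr Result of [detect_homopolymer_context()].
#' @param tr Result of [detect_tandem_repeat_context()].
#' @return One of `"HR+TR"`, `"HR"`, `"TR"`, `"other"`.
#' @export
classify_context <- function(hr, tr) {
  h <- isTRUE(hr$is_homopolymer)
  t <- isTRUE(tr$is_tandem_repeat)
  if (h && t) "HR+TR" else if (h) "HR" else if (t) "TR" else "other"
}

#' Classify the sequence context of a normalized indel
#'
#' Convenience wrapper running both detectors and the label rule.
#'
#' @inheritParams detect_homopolymer_context
#' @param max_unit Largest repeat unit length searched.
#' @return List with fields `is_homopolymer`, `homopolymer_base`,
#'   `homopolymer_run_length`, `is_tandem_repeat`, `repeat_unit`,
#'   `reference_copy_count`, `label`.
#' @export
sequence_context <- function(v, flank, flank_start, min_run = 6L,
                             max_unit = 21L) {
  hr <- detect_homopolymer_context(v, flank, flank_start, min_run)
  tr <- detect_tandem_repeat_context(v, flank, flank_start, max_unit)
  list(is_homopolymer = hr$is_homopolymer,
       homopolymer_base = hr$base,
       homopolymer_run_length = hr$run_length,
       is_tandem_repeat = tr$is_tandem_repeat,
       repeat_unit = tr$unit,
       reference_copy_count = tr$copy_count,
       label = classify_context(hr, tr))
}
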