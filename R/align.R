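# Structure-template selection: Smith-Waterman local alignment against
# a template sequence library with protein-BLAST-style scoring, the
# variant-window identity criterion, and residue mapping onto template
# structures.

# Gapped Karlin-Altschul constants for BLOSUM62 with gap open 11 /
# extend 1 (protein-BLAST defaults).
KA_LAMBDA <- 0.267
KA_K <- 0.041

blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

#' Locally align a target protein against a template sequence
#'
#' Smith-Waterman local alignment with BLOSUM62 scoring and affine gap
#' penalties (open 11, extend 1; a gap of length k costs 11 + k). The
#' raw score is converted to a bit score `b = (lambda*S - ln K)/ln 2`
#' with the gapped constants `lambda = 0.267`, `K = 0.041`, and the
#' E-value is `m * n * 2^-b` where `m` is the target length and `n` the
#' library size in residues.
#'
#' @param target Target protein sequence (one-letter, `X` tolerated; it
#'   scores via BLOSUM62 but never counts as an identity).
#' @param template Template protein sequence.
#' @param library_size Total residues in the searched library.
#' @param template_id Identifier carried into the hit.
#' @param gap_open,gap_extend Affine gap parameters.
#' @return A `template_hit` with the alignment, raw/bit scores, E-value
#'   and global identity over the aligned region. Window fields are
#'   filled by [window_identity()].
#' @export
align_and_score <- function(target, template, library_size,
                            template_id = NA_character_,
                            gap_open = 11, gap_extend = 1) {
  target <- toupper(as.character(target))
  template <- toupper(as.character(template))
  if (!nzchar(target) || !nzchar(template)) stop("empty sequence")
  aln <- sw_align(target, template, blosum62(), gap_open, gap_extend)
  m <- nchar(target)
  bit <- (KA_LAMBDA * aln$score - log(KA_K)) / log(2)
  evalue <- m * library_size * 2^(-bit)
  ta <- strsplit(aln$target_aln, "")[[1]]
  pa <- strsplit(aln$template_aln, "")[[1]]
  ident <- sum(ta == pa & ta != "-" & ta != "X")
  structure(
    list(template_id = template_id,
         target_aln = aln$target_aln, template_aln = aln$template_aln,
         target_start = aln$target_start, target_end = aln$target_end,
         template_start = aln$template_start,
         template_end = aln$template_end,
         raw_score = aln$score, bit_score = bit, e_value = evalue,
         global_identity = if (length(ta)) ident / length(ta) else 0,
         window_identity_count = NA_integer_,
         window_length = NA_integer_,
         window_fraction = NA_real_,
         passes_window = NA),
    class = "template_hit")
}

#' @export
print.template_hit <- function(x, ...) {
  cat(sprintf(
    "<template_hit> %s score=%d bits=%.1f E=%.3g id=%.2f window=%s/%s\n",
    x$template_id, x$raw_score, x$bit_score, x$e_value,
    x$global_identity, x$window_identity_count, x$window_length))
  invisible(x)
}

# Gotoh local alignment with affine gaps; returns best score and one
# optimal alignment (highest-scoring cell, ties broken towards the
# earliest target then template position for determinism).
sw_align <- function(a, b, S, gap_open, gap_extend) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  if (!all(av %in% rownames(S)) || !all(bv %in% rownames(S))) {
    stop("sequence contains letters outside the scoring alphabet")
  }
  n <- length(av); m <- length(bv)
  go <- gap_open + gap_extend  # cost of opening a gap of length 1
  H <- matrix(0, n + 1L, m + 1L)
  E <- matrix(-Inf, n + 1L, m + 1L)  # gap in target (horizontal)
  F <- matrix(-Inf, n + 1L, m + 1L)  # gap in template (vertical)
  for (i in seq_len(n)) {
    srow <- S[av[i], bv]
    for (j in seq_len(m)) {
      E[i + 1L, j + 1L] <- max(H[i + 1L, j] - go, E[i + 1L, j] - gap_extend)
      F[i + 1L, j + 1L] <- max(H[i, j + 1L] - go, F[i, j + 1L] - gap_extend)
      H[i + 1L, j + 1L] <- max(0, H[i, j] + srow[j],
                               E[i + 1L, j + 1L], F[i + 1L, j + 1L])
    }
  }
  best <- max(H)
  if (best <= 0) {
    return(list(score = 0L, target_aln = "", template_aln = "",
                target_start = 0L, target_end = 0L,
                template_start = 0L, template_end = 0L))
  }
  w <- which(H == best, arr.ind = TRUE)
  w <- w[order(w[, 1L], w[, 2L]), , drop = FALSE]
  i <- unname(w[1L, 1L]) - 1L; j <- unname(w[1L, 2L]) - 1L
  ta <- character(0); pa <- character(0)
  ti_end <- i; tj_end <- j
  state <- "H"
  while (i > 0L || j > 0L) {
    if (state == "H") {
      h <- H[i + 1L, j + 1L]
      if (h == 0) break
      if (i > 0L && j > 0L && h == H[i, j] + S[av[i], bv[j]]) {
        ta <- c(av[i], ta); pa <- c(bv[j], pa)
        i <- i - 1L; j <- j - 1L
      } else if (h == E[i + 1L, j + 1L]) {
        state <- "E"
      } else if (h == F[i + 1L, j + 1L]) {
        state <- "F"
      } else stop("traceback failure")
    } else if (state == "E") {
      ta <- c("-", ta); pa <- c(bv[j], pa)
      from_open <- H[i + 1L, j] - go
      from_ext <- E[i + 1L, j] - gap_extend
      cur <- E[i + 1L, j + 1L]
      j <- j - 1L
      state <- if (cur == from_open) "H" else "E"
    } else {
      ta <- c(av[i], ta); pa <- c("-", pa)
      from_open <- H[i, j + 1L] - go
      from_ext <- F[i, j + 1L] - gap_extend
      cur <- F[i + 1L, j + 1L]
      i <- i - 1L
      state <- if (cur == from_open) "H" else "F"
    }
  }
  list(score = as.integer(best),
       target_aln = paste(ta, collapse = ""),
       template_aln = paste(pa, collapse = ""),
       target_start = i + 1L, target_end = ti_end,
       template_start = j + 1L, template_end = tj_end)
}

#' Sequence identity in the variant window of an alignment
#'
#' The window is the set of alignment columns holding the affected
#' target residues plus five flanking columns on each side, truncated
#' at the ends of the aligned region. Gap columns count as mismatches
#' and `X` never counts as an identity. The hit passes when the
#' identity count strictly exceeds `5/11` of the window length (the
#' full-window case is the ">5/11" rule; truncated or longer windows
#' use the proportional strict threshold `count > 5*len/11`).
#'
#' @param hit A `template_hit` from [align_and_score()].
#' @param variant_residue_start,variant_residue_end 1-based target
#'   residue coordinates of the affected span.
#' @param flank Flanking columns on each side (default 5).
#' @return The hit with `window_identity_count`, `window_length`,
#'   `window_fraction` and `passes_window` filled in. When the variant
#'   lies outside the aligned region the hit is marked uncovered
#'   (`passes_window = FALSE`, zero-length window).
#' @export
window_identity <- function(hit, variant_residue_start,
                            variant_residue_end = variant_residue_start,
                            flank = 5L) {
  stopifnot(inherits(hit, "template_hit"))
  ta <- strsplit(hit$target_aln, "")[[1]]
  pa <- strsplit(hit$template_aln, "")[[1]]
  tidx <- cumsum(ta != "-") + hit$target_start - 1L
  tidx[ta == "-"] <- NA_integer_
  cols <- which(!is.na(tidx) & tidx >= variant_residue_start &
                  tidx <= variant_residue_end)
  if (length(cols) == 0L) {
    hit$window_identity_count <- 0L
    hit$window_length <- 0L
    hit$window_fraction <- 0
    hit$passes_window <- FALSE
    hit$window_uncovered <- TRUE
    return(hit)
  }
  lo <- max(1L, min(cols) - flank)
  hi <- min(length(ta), max(cols) + flank)
  win <- lo:hi
  idt <- sum(ta[win] == pa[win] & ta[win] != "-" & ta[win] != "X")
  len <- length(win)
  hit$window_identity_count <- as.integer(idt)
  hit$window_length <- as.integer(len)
  hit$window_fraction <- idt / len
  hit$passes_window <- idt > 5 * len / 11
  hit$window_uncovered <- FALSE
  hit
}

#' Select the best structure template among scored hits
#'
#' Candidates must reach the significance cutoff (`e_value <= 1e-3`)
#' and pass the variant-window identity rule. The winner is chosen by
#' highest window identity fraction, then highest global identity, then
#' lowest E-value, then lexicographic template id; the result does not
#' depend on the order of `hits`.
#'
#' @param hits List of `template_hit` objects with window fields set.
#' @param e_cutoff Significance cutoff (default `1e-3`).
#' @return The winning `template_hit`, or `NULL` when no hit qualifies
#'   (no model is attempted for such variants).
#' @export
select_template <- function(hits, e_cutoff = 1e-3) {
  ok <- Filter(function(h) {
    isTRUE(h$passes_window) && h$e_value <= e_cutoff
  }, hits)
  if (length(ok) == 0L) return(NULL)
  key <- vapply(ok, function(h) {
    sprintf("%012.9f|%012.9f|%020.9e|%s",
            1 - h$window_fraction, 1 - h$global_identity,
            h$e_value, h$template_id)
  }, "")
  ok[[order(key)[1L]]]
}

#' Map target residues onto template structure residues
#'
#' Walks the alignment column by column and pairs each aligned target
#' residue with the corresponding template residue identifier (chain,
#' residue number) taken from the structure's ATOM records. The map is
#' strictly monotone; target residues aligned to template gaps are
#' reported as unmapped.
#'
#' @param hit A `template_hit`.
#' @param structure A [parse_structure()] model containing the template
#'   chain.
#' @param chain Chain identifier in `structure`; defaults to the suffix
#'   of a `templateID_chain` style `template_id`.
#' @return List with `pairs` (data frame `target_index`, `chain`,
#'   `resno`) and `unmapped` (integer target indices aligned to
#'   template gaps).
#' @export
map_residue_to_template <- function(hit, structure, chain = NULL) {
  stopifnot(inherits(hit, "template_hit"))
  if (is.null(chain)) {
    parts <- strsplit(hit$template_id, "_", fixed = TRUE)[[1]]
    chain <- parts[length(parts)]
  }
  res <- chain_residues(structure, chain)
  seq1 <- paste(res$one, collapse = "")
  ta <- strsplit(hit$target_aln, "")[[1]]
  pa <- strsplit(hit$template_aln, "")[[1]]
  # verify the aligned template residues against the ATOM sequence
  tpl_idx <- cumsum(pa != "-") + hit$template_start - 1L
  tpl_idx[pa == "-"] <- NA_integer_
  for (k in which(!is.na(tpl_idx))) {
    if (tpl_idx[k] > nchar(seq1) ||
        substr(seq1, tpl_idx[k], tpl_idx[k]) != pa[k]) {
      stop(sprintf(
        "template sequence inconsistent with ATOM records of chain %s at residue %d ('%s' vs '%s')",
        chain, tpl_idx[k], pa[k],
        ifelse(tpl_idx[k] > nchar(seq1), "",
               substr(seq1, tpl_idx[k], tpl_idx[k]))))
    }
  }
  t_idx <- cumsum(ta != "-") + hit$target_start - 1L
  t_idx[ta == "-"] <- NA_integer_
  both <- !is.na(t_idx) & !is.na(tpl_idx)
  pairs <- data.frame(
    target_index = t_idx[both],
    chain = chain,
    resno = res$resno[tpl_idx[both]],
    stringsAsFactors = FALSE)
  list(pairs = pairs,
       unmapped = t_idx[!is.na(t_idx) & is.na(tpl_idx)])
}

#' Search a template library for a mutated protein
#'
#' Aligns the target against every library sequence, applies the
#' variant-window rule and returns all hits plus the selected template.
#'
#' @param target Target protein sequence.
#' @param library Named character vector of template sequences
#'   (names are `templateID_chain` identifiers).
#' @param variant_residue_start,variant_residue_end Affected residue
#'   span on the target.
#' @param e_cutoff Significance cutoff.
#' @return List with `hits` (all scored hits) and `selected` (winning
#'   hit or `NULL`).
#' @export
search_templates <- function(target, library, variant_residue_start,
                             variant_residue_end = variant_residue_start,
                             e_cutoff = 1e-3) {
  stopifnot(length(library) > 0L, !is.null(names(library)))
  lib_size <- sum(nchar(library))
  hits <- lapply(names(library), function(id) {
    h <- align_and_score(target, library[[id]], lib_size, template_id = id)
    window_identity(h, variant_residue_start, variant_residue_end)
  })
  list(hits = hits, selected = select_template(hits, e_cutoff))
}
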