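# Raw variant representation and VCF-style left normalization.

#' Construct a raw variant
#'
#' A single-locus sequence variant in VCF convention: `position` is the
#' 1-based genomic coordinate of the first reference base of `ref`.
#' Optional read-support fraction and population allele frequency travel
#' with the record so the cohort filters can act on them.
#'
#' @param chromosome Chromosome / contig name.
#' @param position 1-based position of the first REF base.
#' @param ref Reference allele (non-empty nucleotide string).
#' @param alt Alternate allele (non-empty nucleotide string, != ref).
#' @param support_fraction Fraction of reads supporting the variant, in
#'   `[0, 1]`, or `NA` when unknown.
#' @param population_af Population allele frequency in `[0, 1]`, or `NA`.
#' @param id Optional variant identifier.
#' @return An object of class `raw_variant`.
#' @export
raw_variant <- function(chromosome, position, ref, alt,
                        support_fraction = NA_real_,
                        population_af = NA_real_,
                        id = NA_character_) {
  ref <- toupper(as.character(ref))
  alt <- toupper(as.character(alt))
  stopifnot(nzchar(ref), nzchar(alt))
  if (identical(ref, alt)) stop("ref and alt alleles must differ")
  if (!grepl("^[ACGTN]+$", ref) || !grepl("^[ACGTN]+$", alt)) {
    stop("alleles must be nucleotide strings over ACGTN")
  }
  structure(
    list(chromosome = as.character(chromosome),
         position = as.integer(position),
         ref = ref, alt = alt,
         support_fraction = as.numeric(support_fraction),
         population_af = as.numeric(population_af),
         id = as.character(id)),
    class = "raw_variant")
}

#' @export
print.raw_variant <- function(x, ...) {
  cat(sprintf("<raw_variant> %s:%d %s>%s\n",
              x$chromosome, x$position, x$ref, x$alt))
  invisible(x)
}

#' Left-align and trim an indel to its minimal VCF representation
#'
#' Returns the left-most equivalent representation of an indel with the
#' shared prefix/suffix trimmed down to a single VCF-style anchor base.
#' The operation is idempotent and is required before redundancy checks
#' and sequence-context classification, which are defined on normalized
#' representations.
#'
#' @param v A [raw_variant()].
#' @param reference_window Reference nucleotide string covering the
#'   variant and enough left flank for the shift (the caller should
#'   provide at least 25 nt of left flank).
#' @param window_start 1-based genomic position of the first base of
#'   `reference_window`.
#' @return A normalized [raw_variant()].
#' @export
normalize_indel <- function(v, reference_window, window_start) {
  stopifnot(inherits(v, "raw_variant"))
  w <- toupper(as.character(reference_window))
  window_start <- as.integer(window_start)
  pos <- v$position
  ref <- v$ref
  alt <- v$alt

  idx <- function(gpos) gpos - window_start + 1L
  if (idx(pos) < 1L || idx(pos) + nchar(ref) - 1L > nchar(w)) {
    stop("reference_window does not cover the variant")
  }
  observed <- substr(w, idx(pos), idx(pos) + nchar(ref) - 1L)
  if (!identical(observed, ref)) {
    stop(sprintf(
      "reference mismatch at %s:%d: window has '%s' but ref allele is '%s'",
      v$chromosome, pos, observed, ref))
  }

  last1 <- function(s) substr(s, nchar(s), nchar(s))
  # Left-shift: while ref and alt end in the same base (and one of them
  # would not vanish without re-anchoring), drop that base; when an
  # allele empties, prepend the preceding reference base.
  repeat {
    if (nchar(ref) > 0L && nchar(alt) > 0L &&
        last1(ref) == last1(alt) &&
        (nchar(ref) > 1L || nchar(alt) > 1L)) {
      ref <- substr(ref, 1L, nchar(ref) - 1L)
      alt <- substr(alt, 1L, nchar(alt) - 1L)
      if (nchar(ref) == 0L || nchar(alt) == 0L) {
        if (idx(pos - 1L) < 1L) {
          stop("reference_window provides insufficient left flank for normalization")
        }
        pos <- pos - 1L
        b <- substr(w, idx(pos), idx(pos))
        ref <- paste0(b, ref)
        alt <- paste0(b, alt)
      }
    } else break
  }
  # Trim shared prefix down to a single anchor base.
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  raw_variant(v$chromosome, pos, ref, alt,
              v$support_fraction, v$population_af, v$id)
}

#' Net length change of a variant
#' @param v A [raw_variant()].
#' @return Signed integer, `nchar(alt) - nchar(ref)`.
#' @export
net_length_change <- function(v) nchar(v$alt) - nchar(v$ref)

# Decompose a normalized variant into the genomic bases it alters.
# Returns list(type, del_start, del_end, inserted) where for insertions
# del_start/del_end bracket the insertion point (the two flanking bases)
# and inserted holds the inserted sequence.
altered_span <- function(v) {
  ref <- v$ref; alt <- v$alt; pos <- v$position
  # strip shared anchor prefix
  npre <- 0L
  while (npre < min(nchar(ref), nchar(alt)) &&
         substr(ref, npre + 1L, npre + 1L) == substr(alt, npre + 1L, npre + 1L)) {
    npre <- npre + 1L
  }
  r <- substr(ref, npre + 1L, nchar(ref))
  a <- substr(alt, npre + 1L, nchar(alt))
  if (nchar(r) > 0L && nchar(a) == 0L) {
    list(type = "del",
         del_start = pos + npre, del_end = pos + nchar(ref) - 1L,
         inserted = "")
  } else if (nchar(r) == 0L && nchar(a) > 0L) {
    list(type = "ins",
         del_start = pos + npre - 1L, del_end = pos + npre,
         inserted = a)
  } else if (nchar(r) > 0L && nchar(a) > 0L) {
    list(type = "delins",
         del_start = pos + npre, del_end = pos + nchar(ref) - 1L,
         inserted = a)
  } else {
    stop("degenerate variant: ref equals alt")
  }
}
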