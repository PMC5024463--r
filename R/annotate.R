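# Projection of indels onto transcripts, frame and protein-level
# consequence calling, and the cohort quality/frequency filters.

#' Filter thresholds for indel triage
#'
#' Defaults encode the study design: indels supported by fewer than 0.1
#' of reads are discarded, population allele frequency above 1% is
#' deemed benign, samples qualify when at least 99.5% of the target is
#' covered to 50x, changes within 2 bp of intron-exon boundaries are
#' flagged, and a "small" indel gains or loses at most 21 nucleotides.
#'
#' @param max_indel_nt Maximum absolute net length change (nt).
#' @param min_support_fraction Minimum read-support fraction (kept when
#'   `support_fraction >= min_support_fraction`; strict `<` discards).
#' @param max_benign_af Population allele frequency above which a
#'   variant is deemed benign (strict `>` discards).
#' @param min_depth Minimum per-base depth for coverage assessment.
#' @param min_covered_fraction Minimum fraction of target positions at
#'   `min_depth` for a sample to be included.
#' @param splice_window_nt Distance (bp) from an intron-exon boundary
#'   within which a change is flagged splice-proximal.
#' @return A `filter_thresholds` list.
#' @export
filter_thresholds <- function(max_indel_nt = 21L,
                              min_support_fraction = 0.1,
                              max_benign_af = 0.01,
                              min_depth = 50L,
                              min_covered_fraction = 0.995,
                              splice_window_nt = 2L) {
  stopifnot(max_indel_nt >= 1L,
            min_support_fraction >= 0, min_support_fraction <= 1,
            max_benign_af >= 0, max_benign_af <= 1,
            min_depth >= 0L,
            min_covered_fraction >= 0, min_covered_fraction <= 1,
            splice_window_nt >= 0L)
  structure(list(max_indel_nt = as.integer(max_indel_nt),
                 min_support_fraction = min_support_fraction,
                 max_benign_af = max_benign_af,
                 min_depth = as.integer(min_depth),
                 min_covered_fraction = min_covered_fraction,
                 splice_window_nt = as.integer(splice_window_nt)),
            class = "filter_thresholds")
}

new_coding_indel <- function(v, t, status) {
  structure(
    list(variant = v, transcript_id = t$transcript_id,
         gene = t$gene, status = status,
         cds_start = NA_integer_, cds_end = NA_integer_,
         net_length_change = net_length_change(v),
         frame_status = NA_character_,
         affected_residue_start = NA_integer_,
         affected_residue_end = NA_integer_,
         n_affected_residues = NA_integer_,
         hgvs_c = NA_character_, hgvs_p = NA_character_,
         splice_proximal = NA, out_of_scope = FALSE),
    class = "coding_indel")
}

#' @export
print.coding_indel <- function(x, ...) {
  cat(sprintf("<coding_indel> %s %s:%d %s>%s [%s] %s %s\n",
              x$transcript_id, x$variant$chromosome, x$variant$position,
              x$variant$ref, x$variant$alt, x$status,
              x$hgvs_c %||% NA, x$hgvs_p %||% NA))
  invisible(x)
}

#' Project a variant onto a transcript and classify its frame effect
#'
#' Computes strand-aware CDS coordinates for the altered bases, the net
#' length change and the resulting frame status. In-frame coding records
#' within the size limit receive a protein-level consequence via
#' [compute_protein_change()]. Records whose net change exceeds the
#' small-indel limit are retained and marked out-of-scope rather than
#' dropped; purely intronic and exon/intron-junction-spanning changes
#' return typed `"non_coding"` / `"junction_spanning"` results with no
#' protein change.
#'
#' @param v A normalized [raw_variant()].
#' @param t A [transcript_model()].
#' @param th A [filter_thresholds()].
#' @return A `coding_indel` object; its `status` field is one of
#'   `"coding"`, `"non_coding"`, `"junction_spanning"`,
#'   `"terminal_codon"`.
#' @export
project_and_classify_frame <- function(v, t, th = filter_thresholds()) {
  stopifnot(inherits(v, "raw_variant"), inherits(t, "transcript_model"))
  span <- altered_span(v)
  bases <- span$del_start:span$del_end
  cds_pos <- genomic_to_cds(t, bases)
  n_in <- sum(!is.na(cds_pos))
  net <- net_length_change(v)
  frame <- if (abs(net) %% 3L == 0L) "in_frame" else "frameshift"
  oos <- abs(net) > th$max_indel_nt

  status <- if (span$type == "ins") {
    # insertion point between two flanking bases
    if (n_in == 2L) "coding" else if (n_in == 1L) "junction_spanning"
    else "non_coding"
  } else {
    if (n_in == length(bases)) "coding" else if (n_in > 0L) "junction_spanning"
    else "non_coding"
  }

  ci <- new_coding_indel(v, t, status)
  ci$frame_status <- frame
  ci$out_of_scope <- oos
  ci$splice_proximal <- flag_splice_proximity_span(span, t, th)
  if (status != "coding") return(ci)

  ci$cds_start <- min(cds_pos)
  ci$cds_end <- max(cds_pos)
  ci$hgvs_c <- hgvs_cds_name(ci, t, span)
  if (frame == "in_frame" && !oos) ci <- compute_protein_change(ci, t)
  ci
}

# Express a normalized genomic indel in CDS coordinates/orientation.
cds_level_change <- function(ci, t) {
  v <- ci$variant
  span <- altered_span(v)
  ins_seq <- span$inserted
  if (t$strand == "-" && nzchar(ins_seq)) ins_seq <- revcomp(ins_seq)
  if (span$type == "ins") {
    flanks <- genomic_to_cds(t, c(span$del_start, span$del_end))
    list(type = "ins", after = min(flanks), del = integer(0),
         inserted = ins_seq)
  } else {
    cds_pos <- sort(genomic_to_cds(t, span$del_start:span$del_end))
    list(type = span$type, after = NA_integer_,
         del = c(cds_pos[1L], cds_pos[length(cds_pos)]),
         inserted = ins_seq)
  }
}

#' Compute the protein-level consequence of an in-frame coding indel
#'
#' Translates the reference and mutant CDS and names the difference
#' following the HGVS protein convention: the change is placed at its
#' most C-terminal (3'-most) equivalent position, even though the
#' underlying VCF representation is left (5') aligned. Deletions that
#' remove the initiator or the stop codon yield a typed
#' `"terminal_codon"` result with no protein name.
#'
#' @param ci A `coding_indel` with `status == "coding"` and
#'   `frame_status == "in_frame"`.
#' @param t The matching [transcript_model()].
#' @return The `coding_indel` with `hgvs_p`, affected residue range and
#'   `n_affected_residues` filled in.
#' @export
compute_protein_change <- function(ci, t) {
  stopifnot(identical(ci$status, "coding"),
            identical(ci$frame_status, "in_frame"))
  ch <- cds_level_change(ci, t)
  cds <- t$cds_sequence
  n <- nchar(cds)
  if (ch$type != "ins") {
    if (ch$del[1L] <= 3L || ch$del[2L] >= n - 2L) {
      ci$status <- "terminal_codon"
      ci$hgvs_p <- NA_character_
      return(ci)
    }
  }
  mut <- if (ch$type == "ins") {
    paste0(substr(cds, 1L, ch$after), ch$inserted,
           substr(cds, ch$after + 1L, n))
  } else {
    paste0(substr(cds, 1L, ch$del[1L] - 1L), ch$inserted,
           substr(cds, ch$del[2L] + 1L, n))
  }
  wt_p <- sub("\\*$", "", translate_cds(cds))
  mut_p <- sub("\\*$", "", translate_cds(mut))
  premature_stop <- grepl("\\*", mut_p)
  if (premature_stop) {
    # a non-codon-aligned in-frame change whose junction codon is a
    # stop: truncating, named p.(Xaa#Ter)
    mut_p <- sub("\\*.*$", "", mut_p)
  }

  d <- protein_diff(wt_p, mut_p)
  if (premature_stop) {
    rs <- d$prefix + 1L
    ci$hgvs_p <- sprintf("p.(%s%dTer)",
                         AA_THREE[[substr(wt_p, rs, rs)]], rs)
    ci$affected_residue_start <- rs
    ci$affected_residue_end <- rs
    ci$n_affected_residues <- 1L
    return(ci)
  }
  aa3 <- function(i, p = wt_p) {
    if (i > nchar(p)) "Ter" else AA_THREE[[substr(p, i, i)]]
  }
  seq3 <- function(s) paste(vapply(strsplit(s, "")[[1]],
                                   function(a) AA_THREE[[a]], ""),
                            collapse = "")
  a <- d$prefix
  if (!nzchar(d$deleted) && !nzchar(d$inserted)) {
    ci$hgvs_p <- "p.(=)"
    rs <- ceiling(ci$cds_start / 3); re <- ceiling(ci$cds_end / 3)
  } else if (nzchar(d$deleted) && !nzchar(d$inserted)) {
    rs <- a + 1L; re <- a + nchar(d$deleted)
    ci$hgvs_p <- if (rs == re) {
      sprintf("p.(%s%ddel)", aa3(rs), rs)
    } else {
      sprintf("p.(%s%d_%s%ddel)", aa3(rs), rs, aa3(re), re)
    }
  } else if (!nzchar(d$deleted)) {
    rs <- max(a, 1L); re <- rs + 1L
    ci$hgvs_p <- sprintf("p.(%s%d_%s%dins%s)", aa3(rs), rs, aa3(re), re,
                         seq3(d$inserted))
  } else {
    rs <- a + 1L; re <- a + nchar(d$deleted)
    loc <- if (rs == re) sprintf("%s%d", aa3(rs), rs) else
      sprintf("%s%d_%s%d", aa3(rs), rs, aa3(re), re)
    ci$hgvs_p <- sprintf("p.(%sdelins%s)", loc, seq3(d$inserted))
  }
  ci$affected_residue_start <- as.integer(rs)
  ci$affected_residue_end <- as.integer(re)
  ci$n_affected_residues <- as.integer(re - rs + 1L)
  ci
}

# 3'-most protein difference: maximize the common prefix first, then the
# common suffix of the remainders (this is the HGVS 3' shift).
protein_diff <- function(wt, mut) {
  nw <- nchar(wt); nm <- nchar(mut)
  a <- 0L
  while (a < min(nw, nm) &&
         substr(wt, a + 1L, a + 1L) == substr(mut, a + 1L, a + 1L)) {
    a <- a + 1L
  }
  b <- 0L
  while (b < min(nw, nm) - a &&
         substr(wt, nw - b, nw - b) == substr(mut, nm - b, nm - b)) {
    b <- b + 1L
  }
  list(prefix = a,
       deleted = substr(wt, a + 1L, nw - b),
       inserted = substr(mut, a + 1L, nm - b))
}

# HGVS cDNA-level name; the cDNA change is 3'-shifted on the CDS
# sequence per HGVS convention.
hgvs_cds_name <- function(ci, t, span) {
  ch <- cds_level_change(ci, t)
  cds <- t$cds_sequence
  n <- nchar(cds)
  if (ch$type == "del") {
    d1 <- ch$del[1L]; d2 <- ch$del[2L]
    while (d2 + 1L <= n &&
           substr(cds, d1, d1) == substr(cds, d2 + 1L, d2 + 1L)) {
      d1 <- d1 + 1L; d2 <- d2 + 1L
    }
    if (d1 == d2) sprintf("c.%ddel", d1) else sprintf("c.%d_%ddel", d1, d2)
  } else if (ch$type == "ins") {
    p <- ch$after; s <- ch$inserted
    while (p + 1L <= n &&
           substr(cds, p + 1L, p + 1L) == substr(s, 1L, 1L)) {
      s <- paste0(substr(s, 2L, nchar(s)), substr(s, 1L, 1L))
      p <- p + 1L
    }
    sprintf("c.%d_%dins%s", p, p + 1L, s)
  } else {
    sprintf("c.%d_%ddelins%s", ch$del[1L], ch$del[2L], ch$inserted)
  }
}

flag_splice_proximity_span <- function(span, t, th) {
  b <- splice_boundaries(t)
  if (length(b) == 0L) return(FALSE)
  bases <- span$del_start:span$del_end
  any(vapply(bases, function(p) min(abs(p - b)) <= th$splice_window_nt,
             logical(1L)))
}

#' Flag splice-proximal changes
#'
#' A change is splice-proximal when any altered base (for insertions,
#' either base flanking the insertion point) lies within
#' `splice_window_nt` of an intron-exon boundary, boundary bases
#' inclusive.
#'
#' @param ci A projected `coding_indel`.
#' @param t The matching [transcript_model()].
#' @param th A [filter_thresholds()].
#' @return Logical scalar.
#' @export
flag_splice_proximity <- function(ci, t, th = filter_thresholds()) {
  flag_splice_proximity_span(altered_span(ci$variant), t, th)
}

#' Partition indel records into kept and discarded
#'
#' Applies the cohort filters in fixed order -- read support, then
#' benign allele frequency, then size -- and records the first failing
#' rule for each discarded record. Missing `support_fraction` or
#' `population_af` pass the corresponding rule (the study filtered only
#' where the metric existed).
#'
#' @param records Data frame with columns `support_fraction`,
#'   `population_af` and `net_length_change` (extra columns pass
#'   through).
#' @param th A [filter_thresholds()].
#' @return List with elements `kept` (data frame) and `discarded` (data
#'   frame with an extra `reason` column, one of `"support"`,
#'   `"benign_af"`, `"size"`). The partition is exhaustive.
#' @export
apply_filters <- function(records, th = filter_thresholds()) {
  stopifnot(is.data.frame(records))
  reason <- rep(NA_character_, nrow(records))
  sup <- records$support_fraction
  fail_sup <- !is.na(sup) & sup < th$min_support_fraction
  reason[fail_sup] <- "support"
  af <- records$population_af
  fail_af <- is.na(reason) & !is.na(af) & af > th$max_benign_af
  reason[fail_af] <- "benign_af"
  fail_size <- is.na(reason) &
    abs(records$net_length_change) > th$max_indel_nt
  reason[fail_size] <- "size"
  discarded <- records[!is.na(reason), , drop = FALSE]
  discarded$reason <- reason[!is.na(reason)]
  list(kept = records[is.na(reason), , drop = FALSE],
       discarded = discarded)
}

#' Assess per-sample target coverage
#'
#' A sample is included when the fraction of target positions covered
#' to at least `min_depth` is at least `min_covered_fraction`.
#'
#' @param per_base_depths Non-empty vector of non-negative integers.
#' @param th A [filter_thresholds()].
#' @return `"included"` or `"excluded"`.
#' @export
assess_sample_coverage <- function(per_base_depths, th = filter_thresholds()) {
  if (length(per_base_depths) == 0L) stop("empty depth vector")
  if (any(per_base_depths < 0)) stop("negative depths")
  frac <- mean(per_base_depths >= th$min_depth)
  if (frac >= th$min_covered_fraction) "included" else "excluded"
}

#' Read indel candidate records from a VCF file
#'
#' Site-level fields only are required. Multi-allelic records are split
#' into one row per ALT. The read-support fraction is taken from the
#' first sample's `AD` genotype field when present (alt / total), and
#' the population allele frequency from the `AF` INFO field.
#'
#' @param path Path to a VCF (v4.x) file.
#' @return Data frame with columns `chromosome`, `position`, `ref`,
#'   `alt`, `support_fraction`, `population_af`, `id`.
#' @export
read_vcf_variants <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  af_info <- suppressWarnings(vcfR::extract.info(vcf, "AF"))
  ad <- NULL
  if (ncol(vcf@gt) > 1L) {
    ad <- tryCatch(vcfR::extract.gt(vcf, "AD")[, 1L],
                   error = function(e) NULL)
  }
  out <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    afs <- if (!is.null(af_info) && !is.na(af_info[i])) {
      as.numeric(strsplit(af_info[i], ",", fixed = TRUE)[[1]])
    } else rep(NA_real_, length(alts))
    sup <- rep(NA_real_, length(alts))
    if (!is.null(ad) && !is.na(ad[i])) {
      counts <- as.numeric(strsplit(ad[i], ",", fixed = TRUE)[[1]])
      tot <- sum(counts)
      if (tot > 0 && length(counts) >= length(alts) + 1L) {
        sup <- counts[-1L][seq_along(alts)] / tot
      }
    }
    for (k in seq_along(alts)) {
      out[[length(out) + 1L]] <- data.frame(
        chromosome = fix[i, "CHROM"],
        position = as.integer(fix[i, "POS"]),
        ref = fix[i, "REF"], alt = alts[k],
        support_fraction = sup[k],
        population_af = if (k <= length(afs)) afs[k] else NA_real_,
        id = if (!is.na(fix[i, "ID"]) && fix[i, "ID"] != ".")
          fix[i, "ID"] else sprintf("var%04d", length(out) + 1L),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
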