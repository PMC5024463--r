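# Transcript models: construction, IO (JSON dialect and GFF3) and
# coordinate mapping between genome and spliced CDS.

#' Construct a transcript model
#'
#' Exons and CDS intervals are 1-based inclusive genomic intervals,
#' stored sorted in ascending genomic order regardless of strand; the
#' spliced, strand-corrected CDS sequence starts at the initiator codon.
#' Violations of the coding conventions (length divisible by 3, ATG
#' start, stop at the end) raise validation warnings, not errors, so
#' real-world annotation oddities remain inspectable.
#'
#' @param transcript_id Transcript identifier.
#' @param chromosome Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons Matrix or list of `c(start, end)` genomic intervals.
#' @param cds CDS intervals, same convention as `exons`.
#' @param cds_sequence Spliced CDS nucleotide string; if `NULL` and
#'   `genome` is given it is derived from the CDS intervals.
#' @param genome Optional named character vector (or `DNAStringSet`) of
#'   chromosome sequences used to derive `cds_sequence`.
#' @param gene Optional gene symbol.
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, chromosome, strand, exons, cds,
                             cds_sequence = NULL, genome = NULL,
                             gene = NA_character_) {
  stopifnot(strand %in% c("+", "-"))
  as_mat <- function(x) {
    m <- if (is.matrix(x)) x else do.call(rbind, lapply(x, as.integer))
    m <- matrix(as.integer(m), ncol = 2L,
                dimnames = list(NULL, c("start", "end")))
    m[order(m[, 1L]), , drop = FALSE]
  }
  exons <- as_mat(exons)
  cds <- as_mat(cds)
  if (any(exons[, 2L] < exons[, 1L])) stop("exon end precedes start")
  if (nrow(exons) > 1L &&
      any(exons[-1L, 1L] <= exons[-nrow(exons), 2L])) {
    stop("exons overlap or are unsorted")
  }
  if (is.null(cds_sequence)) {
    if (is.null(genome)) stop("provide cds_sequence or a genome to derive it")
    cds_sequence <- derive_cds_sequence(chromosome, strand, cds, genome)
  }
  cds_sequence <- toupper(as.character(cds_sequence))
  if (sum(cds[, 2L] - cds[, 1L] + 1L) != nchar(cds_sequence)) {
    stop("cds_sequence length does not match the CDS intervals")
  }
  if (nchar(cds_sequence) %% 3L != 0L) {
    warning(sprintf("%s: CDS length %d is not divisible by 3",
                    transcript_id, nchar(cds_sequence)))
  }
  if (substr(cds_sequence, 1L, 3L) != "ATG") {
    warning(sprintf("%s: CDS does not begin with ATG", transcript_id))
  }
  n <- nchar(cds_sequence)
  if (n >= 3L && !substr(cds_sequence, n - 2L, n) %in% c("TAA", "TAG", "TGA")) {
    warning(sprintf("%s: CDS does not end with a stop codon", transcript_id))
  }
  structure(
    list(transcript_id = as.character(transcript_id),
         gene = as.character(gene),
         chromosome = as.character(chromosome),
         strand = strand, exons = exons, cds = cds,
         cds_sequence = cds_sequence),
    class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s (%s) %s:%s, %d exon(s), CDS %d nt\n",
              x$transcript_id, x$gene, x$chromosome, x$strand,
              nrow(x$exons), nchar(x$cds_sequence)))
  invisible(x)
}

get_chrom_seq <- function(genome, chromosome) {
  if (methods::is(genome, "DNAStringSet")) {
    as.character(genome[[chromosome]])
  } else {
    s <- genome[[chromosome]]
    if (is.null(s) || is.na(s)) stop("chromosome not found in genome: ", chromosome)
    toupper(as.character(s))
  }
}

#' Derive a spliced, strand-corrected CDS sequence
#'
#' @param chromosome Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param cds CDS interval matrix (ascending genomic order).
#' @param genome Named character vector or `DNAStringSet`.
#' @return CDS nucleotide string beginning at the initiator codon.
#' @export
derive_cds_sequence <- function(chromosome, strand, cds, genome) {
  chrom <- get_chrom_seq(genome, chromosome)
  pieces <- apply(cds, 1L, function(iv) substr(chrom, iv[1L], iv[2L]))
  s <- paste(pieces, collapse = "")
  if (strand == "-") s <- revcomp(s)
  s
}

#' Read transcripts from the package JSON dialect
#'
#' The dialect is a JSON array of objects with fields `transcript_id`,
#' `chromosome`, `strand`, `exons` (array of `[start, end]`), `cds`
#' (idem) and optionally `gene` and `cds_sequence`.
#'
#' @param path JSON file path.
#' @param genome Optional genome used to derive missing CDS sequences.
#' @return List of [transcript_model()] objects named by transcript id.
#' @export
read_transcripts_json <- function(path, genome = NULL) {
  recs <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  txs <- lapply(recs, function(r) {
    transcript_model(r$transcript_id, r$chromosome, r$strand,
                     lapply(r$exons, unlist), lapply(r$cds, unlist),
                     cds_sequence = r$cds_sequence %||% NULL,
                     genome = genome, gene = r$gene %||% NA_character_)
  })
  names(txs) <- vapply(txs, `[[`, "", "transcript_id")
  txs
}

#' Read transcripts from GFF3 CDS features
#'
#' CDS features are grouped by their `Parent` (or `transcript_id`)
#' attribute; exon features are used when present, otherwise exons are
#' taken equal to the CDS intervals.
#'
#' @param path GFF3 file path.
#' @param genome Genome (named character vector or `DNAStringSet`) used
#'   to derive CDS sequences.
#' @return List of [transcript_model()] objects named by transcript id.
#' @export
read_transcripts_gff3 <- function(path, genome) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  parent_of <- function(d) {
    p <- if ("Parent" %in% names(d)) as.character(d$Parent) else NA
    ifelse(is.na(p) | !nzchar(p),
           if ("transcript_id" %in% names(d)) as.character(d$transcript_id) else NA,
           p)
  }
  cds_df <- df[df$type == "CDS", , drop = FALSE]
  if (nrow(cds_df) == 0L) stop("no CDS features in GFF3: ", path)
  cds_df$parent <- parent_of(cds_df)
  exon_df <- df[df$type == "exon", , drop = FALSE]
  if (nrow(exon_df)) exon_df$parent <- parent_of(exon_df)
  txs <- lapply(split(cds_df, cds_df$parent), function(d) {
    ex <- if (nrow(exon_df)) exon_df[exon_df$parent == d$parent[1L], ] else d
    if (nrow(ex) == 0L) ex <- d
    transcript_model(sub("^transcript:", "", d$parent[1L]),
                     as.character(d$seqnames[1L]),
                     as.character(d$strand[1L]),
                     cbind(ex$start, ex$end), cbind(d$start, d$end),
                     genome = genome)
  })
  names(txs) <- vapply(txs, `[[`, "", "transcript_id")
  txs
}

# Map genomic positions to 1-based spliced CDS coordinates.
# Returns NA for positions outside the CDS intervals.
genomic_to_cds <- function(t, gpos) {
  cds <- t$cds
  lens <- cds[, 2L] - cds[, 1L] + 1L
  res <- rep(NA_integer_, length(gpos))
  if (t$strand == "+") {
    offs <- cumsum(c(0L, lens))[seq_len(nrow(cds))]
    for (k in seq_len(nrow(cds))) {
      i <- gpos >= cds[k, 1L] & gpos <= cds[k, 2L]
      res[i] <- offs[k] + (gpos[i] - cds[k, 1L] + 1L)
    }
  } else {
    ord <- rev(seq_len(nrow(cds)))  # descending genomic order
    offs <- cumsum(c(0L, lens[ord]))[seq_len(nrow(cds))]
    for (j in seq_len(nrow(cds))) {
      k <- ord[j]
      i <- gpos >= cds[k, 1L] & gpos <= cds[k, 2L]
      res[i] <- offs[j] + (cds[k, 2L] - gpos[i] + 1L)
    }
  }
  res
}

# Is a genomic position inside any exon of the transcript?
in_exons <- function(t, gpos) {
  vapply(gpos, function(p) any(p >= t$exons[, 1L] & p <= t$exons[, 2L]),
         logical(1L))
}

# Internal splice boundaries: exon edges that abut introns (the
# transcript's outermost ends are not splice sites).
splice_boundaries <- function(t) {
  ex <- t$exons
  if (nrow(ex) < 2L) return(integer(0))
  sort(c(ex[-nrow(ex), 2L], ex[-1L, 1L]))
}
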