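# End-to-end orchestration: annotate -> context -> template search ->
# structure assessment -> evaluation, with deterministic CSV/JSON
# outputs and a run log.

#' Pipeline configuration
#'
#' @param vcf Path to the variant VCF.
#' @param transcripts Path to transcripts (JSON dialect or GFF3; GFF3
#'   requires `genome`).
#' @param genome Path to the genome FASTA.
#' @param template_fasta Optional template library FASTA
#'   (`templateID_chain` identifiers).
#' @param template_pdb_dir Optional directory of `templateID.pdb`
#'   files.
#' @param tool_calls Optional CSV with `variant_id`, `ddig_in`,
#'   `sift_indel`, `provean`.
#' @param clinical Optional CSV with `variant_id`, `clinical`.
#' @param output_dir Output directory.
#' @param thresholds A [filter_thresholds()].
#' @param structure_thresholds A [structure_thresholds()].
#' @param seed Integer seed recorded in the log (the pipeline itself is
#'   deterministic).
#' @return A `pipeline_config` list (paths are checked at run time).
#' @export
pipeline_config <- function(vcf, transcripts, genome,
                            template_fasta = NULL,
                            template_pdb_dir = NULL,
                            tool_calls = NULL, clinical = NULL,
                            output_dir = tempfile("indelstruct_run"),
                            thresholds = filter_thresholds(),
                            structure_thresholds =
                              indelstruct::structure_thresholds(),
                            seed = 1L) {
  structure(list(vcf = vcf, transcripts = transcripts, genome = genome,
                 template_fasta = template_fasta,
                 template_pdb_dir = template_pdb_dir,
                 tool_calls = tool_calls, clinical = clinical,
                 output_dir = output_dir, thresholds = thresholds,
                 structure_thresholds = structure_thresholds,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Annotate every VCF variant against every overlapping transcript
#'
#' Normalizes each variant (left alignment with anchor trimming),
#' projects it onto each transcript whose exon span it touches, and
#' returns one row per variant x transcript with frame, protein-level
#' consequence, splice proximity and sequence context.
#'
#' @param variants Data frame from [read_vcf_variants()].
#' @param transcripts List of [transcript_model()].
#' @param genome Named character vector of chromosome sequences.
#' @param th A [filter_thresholds()].
#' @return Data frame (one row per variant x transcript; variants
#'   touching no transcript get a single `non_coding` row with
#'   `transcript_id = NA`).
#' @export
annotate_variants <- function(variants, transcripts, genome,
                              th = filter_thresholds()) {
  rows <- list()
  for (i in seq_len(nrow(variants))) {
    vr <- variants[i, ]
    chrom <- genome[[vr$chromosome]]
    if (is.null(chrom) || is.na(chrom)) {
      stop("chromosome missing from genome: ", vr$chromosome)
    }
    win_lo <- max(1L, vr$position - 60L)
    win_hi <- min(nchar(chrom), vr$position + nchar(vr$ref) + 60L)
    win <- substr(chrom, win_lo, win_hi)
    v <- raw_variant(vr$chromosome, vr$position, vr$ref, vr$alt,
                     vr$support_fraction, vr$population_af, vr$id)
    nv <- normalize_indel(v, win, win_lo)
    ctx <- sequence_context(nv, win, win_lo)
    span <- altered_span(nv)
    touched <- Filter(function(t) {
      t$chromosome == nv$chromosome &&
        span$del_end >= min(t$exons) - 50L &&
        span$del_start <= max(t$exons) + 50L
    }, transcripts)
    base <- data.frame(
      variant_id = vr$id, chromosome = nv$chromosome,
      position = nv$position, ref = nv$ref, alt = nv$alt,
      support_fraction = vr$support_fraction,
      population_af = vr$population_af,
      net_length_change = net_length_change(nv),
      context_label = ctx$label,
      repeat_unit = ctx$repeat_unit,
      copy_count = ctx$reference_copy_count,
      run_length = ctx$homopolymer_run_length,
      stringsAsFactors = FALSE)
    if (length(touched) == 0L) {
      row <- base
      row$transcript_id <- NA_character_; row$gene <- NA_character_
      row$status <- "non_coding"; row$frame_status <- NA_character_
      row$cds_start <- NA_integer_; row$cds_end <- NA_integer_
      row$hgvs_c <- NA_character_; row$hgvs_p <- NA_character_
      row$affected_residue_start <- NA_integer_
      row$affected_residue_end <- NA_integer_
      row$n_affected_residues <- NA_integer_
      row$splice_proximal <- NA; row$out_of_scope <- FALSE
      rows[[length(rows) + 1L]] <- row
      next
    }
    for (t in touched) {
      ci <- project_and_classify_frame(nv, t, th)
      row <- base
      row$transcript_id <- t$transcript_id; row$gene <- t$gene
      row$status <- ci$status; row$frame_status <- ci$frame_status
      row$cds_start <- ci$cds_start; row$cds_end <- ci$cds_end
      row$hgvs_c <- ci$hgvs_c; row$hgvs_p <- ci$hgvs_p
      row$affected_residue_start <- ci$affected_residue_start
      row$affected_residue_end <- ci$affected_residue_end
      row$n_affected_residues <- ci$n_affected_residues
      row$splice_proximal <- ci$splice_proximal
      row$out_of_scope <- ci$out_of_scope
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

read_template_library <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Run the full triage pipeline
#'
#' Executes annotation, filtering, context classification, template
#' search, structural assessment and (when tool/clinical tables are
#' supplied) the concordance evaluation; writes `variants.csv`,
#' `metrics.json`, `cohort.json` and `run.log` into the output
#' directory. Reruns with identical inputs produce byte-identical
#' CSV/JSON (timestamps are confined to the log).
#'
#' @param cfg A [pipeline_config()].
#' @return Invisibly, a list with the annotated table, verdicts,
#'   metrics and output paths.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  for (p in c("vcf", "transcripts", "genome")) {
    if (!file.exists(cfg[[p]])) stop("config error: missing ", p,
                                     " file: ", cfg[[p]])
  }
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c(sprintf("indelstruct %s",
                         as.character(utils::packageVersion("indelstruct"))),
                 sprintf("started %s", format(Sys.time())),
                 sprintf("seed %d", cfg$seed),
                 sprintf("thresholds: max_indel_nt=%d min_support=%g max_af=%g",
                         cfg$thresholds$max_indel_nt,
                         cfg$thresholds$min_support_fraction,
                         cfg$thresholds$max_benign_af))
  set.seed(cfg$seed)

  genome <- read_genome_fasta(cfg$genome)
  transcripts <- if (grepl("\\.json$", cfg$transcripts)) {
    read_transcripts_json(cfg$transcripts, genome)
  } else {
    read_transcripts_gff3(cfg$transcripts, genome)
  }
  variants <- read_vcf_variants(cfg$vcf)
  if (is.null(variants) || nrow(variants) == 0L) {
    warning("no variant records in VCF; writing empty outputs")
    empty <- data.frame()
    utils::write.csv(empty, file.path(cfg$output_dir, "variants.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(n_variants = 0L),
                         file.path(cfg$output_dir, "cohort.json"),
                         auto_unbox = TRUE)
    writeLines(c(log_lines, "0 variants"),
               file.path(cfg$output_dir, "run.log"))
    return(invisible(list(variants = empty)))
  }

  ann <- annotate_variants(variants, transcripts, genome, cfg$thresholds)
  part <- apply_filters(ann, cfg$thresholds)
  ann$filter <- "kept"
  if (nrow(part$discarded)) {
    key <- paste(part$discarded$variant_id, part$discarded$transcript_id)
    m <- match(paste(ann$variant_id, ann$transcript_id), key)
    ann$filter[!is.na(m)] <- part$discarded$reason[m[!is.na(m)]]
  }
  log_lines <- c(log_lines,
                 sprintf("%d variant records; %d kept, %d discarded",
                         nrow(ann), sum(ann$filter == "kept"),
                         sum(ann$filter != "kept")))

  # structural stages
  ann$template_id <- NA_character_
  ann$template_e_value <- NA_real_
  ann$window_identity <- NA_character_
  ann$verdict <- NA_character_
  ann$mechanism <- NA_character_
  if (!is.null(cfg$template_fasta)) {
    library_seqs <- read_template_library(cfg$template_fasta)
    ann_cache <- new.env()
    assess <- which(ann$filter == "kept" & ann$status == "coding" &
                      ann$frame_status == "in_frame" & !ann$out_of_scope &
                      !is.na(ann$hgvs_p))
    for (i in assess) {
      t <- transcripts[[ann$transcript_id[i]]]
      target <- sub("\\*$", "", translate_cds(t$cds_sequence))
      sr <- search_templates(target, library_seqs,
                             ann$affected_residue_start[i],
                             ann$affected_residue_end[i])
      sel <- sr$selected
      if (is.null(sel)) { ann$verdict[i] <- "unassessable"; next }
      ann$template_id[i] <- sel$template_id
      ann$template_e_value[i] <- sel$e_value
      ann$window_identity[i] <- sprintf("%d/%d",
                                        sel$window_identity_count,
                                        sel$window_length)
      if (is.null(cfg$template_pdb_dir)) next
      pdb_id <- sub("_[^_]*$", "", sel$template_id)
      pdb_path <- file.path(cfg$template_pdb_dir,
                            paste0(pdb_id, ".pdb"))
      if (!file.exists(pdb_path)) {
        ann$verdict[i] <- "unassessable"; next
      }
      if (!exists(pdb_id, envir = ann_cache, inherits = FALSE)) {
        model <- parse_structure(pdb_path)
        ann_cache[[pdb_id]] <- list(
          model = model,
          ann = annotate_structure(model, cfg$structure_thresholds))
      }
      cache <- ann_cache[[pdb_id]]
      map <- map_residue_to_template(sel, cache$model)
      want <- ann$affected_residue_start[i]:ann$affected_residue_end[i]
      hit_rows <- map$pairs[map$pairs$target_index %in% want, ,
                            drop = FALSE]
      affected <- data.frame(chain = hit_rows$chain,
                             resno = hit_rows$resno)
      if (nrow(affected) < length(want)) {
        ann$verdict[i] <- "unassessable"; next
      }
      n_changed <- abs(ann$net_length_change[i]) %/% 3L
      v <- classify_mechanism(cache$ann, affected, n_changed,
                              cfg$structure_thresholds)
      ann$verdict[i] <- v$category
      ann$mechanism[i] <- paste(v$mechanisms, collapse = ",")
    }
    log_lines <- c(log_lines,
                   sprintf("structural assessment: %d assessed, %d with verdict",
                           length(assess),
                           sum(!is.na(ann$verdict) &
                                 ann$verdict != "unassessable")))
  }

  # evaluation
  metrics <- NULL; agreement <- NULL
  if (!is.null(cfg$tool_calls) && !is.null(cfg$clinical)) {
    tools <- utils::read.csv(cfg$tool_calls, stringsAsFactors = FALSE)
    clin <- utils::read.csv(cfg$clinical, stringsAsFactors = FALSE)
    first <- ann[!duplicated(ann$variant_id), , drop = FALSE]
    rec <- merge(merge(first[, c("variant_id", "verdict")], tools,
                       by = "variant_id"),
                 clin, by = "variant_id")
    rec$structural <- ifelse(is.na(rec$verdict), "unassessable",
                             rec$verdict)
    agreement <- vapply(seq_len(nrow(rec)), function(k) {
      compute_agreement(rec$ddig_in[k], rec$sift_indel[k],
                        rec$provean[k])
    }, logical(1L))
    metrics <- evaluate_against_clinical(rec)
  }

  # cohort summary from pipeline counts
  first <- ann[!duplicated(ann$variant_id), , drop = FALSE]
  in_frame_kept <- first$filter == "kept" &
    !is.na(first$frame_status) & first$frame_status == "in_frame" &
    first$status == "coding"
  cohort <- list(
    n_variant_records = nrow(first),
    n_in_frame_kept = sum(in_frame_kept),
    n_modelable = sum(!is.na(first$verdict) &
                        first$verdict != "unassessable"),
    n_tr_context = sum(first$context_label %in% c("TR", "HR+TR")),
    n_hr_context = sum(first$context_label %in% c("HR", "HR+TR")),
    n_tool_agreement = if (!is.null(agreement))
      sum(agreement, na.rm = TRUE) else NA_integer_)

  paths <- list(variants = file.path(cfg$output_dir, "variants.csv"),
                metrics = file.path(cfg$output_dir, "metrics.json"),
                cohort = file.path(cfg$output_dir, "cohort.json"),
                log = file.path(cfg$output_dir, "run.log"))
  utils::write.csv(ann, paths$variants, row.names = FALSE)
  if (!is.null(metrics)) {
    jsonlite::write_json(metrics, paths$metrics, auto_unbox = TRUE,
                         digits = NA, na = "null")
  }
  jsonlite::write_json(cohort, paths$cohort, auto_unbox = TRUE,
                       digits = NA, na = "null")
  writeLines(c(log_lines, sprintf("finished %s", format(Sys.time()))),
             paths$log)
  invisible(list(variants = ann, metrics = metrics, cohort = cohort,
                 paths = paths))
}
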