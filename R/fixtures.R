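# The canonical geometry fixture suite: five ideal structures that
# together exercise every structural context the mechanism rules
# distinguish, with the affected-residue cases and expected verdicts.

#' The five-geometry fixture suite
#'
#' Builds (deterministically) the ideal helix, a two-strand
#' antiparallel sheet, a three-strand single-chain meander sheet, the
#' parallel two-helix dimer and the protein-DNA complex. The suite
#' mirrors the structural contexts of the study's modeled variants:
#' edge strand, central strand, interface helix, DNA-contacting
#' surface loop, loop adjacent to a sheet, and remote surface loop.
#'
#' @return Named list of lists with elements `spec` ([geometry_spec()])
#'   and `pdb` (PDB text).
#' @export
fixture_suite <- function() {
  specs <- list(
    helix = geometry_spec("ideal_helix", n_residues = 20L),
    sheet2 = geometry_spec("beta_sheet", n_residues = 10L,
                           n_strands = 2L),
    meander = geometry_spec("beta_sheet", n_residues = 10L,
                            n_strands = 3L, connect = TRUE),
    coil_dimer = geometry_spec("coiled_coil_dimer", n_residues = 21L),
    protein_dna = geometry_spec("protein_dna_complex", n_residues = 12L))
  lapply(specs, function(sp) list(spec = sp, pdb = build_geometry(sp)))
}

#' Affected-residue cases over the fixture suite
#'
#' One row per mechanism-rule scenario: the fixture to use, the
#' affected chain/residues, the number of residues gained or lost, and
#' the expected verdict. The six scenarios reproduce the verdict
#' pattern of the study's modeled variants (four distinct
#' probably-rules, one unclear, one unlikely).
#'
#' @return Data frame with columns `case`, `fixture`, `chain`,
#'   `resno_start`, `resno_end`, `n_changed`, `expected_category`,
#'   `expected_mechanism`.
#' @export
structure_fixture_cases <- function() {
  data.frame(
    case = c("edge_strand_deletion", "central_strand_deletion",
             "interface_helix_deletion", "dna_salt_bridge_deletion",
             "loop_adjacent_to_strand", "remote_surface_loop"),
    fixture = c("meander", "meander", "coil_dimer", "protein_dna",
                "meander", "protein_dna"),
    chain = "A",
    resno_start = c(5L, 14L, 11L, 6L, 11L, 12L),
    resno_end = c(5L, 20L, 11L, 6L, 11L, 12L),
    n_changed = c(1L, 7L, 1L, 1L, 1L, 1L),
    expected_category = c("probably", "probably", "probably",
                          "probably", "unclear", "unlikely"),
    expected_mechanism = c("beta_sheet_disruption",
                           "beta_sheet_disruption",
                           "helix_register_shift",
                           "binding_site_disruption",
                           "packing_loss", "none"),
    stringsAsFactors = FALSE)
}

#' Run the mechanism rules over the fixture-case suite
#'
#' @param suite Optional pre-built [fixture_suite()].
#' @param th A [structure_thresholds()].
#' @return The [structure_fixture_cases()] table with observed
#'   `category` and `mechanism` columns appended.
#' @export
run_fixture_cases <- function(suite = fixture_suite(),
                              th = structure_thresholds()) {
  cases <- structure_fixture_cases()
  anns <- lapply(suite, function(f) {
    annotate_structure(parse_structure(f$pdb), th)
  })
  cases$category <- NA_character_
  cases$mechanism <- NA_character_
  for (i in seq_len(nrow(cases))) {
    ann <- anns[[cases$fixture[i]]]
    v <- classify_mechanism(
      ann,
      data.frame(chain = cases$chain[i],
                 resno = cases$resno_start[i]:cases$resno_end[i]),
      cases$n_changed[i], th)
    cases$category[i] <- v$category
    cases$mechanism[i] <- paste(v$mechanisms, collapse = ",")
  }
  cases
}

# Deterministic codon per amino acid (reverse translation for
# structure-linked synthetic genes).
CODON_OF <- c(A = "GCT", R = "CGT", N = "AAT", D = "GAT", C = "TGT",
              Q = "CAA", E = "GAA", G = "GGT", H = "CAT", I = "ATT",
              L = "CTG", K = "AAG", M = "ATG", F = "TTT", P = "CCT",
              S = "TCT", T = "ACT", W = "TGG", Y = "TAT", V = "GTT")

#' Generate a structure-linked mini-cohort
#'
#' Builds synthetic single-exon genes whose proteins are exactly the
#' chain-A sequences of the geometry fixtures (plus the initiator
#' methionine), plants one in-frame deletion per fixture case at the
#' corresponding codons, and writes genome, transcripts, VCF, template
#' library (FASTA + PDB files) and per-variant tool/clinical tables.
#' This is the end-to-end pipeline fixture: every planted variant maps
#' back onto the structure it came from, so the verdict distribution
#' is known in advance.
#'
#' @param seed Integer seed (drives only the intergenic sequence).
#' @param dir Output directory; created if needed.
#' @return List with `paths`, `truth` (planted cases with expected
#'   verdicts) and the in-memory objects.
#' @export
generate_structural_cohort <- function(seed, dir) {
  set.seed(seed)
  suite <- fixture_suite()
  cases <- structure_fixture_cases()
  fixture_names <- unique(cases$fixture)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pdb_dir <- file.path(dir, "templates")
  dir.create(pdb_dir, showWarnings = FALSE)

  genome <- character(0); tx <- list(); lib <- character(0)
  for (i in seq_along(fixture_names)) {
    fx <- fixture_names[i]
    model <- parse_structure(suite[[fx]]$pdb)
    seq1 <- paste(chain_residues(model, "A")$one, collapse = "")
    cds <- paste0("ATG", paste(CODON_OF[strsplit(seq1, "")[[1]]],
                               collapse = ""), "TAA")
    chromosome <- sprintf("chrS%02d", i)
    gene <- toupper(fx)
    flank <- paste(sample(c("A", "C", "G", "T"), 100L, replace = TRUE),
                   collapse = "")
    flank2 <- paste(sample(c("A", "C", "G", "T"), 100L, replace = TRUE),
                    collapse = "")
    genome[chromosome] <- paste0(flank, cds, flank2)
    tx[[gene]] <- transcript_model(
      paste0("TX_", gene), chromosome, "+",
      exons = cbind(101L, 100L + nchar(cds)),
      cds = cbind(101L, 100L + nchar(cds)),
      cds_sequence = cds, gene = gene)
    lib[paste0(gene, "_A")] <- seq1
    writeLines(suite[[fx]]$pdb, file.path(pdb_dir, paste0(gene, ".pdb")))
  }

  truth <- cases
  truth$variant_id <- sprintf("SC%02d", seq_len(nrow(cases)))
  vcf_rows <- character(0)
  for (i in seq_len(nrow(cases))) {
    gene <- toupper(cases$fixture[i])
    t <- tx[[gene]]
    chrom <- genome[[t$chromosome]]
    # protein residue = structure residue + 1 (initiator Met)
    res_a <- cases$resno_start[i] + 1L
    res_b <- cases$resno_end[i] + 1L
    cds_a <- 3L * (res_a - 1L) + 1L
    cds_b <- 3L * res_b
    g <- cds_span_to_genomic(t, cds_a, cds_b)
    anchor <- min(g) - 1L
    ref <- substr(chrom, anchor, max(g))
    alt <- substr(chrom, anchor, anchor)
    truth$chromosome[i] <- t$chromosome
    truth$position[i] <- anchor
    truth$ref[i] <- ref; truth$alt[i] <- alt
    truth$gene[i] <- gene
    vcf_rows <- c(vcf_rows, sprintf(
      "%s\t%d\t%s\t%s\t%s\t60\tPASS\t.\tGT:AD:DP\t0/1:60,40:100",
      t$chromosome, anchor, truth$variant_id[i], ref, alt))
  }
  vcf_lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    sprintf("##contig=<ID=%s,length=%d>", names(genome), nchar(genome)),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tCOHORT",
    vcf_rows)

  tool_calls <- data.frame(
    variant_id = truth$variant_id,
    # the DNA-contact case mirrors the one three-tool disagreement
    ddig_in = ifelse(truth$case == "dna_salt_bridge_deletion", "N", "D"),
    sift_indel = "D",
    provean = "D",
    stringsAsFactors = FALSE)
  clinical <- data.frame(
    variant_id = truth$variant_id,
    clinical = ifelse(truth$expected_category == "unlikely",
                      "unlikely", "probably"),
    stringsAsFactors = FALSE)

  paths <- list(genome = file.path(dir, "genome.fa"),
                transcripts = file.path(dir, "transcripts.json"),
                vcf = file.path(dir, "cohort.vcf"),
                templates_fasta = file.path(dir, "templates.fa"),
                template_pdb_dir = pdb_dir,
                tool_calls = file.path(dir, "tool_calls.csv"),
                clinical = file.path(dir, "clinical.csv"),
                truth = file.path(dir, "truth.csv"))
  writeLines(c(rbind(paste0(">", names(genome)), unname(genome))),
             paths$genome)
  write_transcripts_json(tx, paths$transcripts)
  writeLines(vcf_lines, paths$vcf)
  writeLines(c(rbind(paste0(">", names(lib)), unname(lib))),
             paths$templates_fasta)
  utils::write.csv(tool_calls, paths$tool_calls, row.names = FALSE)
  utils::write.csv(clinical, paths$clinical, row.names = FALSE)
  utils::write.csv(truth, paths$truth, row.names = FALSE)
  list(paths = paths, truth = truth, genome = genome, transcripts = tx,
       library = lib)
}
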