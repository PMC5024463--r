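test_that("frame classification follows the net length change", {
  toy <- toy_transcript("+")
  # 3-nt deletion inside the CDS (delete GCC at c.4_6; anchor c.3)
  v <- normalize_indel(raw_variant("chrT", 103, "GGCC", "G"), toy$chrom, 1)
  ci <- project_and_classify_frame(v, toy$t)
  expect_equal(ci$status, "coding")
  expect_equal(ci$frame_status, "in_frame")
  expect_equal(ci$net_length_change, -3L)

  # 4-nt deletion is a frameshift
  v4 <- normalize_indel(raw_variant("chrT", 103, "GGCCG", "G"), toy$chrom, 1)
  expect_equal(project_and_classify_frame(v4, toy$t)$frame_status,
               "frameshift")
})

test_that("a 21-nt in-frame deletion affects seven residues", {
  # CDS with distinct codons so the deleted run is unambiguous
  cds <- paste0("ATG", "TCTGCCGATTGGCATAAGGTT", "CGCTACTAA")  # M SADWHKV RY*
  toy <- toy_transcript("+", cds = cds)
  v <- normalize_indel(raw_variant("chrT", 103,
                                   paste0("G", "TCTGCCGATTGGCATAAGGTT"),
                                   "G"),
                       toy$chrom, 1)
  ci <- project_and_classify_frame(v, toy$t)
  expect_equal(ci$frame_status, "in_frame")
  expect_false(ci$out_of_scope)
  expect_equal(ci$n_affected_residues, 7L)
  expect_equal(ci$hgvs_p, "p.(Ser2_Val8del)")

  # 24-nt deletions stay in the table but are flagged out of scope
  v24 <- normalize_indel(
    raw_variant("chrT", 103, paste0("G", "TCTGCCGATTGGCATAAGGTTCGC"), "G"),
    toy$chrom, 1)
  ci24 <- project_and_classify_frame(v24, toy$t)
  expect_true(ci24$out_of_scope)
})

test_that("protein changes are named by the 3'-most convention", {
  cds <- "ATGGCCGCCAAATAA"  # M A A K *
  toy <- toy_transcript("+", cds = cds)
  # delete c.4_6 and the non-codon-aligned c.5_7: both collapse to Ala3del
  for (anchor_ref in list(c(103, "GGCC"), c(104, "GCCG"))) {
    v <- normalize_indel(raw_variant("chrT", as.integer(anchor_ref[1]),
                                     anchor_ref[2], substr(anchor_ref[2], 1, 1)),
                         toy$chrom, 1)
    ci <- project_and_classify_frame(v, toy$t)
    expect_equal(ci$hgvs_p, "p.(Ala3del)")
  }
  cds2 <- "ATGAAAGCCTAA"  # M K A *
  toy2 <- toy_transcript("+", cds = cds2)
  v <- normalize_indel(raw_variant("chrT", 103, "GAAA", "G"), toy2$chrom, 1)
  expect_equal(project_and_classify_frame(v, toy2$t)$hgvs_p, "p.(Lys2del)")
})

test_that("translate-and-diff agrees with direct translation of both alleles", {
  set.seed(77)
  codons <- setdiff(apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                                      c("A","C","G","T")), 1, paste, collapse = ""),
                    c("TAA", "TAG", "TGA"))
  for (rep in 1:60) {
    body <- sample(codons, 20, replace = TRUE)
    cds <- paste0("ATG", paste(body, collapse = ""), "TAA")
    toy <- toy_transcript("+", cds = cds)
    k <- sample(1:3, 1)                       # codons deleted
    start <- sample(5:(nchar(cds) - 3 * k - 4), 1)  # cds coordinate
    gpos <- 100 + start
    ref <- substr(toy$chrom, gpos - 1, gpos + 3 * k - 1)
    v <- normalize_indel(raw_variant("chrT", gpos - 1, ref,
                                     substr(ref, 1, 1)), toy$chrom, 1)
    ci <- project_and_classify_frame(v, toy$t)
    if (ci$status != "coding") next
    # oracle: translate both alleles and compare directly
    wt <- sub("\\*$", "", as.character(Biostrings::translate(
      Biostrings::DNAString(cds))))
    mut_cds <- paste0(substr(cds, 1, start - 1),
                      substr(cds, start + 3 * k, nchar(cds)))
    mut <- sub("\\*$", "", as.character(Biostrings::translate(
      Biostrings::DNAString(mut_cds))))
    # replacing the affected residues of wt by the (possibly empty)
    # inserted residues must reproduce the mutant translation;
    # non-codon-aligned deletions may carry a substitution component
    rs <- ci$affected_residue_start; re <- ci$affected_residue_end
    if (grepl("Ter", ci$hgvs_p)) {
      # junction codon became a stop: the translated mutant truncates
      # to the wt prefix
      expect_equal(sub("\\*.*$", "", mut), substr(wt, 1, rs - 1))
      next
    }
    ins_len <- nchar(mut) - nchar(wt) + (re - rs + 1)
    expect_gte(ins_len, 0)
    ins <- if (ins_len > 0) substr(mut, rs, rs + ins_len - 1) else ""
    expect_equal(paste0(substr(wt, 1, rs - 1), ins,
                        substr(wt, re + 1, nchar(wt))), mut)
    expect_equal(ci$n_affected_residues, re - rs + 1)
    if (ins_len == 0) expect_match(ci$hgvs_p, "del\\)$")
    else expect_match(ci$hgvs_p, "delins")
  }
})

test_that("deletions hitting the initiator or stop codon are typed terminal", {
  toy <- toy_transcript("+")
  v <- normalize_indel(raw_variant("chrT", 101, "ATGG", "A"), toy$chrom, 1)
  ci <- project_and_classify_frame(v, toy$t)
  expect_equal(ci$status, "terminal_codon")
  expect_true(is.na(ci$hgvs_p))
})

test_that("intronic and junction-spanning indels are typed, not forced", {
  toy <- toy_transcript("+", exon_break = 9L)
  # deep intronic 3-nt deletion (intron spans 110..159)
  v <- normalize_indel(raw_variant("chrT", 125, "TTTT", "T"), toy$chrom, 1)
  expect_equal(project_and_classify_frame(v, toy$t)$status, "non_coding")
  # deletion spanning the exon1/intron boundary
  vj <- raw_variant("chrT", 107, substr(toy$chrom, 107, 112),
                    substr(toy$chrom, 107, 107))
  cij <- project_and_classify_frame(normalize_indel(vj, toy$chrom, 1), toy$t)
  expect_equal(cij$status, "junction_spanning")
  expect_true(is.na(cij$hgvs_p))
})

test_that("splice proximity uses a 2-bp window, boundary inclusive", {
  toy <- toy_transcript("+", exon_break = 9L)
  th <- filter_thresholds()
  # exon1 is 101..109; deletion of base 108 starts 1 bp inside the end
  v1 <- normalize_indel(raw_variant("chrT", 107,
                                    substr(toy$chrom, 107, 108),
                                    substr(toy$chrom, 107, 107)),
                        toy$chrom, 1)
  expect_true(flag_splice_proximity(v1 |> project_and_classify_frame(toy$t, th),
                                    toy$t, th))
  # altered base exactly 3 bp from the boundary is outside the window
  v3 <- normalize_indel(raw_variant("chrT", 105,
                                    substr(toy$chrom, 105, 106),
                                    substr(toy$chrom, 105, 105)),
                        toy$chrom, 1)
  expect_false(flag_splice_proximity(v3 |> project_and_classify_frame(toy$t, th),
                                     toy$t, th))
  # a long single-exon transcript far from any boundary
  toy1 <- toy_transcript("+")
  vfar <- normalize_indel(raw_variant("chrT", 105,
                                      substr(toy1$chrom, 105, 106),
                                      substr(toy1$chrom, 105, 105)),
                          toy1$chrom, 1)
  expect_false(flag_splice_proximity(project_and_classify_frame(vfar, toy1$t, th),
                                     toy1$t, th))
})

test_that("minus-strand projection mirrors the plus strand", {
  cds <- "ATGTCTGCCGATTGGCATAAGGTTCGCTACTAA"
  plus <- toy_transcript("+", cds = cds)
  minus <- toy_transcript("-", cds = cds)
  # delete codon 3 (GCC), cds 7..9; on the minus strand that region is
  # at genomic positions (from the right end)
  vp <- normalize_indel(raw_variant("chrT", 106, "TGCC", "T"), plus$chrom, 1)
  cip <- project_and_classify_frame(vp, plus$t)
  # find the genomic bases on the minus chromosome: cds 7..9 maps to
  # genomic (end - 6) .. (end - 8)
  n <- nchar(cds)
  g <- 100 + n - 8  # left-most genomic base of the codon
  ref <- substr(minus$chrom, g - 1, g + 2)
  vm <- normalize_indel(raw_variant("chrT", g - 1, ref, substr(ref, 1, 1)),
                        minus$chrom, 1)
  cim <- project_and_classify_frame(vm, minus$t)
  expect_equal(cim$hgvs_p, cip$hgvs_p)
  expect_equal(cim$frame_status, "in_frame")
})

test_that("filters partition records with first-failing-rule reasons", {
  rec <- data.frame(
    id = 1:6,
    support_fraction = c(4 / 60, 0.1, 0.5, NA, 0.05, 0.6),
    population_af = c(0.0, 0.0, 0.02, NA, 0.02, NA),
    net_length_change = c(-3, -3, -3, -6, -3, -24))
  out <- apply_filters(rec)
  expect_equal(nrow(out$kept) + nrow(out$discarded), nrow(rec))
  expect_equal(out$discarded$id, c(1L, 3L, 5L, 6L))
  # support fails first even when the AF rule would also fire
  expect_equal(out$discarded$reason, c("support", "benign_af",
                                       "support", "size"))
  expect_true(2L %in% out$kept$id)  # support exactly 0.1 is kept
  expect_true(4L %in% out$kept$id)  # missing metrics pass
})

test_that("sample coverage rule is >= 99.5% of target at >= 50x", {
  d <- c(rep(60L, 996), rep(10L, 4))
  expect_equal(assess_sample_coverage(d), "included")
  d2 <- c(rep(60L, 994), rep(10L, 6))
  expect_equal(assess_sample_coverage(d2), "excluded")
  expect_equal(assess_sample_coverage(rep(0L, 100)), "excluded")
  expect_error(assess_sample_coverage(integer(0)), "empty")
})
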