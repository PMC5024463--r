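flank_of <- function(left, core, right = NULL) {
  # build a flank with >= 30 nt on each side of the interesting core
  paste0(strrep("GCT", 12), left, core, right %||% "",
         strrep("AGC", 12))
}

test_that("homopolymer detection requires a run of six identical bases", {
  # ...C AAAAAA G...: deletion of one A from a run of 6
  flank <- paste0(strrep("GCT", 12), "C", "AAAAAA", "G", strrep("AGC", 12))
  pos_run <- 12 * 3 + 2  # first A
  v <- normalize_indel(raw_variant("c", pos_run, "AA", "A"), flank, 1)
  hr <- detect_homopolymer_context(v, flank, 1)
  expect_true(hr$is_homopolymer)
  expect_equal(hr$base, "A")
  expect_equal(hr$run_length, 6L)

  # run of 5 fails
  flank5 <- paste0(strrep("GCT", 12), "C", "AAAAA", "G", strrep("AGC", 12))
  v5 <- normalize_indel(raw_variant("c", pos_run, "AA", "A"), flank5, 1)
  expect_false(detect_homopolymer_context(v5, flank5, 1)$is_homopolymer)

  # insertion of G inside a GGGGGG run
  flankG <- paste0(strrep("ACT", 12), "T", "GGGGGG", "A", strrep("AGC", 12))
  vg <- normalize_indel(raw_variant("c", pos_run + 2, "G", "GG"), flankG, 1)
  hrg <- detect_homopolymer_context(vg, flankG, 1)
  expect_true(hrg$is_homopolymer)
  expect_equal(hrg$base, "G")
})

test_that("tandem repeats need two consecutive copies covering the indel", {
  # ...A CAGCAG T...: deletion of one CAG
  flank <- paste0(strrep("GCT", 11), "A", "CAGCAG", "T", strrep("AGC", 12))
  pos <- 33 + 1
  v <- normalize_indel(raw_variant("c", pos, "ACAG", "A"), flank, 1)
  tr <- detect_tandem_repeat_context(v, flank, 1)
  expect_true(tr$is_tandem_repeat)
  expect_equal(tr$unit, "CAG")
  expect_equal(tr$copy_count, 2L)

  # single copy fails
  flank1 <- paste0(strrep("GCT", 11), "A", "CAGTTT", "T", strrep("AGC", 12))
  v1 <- normalize_indel(raw_variant("c", pos, "ACAG", "A"), flank1, 1)
  expect_false(detect_tandem_repeat_context(v1, flank1, 1)$is_tandem_repeat)

  # the smallest qualifying unit is reported (CAG, not CAGCAG)
  flank4 <- paste0(strrep("GCT", 11), "A", strrep("CAG", 4), "T",
                   strrep("AGC", 12))
  v4 <- normalize_indel(raw_variant("c", pos, "ACAG", "A"), flank4, 1)
  tr4 <- detect_tandem_repeat_context(v4, flank4, 1)
  expect_equal(tr4$unit, "CAG")
  expect_equal(tr4$copy_count, 4L)
})

test_that("every homopolymer context is also a 1-mer tandem repeat", {
  set.seed(5)
  for (rep in 1:40) {
    base <- sample(c("A", "C", "G", "T"), 1)
    run <- strrep(base, sample(6:9, 1))
    lead <- sample(setdiff(c("A", "C", "G", "T"), base), 1)
    flank <- paste0(strrep("GTC", 12), lead, run, lead, strrep("CTG", 12))
    pos <- 36 + 1
    v <- normalize_indel(raw_variant("c", pos, paste0(lead, base), lead),
                         flank, 1)
    hr <- detect_homopolymer_context(v, flank, 1)
    tr <- detect_tandem_repeat_context(v, flank, 1)
    expect_true(hr$is_homopolymer)
    expect_true(tr$is_tandem_repeat)
    expect_equal(tr$unit, base)
    expect_equal(classify_context(hr, tr), "HR+TR")
  }
})

test_that("context labels combine the two flags", {
  hr_t <- list(is_homopolymer = TRUE); hr_f <- list(is_homopolymer = FALSE)
  tr_t <- list(is_tandem_repeat = TRUE); tr_f <- list(is_tandem_repeat = FALSE)
  expect_equal(classify_context(hr_t, tr_t), "HR+TR")
  expect_equal(classify_context(hr_f, tr_t), "TR")
  expect_equal(classify_context(hr_t, tr_f), "HR")
  expect_equal(classify_context(hr_f, tr_f), "other")
})

test_that("tandem-repeat detection agrees with the unit-enumeration oracle", {
  set.seed(31)
  for (rep in 1:150) {
    # half the cases get a planted repeat array near the variant
    mid <- if (rep %% 2 == 0) {
      unit <- random_dna(sample(1:5, 1))
      strrep(unit, sample(2:4, 1))
    } else random_dna(sample(4:10, 1))
    flank <- paste0(random_dna(34), mid, random_dna(34))
    # deletion of 1-4 bases around the middle
    d <- sample(1:4, 1)
    pos <- 34 + sample.int(max(1, nchar(mid) - d), 1) - 1
    if (pos < 31) next
    v <- normalize_indel(raw_variant("c", pos,
                                     substr(flank, pos, pos + d),
                                     substr(flank, pos, pos)), flank, 1)
    got <- detect_tandem_repeat_context(v, flank, 1)
    sp <- indelstruct:::altered_span(v)
    want <- oracle_tr(flank, sp$del_start, sp$del_end,
                      substr(flank, sp$del_start, sp$del_end),
                      nchar(v$alt) - nchar(v$ref), "del")
    expect_equal(got$is_tandem_repeat, want)
  }
})

test_that("detection is invariant under equivalent indel representations", {
  flank <- paste0(strrep("GCT", 11), "A", strrep("CAG", 3), "TTT",
                  strrep("AGC", 11))
  pos <- 33 + 1
  # right-shifted equivalent of deleting one CAG: delete the last AGC..
  right <- raw_variant("c", pos + 3, "GCAG", "G")
  left <- raw_variant("c", pos, "ACAG", "A")
  nr <- normalize_indel(right, flank, 1)
  nl <- normalize_indel(left, flank, 1)
  expect_equal(nr[c("position", "ref", "alt")],
               nl[c("position", "ref", "alt")])
  expect_equal(detect_tandem_repeat_context(nr, flank, 1),
               detect_tandem_repeat_context(nl, flank, 1))
})

test_that("short flanks are rejected", {
  v <- raw_variant("c", 5, "AT", "A")
  expect_error(detect_homopolymer_context(v, "GCATGCATGC", 1), "flank")
  expect_error(detect_tandem_repeat_context(v, "GCATGCATGC", 1), "flank")
})
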