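test_that("three-tool agreement is unanimity on the D/N calls", {
  expect_true(compute_agreement("D", "D", "D"))
  expect_false(compute_agreement("N", "D", "D"))
  expect_true(compute_agreement("N", "N", "N"))
  expect_true(is.na(compute_agreement(NA, "D", "D")))
})

test_that("the packaged table reproduces the reported tool statistics", {
  t1 <- make_table1_fixture()
  expect_equal(nrow(t1), 8L)
  expect_equal(t1$structural[t1$gene == "FSCN2"], "unlikely")
  expect_equal(t1$ddig_in[t1$gene == "PITX2"], "N")

  m <- evaluate_against_clinical(t1)
  get <- function(p, col) m[m$predictor == p, col]
  # the "possibly" case is excluded, leaving 7 records
  expect_true(all(m$n_evaluated == 7L))
  expect_equal(get("ddig_in", "accuracy"), 0.71)
  expect_equal(get("sift_indel", "accuracy"), 0.86)
  expect_equal(get("provean", "accuracy"), 0.86)
  expect_equal(get("sift_indel", "sensitivity"), 1.00)
  expect_equal(get("provean", "sensitivity"), 1.00)
  # structural mapping (unclear -> positive): 6 TP + 1 TN of 7
  expect_equal(get("structural", "TP"), 6L)
  expect_equal(get("structural", "TN"), 1L)
})

test_that("perfect predictors score accuracy 1 and metrics honour NA rules", {
  rec <- data.frame(variant_id = 1:4,
                    ddig_in = c("D", "D", "N", "N"),
                    sift_indel = c("D", "D", "N", "N"),
                    provean = c("D", "D", "N", "N"),
                    structural = c("probably", "unclear", "unlikely",
                                   "unlikely"),
                    clinical = c("probably", "probably", "unlikely",
                                 "unlikely"))
  m <- evaluate_against_clinical(rec)
  expect_true(all(m$accuracy == 1))
  # no clinical negatives -> specificity NA, not 0/0
  rec2 <- rec[rec$clinical == "probably", ]
  m2 <- evaluate_against_clinical(rec2)
  expect_true(all(is.na(m2$specificity)))
  expect_error(evaluate_against_clinical(
    data.frame(variant_id = 1, ddig_in = "D", sift_indel = "D",
               provean = "D", structural = "probably",
               clinical = "possibly")), "no evaluable")
})

test_that("metrics equal a brute-force recount and ignore record order", {
  set.seed(41)
  for (rep in 1:50) {
    n <- sample(5:40, 1)
    rec <- data.frame(
      variant_id = seq_len(n),
      ddig_in = sample(c("D", "N"), n, TRUE),
      sift_indel = sample(c("D", "N"), n, TRUE),
      provean = sample(c("D", "N"), n, TRUE),
      structural = sample(c("probably", "unclear", "unlikely",
                            "unassessable"), n, TRUE),
      clinical = sample(c("probably", "possibly", "unlikely"), n, TRUE,
                        prob = c(0.5, 0.2, 0.3)))
    if (!any(rec$clinical != "possibly")) next
    m <- tryCatch(evaluate_against_clinical(rec), error = function(e) NULL)
    if (is.null(m)) next
    keep <- rec$clinical != "possibly"
    truth <- rec$clinical[keep] == "probably"
    pred <- rec$structural[keep]
    predb <- ifelse(pred %in% c("probably", "unclear"), TRUE,
                    ifelse(pred == "unlikely", FALSE, NA))
    oc <- oracle_confusion(predb, truth)
    row <- m[m$predictor == "structural", ]
    expect_equal(c(TP = row$TP, FP = row$FP, TN = row$TN, FN = row$FN), oc)
    expect_equal(row$TP + row$FP + row$TN + row$FN, row$n_evaluated)
    # permutation invariance
    m_perm <- evaluate_against_clinical(rec[sample.int(n), ])
    expect_equal(m, m_perm)
  }
})

test_that("cohort rates reproduce the headline figures", {
  s <- summarize_cohort(eye_cohort_counts())
  comb <- s[s$group == "combined", ]
  expect_equal(comb$carrier_rate_pct, 16.8)
  expect_equal(comb$reported_per_tested, 37)
  expect_equal(comb$agreement_pct, 61.8)
  expect_equal(comb$modelable_pct, 14.5)

  z <- summarize_cohort(data.frame(
    group = "x", probands_tested = 100, probands_with_indel = 0,
    indels_detected = 10, indels_clinically_reported = 2,
    indels_modelable = 1, tool_agreement_count = 5))
  expect_equal(z$carrier_rate_pct, 0)
  w <- capture_warnings(
    summarize_cohort(data.frame(
      group = "x", probands_tested = 100, probands_with_indel = 5,
      indels_detected = 0, indels_clinically_reported = 0,
      indels_modelable = 0, tool_agreement_count = 0)))
  expect_match(w, "zero denominator", all = FALSE)
  expect_error(summarize_cohort(data.frame(
    group = "x", probands_tested = 10, probands_with_indel = 20,
    indels_detected = 1, indels_clinically_reported = 1,
    indels_modelable = 0, tool_agreement_count = 0)), "exceed")
})

test_that("reporting precision is centralised: 2 dp metrics, 1 dp percents", {
  expect_equal(round_metric(5 / 7), 0.71)
  expect_equal(round_metric(6 / 7), 0.86)
  expect_equal(round_percent(100 * 112 / 667), 16.8)
  expect_equal(round_percent(100 * 34 / 55), 61.8)
  expect_equal(round_percent(100 * 8 / 55), 14.5)
})
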