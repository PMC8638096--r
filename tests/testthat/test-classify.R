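test_that("positive calling applies mutant-read and VAF thresholds cell-wise", {
  cm <- example_five_sample_counts()
  st <- define_positive(cm, positive_rule(min_mutant_reads = 1))
  expect_equal(as.vector(st$status), c("positive", "TBD", "positive", "TBD", "TBD"))

  zero <- count_matrix(cm$keys, matrix(0L, 1, 5), matrix(50L, 1, 5), cm$samples)
  expect_true(all(define_positive(zero)$status == "TBD"))

  one_read <- count_matrix(cm$keys[1, ], matrix(1L), matrix(100L), "s1")
  expect_equal(as.vector(define_positive(one_read, positive_rule(2))$status), "TBD")
  expect_equal(as.vector(define_positive(one_read, positive_rule(1))$status),
               "positive")
  # a 1% VAF positive is vetoed by a 5% minimum VAF
  expect_equal(as.vector(define_positive(
    one_read, positive_rule(1, min_vaf = 0.05))$status), "TBD")
})

test_that("five-sample walkthrough: B negative, D and E unknown, positives untouched", {
  cm <- example_five_sample_counts()
  st <- classify_msn(cm, rule = positive_rule(1), audit = TRUE)
  expect_equal(as.vector(st$status),
               c("positive", "negative", "positive", "unknown", "unknown"))
  aud <- msn_audit(st)
  expect_equal(nrow(aud), 6L)  # 3 TBD x 2 positives
  get_p <- function(s, vs) aud$p_value[aud$sample == s & aud$vs_positive == vs]
  expect_lt(get_p("B", "A"), 0.01)
  expect_lt(get_p("B", "C"), 0.01)
  expect_lt(get_p("D", "A"), 0.05)
  expect_gte(get_p("D", "C"), 0.05)
  expect_gte(get_p("E", "A"), 0.05)
  expect_gte(get_p("E", "C"), 0.05)
})

test_that("two-biopsy example: adaptive and fixed-coverage rules disagree as published", {
  cm <- example_two_biopsy_counts()
  msn <- classify_msn(cm, rule = positive_rule(2))
  umc <- classify_umc(cm, rule = positive_rule(2), cfg = umc_config(20))
  # T790M (high VAF, 15X follow-up): rescued to negative by the adaptive rule
  expect_equal(msn$status["7:55249071:C:T", "biopsy2"], "negative")
  expect_equal(umc$status["7:55249071:C:T", "biopsy2"], "unknown")
  # C797S (5% VAF, 30X follow-up): 20X coverage rule miscalls it negative
  expect_equal(msn$status["7:55249092:T:A", "biopsy2"], "unknown")
  expect_equal(umc$status["7:55249092:T:A", "biopsy2"], "negative")
  expect_true(all(msn$status[, "biopsy1"] == "positive"))
  expect_true(all(umc$status[, "biopsy1"] == "positive"))
})

test_that("coverage baseline applies its inclusive threshold only to zero-mutant cells", {
  keys <- data.frame(chrom = "1", pos = 1:3, ref = "A", alt = "T")
  cm <- count_matrix(keys,
                     mutant = cbind(p = c(5L, 5L, 5L), q = c(0L, 0L, 1L)),
                     total = cbind(p = c(50L, 50L, 50L), q = c(300L, 0L, 500L)))
  st <- classify_umc(cm, cfg = umc_config(300), rule = positive_rule(2))
  # 300X at threshold 300 qualifies (inclusive), zero coverage and a lone
  # mutant read never do
  expect_equal(as.vector(st$status[, "q"]), c("negative", "unknown", "unknown"))
  st2 <- classify_umc(cm, cfg = umc_config(301), rule = positive_rule(2))
  expect_equal(as.vector(st2$status[1, "q"]), "unknown")
})

test_that("zero-coverage cells and mutations without positives fall back to unknown", {
  keys <- data.frame(chrom = "1", pos = 1:2, ref = "A", alt = "T")
  cm <- count_matrix(keys,
                     mutant = cbind(a = c(8L, 0L), b = c(0L, 0L)),
                     total = cbind(a = c(20L, 10L), b = c(0L, 400L)))
  expect_warning(st <- classify_msn(cm, rule = positive_rule(2)),
                 "no positive sample")
  # row 1: b has zero coverage -> p = 1 -> unknown even against a strong positive
  expect_equal(st$status[1, "b"], "unknown")
  # row 2: nothing is positive -> never negative, despite 400X coverage
  expect_equal(as.vector(st$status[2, ]), c("unknown", "unknown"))
})

test_that("sub-threshold mutant reads never become negative under either policy", {
  keys <- data.frame(chrom = "1", pos = 1L, ref = "A", alt = "T")
  # one strong positive, one cell with a single mutant read at huge depth
  cm <- count_matrix(keys, mutant = cbind(a = 40L, b = 1L),
                     total = cbind(a = 80L, b = 1000L))
  rule <- positive_rule(min_mutant_reads = 2)
  st1 <- classify_msn(cm, rule = rule)  # always-unknown policy
  expect_equal(st1$status[1, "b"], "unknown")
  st2 <- classify_msn(cm, rule = rule,
                      cfg = msn_config(subthreshold_policy = "test-observed-counts"))
  # the observed-count test rejects easily here, yet mutant > 0 forbids negative
  expect_equal(st2$status[1, "b"], "unknown")
})

test_that("supplied positive matrices are validated against the counts", {
  cm <- example_five_sample_counts()
  good <- define_positive(cm, positive_rule(1))
  expect_silent(check <- classify_msn(cm, good))
  bad <- status_matrix(cm$keys,
                       matrix(c("positive", "positive", "TBD", "TBD", "TBD"), 1),
                       cm$samples)  # B has zero mutant reads
  expect_error(classify_msn(cm, bad), "zero mutant reads")
  expect_warning(st <- classify_msn(cm, bad, allow_zero_mutant_positive = TRUE),
                 "zero mutant reads")
  expect_equal(st$status[1, "B"], "positive")  # passed through regardless
  # axis mismatch is rejected
  other <- status_matrix(cm$keys, matrix("TBD", 1, 3), c("X", "Y", "Z"))
  expect_error(classify_msn(cm, other), "different mutations or samples")
  # final labels are not a valid positive input
  final <- status_matrix(cm$keys,
                         matrix(c("positive", "negative", "positive",
                                  "unknown", "unknown"), 1), cm$samples)
  expect_error(classify_msn(cm, final), "'positive' and 'TBD'")
})
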