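test_that("present cells draw Poisson mutant reads at half the tumor fraction", {
  sim <- simulate_counts(scenario(0.90, seed = 21))
  present <- sim$truth$present
  m <- sim$counts$mutant[present]
  lambda <- 200 * 0.45
  se <- sqrt(lambda / length(m))
  expect_lt(abs(mean(m) - lambda), 3 * se)
  expect_true(all(sim$counts$mutant[!present] == 0))
  expect_true(all(sim$counts$total >= sim$counts$mutant))
  expect_true(all(sim$counts$total[!present] == 200))

  # degenerate limit: essentially no mutant reads at a vanishing fraction
  tiny <- simulate_counts(scenario(1e-9, seed = 22))
  expect_true(all(tiny$counts$mutant == 0))

  # clonal rows are always present; subclonal presence is per measurement
  expect_true(all(sim$truth$present[sim$truth$clonal, ]))
})

test_that("exact-half presence model places each subclonal mutation in floor(m/2) measurements", {
  sim <- simulate_counts(scenario(0.2, n_measurements = 4,
                                  presence_model = "exact-half", seed = 3))
  sub <- !sim$truth$clonal
  expect_true(all(rowSums(sim$truth$present[sub, ]) == 2))
})

test_that("never-detected mutations are excluded and both matrices stay aligned", {
  keys <- data.frame(chrom = "s", pos = 1:3, ref = "A", alt = "T")
  cm <- count_matrix(keys,
                     mutant = cbind(m1 = c(0L, 1L, 0L), m2 = c(0L, 0L, 2L),
                                    m3 = c(0L, 0L, 0L)),
                     total = matrix(200L, 3, 3))
  tr <- truth_matrix(keys, matrix(c(FALSE, TRUE, TRUE), 3, 3),
                     clonal = c(FALSE, TRUE, TRUE), samples = colnames(cm$mutant))
  kept <- exclude_undetected(cm, tr)
  expect_equal(nrow(kept$counts$mutant), 2L)
  expect_identical(rownames(kept$counts$mutant), rownames(kept$truth$present))
  expect_false("s:1:A:T" %in% rownames(kept$counts$mutant))

  empty <- exclude_undetected(
    count_matrix(keys[0, ], matrix(integer(), 0, 3), matrix(integer(), 0, 3),
                 colnames(cm$mutant)),
    truth_matrix(keys[0, ], matrix(logical(), 0, 3), logical(0),
                 colnames(cm$mutant)))
  expect_equal(dim(empty$counts$mutant), c(0L, 3L))
})

test_that("scoring cross-tabulates calls against truth and sums to one", {
  keys <- data.frame(chrom = "s", pos = 1:2, ref = "A", alt = "T")
  samples <- c("m1", "m2")
  tr <- truth_matrix(keys, cbind(c(TRUE, TRUE), c(TRUE, FALSE)),
                     clonal = c(TRUE, FALSE), samples)
  all_pos <- status_matrix(keys, matrix("positive", 2, 2), samples)
  sc_all <- score_statuses(all_pos, tr)
  expect_equal(sc_all[["tp"]], 0.75)
  expect_equal(sc_all[["fp"]], 0.25)

  mixed <- status_matrix(keys, cbind(c("positive", "negative"),
                                     c("unknown", "negative")), samples)
  sc <- score_statuses(mixed, tr)
  expect_equal(sc[["fn"]], 0.25)  # one negative call on a present cell
  expect_equal(sc[["tn"]], 0.25)
  expect_equal(sc[["unknown"]], 0.25)
  expect_equal(sum(sc), 1, tolerance = 1e-9)
})

test_that("score fractions always sum to one and detected positives are true positives", {
  set.seed(31)
  for (f in c(0.9, 0.05)) {
    sim <- simulate_counts(scenario(f, n_clonal = 40, n_subclonal = 40))
    kept <- exclude_undetected(sim$counts, sim$truth)
    st <- classify_umc(kept$counts, rule = positive_rule(1), cfg = umc_config(50))
    sc <- score_statuses(st, kept$truth)
    expect_equal(sum(sc), 1, tolerance = 1e-9)
    expect_equal(sc[["fp"]], 0)  # no sequencing-error model: absent => 0 reads
  }
})

test_that("fixed 200X coverage makes the coverage baseline all-or-nothing", {
  sim <- simulate_counts(scenario(0.9, seed = 41))
  kept <- exclude_undetected(sim$counts, sim$truth)
  pos <- define_positive(kept$counts, positive_rule(1))
  # threshold at or below the fixed coverage: every non-positive is negative
  st_low <- classify_umc(kept$counts, pos, umc_config(200))
  expect_equal(score_statuses(st_low, kept$truth)[["unknown"]], 0)
  # threshold above it: no negative can ever be called
  st_high <- classify_umc(kept$counts, pos, umc_config(300))
  sc_high <- score_statuses(st_high, kept$truth)
  expect_equal(sc_high[["tn"]], 0)
  expect_equal(sc_high[["fn"]], 0)
})

test_that("unknown share under an out-of-reach coverage floor matches the closed form", {
  # analytic share of retained statuses that are true-absent cells
  expected <- expected_unknown_umc_high_fraction(100, 100, 3, 0.5)
  expect_equal(expected, 0.2, tolerance = 1e-12)
  set.seed(51)
  reps <- 20
  obs <- vapply(seq_len(reps), function(r) {
    sim <- simulate_counts(scenario(0.9))
    kept <- exclude_undetected(sim$counts, sim$truth)
    st <- classify_umc(kept$counts, rule = positive_rule(1), cfg = umc_config(300))
    score_statuses(st, kept$truth)[["unknown"]]
  }, numeric(1))
  se <- stats::sd(obs) / sqrt(reps)
  expect_lt(abs(mean(obs) - expected), 3 * se)
})

test_that("the benchmark table covers the full scenario-by-method grid", {
  res <- run_scenarios(list(scenario(0.9, n_clonal = 20, n_subclonal = 20),
                            scenario(0.05, n_clonal = 20, n_subclonal = 20)),
                       seed = 61)
  expect_equal(nrow(res), 2 * 6 * 5)  # scenarios x grid x categories
  agg <- aggregate(fraction ~ scenario + method + threshold, res, sum)
  expect_true(all(abs(agg$fraction - 1) < 1e-9))
})
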