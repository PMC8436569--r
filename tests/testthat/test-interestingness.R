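test_that("the worked-example rule GT -> AN reproduces all four measures", {
  p <- rule_probabilities("GT", "AN", hbb_db(), "paper")
  expect_equal(lift(p), 3.75)
  expect_equal(bi_lift(p), 12)
  expect_equal(round_half_up(bi_improve(p), 3), 0.183)
  expect_equal(round_half_up(bi_confidence(p), 3), 0.917)
  expect_equal(round_half_up(improve(p), 3), 0.733)
})

test_that("published measure rows reproduce to three decimals", {
  db <- hbb_db()
  row <- function(a, b) {
    p <- rule_probabilities(a, b, db, "paper")
    round_half_up(c(lift(p), bi_lift(p), bi_improve(p), bi_confidence(p)),
                  3)
  }
  expect_equal(row("FG", "L"), c(0.833, 0.769, -0.1, -0.3))
  expect_equal(row("PT", "V"), c(0.833, 0.786, -0.073, -0.273))
  expect_equal(row("GH", "A"), c(1, 1, 0, 0))
  expect_equal(row("AN", "GK"), c(3, 11, 0.242, 0.909))
  expect_equal(row("GS", "FL"), c(3, 6, 0.167, 0.833))
})

test_that("usefulness is the conjunction of four strict criteria", {
  expect_identical(classify_rules(3.75, 12, 0.183, 0.917), "useful")
  # exact independence is redundant
  expect_identical(classify_rules(1, 1, 0, 0), "redundant")
  # any undefined component fails its clause
  expect_identical(classify_rules(NA, 2, 0.1, 0.1), "redundant")
  expect_identical(classify_rules(2, NA, 0.1, 0.1), "redundant")
  # infinite bi-lift passes the > 1 clause
  expect_identical(classify_rules(2, Inf, 0.1, 0.1), "useful")
  # vectorized
  expect_identical(classify_rules(c(2, 0.9), c(2, 2), c(0.1, 0.1),
                                  c(0.1, 0.1)),
                   c("useful", "redundant"))
})

test_that("hemoglobin beta strong rules split 59 useful / 36 redundant", {
  db <- hbb_db()
  rules <- rule_confidence(enumerate_rules(apriori(db, 3, "paper")),
                           db, "paper")
  metrics <- rule_metrics(filter_strong(rules, 0.9)$accepted, db, "paper")
  expect_identical(sum(metrics$verdict == "useful"), 59L)
  expect_identical(sum(metrics$verdict == "redundant"), 36L)
  # the three published all-redundant singleton-consequent rows
  gh <- metrics[metrics$antecedent == "GH" & metrics$consequent == "A", ]
  expect_identical(gh$verdict, "redundant")
})

test_that("set-mode measures match the 2x2 contingency-table oracle", {
  for (db in random_dbs(3L)) {
    fit <- apriori(db, minsup = 2, mode = "set")
    rules <- enumerate_rules(fit)
    if (nrow(rules) == 0L) next
    take <- seq_len(min(40L, nrow(rules)))
    for (i in take) {
      p <- rule_probabilities(rules$antecedent[i], rules$consequent[i],
                              db, "set")
      o <- oracle_metrics_2x2(rules$antecedent[i], rules$consequent[i],
                              db)
      expect_equal(lift(p), o$lift)
      expect_equal(improve(p), o$improve)
      expect_equal(bi_lift(p), o$bi_lift)
      expect_equal(bi_improve(p), o$bi_improve)
      expect_equal(bi_confidence(p), o$bi_confidence)
    }
  }
})

test_that("lift, bi-improve and bi-confidence are sign-coherent", {
  for (db in random_dbs(3L)) {
    for (mode in c("paper", "set")) {
      fit <- apriori(db, minsup = 2, mode = mode)
      rules <- enumerate_rules(fit)
      for (i in seq_len(min(40L, nrow(rules)))) {
        p <- rule_probabilities(rules$antecedent[i], rules$consequent[i],
                                db, mode)
        delta <- p$p_ab - p$p_a * p$p_b
        bi <- bi_improve(p)
        bc <- bi_confidence(p)
        if (!is.na(bi)) expect_identical(sign(bi), sign(delta))
        if (!is.na(bc)) expect_identical(sign(bc), sign(delta))
        l <- lift(p)
        if (!is.na(l)) expect_identical(l > 1, delta > 0)
      }
    }
  }
})

test_that("set-mode bi-confidence stays within [-1, 1]", {
  for (db in random_dbs(4L)) {
    fit <- apriori(db, minsup = 2, mode = "set")
    rules <- enumerate_rules(fit)
    metrics <- rule_metrics(rules, db, "set")
    bc <- metrics$bi_confidence[!is.na(metrics$bi_confidence)]
    # bound holds exactly in rational arithmetic; allow a float ulp
    expect_true(all(bc >= -1 - 1e-9 & bc <= 1 + 1e-9))
  }
})

test_that("an exactly independent pair scores at the independence limit", {
  # four 2-residue windows {A,C},{A,D},{C,E},{D,E}:
  # P(A)=P(C)=1/2, P(AC)=1/4 = P(A)P(C)
  db <- partition_windows(protein_seq("indep", "ACADCEDE"),
                          window_len = 2)
  p <- rule_probabilities("A", "C", db, "set")
  expect_identical(lift(p), 1)
  expect_identical(bi_lift(p), 1)
  expect_identical(improve(p), 0)
  expect_identical(bi_improve(p), 0)
  expect_identical(bi_confidence(p), 0)
  expect_identical(classify_rules(lift(p), bi_lift(p), bi_improve(p),
                                  bi_confidence(p)), "redundant")
})

test_that("degenerate antecedents yield undefined markers, never errors", {
  # A present in every window: complement probabilities vanish
  db <- partition_windows(protein_seq("allA", "ACAD"), window_len = 2)
  p <- rule_probabilities("A", "C", db, "set")
  expect_identical(p$p_not_a, 0)
  expect_true(is.na(bi_lift(p)))
  expect_true(is.na(bi_improve(p)))
  expect_true(is.na(bi_confidence(p)))
  expect_identical(classify_rules(lift(p), bi_lift(p), bi_improve(p),
                                  bi_confidence(p)), "redundant")
  # B never occurring without A: bi-lift is +Inf and passes its clause
  db2 <- partition_windows(protein_seq("sub", "ACADEF"), window_len = 2)
  p2 <- rule_probabilities("A", "C", db2, "set")
  expect_identical(p2$p_nota_b, 0)
  expect_identical(bi_lift(p2), Inf)
  # overlap is rejected
  expect_error(rule_probabilities("AG", "GK", db, "set"),
               class = "aarules_validation_error")
})
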