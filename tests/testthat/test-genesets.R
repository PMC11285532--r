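# overlap statistics: hypergeometric, Fisher, BH, enrichment tables

test_that("hypergeometric upper tail matches direct enumeration", {
  expect_equal(hypergeom_upper(0, 5, 5, 20), 1)
  expect_equal(hypergeom_upper(6, 6, 7, 20),
               hyper_tail_oracle(6, 6, 7, 20))
  expect_equal(hypergeom_upper(4, 6, 7, 20),
               hyper_tail_oracle(4, 6, 7, 20), tolerance = 1e-12)
  # overlap forced when query = target = background
  expect_equal(hypergeom_upper(8, 8, 8, 8), 1)
  expect_error(hypergeom_upper(5, 4, 6, 20), "exceeds")
})

test_that("hypergeometric agrees with enumeration over a margin sweep", {
  for (N in c(3, 7, 12)) {
    for (q in 0:N) {
      for (t in 0:N) {
        for (k in max(0, q + t - N):min(q, t)) {
          expect_equal(hypergeom_upper(k, q, t, N),
                       hyper_tail_oracle(k, q, t, N), tolerance = 1e-10)
        }
      }
    }
  }
})

test_that("one-sided Fisher equals the hypergeometric tail on shared margins", {
  cases <- list(c(3, 10, 8, 30), c(0, 5, 5, 25), c(4, 6, 7, 20),
                c(2, 12, 3, 15))
  for (cs in cases) {
    expect_equal(fisher_overlap(cs[1], cs[2], cs[3], cs[4]),
                 hypergeom_upper(cs[1], cs[2], cs[3], cs[4]),
                 tolerance = 1e-9)
  }
  expect_equal(fisher_overlap(0, 5, 5, 25), 1)
  expect_error(fisher_overlap(0, 5, 5, 8), "negative cell")
})

test_that("BH adjustment follows the step-up construction", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_adjust(numeric(0)), numeric(0))
  # permutation invariance after realignment
  p <- c(0.4, 0.001, 0.02, 0.9, 0.07)
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
})

test_that("enrichment tables respect margins, score and planted signal", {
  bg <- sprintf("G%03d", 1:100)
  target <- bg[1:10]
  query_hit <- c(bg[1:5], bg[51:55])
  et <- enrich_table(list(hit = query_hit, self = target),
                     list(path = target), bg)
  row <- et[et$query == "hit", ]
  expect_equal(row$k, 5L)
  expect_equal(row$p_value, hyper_tail_oracle(5, 10, 10, 100),
               tolerance = 1e-10)
  expect_equal(row$score, -log10(row$adj_p))
  expect_equal(row$proportion, 0.5)
  # query = target attains the minimal attainable p for those margins
  self <- et[et$query == "self", ]
  expect_equal(self$k, 10L)
  expect_equal(self$p_value, hyper_tail_oracle(10, 10, 10, 100))
  # enrichment score is monotone decreasing in adjusted p
  expect_true(all(diff(et$score[order(et$adj_p)]) <= 1e-12))
  # query genes outside the background are dropped with a message
  expect_message(enrich_table(list(q = c(target, "NOT_THERE")),
                              list(path = target), bg), "outside")
})

test_that("independent random sets stay at the null calibration rate", {
  set.seed(77)
  bg <- sprintf("G%04d", 1:400)
  hits <- 0L
  n_tests <- 0L
  for (r in 1:200) {
    q <- sample(bg, 25)
    t <- sample(bg, 30)
    p <- hypergeom_upper(length(intersect(q, t)), 25, 30, 400)
    hits <- hits + (p < 0.05)
    n_tests <- n_tests + 1L
  }
  # hypergeometric tail is discrete and conservative at the nominal level
  expect_lte(hits / n_tests, 0.05 + 2 * sqrt(0.05 * 0.95 / n_tests))
})

test_that("ORA degenerate cases behave", {
  bg <- sprintf("G%03d", 1:100)
  et <- ora_pathways(bg[1:5], list(disjoint = bg[50:59]), bg)
  expect_equal(et$p_value, 1)
  # query = background: overlap is proportional, no enrichment signal
  et2 <- ora_pathways(bg, list(path = bg[1:10]), bg)
  expect_equal(et2$p_value, 1)
  # toy vs enumeration
  et3 <- ora_pathways(bg[1:5], list(path = c(bg[1:3], bg[11:17])), bg)
  expect_equal(et3$p_value, hyper_tail_oracle(3, 5, 10, 100),
               tolerance = 1e-10)
})

test_that("per-type chi-squared matches the hand formula", {
  counts <- rbind(A = c(30, 10), B = c(10, 30))
  res <- chisq_proportions(counts)
  o <- c(30, 10, 10, 30)
  e <- c(40 * 40, 40 * 40, 40 * 40, 40 * 40) / 80
  stat_hand <- sum((o - e)^2 / e)
  expect_equal(res$statistic[res$cell_type == "A"], stat_hand)
  # identical compositions: statistic 0, p 1
  same <- rbind(A = c(20, 20), B = c(5, 5))
  res0 <- chisq_proportions(same)
  expect_equal(res0$statistic, c(0, 0))
  expect_equal(res0$p_value, c(1, 1))
  # doubling all counts quadruples... scales the statistic, decreasing p
  res2 <- chisq_proportions(counts * 2)
  expect_gt(res2$statistic[1], res$statistic[1])
  expect_lt(res2$p_value[1], res$p_value[1])
  expect_error(chisq_proportions(rbind(A = c(0, 0), B = c(1, 1))),
               "zero margin")
})

test_that("Pearson test matches the textbook formula", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_test(x, 2 * x + 1)$r, 1)
  y <- c(2.1, 0.4, 3.3, 1.0, 2.2)
  res <- pearson_test(x, y)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t_hand <- r_hand * sqrt(3 / (1 - r_hand^2))
  expect_equal(res$r, r_hand, tolerance = 1e-12)
  expect_equal(res$p_value, 2 * pt(-abs(t_hand), 3), tolerance = 1e-12)
  flipped <- pearson_test(x, -y)
  expect_equal(flipped$r, -res$r)
  expect_equal(flipped$p_value, res$p_value)
  expect_error(pearson_test(x, rep(1, 5)), "zero variance")
})

test_that("proportion reporting uses half-up rounding at fixed precision", {
  expect_equal(proportion_report(28, 285), 9.8)
  expect_equal(proportion_report(17, 38), 44.7)
  expect_equal(proportion_report(17, 38, digits = 0), 45)
  expect_equal(proportion_report(0, 10), 0)
  expect_equal(proportion_report(1, 16, digits = 0), 6)  # 6.25 rounds down
  expect_equal(proportion_report(1, 8, digits = 1), 12.5)
  expect_error(proportion_report(5, 0), "positive")
  expect_error(proportion_report(6, 5), "numerator")
})
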