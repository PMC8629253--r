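# The three published contingency tables (student sample, two adult
# samples) drive most expectations here; their agreement measures were
# recomputed by hand from the cell counts before being frozen.

tabs <- published_contingency_tables()

test_that("fixture tables carry the published cells and totals", {
  expect_equal(unlist(tabs$student[c("A", "B", "C", "D")],
                      use.names = FALSE), c(675, 209, 13, 13000))
  expect_equal(attr(tabs$student, "N"), 13897)
  expect_equal(attr(tabs$adult1, "N"), 5330)
  expect_equal(attr(tabs$adult2, "N"), 3145)
  expect_equal(tabs$adult2$A + tabs$adult2$B + tabs$adult2$C + tabs$adult2$D,
               3145)
})

test_that("McNemar's test reproduces the published statistics", {
  mc_s <- mcnemar_test(tabs$student)
  expect_equal(round(mc_s$chi2), 171)
  expect_lt(mc_s$p_value, .001)
  mc_a1 <- mcnemar_test(tabs$adult1)
  expect_equal(round(mc_a1$chi2), 273)
  mc_a2 <- mcnemar_test(tabs$adult2)
  expect_equal(round(mc_a2$chi2, 2), 0.79)
  expect_equal(round(mc_a2$p_value, 3), 0.374)
})

test_that("McNemar continuity handling matches the defining formulas", {
  t0 <- contingency_table(5, 10, 10, 5)
  expect_equal(mcnemar_test(t0)$chi2, 0)          # |B-C| = 0 under correction
  t1 <- contingency_table(5, 209, 13, 5)
  expect_equal(mcnemar_test(t1, continuity = FALSE)$chi2,
               (209 - 13)^2 / 222)
  t2 <- contingency_table(3, 0, 0, 4)
  expect_equal(mcnemar_test(t2), list(chi2 = 0, p_value = 1, df = 1L))
})

test_that("kappa reproduces the published values and standard errors", {
  k_s <- cohens_kappa(tabs$student)
  expect_equal(round(k_s$kappa, 2), 0.85)
  expect_lt(abs(k_s$se - 0.010), 5e-4)
  k_a1 <- cohens_kappa(tabs$adult1)
  expect_equal(round(k_a1$kappa, 2), 0.71)
  expect_lt(abs(k_a1$se - 0.015), 1e-3)
  # the adult-2 table computes to .92 from its cells (.9248)
  k_a2 <- cohens_kappa(tabs$adult2)
  expect_equal(round(k_a2$kappa, 2), 0.92)
  expect_lt(abs(k_a2$se - 0.009), 1e-3)
})

test_that("the two kappa formulas agree on random tables", {
  set.seed(42)
  for (r in 1:200) {
    cells <- rmultinom(1, sample(50:5000, 1),
                       prob = rgamma(4, 1) + 0.02)[, 1]
    if (any(c(cells[1] + cells[2], cells[3] + cells[4],
              cells[1] + cells[3], cells[2] + cells[4]) == 0)) next
    t <- contingency_table(cells[1], cells[2], cells[3], cells[4])
    k <- cohens_kappa(t)
    expect_equal(k$kappa, (k$p0 - k$pe) / (1 - k$pe), tolerance = 1e-12)
  }
})

test_that("perfect agreement gives kappa 1 and zero disagreement", {
  t <- contingency_table(10, 0, 0, 90)
  expect_equal(cohens_kappa(t)$kappa, 1)
  expect_equal(dis_low(t), 0)
  expect_equal(dis_lit(t), 0)
})

test_that("sensitivity and specificity reproduce the published values", {
  expect_equal(round(sensitivity_pct(tabs$student), 2), 98.11)
  expect_equal(round(specificity_pct(tabs$student), 2), 98.42)
  expect_equal(round(sensitivity_pct(tabs$adult1), 2), 97.68)
  expect_equal(round(specificity_pct(tabs$adult1), 2), 93.70)
  expect_equal(round(sensitivity_pct(tabs$adult2), 2), 94.42)
  expect_equal(round(specificity_pct(tabs$adult2), 2), 98.68)
  expect_equal(sensitivity_pct(contingency_table(5, 3, 0, 10)), 100)
})

test_that("disagreement rates reproduce the published values", {
  expect_equal(round(dis_low(tabs$student), 2), 24.75)
  expect_equal(round(dis_lit(tabs$student), 2), 1.68)
  expect_equal(round(dis_low(tabs$adult1), 2), 40.59)
  expect_equal(round(dis_lit(tabs$adult1), 2), 6.51)
  expect_equal(round(dis_low(tabs$adult2), 2), 11.95)
  expect_equal(round(dis_lit(tabs$adult2), 2), 2.31)
})

test_that("DIS_low exceeds DIS_lit exactly when the low side is smaller", {
  set.seed(7)
  for (r in 1:100) {
    cells <- rmultinom(1, 500, prob = rgamma(4, 1) + 0.05)[, 1] + 1
    t <- contingency_table(cells[1], cells[2], cells[3], cells[4])
    lhs <- dis_low(t) >= dis_lit(t)
    rhs <- (t$A + t$B + t$C) <= (t$B + t$C + t$D)
    expect_equal(lhs, rhs)
  }
})

test_that("contingency() cross-tabulates labels in the documented orientation", {
  cm <- c("low", "low", "literate", "literate", "low", NA)
  bm <- c("low", "literate", "low", "literate", "low", "low")
  t <- contingency(cm, bm)
  expect_equal(unlist(t[c("A", "B", "C", "D")], use.names = FALSE),
               c(2, 1, 1, 1))
  expect_equal(attr(t, "n_excluded"), 1L)
  same <- rep(c("low", "literate"), c(3, 7))
  t2 <- contingency(same, same)
  expect_equal(t2$B + t2$C, 0)
  expect_error(contingency(cm, bm[-1]), "equal length")
})

test_that("integer class labels treat class 1 as the low group", {
  cls <- c(1L, 2L, 3L, 1L)
  bm <- c(TRUE, FALSE, FALSE, FALSE)
  t <- contingency(cls, bm)
  expect_equal(unlist(t[c("A", "B", "C", "D")], use.names = FALSE),
               c(1, 1, 0, 2))
})

test_that("agreement_report bundles every measure with verbal bands", {
  r_s <- agreement_report(tabs$student)
  expect_equal(r_s$kappa_band, "almost perfect")
  expect_true(r_s$mcnemar_significant)
  r_a1 <- agreement_report(tabs$adult1)
  expect_equal(r_a1$kappa_band, "substantial")
  r_a2 <- agreement_report(tabs$adult2)
  expect_false(r_a2$mcnemar_significant)
  all_agree <- agreement_report(contingency_table(50, 0, 0, 450))
  expect_equal(all_agree$dis_low, 0)
  expect_equal(all_agree$dis_lit, 0)
  expect_equal(all_agree$kappa, 1)
  expect_equal(all_agree$kappa_band, "perfect")
})

test_that("degenerate tables raise errors rather than nonsense", {
  expect_error(cohens_kappa(contingency_table(0, 0, 5, 5)), "one label")
  expect_error(sensitivity_pct(contingency_table(0, 5, 0, 5)), "undefined")
  expect_error(dis_low(contingency_table(0, 0, 0, 5)), "undefined")
  expect_error(contingency_table(-1, 0, 0, 5), "non-negative")
})

test_that("exact and simplified kappa standard errors are close here", {
  for (t in tabs) {
    k1 <- cohens_kappa(t, se = "fleiss")
    k2 <- cohens_kappa(t, se = "exact")
    expect_lt(abs(k1$se - k2$se), 0.01)
  }
})
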