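test_that("odds_ratio_ci matches the direct log-OR arithmetic", {
  # null table: OR 1, CI symmetric about 1 on the log scale
  null <- odds_ratio_ci(10, 10, 10, 10)
  expect_equal(null$or, 1)
  expect_equal(log(null$ci_low), -log(null$ci_high))

  # direct arithmetic oracle
  res <- odds_ratio_ci(20, 80, 10, 90)
  se <- sqrt(1 / 20 + 1 / 80 + 1 / 10 + 1 / 90)
  z <- qnorm(0.975)
  expect_equal(res$or, 2.25)
  expect_equal(res$ci_low, exp(log(2.25) - z * se))
  expect_equal(res$ci_high, exp(log(2.25) + z * se))
  expect_equal(round(res$ci_low, 3), 0.994)
  expect_equal(round(res$ci_high, 2), 5.09)

  # swapping rows inverts the odds ratio exactly
  swapped <- odds_ratio_ci(10, 90, 20, 80)
  expect_equal(swapped$or, 1 / res$or)
  expect_equal(swapped$ci_low, 1 / res$ci_high)

  # CI contains the point estimate and widens as alpha decreases
  for (alpha in c(0.1, 0.05, 0.01)) {
    ci <- odds_ratio_ci(20, 80, 10, 90, alpha = alpha)
    expect_lt(ci$ci_low, ci$or)
    expect_gt(ci$ci_high, ci$or)
  }
  w95 <- odds_ratio_ci(20, 80, 10, 90, alpha = 0.05)
  w99 <- odds_ratio_ci(20, 80, 10, 90, alpha = 0.01)
  expect_lt(w95$ci_high - w95$ci_low, w99$ci_high - w99$ci_low)

  expect_error(odds_ratio_ci(0, 10, 10, 10), "continuity")
  cc <- odds_ratio_ci(0, 10, 10, 10, continuity = TRUE)
  expect_equal(cc$or, (0.5 * 10.5) / (10.5 * 10.5))
  expect_error(odds_ratio_ci(-1, 10, 10, 10), "non-negative")
})

test_that("FWER adjustment: Bonferroni and Holm", {
  # the emulated family: p = 0.002 among 22 tests adjusts to 0.044
  expect_equal(fwer_adjust(0.002, m = 22), 0.044)
  # cap at 1
  expect_equal(fwer_adjust(0.1, m = 22), 1)
  # Holm step-down with running maximum
  expect_equal(fwer_adjust(c(0.01, 0.02, 0.03), method = "holm"),
               c(0.03, 0.04, 0.04))
  # order preserved
  expect_equal(fwer_adjust(c(0.03, 0.01, 0.02), method = "holm"),
               c(0.04, 0.03, 0.04))
  expect_error(fwer_adjust(c(0.05, 0)), "0, 1")
  expect_error(fwer_adjust(1.2), "0, 1")
  expect_error(fwer_adjust(c(0.1, 0.2), m = 1), "family size")
})

test_that("FWER properties hold and agree with the reference implementation", {
  set.seed(99)
  for (rep in 1:20) {
    p <- runif(sample(3:25, 1))
    bon <- fwer_adjust(p)
    holm <- fwer_adjust(p, method = "holm")
    expect_true(all(bon >= p) && all(holm >= p))
    expect_true(all(holm <= bon))
    expect_true(all(bon <= 1) && all(holm <= 1))
    expect_equal(bon, p.adjust(p, "bonferroni"))
    expect_equal(holm, p.adjust(p, "holm"))
  }
})

test_that("association tables are processed family-wise with CIs", {
  path <- system.file("extdata", "synthetic_pregnancy_associations.tsv",
                      package = "introscan")
  tab <- read_assoc_table(path)
  expect_equal(nrow(tab), 22L)
  res <- process_assoc_table(tab)
  expect_true(all(!is.na(res$or)))
  expect_true(all(res$ci_low < res$or & res$or < res$ci_high))
  expect_true(all(res$p_adjusted >= res$p))
  hit <- res[res$p == 0.002, ]
  expect_equal(hit$p_adjusted, 0.044)
  expect_lt(hit$or, 1)  # the planted protective signal
  # two families are adjusted independently
  tab2 <- tab
  tab2$group[1:11] <- "familyA"
  res2 <- process_assoc_table(tab2)
  expect_equal(res2$p_adjusted[1], min(1, 11 * tab2$p[1]))
  expect_error(process_assoc_table(tab, family_column = "nope"),
               "not found")
})
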