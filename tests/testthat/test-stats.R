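test_that("pearsonTest matches the closed form on hand examples", {
  x <- c(0.3, 1.1, 2.2, 4.5, 5)
  expect_equal(pearsonTest(x, 2 * x + 1)$r, 1)
  expect_equal(pearsonTest(c(1, 2, 3), c(3, 2, 1))$r, -1)

  res <- pearsonTest(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(res$r, 0.8, tolerance = 1e-12)
  t <- 0.8 * sqrt(2 / (1 - 0.64))
  expect_equal(res$p, 2 * pt(-t, df = 2), tolerance = 1e-12)
  expect_equal(res$n, 4)
})

test_that("pearsonTest agrees with stats::cor.test", {
  withSeed(13, {
    for (i in 1:10) {
      n <- sample(4:40, 1)
      x <- rnorm(n); y <- 0.5 * x + rnorm(n)
      ours <- pearsonTest(x, y)
      ref <- cor.test(x, y)
      expect_equal(ours$r, unname(ref$estimate), tolerance = 1e-12)
      expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
    }
  })
})

test_that("pearsonTest handles affine transforms, NAs and degenerate input", {
  x <- c(1, 2, 4, 8, 9); y <- c(2, 1, 5, 6, 9)
  base <- pearsonTest(x, y)$r
  expect_equal(pearsonTest(3 * x + 5, y)$r, base)
  expect_equal(pearsonTest(-x, y)$r, -base)
  # complete-case deletion per pair
  expect_equal(pearsonTest(c(x, NA), c(y, 1))$n, 5)
  expect_error(pearsonTest(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(pearsonTest(c(1, 2), c(3, 4)), "3 complete")
})

test_that("strength categories follow the half-open |r| bins", {
  expect_identical(strengthCategory(-0.59), "moderate")
  expect_identical(strengthCategory(0.25), "negligible")
  expect_identical(strengthCategory(0.30), "low")       # boundary goes up
  expect_identical(strengthCategory(c(0.5, 0.7, 0.9, 1)),
                   c("moderate", "high", "very_high", "very_high"))
  expect_error(strengthCategory(1.2), "exceed")
})

test_that("networkFlowTable reports per-variable rows with NA fallbacks", {
  co <- generateCohort(syntheticConfig(seed = 17), n = 120)
  rec <- cohortRecords(co)
  rep <- networkFlowTable(rec)
  expect_equal(nrow(rep), 5)
  expect_true(all(c("n", "average", "r_v_ave", "sig_v_min") %in% names(rep)))
  # embedded negative downstream-exponent effect shows a negative r
  jd <- rep[rep$variable == "JE_downstream", ]
  expect_lt(jd$r_v_ave, 0)

  # records without junction exponents give NA rows, others intact
  rec2 <- rec; rec2$je_upstream <- NA_real_; rec2$je_downstream <- NA_real_
  rep2 <- networkFlowTable(rec2)
  expect_true(is.na(rep2$r_v_ave[rep2$variable == "JE_downstream"]))
  expect_false(is.na(rep2$r_v_ave[rep2$variable == "Vessel depths (um)"]))
  expect_output(print(rep), "JE_downstream")
})

test_that("outlier rerun removes exactly the high-exponent records", {
  rec <- data.frame(je_downstream = c(1, 2, 2.5, 3, 3.5, 5, 6),
                    v_ave = c(2.2, 2.0, 2.1, 1.9, 1.8, 0.9, 0.7),
                    v_min = c(1.1, 1.0, 1.2, 0.9, 0.8, 0.3, 0.2))
  out <- outlierRerun(rec, jeThreshold = 4)
  expect_equal(out$n_removed, 2)
  expect_equal(out$v_ave$n, 5)

  # nothing above threshold: identical to the full-sample correlation
  low <- rec[rec$je_downstream <= 4, ]
  out2 <- outlierRerun(low, jeThreshold = 4)
  expect_equal(out2$v_ave$r, pearsonTest(low$je_downstream, low$v_ave)$r)

  # planted leverage points inflate |r|; removal deflates it
  withSeed(5, {
    base <- data.frame(je_downstream = runif(30, 1, 3),
                       v_ave = rnorm(30, 2, 0.3))
  })
  base$v_min <- base$v_ave / 2
  lev <- rbind(base, data.frame(je_downstream = c(6, 6.5),
                                v_ave = c(0.2, 0.1), v_min = c(0.1, 0.05)))
  rFull <- pearsonTest(lev$je_downstream, lev$v_ave)$r
  rSub <- outlierRerun(lev)$v_ave$r
  expect_lte(abs(rSub), abs(rFull))

  expect_error(outlierRerun(data.frame(v_ave = 1)), "je_downstream")
  expect_error(outlierRerun(data.frame(je_downstream = c(1, 2, 5, 6),
                                       v_ave = 1:4, v_min = 1:4)),
               "fewer than 3")
})
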