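test_that("predictParentRadius matches closed-form identities", {
  expect_equal(predictParentRadius(4, 4, 3), 4 * 2^(1 / 3))
  expect_equal(predictParentRadius(3, 4, 2), 5)
  # large exponents approach the widest daughter (within 3% at x = 10)
  expect_equal(predictParentRadius(2, 4, 10), (2^10 + 4^10)^(1 / 10))
  expect_lt(abs(predictParentRadius(2, 4, 10) - 4) / 4, 0.03)
  expect_error(predictParentRadius(3, 4, 0), "exponent")
  expect_error(predictParentRadius(-1, 4, 2), "radii")
})

test_that("predicted radius is monotone in the exponent", {
  x <- seq(0.2, 10, by = 0.2)
  unequal <- predictParentRadius(2, 4, x)
  expect_true(all(diff(unequal) < 0))
  equal <- predictParentRadius(3, 3, x)
  expect_true(all(diff(equal) <= 1e-12))
})

test_that("admissibility check catches missing and non-widest parents", {
  expect_identical(checkFittable(2.5, 2.0, 1.5), "FIT")
  expect_identical(checkFittable(1.5, 2.0, 1.0), "NONFIT_PARENT_NOT_WIDEST")
  expect_identical(checkFittable(2.5, NA, 1.5), "NONFIT_MISSING_RADIUS")
  # equality within measurement precision is not fittable either
  expect_identical(checkFittable(2.005, 2.0, 1.0), "NONFIT_PARENT_NOT_WIDEST")
  expect_error(checkFittable(-2, 1, 1), "positive")
})

test_that("grid search recovers constructed and textbook exponents", {
  expect_equal(fitJunctionExponent(5, 3, 4)$exponent, 2)
  expect_equal(fitJunctionExponent(predictParentRadius(4, 4, 3), 4, 4)$exponent, 3)
  expect_equal(fitJunctionExponent(predictParentRadius(3, 4, 2.5), 3, 4)$exponent,
               2.5)
  fit <- fitJunctionExponent(1.5, 2, 1)
  expect_identical(fit$status, "NONFIT_PARENT_NOT_WIDEST")
  expect_true(is.na(fit$exponent))
})

test_that("fitted exponent is scale invariant", {
  for (s in c(0.1, 3, 42)) {
    base <- fitJunctionExponent(predictParentRadius(2.1, 3.3, 1.7), 2.1, 3.3)
    scaled <- fitJunctionExponent(s * predictParentRadius(2.1, 3.3, 1.7),
                                  s * 2.1, s * 3.3)
    expect_equal(scaled$exponent, base$exponent)
  }
})

test_that("coarse grid minimizer agrees with a 10x finer brute force", {
  withSeed(7, {
    for (i in 1:25) {
      r1 <- runif(1, 1.5, 3); r2 <- r1 * runif(1, 0.7, 1)
      x <- runif(1, 0.5, 6)
      rp <- predictParentRadius(r1, r2, x) * exp(rnorm(1, 0, 0.05))
      if (checkFittable(rp, r1, r2) != "FIT") next
      coarse <- fitJunctionExponent(rp, r1, r2)$exponent
      fine <- fitJunctionExponent(rp, r1, r2,
                                  grid = exponentGrid(step = 0.001))$exponent
      expect_lte(abs(coarse - fine), 0.01 + 1e-9)
    }
  })
})

test_that("fitAll emits per-side records with status bookkeeping", {
  # fixed-exponent generator: every fit recovers 2.2 within one grid step
  g <- generateNetwork(syntheticConfig(seed = 3, treeDepth = 3,
                                       exponentMean = 2.2, exponentSd = 0))
  fits <- fitJunctionExponents(g$network)
  fitted <- fits[fits$status == "FIT", ]
  expect_true(all(abs(fitted$exponent - 2.2) <= 0.01 + 1e-9))
  expect_true(all(fits$side[fits$junction_id %in%
    vesselJunctions(g$network)$junction_id[
      vesselJunctions(g$network)$kind == "BIFURCATION"]] == "UPSTREAM"))

  # a VOI with no downstream junction yields only the upstream record
  seg <- data.frame(id = c("P", "a", "b"), length_um = 50,
                    diameter_um = c(9, 4, 4.4))
  jn <- data.frame(junction_id = "J1", kind = "BIFURCATION",
                   major_id = "P", minor1_id = "a", minor2_id = "b")
  one <- fitJunctionExponents(buildNetwork(seg, jn), voiIds = "a")
  expect_identical(one$side, "UPSTREAM")

  # narrowing one parent plants exactly one non-widest status
  seg$diameter_um[1] <- 4.2
  fits2 <- fitJunctionExponents(buildNetwork(seg, jn), voiIds = c("a", "b"))
  expect_equal(sum(fits2$status == "NONFIT_PARENT_NOT_WIDEST"), 2)  # same junction, both VOIs
  expect_equal(length(unique(fits2$junction_id[
    fits2$status == "NONFIT_PARENT_NOT_WIDEST"])), 1)
})
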