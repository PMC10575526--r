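test_that("minimal tree has one feeder, two daughters, one bifurcation", {
  g <- generateNetwork(syntheticConfig(seed = 1, treeDepth = 1))
  net <- g$network
  jn <- vesselJunctions(net)
  expect_equal(sum(jn$kind == "BIFURCATION"), 1)
  expect_equal(length(identifyFeeders(net)), 1)
})

test_that("minimal tree daughters have branch order 2", {
  g <- generateNetwork(syntheticConfig(seed = 1, treeDepth = 1))
  net <- g$network
  jn <- vesselJunctions(net)
  bif <- jn[jn$kind == "BIFURCATION", ]
  expect_identical(unname(branchOrder(net, c(bif$minor1_id, bif$minor2_id))),
                   c(2L, 2L))
  expect_gt(vesselSegments(net)$diameter_um[
    vesselSegments(net)$id == identifyFeeders(net)], 8)
})

test_that("junction radii satisfy the generalized Murray relation exactly", {
  g <- generateNetwork(syntheticConfig(seed = 9, treeDepth = 3,
                                       exponentMean = 2.5, exponentSd = 0,
                                       unorthodoxFraction = 0.25))
  seg <- vesselSegments(g$network)
  r <- setNames(seg$diameter_um / 2, seg$id)
  jn <- vesselJunctions(g$network)
  resid <- vapply(seq_len(nrow(jn)), function(i)
    r[jn$major_id[i]]^2.5 - (r[jn$minor1_id[i]]^2.5 + r[jn$minor2_id[i]]^2.5),
    numeric(1))
  expect_true(all(abs(resid) < 1e-9))

  # and with drawn exponents the truth table closes the identity too
  g2 <- generateNetwork(syntheticConfig(seed = 10, treeDepth = 3))
  seg2 <- vesselSegments(g2$network)
  r2 <- setNames(seg2$diameter_um / 2, seg2$id)
  jn2 <- vesselJunctions(g2$network)
  x2 <- g2$truth$junctions$exponent[match(jn2$junction_id,
                                          g2$truth$junctions$junction_id)]
  resid2 <- vapply(seq_len(nrow(jn2)), function(i)
    r2[jn2$major_id[i]]^x2[i] -
      (r2[jn2$minor1_id[i]]^x2[i] + r2[jn2$minor2_id[i]]^x2[i]), numeric(1))
  expect_true(all(abs(resid2) < 1e-9))
})

test_that("generators are deterministic in the seed", {
  cfg <- syntheticConfig(seed = 23, treeDepth = 3, unorthodoxFraction = 0.25)
  g1 <- generateNetwork(cfg); g2 <- generateNetwork(cfg)
  expect_identical(vesselSegments(g1$network), vesselSegments(g2$network))
  expect_identical(vesselJunctions(g1$network), vesselJunctions(g2$network))

  v1 <- generateVelocityTraces(g1$network, g1$truth, cfg)
  v2 <- generateVelocityTraces(g2$network, g2$truth, cfg)
  expect_identical(lapply(v1$traces, traceSamples),
                   lapply(v2$traces, traceSamples))

  d1 <- generateDepthStack(g1$network, g1$truth, cfg)
  d2 <- generateDepthStack(g2$network, g2$truth, cfg)
  f1 <- tempfile(fileext = ".tiff"); f2 <- tempfile(fileext = ".tiff")
  writeDepthStack(d1$stack, f1); writeDepthStack(d2$stack, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))

  i1 <- generateDivisionImage(4, 50, 1, 0.5, 0.1, seed = 3)
  i2 <- generateDivisionImage(4, 50, 1, 0.5, 0.1, seed = 3)
  expect_identical(i1@image, i2@image)
})

test_that("trace generation matches acquisition counts and the waveform", {
  cfg <- syntheticConfig(seed = 2, treeDepth = 2, samplingRate = 200,
                         duration = 3)
  g <- generateNetwork(cfg)
  vel <- generateVelocityTraces(g$network, g$truth, cfg)
  expect_true(all(vapply(vel$traces, function(t) length(traceSamples(t)),
                         numeric(1)) == 600))

  # noiseless: summarized pulsatility equals the injected P
  cfg0 <- syntheticConfig(seed = 2, treeDepth = 2, traceNoiseSd = 0)
  vel0 <- generateVelocityTraces(g$network, g$truth, cfg0)
  for (i in c(1, 3, 5)) {
    s <- summarizeTrace(vel0$traces[[i]])
    expect_equal(s@pulsatility, vel0$params$pulsatility[i], tolerance = 1e-3)
    expect_equal(s@vAve, vel0$params$v_ave[i], tolerance = 1e-3)
  }

  # missing feeder distance aborts generation
  broken <- g$truth
  broken$segments$feeder_distance_um[2] <- NA
  expect_error(generateVelocityTraces(g$network, broken, cfg), "missing feeder")
})

test_that("null decay settings leave pulsatility uncorrelated with distance", {
  cfg <- syntheticConfig(seed = 31, treeDepth = 8, pulsatilityDecay = 0,
                         vminSlope = 0, pulsatilityAtFeeder = 0.4)
  g <- generateNetwork(cfg)
  expect_gte(nrow(vesselSegments(g$network)), 500)
  vel <- generateVelocityTraces(g$network, g$truth, cfg)
  P <- vapply(vel$traces, function(t) summarizeTrace(t)@pulsatility, numeric(1))
  d <- g$truth$segments$feeder_distance_um
  expect_lt(abs(pearsonTest(P, d)$r), 0.1)
})

test_that("division images render exact bands and reject bad input", {
  v <- generateDivisionImage(4, lengthPx = 30, pxSize = 1)
  band <- v@image[1, ]
  expect_equal(sum(band == 1), 4)
  expect_true(all(band %in% c(0, 1)))
  expect_true(all(apply(v@image, 1, identical, band)))
  expect_error(generateDivisionImage(0.5, 30, 1), "pixel")
  expect_error(generateDivisionImage(-1, 30, 1), "positive")
})

test_that("invalid configurations are rejected at construction", {
  expect_error(syntheticConfig(treeDepth = 0), "treeDepth")
  expect_error(syntheticConfig(exponentSd = -1), "deviation")
  expect_error(syntheticConfig(depthWeights = c(0.5, 0.4)), "sum to 1")
  expect_error(syntheticConfig(samplingRate = 250), "200 or 300")
  expect_error(syntheticConfig(duration = 3.001), "integer sample")
})
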