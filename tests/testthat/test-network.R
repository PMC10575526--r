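test_that("buildNetwork assembles a junction and keeps isolated segments", {
  seg <- data.frame(id = c("p", "a", "b"), length_um = c(100, 60, 70),
                    diameter_um = c(9, 4.5, 4.2))
  jn <- data.frame(junction_id = "J1", kind = "BIFURCATION",
                   major_id = "p", minor1_id = "a", minor2_id = "b")
  net <- buildNetwork(seg, jn)
  el <- capnet:::.edgeList(net)
  expect_equal(nrow(vesselJunctions(net)), 1)
  expect_equal(sum(el$from == "p"), 2)

  # empty edge table: everything isolated and unclassified
  net0 <- buildNetwork(seg, jn[0, ])
  expect_true(all(classifySegments(net0) == "UNCLASSIFIED"))
})

test_that("buildNetwork rejects malformed input naming the offender", {
  seg <- data.frame(id = c("p", "a", "b"), length_um = 50, diameter_um = 4)
  jn <- data.frame(junction_id = "J1", kind = "BIFURCATION",
                   major_id = "p", minor1_id = "a", minor2_id = "99")
  expect_error(buildNetwork(seg, jn), "99")
  segDup <- rbind(seg, seg[1, ])
  expect_error(buildNetwork(segDup, jn[0, ]), "duplicate")
  jnBad <- data.frame(junction_id = "J1", kind = "BIFURCATION",
                      major_id = "p", minor1_id = "a", minor2_id = "a")
  expect_error(buildNetwork(seg, jnBad), "3 distinct")
})

test_that("validateNetwork flags direction and kind violations", {
  expect_identical(nrow(validateNetwork(diamondNetwork())), 0L)
  g <- generateNetwork(syntheticConfig(seed = 4, treeDepth = 3))
  expect_identical(nrow(validateNetwork(g$network)), 0L)

  # true confluence mislabeled as a bifurcation (J0 anchors the feeder side)
  seg <- data.frame(id = c("F", "P", "Q", "a", "b", "c"), length_um = 50,
                    diameter_um = c(10, 9, 4, 4, 4, 5))
  jn <- data.frame(junction_id = c("J0", "J1", "J2"),
                   kind = c("BIFURCATION", "BIFURCATION", "BIFURCATION"),
                   major_id = c("F", "P", "c"),
                   minor1_id = c("P", "a", "a"),
                   minor2_id = c("Q", "b", "b"))
  rep <- validateNetwork(buildNetwork(seg, jn))
  expect_equal(sum(rep$type == "kind_mismatch"), 1)
  expect_equal(rep$id[rep$type == "kind_mismatch"], "J2")

  # declared feeder that receives flow
  seg2 <- data.frame(id = c("x", "y", "z"), length_um = 50,
                     diameter_um = c(9, 9, 4), is_feeder = c(FALSE, TRUE, FALSE))
  jn2 <- data.frame(junction_id = "J1", kind = "BIFURCATION",
                    major_id = "x", minor1_id = "y", minor2_id = "z")
  rep2 <- validateNetwork(buildNetwork(seg2, jn2))
  expect_equal(sum(rep2$type == "feeder_inflow"), 1)
})

test_that("identifyFeeders needs a wide parentless vessel", {
  net <- diamondNetwork()
  expect_identical(identifyFeeders(net), "P")

  seg <- data.frame(id = c("p", "a", "b"), length_um = 50,
                    diameter_um = c(7.9, 4, 4))
  jn <- data.frame(junction_id = "J1", kind = "BIFURCATION",
                   major_id = "p", minor1_id = "a", minor2_id = "b")
  expect_error(identifyFeeders(buildNetwork(seg, jn)), "feed")

  # two disconnected components, each with its own wide root
  seg2 <- data.frame(id = c("p1", "a1", "b1", "p2", "a2", "b2"),
                     length_um = 50, diameter_um = c(9, 4, 4, 10, 4, 4))
  jn2 <- data.frame(junction_id = c("J1", "J2"), kind = "BIFURCATION",
                    major_id = c("p1", "p2"), minor1_id = c("a1", "a2"),
                    minor2_id = c("b1", "b2"))
  expect_setequal(identifyFeeders(buildNetwork(seg2, jn2)), c("p1", "p2"))
})

test_that("capillary classification follows the end-junction taxonomy", {
  # chain: P -(bif)-> t -(conf)-> v gives a terminal capillary;
  # mirrored order gives the unorthodox type
  seg <- data.frame(id = c("P", "t", "x", "v", "w", "u1", "u2"),
                    length_um = 50, diameter_um = c(9, 4, 4, 6, 5, 4, 4))
  jn <- data.frame(
    junction_id = c("J1", "J2", "J3"),
    kind = c("BIFURCATION", "CONFLUENCE", "BIFURCATION"),
    major_id = c("P", "w", "w"),
    minor1_id = c("t", "t", "u1"),
    minor2_id = c("x", "x", "u2"))
  net <- buildNetwork(seg, jn)
  cls <- classifySegments(net)
  expect_equal(unname(cls["t"]), "TC")   # bifurcation in, confluence out
  expect_equal(unname(cls["w"]), "WC")   # confluence in, bifurcation out
  expect_equal(unname(cls["u1"]), "UNCLASSIFIED")  # downstream end unknown
  expect_error(classifySegment(net, "nope"), "unknown")

  # totality: one label each, counts sum to the segment count
  expect_equal(length(cls), nrow(vesselSegments(net)))
  expect_equal(sum(table(cls)), nrow(vesselSegments(net)))
})

test_that("branch order counts bifurcations from the order-1 feeder", {
  net <- diamondNetwork()
  expect_identical(branchOrder(net, "P"), c(P = 1L))
  expect_identical(unname(branchOrder(net, c("a", "b"))), c(2L, 2L))
  # confluences do not increment the order
  expect_identical(unname(branchOrder(net, "c")), 2L)

  ch <- chainNetwork(8)
  expect_identical(unname(branchOrder(ch$net, ch$tip)), 9L)
  expect_error(branchOrder(diamondNetwork(), "zzz"), "zzz")
})

test_that("feeder distance sums upstream lengths plus half the segment", {
  net <- diamondNetwork()
  expect_equal(unname(feederDistance(net, "P")), 50)     # half its own length
  expect_equal(unname(feederDistance(net, "a")), 100 + 40)

  # chain 100, 50 then a 30 um segment: 100 + 50 + 15
  seg <- data.frame(id = c("P", "m", "x1", "t", "x2"),
                    length_um = c(100, 50, 40, 30, 20),
                    diameter_um = c(9, 5, 4, 4, 4))
  jn <- data.frame(junction_id = c("J1", "J2"), kind = "BIFURCATION",
                   major_id = c("P", "m"), minor1_id = c("m", "t"),
                   minor2_id = c("x1", "x2"))
  expect_equal(unname(feederDistance(buildNetwork(seg, jn), "t")), 165)
})

test_that("multiple upstream paths resolve to the shortest summed length", {
  # diamond: via a = 100 + 80 = 180, via b = 100 + 140 = 240
  net <- diamondNetwork(lenP = 100, lenA = 80, lenB = 140, lenC = 30)
  # brute-force oracle: enumerate both paths
  viaA <- 100 + 80 + 30 / 2
  viaB <- 100 + 140 + 30 / 2
  expect_equal(unname(feederDistance(net, "c")), min(viaA, viaB))

  # additivity across a bifurcation junction
  g <- generateNetwork(syntheticConfig(seed = 2, treeDepth = 3))
  net2 <- g$network
  jn <- vesselJunctions(net2)
  bif <- jn[jn$kind == "BIFURCATION", ][1, ]
  seg <- vesselSegments(net2)
  lenOf <- function(i) seg$length_um[seg$id == i]
  dp <- feederDistance(net2, bif$major_id)
  dc <- feederDistance(net2, bif$minor1_id)
  expect_equal(unname(dc),
               unname(dp) + lenOf(bif$major_id) / 2 + lenOf(bif$minor1_id) / 2)
})

test_that("crossings are stored but never traversed", {
  segc <- data.frame(id = c("P", "a", "b", "q"), length_um = c(100, 80, 140, 10),
                     diameter_um = c(9, 4.5, 4.2, 4))
  jn <- data.frame(junction_id = "J1", kind = "BIFURCATION",
                   major_id = "P", minor1_id = "a", minor2_id = "b")
  cross <- data.frame(seg_a = "q", seg_b = "a")
  net <- buildNetwork(segc, jn, crossings = cross)
  expect_equal(nrow(networkCrossings(net)), 1)
  expect_equal(unname(feederDistance(net, "a")), 140)
  expect_identical(unname(branchOrder(net, "a")), 2L)
  expect_error(branchOrder(net, "q"), "reachable")  # crossing adds no path
})

test_that("derived topology equals generator ground truth exactly", {
  g <- generateNetwork(syntheticConfig(seed = 11, treeDepth = 4,
                                       unorthodoxFraction = 0.25))
  topo <- topologyTable(g$network)
  tr <- g$truth$segments[match(topo$id, g$truth$segments$id), ]
  expect_identical(topo$branch_order, tr$branch_order)
  expect_equal(topo$feeder_distance_um, tr$feeder_distance_um)
})
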