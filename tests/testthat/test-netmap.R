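mkSession <- function(ids, regions = "VRC") {
  newSession(mapply(function(id, rg)
    spikeTrain(id, sort(runif(20, 0, 10)), c(0, 10), rg),
    ids, rep(regions, length.out = length(ids)), SIMPLIFY = FALSE))
}

mkEdge <- function(source, target, sign, position) {
  data.frame(source = source, target = target, sign = sign,
             position = position, extremum_lag_s = 0.002, di = 5,
             p_mc = 0.001, q_value = 0.01, significant = TRUE,
             stringsAsFactors = FALSE)
}

test_that("edge typing follows the offset/central peak/trough rules", {
  withr::local_seed(1)
  ses <- mkSession(c("V1", "V4", "P1"))
  map <- buildFeatureMap(ses, NULL, rbind(
    mkEdge("V1", "V4", "inhibition", "offset"),
    mkEdge("V1", "P1", "shared_drive", "central")))
  ed <- mapEdges(map)
  expect_true(ed$directed[ed$sign == "inhibition"])
  expect_false(ed$directed[ed$sign == "shared_drive"])
  # empty edge list: nodes only
  empty <- buildFeatureMap(ses, NULL)
  expect_equal(nrow(mapNodes(empty)), 3)
  expect_equal(nrow(mapEdges(empty)), 0)
  expect_error(buildFeatureMap(ses, NULL, mkEdge("V1", "ZZ",
                                                 "excitation", "offset")),
               "unknown neuron")
})

test_that("connectivity summaries count nodes, signs and motifs", {
  withr::local_seed(2)
  ids <- sprintf("n%02d", 1:20)
  ses <- mkSession(ids, c(rep("VRC", 10), rep("raphe", 5), rep("pons", 5)))
  edges <- rbind(mkEdge("n01", "n02", "inhibition", "offset"),
                 mkEdge("n02", "n03", "inhibition", "offset"),
                 mkEdge("n04", "n05", "excitation", "offset"),
                 mkEdge("n06", "n07", "shared_drive", "central"),
                 mkEdge("n08", "n09", "excitation", "offset"),
                 mkEdge("n09", "n10", "excitation", "offset"))
  map <- buildFeatureMap(ses, NULL, edges)
  s <- summarizeConnectivity(map)
  all <- s$groups[s$groups$group == "all", ]
  expect_equal(all$n_recorded, 20)
  expect_equal(all$n_connected, 10)
  expect_equal(all$fraction, 0.5)
  expect_equal(unname(s$edge_counts[["inhibition"]]), 2)
  # one A -| B -| C chain
  expect_equal(s$disinhibition_motifs, 1)
  # permutation invariance of totals
  map2 <- buildFeatureMap(
    newSession(rev(sessionTrains(ses))), NULL, edges)
  s2 <- summarizeConnectivity(map2)
  expect_equal(s2$groups[s2$groups$group == "all", -1],
               all[, -1])
  expect_equal(s2$disinhibition_motifs, s$disinhibition_motifs)
})

test_that("the rate heat map is row-normalized and scale invariant", {
  tr1 <- spikeTrain("a", c(5.1, 5.2, 5.3), c(0, 10))     # one active bin
  tr2 <- poissonTrain("b", 20, 10, seed = 3)
  M <- rateHeatmapMatrix(list(tr1, tr2), bin_width = 1)
  expect_equal(unname(M["a", ]), c(0, 0, 0, 0, 0, 1, 0, 0, 0, 0))
  expect_equal(max(M["b", ]), 1)
  expect_gt(min(M["b", ]), 0.2)               # roughly constant rate
  # silent neuron: all-zero row
  M0 <- rateHeatmapMatrix(list(spikeTrain("s", numeric(0), c(0, 10))), 1)
  expect_true(all(M0 == 0))
  # uniform time dilation leaves the normalized row unchanged
  tr3 <- spikeTrain("c", spikeTimes(tr2) * 2, c(0, 20))
  M2 <- rateHeatmapMatrix(list(tr3), bin_width = 2)
  expect_equal(unname(M2["c", ]), unname(M["b", ]))
})

test_that("GraphML export/import round-trips nodes, edges and attributes", {
  withr::local_seed(4)
  ses <- mkSession(c("V1", "V2", "R1"), c("VRC", "VRC", "raphe"))
  classes <- data.frame(neuron_id = c("V1", "V2", "R1"),
                        modulation = c("I", "E", "NRM"),
                        subtype = c("Aug", "Dec", "other"),
                        tonicity = c("phasic", "tonic", "tonic"),
                        stringsAsFactors = FALSE)
  map <- buildFeatureMap(ses, classes, rbind(
    mkEdge("V1", "V2", "excitation", "offset"),
    mkEdge("V1", "R1", "shared_opposite", "central")))
  p <- file.path(withr::local_tempdir(), "map.graphml")
  exportFeatureMap(map, p)
  back <- importFeatureMap(p)
  expect_equal(mapNodes(back), mapNodes(map))
  expect_equal(mapEdges(back)[order(mapEdges(back)$target), ],
               mapEdges(map)[order(mapEdges(map)$target), ],
               ignore_attr = TRUE)
  # DOT export produces a file
  pd <- sub("graphml$", "dot", p)
  exportFeatureMap(map, pd)
  expect_gt(file.size(pd), 0)
})
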