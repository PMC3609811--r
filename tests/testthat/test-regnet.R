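mkDe <- function(ids, dir = "up") {
  data.frame(gene_id = ids, p_value = 0.01, direction = dir,
             stringsAsFactors = FALSE)
}

test_that("network assembly counts nodes and edges correctly", {
  matches <- data.frame(motif_id = c("M1", "M2"), tf = c("TFA", "TFB"),
                        stringsAsFactors = FALSE)
  inst <- data.frame(gene_id = c("g1", "g2", "g3"),
                     stringsAsFactors = FALSE)
  net <- assembleNetwork(matches, list(M1 = inst, M2 = inst),
                         mkDe(c("g1", "g2", "g3")))
  expect_equal(nrow(netNodes(net)), 5L)
  expect_equal(nrow(netEdges(net)), 6L)
  expect_setequal(netNodes(net)$role[netNodes(net)$id %in%
                                     c("TFA", "TFB")], "TF")
  expect_true(all(netNodes(net)$regulation[netNodes(net)$role ==
                                           "target"] == "up"))
  expect_error(assembleNetwork(matches, list(M1 = inst, M2 = inst),
                               mkDe(c("g1", "g2"))), "g3")
})

test_that("an empty match table gives an empty network", {
  net <- assembleNetwork(data.frame(motif_id = character(),
                                    tf = character()),
                         list(), mkDe("g1"))
  expect_equal(nrow(netNodes(net)), 0L)
  expect_equal(nrow(netEdges(net)), 0L)
})

test_that("a directed ring has exactly uniform PageRank", {
  n <- 7
  ids <- paste0("n", 1:n)
  edges <- data.frame(tf = ids, target = ids[c(2:n, 1)],
                      stringsAsFactors = FALSE)
  nodes <- data.frame(id = ids, role = "target",
                      regulation = NA_character_, stringsAsFactors = FALSE)
  pr <- pageRank(RegNetwork(nodes, edges))
  expect_equal(unname(pr), rep(1 / n, n), tolerance = 1e-9)
  expect_equal(sum(pr), 1, tolerance = 1e-10)
})

test_that("the two-node chain matches the closed-form dense solution", {
  nodes <- data.frame(id = c("A", "B"), role = c("TF", "target"),
                      regulation = c(NA, "up"), stringsAsFactors = FALSE)
  edges <- data.frame(tf = "A", target = "B", stringsAsFactors = FALSE)
  pr <- pageRank(RegNetwork(nodes, edges))
  oracle <- densePageRank(c("A", "B"), edges, 0.85)
  expect_equal(pr[order(names(pr))], oracle[order(names(oracle))],
               tolerance = 1e-8)
})

test_that("power iteration matches the dense solve on random digraphs", {
  for (s in 1:20) {
    net <- randomNetwork(sample(3:30, 1), runif(1, 0.05, 0.3), seed = s)
    pr <- pageRank(net)
    oracle <- densePageRank(netNodes(net)$id, as.data.frame(netEdges(net)))
    expect_equal(pr, oracle[names(pr)], tolerance = 1e-8)
    expect_equal(sum(pr), 1, tolerance = 1e-10)
    expect_true(all(pr > 0))
  }
})

test_that("PageRank agrees with an independent graph library", {
  skip_if_not_installed("igraph")
  net <- randomNetwork(25, 0.15, seed = 99)
  pr <- pageRank(net)
  g <- igraph::graph_from_data_frame(
    as.data.frame(netEdges(net)), directed = TRUE,
    vertices = netNodes(net)$id)
  ref <- igraph::page_rank(g, damping = 0.85)$vector
  expect_equal(pr[names(ref)], ref, tolerance = 1e-6)
})

test_that("scores are independent of node insertion order", {
  net <- randomNetwork(12, 0.2, seed = 5)
  nodes <- as.data.frame(netNodes(net))
  edges <- as.data.frame(netEdges(net))
  shuffled <- RegNetwork(nodes[rev(seq_len(nrow(nodes))), ], edges)
  pr1 <- pageRank(net); pr2 <- pageRank(shuffled)
  expect_equal(pr1[sort(names(pr1))], pr2[sort(names(pr2))],
               tolerance = 1e-12)
})

test_that("core-gene reporting ranks the hub first with its TFs listed", {
  ids <- c("hub", paste0("leaf", 1:5))
  edges <- data.frame(tf = paste0("leaf", 1:5), target = "hub",
                      stringsAsFactors = FALSE)
  nodes <- data.frame(id = ids, role = c("target", rep("TF", 5)),
                      regulation = c("up", rep(NA, 5)),
                      stringsAsFactors = FALSE)
  net <- RegNetwork(nodes, edges)
  pr <- pageRank(net)
  top <- topCoreGenes(pr, net, n = 10)
  expect_equal(top$gene[1], "hub")
  expect_equal(top$transcription_factor[1],
               paste(paste0("leaf", 1:5), collapse = ", "))
  expect_equal(names(top), c("gene", "transcription_factor", "pagerank"))
  expect_equal(nrow(top), 1L)   # only target-role nodes reported
  topAll <- topCoreGenes(pr, net, n = 100, includeTfs = TRUE)
  expect_equal(nrow(topAll), 6L)
})

test_that("SIF export round-trips the edge set and node attributes", {
  net <- randomNetwork(10, 0.2, seed = 3)
  pr <- pageRank(net)
  sif <- tempfile(fileext = ".sif"); nodeF <- tempfile(fileext = ".tsv")
  exportNetwork(net, pr, sif, nodeF)
  back <- readNetworkSif(sif)
  expect_setequal(paste(back$tf, back$target),
                  paste(netEdges(net)$tf, netEdges(net)$target))
  nodeTab <- read.delim(nodeF)
  expect_setequal(nodeTab$id, netNodes(net)$id)
  expect_equal(nodeTab$pagerank[match(names(pr), nodeTab$id)],
               unname(pr), tolerance = 1e-12)
  ## empty network exports empty files that round-trip
  emptyNet <- assembleNetwork(data.frame(motif_id = character(),
                                         tf = character()),
                              list(), mkDe("g1"))
  exportNetwork(emptyNet, NULL, sif, nodeF)
  expect_equal(nrow(readNetworkSif(sif)), 0L)
})

test_that("up/down node attributes mirror the DE directions", {
  matches <- data.frame(motif_id = "M1", tf = "TFA",
                        stringsAsFactors = FALSE)
  inst <- data.frame(gene_id = c("g1", "g2"), stringsAsFactors = FALSE)
  de <- data.frame(gene_id = c("g1", "g2"), p_value = 0.01,
                   direction = c("up", "down"), stringsAsFactors = FALSE)
  net <- assembleNetwork(matches, list(M1 = inst), de)
  nd <- netNodes(net)
  expect_equal(nd$regulation[nd$id == "g1"], "up")
  expect_equal(nd$regulation[nd$id == "g2"], "down")
})
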