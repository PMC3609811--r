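## Shared fixtures: small, fast configurations used across test files.
## Reduced promoter windows and database sizes keep the statistical suites
## desk-scale; structural settings (3 groups x 3 replicates, fold range,
## 8 species) follow the emulated study design.

smallCfg <- function(seed = 1, ...) {
  args <- list(nGenes = 60, promoterWindow = c(-150, 50), pwmDbSize = 6,
               noiseSd = 0.1, deFraction = 0.15, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  if (is.null(extra$termSize))
    args$termSize <- max(2L, min(10L, args$nGenes %/% 2L))
  do.call(simConfig, args)
}

## Expression SummarizedExperiment from an explicit intensity matrix.
seFromMatrix <- function(mat, groups) {
  SummarizedExperiment::SummarizedExperiment(
    assays = list(intensity = mat),
    colData = S4Vectors::DataFrame(group = groups,
                                   row.names = colnames(mat)))
}

## Positive/negative promoter sets with a motif planted in a fraction of
## the positives, built through the package's own generator.
plantedPromoterSets <- function(seed, nGenes = 100, window = c(-250, 50),
                               rate = 0.8, consensus = "TGACGTCATG") {
  cfg <- simConfig(nGenes = nGenes, deFraction = 0.5,
                   promoterWindow = window, motifConsensus = consensus,
                   motifInsertionRate = rate, noiseSd = 0.1, seed = seed)
  expr <- simulateExpression(cfg)
  gen <- simulateGenome(cfg, expr$truth)
  prom <- extractPromoters(gen$genome, gen$genes, window)
  de <- expr$truth$gene_id[expr$truth$is_de]
  list(pos = prom[de], neg = prom[setdiff(expr$truth$gene_id, de)],
       cfg = cfg, motifTruth = gen$motifTruth)
}

## Random alignment block as a named character vector (ref first).
randomBlock <- function(L, S, seed) {
  set.seed(seed)
  ref <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
               collapse = "")
  rows <- c(ref = ref)
  for (s in seq_len(S)) {
    v <- strsplit(ref, "")[[1]]
    flip <- runif(L) < 0.5
    v[flip] <- sample(c("A", "C", "G", "T"), sum(flip), replace = TRUE)
    rows[paste0("sp", s)] <- paste(v, collapse = "")
  }
  rows
}

## Independent brute-force posterior by enumerating all 2^L state paths.
enumeratePosterior <- function(block, params) {
  mc <- alignmentMatchCounts(block)
  em <- columnEmissions(mc$m, mc$S, params)
  L <- mc$L
  Tm <- matrix(c(params$pStayCons, 1 - params$pStayCons,
                 1 - params$pStayNon, params$pStayNon),
               nrow = 2, byrow = TRUE)
  post <- numeric(L)
  total <- 0
  paths <- expand.grid(rep(list(1:2), L))
  for (r in seq_len(nrow(paths))) {
    s <- as.integer(paths[r, ])
    p <- params$pi[s[1]] * em[s[1], 1]
    if (L > 1)
      for (j in 2:L) p <- p * Tm[s[j - 1], s[j]] * em[s[j], j]
    total <- total + p
    post[s == 1] <- post[s == 1] + p
  }
  post / total
}

## Dense linear-system PageRank oracle: solves (I - d M) x = teleport,
## where M is the column-stochastic transition with dangling columns
## replaced by uniform.
densePageRank <- function(nodes, edges, d = 0.85) {
  n <- length(nodes)
  M <- matrix(0, n, n)
  from <- match(edges$tf, nodes)
  to <- match(edges$target, nodes)
  for (i in seq_along(from)) M[to[i], from[i]] <- 1
  outDeg <- colSums(M)
  for (j in seq_len(n)) {
    if (outDeg[j] == 0) M[, j] <- 1 / n else M[, j] <- M[, j] / outDeg[j]
  }
  A <- diag(n) - d * M
  x <- solve(A, rep((1 - d) / n, n))
  names(x) <- nodes
  x / sum(x)
}

## Random digraph as a RegNetwork (roles irrelevant for PageRank tests).
randomNetwork <- function(nNodes, pEdge, seed) {
  set.seed(seed)
  ids <- sprintf("n%02d", seq_len(nNodes))
  pairs <- expand.grid(tf = ids, target = ids,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$tf != pairs$target, ]
  edges <- pairs[runif(nrow(pairs)) < pEdge, ]
  rownames(edges) <- NULL
  nodes <- data.frame(id = ids, role = "target",
                      regulation = NA_character_,
                      stringsAsFactors = FALSE)
  RegNetwork(nodes, edges)
}

hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

revcompStr <- function(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
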