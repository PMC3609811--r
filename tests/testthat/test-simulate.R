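test_that("generators are bitwise deterministic under a fixed seed", {
  cfg <- smallCfg(seed = 7)
  a <- simulateAll(cfg)
  b <- simulateAll(cfg)
  expect_identical(SummarizedExperiment::assay(a$expression$se),
                   SummarizedExperiment::assay(b$expression$se))
  expect_identical(a$geneSets$sets, b$geneSets$sets)
  expect_identical(as.character(a$genome$genome),
                   as.character(b$genome$genome))
  expect_identical(lapply(a$alignments$blocks, as.character),
                   lapply(b$alignments$blocks, as.character))
  expect_identical(a$pwmDb, b$pwmDb)
  expect_identical(a$qpcr, b$qpcr)
})

test_that("no planted effect and no noise gives group-mean ratios of 1", {
  cfg <- smallCfg(noiseSd = 0, deFraction = 0)
  sim <- simulateExpression(cfg)
  r <- groupMeans(sim$se, "stress7") / groupMeans(sim$se, "control")
  expect_equal(unname(r), rep(1, cfg$nGenes))
})

test_that("planted fold changes are recovered on average", {
  cfg <- simConfig(nGenes = 1000, deFraction = 1, foldRange = c(2, 2),
                   noiseSd = 0.2, seed = 1)
  sim <- simulateExpression(cfg)
  r <- groupMeans(sim$se, "stress7") / groupMeans(sim$se, "control")
  rel <- r / sim$truth$expected_ratio
  expect_lt(abs(mean(rel) - 1), 0.025)   # 2.0 +/- 0.05 on the fold scale
  expect_true(all(SummarizedExperiment::assay(sim$se) > 0))
})

test_that("planted gene sets contain the configured DE enrichment", {
  cfg <- smallCfg(deFraction = 0.5, plantedTermEnrichment = 1,
                  termSize = 10)
  sim <- simulateExpression(cfg)
  sets <- simulateGeneSets(cfg, sim$truth)
  planted <- sets$terms$term_id[sets$terms$planted]
  de <- sim$truth$gene_id[sim$truth$is_de]
  for (t in planted)
    expect_true(all(sets$sets[[t]] %in% de))
  expect_error(simConfig(nGenes = 100, termSize = 1000), "termSize")
})

test_that("insertion rate 1 plants the consensus exactly once per DE promoter", {
  cfg <- smallCfg(motifInsertionRate = 1, deFraction = 0.3)
  sim <- simulateExpression(cfg)
  gen <- simulateGenome(cfg, sim$truth)
  prom <- extractPromoters(gen$genome, gen$genes, cfg$promoterWindow)
  mt <- gen$motifTruth
  de <- sim$truth$gene_id[sim$truth$is_de]
  expect_setequal(mt$gene_id[mt$planted], de)
  for (g in de) {
    s <- as.character(promoterSeqs(prom[g])[[1]])
    n <- length(gregexpr(cfg$motifConsensus, s, fixed = TRUE)[[1]])
    expect_equal(n, 1L)
    o <- mt$offset[mt$gene_id == g]
    expect_equal(substr(s, o, o + nchar(cfg$motifConsensus) - 1L),
                 cfg$motifConsensus)
  }
})

test_that("insertion count falls in the central binomial interval", {
  cfg <- simConfig(nGenes = 100, deFraction = 1, motifInsertionRate = 0.8,
                   promoterWindow = c(-150, 50), seed = 3)
  sim <- simulateExpression(cfg)
  gen <- simulateGenome(cfg, sim$truth)
  n <- sum(gen$motifTruth$planted)
  bounds <- qbinom(c(0.005, 0.995), 100, 0.8)
  expect_gte(n, bounds[1])
  expect_lte(n, bounds[2])
})

test_that("planted site on a minus-strand gene is recoverable after extraction", {
  cfg <- smallCfg(motifInsertionRate = 1, deFraction = 0.5, seed = 11)
  sim <- simulateExpression(cfg)
  gen <- simulateGenome(cfg, sim$truth)
  minus <- gen$genes$gene_id[gen$genes$strand == "-"]
  g <- intersect(minus, gen$motifTruth$gene_id[gen$motifTruth$planted])[1]
  expect_false(is.na(g))
  prom <- extractPromoters(gen$genome, gen$genes, cfg$promoterWindow)
  s <- as.character(promoterSeqs(prom[g])[[1]])
  o <- gen$motifTruth$offset[gen$motifTruth$gene_id == g]
  expect_equal(substr(s, o, o + 9L), cfg$motifConsensus)
  ## brute-force check: the reverse complement of the raw genomic slice
  ## contains the consensus, the forward slice contains its complement
  expect_true(grepl(revcompStr(cfg$motifConsensus),
                    as.character(sim <- gen$genome[[
                      gen$genes$chrom[gen$genes$gene_id == g]]])))
})

test_that("alignment blocks separate conserved from background columns", {
  cfg <- smallCfg(motifInsertionRate = 1, deFraction = 0.5,
                  conservedIdent = 0.95, backgroundIdent = 0.4, seed = 5)
  sim <- simulateExpression(cfg)
  gen <- simulateGenome(cfg, sim$truth)
  prom <- extractPromoters(gen$genome, gen$genes, cfg$promoterWindow)
  aln <- simulateAlignments(cfg, prom, gen$motifTruth)
  ct <- aln$conservedTruth
  expect_gt(nrow(ct), 0)
  fracs <- vapply(seq_len(nrow(ct)), function(i) {
    mc <- alignmentMatchCounts(aln$blocks[[ct$gene_id[i]]])
    inside <- mean(mc$m[ct$start[i]:ct$end[i]]) / mc$S
    outside <- mean(mc$m[-(ct$start[i]:ct$end[i])]) / mc$S
    inside - outside
  }, numeric(1))
  expect_gt(mean(fracs), 0.4)
})

test_that("full conservation makes conserved columns invariant", {
  cfg <- smallCfg(motifInsertionRate = 1, deFraction = 0.5,
                  conservedIdent = 1 - 1e-12, seed = 2)
  ## per-species match probability ~1 inside conserved intervals
  sim <- simulateExpression(cfg)
  gen <- simulateGenome(cfg, sim$truth)
  prom <- extractPromoters(gen$genome, gen$genes, cfg$promoterWindow)
  aln <- simulateAlignments(cfg, prom, gen$motifTruth)
  ct <- aln$conservedTruth[1, ]
  mc <- alignmentMatchCounts(aln$blocks[[ct$gene_id]])
  expect_true(all(mc$m[ct$start:ct$end] == mc$S))
})

test_that("the PWM database embeds the planted consensus with normalised columns", {
  cfg <- smallCfg()
  db <- simulatePwmDb(cfg)
  planted <- db[[attr(db, "plantedTf")]]
  cons <- paste(rownames(planted)[apply(planted, 2, which.max)],
                collapse = "")
  expect_equal(cons, cfg$motifConsensus)
  probs <- sweep(planted, 2, colSums(planted), "/")
  expect_true(all(abs(colSums(probs) - 1) < 1e-12))
  ## random records resemble the planted record less than it does itself
  selfSim <- pwmSimilarity(planted, planted)$similarity
  for (nm in setdiff(names(db), attr(db, "plantedTf")))
    expect_lt(pwmSimilarity(db[[nm]], planted)$similarity, selfSim)
})

test_that("qPCR generator encodes folds exactly when noise-free", {
  cfg <- smallCfg(qpcrNoiseSd = 0,
                  qpcrFold = list(X = c(stress7 = 2, stress21 = 1)))
  ct <- simulateQpcr(cfg)
  rel <- relativeQuantity(ct, "X", "control")
  g <- rel$groups
  expect_equal(g$ratio[g$group == "stress7"], 2)
  expect_equal(g$ratio[g$group == "stress21"], 1)
})

test_that("configuration validation rejects malformed inputs", {
  expect_error(simConfig(nGenes = 0), "nGenes")
  expect_error(simConfig(deFraction = 1.5), "deFraction")
  expect_error(simConfig(foldRange = c(0.5, 2)), "foldRange")
  expect_error(simConfig(motifConsensus = "ACGTN"), "motifConsensus")
  expect_error(simConfig(qpcrFold = list(X = c(stress7 = -1))),
               "positive")
})
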