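test_that("site log-odds is zero for the background motif and matches hand sums", {
  f <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  pwm <- matrix(0.25, 4, 8, dimnames = list(names(f), NULL))
  expect_equal(siteLogOdds("ACGTACGT", pwm, f), 0)
  ## deterministic pwm from one site with pseudocount 0.25:
  ## matched base (1 + 0.25)/2, others 0.25/2
  sites <- "AAAAAAAA"
  pwm2 <- cisRegNet:::pwmFromSites(sites, 0.25)
  theta <- 1.25 / 2
  expect_equal(siteLogOdds("AAAAAAAA", pwm2, f), 8 * log(theta / 0.25))
  expect_gt(min(pwm2), 0)   # pseudocount keeps every entry positive
  expect_error(siteLogOdds("AAAA", pwm2, f), "length")
  expect_error(siteLogOdds("AAAANAAA", pwm2, f), "ambiguous")
})

test_that("best site scanning matches an exhaustive per-offset oracle", {
  set.seed(1)
  f <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  for (rep in 1:10) {
    w <- sample(c(6, 8), 1)
    pwm <- cisRegNet:::pwmFromSites(
      paste(sample(c("A", "C", "G", "T"), w, replace = TRUE),
            collapse = ""), 0.25)
    s <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
               collapse = "")
    hit <- bestSite(s, pwm, f)
    ## oracle: score every window on both strands via siteLogOdds
    scores <- vapply(1:(60 - w + 1), function(o) {
      fwd <- siteLogOdds(substr(s, o, o + w - 1), pwm, f)
      rev <- siteLogOdds(revcompStr(substr(s, o, o + w - 1)), pwm, f)
      max(fwd, rev)
    }, numeric(1))
    expect_equal(hit$score, max(scores), tolerance = 1e-12)
    ## the returned offset attains the maximum (ties may be exact in one
    ## summation order and within rounding in the other)
    expect_equal(scores[hit$offset], max(scores), tolerance = 1e-12)
  }
})

test_that("a planted perfect site is located exactly", {
  f <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  motif <- "TGACGTCATG"
  pwm <- cisRegNet:::pwmFromSites(rep(motif, 20), 0.25)
  s <- paste0(strrep("A", 37), motif, strrep("A", 20))
  expect_equal(bestSite(s, pwm, f)$offset, 38L)
  ## reverse-complement plant is found on the minus strand
  s2 <- paste0(strrep("A", 12), revcompStr(motif), strrep("A", 20))
  hit <- bestSite(s2, pwm, f)
  expect_equal(hit$offset, 13L)
  expect_equal(hit$strand, "-")
  expect_error(bestSite(strrep("N", 30), pwm, f), "ambiguous")
})

test_that("palindromic ties resolve to the plus strand at the same offset", {
  f <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  pal <- "TGCA"   # reverse complement of itself
  pwm <- cisRegNet:::pwmFromSites(rep(pal, 10), 0.25)
  s <- paste0("CCCC", pal, "CCCC")
  hit <- bestSite(s, pwm, f)
  expect_equal(hit$strand, "+")
  expect_equal(hit$offset, 5L)
})

test_that("the discriminative score is zero on identical sets and antisymmetric", {
  set.seed(2)
  f <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  seqs <- vapply(1:5, function(i)
    paste(sample(c("A", "C", "G", "T"), 50, replace = TRUE),
          collapse = ""), character(1))
  pwm <- cisRegNet:::pwmFromSites("ACGTACGT", 0.25)
  expect_equal(discriminativeScore(pwm, seqs, seqs, f), 0)
  other <- vapply(1:5, function(i)
    paste(sample(c("A", "C", "G", "T"), 50, replace = TRUE),
          collapse = ""), character(1))
  expect_equal(discriminativeScore(pwm, seqs, other, f),
               -discriminativeScore(pwm, other, seqs, f),
               tolerance = 1e-12)
})

test_that("a planted motif dominates background candidates on a toy set", {
  set.seed(3)
  motif <- "TGACGTCATG"
  pos <- vapply(1:6, function(i) {
    bg <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
                collapse = "")
    paste0(substr(bg, 1, 20), motif, substr(bg, 31, 60))
  }, character(1))
  neg <- vapply(1:6, function(i)
    paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
          collapse = ""), character(1))
  f <- backgroundComposition(pos, neg)
  planted <- cisRegNet:::pwmFromSites(rep(motif, 6), 0.25)
  sPlant <- discriminativeScore(planted, pos, neg, f)
  expect_gt(sPlant, 0)
  for (i in 1:20) {
    rnd <- cisRegNet:::pwmFromSites(
      paste(sample(c("A", "C", "G", "T"), 10, replace = TRUE),
            collapse = ""), 0.25)
    expect_gt(sPlant, discriminativeScore(rnd, pos, neg, f))
  }
})

test_that("refinement is a fixed point on a clean plant and monotone elsewhere", {
  set.seed(4)
  motif <- "TGACGTCATG"
  pos <- vapply(1:8, function(i) {
    bg <- paste(sample(c("A", "C", "G", "T"), 80, replace = TRUE),
                collapse = "")
    o <- sample(1:70, 1)
    paste0(substr(bg, 1, o - 1), motif, substr(bg, o + 10, 80))
  }, character(1))
  neg <- vapply(1:8, function(i)
    paste(sample(c("A", "C", "G", "T"), 80, replace = TRUE),
          collapse = ""), character(1))
  m <- refineMotif(motif, pos, neg)
  expect_equal(motifConsensus(m), motif)
  expect_equal(nrow(motifInstances(m)), 8L)
  expect_true(all(motifInstances(m)$site == motif))
  ## maxIter = 0 returns the seed-count motif unrefined
  m0 <- refineMotif(motif, pos, neg, maxIter = 0)
  expect_equal(motifConsensus(m0), motif)
  expect_error(refineMotif("GGGGGGGGGG", c("AAAA"), neg), "seed")
})

test_that("the refinement objective never decreases across random toys", {
  set.seed(5)
  for (t in 1:30) {
    pos <- vapply(1:5, function(i)
      paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE),
            collapse = ""), character(1))
    neg <- vapply(1:5, function(i)
      paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE),
            collapse = ""), character(1))
    seed <- substr(pos[1], 1, 8)
    f <- backgroundComposition(pos, neg)
    m0 <- refineMotif(seed, pos, neg, bg = f, maxIter = 0)
    m <- refineMotif(seed, pos, neg, bg = f)
    expect_gte(motifScore(m), motifScore(m0) - 1e-12)
  }
})

test_that("discovery recovers a planted motif and respects topN", {
  sets <- plantedPromoterSets(seed = 42, nGenes = 60,
                              window = c(-120, 40))
  motifs <- discoverMotifs(sets$pos, sets$neg, widths = 10, topN = 5,
                           maxSeeds = 50)
  expect_lte(length(motifs), 5)
  cons <- motifConsensus(motifs[[1]])
  d <- min(hamming(cons, sets$cfg$motifConsensus),
           hamming(cons, revcompStr(sets$cfg$motifConsensus)))
  expect_lte(d, 1)
  ## determinism of the ranked list
  motifs2 <- discoverMotifs(sets$pos, sets$neg, widths = 10, topN = 5,
                            maxSeeds = 50)
  expect_identical(vapply(motifs, motifConsensus, character(1)),
                   vapply(motifs2, motifConsensus, character(1)))
  expect_identical(vapply(motifs, motifScore, numeric(1)),
                   vapply(motifs2, motifScore, numeric(1)))
})

test_that("identical positive and negative sets yield no discriminative motif", {
  set.seed(6)
  seqs <- vapply(1:20, function(i)
    paste(sample(c("A", "C", "G", "T"), 150, replace = TRUE),
          collapse = ""), character(1))
  names(seqs) <- paste0("g", 1:20)
  motifs <- suppressWarnings(
    discoverMotifs(seqs, seqs, widths = 10, topN = 20, qMin = 0.1))
  if (length(motifs))
    expect_lt(max(vapply(motifs, motifScore, numeric(1))), 0.5)
  else succeed()
})

test_that("duplicate consensus collapsing merges shifts and reverse complements", {
  expect_true(cisRegNet:::consensusDuplicate("TGACGTCATG", "TGACGTCATG"))
  expect_true(cisRegNet:::consensusDuplicate("TGACGTCATG",
                                             revcompStr("TGACGTCATG")))
  ## one-position shift with w-1 matching positions in the overlap
  expect_true(cisRegNet:::consensusDuplicate("TGACGTCATG", "GACGTCATGA"))
  expect_false(cisRegNet:::consensusDuplicate("AAAAAAAAAA", "CCCCCCCCCC"))
})
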