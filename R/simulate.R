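#' Simulation configuration
#'
#' Bundles every parameter of the synthetic-data generator. Defaults mirror
#' the study design the package emulates: three groups (control plus two
#' stress durations) with three replicate arrays each, planted linear fold
#' changes drawn from [1.5, 3], promoter windows of -3000..+500 around the
#' TSS, alignments of the reference against eight non-reference vertebrate
#' species, and qPCR tables of nine animals per group.
#'
#' @param nGenes Number of genes on the simulated platform.
#' @param nSamplesPerGroup Replicate arrays per group (default 3).
#' @param groups Group labels; the first is the control/calibrator group.
#' @param deFraction Fraction of genes planted as differentially expressed.
#' @param foldRange Linear fold-change interval for planted genes.
#' @param noiseSd Log2-scale intensity noise standard deviation.
#' @param nTerms Number of gene sets in the simulated collection.
#' @param termSize Members per gene set.
#' @param nPlantedTerms Gene sets planted with DE enrichment.
#' @param plantedTermEnrichment Fraction of a planted term's members drawn
#'   from the DE genes.
#' @param promoterWindow `c(upstream, downstream)` relative to the TSS;
#'   default `c(-3000, 500)`.
#' @param motifConsensus Planted motif consensus (A/C/G/T string).
#' @param motifInsertionRate Probability a DE-gene promoter carries the
#'   planted motif.
#' @param nSpecies Non-reference species rows per alignment block
#'   (default 8).
#' @param conservedIdent Per-species reference-match probability inside
#'   conserved alignment intervals.
#' @param backgroundIdent Match probability outside conserved intervals.
#' @param conservedFlank Conserved padding (bp) around each planted site.
#' @param background Base composition (A,C,G,T) of simulated sequence.
#' @param pwmDbSize Records in the simulated TF PWM database (including the
#'   planted TF).
#' @param qpcrFold Named list: gene -> named numeric vector of linear folds
#'   per non-control group.
#' @param qpcrN qPCR samples per group.
#' @param qpcrNoiseSd Ct noise standard deviation (cycles).
#' @param seed Integer master seed; fixes every generator output.
#' @return A validated `SimConfig` list.
#' @examples
#' cfg <- simConfig(nGenes = 50, seed = 1)
#' @export
simConfig <- function(nGenes = 200,
                      nSamplesPerGroup = 3,
                      groups = c("control", "stress7", "stress21"),
                      deFraction = 0.1,
                      foldRange = c(1.5, 3.0),
                      noiseSd = 0.2,
                      nTerms = 20,
                      termSize = 20,
                      nPlantedTerms = 2,
                      plantedTermEnrichment = 0.5,
                      promoterWindow = c(-3000, 500),
                      motifConsensus = "TGACGTCATG",
                      motifInsertionRate = 0.8,
                      nSpecies = 8,
                      conservedIdent = 0.95,
                      backgroundIdent = 0.4,
                      conservedFlank = 25,
                      background = c(0.25, 0.25, 0.25, 0.25),
                      pwmDbSize = 10,
                      qpcrFold = list(
                        Gabra1 = c(stress7 = 1.31, stress21 = 1.55),
                        Crhr2  = c(stress7 = 0.52, stress21 = 0.49),
                        Fadd   = c(stress7 = 1.63, stress21 = 1.96),
                        Cdk6   = c(stress7 = 0.82, stress21 = 0.57)),
                      qpcrN = 9,
                      qpcrNoiseSd = 0.2,
                      seed = 1) {
  stopifnotScalarCount(nGenes, "nGenes")
  stopifnotScalarCount(nSamplesPerGroup, "nSamplesPerGroup")
  stopifnotScalarCount(nSpecies, "nSpecies")
  stopifnotScalarCount(pwmDbSize, "pwmDbSize")
  if (deFraction < 0 || deFraction > 1)
    stop("deFraction must lie in [0,1]")
  if (plantedTermEnrichment < 0 || plantedTermEnrichment > 1)
    stop("plantedTermEnrichment must lie in [0,1]")
  if (motifInsertionRate < 0 || motifInsertionRate > 1)
    stop("motifInsertionRate must lie in [0,1]")
  if (foldRange[1] < 1 || foldRange[2] < foldRange[1])
    stop("foldRange lower bound must be >= 1 and range non-decreasing")
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  if (promoterWindow[1] > 0 || promoterWindow[2] < 0)
    stop("promoterWindow must bracket the TSS: c(-upstream, +downstream)")
  if (!grepl("^[ACGT]+$", motifConsensus))
    stop("motifConsensus must be a non-empty string over A,C,G,T")
  if (abs(sum(background) - 1) > 1e-9 || any(background <= 0))
    stop("background must be 4 positive probabilities summing to 1")
  if (any(unlist(qpcrFold) <= 0))
    stop("qPCR folds must be positive")
  if (termSize > nGenes) stop("termSize cannot exceed nGenes")
  cfg <- list(nGenes = as.integer(nGenes),
              nSamplesPerGroup = as.integer(nSamplesPerGroup),
              groups = groups, deFraction = deFraction,
              foldRange = foldRange, noiseSd = noiseSd,
              nTerms = as.integer(nTerms), termSize = as.integer(termSize),
              nPlantedTerms = as.integer(nPlantedTerms),
              plantedTermEnrichment = plantedTermEnrichment,
              promoterWindow = promoterWindow,
              motifConsensus = motifConsensus,
              motifInsertionRate = motifInsertionRate,
              nSpecies = as.integer(nSpecies),
              conservedIdent = conservedIdent,
              backgroundIdent = backgroundIdent,
              conservedFlank = as.integer(conservedFlank),
              background = background, pwmDbSize = as.integer(pwmDbSize),
              qpcrFold = qpcrFold, qpcrN = as.integer(qpcrN),
              qpcrNoiseSd = qpcrNoiseSd, seed = as.integer(seed))
  class(cfg) <- "SimConfig"
  cfg
}

#' Simulate a replicate fluorescence-intensity matrix
#'
#' Log2 intensities are drawn as `mu_g + effect + N(0, noiseSd)` and
#' exponentiated, so a gene planted at linear fold F has expected
#' group-mean intensity ratio F against control and non-planted genes have
#' expected ratio 1. The same planted effect is applied to every
#' non-control group.
#'
#' @param cfg A [simConfig()] object.
#' @return A list with `se` (a
#'   [SummarizedExperiment::SummarizedExperiment] with assay `intensity`
#'   and `colData$group`) and `truth` (per-gene `is_de`, `fold`,
#'   `direction`).
#' @examples
#' sim <- simulateExpression(simConfig(nGenes = 20, seed = 1))
#' @export
simulateExpression <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  withSeed(childSeed(cfg$seed, 1L), {
    n <- cfg$nGenes
    geneIds <- sprintf("G%04d", seq_len(n))
    nDe <- round(cfg$deFraction * n)
    deIdx <- if (nDe > 0) sort(sample.int(n, nDe)) else integer(0)
    direction <- rep("none", n)
    fold <- rep(1, n)
    if (nDe > 0) {
      direction[deIdx] <- sample(c("up", "down"), nDe, replace = TRUE)
      fold[deIdx] <- runif(nDe, cfg$foldRange[1], cfg$foldRange[2])
    }
    effect <- ifelse(direction == "up", log2(fold),
                     ifelse(direction == "down", -log2(fold), 0))
    mu <- runif(n, 6, 12)
    groups <- rep(cfg$groups, each = cfg$nSamplesPerGroup)
    sampleIds <- paste0(groups, "_", seq_len(cfg$nSamplesPerGroup))
    isCtl <- groups == cfg$groups[1]
    logx <- outer(mu, rep(0, length(groups)), "+")
    logx <- logx + outer(effect, as.numeric(!isCtl))
    logx <- logx + matrix(rnorm(length(logx), 0, cfg$noiseSd), nrow = n)
    mat <- 2^logx
    dimnames(mat) <- list(geneIds, sampleIds)
    se <- SummarizedExperiment(
      assays = list(intensity = mat),
      colData = S4Vectors::DataFrame(group = groups, row.names = sampleIds))
    truth <- data.frame(gene_id = geneIds, is_de = direction != "none",
                        fold = fold, direction = direction,
                        stringsAsFactors = FALSE)
    ## planted folds are reported on the linear scale relative to control;
    ## a "down" gene at fold F has expected ratio 1/F
    truth$expected_ratio <- ifelse(truth$direction == "down",
                                   1 / truth$fold, truth$fold)
    list(se = se, truth = truth)
  })
}

#' Simulate a gene-set collection with planted enrichment
#'
#' Planted terms draw a configured fraction of their members from the DE
#' genes; all other terms sample the universe uniformly.
#'
#' @param cfg A [simConfig()] object.
#' @param truth Per-gene truth table from [simulateExpression()].
#' @return List with `sets` (named list of gene-id vectors), `universe`,
#'   and `terms` (term_id, planted flag).
#' @export
simulateGeneSets <- function(cfg, truth) {
  stopifnot(inherits(cfg, "SimConfig"))
  if (cfg$termSize > cfg$nGenes)
    stop("term size exceeds the number of genes")
  withSeed(childSeed(cfg$seed, 2L), {
    universe <- truth$gene_id
    deGenes <- truth$gene_id[truth$is_de]
    other <- setdiff(universe, deGenes)
    termIds <- sprintf("TERM%03d", seq_len(cfg$nTerms))
    planted <- seq_len(cfg$nTerms) <= cfg$nPlantedTerms
    sets <- lapply(seq_len(cfg$nTerms), function(i) {
      if (planted[i] && length(deGenes) > 0) {
        nDe <- min(round(cfg$plantedTermEnrichment * cfg$termSize),
                   length(deGenes))
        c(sample(deGenes, nDe),
          sample(other, cfg$termSize - nDe))
      } else sample(universe, cfg$termSize)
    })
    names(sets) <- termIds
    list(sets = sets, universe = universe,
         terms = data.frame(term_id = termIds, planted = planted,
                            stringsAsFactors = FALSE))
  })
}

#' Simulate a genome with annotated genes and planted promoter motifs
#'
#' Genes are spaced so promoter windows never overlap (about 50 genes per
#' chromosome). Each DE gene's promoter receives the planted consensus at
#' the configured insertion rate, written in gene orientation (so it is
#' reverse-complemented on the genome for minus-strand genes).
#'
#' @param cfg A [simConfig()] object.
#' @param truth Per-gene truth from [simulateExpression()].
#' @return List with `genome` (DNAStringSet), `genes` (BED-like
#'   data.frame: chrom, start, end, gene_id, score, strand; 0-based
#'   half-open), and `motifTruth` (gene_id, planted, offset of the site
#'   within the promoter, 1-based, gene orientation).
#' @export
simulateGenome <- function(cfg, truth) {
  stopifnot(inherits(cfg, "SimConfig"))
  withSeed(childSeed(cfg$seed, 3L), {
    up <- -cfg$promoterWindow[1]
    down <- cfg$promoterWindow[2]
    plen <- up + down
    w <- nchar(cfg$motifConsensus)
    if (w > plen) stop("motif consensus longer than the promoter window")
    pad <- plen + 1000L
    perChrom <- 50L
    n <- cfg$nGenes
    nChrom <- ceiling(n / perChrom)
    consCode <- encodeDNA(cfg$motifConsensus)
    genes <- vector("list", n)
    motifTruth <- vector("list", n)
    chromSeqs <- character(nChrom)
    g <- 0L
    for (ch in seq_len(nChrom)) {
      nOn <- min(perChrom, n - (ch - 1L) * perChrom)
      chrlen <- 2L * pad * nOn + pad
      chromv <- sample.int(4L, chrlen, replace = TRUE,
                           prob = cfg$background)
      for (i in seq_len(nOn)) {
        g <- g + 1L
        tss <- pad + (i - 1L) * 2L * pad       # 0-based TSS coordinate
        strand <- sample(c("+", "-"), 1L)
        planted <- FALSE
        offset <- NA_integer_
        if (truth$is_de[g] && runif(1) < cfg$motifInsertionRate) {
          planted <- TRUE
          offset <- sample.int(plen - w + 1L, 1L)  # 1-based in promoter
          o0 <- offset - 1L
          if (strand == "+") {
            gstart <- tss - up + o0              # 0-based genomic start
            chromv[(gstart + 1L):(gstart + w)] <- consCode
          } else {
            gstart <- tss + up - o0 - w + 1L
            chromv[(gstart + 1L):(gstart + w)] <- revcompCode(consCode)
          }
        }
        if (strand == "+") {
          gs <- tss; ge <- tss + 1000L
        } else {
          ge <- tss + 1L; gs <- ge - 1000L
        }
        genes[[g]] <- data.frame(
          chrom = paste0("chr", ch), start = gs, end = ge,
          gene_id = truth$gene_id[g], score = 0L, strand = strand,
          stringsAsFactors = FALSE)
        motifTruth[[g]] <- data.frame(
          gene_id = truth$gene_id[g], planted = planted, offset = offset,
          stringsAsFactors = FALSE)
      }
      chromSeqs[ch] <- paste(BASES[chromv], collapse = "")
    }
    genome <- DNAStringSet(chromSeqs)
    names(genome) <- paste0("chr", seq_len(nChrom))
    list(genome = genome, genes = do.call(rbind, genes),
         motifTruth = do.call(rbind, motifTruth))
  })
}

#' Simulate multi-species promoter alignment blocks
#'
#' One block per promoter: the reference promoter sequence plus `nSpecies`
#' rows in which each base matches the reference with probability
#' `conservedIdent` inside conserved intervals (the planted site padded by
#' `conservedFlank`) and `backgroundIdent` elsewhere. No indels are
#' simulated; the conservation model downstream is column-based.
#'
#' @param cfg A [simConfig()] object.
#' @param promoters A [PromoterSet-class] (reference rows).
#' @param motifTruth Planted-site table from [simulateGenome()].
#' @param motifWidth Width of the planted consensus (defaults to
#'   `nchar(cfg$motifConsensus)`).
#' @return List with `blocks` (named list of DNAStringSet, reference row
#'   first, named `ref`, `sp1`, ...) and `conservedTruth` (gene_id, start,
#'   end of conserved intervals, 1-based inclusive promoter coordinates).
#' @export
simulateAlignments <- function(cfg, promoters, motifTruth,
                               motifWidth = nchar(cfg$motifConsensus)) {
  stopifnot(inherits(cfg, "SimConfig"), is(promoters, "PromoterSet"))
  if (cfg$nSpecies < 1) stop("nSpecies must be >= 1")
  withSeed(childSeed(cfg$seed, 4L), {
    ids <- promoterAnno(promoters)$gene_id
    blocks <- vector("list", length(ids))
    names(blocks) <- ids
    consTruth <- vector("list", length(ids))
    for (i in seq_along(ids)) {
      refStr <- as.character(promoterSeqs(promoters)[[i]])
      refv <- encodeDNA(refStr)
      L <- length(refv)
      ident <- rep(cfg$backgroundIdent, L)
      mt <- motifTruth[motifTruth$gene_id == ids[i], , drop = FALSE]
      if (nrow(mt) && isTRUE(mt$planted[1]) && !is.na(mt$offset[1])) {
        s <- max(1L, mt$offset[1] - cfg$conservedFlank)
        e <- min(L, mt$offset[1] + motifWidth - 1L + cfg$conservedFlank)
        ident[s:e] <- cfg$conservedIdent
        consTruth[[i]] <- data.frame(gene_id = ids[i], start = s, end = e,
                                     stringsAsFactors = FALSE)
      }
      rows <- character(cfg$nSpecies + 1L)
      rows[1] <- refStr
      for (s in seq_len(cfg$nSpecies)) {
        v <- refv
        mm <- which(runif(L) >= ident)
        if (length(mm))
          v[mm] <- (v[mm] - 1L + sample.int(3L, length(mm),
                                            replace = TRUE)) %% 4L + 1L
        rows[s + 1L] <- paste(BASES[v], collapse = "")
      }
      b <- DNAStringSet(rows)
      names(b) <- c("ref", paste0("sp", seq_len(cfg$nSpecies)))
      blocks[[i]] <- b
    }
    consTruth <- consTruth[!vapply(consTruth, is.null, logical(1))]
    conservedTruth <- if (length(consTruth)) do.call(rbind, consTruth)
      else data.frame(gene_id = character(), start = integer(),
                      end = integer())
    list(blocks = blocks, conservedTruth = conservedTruth)
  })
}

#' Simulate a TF PWM database containing the planted motif
#'
#' One record is a sharp count matrix derived from the planted consensus
#' (91 counts on the consensus base, 3 on each alternative); the remaining
#' records are random sharp-column PWMs of widths 8-16.
#'
#' @param cfg A [simConfig()] object.
#' @return A named list of 4 x w count matrices (rows A,C,G,T) with
#'   attribute `plantedTf` naming the planted record.
#' @export
simulatePwmDb <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  if (cfg$pwmDbSize < 1) stop("pwmDbSize must be >= 1")
  withSeed(childSeed(cfg$seed, 5L), {
    n <- cfg$pwmDbSize
    nms <- sprintf("TF%03d", seq_len(n))
    plantedIdx <- sample.int(n, 1L)
    db <- vector("list", n)
    for (i in seq_len(n)) {
      if (i == plantedIdx) {
        code <- encodeDNA(cfg$motifConsensus)
        m <- matrix(3, nrow = 4, ncol = length(code),
                    dimnames = list(BASES, NULL))
        m[cbind(code, seq_along(code))] <- 91
      } else {
        w <- sample(8:16, 1L)
        m <- matrix(0, nrow = 4, ncol = w, dimnames = list(BASES, NULL))
        for (j in seq_len(w)) {
          gam <- stats::rgamma(4, shape = 0.5)
          m[, j] <- as.vector(stats::rmultinom(1, 100, gam / sum(gam)))
        }
      }
      db[[i]] <- m
    }
    names(db) <- nms
    attr(db, "plantedTf") <- nms[plantedIdx]
    db
  })
}

#' Simulate a qPCR Ct table with planted fold changes
#'
#' For each gene and group, per-sample target and reference Ct values are
#' drawn so that the target-minus-reference difference is shifted by
#' `-log2(fold)` relative to control, encoding the planted linear fold.
#'
#' @param cfg A [simConfig()] object.
#' @return Data frame: sample, group, gene, ct_target, ct_reference.
#' @export
simulateQpcr <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  withSeed(childSeed(cfg$seed, 6L), {
    out <- list()
    for (gene in names(cfg$qpcrFold)) {
      folds <- cfg$qpcrFold[[gene]]
      for (grp in cfg$groups) {
        fold <- if (grp == cfg$groups[1]) 1 else {
          if (!grp %in% names(folds))
            stop(sprintf("no planted qPCR fold for gene %s group %s",
                         gene, grp))
          folds[[grp]]
        }
        ctRef <- 20 + rnorm(cfg$qpcrN, 0, cfg$qpcrNoiseSd)
        ctTar <- ctRef + 4 - log2(fold) + rnorm(cfg$qpcrN, 0, cfg$qpcrNoiseSd)
        out[[length(out) + 1L]] <- data.frame(
          sample = paste0(grp, "_", seq_len(cfg$qpcrN)),
          group = grp, gene = gene, ct_target = ctTar,
          ct_reference = ctRef, stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, out)
  })
}

#' Run every generator with one configuration
#'
#' @param cfg A [simConfig()] object.
#' @return A list with components `expression` (se + truth), `geneSets`,
#'   `genome`, `promoters` (a [PromoterSet-class] extracted from the
#'   simulated genome), `alignments`, `pwmDb`, `qpcr`.
#' @examples
#' sim <- simulateAll(simConfig(nGenes = 30, promoterWindow = c(-150, 50),
#'                              seed = 1))
#' @export
simulateAll <- function(cfg) {
  expr <- simulateExpression(cfg)
  sets <- simulateGeneSets(cfg, expr$truth)
  gen <- simulateGenome(cfg, expr$truth)
  prom <- extractPromoters(gen$genome, gen$genes,
                           window = cfg$promoterWindow)
  aln <- simulateAlignments(cfg, prom, gen$motifTruth)
  db <- simulatePwmDb(cfg)
  qpcr <- simulateQpcr(cfg)
  list(expression = expr, geneSets = sets, genome = gen,
       promoters = prom, alignments = aln, pwmDb = db, qpcr = qpcr)
}
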