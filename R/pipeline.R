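#' Run the full synthetic-to-network workflow
#'
#' Generates every input with [simulateAll()], then for each non-control
#' group: calls DE genes by signal ratio + Welch test, runs gene-set
#' enrichment, builds positive (DE) and negative (non-differential)
#' promoter sets, discovers discriminative motifs, filters their instances
#' by the conservation HMM, matches the surviving motifs against the PWM
#' database, assembles the TF -> target network and ranks core genes by
#' PageRank. A qPCR report is produced for every gene with planted folds.
#' All stage outputs are written under `outDir` and checksummed in a run
#' manifest; reruns with an identical configuration are bitwise identical.
#'
#' @param cfg A [simConfig()]; its seed fixes the whole run.
#' @param outDir Output directory (created).
#' @param ratioLow,ratioHigh,alpha DE-calling parameters.
#' @param pMin Negative-set eligibility threshold on the DE p-value.
#' @param widths,topN,qMin,maxSeeds,maxIter Motif-discovery parameters.
#' @param hmm [hmmParams()] for conservation scoring.
#' @param consThreshold Minimum mean conservation of a kept instance.
#' @param pMax,topTfs,nNull PWM-matching parameters.
#' @return List with `sim`, `branches` (one per stress group: de, enrich,
#'   motifs, instances, match, network, pagerank, coreGenes), `qpcr`, and
#'   `manifest` (stage, file, md5).
#' @examples
#' \donttest{
#' cfg <- simConfig(nGenes = 60, promoterWindow = c(-150, 50),
#'                  pwmDbSize = 6, seed = 1)
#' res <- runPipeline(cfg, tempfile("run"), nNull = 20000, pMax = 5e-4)
#' res$branches$stress7$coreGenes
#' }
#' @export
runPipeline <- function(cfg, outDir,
                        ratioLow = 0.67, ratioHigh = 1.5, alpha = 0.05,
                        pMin = 0.9,
                        widths = nchar(cfg$motifConsensus), topN = 20,
                        qMin = 0.2, maxSeeds = 50, maxIter = 50,
                        hmm = hmmParams(), consThreshold = 0.8,
                        pMax = 1e-4, topTfs = 5, nNull = 200000) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  note <- function(stage, files)
    manifest[[length(manifest) + 1L]] <<- data.frame(
      stage = stage, file = basename(files),
      md5 = unname(md5sum(files)), stringsAsFactors = FALSE)

  sim <- simulateAll(cfg)
  se <- sim$expression$se
  writeExpressionTsv(se, file.path(outDir, "expression.tsv"),
                     file.path(outDir, "groups.tsv"))
  writeGmt(sim$geneSets$sets, file.path(outDir, "genesets.gmt"))
  writeXStringSet(sim$genome$genome, file.path(outDir, "genome.fa"))
  writeGeneBed(sim$genome$genes, file.path(outDir, "genes.bed"))
  writeJasparPwm(sim$pwmDb, file.path(outDir, "pwmdb.txt"))
  writeTsv(sim$qpcr, file.path(outDir, "qpcr.tsv"))
  writePromoterFasta(sim$promoters, file.path(outDir, "promoters.fa"))
  note("simulate", file.path(outDir, c("expression.tsv", "groups.tsv",
       "genesets.gmt", "genome.fa", "genes.bed", "pwmdb.txt", "qpcr.tsv",
       "promoters.fa")))

  tracks <- conservationTracks(sim$alignments$blocks, hmm)
  control <- cfg$groups[1]
  branches <- list()
  for (grp in cfg$groups[-1]) {
    de <- callDE(se, grp, control, ratioLow, ratioHigh, alpha)
    deFile <- file.path(outDir, sprintf("de_%s.tsv", grp))
    writeDeTable(de, deFile)
    note("de", deFile)

    deGenes <- de$gene_id[de$direction != "none"]
    enr <- if (length(deGenes))
      enrichTerms(deGenes, sim$geneSets$sets, sim$geneSets$universe)
    else data.frame()
    enrFile <- file.path(outDir, sprintf("enrich_%s.tsv", grp))
    writeTsv(enr, enrFile)
    note("enrich", enrFile)

    branch <- list(de = de, enrich = enr, motifs = list(),
                   instances = list(), match = NULL, network = NULL,
                   pagerank = NULL, coreGenes = NULL)
    if (length(deGenes) >= 2) {
      pos <- sim$promoters[deGenes]
      negIds <- selectNegativeSet(de, deGenes, pMin,
                                  seed = childSeed(cfg$seed, 8L))
      neg <- sim$promoters[negIds]
      motifs <- discoverMotifs(pos, neg, widths = widths, topN = topN,
                               qMin = qMin, maxSeeds = maxSeeds,
                               maxIter = maxIter)
      branch$motifs <- motifs
      if (length(motifs)) {
        mrep <- motifReport(motifs)
        writeTsv(mrep, file.path(outDir, sprintf("motifs_%s.tsv", grp)))
        note("motifs", file.path(outDir, sprintf("motifs_%s.tsv", grp)))

        instances <- lapply(motifs, function(m)
          filterConserved(motifInstances(m), tracks, consThreshold))
        names(instances) <- mrep$motif_id
        branch$instances <- instances
        instTab <- do.call(rbind, lapply(names(instances), function(id) {
          d <- instances[[id]]
          if (!nrow(d)) return(NULL)
          cbind(motif_id = id, d)
        }))
        instFile <- file.path(outDir, sprintf("instances_%s.tsv", grp))
        writeTsv(if (is.null(instTab)) data.frame() else instTab, instFile)
        note("conservation", instFile)

        keep <- vapply(instances, nrow, integer(1)) > 0
        if (any(keep)) {
          mm <- matchDatabase(setNames(motifs[keep], mrep$motif_id[keep]),
                              sim$pwmDb, pMax = pMax, topTfs = topTfs,
                              nNull = nNull,
                              seed = childSeed(cfg$seed, 9L))
          branch$match <- mm
          mFile <- file.path(outDir, sprintf("matches_%s.tsv", grp))
          writeTsv(mm$matches, mFile)
          tFile <- file.path(outDir, sprintf("toptfs_%s.tsv", grp))
          writeTsv(mm$topTfs, tFile)
          note("match", c(mFile, tFile))

          if (nrow(mm$matches)) {
            net <- assembleNetwork(mm$matches, instances, de)
            pr <- pageRank(net)
            core <- topCoreGenes(pr, net, n = 10)
            branch$network <- net
            branch$pagerank <- pr
            branch$coreGenes <- core
            sif <- file.path(outDir, sprintf("network_%s.sif", grp))
            nodes <- file.path(outDir, sprintf("nodes_%s.tsv", grp))
            exportNetwork(net, pr, sif, nodes)
            coreFile <- file.path(outDir, sprintf("coregenes_%s.tsv", grp))
            writeTsv(core, coreFile)
            note("network", c(sif, nodes, coreFile))
          }
        }
      }
    }
    branches[[grp]] <- branch
  }

  qpcrTabs <- lapply(names(cfg$qpcrFold), function(g)
    cbind(gene = g, qpcrReport(sim$qpcr, g, control)))
  qpcrTab <- do.call(rbind, qpcrTabs)
  qFile <- file.path(outDir, "qpcr_report.tsv")
  writeTsv(qpcrTab, qFile)
  note("qpcr", qFile)

  manifest <- do.call(rbind, manifest)
  writeTsv(manifest, file.path(outDir, "manifest.tsv"))
  list(sim = sim, branches = branches, qpcr = qpcrTab,
       manifest = manifest)
}
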