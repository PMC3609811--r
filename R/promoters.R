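#' Extract promoter sequences around annotated TSSs
#'
#' For a plus-strand gene the promoter is the genomic slice
#' `[TSS - upstream, TSS + downstream)`; for a minus-strand gene (TSS =
#' `end - 1` of its BED interval) it is `[TSS - downstream + 1,
#' TSS + upstream + 1)` reverse-complemented, so stored sequences always
#' read 5'->3' relative to the gene. Windows extending beyond a contig end
#' are clipped and the TSS offset adjusted.
#'
#' @param genome Named [Biostrings::DNAStringSet] of contigs.
#' @param genes BED-like data frame (chrom, start, end, gene_id, score,
#'   strand; 0-based half-open).
#' @param window `c(-upstream, +downstream)` in bp; default
#'   `c(-3000, 500)`.
#' @return A [PromoterSet-class].
#' @examples
#' sim <- simulateGenome(simConfig(nGenes = 10, seed = 1),
#'                       simulateExpression(simConfig(nGenes = 10,
#'                                                    seed = 1))$truth)
#' extractPromoters(sim$genome, sim$genes)
#' @export
extractPromoters <- function(genome, genes, window = c(-3000, 500)) {
  up <- -window[1]; down <- window[2]
  if (up < 0 || down < 0) stop("window must be c(-upstream, +downstream)")
  missingChrom <- setdiff(unique(genes$chrom), names(genome))
  if (length(missingChrom))
    stop("chromosomes absent from the genome: ",
         paste(missingChrom, collapse = ", "))
  n <- nrow(genes)
  seqs <- character(n)
  anno <- data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                     start = NA_integer_, end = NA_integer_,
                     strand = genes$strand, tss_offset = NA_integer_,
                     stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    L <- length(genome[[genes$chrom[i]]])
    if (genes$strand[i] == "+") {
      tss <- genes$start[i]                       # 0-based
      if (tss < 0 || tss >= L)
        stop(sprintf("TSS of gene %s outside contig %s",
                     genes$gene_id[i], genes$chrom[i]))
      s <- max(0L, tss - up); e <- min(L, tss + down)
      seqs[i] <- as.character(subseq(genome[[genes$chrom[i]]], s + 1L, e))
      anno$tss_offset[i] <- tss - s
    } else {
      tss <- genes$end[i] - 1L                    # 0-based, last base
      if (tss < 0 || tss >= L)
        stop(sprintf("TSS of gene %s outside contig %s",
                     genes$gene_id[i], genes$chrom[i]))
      s <- max(0L, tss - down + 1L); e <- min(L, tss + up + 1L)
      sl <- subseq(genome[[genes$chrom[i]]], s + 1L, e)
      seqs[i] <- as.character(reverseComplement(sl))
      ## after reverse complement, distance from the 5' end of the stored
      ## sequence to the TSS equals the clipped upstream extent
      anno$tss_offset[i] <- (e - 1L) - tss
    }
    anno$start[i] <- if (genes$strand[i] == "+") max(0L, tss - up) else s
    anno$end[i] <- if (genes$strand[i] == "+") min(L, tss + down) else e
  }
  PromoterSet(DNAStringSet(seqs), anno)
}

#' Select the negative promoter set
#'
#' Uniform random sample (without replacement) of non-differential genes
#' whose DE p-value is at least `pMin`, matched in size to the positive
#' set and disjoint from it.
#'
#' @param deTable Result of [callDE()] (needs gene_id, p_value, direction).
#' @param posIds Character vector: positive-set gene ids.
#' @param pMin Minimum p-value for eligibility (default 0.9,
#'   operationalising "p-value close to 1").
#' @param seed Integer seed for the reproducible draw.
#' @return Character vector of gene ids, `length(posIds)` long.
#' @export
selectNegativeSet <- function(deTable, posIds, pMin = 0.9, seed = 1) {
  if (pMin <= 0 || pMin >= 1) stop("pMin must lie in (0,1)")
  pool <- deTable$gene_id[deTable$p_value >= pMin &
                            deTable$direction == "none" &
                            !(deTable$gene_id %in% posIds)]
  if (length(pool) < length(posIds))
    stop(sprintf(paste("eligible pool (%d genes with p >= %g) smaller than",
                       "the positive set (%d); lower pMin"),
                 length(pool), pMin, length(posIds)))
  if (length(pool) == length(posIds)) return(sort(pool))
  withSeed(childSeed(seed, 7L), sort(sample(pool, length(posIds))))
}
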