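## Discriminative de-novo motif discovery on positive vs negative promoter
## sets. The objective is the log likelihood-score ratio: the mean best-site
## log-odds over positive promoters minus the same mean over negative
## promoters. Candidates are seeded from frequent w-mers and refined by a
## deterministic fixed-point iteration (best site per positive sequence ->
## rebuild PWM), with no unseeded randomness anywhere.

asSeqStrings <- function(x) {
  if (is(x, "PromoterSet")) {
    s <- as.character(promoterSeqs(x)); names(s) <- promoterAnno(x)$gene_id
  } else if (is(x, "DNAStringSet")) {
    s <- as.character(x)
    if (is.null(names(s))) names(s) <- paste0("seq", seq_along(s))
  } else {
    s <- as.character(x)
    if (!is.null(names(x))) names(s) <- names(x)
    if (is.null(names(s))) names(s) <- paste0("seq", seq_along(s))
  }
  out <- toupper(s)        # toupper drops names
  names(out) <- names(s)
  out
}

encodeSet <- function(x) lapply(asSeqStrings(x), encodeDNA)

#' Background base composition of a sequence collection
#'
#' Zero-order composition `f` of the pooled positive and negative promoter
#' sets; the reference distribution of the log-odds scores.
#'
#' @param ... Sequence collections ([PromoterSet-class], DNAStringSet or
#'   character vectors), pooled.
#' @return Named numeric vector (A,C,G,T) summing to 1.
#' @export
backgroundComposition <- function(...) {
  seqs <- unlist(lapply(list(...), asSeqStrings), use.names = FALSE)
  codes <- unlist(lapply(seqs, encodeDNA), use.names = FALSE)
  counts <- tabulate(codes, nbins = 4L)
  if (sum(counts) == 0) stop("no unambiguous bases in the input")
  f <- counts / sum(counts)
  if (any(f == 0)) {           # guard against absent bases in tiny toys
    f <- (counts + 1) / (sum(counts) + 4)
  }
  names(f) <- BASES
  f
}

## Probability PWM from site strings with pseudocount epsilon.
pwmFromSites <- function(sites, epsilon = 0.25) {
  codes <- lapply(sites, encodeDNA)
  w <- length(codes[[1L]])
  counts <- matrix(epsilon, nrow = 4L, ncol = w, dimnames = list(BASES, NULL))
  for (v in codes) counts[cbind(v, seq_len(w))] <-
    counts[cbind(v, seq_len(w))] + 1
  sweep(counts, 2L, colSums(counts), "/")
}

consensusOf <- function(pwm) paste(BASES[apply(pwm, 2L, which.max)],
                                   collapse = "")

#' Log-odds score of a single site against a PWM
#'
#' `sum_i log(pwm_i(site_i) / f(site_i))`, the per-site term of the
#' likelihood-score ratio.
#'
#' @param site Character string over A,C,G,T with `nchar(site) ==
#'   ncol(pwm)`.
#' @param pwm 4 x w probability matrix (rows A,C,G,T).
#' @param bg Background base probabilities (A,C,G,T).
#' @return Numeric log score.
#' @examples
#' pwm <- matrix(0.25, 4, 8, dimnames = list(c("A","C","G","T"), NULL))
#' siteLogOdds("ACGTACGT", pwm, rep(0.25, 4))  # 0: background motif
#' @export
siteLogOdds <- function(site, pwm, bg) {
  v <- encodeDNA(site)
  if (length(v) != ncol(pwm))
    stop("site length does not match PWM width")
  if (anyNA(v)) stop("site contains ambiguous bases")
  sum(log(pwm[cbind(v, seq_along(v))] / bg[v]))
}

## Score every offset of an encoded sequence against a log-odds matrix.
## Windows touching an ambiguous base score NA (skipped downstream).
scanScores <- function(enc, lom) {
  w <- ncol(lom)
  n <- length(enc) - w + 1L
  if (n < 1L) return(numeric(0))
  sc <- numeric(n)
  for (j in seq_len(w)) sc <- sc + lom[, j][enc[j:(j + n - 1L)]]
  sc
}

logOddsMatrix <- function(pwm, bg) log(sweep(pwm, 1L, bg, "/"))

## Best site of one encoded sequence. Ties: smallest forward offset
## across both strands, then '+' strand.
bestSiteEnc <- function(enc, lom, bothStrands = TRUE) {
  w <- ncol(lom); L <- length(enc)
  fw <- scanScores(enc, lom)
  if (!length(fw)) stop("sequence shorter than the PWM width")
  rv <- if (bothStrands) scanScores(revcompCode(enc), lom) else numeric(0)
  fwMax <- suppressWarnings(max(fw, na.rm = TRUE))
  rvMax <- if (length(rv)) suppressWarnings(max(rv, na.rm = TRUE)) else -Inf
  best <- max(fwMax, rvMax)
  if (!is.finite(best))
    stop("no scannable window (ambiguous bases throughout)")
  plusOff <- if (fwMax == best) which(fw == best) else integer(0)
  ## a reverse-scan offset r corresponds to forward offset L - w + 2 - r
  minusOff <- if (rvMax == best) L - w + 2L - which(rv == best)
              else integer(0)
  off <- min(c(plusOff, minusOff))
  strand <- if (off %in% plusOff) "+" else "-"
  list(offset = off, strand = strand, score = best)
}

#' Best-scoring site of a promoter under a PWM
#'
#' Scans every offset (and the reverse complement when `bothStrands`) and
#' returns the maximal [siteLogOdds()] site. Ties are broken by smallest
#' offset, then plus strand. Windows containing ambiguous bases are
#' skipped.
#'
#' @param seq Character string (promoter sequence).
#' @param pwm 4 x w probability matrix.
#' @param bg Background base probabilities.
#' @param bothStrands Scan the reverse complement too (default TRUE).
#' @return List with `offset` (1-based), `strand`, `score`.
#' @export
bestSite <- function(seq, pwm, bg, bothStrands = TRUE) {
  bestSiteEnc(encodeDNA(seq), logOddsMatrix(pwm, bg), bothStrands)
}

meanBest <- function(encs, lom, bothStrands) {
  mean(vapply(encs, function(e)
    bestSiteEnc(e, lom, bothStrands)$score, numeric(1)))
}

#' Discriminative score of a motif
#'
#' Mean best-site log-odds over the positive set minus the mean over the
#' negative set: the log of the ratio of per-set likelihood scores that
#' ranks discovered motifs.
#'
#' @param pwm 4 x w probability matrix.
#' @param pos,neg Sequence collections (PromoterSet / DNAStringSet /
#'   character).
#' @param bg Background base probabilities.
#' @param bothStrands Scan both strands (default TRUE).
#' @return Numeric log score ratio.
#' @export
discriminativeScore <- function(pwm, pos, neg, bg, bothStrands = TRUE) {
  posE <- encodeSet(pos); negE <- encodeSet(neg)
  if (!length(posE) || !length(negE))
    stop("positive and negative sets must be non-empty")
  lom <- logOddsMatrix(pwm, bg)
  meanBest(posE, lom, bothStrands) - meanBest(negE, lom, bothStrands)
}

## Site strings at given offsets/strands.
sitesAt <- function(seqs, hits, w) {
  vapply(seq_along(seqs), function(i) {
    s <- substr(seqs[[i]], hits$offset[i], hits$offset[i] + w - 1L)
    if (hits$strand[i] == "-") revcompString(s) else s
  }, character(1))
}

#' Refine a seed word into a motif by fixed-point iteration
#'
#' Starting from the PWM of the seed's exact occurrences in the positive
#' set, alternates (a) collecting the best site per positive sequence
#' under the current PWM with (b) rebuilding the PWM from those sites
#' (pseudocount `epsilon`), until the site set is unchanged, the
#' discriminative objective would decrease, or `maxIter` is reached. The
#' motif with the highest objective seen is returned, so the objective is
#' non-decreasing across accepted iterations by construction.
#'
#' @param seed Seed word (w-mer) occurring in at least one positive
#'   sequence.
#' @param pos,neg Sequence collections.
#' @param bg Background probabilities; computed from `pos` and `neg` when
#'   NULL.
#' @param epsilon PWM pseudocount (default 0.25).
#' @param maxIter Refinement iteration cap (default 50); 0 returns the
#'   seed-count motif unrefined.
#' @param bothStrands Scan both strands (default TRUE).
#' @return A [MotifModel-class].
#' @export
refineMotif <- function(seed, pos, neg, bg = NULL, epsilon = 0.25,
                        maxIter = 50, bothStrands = TRUE) {
  posS <- asSeqStrings(pos)
  negE <- encodeSet(neg)
  posE <- lapply(posS, encodeDNA)
  if (is.null(bg)) bg <- backgroundComposition(pos, neg)
  w <- nchar(seed)
  ## seed-count motif: exact occurrences of the seed (forward, plus the
  ## reverse complement when scanning both strands), one per sequence
  seedRc <- revcompString(seed)
  init <- character(0)
  for (s in posS) {
    if (grepl(seed, s, fixed = TRUE)) init <- c(init, seed)
    else if (bothStrands && grepl(seedRc, s, fixed = TRUE))
      init <- c(init, seed)
  }
  if (!length(init))
    stop("seed does not occur in any positive sequence")
  pwm <- pwmFromSites(init, epsilon)
  score <- discriminativeScore(pwm, posS, asSeqStrings(neg), bg,
                               bothStrands)
  hits <- NULL
  if (maxIter > 0) {
    prevKey <- ""
    for (it in seq_len(maxIter)) {
      lom <- logOddsMatrix(pwm, bg)
      bl <- lapply(posE, bestSiteEnc, lom = lom, bothStrands = bothStrands)
      newHits <- data.frame(
        offset = vapply(bl, `[[`, numeric(1), "offset"),
        strand = vapply(bl, `[[`, character(1), "strand"),
        stringsAsFactors = FALSE)
      key <- paste(newHits$offset, newHits$strand, collapse = ";")
      sites <- sitesAt(posS, newHits, w)
      newPwm <- pwmFromSites(sites, epsilon)
      newScore <- discriminativeScore(newPwm, posS, asSeqStrings(neg), bg,
                                      bothStrands)
      if (newScore < score - 1e-12) break
      pwm <- newPwm; score <- newScore; hits <- newHits
      if (key == prevKey) break
      prevKey <- key
    }
  }
  if (is.null(hits)) {
    lom <- logOddsMatrix(pwm, bg)
    bl <- lapply(posE, bestSiteEnc, lom = lom, bothStrands = bothStrands)
    hits <- data.frame(
      offset = vapply(bl, `[[`, numeric(1), "offset"),
      strand = vapply(bl, `[[`, character(1), "strand"),
      stringsAsFactors = FALSE)
  }
  inst <- S4Vectors::DataFrame(gene_id = names(posS),
                               offset = as.integer(hits$offset),
                               strand = hits$strand,
                               site = sitesAt(posS, hits, w))
  MotifModel(pwm, consensusOf(pwm), inst, score)
}

## TRUE when two consensus strings align (any offset shift, either
## orientation) with at least min(width) - 1 matching positions.
consensusDuplicate <- function(a, b) {
  dupOne <- function(a, b) {
    wa <- nchar(a); wb <- nchar(b)
    need <- min(wa, wb) - 1L
    av <- strsplit(a, "")[[1L]]; bv <- strsplit(b, "")[[1L]]
    for (shift in -(wb - 1L):(wa - 1L)) {
      ia <- max(1L, 1L + shift):min(wa, wb + shift)
      if (length(ia) < need) next
      ib <- ia - shift
      if (sum(av[ia] == bv[ib]) >= need) return(TRUE)
    }
    FALSE
  }
  dupOne(a, b) || dupOne(a, revcompString(b))
}

#' Discover discriminative motifs in positive vs negative promoters
#'
#' Seeds are the most frequent w-mers present in at least `qMin` of the
#' positive sequences (per width), each refined by [refineMotif()];
#' near-identical candidates (consensus alignment with >= w-1 matches in
#' either orientation) are collapsed, and the survivors are ranked by
#' descending discriminative score across all widths (ties by consensus)
#' with the first `topN` returned.
#'
#' @param pos,neg Sequence collections (PromoterSet / DNAStringSet /
#'   character).
#' @param widths Motif widths to search (default `c(8, 10, 12, 14)`).
#' @param topN Motifs to return (default 20).
#' @param epsilon PWM pseudocount (default 0.25).
#' @param qMin Minimum fraction of positive sequences a seed must occur in
#'   (default 0.2).
#' @param maxSeeds Seeds refined per width (default 500).
#' @param maxIter Refinement iteration cap (default 50).
#' @param bothStrands Scan both strands (default TRUE).
#' @param bg Background probabilities; pooled composition of `pos` and
#'   `neg` when NULL.
#' @return List of [MotifModel-class], ranked; empty (with a warning) when
#'   no seed passes the frequency filter.
#' @examples
#' pos <- paste0(strrep("A", 10), "TGACGTCATG", strrep("C", 10))
#' neg <- strrep("ACGT", 8)
#' m <- discoverMotifs(rep(pos, 4), rep(neg, 4), widths = 10, topN = 3)
#' motifConsensus(m[[1]])
#' @export
discoverMotifs <- function(pos, neg, widths = c(8, 10, 12, 14),
                           topN = 20, epsilon = 0.25, qMin = 0.2,
                           maxSeeds = 500, maxIter = 50,
                           bothStrands = TRUE, bg = NULL) {
  posS <- asSeqStrings(pos); negS <- asSeqStrings(neg)
  if (!length(posS) || !length(negS))
    stop("positive and negative sets must be non-empty")
  if (is.null(bg)) bg <- backgroundComposition(posS, negS)
  cands <- list()
  for (w in widths) {
    ## per-sequence presence counts of every clean w-mer
    perSeq <- lapply(posS, function(s) {
      L <- nchar(s)
      if (L < w) return(character(0))
      km <- substring(s, 1:(L - w + 1L), w:L)
      unique(km[!grepl("[^ACGT]", km)])
    })
    tab <- table(unlist(perSeq, use.names = FALSE))
    minCount <- max(1, ceiling(qMin * length(posS)))
    tab <- tab[tab >= minCount]
    if (!length(tab)) next
    ord <- order(-as.integer(tab), names(tab))
    seeds <- head(names(tab)[ord], maxSeeds)
    for (sd in seeds)
      cands[[length(cands) + 1L]] <-
        refineMotif(sd, posS, negS, bg, epsilon, maxIter, bothStrands)
  }
  if (!length(cands)) {
    warning("no seed passed the positive-set frequency filter")
    return(list())
  }
  scores <- vapply(cands, motifScore, numeric(1))
  cons <- vapply(cands, motifConsensus, character(1))
  ord <- order(-scores, cons)
  kept <- list()
  for (i in ord) {
    dup <- FALSE
    for (k in kept)
      if (consensusDuplicate(cons[i], motifConsensus(k))) { dup <- TRUE; break }
    if (!dup) kept[[length(kept) + 1L]] <- cands[[i]]
    if (length(kept) >= topN) break
  }
  kept
}

#' Summary table of discovered motifs
#'
#' @param motifs List of [MotifModel-class] from [discoverMotifs()].
#' @return Data frame: motif_id, consensus, width, score, score_per_base,
#'   n_sites.
#' @export
motifReport <- function(motifs) {
  data.frame(
    motif_id = sprintf("M%03d", seq_along(motifs)),
    consensus = vapply(motifs, motifConsensus, character(1)),
    width = vapply(motifs, motifWidth, integer(1)),
    score = vapply(motifs, motifScore, numeric(1)),
    score_per_base = vapply(motifs, function(m)
      motifScore(m) / motifWidth(m), numeric(1)),
    n_sites = vapply(motifs, function(m) nrow(motifInstances(m)),
                     integer(1)),
    stringsAsFactors = FALSE)
}
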