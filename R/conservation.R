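## Per-position conservation scoring of promoter alignment blocks with a
## two-state (conserved / non-conserved) hidden Markov model. Emissions are
## binomial in the number of non-reference species matching the reference
## base per column; the posterior probability of the conserved state is the
## per-position score in [0,1] (1 = most conserved), computed by
## forward-backward in log space.

#' Parameters of the two-state conservation HMM
#'
#' @param pStayCons,pStayNon Self-transition probabilities of the
#'   conserved and non-conserved states (defaults 0.99).
#' @param eCons,eNon Per-species probabilities of matching the reference
#'   base under each state; `eCons > eNon` (defaults 0.9 / 0.4).
#' @param pi Initial state distribution `c(cons, non)`; defaults to the
#'   stationary distribution of the transition matrix.
#' @return Validated parameter list.
#' @export
hmmParams <- function(pStayCons = 0.99, pStayNon = 0.99, eCons = 0.9,
                      eNon = 0.4, pi = NULL) {
  ps <- c(pStayCons, pStayNon, eCons, eNon)
  if (any(ps <= 0) || any(ps >= 1))
    stop("all HMM probabilities must lie in (0,1)")
  if (eCons <= eNon) stop("eCons must exceed eNon")
  if (is.null(pi)) {
    ## stationary distribution of [[p_cc, 1-p_cc], [1-p_nn, p_nn]]
    piCons <- (1 - pStayNon) / ((1 - pStayCons) + (1 - pStayNon))
    pi <- c(piCons, 1 - piCons)
  }
  if (length(pi) != 2L || any(pi <= 0) || abs(sum(pi) - 1) > 1e-9)
    stop("pi must be two positive probabilities summing to 1")
  list(pStayCons = pStayCons, pStayNon = pStayNon, eCons = eCons,
       eNon = eNon, pi = pi)
}

#' Per-column reference-match counts of an alignment block
#'
#' @param block DNAStringSet (or character vector) with the reference row
#'   first; all rows equal length, no indels.
#' @return List with `m` (integer; species matching the reference per
#'   column, NA where the column holds a gap or ambiguous base), `S`
#'   (number of non-reference rows) and `L` (columns).
#' @export
alignmentMatchCounts <- function(block) {
  rows <- toupper(as.character(block))
  if (length(rows) < 2L)
    stop("an alignment block needs a reference row plus >= 1 species")
  L <- unique(nchar(rows))
  if (length(L) != 1L) stop("alignment rows differ in length")
  mat <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  ok <- mat %in% BASES
  dim(ok) <- dim(mat)
  missing <- !apply(ok, 2L, all)
  S <- nrow(mat) - 1L
  m <- colSums(mat[-1L, , drop = FALSE] ==
               matrix(mat[1L, ], nrow = S, ncol = L, byrow = TRUE))
  m[missing] <- NA_integer_
  list(m = as.integer(m), S = S, L = L)
}

#' Column likelihoods under the conserved and non-conserved states
#'
#' `P(m_j | state) = Binomial(S, e_state)` mass at `m_j`; missing columns
#' (gap or ambiguous base) emit likelihood 1 under both states so they are
#' uninformative.
#'
#' @param m Integer vector of per-column match counts (NA = missing).
#' @param S Number of species rows.
#' @param params [hmmParams()] list.
#' @return 2 x L matrix of likelihoods (rows: conserved, non-conserved).
#' @export
columnEmissions <- function(m, S, params) {
  if (any(m > S, na.rm = TRUE)) stop("match count exceeds species count")
  if (any(m < 0, na.rm = TRUE)) stop("negative match count")
  e <- rbind(cons = dbinom(m, S, params$eCons),
             non = dbinom(m, S, params$eNon))
  e[, is.na(m)] <- 1
  e
}

#' Posterior conservation track of an alignment block
#'
#' Forward-backward posterior probability of the conserved state per
#' column, computed in log space.
#'
#' @param block Alignment block (reference row first).
#' @param params [hmmParams()] list.
#' @return Numeric vector in [0,1], one score per column.
#' @examples
#' b <- c(ref = "ACGTAC", sp1 = "ACGTAC", sp2 = "ACGTAC")
#' range(posteriorTrack(b, hmmParams()))
#' @export
posteriorTrack <- function(block, params = hmmParams()) {
  mc <- alignmentMatchCounts(block)
  em <- columnEmissions(mc$m, mc$S, params)
  forwardBackward(em, params)
}

## Log-space forward-backward on a 2 x L emission matrix (rows: conserved,
## non-conserved); returns the conserved-state posterior per column.
forwardBackward <- function(em, params) {
  logEm <- log(em)
  L <- ncol(em)
  logT <- log(matrix(c(params$pStayCons, 1 - params$pStayCons,
                       1 - params$pStayNon, params$pStayNon),
                     nrow = 2L, byrow = TRUE))   # [from, to]
  logSumExp <- function(x) {
    mx <- max(x)
    if (!is.finite(mx)) return(mx)
    mx + log(sum(exp(x - mx)))
  }
  fwd <- matrix(-Inf, 2L, L)
  fwd[, 1L] <- log(params$pi) + logEm[, 1L]
  for (j in seq_len(L - 1L) + 1L)
    for (s in 1:2)
      fwd[s, j] <- logSumExp(fwd[, j - 1L] + logT[, s]) + logEm[s, j]
  bwd <- matrix(0, 2L, L)
  if (L > 1L)
    for (j in rev(seq_len(L - 1L)))
      for (s in 1:2)
        bwd[s, j] <- logSumExp(logT[s, ] + logEm[, j + 1L] + bwd[, j + 1L])
  post <- fwd + bwd
  norm <- apply(post, 2L, logSumExp)
  exp(post[1L, ] - norm)
}

#' Mean conservation score over an interval
#'
#' @param track Numeric conservation track.
#' @param interval `c(start, end)`, 1-based inclusive.
#' @return Arithmetic mean of the per-position scores.
#' @export
meanScore <- function(track, interval) {
  s <- interval[1]; e <- interval[2]
  if (s > e || s < 1 || e > length(track))
    stop("interval outside the track (or empty)")
  mean(track[s:e])
}

#' Filter motif instances by conservation
#'
#' Keeps an instance iff the mean (or minimum) posterior conservation over
#' its promoter interval is at least `threshold` (inclusive).
#'
#' @param instances Data frame / DataFrame with columns `gene_id`,
#'   `offset` (1-based), plus any others; widths taken from `width` or
#'   `nchar(site)`.
#' @param tracks Named list of conservation tracks (names = gene ids).
#' @param threshold Minimum score (default 0.8).
#' @param stat "mean" (default) or "min" per-base statistic.
#' @return The filtered instance table with a `cons_score` column.
#' @export
filterConserved <- function(instances, tracks, threshold = 0.8,
                            stat = c("mean", "min")) {
  stat <- match.arg(stat)
  instances <- as.data.frame(instances)
  if (!nrow(instances)) {
    instances$cons_score <- numeric(0)
    return(instances)
  }
  w <- if ("width" %in% names(instances)) instances$width
       else nchar(instances$site)
  score <- vapply(seq_len(nrow(instances)), function(i) {
    tr <- tracks[[instances$gene_id[i]]]
    if (is.null(tr))
      stop(sprintf("no conservation track for gene %s",
                   instances$gene_id[i]))
    idx <- instances$offset[i]:(instances$offset[i] + w[i] - 1L)
    if (max(idx) > length(tr))
      stop(sprintf("instance of gene %s extends beyond its track",
                   instances$gene_id[i]))
    if (stat == "mean") mean(tr[idx]) else min(tr[idx])
  }, numeric(1))
  instances$cons_score <- score
  instances[score >= threshold, , drop = FALSE]
}

#' Conservation tracks for a list of alignment blocks
#'
#' @param blocks Named list of alignment blocks.
#' @param params [hmmParams()] list.
#' @return Named list of numeric tracks.
#' @export
conservationTracks <- function(blocks, params = hmmParams()) {
  lapply(blocks, posteriorTrack, params = params)
}
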