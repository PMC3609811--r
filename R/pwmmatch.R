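## Comparison of discovered motifs against a TF PWM database: ungapped
## sliding alignment scored by the mean per-column Pearson correlation
## (both orientations), with an empirical column-shuffle null for the
## similarity p-value. Matches at p <= pMax are kept and the best TFs per
## comparison reported.

## Counts (or probabilities) -> probability PWM with pseudocount.
asProbPwm <- function(m, pseudocount = 0.25) {
  m <- as.matrix(m)
  if (nrow(m) != 4L) stop("a PWM needs 4 rows (A,C,G,T)")
  rownames(m) <- BASES
  if (all(abs(colSums(m) - 1) < 1e-9)) return(m)
  sweep(m + pseudocount, 2L, colSums(m + pseudocount), "/")
}

## Reverse complement of a PWM: reverse columns, swap A<->T and C<->G.
revcompPwm <- function(m) m[4:1, rev(seq_len(ncol(m))), drop = FALSE]

## Pearson correlation between paired columns of two 4 x n matrices;
## zero-variance columns score 0.
colCor <- function(A, B) {
  Ac <- sweep(A, 2L, colMeans(A))
  Bc <- sweep(B, 2L, colMeans(B))
  sa <- colSums(Ac^2); sb <- colSums(Bc^2)
  r <- numeric(ncol(A))
  ok <- sa > 0 & sb > 0
  r[ok] <- colSums(Ac[, ok, drop = FALSE] * Bc[, ok, drop = FALSE]) /
    sqrt(sa[ok] * sb[ok])
  r
}

#' Similarity between two PWMs
#'
#' Maximal mean per-aligned-column Pearson correlation over all ungapped
#' offsets with full overlap of the shorter matrix, in both orientations
#' (the second matrix is also compared reverse-complemented). Ties are
#' broken by smallest offset, then + orientation.
#'
#' @param a,b PWMs: 4 x w matrices of counts or probabilities (rows
#'   A,C,G,T), both widths >= 4.
#' @return List with `similarity` (in [-1,1]), `offset` (0-based shift of
#'   the shorter matrix along the longer) and `orientation` ("+"/"-").
#' @examples
#' db <- simulatePwmDb(simConfig(seed = 1))
#' pwmSimilarity(db[[1]], db[[1]])$similarity  # self-match: 1
#' @export
pwmSimilarity <- function(a, b) {
  a <- asProbPwm(a); b <- asProbPwm(b)
  if (ncol(a) < 4L || ncol(b) < 4L) stop("PWM widths must be >= 4")
  best <- list(similarity = -Inf, offset = NA_integer_, orientation = NA)
  for (ori in c("+", "-")) {
    bb <- if (ori == "+") b else revcompPwm(b)
    wa <- ncol(a); wb <- ncol(bb)
    short <- if (wa <= wb) a else bb
    long <- if (wa <= wb) bb else a
    ws <- ncol(short); wl <- ncol(long)
    for (off in 0:(wl - ws)) {
      sim <- mean(colCor(short, long[, (off + 1L):(off + ws), drop = FALSE]))
      if (sim > best$similarity + 1e-15)
        best <- list(similarity = sim, offset = off, orientation = ori)
    }
  }
  best
}

#' Empirical null distribution of PWM similarity at a given width
#'
#' Draws `nNull` random query PWMs of `width` columns sampled uniformly
#' (with replacement) from the pool of all database columns and scores
#' each, column-wise, against a random same-width contiguous segment of a
#' random database record. Seeded and fully reproducible.
#'
#' @param width Number of columns of the (shorter) query motif.
#' @param db Named list of database PWMs (counts or probabilities).
#' @param nNull Null sample size (default 200000).
#' @param seed Integer seed.
#' @return Sorted numeric vector of null similarity scores.
#' @export
similarityNull <- function(width, db, nNull = 200000, seed = 1) {
  if (!length(db)) stop("empty PWM database")
  probs <- lapply(db, asProbPwm)
  pool <- do.call(cbind, probs)
  widths <- vapply(probs, ncol, integer(1))
  wide <- which(widths >= width)
  if (!length(wide))
    stop("no database record is at least as wide as the query motif")
  withSeed(childSeed(seed, 11L), {
    out <- numeric(nNull)
    chunk <- 50000L
    done <- 0L
    while (done < nNull) {
      nc <- min(chunk, nNull - done)
      qIdx <- sample.int(ncol(pool), nc * width, replace = TRUE)
      rec <- wide[sample.int(length(wide), nc, replace = TRUE)]
      segStart <- vapply(rec, function(r)
        sample.int(widths[r] - width + 1L, 1L), integer(1))
      segCols <- unlist(lapply(seq_len(nc), function(i) {
        base <- if (rec[i] == 1L) 0L else sum(widths[seq_len(rec[i] - 1L)])
        base + segStart[i] - 1L + seq_len(width)
      }), use.names = FALSE)
      r <- colCor(pool[, qIdx, drop = FALSE],
                  pool[, segCols, drop = FALSE])
      out[done + seq_len(nc)] <-
        colMeans(matrix(r, nrow = width))
      done <- done + nc
    }
    sort(out)
  })
}

#' Empirical p-value of a PWM similarity score
#'
#' `p = (1 + #\{null >= similarity\}) / (1 + nNull)`; the attainable floor
#' is `1/(nNull + 1)`, never 0.
#'
#' @param similarity Observed similarity score.
#' @param null Sorted null scores from [similarityNull()] (or a width, in
#'   which case `db`, `nNull`, `seed` are used to build it).
#' @param db,nNull,seed Used only when `null` is a width.
#' @return Numeric p-value in (0,1].
#' @export
similarityPvalue <- function(similarity, null, db = NULL, nNull = 200000,
                             seed = 1) {
  if (length(null) == 1L && !is.null(db))
    null <- similarityNull(null, db, nNull, seed)
  n <- length(null)
  ge <- n - findInterval(similarity - 1e-15, null)
  (1 + ge) / (1 + n)
}

#' Match discovered motifs against a TF PWM database
#'
#' Computes the similarity and empirical p-value of every (motif, TF)
#' pair, keeps pairs with `p <= pMax` (inclusive), retains each TF's best
#' p, and returns the TFs ranked by ascending p (ties: descending
#' similarity, then name), the first `topTfs` of them.
#'
#' @param motifs List of [MotifModel-class] (or named list of PWMs).
#' @param db Named list of database PWMs.
#' @param pMax Maximum similarity p-value (default 1e-4).
#' @param topTfs TFs reported (default 5).
#' @param nNull Null sample size; must satisfy `nNull >= 10/pMax` so the
#'   p-value floor lies below `pMax`.
#' @param seed Integer seed for the null.
#' @return List with `matches` (all passing pairs: motif_id, tf,
#'   similarity, offset, orientation, p_value), `topTfs` (ranked TF
#'   table), and `all` (every scored pair, for diagnostics).
#' @export
matchDatabase <- function(motifs, db, pMax = 1e-4, topTfs = 5,
                          nNull = 200000, seed = 1) {
  if (!length(db)) stop("empty PWM database")
  if (!length(motifs)) stop("no motifs to match")
  if (nNull < 10 / pMax)
    stop("nNull too small: need nNull >= 10/pMax so the empirical floor ",
         "1/(nNull+1) lies below pMax")
  pwms <- lapply(motifs, function(m)
    if (is(m, "MotifModel")) motifPwm(m) else asProbPwm(m))
  ids <- if (!is.null(names(motifs))) names(motifs)
         else sprintf("M%03d", seq_along(motifs))
  widths <- vapply(pwms, ncol, integer(1))
  dbW <- vapply(db, function(m) ncol(as.matrix(m)), integer(1))
  nulls <- list()
  rows <- list()
  for (i in seq_along(pwms)) {
    for (j in seq_along(db)) {
      shorter <- min(widths[i], dbW[j])
      key <- as.character(shorter)
      if (is.null(nulls[[key]]))
        nulls[[key]] <- similarityNull(shorter, db, nNull, seed)
      s <- pwmSimilarity(pwms[[i]], db[[j]])
      p <- similarityPvalue(s$similarity, nulls[[key]])
      rows[[length(rows) + 1L]] <- data.frame(
        motif_id = ids[i], tf = names(db)[j], similarity = s$similarity,
        offset = s$offset, orientation = s$orientation, p_value = p,
        stringsAsFactors = FALSE)
    }
  }
  all <- do.call(rbind, rows)
  matches <- all[all$p_value <= pMax, , drop = FALSE]
  top <- data.frame(tf = character(), p_value = numeric(),
                    similarity = numeric(), stringsAsFactors = FALSE)
  if (nrow(matches)) {
    byTf <- split(matches, matches$tf)
    top <- do.call(rbind, lapply(byTf, function(d)
      d[order(d$p_value, -d$similarity)[1L],
        c("tf", "p_value", "similarity", "motif_id")]))
    top <- top[order(top$p_value, -top$similarity, top$tf), , drop = FALSE]
    rownames(top) <- NULL
    top <- head(top, topTfs)
  }
  list(matches = matches, topTfs = top, all = all)
}
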