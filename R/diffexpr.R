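#' Per-gene group mean intensities
#'
#' Arithmetic mean of the raw (linear-scale) fluorescence intensities over
#' the samples of one group.
#'
#' @param se SummarizedExperiment with assay `intensity` and
#'   `colData$group`.
#' @param group Group label.
#' @return Named numeric vector, one mean per gene.
#' @examples
#' sim <- simulateExpression(simConfig(nGenes = 10, seed = 1))
#' head(groupMeans(sim$se, "control"))
#' @export
groupMeans <- function(se, group) {
  sel <- colData(se)$group == group
  if (!any(sel)) stop(sprintf("unknown group label '%s'", group))
  m <- assay(se, "intensity")[, sel, drop = FALSE]
  rowMeans(m)
}

## Vectorised two-sided Welch t-test on log2 intensities.
## Degenerate genes (zero variance in both groups): p = 1 if the means are
## equal, p = 0 otherwise, so the ratio threshold alone decides the call.
welchP <- function(xa, xb) {
  na <- ncol(xa); nb <- ncol(xb)
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  va <- apply(xa, 1L, stats::var); vb <- apply(xb, 1L, stats::var)
  sem2 <- va / na + vb / nb
  tstat <- (ma - mb) / sqrt(sem2)
  df <- sem2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * pt(-abs(tstat), df)
  degen <- sem2 == 0
  p[degen] <- ifelse(abs(ma[degen] - mb[degen]) < .Machine$double.eps^0.5,
                     1, 0)
  p
}

#' Per-gene two-sided p-values between two groups
#'
#' Welch's unequal-variance t-test on log2-transformed intensities.
#'
#' @param se SummarizedExperiment (assay `intensity`, `colData$group`).
#' @param groupA,groupB Group labels; both need at least two samples.
#' @return Named numeric vector of p-values in [0,1].
#' @export
testPerGene <- function(se, groupA, groupB) {
  grp <- colData(se)$group
  selA <- grp == groupA; selB <- grp == groupB
  if (!any(selA)) stop(sprintf("unknown group label '%s'", groupA))
  if (!any(selB)) stop(sprintf("unknown group label '%s'", groupB))
  if (sum(selA) < 2 || sum(selB) < 2)
    stop("both groups need at least 2 replicates for the t-test")
  m <- assay(se, "intensity")
  if (any(m <= 0)) stop("intensities must be strictly positive")
  lm2 <- log2(m)
  welchP(lm2[, selA, drop = FALSE], lm2[, selB, drop = FALSE])
}

#' Call differentially expressed genes by signal ratio and significance
#'
#' A gene is called up-regulated when its experimental/control mean
#' intensity ratio is `>= ratioHigh` (inclusive) and its Welch p-value is
#' below `alpha`; down-regulated when the ratio is `<= ratioLow`
#' (inclusive) with p below `alpha`. No multiple-testing correction is
#' applied to the calls; a BH-adjusted column is reported alongside.
#'
#' @param se SummarizedExperiment (assay `intensity`, `colData$group`).
#' @param experimental,control Group labels.
#' @param ratioLow,ratioHigh Signal-ratio thresholds (defaults 0.67 / 1.5).
#' @param alpha Significance level (default 0.05).
#' @return Data frame with one row per gene: gene_id, mean_exp, mean_ctl,
#'   ratio, p_value, p_adj, direction ("up"/"down"/"none"); attribute
#'   `summary` holds c(total, up, down).
#' @examples
#' sim <- simulateExpression(simConfig(nGenes = 50, seed = 1))
#' de <- callDE(sim$se, "stress7", "control")
#' attr(de, "summary")
#' @export
callDE <- function(se, experimental, control, ratioLow = 0.67,
                   ratioHigh = 1.5, alpha = 0.05) {
  if (!(ratioLow > 0 && ratioLow < 1 && ratioHigh > 1))
    stop("need 0 < ratioLow < 1 < ratioHigh")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0,1)")
  meanExp <- groupMeans(se, experimental)
  meanCtl <- groupMeans(se, control)
  ratio <- meanExp / meanCtl
  p <- testPerGene(se, experimental, control)
  direction <- rep("none", length(ratio))
  direction[ratio >= ratioHigh & p < alpha] <- "up"
  direction[ratio <= ratioLow & p < alpha] <- "down"
  res <- data.frame(gene_id = rownames(se), mean_exp = meanExp,
                    mean_ctl = meanCtl, ratio = ratio, p_value = p,
                    p_adj = p.adjust(p, "BH"), direction = direction,
                    row.names = NULL, stringsAsFactors = FALSE)
  up <- sum(direction == "up"); down <- sum(direction == "down")
  attr(res, "summary") <- c(total = up + down, up = up, down = down)
  res
}

#' Write a DE result table with its summary line
#' @param de Result of [callDE()].
#' @param file Path.
#' @export
writeDeTable <- function(de, file) {
  writeTsv(de, file)
  s <- attr(de, "summary")
  cat(sprintf("# total/up/down\t%d/%d/%d\n", s["total"], s["up"],
              s["down"]), file = paste0(file, ".summary"))
  invisible(file)
}
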