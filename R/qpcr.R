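#' Relative quantification by the 2^-ddCt method
#'
#' Per sample, dCt = Ct(target) - Ct(reference); ddCt = dCt minus the mean
#' control-group dCt (the calibrator); RQ = 2^-ddCt. Group summaries report
#' mean and sample standard deviation (n-1) of RQ, and the ratio of each
#' group's mean RQ to the control mean RQ (the control ratio is exactly 1
#' by construction).
#'
#' @param records qPCR table (sample, group, gene, ct_target,
#'   ct_reference), e.g. from [simulateQpcr()].
#' @param gene Gene to quantify.
#' @param controlGroup Calibrator group label.
#' @return List with `samples` (per-sample dCt, ddCt, RQ) and `groups`
#'   (group, n, mean_rq, sd_rq, ratio).
#' @examples
#' ct <- simulateQpcr(simConfig(qpcrNoiseSd = 0, seed = 1))
#' relativeQuantity(ct, "Fadd", "control")$groups
#' @export
relativeQuantity <- function(records, gene, controlGroup) {
  d <- records[records$gene == gene, , drop = FALSE]
  if (!nrow(d)) stop(sprintf("gene '%s' absent from the Ct table", gene))
  if (!any(d$group == controlGroup))
    stop(sprintf("control group '%s' absent for gene %s", controlGroup,
                 gene))
  ct <- c(d$ct_target, d$ct_reference)
  if (any(!is.finite(ct))) stop("non-finite Ct values")
  if (any(ct < 10 | ct > 40))
    warning("Ct values outside the typical 10-40 cycle range")
  d$dct <- d$ct_target - d$ct_reference
  calibrator <- mean(d$dct[d$group == controlGroup])
  d$ddct <- d$dct - calibrator
  d$rq <- 2^(-d$ddct)
  grps <- unique(d$group)
  ctlMean <- mean(d$rq[d$group == controlGroup])
  groups <- data.frame(
    group = grps,
    n = vapply(grps, function(g) sum(d$group == g), integer(1)),
    mean_rq = vapply(grps, function(g) mean(d$rq[d$group == g]),
                     numeric(1)),
    sd_rq = vapply(grps, function(g) sd(d$rq[d$group == g]), numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  groups$ratio <- groups$mean_rq / ctlMean
  list(samples = d, groups = groups, gene = gene,
       controlGroup = controlGroup)
}

#' Significance of each group versus control
#'
#' Two-sided Welch t-test of per-sample RQ values (or ddCt values with
#' `onDdct = TRUE`) against the control group, flagged at the 0.05 (`*`)
#' and 0.01 (`**`) levels.
#'
#' @param rel Result of [relativeQuantity()].
#' @param alphas Flag levels (default `c(0.05, 0.01)`).
#' @param onDdct Test on the ddCt scale instead of RQ.
#' @return Data frame: group, p_value, stars.
#' @export
compareToControl <- function(rel, alphas = c(0.05, 0.01), onDdct = FALSE) {
  d <- rel$samples
  val <- if (onDdct) d$ddct else d$rq
  ctl <- val[d$group == rel$controlGroup]
  grps <- unique(d$group)
  if (any(vapply(grps, function(g) sum(d$group == g), integer(1)) < 2))
    stop("every group needs >= 2 samples for the t-test")
  res <- data.frame(group = grps, p_value = NA_real_, stars = "",
                    stringsAsFactors = FALSE)
  for (i in seq_along(grps)) {
    if (grps[i] == rel$controlGroup) { res$p_value[i] <- 1; next }
    x <- val[d$group == grps[i]]
    p <- tryCatch(stats::t.test(x, ctl)$p.value, error = function(e) 1)
    res$p_value[i] <- p
    res$stars[i] <- if (p < min(alphas)) "**"
                    else if (p < max(alphas)) "*" else ""
  }
  res
}

#' Report table of a qPCR quantification
#'
#' One row per group: n, `mean +/- SD` of RQ, the group/control ratio and
#' the significance stars.
#'
#' @param records qPCR Ct table.
#' @param gene Gene to quantify.
#' @param controlGroup Calibrator group.
#' @return Data frame: group, n, rq (formatted mean+/-SD), ratio, stars.
#' @export
qpcrReport <- function(records, gene, controlGroup) {
  rel <- relativeQuantity(records, gene, controlGroup)
  sig <- compareToControl(rel)
  g <- rel$groups
  g$stars <- sig$stars[match(g$group, sig$group)]
  data.frame(group = g$group, n = g$n,
             rq = sprintf("%.2f±%.2f", g$mean_rq, g$sd_rq),
             ratio = round(g$ratio, 2), stars = g$stars,
             stringsAsFactors = FALSE)
}
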