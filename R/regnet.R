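#' Assemble the TF -> target regulation network
#'
#' Creates a directed edge TF -> gene for every surviving (conserved,
#' database-matched) motif instance: each TF matched to a motif is
#' connected to every gene in which that motif has a surviving instance.
#' Multi-edges are collapsed; target nodes carry the up/down regulation
#' direction from the DE table.
#'
#' @param matches Match table from [matchDatabase()] (`$matches`): columns
#'   motif_id, tf.
#' @param instanceMap Named list: motif_id -> data frame of surviving
#'   instances (needs `gene_id`), e.g. the output of [filterConserved()]
#'   per motif.
#' @param deTable Result of [callDE()]; every instance gene must appear.
#' @param damping,tol,maxIter PageRank parameters stored on the network.
#' @return A [RegNetwork-class].
#' @export
assembleNetwork <- function(matches, instanceMap, deTable,
                            damping = 0.85, tol = 1e-10, maxIter = 200L) {
  edges <- data.frame(tf = character(), target = character(),
                      stringsAsFactors = FALSE)
  if (nrow(matches)) {
    rows <- list()
    for (i in seq_len(nrow(matches))) {
      inst <- instanceMap[[matches$motif_id[i]]]
      if (is.null(inst) || !nrow(inst)) next
      rows[[length(rows) + 1L]] <- data.frame(
        tf = matches$tf[i], target = unique(inst$gene_id),
        stringsAsFactors = FALSE)
    }
    if (length(rows)) {
      edges <- unique(do.call(rbind, rows))
      edges <- edges[order(edges$tf, edges$target), , drop = FALSE]
      rownames(edges) <- NULL
    }
  }
  targets <- unique(edges$target)
  unknown <- setdiff(targets, deTable$gene_id)
  if (length(unknown))
    stop("instance gene(s) absent from the DE table: ",
         paste(unknown, collapse = ", "))
  tfs <- unique(edges$tf)
  reg <- deTable$direction[match(targets, deTable$gene_id)]
  mk <- function(ids, role, regulation) {
    if (!length(ids)) return(NULL)
    data.frame(id = ids, role = role, regulation = regulation,
               stringsAsFactors = FALSE)
  }
  both <- intersect(tfs, targets)
  parts <- list(mk(setdiff(tfs, targets), "TF", NA_character_),
                mk(both, "both", reg[match(both, targets)]),
                mk(setdiff(targets, tfs), "target",
                   reg[match(setdiff(targets, tfs), targets)]))
  nodes <- do.call(rbind, parts[!vapply(parts, is.null, logical(1))])
  if (is.null(nodes))
    nodes <- data.frame(id = character(), role = character(),
                        regulation = character(), stringsAsFactors = FALSE)
  nodes <- nodes[order(nodes$id), , drop = FALSE]
  rownames(nodes) <- NULL
  RegNetwork(nodes, edges, damping, tol, maxIter)
}

#' PageRank scores of a regulation network
#'
#' Power iteration on the column-stochastic transition matrix of the
#' directed TF -> target graph with uniform teleport (probability
#' `1 - damping`) and uniform redistribution of dangling-node mass;
#' converged when the L1 change falls below `tol`.
#'
#' @param net A [RegNetwork-class].
#' @return Named numeric vector of scores summing to 1.
#' @examples
#' nodes <- data.frame(id = c("A", "B"), role = c("TF", "target"),
#'                     regulation = c(NA, "up"))
#' edges <- data.frame(tf = "A", target = "B")
#' pageRank(RegNetwork(nodes, edges))
#' @export
pageRank <- function(net) {
  ids <- netNodes(net)$id
  n <- length(ids)
  if (n == 0L) stop("the network has no nodes")
  d <- net@damping
  e <- netEdges(net)
  from <- match(e$tf, ids); to <- match(e$target, ids)
  outDeg <- tabulate(from, nbins = n)
  x <- rep(1 / n, n)
  for (it in seq_len(net@maxIter)) {
    contrib <- ifelse(outDeg > 0, x / pmax(outDeg, 1L), 0)
    xNew <- numeric(n)
    if (length(from)) {
      agg <- rowsum(contrib[from], to)
      xNew[as.integer(rownames(agg))] <- agg[, 1L]
    }
    dangling <- sum(x[outDeg == 0L])
    xNew <- d * (xNew + dangling / n) + (1 - d) / n
    delta <- sum(abs(xNew - x))
    x <- xNew
    if (delta < net@tol) {
      names(x) <- ids
      return(x)
    }
  }
  stop(sprintf("PageRank did not converge in %d iterations (L1 residual %g)",
               net@maxIter, delta))
}

#' Top core genes of the network by PageRank
#'
#' Ranks nodes by descending PageRank (ties by name) and reports, for each
#' of the first `n`, its regulating TFs (in-neighbours) and its score to
#' six decimals. By default only target-role nodes are ranked; TFs are
#' listed in the `transcription_factor` column.
#'
#' @param scores Named score vector from [pageRank()].
#' @param net The [RegNetwork-class] the scores came from.
#' @param n Rows to report (default 10); the full list when the network is
#'   smaller.
#' @param includeTfs Rank TF-role nodes too (default FALSE).
#' @return Data frame: gene, transcription_factor (comma-separated),
#'   pagerank.
#' @export
topCoreGenes <- function(scores, net, n = 10, includeTfs = FALSE) {
  nodes <- netNodes(net)
  keep <- if (includeTfs) nodes$id else nodes$id[nodes$role != "TF"]
  s <- scores[keep]
  ord <- order(-s, names(s))
  sel <- head(ord, n)
  e <- netEdges(net)
  tfsOf <- function(g) paste(sort(unique(e$tf[e$target == g])),
                             collapse = ", ")
  data.frame(
    gene = names(s)[sel],
    transcription_factor = vapply(names(s)[sel], tfsOf, character(1)),
    pagerank = as.numeric(sprintf("%.6f", s[sel])),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Export a network as SIF + node attributes
#'
#' Writes a Cytoscape-loadable SIF edge list (`TF regulates target`) and a
#' node-attribute TSV (role, regulation, pagerank).
#'
#' @param net A [RegNetwork-class].
#' @param scores Named PageRank vector (optional; NA column when absent).
#' @param sifFile,nodeFile Output paths.
#' @return Invisibly, the two paths.
#' @export
exportNetwork <- function(net, scores = NULL, sifFile, nodeFile) {
  e <- netEdges(net)
  lines <- if (nrow(e)) sprintf("%s\tregulates\t%s", e$tf, e$target)
           else character(0)
  writeLines(lines, sifFile)
  nodes <- as.data.frame(netNodes(net))
  nodes$pagerank <- if (is.null(scores)) rep(NA_real_, nrow(nodes))
                    else unname(scores[nodes$id])
  writeTsv(nodes, nodeFile)
  invisible(c(sifFile, nodeFile))
}

#' Re-import a SIF edge list written by [exportNetwork()]
#' @param sifFile Path.
#' @return Data frame with columns tf, target.
#' @export
readNetworkSif <- function(sifFile) {
  lines <- readLines(sifFile)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(data.frame(tf = character(), target = character(),
                      stringsAsFactors = FALSE))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(tf = vapply(parts, `[`, character(1), 1L),
             target = vapply(parts, `[`, character(1), 3L),
             stringsAsFactors = FALSE)
}
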