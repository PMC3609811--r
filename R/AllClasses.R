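#' PromoterSet: strand-aware promoter sequences with genomic provenance
#'
#' Container for promoter sequences extracted around transcription start
#' sites. Sequences are stored 5'->3' relative to the gene (minus-strand
#' promoters are reverse-complemented at extraction time), together with the
#' genomic interval each sequence came from and the position of the TSS
#' within the sequence.
#'
#' @slot seqs A [Biostrings::DNAStringSet], one entry per gene.
#' @slot anno A [S4Vectors::DataFrame] with columns `gene_id`, `chrom`,
#'   `start`, `end` (0-based half-open genomic interval of the slice),
#'   `strand` and `tss_offset` (0-based position of the TSS within the
#'   stored sequence).
#'
#' @exportClass PromoterSet
setClass("PromoterSet",
  representation(seqs = "DNAStringSet", anno = "DataFrame"))

setValidity("PromoterSet", function(object) {
  msg <- NULL
  need <- c("gene_id", "chrom", "start", "end", "strand", "tss_offset")
  if (!all(need %in% colnames(object@anno)))
    msg <- c(msg, paste("anno must have columns:", paste(need, collapse = ", ")))
  else {
    if (nrow(object@anno) != length(object@seqs))
      msg <- c(msg, "anno rows must match number of sequences")
    if (!all(object@anno$strand %in% c("+", "-")))
      msg <- c(msg, "strand must be '+' or '-'")
    if (nrow(object@anno) &&
        !all(Biostrings::width(object@seqs) ==
             object@anno$end - object@anno$start))
      msg <- c(msg, "sequence widths must equal genomic interval lengths")
  }
  if (is.null(msg)) TRUE else msg
})

#' Construct a PromoterSet
#' @param seqs DNAStringSet of promoter sequences (gene orientation).
#' @param anno DataFrame of genomic provenance (see class docs).
#' @return A [PromoterSet-class] object.
#' @export
PromoterSet <- function(seqs, anno) {
  if (is.data.frame(anno)) anno <- S4Vectors::DataFrame(anno)
  names(seqs) <- anno$gene_id
  new("PromoterSet", seqs = seqs, anno = anno)
}

setMethod("show", "PromoterSet", function(object) {
  cat("PromoterSet with", length(object@seqs), "promoters\n")
  if (length(object@seqs)) {
    w <- range(Biostrings::width(object@seqs))
    cat("  widths:", w[1], "-", w[2], "bp;",
        sum(object@anno$strand == "-"), "on minus strand\n")
  }
})

#' @describeIn PromoterSet-class number of promoters
#' @param x,object A `PromoterSet`.
#' @export
setMethod("length", "PromoterSet", function(x) length(x@seqs))

#' Accessors for PromoterSet
#' @param x A [PromoterSet-class].
#' @return `promoterSeqs` returns the DNAStringSet; `promoterAnno` the
#'   annotation DataFrame.
#' @export
promoterSeqs <- function(x) x@seqs

#' @rdname promoterSeqs
#' @export
promoterAnno <- function(x) x@anno

#' Subset a PromoterSet by gene identifiers
#' @param x A PromoterSet.
#' @param i Character vector of gene ids or logical/integer index.
#' @param j,drop,... Ignored.
#' @export
setMethod("[", "PromoterSet", function(x, i, j, ..., drop = TRUE) {
  if (is.character(i)) i <- match(i, x@anno$gene_id)
  if (anyNA(i)) stop("unknown gene id in promoter subset")
  PromoterSet(x@seqs[i], x@anno[i, , drop = FALSE])
})

#' MotifModel: a position weight matrix with its supporting sites
#'
#' Result of discriminative motif discovery: a probability PWM (columns sum
#' to one), its consensus string, the best supporting site per positive
#' promoter, and the discriminative log likelihood-score ratio that ranked
#' it.
#'
#' @slot pwm 4 x w probability matrix, rows A,C,G,T.
#' @slot consensus Character; per-column argmax bases.
#' @slot instances DataFrame with columns `gene_id`, `offset` (1-based
#'   within the promoter, gene orientation), `strand`, `site`.
#' @slot score Numeric; discriminative score (mean positive best-site
#'   log-odds minus mean negative best-site log-odds).
#' @exportClass MotifModel
setClass("MotifModel",
  representation(pwm = "matrix", consensus = "character",
                 instances = "DataFrame", score = "numeric"))

setValidity("MotifModel", function(object) {
  msg <- NULL
  if (nrow(object@pwm) != 4L) msg <- c(msg, "pwm must have 4 rows (A,C,G,T)")
  if (any(abs(colSums(object@pwm) - 1) > 1e-9))
    msg <- c(msg, "pwm columns must sum to 1")
  if (nchar(object@consensus) != ncol(object@pwm))
    msg <- c(msg, "consensus length must equal pwm width")
  if (is.null(msg)) TRUE else msg
})

MotifModel <- function(pwm, consensus, instances, score) {
  if (is.data.frame(instances)) instances <- S4Vectors::DataFrame(instances)
  rownames(pwm) <- BASES
  new("MotifModel", pwm = pwm, consensus = consensus,
      instances = instances, score = score)
}

setMethod("show", "MotifModel", function(object) {
  cat(sprintf("MotifModel %s (w=%d, score=%.3f, %d sites)\n",
              object@consensus, ncol(object@pwm), object@score,
              nrow(object@instances)))
})

#' Accessors for MotifModel
#' @param x A [MotifModel-class].
#' @return `motifPwm`: probability matrix; `motifConsensus`: string;
#'   `motifScore`: discriminative score; `motifInstances`: site table;
#'   `motifWidth`: integer width.
#' @export
motifPwm <- function(x) x@pwm

#' @rdname motifPwm
#' @export
motifConsensus <- function(x) x@consensus

#' @rdname motifPwm
#' @export
motifScore <- function(x) x@score

#' @rdname motifPwm
#' @export
motifInstances <- function(x) x@instances

#' @rdname motifPwm
#' @export
motifWidth <- function(x) ncol(x@pwm)

#' RegNetwork: a directed TF -> target regulation network
#'
#' @slot nodes DataFrame with columns `id`, `role` ("TF", "target" or
#'   "both") and `regulation` ("up", "down" or NA for TFs).
#' @slot edges DataFrame with columns `tf`, `target`; deduplicated.
#' @slot damping PageRank damping factor in (0,1).
#' @slot tol L1 convergence tolerance of the power iteration.
#' @slot maxIter Iteration cap.
#' @exportClass RegNetwork
setClass("RegNetwork",
  representation(nodes = "DataFrame", edges = "DataFrame",
                 damping = "numeric", tol = "numeric", maxIter = "integer"))

setValidity("RegNetwork", function(object) {
  msg <- NULL
  if (!all(c("id", "role", "regulation") %in% colnames(object@nodes)))
    msg <- c(msg, "nodes needs columns id, role, regulation")
  if (!all(c("tf", "target") %in% colnames(object@edges)))
    msg <- c(msg, "edges needs columns tf, target")
  else {
    ids <- object@nodes$id
    if (!all(c(object@edges$tf, object@edges$target) %in% ids))
      msg <- c(msg, "every edge endpoint must be a node")
    if (anyDuplicated(paste(object@edges$tf, object@edges$target)))
      msg <- c(msg, "duplicate edges are not allowed")
  }
  if (object@damping <= 0 || object@damping >= 1)
    msg <- c(msg, "damping must lie in (0,1)")
  if (is.null(msg)) TRUE else msg
})

RegNetwork <- function(nodes, edges, damping = 0.85, tol = 1e-10,
                       maxIter = 200L) {
  if (is.data.frame(nodes)) nodes <- S4Vectors::DataFrame(nodes)
  if (is.data.frame(edges)) edges <- S4Vectors::DataFrame(edges)
  new("RegNetwork", nodes = nodes, edges = edges, damping = damping,
      tol = tol, maxIter = as.integer(maxIter))
}

setMethod("show", "RegNetwork", function(object) {
  cat(sprintf("RegNetwork: %d nodes (%d TFs), %d edges\n",
              nrow(object@nodes), sum(object@nodes$role != "target"),
              nrow(object@edges)))
})

#' Accessors for RegNetwork
#' @param x A [RegNetwork-class].
#' @return `netNodes` / `netEdges` return the node and edge DataFrames.
#' @export
netNodes <- function(x) x@nodes

#' @rdname netNodes
#' @export
netEdges <- function(x) x@edges
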