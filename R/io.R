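## Readers and writers for the plain-text interchange formats used by the
## pipeline: expression TSV + group sidecar, GMT gene sets, BED-like gene
## annotation, FASTA (via Biostrings), JASPAR-style PWM text, alignment
## blocks as per-promoter multi-FASTA, qPCR TSV.

#' Write / read an expression matrix as TSV with a group sidecar
#'
#' The main file has a `gene_id` column plus one column per sample; the
#' sidecar lists `sample` and `group`.
#'
#' @param se SummarizedExperiment with assay `intensity` and
#'   `colData$group`.
#' @param file,groupsFile Paths for the matrix and the sidecar.
#' @return `readExpressionTsv` returns a SummarizedExperiment.
#' @export
writeExpressionTsv <- function(se, file, groupsFile) {
  mat <- assay(se, "intensity")
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  writeTsv(df, file)
  writeTsv(data.frame(sample = colnames(mat),
                      group = colData(se)$group), groupsFile)
  invisible(c(file, groupsFile))
}

#' @rdname writeExpressionTsv
#' @export
readExpressionTsv <- function(file, groupsFile) {
  df <- readTsv(file)
  groups <- readTsv(groupsFile)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df$gene_id
  ord <- match(colnames(mat), groups$sample)
  if (anyNA(ord)) stop("group sidecar does not cover all samples")
  SummarizedExperiment(
    assays = list(intensity = mat),
    colData = S4Vectors::DataFrame(group = groups$group[ord],
                                   row.names = colnames(mat)))
}

#' Write / read gene sets in GMT format
#' @param sets Named list of gene-id vectors.
#' @param file Path.
#' @return `readGmt` returns a named list of gene-id vectors.
#' @export
writeGmt <- function(sets, file) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, nm, sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, file)
  invisible(file)
}

#' @rdname writeGmt
#' @export
readGmt <- function(file) {
  lines <- readLines(file)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[`, character(1), 1L)
  sets
}

#' Write / read the BED-like gene annotation table
#'
#' Six columns (chrom, start, end, gene_id, score, strand), 0-based
#' half-open; the TSS is `start` on the plus strand and `end - 1` on the
#' minus strand.
#' @param genes Data frame as produced by [simulateGenome()].
#' @param file Path.
#' @return `readGeneBed` returns the data frame.
#' @export
writeGeneBed <- function(genes, file) {
  writeTsv(genes[, c("chrom", "start", "end", "gene_id", "score",
                     "strand")], file)
}

#' @rdname writeGeneBed
#' @export
readGeneBed <- function(file) readTsv(file)

#' Write / read a PWM database in JASPAR-style text
#'
#' Records are `>NAME` followed by four rows `A [ n n ... ]`,
#' `C [ ... ]`, `G [ ... ]`, `T [ ... ]` of counts.
#' @param db Named list of 4 x w count matrices (rows A,C,G,T).
#' @param file Path.
#' @return `readJasparPwm` returns the named list of count matrices.
#' @export
writeJasparPwm <- function(db, file) {
  con <- file(file, "w")
  on.exit(close(con))
  for (nm in names(db)) {
    writeLines(paste0(">", nm), con)
    m <- db[[nm]]
    for (b in BASES)
      writeLines(sprintf("%s [ %s ]", b,
                         paste(format(m[b, ], trim = TRUE),
                               collapse = " ")), con)
  }
  invisible(file)
}

#' @rdname writeJasparPwm
#' @export
readJasparPwm <- function(file) {
  lines <- readLines(file)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  if (!length(starts)) stop("no PWM records found in ", file)
  db <- vector("list", length(starts))
  nms <- character(length(starts))
  bounds <- c(starts, length(lines) + 1L)
  for (i in seq_along(starts)) {
    nms[i] <- sub("^>\\s*", "", lines[starts[i]])
    body <- lines[(starts[i] + 1L):(bounds[i + 1L] - 1L)]
    rows <- lapply(BASES, function(b) {
      ln <- grep(paste0("^\\s*", b, "\\b"), body, value = TRUE)
      if (length(ln) != 1L)
        stop("malformed PWM record '", nms[i], "': missing row ", b)
      as.numeric(strsplit(trimws(gsub(paste0("^\\s*", b, "\\s*\\[|\\]"),
                                      "", ln)), "\\s+")[[1L]])
    })
    if (length(unique(lengths(rows))) != 1L)
      stop("ragged PWM record '", nms[i], "'")
    m <- do.call(rbind, rows)
    rownames(m) <- BASES
    db[[i]] <- m
  }
  names(db) <- nms
  db
}

#' Write / read promoter alignment blocks as multi-FASTA files
#'
#' One file per promoter (`<gene_id>.fa`), reference row first.
#' @param blocks Named list of DNAStringSet blocks ([simulateAlignments()]).
#' @param dir Output directory (created if needed).
#' @return `readAlignmentBlocks` returns the named list of blocks.
#' @export
writeAlignmentBlocks <- function(blocks, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(blocks))
    writeXStringSet(blocks[[nm]], file.path(dir, paste0(nm, ".fa")))
  invisible(dir)
}

#' @rdname writeAlignmentBlocks
#' @export
readAlignmentBlocks <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.fa$", full.names = TRUE))
  blocks <- lapply(files, readDNAStringSet)
  names(blocks) <- sub("\\.fa$", "", basename(files))
  blocks
}

#' Write a PromoterSet as FASTA
#'
#' Record ids are gene ids; descriptions carry the genomic interval and
#' strand.
#' @param promoters A [PromoterSet-class].
#' @param file Path.
#' @export
writePromoterFasta <- function(promoters, file) {
  a <- promoterAnno(promoters)
  s <- promoterSeqs(promoters)
  names(s) <- sprintf("%s %s:%d-%d(%s)", a$gene_id, a$chrom, a$start,
                      a$end, a$strand)
  writeXStringSet(s, file)
  invisible(file)
}
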