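## Internal helpers shared across modules.

BASES <- c("A", "C", "G", "T")

#' Run code with a temporary RNG seed
#'
#' Evaluates an expression under `set.seed(seed)` and restores the caller's
#' RNG state afterwards, so seeded module internals never perturb user-level
#' random streams.
#' @noRd
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

## Derive a stream-specific child seed from a user seed, kept < 2^31.
childSeed <- function(seed, stream) {
  (as.numeric(seed) * 1103L + stream * 12347L) %% 2147483587
}

## Encode a DNA string as integers 1..4 (A,C,G,T); anything else -> NA.
encodeDNA <- function(x) {
  v <- match(strsplit(toupper(as.character(x)), "", fixed = TRUE)[[1L]], BASES)
  v
}

decodeDNA <- function(v) paste(BASES[v], collapse = "")

## Integer-coded reverse complement (1<->4, 2<->3).
revcompCode <- function(v) rev(5L - v)

revcompString <- function(s) {
  as.character(reverseComplement(DNAStringSet(s))[[1L]])
}

## Random DNA string(s) with given base composition.
randomDNA <- function(n, len, bg = rep(0.25, 4)) {
  vapply(seq_len(n), function(i)
    paste(sample(BASES, len, replace = TRUE, prob = bg), collapse = ""),
    character(1))
}

stopifnotScalarCount <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 ||
      x != floor(x))
    stop(sprintf("'%s' must be a positive integer", name), call. = FALSE)
}

## Deterministic TSV writer (no quotes, no row names).
writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

readTsv <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
}

## Round-half-even formatting used in enrichment reports.
roundHalfEven <- function(x, digits) round(x, digits)
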