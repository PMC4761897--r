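## Shared internal helpers: seeded RNG scoping, sequence encoding, small IO.

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded package operations do not
#' disturb the caller's random-number stream. All stochastic operations in
#' hybridase route their `seed` argument through this helper, with
#' per-operation substreams derived by fixed offsets (see [derive_seed()]).
#'
#' @param seed integer seed, or `NULL` to use the current stream.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Derive a substream seed by a fixed offset
#'
#' Keeps derived seeds inside the 32-bit integer range so they remain valid
#' arguments to [set.seed()].
#'
#' @param seed base integer seed.
#' @param offset fixed non-negative offset identifying the operation.
#' @return An integer seed.
#' @keywords internal
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% 2147483629L)
}

BASES <- c("A", "C", "G", "T")

## Encode an ACGT string as integers 1..4; other characters become NA.
encode_dna <- function(seq) {
  match(strsplit(toupper(seq), NULL)[[1L]], BASES)
}

## Reverse complement of a plain character string (ACGTN preserved).
revcomp <- function(seq) {
  paste(rev(strsplit(chartr("ACGTacgtN", "TGCAtgcaN", seq), NULL)[[1L]]),
        collapse = "")
}

## Random uniform-composition DNA string(s).
random_dna <- function(n, len) {
  vapply(seq_len(n),
         function(i) paste(sample(BASES, len, replace = TRUE), collapse = ""),
         character(1))
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv <- function(path, ...) {
  read.delim(path, stringsAsFactors = FALSE, na.strings = "", ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
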