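## The allele-resolved count container shared by the simulator, the read
## counter and the ASE/CSE stages.

#' Construct an allele-resolved count table
#'
#' Holds integer counts `K[gene, column]` where each column is one
#' (hybrid, allele, replicate) library, together with the column annotation,
#' library sizes (column sums) and TMM normalization factors (`NA` until
#' [tmm_factors()] is run).
#'
#' @param counts integer matrix, genes x columns, with gene rownames.
#' @param samples data.frame with one row per column and columns `hybrid`
#'   (e.g. `"WExSA"`), `allele` (parental strain of origin) and `replicate`.
#' @return An object of class `allele_counts`: a list with elements
#'   `counts`, `samples` (gains `lib.size` and `norm.factors`).
#' @export
allele_counts <- function(counts, samples) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stopf("counts must have gene rownames")
  if (nrow(samples) != ncol(counts))
    stopf("samples has %d rows but counts has %d columns",
          nrow(samples), ncol(counts))
  if (any(counts < 0) || any(counts != round(counts)))
    stopf("counts must be non-negative integers")
  storage.mode(counts) <- "integer"
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  samples$lib.size <- colSums(counts)
  if (is.null(samples$norm.factors)) samples$norm.factors <- NA_real_
  colnames(counts) <- paste(samples$hybrid, samples$allele,
                            samples$replicate, sep = ".")
  rownames(samples) <- colnames(counts)
  structure(list(counts = counts, samples = samples), class = "allele_counts")
}

#' @export
print.allele_counts <- function(x, ...) {
  cat(sprintf("allele_counts: %d genes x %d libraries (%d hybrids, %d replicates)\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$samples$hybrid)),
              max(x$samples$replicate)))
  if (!anyNA(x$samples$norm.factors)) cat("TMM factors computed\n")
  invisible(x)
}

#' @export
dim.allele_counts <- function(x) dim(x$counts)

#' Subset an allele count table to one hybrid
#'
#' @param x an [allele_counts()] object.
#' @param hybrid hybrid identifier as in `x$samples$hybrid`.
#' @return An `allele_counts` object with only that hybrid's columns
#'   (library sizes preserved from the full table).
#' @export
subset_hybrid <- function(x, hybrid) {
  sel <- x$samples$hybrid == hybrid
  if (!any(sel)) stopf("hybrid '%s' not found", hybrid)
  out <- x
  out$counts <- x$counts[, sel, drop = FALSE]
  out$samples <- x$samples[sel, , drop = FALSE]
  out
}

#' Write / read allele counts as long-format TSV
#'
#' Columns: gene, hybrid, allele, replicate, count.
#'
#' @param x an [allele_counts()] object.
#' @param path TSV path.
#' @return `write_counts` returns `path` invisibly; `read_counts` returns an
#'   [allele_counts()] object.
#' @export
write_counts <- function(x, path) {
  long <- data.frame(
    gene = rep(rownames(x$counts), times = ncol(x$counts)),
    hybrid = rep(x$samples$hybrid, each = nrow(x$counts)),
    allele = rep(x$samples$allele, each = nrow(x$counts)),
    replicate = rep(x$samples$replicate, each = nrow(x$counts)),
    count = as.vector(x$counts))
  write_tsv(long, path)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  long <- read_tsv(path)
  need <- c("gene", "hybrid", "allele", "replicate", "count")
  if (!all(need %in% names(long)))
    stopf("counts TSV must have columns: %s", paste(need, collapse = ", "))
  key <- paste(long$hybrid, long$allele, long$replicate, sep = ".")
  cols <- unique(key)
  genes <- unique(long$gene)
  m <- matrix(0L, length(genes), length(cols),
              dimnames = list(genes, cols))
  m[cbind(match(long$gene, genes), match(key, cols))] <- as.integer(long$count)
  first <- !duplicated(key)
  allele_counts(m, data.frame(hybrid = long$hybrid[first],
                              allele = long$allele[first],
                              replicate = long$replicate[first]))
}

## Effective library sizes: lib.size * norm.factors (factors default to 1).
effective_libsize <- function(x) {
  nf <- x$samples$norm.factors
  nf[is.na(nf)] <- 1
  x$samples$lib.size * nf
}
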