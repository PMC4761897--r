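## Directional allelic selection: per-parent sets of alleles that are
## significantly maximally / minimally expressed in all three hybrids
## sharing that parent, plus hypergeometric gene-set enrichment.

#' Directional allelic selection sets for one parental strain
#'
#' A gene's allele from `parent` is *maximally expressed* when its ASE is
#' significant (`q < q_threshold`) with the parent's allele up (`M > 0`
#' after orienting toward the parent) in all three hybrids containing that
#' parent, and *minimally expressed* symmetrically with the parent's allele
#' down. Genes failing the UDA filter in any of the three hybrids are
#' excluded so the sets are comparable across crosses.
#'
#' @param ase_tabs named list of [ase_fit()] tables for all hybrids.
#' @param parent parental strain; must appear in exactly three hybrids.
#' @param q_threshold significance threshold (default 0.05, i.e. FDR 5%).
#' @param uda named logical vector from [apply_filters()] (`NULL` to skip
#'   the UDA restriction).
#' @return An object of class `directional_set`: list with `parent`,
#'   `max_expressed`, `min_expressed` and `support` (gene, hybrid, M
#'   oriented toward the parent, q).
#' @export
directional_sets <- function(ase_tabs, parent, q_threshold = 0.05,
                             uda = NULL) {
  has_parent <- vapply(ase_tabs, function(t)
    parent %in% c(t$allele1[1L], t$allele2[1L]), logical(1))
  if (sum(has_parent) != 3L)
    stopf("parent '%s' appears in %d hybrids; exactly 3 required",
          parent, sum(has_parent))
  tabs <- ase_tabs[has_parent]
  oriented <- lapply(tabs, function(t) {
    m <- ifelse(t$allele1 == parent, t$M, -t$M)
    data.frame(gene = t$gene, hybrid = t$hybrid, M = m, q = t$q)
  })
  support <- do.call(rbind, oriented)
  genes <- Reduce(intersect, lapply(oriented, function(o)
    o$gene[!is.na(o$q)]))
  if (!is.null(uda)) genes <- genes[genes %in% names(uda)[uda]]
  status <- vapply(genes, function(g) {
    rows <- support[support$gene == g, ]
    sig <- all(rows$q < q_threshold)
    if (sig && all(rows$M > 0)) return("max")
    if (sig && all(rows$M < 0)) return("min")
    "none"
  }, character(1))
  structure(list(parent = parent,
                 max_expressed = genes[status == "max"],
                 min_expressed = genes[status == "min"],
                 support = support[support$gene %in% genes, ]),
            class = "directional_set")
}

#' @export
print.directional_set <- function(x, ...) {
  cat(sprintf("directional_set %s: %d maximally / %d minimally expressed alleles\n",
              x$parent, length(x$max_expressed), length(x$min_expressed)))
  invisible(x)
}

#' Hypergeometric gene-set enrichment
#'
#' One-sided upper-tail hypergeometric test of each category's overlap with
#' the query set against the universe, with Benjamini-Hochberg correction.
#' Fold enrichment is `(overlap / |set|) / (|category in universe| /
#' |universe|)`.
#'
#' @param genes query gene set (restricted to the universe).
#' @param universe background gene ids (non-empty).
#' @param collection named list of category gene vectors (e.g. from
#'   [read_gmt()]).
#' @param fdr FDR threshold for the `significant` flag (default 0.10).
#' @return data.frame sorted by p: category, overlap, set_size,
#'   category_size (in universe), universe_size, fold, p, q, significant.
#' @export
enrich <- function(genes, universe, collection, fdr = 0.10) {
  if (length(universe) == 0L) stopf("empty universe")
  universe <- unique(universe)
  genes <- intersect(unique(genes), universe)
  n <- length(genes)
  rows <- lapply(names(collection), function(nm) {
    cat_u <- intersect(collection[[nm]], universe)
    k <- length(intersect(genes, cat_u))
    p <- if (length(cat_u) == 0L) 1 else
      phyper(k - 1, length(cat_u), length(universe) - length(cat_u), n,
             lower.tail = FALSE)
    fold <- if (n == 0L || length(cat_u) == 0L) 0 else
      (k / n) / (length(cat_u) / length(universe))
    data.frame(category = nm, overlap = k, set_size = n,
               category_size = length(cat_u),
               universe_size = length(universe), fold = fold, p = p)
  })
  out <- do.call(rbind, rows)
  out$q <- p.adjust(out$p, method = "BH")
  out$significant <- out$q < fdr
  out[order(out$p), , drop = FALSE]
}

#' Read / write gene sets in GMT format
#'
#' Reading delegates to [fgsea::gmtPathways()]; writing emits the standard
#' tab-separated name, description, genes... layout.
#'
#' @param path GMT file path.
#' @return `read_gmt` returns a named list of gene-id vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' @rdname read_gmt
#' @param collection named list of gene-id vectors.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection), function(nm)
    paste(c(nm, "na", collection[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}
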