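## Orthologous allele pairing and SNP-aware allele-specific read
## classification. Full read alignment is replaced by exact-coordinate
## placement over equal-length substitution-only allele pairs, which makes
## every placement enumerable and auditable.

#' Pair orthologous sequences between two strains
#'
#' Builds one record per shared gene holding both strains' promoter windows
#' and ORFs, exclusion flags, and the discriminating (SNP) positions of the
#' ORF pair. Promoter windows are cut from the supplied upstream sequences
#' using signed offsets relative to the ATG/TSS, 0-based half-open, with -1
#' the base immediately upstream: the default window `c(-250, -50)` spans
#' positions -250..-51 (200 bp).
#'
#' Genes are flagged rather than dropped: `missing_in_strain` when absent
#' from one strain, `length_mismatch` when ORF lengths differ or the
#' upstream sequence is too short for the requested window, `has_N` when
#' either ORF or promoter window contains a non-ACGT base. Downstream
#' operations skip flagged pairs.
#'
#' @param seqs_a,seqs_b per-strain sequence sets: lists with named character
#'   vectors `promoter` (upstream sequence ending at the ATG) and `orf`,
#'   as returned by [read_strain_fasta()] or found in a `hybrid_sim`.
#' @param strains length-2 character vector of strain identifiers.
#' @param promoter_window signed offsets `c(from, to)` with `from < to <= 0`.
#' @return An object of class `allele_pairs`: a named list of per-gene pair
#'   records (`gene`, `promoter`, `orf`, `flags`, `snp_orf`, `snp_promoter`;
#'   SNP offsets are 0-based), with attributes `strains` and `window`.
#' @export
pair_alleles <- function(seqs_a, seqs_b, strains = c("A", "B"),
                         promoter_window = c(-250, -50)) {
  if (promoter_window[1L] >= promoter_window[2L] || promoter_window[2L] > 0)
    stopf("promoter_window must satisfy from < to <= 0")
  genes <- union(names(seqs_a$orf), names(seqs_b$orf))
  shared <- intersect(names(seqs_a$orf), names(seqs_b$orf))
  if (length(shared) == 0L) stopf("no shared gene ids between strains")
  cut_window <- function(u) {
    n <- nchar(u)
    lo <- n + promoter_window[1L] + 1L
    hi <- n + promoter_window[2L]
    if (is.na(u) || lo < 1L) NA_character_ else substr(u, lo, hi)
  }
  getseq <- function(v, g)
    if (!is.null(v) && g %in% names(v)) unname(v[g]) else NA_character_
  pairs <- lapply(genes, function(g) {
    oa <- getseq(seqs_a$orf, g)
    ob <- getseq(seqs_b$orf, g)
    ua <- getseq(seqs_a$promoter, g)
    ub <- getseq(seqs_b$promoter, g)
    missing <- is.na(oa) || is.na(ob)
    pa <- if (!is.na(ua)) cut_window(ua) else NA_character_
    pb <- if (!is.na(ub)) cut_window(ub) else NA_character_
    len_mm <- !missing && (nchar(oa) != nchar(ob) || is.na(pa) || is.na(pb) ||
                             nchar(pa) != nchar(pb))
    has_n <- FALSE
    snp_orf <- integer(0)
    snp_prom <- integer(0)
    if (!missing && !len_mm) {
      has_n <- grepl("[^ACGT]", oa) || grepl("[^ACGT]", ob) ||
        grepl("[^ACGT]", pa) || grepl("[^ACGT]", pb)
      if (!has_n) {
        snp_orf <- which(strsplit(oa, NULL)[[1L]] !=
                           strsplit(ob, NULL)[[1L]]) - 1L
        snp_prom <- which(strsplit(pa, NULL)[[1L]] !=
                            strsplit(pb, NULL)[[1L]]) - 1L
      }
    }
    list(gene = g,
         promoter = setNames(c(pa, pb), strains),
         orf = setNames(c(oa, ob), strains),
         flags = list(has_N = has_n, missing_in_strain = missing,
                      length_mismatch = len_mm),
         snp_orf = snp_orf, snp_promoter = snp_prom)
  })
  names(pairs) <- genes
  structure(pairs, strains = strains, window = promoter_window,
            class = "allele_pairs")
}

#' @export
print.allele_pairs <- function(x, ...) {
  excl <- sum(vapply(x, function(p) any(unlist(p$flags)), logical(1)))
  cat(sprintf("allele_pairs: %d genes for %s; %d flagged for exclusion\n",
              length(x), paste(attr(x, "strains"), collapse = " vs "), excl))
  invisible(x)
}

#' Per-gene exclusion report
#'
#' @param pairs an `allele_pairs` collection.
#' @return data.frame with gene, the three exclusion flags, an `excluded`
#'   summary column and the number of ORF SNPs.
#' @export
exclusion_report <- function(pairs) {
  do.call(rbind, lapply(pairs, function(p)
    data.frame(gene = p$gene, has_N = p$flags$has_N,
               missing_in_strain = p$flags$missing_in_strain,
               length_mismatch = p$flags$length_mismatch,
               excluded = any(unlist(p$flags)),
               n_snps_orf = length(p$snp_orf), row.names = NULL)))
}

#' Classify a read to a parental allele
#'
#' Places the read at every offset of the equal-length ORF pair, on both
#' strands, and finds the placements minimizing the mismatch count against
#' the nearer allele. Among equally good placements, one that covers a
#' discriminating position and separates the alleles wins (forward strand
#' preferred, then the leftmost offset); the read is assigned to the allele
#' with strictly fewer mismatches there. It is `"uninformative"` when no
#' best placement discriminates (mismatch tie or no covered SNP) or when
#' the minimum mismatch count exceeds `max_mismatch`.
#'
#' @param read read sequence (character).
#' @param pair an allele pair record from [pair_alleles()]; must not be
#'   flagged for exclusion.
#' @param max_mismatch maximum mismatches tolerated at the best placement.
#' @return One of the two strain names of the pair, or `"uninformative"`.
#' @export
classify_read <- function(read, pair, max_mismatch = 2) {
  if (any(unlist(pair$flags))) stopf("gene '%s' is flagged for exclusion", pair$gene)
  orf_a <- pair$orf[[1L]]
  orf_b <- pair$orf[[2L]]
  L <- nchar(read)
  n <- nchar(orf_a)
  if (L > n) stopf("read (%d bp) longer than ORF (%d bp)", L, n)
  starts <- seq_len(n - L + 1L)
  sa <- Biostrings::DNAString(orf_a)
  sb <- Biostrings::DNAString(orf_b)
  fw <- Biostrings::DNAString(read)
  rv <- Biostrings::reverseComplement(fw)
  mm <- rbind(
    a_fwd = Biostrings::neditStartingAt(fw, sa, starting.at = starts,
                                        with.indels = FALSE),
    b_fwd = Biostrings::neditStartingAt(fw, sb, starting.at = starts,
                                        with.indels = FALSE),
    a_rev = Biostrings::neditStartingAt(rv, sa, starting.at = starts,
                                        with.indels = FALSE),
    b_rev = Biostrings::neditStartingAt(rv, sb, starting.at = starts,
                                        with.indels = FALSE))
  best_fwd <- pmin(mm["a_fwd", ], mm["b_fwd", ])
  best_rev <- pmin(mm["a_rev", ], mm["b_rev", ])
  best <- min(best_fwd, best_rev)
  if (best > max_mismatch) return("uninformative")
  covers <- vapply(starts, function(off)
    any(pair$snp_orf >= off - 1L & pair$snp_orf <= off - 2L + L), logical(1))
  ## among best placements, a discriminating one wins (forward strand
  ## preferred, then leftmost offset)
  for (strand in c("fwd", "rev")) {
    ma_v <- mm[paste0("a_", strand), ]
    mb_v <- mm[paste0("b_", strand), ]
    cand <- which(pmin(ma_v, mb_v) == best & ma_v != mb_v & covers)
    if (length(cand)) {
      off <- cand[1L]
      return(names(pair$orf)[if (ma_v[off] < mb_v[off]) 1L else 2L])
    }
  }
  "uninformative"
}

#' Count classified reads per allele
#'
#' Classifies a set of reads against their genes' allele pairs and sums
#' reads per (gene, allele); uninformative reads are tallied separately and
#' reported as an informativeness fraction.
#'
#' @param reads data.frame with columns `read` and `gene` (as produced by
#'   [simulate_reads()]); a `hybrid` / `replicate` column pair is carried
#'   through if present.
#' @param pairs an `allele_pairs` collection covering the read genes.
#' @param hybrid,replicate labels stored in the output (defaults taken from
#'   `reads` when present).
#' @param max_mismatch passed to [classify_read()].
#' @return A list with `counts` (data.frame gene, hybrid, allele, replicate,
#'   count, over both strains), `uninformative` (per-gene count) and
#'   `informative_fraction`.
#' @export
count_alleles <- function(reads, pairs, hybrid = NULL, replicate = NULL,
                          max_mismatch = 2) {
  strains <- attr(pairs, "strains")
  hybrid <- hybrid %||% (if (!is.null(reads$hybrid)) reads$hybrid[1L] else
                           paste(strains, collapse = "x"))
  replicate <- replicate %||% (if (!is.null(reads$replicate))
    reads$replicate[1L] else 1L)
  genes <- sort(unique(reads$gene))
  calls <- character(nrow(reads))
  for (g in genes) {
    sel <- which(reads$gene == g)
    p <- pairs[[g]]
    if (is.null(p)) stopf("no allele pair for gene '%s'", g)
    if (any(unlist(p$flags))) {
      calls[sel] <- "excluded"
    } else {
      calls[sel] <- vapply(reads$read[sel], classify_read, character(1),
                           pair = p, max_mismatch = max_mismatch,
                           USE.NAMES = FALSE)
    }
  }
  tab <- table(factor(reads$gene, levels = genes),
               factor(calls, levels = c(strains, "uninformative", "excluded")))
  counts <- do.call(rbind, lapply(strains, function(s)
    data.frame(gene = genes, hybrid = hybrid, allele = s,
               replicate = replicate, count = as.integer(tab[, s]))))
  informative <- sum(tab[, strains])
  list(counts = counts,
       uninformative = setNames(as.integer(tab[, "uninformative"]), genes),
       informative_fraction = informative / max(1L, sum(calls != "excluded")))
}
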