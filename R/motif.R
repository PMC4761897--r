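## PWM models, MEME-format IO, GOMER promoter occupancy and allele-specific
## binding (ASB).

#' Construct a TF motif model
#'
#' A motif model holds a position frequency matrix theta with one row per
#' motif position and columns A, C, G, T. A pseudocount `alpha` is added to
#' every entry and rows are renormalized, so all stored probabilities are
#' strictly positive and each row sums to one.
#'
#' @param name TF or motif name.
#' @param prob numeric matrix, L x 4, rows summing to 1 (tolerance 1e-6
#'   before pseudocounting). Columns are taken in A, C, G, T order.
#' @param pseudocount per-entry pseudocount alpha (default 0.01).
#' @return An object of class `motif_model` with elements `name`, `prob`
#'   (pseudocounted L x 4 matrix), `length`, `consensus` and `pseudocount`.
#' @examples
#' m <- motif_model("toy", matrix(c(1, 0, 0, 0, 0, 0, 0, 1), 2, 4, byrow = TRUE))
#' m$consensus
#' @export
motif_model <- function(name, prob, pseudocount = 0.01) {
  prob <- as.matrix(prob)
  if (ncol(prob) != 4L) stopf("motif '%s': matrix must have 4 columns", name)
  if (nrow(prob) < 1L) stopf("motif '%s': length must be >= 1", name)
  if (any(prob < 0)) stopf("motif '%s': negative probabilities", name)
  rs <- rowSums(prob)
  if (any(abs(rs - 1) > 1e-6))
    stopf("motif '%s': row %d sums to %.6f, not 1", name,
          which.max(abs(rs - 1)), rs[which.max(abs(rs - 1))])
  prob <- (prob + pseudocount) / (1 + 4 * pseudocount)
  prob <- prob / rowSums(prob)
  dimnames(prob) <- list(NULL, BASES)
  structure(list(name = name, prob = prob, length = nrow(prob),
                 consensus = paste(BASES[max.col(prob, ties.method = "first")],
                                   collapse = ""),
                 pseudocount = pseudocount),
            class = "motif_model")
}

#' @export
print.motif_model <- function(x, ...) {
  cat(sprintf("motif_model '%s': length %d, consensus %s\n",
              x$name, x$length, x$consensus))
  invisible(x)
}

## Reverse-complement a motif: reverse positions, complement bases.
motif_revcomp <- function(motif) {
  p <- motif$prob[rev(seq_len(motif$length)), c("T", "G", "C", "A"),
                  drop = FALSE]
  colnames(p) <- BASES
  out <- motif
  out$prob <- p
  out$consensus <- paste(BASES[max.col(p, ties.method = "first")],
                         collapse = "")
  out
}

#' Read motifs from a MEME-format file
#'
#' Parses minimal MEME motif format (a `MOTIF` line followed by a
#' `letter-probability matrix:` block of A C G T probabilities). Each motif
#' is pseudocounted and renormalized on load via [motif_model()].
#'
#' @param path path to a MEME-format text file.
#' @param pseudocount per-entry pseudocount applied at load.
#' @return A named list of [motif_model()] objects.
#' @export
read_meme <- function(path, pseudocount = 0.01) {
  lines <- readLines(path)
  starts <- grep("^MOTIF\\b", lines)
  if (length(starts) == 0L) stopf("%s: no MOTIF blocks found", path)
  motifs <- list()
  for (s in starts) {
    name <- strsplit(trimws(sub("^MOTIF", "", lines[s])), "\\s+")[[1L]][1L]
    if (is.na(name) || !nzchar(name)) stopf("%s:%d: MOTIF without a name", path, s)
    hdr <- s + which(grepl("letter-probability matrix", lines[(s + 1):length(lines)]))[1L]
    if (is.na(hdr)) stopf("%s:%d: motif '%s' has no letter-probability matrix",
                          path, s, name)
    w <- suppressWarnings(as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[hdr])))
    rows <- list()
    i <- hdr + 1L
    while (i <= length(lines)) {
      ln <- trimws(lines[i])
      if (!nzchar(ln)) { if (length(rows)) break else { i <- i + 1L; next } }
      if (grepl("^(MOTIF|URL|\\p{L})", ln, perl = TRUE) &&
          !grepl("^[0-9eE.+-]", ln)) break
      vals <- suppressWarnings(as.numeric(strsplit(ln, "\\s+")[[1L]]))
      if (length(vals) != 4L || anyNA(vals))
        stopf("%s:%d: malformed probability row in motif '%s'", path, i, name)
      rows[[length(rows) + 1L]] <- vals
      i <- i + 1L
    }
    if (!is.na(w) && length(rows) != w)
      stopf("%s:%d: motif '%s' declares w=%d but has %d rows",
            path, hdr, name, w, length(rows))
    mat <- do.call(rbind, rows)
    if (any(abs(rowSums(mat) - 1) > 1e-3))
      stopf("%s:%d: motif '%s' rows do not sum to ~1", path, hdr, name)
    mat <- mat / rowSums(mat)
    motifs[[name]] <- motif_model(name, mat, pseudocount)
  }
  motifs
}

#' Write motifs to a MEME-format file
#'
#' @param motifs a list of [motif_model()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_meme <- function(motifs, path) {
  if (inherits(motifs, "motif_model")) motifs <- list(motifs)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               "A 0.25 C 0.25 G 0.25 T 0.25", ""), con)
  for (m in motifs) {
    writeLines(sprintf("MOTIF %s", m$name), con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
                       m$length), con)
    writeLines(apply(m$prob, 1L, function(r)
      paste(sprintf("%.6f", r), collapse = " ")), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Score a single window under a motif
#'
#' In the default `"prob"` mode the score is the PWM probability of the
#' window, prod_j theta[j, base_j], in (0, 1]. In `"affinity"` mode the
#' relative affinity K = prod_j theta[j, base_j] / bg is saturated to
#' K / (1 + K).
#'
#' @param motif a [motif_model()].
#' @param window character string of length equal to the motif length,
#'   ACGT only.
#' @param mode `"prob"` (default) or `"affinity"`.
#' @param background background base probability used in affinity mode.
#' @return A single numeric score in (0, 1].
#' @export
window_score <- function(motif, window, mode = c("prob", "affinity"),
                         background = 0.25) {
  mode <- match.arg(mode)
  x <- encode_dna(window)
  if (length(x) != motif$length)
    stopf("window length %d != motif length %d", length(x), motif$length)
  if (anyNA(x)) stopf("window contains non-ACGT characters")
  p <- prod(motif$prob[cbind(seq_along(x), x)])
  if (mode == "affinity") {
    k <- p / background^motif$length
    p <- k / (1 + k)
  }
  p
}

## Vectorized one-strand scan: window scores at every offset of an encoded
## sequence. NA bases (Ns) poison every window that overlaps them; those
## windows score 0. Returns numeric(0) when the sequence is shorter than L.
scan_strand <- function(motif, x, mode, background) {
  L <- motif$length
  n <- length(x)
  if (n < L) return(numeric(0))
  w <- n - L + 1L
  lpv <- as.vector(log(motif$prob))  # column-major: (j, base) at (base-1)*L + j
  s <- lpv[(x[seq_len(w)] - 1L) * L + 1L]
  if (L > 1L) for (j in 2:L) s <- s + lpv[(x[j:(w + j - 1L)] - 1L) * L + j]
  p <- exp(s)
  if (mode == "affinity") {
    k <- exp(s - L * log(background))
    p <- k / (1 + k)
  }
  p[is.na(p)] <- 0
  p
}

## Window scores on both strands of a promoter. The reverse strand is scored
## by scanning the reverse-complemented motif along the forward sequence, so
## scores stay indexed by forward-strand offset. Non-ACGT characters other
## than N are an error; N-containing windows score 0 with a warning.
scan_windows <- function(motif, seq, mode = "prob", background = 0.25,
                         both_strands = TRUE) {
  x <- encode_dna(seq)
  bad <- is.na(x) & strsplit(toupper(seq), NULL)[[1L]] != "N"
  if (any(bad)) stopf("sequence contains non-ACGTN character '%s'",
                      substr(seq, which(bad)[1L], which(bad)[1L]))
  if (anyNA(x) && length(x) >= motif$length)
    warning("windows overlapping N are skipped (score 0)", call. = FALSE)
  fwd <- scan_strand(motif, x, mode, background)
  if (!both_strands) return(list(fwd = fwd, rev = numeric(0)))
  list(fwd = fwd, rev = scan_strand(motif_revcomp(motif), x, mode, background))
}

#' GOMER probability that a promoter is bound
#'
#' Aggregates per-window binding probabilities over every offset on both
#' strands under the independent-sites assumption:
#' P_bound = 1 - prod_i (1 - p_i), where p_i is [window_score()] at offset i.
#' A promoter shorter than the motif has P_bound = 0.
#'
#' @inheritParams window_score
#' @param promoter promoter sequence (ACGT, N allowed; windows overlapping N
#'   are skipped with a warning).
#' @param both_strands score the reverse strand as well (default TRUE).
#' @return P_bound in \[0, 1\].
#' @examples
#' m <- motif_model("toy", matrix(0.25, 3, 4))
#' gomer_pbound(m, "ACGTACGTACGT")
#' @export
gomer_pbound <- function(motif, promoter, mode = c("prob", "affinity"),
                         background = 0.25, both_strands = TRUE) {
  mode <- match.arg(mode)
  sc <- scan_windows(motif, promoter, mode, background, both_strands)
  p <- c(sc$fwd, sc$rev)
  if (length(p) == 0L) return(0)
  ## complement product in log space; log1p(-1) = -Inf gives an exact 1
  -expm1(sum(log1p(-pmin(p, 1))))
}

#' Allele-specific binding (ASB)
#'
#' Difference between the GOMER binding probabilities of two promoter
#' alleles: `gomer_pbound(A) - gomer_pbound(B)`, in \[-1, 1\]. Positive
#' values mean the first allele is predicted to be bound more.
#'
#' @inheritParams gomer_pbound
#' @param promoter_a,promoter_b the two allelic promoter sequences.
#' @return A single number in \[-1, 1\].
#' @export
asb <- function(motif, promoter_a, promoter_b, mode = c("prob", "affinity"),
                background = 0.25) {
  mode <- match.arg(mode)
  gomer_pbound(motif, promoter_a, mode, background) -
    gomer_pbound(motif, promoter_b, mode, background)
}

#' Best motif score per gene
#'
#' The maximum single-window score over both strands; used to rank genes as
#' candidate targets of a TF (see [define_targets()]).
#'
#' @inheritParams gomer_pbound
#' @return Maximum window score (0 for promoters shorter than the motif).
#' @export
motif_score_max <- function(motif, promoter, mode = c("prob", "affinity"),
                            background = 0.25) {
  mode <- match.arg(mode)
  sc <- scan_windows(motif, promoter, mode, background)
  p <- c(sc$fwd, sc$rev)
  if (length(p) == 0L) return(0)
  max(p)
}

#' Per-SNP attribution of binding differences between two promoter alleles
#'
#' For every position at which the two alleles differ, reports the maximal
#' window score among windows overlapping that position in each allele
#' (over both strands) and the relative change, sorted by the absolute
#' score change. SNPs whose best window score falls below `score_threshold`
#' in both alleles are flagged `below_threshold`.
#'
#' @inheritParams asb
#' @param score_threshold windows at or above this score count as candidate
#'   sites; defaults to half the motif's consensus-sequence score.
#' @return A data.frame sorted by decreasing absolute score change, with
#'   columns `position` (0-based), `base_a`, `base_b`, `best_score_a`,
#'   `best_score_b`, `rel_change`, `below_threshold`.
#' @export
snp_binding_report <- function(motif, promoter_a, promoter_b,
                               mode = c("prob", "affinity"),
                               background = 0.25, score_threshold = NULL) {
  mode <- match.arg(mode)
  if (nchar(promoter_a) != nchar(promoter_b))
    stopf("promoter alleles differ in length; substitution-only pairs required")
  a <- strsplit(toupper(promoter_a), NULL)[[1L]]
  b <- strsplit(toupper(promoter_b), NULL)[[1L]]
  snps <- which(a != b)
  if (is.null(score_threshold))
    score_threshold <- 0.5 * prod(apply(motif$prob, 1L, max))
  if (length(snps) == 0L)
    return(data.frame(position = integer(0), base_a = character(0),
                      base_b = character(0), best_score_a = numeric(0),
                      best_score_b = numeric(0), rel_change = numeric(0),
                      below_threshold = logical(0)))
  sa <- scan_windows(motif, promoter_a, mode, background)
  sb <- scan_windows(motif, promoter_b, mode, background)
  L <- motif$length
  nw <- length(sa$fwd)
  best_at <- function(sc, pos1) {
    lo <- max(1L, pos1 - L + 1L)
    hi <- min(nw, pos1)
    if (nw == 0L || hi < lo) return(0)
    max(c(sc$fwd[lo:hi], sc$rev[lo:hi]))
  }
  rows <- lapply(snps, function(pos1) {
    ba <- best_at(sa, pos1)
    bb <- best_at(sb, pos1)
    data.frame(position = pos1 - 1L, base_a = a[pos1], base_b = b[pos1],
               best_score_a = ba, best_score_b = bb,
               rel_change = if (ba > 0) (bb - ba) / ba else if (bb > 0) Inf else 0,
               below_threshold = max(ba, bb) < score_threshold)
  })
  out <- do.call(rbind, rows)
  ## rank by absolute score change: tiny background windows can have huge
  ## relative changes without any binding relevance
  out[order(-abs(out$best_score_b - out$best_score_a)), , drop = FALSE]
}

## GOMER aggregate for a pre-encoded sequence (both strands).
.gomer_encoded <- function(motif, x, motif_rc, mode, background) {
  p <- c(scan_strand(motif, x, mode, background),
         scan_strand(motif_rc, x, mode, background))
  if (length(p) == 0L) return(0)
  -expm1(sum(log1p(-pmin(p, 1))))
}

#' Binding probabilities for every (gene, TF, strain) combination
#'
#' Computes [gomer_pbound()] once per strain promoter and TF; hybrids share
#' parental strains, so per-hybrid ASB tables should be derived from this
#' matrix with [asb_from_pbound()] rather than rescanning per hybrid.
#' Promoters containing characters other than ACGT (e.g. N) get `NA`.
#'
#' @param motifs named list of [motif_model()] objects.
#' @param sequences named list: strain -> list with a named `promoter`
#'   character vector (as in a `hybrid_sim` or from [read_strain_fasta()]).
#' @inheritParams gomer_pbound
#' @return A 3-d array gene x TF x strain of P_bound values.
#' @export
pbound_matrix <- function(motifs, sequences, mode = c("prob", "affinity"),
                          background = 0.25) {
  mode <- match.arg(mode)
  strains <- names(sequences)
  genes <- names(sequences[[1L]]$promoter)
  out <- array(NA_real_, c(length(genes), length(motifs), length(strains)),
               dimnames = list(genes, names(motifs), strains))
  for (s in strains) {
    proms <- sequences[[s]]$promoter[genes]
    enc <- lapply(proms, function(p) if (is.na(p)) NULL else encode_dna(p))
    ok <- !vapply(enc, function(e) is.null(e) || anyNA(e), logical(1))
    for (tf in names(motifs)) {
      m <- motifs[[tf]]
      mrc <- motif_revcomp(m)
      out[ok, tf, s] <- vapply(enc[ok], .gomer_encoded, numeric(1),
                               motif = m, motif_rc = mrc, mode = mode,
                               background = background)
    }
  }
  out
}

#' Per-hybrid ASB from a binding-probability matrix
#'
#' @param pb array from [pbound_matrix()].
#' @param hybrids character vector of hybrid ids `"s1xs2"`; ASB is
#'   `P_bound(s1) - P_bound(s2)`.
#' @param exclude optional named list hybrid -> gene ids to drop (e.g.
#'   pairs flagged by [pair_alleles()]).
#' @return Long data.frame: gene, tf, hybrid, asb.
#' @export
asb_from_pbound <- function(pb, hybrids, exclude = NULL) {
  do.call(rbind, lapply(hybrids, function(h) {
    ss <- strsplit(h, "x", fixed = TRUE)[[1L]]
    d <- pb[, , ss[1L], drop = FALSE] - pb[, , ss[2L], drop = FALSE]
    df <- data.frame(gene = rep(rownames(pb), ncol(pb)),
                     tf = rep(colnames(pb), each = nrow(pb)),
                     hybrid = h, asb = as.vector(d))
    drop <- c(rownames(pb)[apply(is.na(d), 1L, any)],
              exclude[[h]] %||% character(0))
    df[!df$gene %in% drop, , drop = FALSE]
  }))
}

#' ASB table across genes, TFs and hybrids
#'
#' Applies [gomer_pbound()] to every (gene, TF, strain) combination of an
#' [pair_alleles()] collection and tabulates per-strain binding
#' probabilities and the per-hybrid ASB difference. Excluded gene pairs are
#' skipped.
#'
#' @param motifs named list of [motif_model()] objects.
#' @param pairs an `allele_pairs` collection (see [pair_alleles()]).
#' @inheritParams gomer_pbound
#' @return A list with `pbound` (data.frame gene, tf, strain, p_bound) and
#'   `asb` (data.frame gene, tf, hybrid, asb), plus the strain pair.
#' @export
asb_table <- function(motifs, pairs, mode = c("prob", "affinity"),
                      background = 0.25) {
  mode <- match.arg(mode)
  strains <- attr(pairs, "strains")
  hybrid <- paste(strains, collapse = "x")
  keep <- Filter(function(p) !any(unlist(p$flags)), pairs)
  genes <- vapply(keep, function(p) p$gene, character(1))
  res <- lapply(motifs, function(m) {
    pa <- vapply(keep, function(p) gomer_pbound(m, p$promoter[[1L]], mode,
                                                background), numeric(1))
    pb <- vapply(keep, function(p) gomer_pbound(m, p$promoter[[2L]], mode,
                                                background), numeric(1))
    list(pa = pa, pb = pb)
  })
  pbound <- do.call(rbind, lapply(names(res), function(tf)
    data.frame(gene = rep(genes, 2L), tf = tf,
               strain = rep(strains, each = length(genes)),
               p_bound = c(res[[tf]]$pa, res[[tf]]$pb))))
  asb_df <- do.call(rbind, lapply(names(res), function(tf)
    data.frame(gene = genes, tf = tf, hybrid = hybrid,
               asb = res[[tf]]$pa - res[[tf]]$pb)))
  list(pbound = pbound, asb = asb_df, strains = strains, hybrid = hybrid)
}
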