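## Genome-wide association of allele-specific binding with allele-specific
## expression: per-TF correlations, gene-label permutation nulls, K-S
## comparison of observed vs permuted correlation pools, and per-motif
## significance with Bonferroni correction.

## Align an ASB long table (gene, tf, hybrid, asb) and an ase_table into a
## complete-case gene x TF matrix plus the matching ASE (M) vector.
.align_asb_ase <- function(asb_df, ase_tab, hybrid) {
  asb_df <- asb_df[asb_df$hybrid == hybrid, , drop = FALSE]
  ase_tab <- ase_tab[ase_tab$hybrid == hybrid & !is.na(ase_tab$M), ,
                     drop = FALSE]
  tfs <- unique(asb_df$tf)
  genes <- intersect(unique(asb_df$gene), ase_tab$gene)
  if (length(genes) == 0L) stopf("no shared genes between ASB and ASE tables")
  A <- matrix(NA_real_, length(genes), length(tfs),
              dimnames = list(genes, tfs))
  A[cbind(match(asb_df$gene, genes), match(asb_df$tf, tfs))] <- asb_df$asb
  keep <- rowSums(is.na(A)) == 0L
  A <- A[keep, , drop = FALSE]
  m <- setNames(ase_tab$M, ase_tab$gene)[rownames(A)]
  list(asb = A, ase = m)
}

#' Per-TF correlation of ASB with ASE
#'
#' Correlates each TF's allele-specific binding values with the
#' hybrid-specific ASE log-ratios over the genes that have both. Positive
#' correlations mean the allele bound more is also expressed more
#' (activator-consistent); negative correlations are repressor-consistent.
#'
#' @param asb_df long-format ASB table (columns gene, tf, hybrid, asb), e.g.
#'   `asb_table()$asb`.
#' @param ase_tab an [ase_fit()] table for the same hybrid.
#' @param hybrid hybrid identifier.
#' @param method `"pearson"` or `"spearman"`.
#' @param min_n minimum genes per TF (default 10); below it the TF is
#'   flagged `insufficient`.
#' @return data.frame: tf, hybrid, n, r, flag (`"ok"`, `"insufficient"`, or
#'   `"zero_variance"`).
#' @export
correlate_asb_ase <- function(asb_df, ase_tab, hybrid,
                              method = c("pearson", "spearman"),
                              min_n = 10) {
  method <- match.arg(method)
  al <- .align_asb_ase(asb_df, ase_tab, hybrid)
  n <- nrow(al$asb)
  r <- rep(NA_real_, ncol(al$asb))
  flag <- rep("ok", ncol(al$asb))
  for (j in seq_len(ncol(al$asb))) {
    x <- al$asb[, j]
    if (n < min_n) { flag[j] <- "insufficient"; next }
    if (sd(x) == 0 || sd(al$ase) == 0) { flag[j] <- "zero_variance"; next }
    r[j] <- cor(x, al$ase, method = method)
  }
  data.frame(tf = colnames(al$asb), hybrid = hybrid, n = n, r = r,
             flag = flag, row.names = NULL)
}

#' Gene-label permutation null for ASB/ASE correlations
#'
#' Permutes the gene labels of the ASE vector (keeping the ASB matrix, and
#' hence the dependence between TFs, intact), recomputes the per-TF Pearson
#' correlation for each permutation, and returns the null sample together
#' with two-sided empirical p-values
#' `(1 + #\{|R_null| >= |R_obs|\}) / (n_perm + 1)`.
#'
#' @inheritParams correlate_asb_ase
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed; the null sample is deterministic given it.
#' @return A list with `observed` (as [correlate_asb_ase()]), `null` (matrix
#'   n_perm x TF of permuted correlations) and `p_perm` (named vector).
#' @export
permutation_null <- function(asb_df, ase_tab, hybrid, n_perm = 1000,
                             seed = 1, method = "pearson") {
  if (n_perm < 100) stopf("n_perm must be >= 100")
  al <- .align_asb_ase(asb_df, ase_tab, hybrid)
  obs <- correlate_asb_ase(asb_df, ase_tab, hybrid, method = method)
  A <- al$asb
  y <- al$ase
  if (method == "spearman") {
    A <- apply(A, 2L, rank)
    y <- rank(y)
  }
  null <- with_seed(derive_seed(seed, 5L), {
    t(vapply(seq_len(n_perm),
             function(i) as.vector(suppressWarnings(cor(A, sample(y)))),
             numeric(ncol(A))))
  })
  colnames(null) <- colnames(A)
  robs <- setNames(obs$r, obs$tf)
  p_perm <- vapply(colnames(null), function(tf) {
    if (is.na(robs[tf])) return(NA_real_)
    (1 + sum(abs(null[, tf]) >= abs(robs[tf]))) / (n_perm + 1)
  }, numeric(1))
  list(observed = obs, null = null, p_perm = p_perm)
}

#' Kolmogorov-Smirnov test of observed vs permuted correlation pools
#'
#' Two-sample K-S comparison of the pooled observed per-TF correlations
#' against the pooled permutation-null correlations; a significant result
#' means ASB relates to ASE more (or differently) than chance across TFs.
#'
#' @param observed numeric pool of observed correlations.
#' @param permuted numeric pool of permuted correlations.
#' @return A list with `D`, `p` and the two pool sizes.
#' @export
ks_actual_vs_permuted <- function(observed, permuted) {
  observed <- observed[!is.na(observed)]
  permuted <- permuted[!is.na(permuted)]
  if (length(observed) == 0L || length(permuted) == 0L)
    stopf("both correlation pools must be non-empty")
  kt <- suppressWarnings(ks.test(observed, permuted))
  list(D = unname(kt$statistic), p = kt$p.value,
       n_observed = length(observed), n_permuted = length(permuted))
}

#' Per-motif significance with Bonferroni correction
#'
#' Analytic Spearman test per TF (matching the per-motif reporting style),
#' Bonferroni-adjusted over all tested motifs; permutation p-values are
#' carried alongside when supplied.
#'
#' @inheritParams correlate_asb_ase
#' @param p_perm optional named vector of permutation p-values to carry.
#' @param alpha family-wise error target (default 0.05).
#' @return data.frame sorted by r: tf, hybrid, n, r (Spearman), p_analytic,
#'   p_bonferroni, p_perm, significant.
#' @export
per_motif_significance <- function(asb_df, ase_tab, hybrid, p_perm = NULL,
                                   alpha = 0.05) {
  al <- .align_asb_ase(asb_df, ase_tab, hybrid)
  res <- do.call(rbind, lapply(colnames(al$asb), function(tf) {
    x <- al$asb[, tf]
    if (sd(x) == 0 || sd(al$ase) == 0)
      return(data.frame(tf = tf, hybrid = hybrid, n = length(x),
                        r = NA_real_, p_analytic = NA_real_))
    ct <- suppressWarnings(cor.test(x, al$ase, method = "spearman",
                                    exact = FALSE))
    data.frame(tf = tf, hybrid = hybrid, n = length(x),
               r = unname(ct$estimate), p_analytic = ct$p.value)
  }))
  m <- sum(!is.na(res$p_analytic))
  res$p_bonferroni <- pmin(1, res$p_analytic * m)
  res$p_perm <- if (!is.null(p_perm)) unname(p_perm[res$tf]) else NA_real_
  res$significant <- !is.na(res$p_bonferroni) & res$p_bonferroni < alpha
  res[order(-res$r, na.last = TRUE), , drop = FALSE]
}

#' Full cis-mapping stage for one or more hybrids
#'
#' Runs [correlate_asb_ase()], [permutation_null()],
#' [ks_actual_vs_permuted()] (pooled across the supplied hybrids) and
#' [per_motif_significance()] per hybrid.
#'
#' @param asb_df long-format ASB table covering the hybrids.
#' @param ase_tabs named list of [ase_fit()] tables, one per hybrid.
#' @param n_perm,seed,alpha passed through.
#' @return An object of class `cis_map`: list with `per_hybrid` (each with
#'   observed/null/p_perm and the per-motif table), `ks` (pooled), and the
#'   pooled correlation vectors.
#' @export
cis_map <- function(asb_df, ase_tabs, n_perm = 1000, seed = 1,
                    alpha = 0.05) {
  hybrids <- names(ase_tabs)
  per_hybrid <- lapply(hybrids, function(h) {
    pn <- permutation_null(asb_df, ase_tabs[[h]], h, n_perm = n_perm,
                           seed = derive_seed(seed, match(h, hybrids)))
    motifs <- per_motif_significance(asb_df, ase_tabs[[h]], h,
                                     p_perm = pn$p_perm, alpha = alpha)
    list(observed = pn$observed, null = pn$null, p_perm = pn$p_perm,
         motifs = motifs)
  })
  names(per_hybrid) <- hybrids
  obs_pool <- unlist(lapply(per_hybrid, function(x) x$observed$r))
  null_pool <- unlist(lapply(per_hybrid, function(x) as.vector(x$null)))
  structure(list(per_hybrid = per_hybrid,
                 ks = ks_actual_vs_permuted(obs_pool, null_pool),
                 observed_pool = obs_pool, null_pool = null_pool),
            class = "cis_map")
}

#' @export
print.cis_map <- function(x, ...) {
  cat(sprintf("cis_map over %d hybrid(s): K-S D = %.3f, p = %.3g (%d observed vs %d permuted Rs)\n",
              length(x$per_hybrid), x$ks$D, x$ks$p, x$ks$n_observed,
              x$ks$n_permuted))
  invisible(x)
}
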