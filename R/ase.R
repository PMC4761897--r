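## Normalization, filtering and allele-imbalance testing: TMM factors, the
## 10-read detectability filters, qCML common dispersion, the conditional
## negative-binomial exact test, and Storey/BH q-values.

#' TMM normalization factors
#'
#' Trimmed mean of M-values: the reference column is the one whose upper
#' quartile (of counts divided by library size) is closest to the mean upper
#' quartile; each column's factor is the weighted, doubly-trimmed mean of
#' per-gene log2 ratios against the reference (genes with a zero in either
#' column are excluded; weights are inverse asymptotic variances of M).
#' Factors are rescaled so their geometric mean is 1.
#'
#' @param x an [allele_counts()] object or a counts matrix.
#' @param trim_M two-sided trim fraction on the log-ratios (default 0.3).
#' @param trim_A two-sided trim fraction on average abundance (default 0.05).
#' @param lib.size optional library sizes (defaults to column sums).
#' @return For a matrix, a numeric vector of factors; for `allele_counts`,
#'   the object with `samples$norm.factors` filled in.
#' @export
tmm_factors <- function(x, trim_M = 0.3, trim_A = 0.05, lib.size = NULL) {
  if (inherits(x, "allele_counts")) {
    x$samples$norm.factors <- tmm_factors(x$counts, trim_M, trim_A,
                                          x$samples$lib.size)
    return(x)
  }
  K <- as.matrix(x)
  if (ncol(K) < 2L) stopf("TMM needs at least two columns")
  N <- lib.size %||% colSums(K)
  zero <- which(N == 0)
  if (length(zero)) stopf("column '%s' has zero total count",
                          colnames(K)[zero[1L]] %||% zero[1L])
  uq <- vapply(seq_len(ncol(K)),
               function(j) quantile(K[, j] / N[j], 0.75), numeric(1))
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(K)), function(j) {
    if (j == ref) return(1)
    .tmm_pair(K[, j], K[, ref], N[j], N[ref], trim_M, trim_A)
  }, numeric(1))
  f / exp(mean(log(f)))
}

## One column's TMM factor against the reference (on the 2^ scale).
.tmm_pair <- function(obs, ref, n_obs, n_ref, trim_M, trim_A) {
  keep0 <- obs > 0 & ref > 0
  obs <- obs[keep0]; ref <- ref[keep0]
  if (length(obs) == 0L) return(1)
  M <- log2((obs / n_obs) / (ref / n_ref))
  A <- (log2(obs / n_obs) + log2(ref / n_ref)) / 2
  w <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  n <- length(M)
  loM <- floor(n * trim_M) + 1; hiM <- n + 1 - loM
  loA <- floor(n * trim_A) + 1; hiA <- n + 1 - loA
  rM <- rank(M); rA <- rank(A)
  keep <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
  if (!any(keep) || all(w[keep] == 0)) return(1)
  fa <- sum(M[keep] / w[keep]) / sum(1 / w[keep])
  if (!is.finite(fa)) 1 else 2^fa
}

#' Detectability filters on raw allele counts
#'
#' Two read-support criteria on the unnormalized counts: a gene is
#' `hybrid_detectable` in a hybrid when at least one replicate has both
#' alleles at or above `min_reads`; it is a universally detectable ASE (UDA)
#' gene when every replicate of every hybrid has both alleles at or above
#' `min_reads`, making its ASE comparable across all crosses.
#'
#' @param x an [allele_counts()] object (raw counts).
#' @param min_reads minimum reads per allele (default 10).
#' @return A list with `hybrid_detectable` (logical matrix gene x hybrid)
#'   and `uda` (named logical vector).
#' @export
apply_filters <- function(x, min_reads = 10) {
  stopifnot(inherits(x, "allele_counts"))
  hybrids <- unique(x$samples$hybrid)
  det <- sapply(hybrids, function(h) {
    sel <- x$samples$hybrid == h
    sm <- x$samples[sel, ]
    K <- x$counts[, sel, drop = FALSE]
    alleles <- unique(sm$allele)
    vapply(sort(unique(sm$replicate)), function(r) {
      c1 <- K[, sm$allele == alleles[1L] & sm$replicate == r, drop = FALSE]
      c2 <- K[, sm$allele == alleles[2L] & sm$replicate == r, drop = FALSE]
      rowSums(c1) >= min_reads & rowSums(c2) >= min_reads
    }, logical(nrow(K)))
  }, simplify = FALSE)
  ng <- nrow(x$counts)
  hybrid_detectable <- vapply(det, function(m) rowSums(matrix(m, ng)) > 0,
                              logical(ng))
  if (is.null(dim(hybrid_detectable)))
    hybrid_detectable <- matrix(hybrid_detectable, ng,
                                dimnames = list(rownames(x$counts), hybrids))
  rownames(hybrid_detectable) <- rownames(x$counts)
  uda <- Reduce(`&`, lapply(det, function(m) {
    mm <- matrix(m, ng)
    rowSums(mm) == ncol(mm)
  }))
  list(hybrid_detectable = hybrid_detectable,
       uda = setNames(uda, rownames(x$counts)))
}

#' Common negative-binomial dispersion by conditional maximum likelihood
#'
#' Estimates one table-wide dispersion phi for a single hybrid by maximizing
#' the conditional NB log-likelihood summed over genes, conditioning on each
#' gene's total within each allele group (which removes the mean parameter),
#' after scaling counts to equalized effective library sizes.
#'
#' @param x an [allele_counts()] for one hybrid, with >= 2 replicates per
#'   allele; TMM factors are used if present.
#' @param interval search interval for phi.
#' @return The estimated dispersion (a single non-negative number).
#' @export
estimate_common_dispersion <- function(x, interval = c(1e-6, 5)) {
  stopifnot(inherits(x, "allele_counts"))
  if (length(unique(x$samples$hybrid)) != 1L)
    stopf("restrict the table to one hybrid first (see subset_hybrid)")
  eff <- effective_libsize(x)
  common <- exp(mean(log(eff)))
  pseudo <- sweep(x$counts, 2L, common / eff, `*`)
  groups <- split(seq_len(ncol(pseudo)), x$samples$allele)
  if (any(lengths(groups) < 2L)) stopf("need >= 2 replicates per allele")
  keep <- rowSums(pseudo) > 0
  pseudo <- pseudo[keep, , drop = FALSE]
  if (nrow(pseudo) == 0L) return(0)
  cond_ll <- function(log_phi) {
    r <- 1 / exp(log_phi)
    ll <- 0
    for (idx in groups) {
      y <- pseudo[, idx, drop = FALSE]
      n <- length(idx)
      z <- rowSums(y)
      ll <- ll + sum(rowSums(lgamma(y + r)) - n * lgamma(r) +
                       lgamma(n * r) - lgamma(z + n * r))
    }
    ll
  }
  opt <- optimize(cond_ll, interval = log(interval), maximum = TRUE,
                  tol = 1e-6)
  ## boundary: likelihood flat or decreasing in phi means no overdispersion
  if (cond_ll(log(interval[1L])) >= opt$objective) return(interval[1L])
  exp(opt$maximum)
}

#' Conditional negative-binomial exact test for allele imbalance
#'
#' Compares the two alleles of a gene as if they were the same gene in two
#' conditions with replicate NB counts and common dispersion `phi`. Counts
#' are scaled to a common effective library size, group sums are rounded,
#' and the two-sided p-value is computed by conditioning on the total: all
#' splits of the total whose conditional probability does not exceed that of
#' the observed split contribute. At `phi = 0` this is the conditional
#' binomial (each group sum Poisson); for `phi > 0` group sums are NB with
#' size `n_replicates / phi`.
#'
#' @param y1,y2 integer count vectors (replicates) for the two alleles.
#' @param size1,size2 effective library sizes per replicate.
#' @param phi common NB dispersion.
#' @return A list with `M` (log2 ratio of 0.5-pseudocounted normalized
#'   allele means), `abundance` (mean normalized count), and `p` in (0, 1].
#' @export
ase_test <- function(y1, y2, size1 = rep(1, length(y1)),
                     size2 = rep(1, length(y2)), phi = 0) {
  if (any(c(size1, size2) <= 0)) stopf("effective library sizes must be > 0")
  common <- exp(mean(log(c(size1, size2))))
  p1 <- y1 * common / size1
  p2 <- y2 * common / size2
  M <- log2((mean(p1) + 0.5) / (mean(p2) + 0.5))
  s1 <- round(sum(p1)); s2 <- round(sum(p2))
  p <- .exact_nb_p(s1, s2, length(y1), length(y2), phi)
  list(M = M, abundance = mean(c(p1, p2)), p = p)
}

## Two-sided conditional exact p for group sums s1, s2 from n1, n2 replicates
## at dispersion phi (equalized sizes). Probability-ordering ("doubletail by
## smaller-probability outcomes") definition.
.exact_nb_p <- function(s1, s2, n1, n2, phi) {
  s <- s1 + s2
  if (s == 0) return(1)
  k <- 0:s
  if (phi < 1e-12) {
    lp <- dbinom(k, s, n1 / (n1 + n2), log = TRUE)
  } else {
    r1 <- n1 / phi
    r2 <- n2 / phi
    mu <- s / (n1 + n2)
    lp <- dnbinom(k, size = r1, mu = n1 * mu, log = TRUE) +
      dnbinom(s - k, size = r2, mu = n2 * mu, log = TRUE)
    lp <- lp - max(lp)
    lp <- lp - log(sum(exp(lp)))
  }
  pr <- exp(lp)
  obs <- pr[s1 + 1L]
  min(1, sum(pr[pr <= obs * (1 + 1e-10)]))
}

#' q-values for multiple testing
#'
#' Storey's method estimates the proportion of true nulls pi0 from the
#' p-value distribution on the lambda grid 0.05..0.95 (cubic smoothing
#' spline, evaluated at the largest lambda, clipped to (0, 1\]) and returns
#' `q_i = min over p_j >= p_i of pi0 * m * p_j / rank(p_j)`. With
#' `method = "bh"` (or `pi0 = 1`) this reduces to Benjamini-Hochberg
#' adjusted p-values.
#'
#' @param p vector of p-values in \[0, 1\].
#' @param method `"storey"` or `"bh"`.
#' @param pi0 optional override of the null proportion.
#' @return A vector of q-values; the pi0 used is attached as attribute
#'   `"pi0"`.
#' @export
qvalues <- function(p, method = c("storey", "bh"), pi0 = NULL) {
  method <- match.arg(method)
  if (any(is.na(p)) || any(p < 0 | p > 1)) stopf("p-values must be in [0, 1]")
  m <- length(p)
  if (m == 0L) return(numeric(0))
  if (is.null(pi0)) {
    if (method == "bh" || m < 100L) {
      pi0 <- 1
    } else {
      lambda <- seq(0.05, 0.95, 0.05)
      pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
      fit <- smooth.spline(lambda, pi0_l, df = 3)
      pi0 <- predict(fit, x = max(lambda))$y
      pi0 <- min(1, max(pi0, 1e-8))
    }
  }
  o <- order(p, decreasing = TRUE)
  q <- numeric(m)
  q[o] <- cummin(pi0 * m * p[o] / rank(p, ties.method = "max")[o])
  q <- pmin(q, 1)
  attr(q, "pi0") <- pi0
  q
}

#' Per-hybrid allele-specific expression analysis
#'
#' The full per-hybrid ASE stage: TMM factors over the hybrid's columns,
#' detectability filters, qCML common dispersion, the conditional NB exact
#' test per detectable gene, and q-values. Genes failing the filters are
#' carried with `NA` statistics and a reason code, never dropped.
#'
#' @param x an [allele_counts()] covering one or more hybrids.
#' @param hybrid which hybrid to analyse (default: the only one present).
#' @param min_reads detectability threshold (default 10 reads per allele).
#' @param qvalue_method `"storey"` or `"bh"`.
#' @param excluded optional character vector of gene ids excluded upstream
#'   (e.g. by [pair_alleles()] flags); carried with reason `"excluded"`.
#' @return A data.frame of class `ase_table`: gene, hybrid, `allele1`,
#'   `allele2`, M (log2 allele1/allele2), abundance, p, q, `detectable`,
#'   `reason`; the dispersion estimate and pi0 are attached as attributes.
#' @export
ase_fit <- function(x, hybrid = NULL, min_reads = 10,
                    qvalue_method = "storey", excluded = NULL) {
  stopifnot(inherits(x, "allele_counts"))
  hybrid <- hybrid %||% unique(x$samples$hybrid)
  if (length(hybrid) != 1L) stopf("specify one hybrid")
  xh <- subset_hybrid(x, hybrid)
  xh <- tmm_factors(xh)
  filt <- apply_filters(xh, min_reads)
  detectable <- filt$hybrid_detectable[, 1L]
  phi <- estimate_common_dispersion(xh)
  alleles <- strsplit(hybrid, "x", fixed = TRUE)[[1L]]
  eff <- effective_libsize(xh)
  i1 <- xh$samples$allele == alleles[1L]
  i2 <- xh$samples$allele == alleles[2L]
  genes <- rownames(xh$counts)
  out <- data.frame(gene = genes, hybrid = hybrid,
                    allele1 = alleles[1L], allele2 = alleles[2L],
                    M = NA_real_, abundance = NA_real_, p = NA_real_,
                    q = NA_real_, detectable = detectable,
                    reason = "", stringsAsFactors = FALSE)
  is_exc <- genes %in% (excluded %||% character(0))
  out$reason[!detectable] <- "low_reads"
  out$reason[is_exc] <- "excluded"
  test_idx <- which(detectable & !is_exc)
  for (g in test_idx) {
    r <- ase_test(xh$counts[g, i1], xh$counts[g, i2], eff[i1], eff[i2], phi)
    out$M[g] <- r$M
    out$abundance[g] <- r$abundance
    out$p[g] <- r$p
  }
  if (length(test_idx)) {
    q <- qvalues(out$p[test_idx], method = qvalue_method)
    out$q[test_idx] <- q
    attr(out, "pi0") <- attr(q, "pi0")
  }
  attr(out, "dispersion") <- phi
  class(out) <- c("ase_table", "data.frame")
  out
}

#' @export
print.ase_table <- function(x, ...) {
  if (is.null(x$hybrid) || is.null(attr(x, "dispersion"))) {
    print.data.frame(x, ...)
    return(invisible(x))
  }
  tested <- sum(!is.na(x$p))
  cat(sprintf("ase_table %s: %d genes, %d tested (dispersion %.4f), %d at q < 0.05\n",
              x$hybrid[1L], nrow(x), tested, attr(x, "dispersion"),
              sum(x$q < 0.05, na.rm = TRUE)))
  invisible(x)
}
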