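## Independent brute-force oracles and small generators shared by the unit
## and acceptance tests. These deliberately avoid the package's vectorized
## code paths: plain loops and direct formulas only.

## GOMER occupancy by exhaustive window enumeration on both strands,
## products computed base by base.
oracle_gomer <- function(motif, promoter) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  chars <- strsplit(promoter, NULL)[[1L]]
  L <- motif$length
  n <- length(chars)
  if (n < L) return(0)
  probs <- c()
  for (i in 1:(n - L + 1L)) {
    pf <- 1
    pr <- 1
    for (j in 1:L) {
      pf <- pf * motif$prob[j, chars[i + j - 1L]]
      pr <- pr * motif$prob[j, comp[chars[i + L - j]]]
    }
    probs <- c(probs, pf, pr)
  }
  1 - prod(1 - probs)
}

## TMM factors re-implemented directly from the definition.
oracle_tmm <- function(K, trim_M = 0.3, trim_A = 0.05) {
  N <- colSums(K)
  uq <- sapply(seq_len(ncol(K)), function(j) quantile(K[, j] / N[j], 0.75))
  ref <- which.min(abs(uq - mean(uq)))
  f <- numeric(ncol(K))
  for (j in seq_len(ncol(K))) {
    if (j == ref) { f[j] <- 1; next }
    keep <- K[, j] > 0 & K[, ref] > 0
    o <- K[keep, j]; r <- K[keep, ref]
    M <- log2((o / N[j]) / (r / N[ref]))
    A <- 0.5 * log2((o / N[j]) * (r / N[ref]))
    w <- (N[j] - o) / (N[j] * o) + (N[ref] - r) / (N[ref] * r)
    n <- length(M)
    loM <- floor(n * trim_M) + 1; hiM <- n + 1 - loM
    loA <- floor(n * trim_A) + 1; hiA <- n + 1 - loA
    sel <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
    f[j] <- 2^(sum(M[sel] / w[sel]) / sum(1 / w[sel]))
  }
  f / exp(mean(log(f)))
}

## Detectability filters by explicit double loop.
oracle_filters <- function(x, min_reads = 10) {
  hybrids <- unique(x$samples$hybrid)
  genes <- rownames(x$counts)
  det <- matrix(FALSE, length(genes), length(hybrids),
                dimnames = list(genes, hybrids))
  uda <- rep(TRUE, length(genes))
  for (g in seq_along(genes)) {
    for (h in hybrids) {
      sm <- x$samples
      alleles <- unique(sm$allele[sm$hybrid == h])
      any_rep <- FALSE
      for (r in unique(sm$replicate[sm$hybrid == h])) {
        c1 <- x$counts[g, sm$hybrid == h & sm$allele == alleles[1] &
                         sm$replicate == r]
        c2 <- x$counts[g, sm$hybrid == h & sm$allele == alleles[2] &
                         sm$replicate == r]
        ok <- c1 >= min_reads && c2 >= min_reads
        any_rep <- any_rep || ok
        if (!ok) uda[g] <- FALSE
      }
      det[g, h] <- any_rep
    }
  }
  list(hybrid_detectable = det, uda = setNames(uda, genes))
}

## Conditional exact p by numeric convolution of per-replicate NB pmfs
## (never uses the NB group-sum closed form the implementation relies on).
oracle_exact_p <- function(s1, s2, n1, n2, phi) {
  s <- s1 + s2
  if (s == 0) return(1)
  rep_pmf <- function(k) {
    if (phi == 0) dpois(k, 1) else dnbinom(k, size = 1 / phi, mu = 1)
  }
  base <- rep_pmf(0:s)
  conv_n <- function(n) {
    out <- base
    if (n > 1) for (i in 2:n) {
      new <- numeric(s + 1)
      for (tot in 0:s)
        new[tot + 1] <- sum(out[seq_len(tot + 1)] * base[(tot + 1):1])
      out <- new
    }
    out
  }
  g1 <- conv_n(n1)
  g2 <- conv_n(n2)
  joint <- g1 * rev(g2)          # P(sum1 = k, sum2 = s - k)
  cond <- joint / sum(joint)
  obs <- cond[s1 + 1]
  min(1, sum(cond[cond <= obs * (1 + 1e-10)]))
}

## Sharp random motif with a given consensus probability.
rand_motif <- function(name, L = 8, sharp = 0.88, seed = NULL) {
  build <- function() {
    cons <- sample.int(4L, L, replace = TRUE)
    pr <- matrix((1 - sharp) / 3, L, 4L)
    pr[cbind(seq_len(L), cons)] <- sharp
    motif_model(name, pr)
  }
  if (is.null(seed)) build() else hybridase:::with_seed(seed, build())
}

## Fully random (Dirichlet-ish) motif for oracle comparisons.
rand_soft_motif <- function(name, L) {
  pr <- matrix(runif(4 * L, 0.05, 1), L, 4L)
  pr <- pr / rowSums(pr)
  motif_model(name, pr, pseudocount = 0)
}

random_seq <- function(len) paste(sample(c("A", "C", "G", "T"), len,
                                         replace = TRUE), collapse = "")
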