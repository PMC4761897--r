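make_seqs <- function(orfs, proms = NULL) {
  genes <- names(orfs)
  if (is.null(proms))
    proms <- setNames(rep(paste(rep("A", 60), collapse = ""),
                          length(genes)), genes)
  list(promoter = proms, orf = orfs)
}

test_that("pair_alleles sets exclusion flags and discriminating positions", {
  a <- make_seqs(c(g1 = "ACGTACGTAC", g2 = "AAAAAAAAAA", g3 = "ACGT"))
  b <- make_seqs(c(g1 = "ACGTACGTAC", g2 = "AAAAANAAAA", g4 = "ACGT"))
  pr <- pair_alleles(a, b, c("A", "B"), promoter_window = c(-10, 0))
  expect_true(pr$g3$flags$missing_in_strain)
  expect_true(pr$g4$flags$missing_in_strain)
  expect_true(pr$g2$flags$has_N)
  expect_false(any(unlist(pr$g1$flags)))
  expect_identical(pr$g1$snp_orf, integer(0))
  ## differences at exactly the stated 0-based offsets
  orf_a <- paste(rep("A", 300), collapse = "")
  orf_b <- orf_a
  substr(orf_b, 11, 11) <- "C"   # 0-based offset 10
  substr(orf_b, 251, 251) <- "G" # 0-based offset 250
  pr2 <- pair_alleles(make_seqs(c(gx = orf_a)), make_seqs(c(gx = orf_b)),
                      c("A", "B"), promoter_window = c(-10, 0))
  expect_identical(pr2$gx$snp_orf, c(10L, 250L))
  ## length mismatch flag
  pr3 <- pair_alleles(make_seqs(c(gy = "ACGTACGT")),
                      make_seqs(c(gy = "ACGTACG")), c("A", "B"),
                      promoter_window = c(-10, 0))
  expect_true(pr3$gy$flags$length_mismatch)
  expect_error(pair_alleles(make_seqs(c(q1 = "ACGT")),
                            make_seqs(c(q2 = "ACGT"))), "no shared")
})

test_that("promoter windows use signed upstream offsets, 0-based half-open", {
  u <- random_seq(300)
  pr <- pair_alleles(make_seqs(c(g = "ACGT"), c(g = u)),
                     make_seqs(c(g = "ACGT"), c(g = u)),
                     c("A", "B"), promoter_window = c(-250, -50))
  expect_identical(pr$g$promoter[["A"]], substr(u, 51, 250))
  expect_equal(nchar(pr$g$promoter[["A"]]), 200)
  ## -1 is the base immediately upstream
  pr2 <- pair_alleles(make_seqs(c(g = "ACGT"), c(g = u)),
                      make_seqs(c(g = "ACGT"), c(g = u)),
                      c("A", "B"), promoter_window = c(-1, 0))
  expect_identical(pr2$g$promoter[["A"]], substr(u, 300, 300))
  ## too-short upstream sequence is flagged
  pr3 <- pair_alleles(make_seqs(c(g = "ACGT"), c(g = "ACGTAC")),
                      make_seqs(c(g = "ACGT"), c(g = "ACGTAC")),
                      c("A", "B"), promoter_window = c(-250, -50))
  expect_true(pr3$g$flags$length_mismatch)
})

test_that("classify_read handles SNP-spanning, SNP-free and erroneous reads", {
  orf_a <- "ACGTACGTACGTACGTACGTGCAT"
  orf_b <- orf_a
  substr(orf_b, 10, 10) <- "A"   # SNP at 0-based 9
  pr <- pair_alleles(make_seqs(c(g = orf_a)), make_seqs(c(g = orf_b)),
                     c("A", "B"), promoter_window = c(-10, 0))$g
  expect_identical(classify_read(substr(orf_a, 6, 13), pr), "A")
  expect_identical(classify_read(substr(orf_b, 6, 13), pr), "B")
  ## read from a SNP-free, non-repetitive region
  expect_identical(classify_read(substr(orf_a, 17, 24), pr), "uninformative")
  ## reverse-complement read still classified
  rc <- function(s) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s)))
  expect_identical(classify_read(rc(substr(orf_a, 6, 13)), pr), "A")
  ## one sequencing error, still nearer allele A
  err <- substr(orf_a, 6, 13)
  substr(err, 1, 1) <- "T"
  expect_identical(classify_read(err, pr, max_mismatch = 2), "A")
  expect_identical(classify_read(err, pr, max_mismatch = 0), "uninformative")
  expect_error(classify_read(paste(rep("A", 50), collapse = ""), pr),
               "longer")
})

test_that("classify_read agrees with exhaustive offset enumeration", {
  brute <- function(read, pr, max_mismatch) {
    rc <- function(s) as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(s)))
    L <- nchar(read)
    n <- nchar(pr$orf[[1]])
    rows <- NULL
    for (strand in c("f", "r")) {
      rd <- strsplit(if (strand == "f") read else rc(read), NULL)[[1]]
      for (off in 1:(n - L + 1)) {
        ma <- sum(rd != strsplit(substr(pr$orf[[1]], off, off + L - 1),
                                 NULL)[[1]])
        mb <- sum(rd != strsplit(substr(pr$orf[[2]], off, off + L - 1),
                                 NULL)[[1]])
        covered <- any(pr$snp_orf >= off - 1 & pr$snp_orf <= off + L - 2)
        rows <- rbind(rows, data.frame(strand, off, ma, mb, covered))
      }
    }
    best <- min(pmin(rows$ma, rows$mb))
    if (best > max_mismatch) return("uninformative")
    cand <- rows[pmin(rows$ma, rows$mb) == best & rows$ma != rows$mb &
                   rows$covered, ]
    cand <- cand[order(cand$strand, cand$off), ]  # "f" < "r", then leftmost
    if (nrow(cand) == 0) return("uninformative")
    names(pr$orf)[if (cand$ma[1] < cand$mb[1]) 1 else 2]
  }
  set.seed(77)
  for (rep in 1:25) {
    orf_a <- random_seq(60)
    orf_b <- orf_a
    pos <- sample(60, 3)
    for (p in pos) substr(orf_b, p, p) <-
        sample(setdiff(c("A", "C", "G", "T"), substr(orf_a, p, p)), 1)
    pr <- pair_alleles(make_seqs(c(g = orf_a)), make_seqs(c(g = orf_b)),
                       c("A", "B"), promoter_window = c(-10, 0))$g
    src <- if (rep %% 2) orf_a else orf_b
    start <- sample(41, 1)
    read <- substr(src, start, start + 19)
    if (rep %% 3 == 0) { # inject an error
      q <- sample(20, 1)
      substr(read, q, q) <- sample(c("A", "C", "G", "T"), 1)
    }
    expect_identical(classify_read(read, pr, max_mismatch = 2),
                     brute(read, pr, 2))
  }
})

test_that("classification is symmetric in allele order", {
  set.seed(12)
  orf_a <- random_seq(80)
  orf_b <- orf_a
  substr(orf_b, 30, 30) <- "N"  # will be replaced below to stay ACGT
  substr(orf_b, 30, 30) <- if (substr(orf_a, 30, 30) == "A") "C" else "A"
  fwd <- pair_alleles(make_seqs(c(g = orf_a)), make_seqs(c(g = orf_b)),
                      c("A", "B"), promoter_window = c(-10, 0))$g
  rev <- pair_alleles(make_seqs(c(g = orf_b)), make_seqs(c(g = orf_a)),
                      c("B", "A"), promoter_window = c(-10, 0))$g
  for (i in 1:15) {
    start <- sample(61, 1)
    read <- substr(if (i %% 2) orf_a else orf_b, start, start + 19)
    c1 <- classify_read(read, fwd)
    c2 <- classify_read(read, rev)
    expect_identical(c1, c2)  # labels are strain names, so symmetric
  }
})

test_that("count_alleles recovers true counts for error-free reads", {
  cfg <- sim_config(n_genes = 25, n_strains = 2, strains = c("A", "B"),
                    baseline_mean = 15, orf_len = 300, snp_rate = 0.02,
                    seed = 31)
  sim <- simulate_strains(cfg)
  cnt <- simulate_counts(sim)
  one_col <- cnt
  one_col$counts <- one_col$counts[, 1:2]      # one replicate, both alleles
  one_col$samples <- one_col$samples[1:2, ]
  reads <- simulate_reads(sim, one_col, read_len = 100, error_rate = 0,
                          seed = 3)
  pairs <- pair_alleles(sim$sequences$A, sim$sequences$B, c("A", "B"),
                        promoter_window = c(-200, 0))
  res <- count_alleles(reads, pairs)
  ## every classified read must be correct; informative = covers >= 1 SNP
  for (s in c("A", "B")) {
    got <- res$counts[res$counts$allele == s, ]
    truth <- vapply(got$gene, function(g) {
      rr <- reads[reads$gene == g & reads$allele == s, ]
      pr <- pairs[[g]]
      sum(vapply(seq_len(nrow(rr)), function(i)
        any(pr$snp_orf >= rr$start[i] & pr$snp_orf <= rr$start[i] + 99),
        logical(1)))
    }, numeric(1))
    expect_equal(got$count, unname(truth))
  }
  ## informativeness matches the exact coverage probability (uniform read
  ## starts over known SNP positions)
  expected <- mean(vapply(pairs, function(p) {
    ok <- 0
    for (st in 0:200) ok <- ok + any(p$snp_orf >= st & p$snp_orf <= st + 99)
    ok / 201
  }, numeric(1)))
  expect_lt(abs(res$informative_fraction - expected), 0.05)
})
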