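test_that("motif construction validates and pseudocounts", {
  m <- motif_model("toy", matrix(c(1, 0, 0, 0,
                                   0, 0, 0, 1), 2, 4, byrow = TRUE),
                   pseudocount = 0.01)
  expect_equal(m$length, 2)
  expect_identical(m$consensus, "AT")
  expect_true(all(m$prob > 0))
  expect_equal(rowSums(m$prob), c(1, 1), tolerance = 1e-12)
  expect_error(motif_model("bad", matrix(c(0.5, 0.2, 0.2, 0.2), 1, 4)),
               "sums")
})

test_that("MEME files round-trip and report parse errors with location", {
  set.seed(5)
  motifs <- list(rand_soft_motif("M1", 6), rand_soft_motif("M2", 9))
  names(motifs) <- c("M1", "M2")
  path <- tempfile(fileext = ".meme")
  write_meme(motifs, path)
  back <- read_meme(path, pseudocount = 0)
  expect_length(back, 2)
  expect_equal(back$M1$prob, motifs$M1$prob, tolerance = 1e-5)
  expect_equal(back$M2$prob, motifs$M2$prob, tolerance = 1e-5)
  ## zero entries become strictly positive under the load pseudocount
  m0 <- motif_model("z", matrix(c(1, 0, 0, 0), 3, 4, byrow = TRUE),
                    pseudocount = 0)
  write_meme(list(z = m0), path)
  expect_true(all(read_meme(path, pseudocount = 0.01)$z$prob > 0))
  ## malformed matrix row (3 values instead of 4)
  lines <- readLines(path)
  lines[grep("^[0-9]", lines)[1]] <- "0.1 0.2 0.3"
  bad <- tempfile(fileext = ".meme")
  writeLines(lines, bad)
  expect_error(read_meme(bad), "malformed|rows|sum")
})

test_that("window scores are PWM probability products", {
  m <- motif_model("u", matrix(0.25, 3, 4), pseudocount = 0)
  expect_equal(window_score(m, "ACG"), 0.25^3, tolerance = 1e-15)
  sharp <- rand_motif("s", L = 5, sharp = 0.97, seed = 2)
  ## consensus probability (0.97 + alpha) / (1 + 4 alpha) per position
  expect_equal(window_score(sharp, sharp$consensus), (0.98 / 1.04)^5,
               tolerance = 1e-12)
  ## independent product oracle on random motif/window pairs
  set.seed(8)
  for (i in 1:20) {
    mm <- rand_soft_motif(paste0("r", i), sample(3:9, 1))
    w <- random_seq(mm$length)
    chars <- strsplit(w, NULL)[[1]]
    manual <- 1
    for (j in seq_len(mm$length)) manual <- manual * mm$prob[j, chars[j]]
    expect_lt(abs(window_score(mm, w) - unname(manual)), 1e-12)
  }
  expect_error(window_score(m, "ACGT"), "length")
  expect_error(window_score(m, "ANG"), "non-ACGT")
})

test_that("gomer_pbound matches exhaustive both-strand enumeration", {
  set.seed(21)
  for (i in 1:30) {
    m <- rand_soft_motif(paste0("m", i), sample(2:8, 1))
    prom <- random_seq(sample(0:40, 1))
    expect_lt(abs(gomer_pbound(m, prom) - oracle_gomer(m, prom)), 1e-12)
  }
  ## promoter shorter than motif
  m <- rand_soft_motif("m", 6)
  expect_equal(gomer_pbound(m, "ACG"), 0)
  ## an absorbing p = 1 site forces P_bound = 1
  hard <- motif_model("h", matrix(c(1, 0, 0, 0), 2, 4, byrow = TRUE),
                      pseudocount = 0)
  expect_equal(gomer_pbound(hard, "CCAACC"), 1)
})

test_that("gomer_pbound is strand-invariant and monotone, ASB antisymmetric", {
  set.seed(33)
  rc <- function(s) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s)))
  for (i in 1:15) {
    m <- rand_soft_motif(paste0("m", i), sample(3:8, 1))
    a <- random_seq(30)
    b <- random_seq(30)
    ## strand invariance: scanning the reverse-complement sequence with the
    ## same motif gives the same occupancy
    expect_equal(gomer_pbound(m, a), gomer_pbound(m, rc(a)),
                 tolerance = 1e-12)
    ## bounds and antisymmetry
    v <- asb(m, a, b)
    expect_true(v >= -1 && v <= 1)
    expect_equal(v, -asb(m, b, a), tolerance = 1e-15)
    expect_equal(asb(m, a, a), 0)
  }
  ## monotonicity: strengthening the best site cannot decrease occupancy
  m <- rand_motif("mono", L = 6, sharp = 0.9, seed = 3)
  weak <- random_seq(40)
  strong <- weak
  substr(strong, 10, 15) <- m$consensus
  expect_gt(gomer_pbound(m, strong), gomer_pbound(m, weak))
})

test_that("affinity mode saturates and stays within bounds", {
  m <- rand_motif("aff", L = 6, sharp = 0.95, seed = 7)
  p <- gomer_pbound(m, paste0("AAAA", m$consensus, "AAAA"),
                    mode = "affinity")
  expect_true(p > 0 && p <= 1)
  k <- window_score(m, m$consensus) / 0.25^6
  expect_equal(window_score(m, m$consensus, mode = "affinity"),
               k / (1 + k), tolerance = 1e-12)
})

test_that("N-containing windows are skipped with a warning", {
  m <- rand_soft_motif("n", 4)
  prom <- paste0(random_seq(10), "N", random_seq(10))
  expect_warning(p <- gomer_pbound(m, prom), "skipped")
  clean_left <- substr(prom, 1, 10)
  clean_right <- substr(prom, 12, 21)
  manual <- 1 - (1 - oracle_gomer(m, clean_left)) *
    (1 - oracle_gomer(m, clean_right))
  expect_equal(p, manual, tolerance = 1e-12)
  expect_error(gomer_pbound(m, "ACGTXACGT"), "non-ACGTN")
})

test_that("snp_binding_report attributes disruptions to the right SNP", {
  m <- rand_motif("rep", L = 8, sharp = 0.9, seed = 13)
  base <- random_seq(60)
  a <- base
  substr(a, 21, 28) <- m$consensus
  b <- a
  info <- rowSums(m$prob * log(m$prob))
  jmax <- which.max(info)
  weak <- c("A", "C", "G", "T")[which.min(m$prob[jmax, ])]
  substr(b, 20 + jmax, 20 + jmax) <- weak
  ## add a second, irrelevant SNP far from the site
  substr(b, 50, 50) <- if (substr(a, 50, 50) == "A") "C" else "A"
  rep_tab <- snp_binding_report(m, a, b)
  expect_equal(nrow(rep_tab), 2)
  expect_equal(rep_tab$position[1], 20 + jmax - 1)  # 0-based; ranked first
  expect_lt(rep_tab$rel_change[1], 0)               # disruption lowers score
  expect_true(rep_tab$below_threshold[2])
  ## identical promoters: empty report
  expect_equal(nrow(snp_binding_report(m, a, a)), 0)
})

test_that("pbound_matrix equals per-promoter gomer_pbound", {
  set.seed(41)
  motifs <- setNames(lapply(1:3, function(i) rand_soft_motif(paste0("t", i), 5)),
                     paste0("t", 1:3))
  seqs <- list(
    A = list(promoter = setNames(replicate(4, random_seq(30)),
                                 paste0("g", 1:4))),
    B = list(promoter = setNames(replicate(4, random_seq(30)),
                                 paste0("g", 1:4))))
  pb <- pbound_matrix(motifs, seqs)
  for (tf in names(motifs))
    for (s in c("A", "B"))
      for (g in paste0("g", 1:4))
        expect_equal(pb[g, tf, s],
                     gomer_pbound(motifs[[tf]], seqs[[s]]$promoter[[g]]),
                     tolerance = 1e-14)
  asb_df <- asb_from_pbound(pb, "AxB")
  expect_equal(asb_df$asb,
               as.vector(pb[, , "A"] - pb[, , "B"]), tolerance = 1e-14)
})
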