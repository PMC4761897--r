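test_that("generator is deterministic and substitution-only", {
  cfg <- sim_config(n_genes = 20, seed = 42)
  s1 <- simulate_strains(cfg)
  s2 <- simulate_strains(cfg)
  expect_identical(s1$sequences, s2$sequences)
  expect_identical(s1$truth$cis, s2$truth$cis)
  d1 <- file.path(tempdir(), "simA"); d2 <- file.path(tempdir(), "simB")
  write_sim(s1, d1); write_sim(s2, d2)
  for (f in list.files(d1, pattern = "fasta$"))
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  ## equal lengths: alleles differ by substitutions only
  for (s in cfg$strains) {
    expect_identical(nchar(s1$sequences[[s]]$promoter),
                     nchar(s1$sequences[[1]]$promoter))
    expect_identical(nchar(s1$sequences[[s]]$orf),
                     nchar(s1$sequences[[1]]$orf))
  }
  ## zero SNP rate: all strains identical
  s0 <- simulate_strains(sim_config(n_genes = 10, snp_rate = 0, seed = 1))
  expect_identical(s0$sequences[[1]], s0$sequences[[2]])
})

test_that("realized pairwise SNP density matches the configured rate", {
  cfg <- sim_config(n_genes = 1000, n_strains = 2, strains = c("A", "B"),
                    promoter_len = 200, snp_rate = 0.005, seed = 3)
  sim <- simulate_strains(cfg)
  pairs <- pair_alleles(sim$sequences$A, sim$sequences$B, c("A", "B"),
                        promoter_window = c(-200, 0))
  snps <- vapply(pairs, function(p) length(p$snp_promoter), numeric(1))
  ## expectation ~1 SNP per 200-bp promoter; SE of the mean ~ sqrt(1/1000)
  expect_lt(abs(mean(snps) - 1), 3 * sqrt(1 / 1000) + 0.02)
})

test_that("planted cis effects set the allele count ratio", {
  cfg <- sim_config(n_genes = 400, n_strains = 2, strains = c("A", "B"),
                    baseline_mean = 500, dispersion = 0.01,
                    frac_cis = 1, cis_log2_effect = 1,
                    library_size_range = c(2e5, 2e5), seed = 9)
  sim <- simulate_strains(cfg)
  cnt <- simulate_counts(sim)
  eff <- sim$truth$cis[, "A"] - sim$truth$cis[, "B"]
  sm <- cnt$samples
  m_a <- rowMeans(cnt$counts[, sm$allele == "A", drop = FALSE])
  m_b <- rowMeans(cnt$counts[, sm$allele == "B", drop = FALSE])
  ratio <- mean((log2(m_a / m_b))[eff == 1])
  expect_lt(abs(ratio - 1), 0.1)
  ratio_dn <- mean((log2(m_a / m_b))[eff == -1])
  expect_lt(abs(ratio_dn + 1), 0.1)
})

test_that("zero dispersion gives Poisson-like counts", {
  cfg <- sim_config(n_genes = 3000, n_strains = 2, strains = c("A", "B"),
                    baseline_mean = 100, dispersion = 0,
                    library_size_range = c(3e5, 3e5), seed = 5)
  cnt <- simulate_counts(simulate_strains(cfg))
  x <- cnt$counts[, 1]
  expect_lt(abs(var(x) / mean(x) - 1), 0.1)
})

test_that("library sizes land in the configured range", {
  cfg <- sim_config(n_genes = 500, n_strains = 2, strains = c("A", "B"),
                    baseline_mean = 100, seed = 2)
  cnt <- simulate_counts(simulate_strains(cfg))
  ## column sums concentrate near their drawn totals (multiplier mean ~1)
  expect_true(all(cnt$samples$lib.size > 0.85 * cfg$library_size_range[1]))
  expect_true(all(cnt$samples$lib.size < 1.15 * cfg$library_size_range[2]))
})

test_that("motif planting embeds a recoverable, optionally disrupted site", {
  m <- rand_motif("TFX", L = 8, seed = 11)
  cfg <- sim_config(n_genes = 30, n_strains = 2, strains = c("A", "B"),
                    seed = 13)
  sim <- simulate_strains(cfg)
  genes <- rownames(sim$truth$cis)[1:10]
  sim <- plant_motifs(sim, m, genes, disrupt_in_strain = "B",
                      cis_link_log2 = 0.5, seed = 17)
  plants <- sim$truth$plants
  expect_setequal(plants$gene, genes)
  for (i in seq_len(nrow(plants))) {
    g <- plants$gene[i]
    prom_a <- sim$sequences$A$promoter[[g]]
    ## site recoverable: the argmax-scoring window sits at the recorded offset
    sc <- vapply(seq_len(nchar(prom_a) - m$length + 1), function(o)
      window_score(m, substr(prom_a, o, o + m$length - 1)), numeric(1))
    expect_equal(which.max(sc) - 1L, plants$offset[i])
    ## disrupted allele binds less
    expect_gt(gomer_pbound(m, prom_a),
              gomer_pbound(m, sim$sequences$B$promoter[[g]]))
    ## cis link lowered the disrupted strain's allele
    expect_equal(unname(sim$truth$cis[g, "B"]), -0.5)
  }
  ## no disruption and no background SNPs: identical alleles, ASB exactly 0
  cfg0 <- sim_config(n_genes = 30, n_strains = 2, strains = c("A", "B"),
                     snp_rate = 0, seed = 13)
  sim2 <- plant_motifs(simulate_strains(cfg0), m, genes, seed = 19)
  for (g in genes) {
    expect_identical(sim2$sequences$A$promoter[[g]],
                     sim2$sequences$B$promoter[[g]])
    expect_equal(asb(m, sim2$sequences$A$promoter[[g]],
                     sim2$sequences$B$promoter[[g]]), 0)
  }
  expect_error(plant_motifs(sim, rand_motif("long", L = 300, seed = 1),
                            genes[1]), "longer")
})

test_that("simulated reads carry labels and respect the error model", {
  cfg <- sim_config(n_genes = 40, n_strains = 2, strains = c("A", "B"),
                    baseline_mean = 20, orf_len = 300, seed = 23)
  sim <- simulate_strains(cfg)
  cnt <- simulate_counts(sim)
  expect_error(simulate_reads(sim, cnt, read_len = 400), "exceeds")
  reads <- simulate_reads(sim, cnt, read_len = 100, error_rate = 0, seed = 1)
  expect_equal(nrow(reads), sum(cnt$counts))
  ## error-free forward reads are exact substrings of their allele of origin
  sel <- which(reads$strand == "+")[1:50]
  for (i in sel) {
    orf <- sim$sequences[[reads$allele[i]]]$orf[[reads$gene[i]]]
    expect_identical(reads$read[i],
                     substr(orf, reads$start[i] + 1, reads$start[i] + 100))
  }
})
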