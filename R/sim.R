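## Synthetic-data generator: parental strain sequences, motif plants,
## allele-resolved negative-binomial counts and reads, all with recorded
## ground truth and fully determined by the configuration seed.

#' Simulation configuration
#'
#' Defines the study design emulated by the generator: four parental strains
#' whose sequences diverge by substitutions at a pairwise density of about
#' one SNP per 200 bp, all pairwise F1 hybrids grown in triplicate, and
#' negative-binomial allele counts (variance mu + phi mu^2) with optional
#' planted cis effects and strain-specific TF trans-activities.
#'
#' @param n_genes number of genes.
#' @param n_strains number of parental strains (default 4).
#' @param strains strain identifiers (default WE, NAm, WA, SA; `NAm` is used
#'   for the North American strain to avoid R's reserved `NA` token).
#' @param promoter_len promoter length in bp (default 200).
#' @param orf_len ORF length in bp (default 500).
#' @param snp_rate expected pairwise substitution density per bp between two
#'   strains (default 0.005, i.e. ~1 SNP / 200 bp).
#' @param n_replicates replicates per hybrid (default 3).
#' @param baseline_mean expected counts per allele per replicate (default 200).
#' @param dispersion negative-binomial dispersion phi, so that
#'   variance = mu + phi * mu^2 (default 0.05; 0 gives Poisson counts).
#' @param frac_cis fraction of genes carrying a cis effect (default 0).
#' @param cis_log2_effect absolute log2 fold difference between alleles for
#'   cis genes (default 1).
#' @param tf_activities optional numeric matrix (TF x strain) of
#'   multiplicative trans activities; entries of 1 mean no effect.
#' @param library_size_range numeric length-2 vector of total column counts;
#'   defaults to `baseline_mean * n_genes * c(0.9, 1.1)`.
#' @param seed integer seed; the seed fully determines all generator output.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_genes, n_strains = 4,
                       strains = c("WE", "NAm", "WA", "SA")[seq_len(n_strains)],
                       promoter_len = 200, orf_len = 500, snp_rate = 0.005,
                       n_replicates = 3, baseline_mean = 200,
                       dispersion = 0.05, frac_cis = 0, cis_log2_effect = 1,
                       tf_activities = NULL, library_size_range = NULL,
                       seed = 1) {
  if (n_genes < 1 || promoter_len < 1 || orf_len < 1 || n_replicates < 1 ||
      n_strains < 2)
    stopf("counts and lengths must be positive (and n_strains >= 2)")
  if (snp_rate < 0 || snp_rate >= 1) stopf("snp_rate must be in [0, 1)")
  if (dispersion < 0) stopf("dispersion must be >= 0")
  if (baseline_mean <= 0) stopf("baseline_mean must be > 0")
  if (frac_cis < 0 || frac_cis > 1) stopf("frac_cis must be in [0, 1]")
  if (length(strains) != n_strains) stopf("need %d strain names", n_strains)
  if (is.null(library_size_range))
    library_size_range <- baseline_mean * n_genes * c(0.9, 1.1)
  if (!is.null(tf_activities)) {
    tf_activities <- as.matrix(tf_activities)
    if (is.null(colnames(tf_activities))) colnames(tf_activities) <- strains
    if (!all(strains %in% colnames(tf_activities)))
      stopf("tf_activities must have one column per strain")
    if (any(tf_activities <= 0)) stopf("tf_activities must be positive")
  }
  structure(list(n_genes = as.integer(n_genes),
                 n_strains = as.integer(n_strains), strains = strains,
                 promoter_len = as.integer(promoter_len),
                 orf_len = as.integer(orf_len), snp_rate = snp_rate,
                 n_replicates = as.integer(n_replicates),
                 baseline_mean = baseline_mean, dispersion = dispersion,
                 frac_cis = frac_cis, cis_log2_effect = cis_log2_effect,
                 tf_activities = tf_activities,
                 library_size_range = library_size_range,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("sim_config: %d genes, %d strains (%s), %d replicates/hybrid\n",
                     "  promoter %d bp, ORF %d bp, pairwise SNP rate %.4g/bp\n",
                     "  NB mean %.4g, dispersion %.3g, %.0f%% cis genes ",
                     "(|log2| = %.3g), seed %d\n"),
              x$n_genes, x$n_strains, paste(x$strains, collapse = ", "),
              x$n_replicates, x$promoter_len, x$orf_len, x$snp_rate,
              x$baseline_mean, x$dispersion, 100 * x$frac_cis,
              x$cis_log2_effect, x$seed))
  invisible(x)
}

#' Simulate parental strain sequences and cis-effect ground truth
#'
#' Generates an ancestral promoter and ORF per gene (uniform base
#' composition) and derives each strain by independent substitutions at rate
#' `snp_rate / 2` per bp, so two strains differ at close to `snp_rate` per
#' bp. Alleles differ by substitutions only, preserving coordinates. A
#' fraction `frac_cis` of genes receive a cis effect: one randomly chosen
#' strain's allele is shifted by +/- `cis_log2_effect` on the log2 scale.
#'
#' @param config a [sim_config()].
#' @return An object of class `hybrid_sim`: a list with `config`,
#'   `sequences` (per strain: named character vectors `promoter`, `orf`) and
#'   `truth` (list with `cis` gene x strain log2 matrix, `targets`,
#'   `plants`, `tf_activities`).
#' @export
simulate_strains <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(derive_seed(config$seed, 1L), {
    genes <- sprintf("g%04d", seq_len(config$n_genes))
    anc_prom <- random_dna(config$n_genes, config$promoter_len)
    anc_orf <- random_dna(config$n_genes, config$orf_len)
    mut <- function(seqs) {
      rate <- config$snp_rate / 2
      if (rate == 0) return(seqs)
      vapply(seqs, function(s) {
        x <- strsplit(s, NULL)[[1L]]
        hit <- which(runif(length(x)) < rate)
        if (length(hit))
          x[hit] <- vapply(x[hit], function(b)
            sample(setdiff(BASES, b), 1L), character(1))
        paste(x, collapse = "")
      }, character(1), USE.NAMES = FALSE)
    }
    sequences <- lapply(setNames(config$strains, config$strains), function(s) {
      list(promoter = setNames(mut(anc_prom), genes),
           orf = setNames(mut(anc_orf), genes))
    })
    cis <- matrix(0, config$n_genes, config$n_strains,
                  dimnames = list(genes, config$strains))
    n_cis <- round(config$frac_cis * config$n_genes)
    if (n_cis > 0) {
      cis_genes <- sample(genes, n_cis)
      cis[cbind(match(cis_genes, genes),
                sample.int(config$n_strains, n_cis, replace = TRUE))] <-
        sample(c(-1, 1), n_cis, replace = TRUE) * config$cis_log2_effect
    }
    structure(list(config = config, sequences = sequences,
                   truth = list(cis = cis, targets = list(),
                                plants = data.frame(),
                                tf_activities = config$tf_activities)),
              class = "hybrid_sim")
  })
}

#' @export
print.hybrid_sim <- function(x, ...) {
  cat(sprintf("hybrid_sim: %d genes x %d strains; %d motif plants recorded\n",
              x$config$n_genes, x$config$n_strains, nrow(x$truth$plants)))
  invisible(x)
}

#' Plant motif instances into simulated promoters
#'
#' Embeds the motif's consensus sequence at a random offset of each target
#' gene's promoter (the same offset in every strain, so the planted site is
#' identical across alleles). If `disrupt_in_strain` is given, that strain's
#' copy receives one substitution at the motif's highest-information
#' position, replacing the consensus base with the least-preferred base --
#' the classic intact-versus-broken binding site polymorphism. Optionally
#' ties a cis expression effect to site intactness via `cis_link_log2`
#' (the disrupted strain's allele is lowered by that many log2 units).
#'
#' @param sim a `hybrid_sim` from [simulate_strains()].
#' @param motif a [motif_model()]; must be shorter than the promoter.
#' @param target_genes gene ids to receive a planted site.
#' @param disrupt_in_strain `NULL` (no disruption), a strain id, `"random"`
#'   (pick a strain per gene), or a vector of strain ids per target gene.
#' @param cis_link_log2 log2 expression penalty applied to the disrupted
#'   allele (default 0 = none).
#' @param seed integer seed for offsets and strain choices.
#' @return The modified `hybrid_sim`, with `truth$targets[[motif$name]]`,
#'   `truth$plants` (gene, tf, offset, disrupt_strain) and `truth$cis`
#'   updated.
#' @export
plant_motifs <- function(sim, motif, target_genes, disrupt_in_strain = NULL,
                         cis_link_log2 = 0, seed = sim$config$seed) {
  stopifnot(inherits(sim, "hybrid_sim"), inherits(motif, "motif_model"))
  L <- motif$length
  if (L > sim$config$promoter_len)
    stopf("motif '%s' (%d bp) is longer than the promoter (%d bp)",
          motif$name, L, sim$config$promoter_len)
  genes <- names(sim$sequences[[1L]]$promoter)
  if (!all(target_genes %in% genes)) stopf("unknown target genes")
  with_seed(derive_seed(seed, 2L), {
    n <- length(target_genes)
    offsets <- sample.int(sim$config$promoter_len - L + 1L, n,
                          replace = TRUE)
    disrupt <- if (is.null(disrupt_in_strain)) rep(NA_character_, n)
      else if (identical(disrupt_in_strain, "random"))
        sample(sim$config$strains, n, replace = TRUE)
      else rep_len(disrupt_in_strain, n)
    if (!all(disrupt[!is.na(disrupt)] %in% sim$config$strains))
      stopf("disrupt_in_strain must name simulated strains")
    ## highest-information position: max sum p log p; disrupting base: argmin
    info <- rowSums(motif$prob * log(motif$prob))
    jmax <- which.max(info)
    weak <- BASES[which.min(motif$prob[jmax, ])]
    consensus <- motif$consensus
    broken <- consensus
    substr(broken, jmax, jmax) <- weak
    for (i in seq_len(n)) {
      g <- target_genes[i]
      for (s in sim$config$strains) {
        site <- if (!is.na(disrupt[i]) && s == disrupt[i]) broken else consensus
        p <- sim$sequences[[s]]$promoter[[g]]
        substr(p, offsets[i], offsets[i] + L - 1L) <- site
        sim$sequences[[s]]$promoter[[g]] <- p
      }
      if (!is.na(disrupt[i]) && cis_link_log2 != 0)
        sim$truth$cis[g, disrupt[i]] <-
          sim$truth$cis[g, disrupt[i]] - cis_link_log2
    }
    sim$truth$targets[[motif$name]] <-
      union(sim$truth$targets[[motif$name]], target_genes)
    sim$truth$plants <- rbind(sim$truth$plants,
      data.frame(gene = target_genes, tf = motif$name,
                 offset = offsets - 1L, disrupt_strain = disrupt))
    sim
  })
}

## Expected mean matrix for one (hybrid, allele) column set, before library
## scaling: 2^cis[, allele] times the partner strain's TF activities on that
## TF's target genes.
.expected_mult <- function(sim, allele, partner) {
  m <- 2^sim$truth$cis[, allele]
  act <- sim$truth$tf_activities
  if (!is.null(act)) {
    for (tf in rownames(act)) {
      tg <- sim$truth$targets[[tf]]
      if (!is.null(tg) && act[tf, partner] != 1)
        m[tg] <- m[tg] * act[tf, partner]
    }
  }
  m
}

#' Simulate allele-resolved counts for all hybrids
#'
#' Draws negative-binomial counts with mean
#' `mu[g, col] = L[col] / n_genes * 2^cis[g, allele] * prod_TF activity(TF,
#' partner)^target(g, TF)` and variance `mu + phi mu^2`, for every column
#' (hybrid x allele x replicate) over all pairwise hybrids of the simulated
#' strains. Trans activity acts on an allele through its hybrid partner
#' strain's TF activities, which is what the CSE statistic contrasts.
#' Column totals `L[col]` are drawn uniformly from `library_size_range`.
#'
#' @param sim a `hybrid_sim`.
#' @param seed integer seed (defaults to the configuration seed).
#' @return An [allele_counts()] object.
#' @export
simulate_counts <- function(sim, seed = sim$config$seed) {
  stopifnot(inherits(sim, "hybrid_sim"))
  cfg <- sim$config
  hyb <- combn(cfg$strains, 2L)
  samples <- do.call(rbind, lapply(seq_len(ncol(hyb)), function(k) {
    expand.grid(replicate = seq_len(cfg$n_replicates),
                allele = hyb[, k], hybrid = paste(hyb[, k], collapse = "x"),
                stringsAsFactors = FALSE)[, c("hybrid", "allele", "replicate")]
  }))
  with_seed(derive_seed(seed, 3L), {
    L <- runif(nrow(samples), cfg$library_size_range[1L],
               cfg$library_size_range[2L])
    counts <- matrix(0L, cfg$n_genes, nrow(samples))
    rownames(counts) <- rownames(sim$truth$cis)
    for (j in seq_len(nrow(samples))) {
      parts <- strsplit(samples$hybrid[j], "x", fixed = TRUE)[[1L]]
      partner <- setdiff(parts, samples$allele[j])
      mu <- L[j] / cfg$n_genes * .expected_mult(sim, samples$allele[j], partner)
      counts[, j] <- if (cfg$dispersion == 0) rpois(cfg$n_genes, mu)
        else rnbinom(cfg$n_genes, mu = mu, size = 1 / cfg$dispersion)
    }
    allele_counts(counts, samples)
  })
}

#' Simulate reads from allele-labelled ORFs
#'
#' Draws each counted fragment as a `read_len`-bp read starting uniformly
#' along the ORF of its allele of origin, on a random strand, with
#' independent substitution errors at `error_rate` per base. True labels are
#' retained so classification accuracy can be scored.
#'
#' @param sim a `hybrid_sim`.
#' @param counts an [allele_counts()] giving reads per (gene, column);
#'   usually from [simulate_counts()] on a small design.
#' @param read_len read length in bp; must not exceed the ORF length.
#' @param error_rate per-base substitution error probability.
#' @param seed integer seed.
#' @return A data.frame with columns `read`, `gene`, `hybrid`, `allele`,
#'   `replicate`, `start` (0-based on the ORF), `strand`.
#' @export
simulate_reads <- function(sim, counts, read_len = 100, error_rate = 0,
                           seed = sim$config$seed) {
  stopifnot(inherits(sim, "hybrid_sim"), inherits(counts, "allele_counts"))
  if (read_len > sim$config$orf_len)
    stopf("read_len %d exceeds ORF length %d", read_len, sim$config$orf_len)
  with_seed(derive_seed(seed, 4L), {
    K <- counts$counts
    idx <- which(K > 0, arr.ind = TRUE)
    gene <- rownames(K)[rep(idx[, 1L], K[idx])]
    col <- rep(idx[, 2L], K[idx])
    n <- length(gene)
    allele <- counts$samples$allele[col]
    start <- sample.int(sim$config$orf_len - read_len + 1L, n, replace = TRUE)
    strand <- sample(c("+", "-"), n, replace = TRUE)
    reads <- character(n)
    for (s in unique(allele)) {
      orfs <- sim$sequences[[s]]$orf
      sel <- which(allele == s)
      reads[sel] <- substr(orfs[gene[sel]], start[sel],
                           start[sel] + read_len - 1L)
    }
    rev_sel <- which(strand == "-")
    if (length(rev_sel))
      reads[rev_sel] <- vapply(reads[rev_sel], revcomp, character(1),
                               USE.NAMES = FALSE)
    if (error_rate > 0) {
      nerr <- rbinom(n, read_len, error_rate)
      for (i in which(nerr > 0)) {
        x <- strsplit(reads[i], NULL)[[1L]]
        pos <- sample.int(read_len, nerr[i])
        x[pos] <- vapply(x[pos], function(b)
          sample(setdiff(BASES, b), 1L), character(1))
        reads[i] <- paste(x, collapse = "")
      }
    }
    data.frame(read = reads, gene = gene,
               hybrid = counts$samples$hybrid[col], allele = allele,
               replicate = counts$samples$replicate[col],
               start = start - 1L, strand = strand)
  })
}

#' Write a simulation to disk in standard formats
#'
#' Emits one FASTA per strain (records `gene|strain|promoter` and
#' `gene|strain|orf`), a long-format counts TSV if counts are supplied, a
#' ground-truth TSV of per-gene per-strain cis log2 effects plus the motif
#' plant table, and a JSON sidecar of the configuration.
#'
#' @param sim a `hybrid_sim`.
#' @param dir output directory (created if needed).
#' @param counts optional [allele_counts()] to write alongside.
#' @return `dir`, invisibly.
#' @export
write_sim <- function(sim, dir, counts = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in names(sim$sequences)) {
    prom <- sim$sequences[[s]]$promoter
    orf <- sim$sequences[[s]]$orf
    seqs <- Biostrings::DNAStringSet(c(prom, orf))
    names(seqs) <- c(paste(names(prom), s, "promoter", sep = "|"),
                     paste(names(orf), s, "orf", sep = "|"))
    Biostrings::writeXStringSet(seqs, file.path(dir, paste0(s, ".fasta")))
  }
  cis <- sim$truth$cis
  truth <- data.frame(gene = rep(rownames(cis), ncol(cis)),
                      strain = rep(colnames(cis), each = nrow(cis)),
                      cis_log2 = as.vector(cis))
  write_tsv(truth[truth$cis_log2 != 0, , drop = FALSE],
            file.path(dir, "truth_cis.tsv"))
  if (nrow(sim$truth$plants))
    write_tsv(sim$truth$plants, file.path(dir, "truth_plants.tsv"))
  cfg <- sim$config
  cfg$tf_activities <- if (!is.null(cfg$tf_activities))
    as.data.frame(cfg$tf_activities)
  jsonlite::write_json(unclass(cfg), file.path(dir, "sim_config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(counts)) write_counts(counts, file.path(dir, "counts.tsv"))
  invisible(dir)
}

#' Read per-strain sequences written by [write_sim()]
#'
#' @param path FASTA file with ids `gene|strain|kind`.
#' @return A list with named character vectors `promoter` and `orf`.
#' @export
read_strain_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  parts <- strsplit(names(seqs), "|", fixed = TRUE)
  gene <- vapply(parts, `[`, character(1), 1L)
  kind <- vapply(parts, `[`, character(1), 3L)
  chr <- as.character(seqs)
  list(promoter = setNames(chr[kind == "promoter"], gene[kind == "promoter"]),
       orf = setNames(chr[kind == "orf"], gene[kind == "orf"]))
}
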