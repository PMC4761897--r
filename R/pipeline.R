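## End-to-end driver: simulate (or load) -> ASE -> binding/ASB -> cis map ->
## CSE/trans map -> directional selection + enrichment, with a JSON manifest
## recording configuration hash, seeds and per-stage row counts. All stages
## communicate through the documented TSV/FASTA/JSON interfaces only.

#' Load and validate a pipeline run configuration
#'
#' Configurations are YAML (or an equivalent R list) with blocks `simulate`
#' (synthetic-data mode) or `inputs` (paths to counts TSV, per-strain
#' FASTAs, MEME motifs, optional GMT gene sets), plus `thresholds`
#' (`min_reads`, `ase_fdr`, `cse_alpha`, `enrich_fdr`), `n_perm`, `seed`,
#' `qvalue_method` and `gomer_mode`.
#'
#' @param config path to a YAML file or a list.
#' @return A validated configuration list of class `run_config`.
#' @export
run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stopf("config file '%s' not found", config)
    config <- yaml::read_yaml(config)
  }
  config$seed <- as.integer(config$seed %||% 1L)
  config$n_perm <- as.integer(config$n_perm %||% 200L)
  config$qvalue_method <- config$qvalue_method %||% "storey"
  config$gomer_mode <- config$gomer_mode %||% "prob"
  th <- config$thresholds %||% list()
  th$min_reads <- th$min_reads %||% 10
  th$ase_fdr <- th$ase_fdr %||% 0.05
  th$cse_alpha <- th$cse_alpha %||% 0.1
  th$enrich_fdr <- th$enrich_fdr %||% 0.1
  for (nm in c("ase_fdr", "cse_alpha", "enrich_fdr"))
    if (th[[nm]] <= 0 || th[[nm]] >= 1) stopf("threshold %s must be in (0,1)", nm)
  config$thresholds <- th
  if (is.null(config$simulate) && is.null(config$inputs))
    stopf("config needs a 'simulate' or an 'inputs' block")
  if (!is.null(config$inputs)) {
    for (f in unlist(config$inputs))
      if (!file.exists(f)) stopf("input '%s' not found", f)
  }
  class(config) <- "run_config"
  config
}

## Random informative motifs for the demo simulator: a sharp consensus with
## modest off-consensus probability mass.
.random_motifs <- function(n_tfs, motif_length, seed) {
  with_seed(derive_seed(seed, 11L), {
    motifs <- lapply(seq_len(n_tfs), function(i) {
      consensus <- sample.int(4L, motif_length, replace = TRUE)
      prob <- matrix(0.04, motif_length, 4L)
      prob[cbind(seq_len(motif_length), consensus)] <- 0.88
      motif_model(sprintf("TF%02d", i), prob, pseudocount = 0.01)
    })
    setNames(motifs, vapply(motifs, function(m) m$name, character(1)))
  })
}

## Build the synthetic study described by the config's `simulate` block:
## strains, planted binding-site polymorphisms tied to cis effects, one TF
## with altered trans-activity in one strain, and a cis-boosted functional
## category for the enrichment stage.
.sim_stage <- function(sc, seed) {
  cfg <- sim_config(
    n_genes = sc$n_genes %||% 300, n_strains = sc$n_strains %||% 4,
    promoter_len = sc$promoter_len %||% 200, orf_len = sc$orf_len %||% 500,
    snp_rate = sc$snp_rate %||% 0.005,
    n_replicates = sc$n_replicates %||% 3,
    baseline_mean = sc$baseline_mean %||% 150,
    dispersion = sc$dispersion %||% 0.05,
    frac_cis = sc$frac_cis %||% 0.1,
    cis_log2_effect = sc$cis_log2_effect %||% 1,
    seed = seed)
  motifs <- .random_motifs(sc$n_tfs %||% 6, sc$motif_length %||% 8, seed)
  act <- matrix(1, length(motifs), cfg$n_strains,
                dimnames = list(names(motifs), cfg$strains))
  trans_tf <- sc$trans_tf %||% names(motifs)[2L]
  trans_fg <- sc$trans_foreground %||% cfg$strains[4L]
  act[trans_tf, trans_fg] <- sc$trans_activity %||% 2
  cfg$tf_activities <- act
  sim <- simulate_strains(cfg)
  genes <- rownames(sim$truth$cis)
  with_seed(derive_seed(seed, 12L), {
    planted_tf <- sc$planted_tf %||% names(motifs)[1L]
    n_pl <- sc$n_planted_targets %||% 40
    sim <- plant_motifs(sim, motifs[[planted_tf]],
                        sample(genes, n_pl), disrupt_in_strain = "random",
                        cis_link_log2 = sc$cis_link_log2 %||% 0.8,
                        seed = derive_seed(seed, 13L))
    sim <- plant_motifs(sim, motifs[[trans_tf]],
                        sample(genes, sc$n_trans_targets %||% 40),
                        seed = derive_seed(seed, 14L))
    ## cis-boosted functional category for the enrichment stage
    cat_genes <- sample(genes, sc$category_size %||% 25)
    cat_strain <- sc$category_strain %||% cfg$strains[1L]
    sim$truth$cis[cat_genes, cat_strain] <-
      sim$truth$cis[cat_genes, cat_strain] + (sc$category_log2 %||% 1.5)
    collection <- c(list(planted_category = cat_genes),
                    lapply(setNames(1:6, sprintf("random_set_%d", 1:6)),
                           function(i) sample(genes, 25)))
    list(sim = sim, motifs = motifs, collection = collection,
         category = "planted_category")
  })
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order -- simulate/load counts and
#' sequences, per-hybrid ASE, per-strain binding probabilities and
#' per-hybrid ASB, ASB/ASE cis mapping with permutation nulls, CSE/trans
#' mapping, directional allelic selection and enrichment -- writing each
#' stage's outputs as TSV under `out_dir` and a `manifest.json` holding the
#' configuration hash, seed and per-stage row counts. Re-running with the
#' same configuration reproduces identical outputs. Any stage failure
#' aborts with the stage name, leaving a `failed` marker file.
#'
#' @param config a [run_config()], a list, or a YAML path.
#' @param out_dir output directory (created; reused if it exists).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  config <- run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  unlink(file.path(out_dir, "failed"))
  manifest <- list(package = "hybridase",
                   version = as.character(packageVersion("hybridase")),
                   seed = config$seed, stages = list())
  stage <- "configure"
  note <- function(name, rows, files) {
    manifest$stages[[name]] <<- list(rows = rows, files = files)
  }
  tryCatch({
    ## ---- stage: data (simulate or load) ----
    stage <- "simulate"
    th <- config$thresholds
    if (!is.null(config$simulate)) {
      st <- .sim_stage(config$simulate, config$seed)
      sim <- st$sim
      motifs <- st$motifs
      collection <- st$collection
      counts <- simulate_counts(sim)
      strains <- sim$config$strains
      seq_sets <- sim$sequences
      window <- c(-sim$config$promoter_len, 0)
      write_sim(sim, file.path(out_dir, "sim"), counts)
      write_meme(motifs, file.path(out_dir, "sim", "motifs.meme"))
      write_gmt(collection, file.path(out_dir, "sim", "gene_sets.gmt"))
    } else {
      stage <- "load"
      counts <- read_counts(config$inputs$counts)
      motifs <- read_meme(config$inputs$motifs)
      fas <- config$inputs$sequences
      strains <- sub("[.]fasta$", "", basename(unlist(fas)))
      seq_sets <- setNames(lapply(unlist(fas), read_strain_fasta), strains)
      window <- unlist(config$promoter_window %||% c(-250, -50))
      collection <- if (!is.null(config$inputs$gene_sets))
        read_gmt(config$inputs$gene_sets) else NULL
    }
    hybrids <- unique(counts$samples$hybrid)
    note("data", nrow(counts$counts), c("sim/counts.tsv"))

    ## ---- stage: ase ----
    stage <- "ase"
    pairs_by_hybrid <- lapply(setNames(hybrids, hybrids), function(h) {
      ss <- strsplit(h, "x", fixed = TRUE)[[1L]]
      pair_alleles(seq_sets[[ss[1L]]], seq_sets[[ss[2L]]], strains = ss,
                   promoter_window = window)
    })
    filt <- apply_filters(counts, th$min_reads)
    ase_tabs <- lapply(setNames(hybrids, hybrids), function(h) {
      excl <- exclusion_report(pairs_by_hybrid[[h]])
      ase_fit(counts, h, min_reads = th$min_reads,
              qvalue_method = config$qvalue_method,
              excluded = excl$gene[excl$excluded])
    })
    ase_all <- do.call(rbind, lapply(ase_tabs, as.data.frame))
    write_tsv(ase_all, file.path(out_dir, "ase.tsv"))
    note("ase", nrow(ase_all), "ase.tsv")

    ## ---- stage: bind / asb ----
    stage <- "bind"
    pb <- pbound_matrix(motifs, seq_sets, mode = config$gomer_mode)
    excl_by_hybrid <- lapply(pairs_by_hybrid, function(pp) {
      er <- exclusion_report(pp)
      er$gene[er$excluded]
    })
    asb_all <- asb_from_pbound(pb, hybrids, exclude = excl_by_hybrid)
    pb_all <- data.frame(gene = rep(rownames(pb), prod(dim(pb)[2:3])),
                         tf = rep(rep(colnames(pb), each = nrow(pb)),
                                  dim(pb)[3L]),
                         strain = rep(dimnames(pb)[[3L]],
                                      each = prod(dim(pb)[1:2])),
                         p_bound = as.vector(pb))
    write_tsv(pb_all, file.path(out_dir, "pbound.tsv"))
    write_tsv(asb_all, file.path(out_dir, "asb.tsv"))
    note("bind", nrow(asb_all), c("pbound.tsv", "asb.tsv"))

    ## ---- stage: cis ----
    stage <- "cis"
    cm <- cis_map(asb_all, ase_tabs, n_perm = config$n_perm,
                  seed = config$seed)
    cis_tab <- do.call(rbind, lapply(cm$per_hybrid, function(x) x$motifs))
    write_tsv(cis_tab, file.path(out_dir, "cis_map.tsv"))
    jsonlite::write_json(cm$ks, file.path(out_dir, "cis_ks.json"),
                         auto_unbox = TRUE, digits = NA)
    note("cis", nrow(cis_tab), c("cis_map.tsv", "cis_ks.json"))

    ## ---- stage: cse ----
    stage <- "cse"
    score_mat <- .motif_score_matrix(motifs, seq_sets,
                                     pairs_by_hybrid, config$gomer_mode)
    tm <- trans_map(counts, score_mat, alpha = th$cse_alpha)
    write_tsv(as.data.frame(tm$activity), file.path(out_dir, "cse_activity.tsv"))
    note("cse", nrow(tm$activity), "cse_activity.tsv")

    ## ---- stage: selection ----
    stage <- "selection"
    parents <- strains[vapply(strains, function(s)
      sum(grepl(paste0("(^|x)", s, "($|x)"), hybrids)) == 3L, logical(1))]
    das <- lapply(setNames(parents, parents), function(p)
      directional_sets(ase_tabs, p, q_threshold = th$ase_fdr,
                       uda = filt$uda))
    das_tab <- do.call(rbind, lapply(das, function(d) {
      if (!length(d$max_expressed) && !length(d$min_expressed))
        return(NULL)
      data.frame(parent = d$parent,
                 gene = c(d$max_expressed, d$min_expressed),
                 set = rep(c("max", "min"), c(length(d$max_expressed),
                                              length(d$min_expressed))))
    }))
    if (is.null(das_tab))
      das_tab <- data.frame(parent = character(0), gene = character(0),
                            set = character(0))
    write_tsv(das_tab, file.path(out_dir, "directional_sets.tsv"))
    enr_tab <- NULL
    if (!is.null(collection)) {
      universe <- names(filt$uda)[filt$uda]
      enr_tab <- do.call(rbind, lapply(names(das), function(p) {
        do.call(rbind, lapply(c("max", "min"), function(side) {
          gs <- if (side == "max") das[[p]]$max_expressed else
            das[[p]]$min_expressed
          if (!length(gs)) return(NULL)
          e <- enrich(gs, universe, collection, fdr = th$enrich_fdr)
          cbind(parent = p, set = side, e)
        }))
      }))
      if (!is.null(enr_tab))
        write_tsv(enr_tab, file.path(out_dir, "enrichment.tsv"))
    }
    note("selection", nrow(das_tab),
         c("directional_sets.tsv",
           if (!is.null(enr_tab)) "enrichment.tsv"))

    ## ---- manifest ----
    stage <- "manifest"
    cfg_json <- file.path(out_dir, "config.json")
    jsonlite::write_json(unclass(config), cfg_json, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, force = TRUE)
    manifest$config_md5 <- unname(tools::md5sum(cfg_json))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(manifest)
  }, error = function(e) {
    writeLines(sprintf("stage: %s\nerror: %s", stage, conditionMessage(e)),
               file.path(out_dir, "failed"))
    stopf("pipeline failed at stage '%s': %s", stage, conditionMessage(e))
  })
}

## Per-gene motif score matrix: mean across strains of the best single
## window score in each gene's promoter.
.motif_score_matrix <- function(motifs, seq_sets, pairs_by_hybrid, mode) {
  genes <- names(seq_sets[[1L]]$promoter)
  strains <- names(seq_sets)
  out <- matrix(0, length(genes), length(motifs),
                dimnames = list(genes, names(motifs)))
  for (tf in names(motifs)) {
    acc <- matrix(NA_real_, length(genes), length(strains))
    for (k in seq_along(strains)) {
      proms <- seq_sets[[strains[k]]]$promoter[genes]
      acc[, k] <- vapply(proms, function(p)
        if (is.na(p) || grepl("[^ACGT]", p)) NA_real_ else
          motif_score_max(motifs[[tf]], p, mode = mode), numeric(1))
    }
    out[, tf] <- rowMeans(acc, na.rm = TRUE)
  }
  out[is.nan(out)] <- 0
  out
}
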