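# Demo pipeline configuration: a small fully synthetic study with planted
# cis effects (binding-site disruptions linked to expression), one TF with
# doubled trans-activity in the SA background, and a cis-boosted gene
# category for the enrichment stage.
seed: 42
n_perm: 200
qvalue_method: storey
gomer_mode: prob
thresholds:
  min_reads: 10
  ase_fdr: 0.05
  cse_alpha: 0.1
  enrich_fdr: 0.1
simulate:
  n_genes: 300
  n_strains: 4
  promoter_len: 200
  orf_len: 500
  snp_rate: 0.005
  n_replicates: 3
  baseline_mean: 150
  dispersion: 0.05
  frac_cis: 0.1
  cis_log2_effect: 1
  n_tfs: 6
  motif_length: 8
  planted_tf: TF01
  n_planted_targets: 40
  cis_link_log2: 0.8
  trans_tf: TF02
  trans_foreground: SA
  trans_activity: 2
  n_trans_targets: 40
  category_size: 25
  category_strain: WE
  category_log2: 1.5
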