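{
  "config": {
    "cohort_tsv": "inst/extdata/synthetic_cohort8/cohort_variants.tsv",
    "vcf_paths": {},
    "annotation_tsv": {},
    "clinical_tsv": "inst/extdata/synthetic_cohort8/clinical.tsv",
    "panel_bed": "inst/extdata/synthetic_cohort8/panel.bed",
    "vaf_threshold_pct": 1,
    "min_alt_reads": 10,
    "pop_af_max": 0.01,
    "prevalence_cap": 0.5,
    "drop_singletons": true,
    "linkage": "ward.D2",
    "k": 2,
    "ties": "breslow",
    "horizon": 60,
    "skip_survival": false,
    "outdir": "inst/extdata/synthetic_cohort8/golden",
    "seed": 83
  },
  "config_hash": "1884ec4117af726d91e7b28c6da05539",
  "seed": 83,
  "package_version": "0.1.0",
  "n_patients": 8,
  "n_clustering_variants": 16
}
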