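{
  "classifier_reports.json": "8df75e5b167326bbe5231ede79d16cfc",
  "classifier_summary.csv": "dee54afc8f35493fad38a13a6484d306",
  "glm_comparison.csv": "187a45bb738aada835b6c59e1864c087",
  "patch_stats.csv": "64eedd0448b7a1fe263ea1f9dc73b5c6",
  "progression_labels.csv": "1e88337b639d7b3bb750b3376da9a9bc",
  "tpf.csv": "c9aa6fab7faee906c063c9a067c90d32",
  "wilcoxon_bl_vs_y3.csv": "fd76373a00976962b7795246e868c059"
}
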