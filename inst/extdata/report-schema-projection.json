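{
  "title": "mirSig projection run report",
  "type": "object",
  "required": ["stage", "seed", "n_genes", "n_samples", "match_rate",
               "matched_genes", "branch_sizes", "differential_counts",
               "fdr", "outputs"],
  "properties": {
    "stage": {"type": "string"},
    "seed": {"type": "integer"},
    "n_genes": {"type": "integer"},
    "n_samples": {"type": "integer"},
    "match_rate": {"type": "number"},
    "matched_genes": {"type": "integer"},
    "branch_sizes": {"type": "object"},
    "differential_counts": {"type": "object"},
    "fdr": {"type": "number"},
    "outputs": {"type": "array"}
  }
}
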