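{
  "title": "mirSig discovery run report",
  "type": "object",
  "required": ["stage", "seed", "n_genes", "n_samples", "cluster_count",
               "cluster_sizes", "differential_counts", "signature_size",
               "reduced_signature_size", "outputs"],
  "properties": {
    "stage": {"type": "string"},
    "seed": {"type": "integer"},
    "n_genes": {"type": "integer"},
    "n_samples": {"type": "integer"},
    "cluster_count": {"type": "integer"},
    "cluster_sizes": {"type": "object"},
    "cluster_patterns": {"type": "object"},
    "collective_p": {"type": "object"},
    "differential_counts": {"type": "object"},
    "signature_size": {"type": "integer"},
    "reduced_signature_size": {"type": "integer"},
    "outputs": {"type": "array"}
  }
}
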