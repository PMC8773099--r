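# Example data

`ppi_edges_synthetic.tsv` — a small **synthetic** protein–protein
interaction edge list in the two-column symbol-pair format accepted by
`read_edge_list()`. It is constructed so that the five example signature
genes (IQSEC1, PSD3, BTBD7, GLIS3, LRBA) are joined into one connected
component through single bridge proteins, alongside a few unrelated decoy
edges. It is illustrative plumbing for examples and tests, not curated
interaction evidence; point `build_subnetwork()` at a real BioGRID TAB
export for actual analyses.
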