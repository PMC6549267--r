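{
  "id": "msinet-viewer/1",
  "description": "Data contract for an interactive community-graph viewer: collapsed community nodes with member m/z lists and map image references, community/hybrid/mz edges, and the selected threshold.",
  "required": [
    "schema",
    "grid_shape",
    "threshold",
    "effective_min_weight",
    "n_edges",
    "communities",
    "community_edges",
    "hybrid_edges",
    "mz_edges",
    "expanded"
  ],
  "community_required": ["id", "indivisible", "members", "map", "map_mode"],
  "edge_arity": 2
}
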