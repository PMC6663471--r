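{
  "comment": "Default simulated scenario: 4 reference networks, each a coarse modular decomposition of the 221-ROI atlas into 2-3 large modules (node membership shuffled per network, seed layout_seed + network_id, so the planted partitions are mutually near-orthogonal; ~10% of nodes per network stay as background except network 4). Networks activate in sequence over 60 s with background gaps and a repeated short activation of network 2 at the end. Editable; see sim_config() and make_reference_networks().",
  "n_nodes": 221,
  "within_weight": 0.7,
  "layout_seed": 100,
  "layouts": [
    {"network_id": 1, "assign": "shuffled", "sizes": [95, 96]},
    {"network_id": 2, "assign": "shuffled", "sizes": [65, 65, 60]},
    {"network_id": 3, "assign": "shuffled", "sizes": [78, 60, 58]},
    {"network_id": 4, "assign": "shuffled", "sizes": [111, 110]}
  ],
  "timeline": {
    "duration_s": 60,
    "epochs": [
      {"network_id": 1, "onset_s": 3,    "offset_s": 12},
      {"network_id": 2, "onset_s": 16,   "offset_s": 26},
      {"network_id": 3, "onset_s": 31,   "offset_s": 41},
      {"network_id": 4, "onset_s": 46,   "offset_s": 55},
      {"network_id": 2, "onset_s": 57.5, "offset_s": 60}
    ]
  }
}
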