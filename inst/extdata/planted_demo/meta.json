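{"seed": 23, "n_nodes": 8, "n_true_edges": 8, "n_spurious": 4, "inputs": ["g04", "g05"], "degenerate": false}
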