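{
  "name": "dmn",
  "n_total": 264,
  "indices": [100, 101, 102, 103, 104, 105, 106, 107, 108, 109, 110, 111, 112, 113, 114, 115, 116, 117, 118, 119, 120, 121, 122, 123, 124, 125, 126, 127, 128, 129, 130, 131, 132, 133, 134, 135, 136, 137, 138, 139, 140, 141, 142, 143, 144, 145, 146, 147, 148, 149, 150, 151, 152, 153, 154, 155, 156, 157],
  "note": "Indices are synthetic placeholders into the 264-node whole-brain ordering; substitute the true atlas indices for real data. Indices are 0-based in this file."
}
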