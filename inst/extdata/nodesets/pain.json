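{
  "name": "pain",
  "n_total": 264,
  "indices": [0, 1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12, 13, 14, 15],
  "labels": ["vermis cerebellum", "anterior/mid insula (right)", "superior temporal gyrus", "calcarine gyrus", "ventrolateral thalamus (right)", "mid insula (left)", "hypothalamus", "ventrolateral thalamus (left)", "frontal operculum/temporal pole", "dorsal posterior insula/secondary somatosensory area (left)", "dorsal posterior insula (right)", "somatosensory area (right)", "temporoparietal junction", "dorsal anterior cingulate cortex", "supramarginal gyrus", "inferior parietal lobule"],
  "note": "Indices are synthetic placeholders into the 264-node whole-brain ordering; substitute the true atlas indices for real data. Indices are 0-based in this file."
}
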