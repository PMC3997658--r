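{
  "name": "control",
  "nodes": [
    {"abbrev": "MTG",  "name": "Middle temporal gyrus (left)",  "peak_mni": [-57, -27, -5], "radius_mm": 5},
    {"abbrev": "IFG",  "name": "Inferior frontal gyrus (left)", "peak_mni": [-51, 20, 15],  "radius_mm": 5},
    {"abbrev": "Thal", "name": "Thalamus (left)",               "peak_mni": [-6, -11, 5],   "radius_mm": 5},
    {"abbrev": "AG",   "name": "Angular gyrus (left)",          "peak_mni": [-48, -56, 29], "radius_mm": 5}
  ]
}
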