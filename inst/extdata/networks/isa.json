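{
  "name": "isa",
  "nodes": [
    {"abbrev": "SGC",   "name": "Subgenual cingulate cortex",      "peak_mni": [0, 32, -12],   "radius_mm": 5},
    {"abbrev": "ACC",   "name": "Anterior cingulate cortex",       "peak_mni": [0, 36, 10],    "radius_mm": 5},
    {"abbrev": "AmyL",  "name": "Amygdala (left)",                 "peak_mni": [-22, -6, -24], "radius_mm": 5},
    {"abbrev": "PrC",   "name": "Precuneus",                       "peak_mni": [-4, -54, 22],  "radius_mm": 5},
    {"abbrev": "dmPFC", "name": "Dorsomedial prefrontal cortex",   "peak_mni": [-2, 52, 14],   "radius_mm": 5}
  ]
}
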