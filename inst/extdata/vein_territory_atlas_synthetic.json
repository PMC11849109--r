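{
  "comment": "Synthetic approximation of a Destrieux-label to venous drainage territory assignment. The published allocation exists only pictorially; edit freely. Labels: aparc.a2009s cortical ids (11xxx left, 12xxx right) and aseg subcortical ids.",
  "mapping": {
    "SSS V": [11125, 12125, 11127, 12127, 11157, 12157, 11168, 12168],
    "SSS H": [11114, 12114, 11115, 12115, 11116, 12116, 11170, 12170],
    "SS": [11121, 12121, 11122, 12122, 11145, 12145],
    "BVs": [11117, 12117, 11118, 12118, 11149, 12149],
    "ICVs": [10, 49, 11, 50, 12, 51]
  },
  "upstream": {
    "SS": ["ICVs", "BVs"],
    "SSS V": ["SSS H"]
  }
}
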