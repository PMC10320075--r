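{
  "version": "1.0",
  "anchor_index": 50,
  "segments_common": {
    "name": ["bA", "aA", "bB", "bBbC", "bC", "bD", "bE", "bF", "aB"],
    "kind": ["strand", "helix", "strand", "turn", "strand", "strand", "strand", "strand", "helix"],
    "rank": [1, 2, 3, 4, 5, 6, 7, 8, 9]
  },
  "segments_stat": {
    "name": ["bA", "aA", "bB", "bBbC", "bC", "bD", "aBp", "aB"],
    "kind": ["strand", "helix", "strand", "turn", "strand", "strand", "helix", "helix"],
    "rank": [1, 2, 3, 4, 5, 6, 7, 8]
  },
  "sheinerman_positions": ["aAx43", "aAx47", "bBx50", "bBx52", "bBbCx49", "bBbCx50", "bDx50", "bDx52"],
  "flvr_exception_proteins": ["RIN2", "TYK2", "SH2D5"]
}
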