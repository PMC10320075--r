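{
  "version": "1.0",
  "stat5b": {
    "protein_id": "STAT5B",
    "domain_slot": "N",
    "layout": "STAT",
    "anchors": {
      "segment": ["aA", "bB", "bBbC", "bD"],
      "index": [43, 50, 49, 50],
      "residue": [600, 618, 621, 642]
    },
    "spans": {
      "segment": ["aA", "bB", "bBbC", "bD"],
      "index_min": [42, 46, 49, 47],
      "index_max": [50, 52, 50, 52]
    }
  },
  "shp2_n": {
    "protein_id": "SHP2",
    "domain_slot": "N",
    "layout": "common",
    "anchors": {
      "segment": ["bE"],
      "index": [48],
      "residue": [62]
    },
    "spans": {
      "segment": ["bE"],
      "index_min": [48],
      "index_max": [50]
    },
    "notes": "D61 sits in the unnumbered bDbE blocking loop; Y62 is the first position of the bE strand (bEx48)."
  },
  "flvr_exceptions": ["RIN2", "TYK2", "SH2D5"]
}
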