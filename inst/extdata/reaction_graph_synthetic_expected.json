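{
  "comment": "Hand-derived expected gene sets for the synthetic fixture graph, carbon source 'arabinose', directed traversal, top 3 shortest paths. Derivation: reactions = edges incident to arabinose (R01, R03). pathways = pathways whose compound list contains arabinose (pw_pentose). paths = loopless directed paths to the nearest destinations, ranked by reaction-step count with lexicographic node-sequence tie-break: [R03,R04,R06] (3 steps to g3p), [R01,R02,R05,R06] (4 steps to g3p), [R03,R04,R06,R11] (4 steps to pep); union of their reaction gene sets.",
  "carbon": "arabinose",
  "reactions": ["K01", "K03"],
  "pathways": ["K01", "K02", "K03", "K04", "K05", "K06"],
  "paths": ["K01", "K02", "K03", "K04", "K05", "K06", "K11"]
}
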