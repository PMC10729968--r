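{
  "comment": "Synthetic toy reaction graph (hand-built, not derived from any database dump): 15 compounds, 16 directed reactions, 3 pathways emulating pentose degradation, glycolysis and the TCA entry. Edge direction is substrate -> product.",
  "compounds": [
    "arabinose", "arabitol", "xylulose", "xylulose5P", "ribulose5P",
    "glucose", "glucose6P", "fructose6P", "fructose16BP", "g3p",
    "pep", "pyruvate", "acetylCoA", "citrate", "oxaloacetate"
  ],
  "reactions": [
    {"id": "R01", "substrate": "arabinose", "product": "arabitol", "kos": ["K01"]},
    {"id": "R02", "substrate": "arabitol", "product": "xylulose", "kos": ["K02"]},
    {"id": "R03", "substrate": "arabinose", "product": "ribulose5P", "kos": ["K03"]},
    {"id": "R04", "substrate": "ribulose5P", "product": "xylulose5P", "kos": ["K04"]},
    {"id": "R05", "substrate": "xylulose", "product": "xylulose5P", "kos": ["K05"]},
    {"id": "R06", "substrate": "xylulose5P", "product": "g3p", "kos": ["K06"]},
    {"id": "R07", "substrate": "glucose", "product": "glucose6P", "kos": ["K07"]},
    {"id": "R08", "substrate": "glucose6P", "product": "fructose6P", "kos": ["K08"]},
    {"id": "R09", "substrate": "fructose6P", "product": "fructose16BP", "kos": ["K09"]},
    {"id": "R10", "substrate": "fructose16BP", "product": "g3p", "kos": ["K10"]},
    {"id": "R11", "substrate": "g3p", "product": "pep", "kos": ["K11"]},
    {"id": "R12", "substrate": "pep", "product": "pyruvate", "kos": ["K12"]},
    {"id": "R13", "substrate": "pyruvate", "product": "acetylCoA", "kos": ["K13"]},
    {"id": "R14", "substrate": "acetylCoA", "product": "citrate", "kos": ["K14"]},
    {"id": "R15", "substrate": "oxaloacetate", "product": "citrate", "kos": ["K15"]},
    {"id": "R16", "substrate": "glucose6P", "product": "ribulose5P", "kos": ["K16"]}
  ],
  "pathways": {
    "pw_pentose": {
      "compounds": ["arabinose", "arabitol", "xylulose", "xylulose5P", "ribulose5P", "g3p"],
      "kos": ["K01", "K02", "K03", "K04", "K05", "K06"]
    },
    "pw_glycolysis": {
      "compounds": ["glucose", "glucose6P", "fructose6P", "fructose16BP", "g3p", "pep", "pyruvate"],
      "kos": ["K07", "K08", "K09", "K10", "K11", "K12"]
    },
    "pw_tca": {
      "compounds": ["pyruvate", "acetylCoA", "citrate", "oxaloacetate"],
      "kos": ["K13", "K14", "K15"]
    }
  },
  "destinations": ["glucose", "fructose6P", "g3p", "pep", "pyruvate", "citrate"]
}
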