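{
  "fig2a": {
    "variant": "seasonal",
    "epi": {"a0": 10, "q0": 0.5, "b": 1, "alpha": 1, "gamma": 1,
            "beta": 0.2, "amp": 0.5},
    "note": "resident dynamics with seasonally varying competition"
  },
  "fig2b": {
    "variant": "seasonal",
    "epi": {"a0": 10, "q0": 0.5, "b": 1, "alpha": 1, "gamma": 1,
            "beta": 0.2, "amp": 0.5},
    "tradeoff": {"a_ref": 10, "beta_ref": 0.2, "tau1": 1.58, "tau2": -3},
    "trait_range": [0.05, 0.5],
    "bracket": [0.05, 0.5],
    "note": "decelerating trade-off; continuously stable strategy"
  },
  "fig2c": {
    "variant": "seasonal",
    "epi": {"a0": 10, "q0": 0.5, "b": 1, "alpha": 1, "gamma": 1,
            "beta": 0.2, "amp": 0.5},
    "tradeoff": {"a_ref": 10, "beta_ref": 0.2, "tau1": 1.58, "tau2": 3},
    "trait_range": [0.05, 0.5],
    "bracket": [0.05, 0.5],
    "note": "accelerating trade-off; evolutionary branching point"
  },
  "fig3a": {
    "variant": "seasonal",
    "epi": {"a0": 10, "q0": 0.5, "b": 1, "alpha": 1, "gamma": 1,
            "beta": 0.2, "amp": 0},
    "tradeoff": {"a_ref": 10, "beta_ref": 0.2, "tau2": -3,
                 "calibrate_tau1": true},
    "bracket": [0.05, 0.6],
    "sweep": {"param": "amp", "values": [0, 0.15, 0.3, 0.45, 0.6, 0.75, 0.9],
              "panel_param": "q0", "panel_values": [0.1, 0.5],
              "calibrate_tau1": true},
    "note": "CSS location vs forcing amplitude at weak and strong competition"
  },
  "fig3b": {
    "variant": "seasonal",
    "epi": {"a0": 10, "q0": 0.5, "b": 1, "alpha": 1, "gamma": 1,
            "beta": 0.2, "amp": 0.5},
    "tradeoff": {"a_ref": 10, "beta_ref": 0.2, "tau2": -3,
                 "calibrate_tau1": true},
    "bracket": [0.05, 0.8],
    "sweep": {"param": "alpha", "values": [0.5, 1, 1.5, 2, 3, 4, 5],
              "panel_param": "gamma", "panel_values": [0.1, 1, 3],
              "calibrate_tau1": true},
    "note": "CSS location vs virulence at low and high recovery"
  },
  "fig4": {
    "variant": "free_living",
    "epi": {"a0": 10, "q0": 0.1, "b": 1, "alpha": 1, "gamma": 0.1,
            "beta": 0.1, "amp": 0, "theta": 5, "decay": 0.1},
    "note": "free-living parasite stages; intrinsic limit cycle of period about 10.13"
  },
  "fig4b": {
    "variant": "free_living",
    "epi": {"a0": 10, "q0": 0.1, "b": 1, "alpha": 1, "gamma": 0.1,
            "beta": 0.1, "amp": 0, "theta": 5, "decay": 0.1},
    "tradeoff": {"a_ref": 10, "beta_ref": 0.1, "tau1": 75, "tau2": -400},
    "trait_range": [0.02, 0.2],
    "bracket": [0.02, 0.2],
    "note": "free-living model with trade-off; pairwise invasion plot"
  },
  "fig5a": {
    "variant": "free_living",
    "epi": {"a0": 10, "q0": 0.1, "b": 1, "alpha": 1, "gamma": 0.1,
            "beta": 0.1, "amp": 0, "theta": 5, "decay": 0.1},
    "tradeoff": {"a_ref": 10, "beta_ref": 0.1, "tau1": 75, "tau2": -400},
    "bracket": [0.02, 0.2],
    "sweep": {"param": "q0",
              "values": [0.02, 0.04, 0.06, 0.08, 0.1, 0.14, 0.18, 0.25]},
    "note": "CSS vs competition; trend flips where cycles give way to equilibria"
  },
  "fig5b": {
    "variant": "free_living",
    "epi": {"a0": 10, "q0": 0.1, "b": 1, "alpha": 1, "gamma": 0.1,
            "beta": 0.1, "amp": 0, "theta": 5, "decay": 0.1},
    "tradeoff": {"a_ref": 10, "beta_ref": 0.1, "tau1": 75, "tau2": -400},
    "bracket": [0.02, 0.2],
    "sweep": {"param": "theta", "values": [1, 2, 3, 4, 5, 6, 8, 10]},
    "note": "CSS vs parasite production; cycles emerge at high shedding"
  }
}
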