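{
  "_comment": "Frozen worked-example age-prediction tree. Convention: z < threshold goes left. Only three root-to-leaf paths are constrained by the published worked example (leaves 77.6, 63.1, 55.7 years and the task_BOLD split at -0.18); every node or threshold marked synthetic=true is an invented placeholder, not part of any published model.",
  "leaf": false,
  "modality": "GM_volume",
  "threshold": -0.5,
  "synthetic": true,
  "left": {
    "leaf": false,
    "modality": "WM_FA",
    "threshold": 0.0,
    "synthetic": true,
    "left": {
      "leaf": true,
      "value": 77.6,
      "synthetic": false
    },
    "right": {
      "leaf": false,
      "modality": "task_BOLD",
      "threshold": -0.18,
      "synthetic": false,
      "left": {
        "leaf": true,
        "value": 63.1,
        "synthetic": false
      },
      "right": {
        "leaf": true,
        "value": 55.7,
        "synthetic": false
      }
    }
  },
  "right": {
    "leaf": true,
    "value": 45.0,
    "synthetic": true
  }
}
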