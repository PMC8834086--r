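{
  "start": [0, 0],
  "goals": [[-3, 4], [3, 4]],
  "trajectories": [
    {"goal_id": 1, "curve_index": 1,
     "points": [[0, 0], [-0.75, 1], [-1.5, 2], [-2.25, 3], [-3, 4]]},
    {"goal_id": 2, "curve_index": 1,
     "points": [[0, 0], [0.75, 1], [1.5, 2], [2.25, 3], [3, 4]]}
  ]
}
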