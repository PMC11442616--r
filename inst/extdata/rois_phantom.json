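[
  {
    "kind": "projection",
    "hemisphere": "left",
    "start_voxel": [4, 8, 2],
    "size_voxels": [2, 2, 1]
  },
  {
    "kind": "association",
    "hemisphere": "left",
    "start_voxel": [14, 8, 2],
    "size_voxels": [2, 2, 1]
  }
]
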