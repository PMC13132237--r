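[
  [15, 45],
  [15, 80],
  [20, 40],
  [30, 60],
  [45, 75],
  [60, 90],
  [80, 140],
  [90, 120],
  [100, 131],
  [40, 70],
  [70, 100],
  [100, 130],
  [130, 160],
  [160, 190],
  [190, 220],
  [220, 250],
  [250, 280],
  [280, 310],
  [310, 340],
  [35, 55],
  [45, 65],
  [55, 75],
  [95, 115],
  [105, 125],
  [115, 135],
  [170, 190],
  [180, 200],
  [190, 210],
  [200, 220],
  [240, 260],
  [270, 290],
  [300, 320]
]
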