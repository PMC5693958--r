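# Default 7-cylinder test phantom, in units of the slab thickness z_max.
# cx, cy: lateral center; radius; top: depth of top face; height; density.
cylinders:
  - {cx: -1.00, cy:  0.80, radius: 0.30, top: 0.10, height: 0.35, density: 1}
  - {cx:  0.90, cy:  0.90, radius: 0.20, top: 0.55, height: 0.35, density: 1}
  - {cx:  0.90, cy: -0.90, radius: 0.15, top: 0.15, height: 0.25, density: 1}
  - {cx: -0.90, cy: -0.90, radius: 0.25, top: 0.50, height: 0.40, density: 1}
  - {cx:  0.00, cy:  0.00, radius: 0.10, top: 0.30, height: 0.50, density: 1}
  - {cx:  0.00, cy:  1.20, radius: 0.12, top: 0.65, height: 0.25, density: 1}
  - {cx:  0.00, cy: -1.30, radius: 0.18, top: 0.20, height: 0.60, density: 1}
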