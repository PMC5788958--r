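# Minimal scene: a nest tree (nest 10 cm from its base) and a foraging tree
# 3 m from the nest. Units: metres; intensities: 8-bit grey levels.
trees:
  - id: foraging
    x: 0.0
    y: 0.0
    radius: 0.15
    height: 8.0
    canopy_radius: 2.0
    canopy_height: 6.5
  - id: nest
    x: 0.0
    y: 3.22
    radius: 0.12
    height: 6.0
    canopy_radius: 1.5
    canopy_height: 4.5
nest:
  x: 0.0
  y: 3.0
  tree: nest
intensity:
  sky: 255
  ground: 45
  trunk: 60
  canopy: 50
  screen: 30
noise:
  amplitude: 40
  bark_amplitude: 70
  seed: 1
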