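# The on-tree displacement protocol: releases at the four cardinal trunk
# azimuths, 2 m high, 15 foragers per condition, plus the landmark-blocking
# condition on the nest tree (release opposite the nest at 1.5 m, n = 20).
seed: 1
conditions:
  - release_azimuth: 0
    n: 15
  - release_azimuth: 90
    n: 15
  - release_azimuth: 180
    n: 15
  - release_azimuth: 270
    n: 15
  - release_azimuth: 180
    n: 20
    blocked: true
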