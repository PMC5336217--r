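name: scenario_2a
description: >-
  Single Anatolian refugium, maritime route: Anatolia (pool1) to the Balkans (pool2), then through western Europe (pool4) to northeastern Europe (pool3).
status: reconstructed
pools:
  - {id: pool1, size: N1}
  - {id: pool2, size: N2}
  - {id: pool3, size: N3}
  - {id: pool4, size: N4}
events:
  - {type: merge, time: td, source: pool3, sink: pool4}
  - {type: merge, time: t1, source: pool4, sink: pool2}
  - {type: merge, time: t2, source: pool2, sink: pool1}
  - {type: sizechange, time: t2, pool: pool1, size: NAnc}
priors:
  N1: {dist: uniform, min: 100, max: 10000}
  N2: {dist: uniform, min: 100, max: 10000}
  N3: {dist: uniform, min: 100, max: 10000}
  N4: {dist: uniform, min: 100, max: 10000}
  NAnc: {dist: uniform, min: 100, max: 10000}
  t2: {dist: uniform, min: 20, max: 60}
  t1: {dist: uniform, min: 10, max: 25}
  td: {dist: uniform, min: 1, max: 15}
constraints:
  - "t2 > t1"
  - "t1 > td"
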