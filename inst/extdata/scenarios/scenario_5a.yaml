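name: scenario_5a
description: >-
  Independent dispersal from Anatolia (pool1) and western Europe (pool4) into the Balkans with admixture (pool2); expansion from western to northeastern Europe (pool3); recent decline of western Europe.
status: reconstructed
pools:
  - {id: pool1, size: N1}
  - {id: pool2, size: N2}
  - {id: pool3, size: N3}
  - {id: pool4, size: N4}
events:
  - {type: sizechange, time: tm, pool: pool4, size: Nm}
  - {type: merge, time: t1, source: pool3, sink: pool4}
  - {type: admix, time: t2, derived: pool2, parentA: pool1, parentB: pool4, rate: ra}
  - {type: merge, time: t4, source: pool4, sink: pool1}
  - {type: sizechange, time: t4, pool: pool1, size: NAnc}
priors:
  N1: {dist: uniform, min: 100, max: 10000}
  N2: {dist: uniform, min: 100, max: 10000}
  N3: {dist: uniform, min: 100, max: 10000}
  N4: {dist: uniform, min: 100, max: 10000}
  Nm: {dist: uniform, min: 100, max: 10000}
  NAnc: {dist: uniform, min: 100, max: 10000}
  t4: {dist: uniform, min: 100, max: 10000}
  t2: {dist: uniform, min: 20, max: 60}
  t1: {dist: uniform, min: 10, max: 25}
  tm: {dist: uniform, min: 1, max: 10}
  ra: {dist: uniform, min: 0.001, max: 0.999}
constraints:
  - "t4 > t2"
  - "t2 > t1"
  - "t1 > tm"
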