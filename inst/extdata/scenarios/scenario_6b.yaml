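name: scenario_6b
description: >-
  Three glacial refugia (Anatolia pool1, Balkan ancestral pool NG1, western Europe pool4); Balkan pool2 founded at t2 by admixture between pool1 and NG1 (ra weighting pool1); northeastern pool3 founded at t1 by admixture between pool4 and pool2 (rb weighting pool4); pool4 diverges from NG1 at t3; pool3 expands at td; pool4 declines at tm.
status: reconstructed
pools:
  - {id: pool1, size: N1}
  - {id: pool2, size: N2}
  - {id: pool3, size: N3}
  - {id: pool4, size: N4}
  - {id: poolG1, size: NG1}
events:
  - {type: sizechange, time: tm, pool: pool4, size: Nm}
  - {type: sizechange, time: td, pool: pool3, size: Nd}
  - {type: admix, time: t1, derived: pool3, parentA: pool4, parentB: pool2, rate: rb}
  - {type: admix, time: t2, derived: pool2, parentA: pool1, parentB: poolG1, rate: ra}
  - {type: merge, time: t3, source: pool4, sink: poolG1}
  - {type: merge, time: t4, source: poolG1, sink: pool1}
  - {type: sizechange, time: t4, pool: pool1, size: NAnc}
priors:
  N1: {dist: uniform, min: 100, max: 10000}
  N2: {dist: uniform, min: 100, max: 10000}
  N3: {dist: uniform, min: 100, max: 10000}
  N4: {dist: uniform, min: 100, max: 10000}
  Nm: {dist: uniform, min: 100, max: 10000}
  Nd: {dist: uniform, min: 100, max: 10000}
  NG1: {dist: uniform, min: 100, max: 10000}
  NAnc: {dist: uniform, min: 100, max: 10000}
  t4: {dist: uniform, min: 100, max: 10000}
  t3: {dist: uniform, min: 10, max: 200}
  t2: {dist: uniform, min: 20, max: 60}
  t1: {dist: uniform, min: 10, max: 25}
  td: {dist: uniform, min: 1, max: 15}
  tm: {dist: uniform, min: 1, max: 10}
  ra: {dist: uniform, min: 0.001, max: 0.999}
  rb: {dist: uniform, min: 0.001, max: 0.999}
constraints:
  - "t4 > t3"
  - "t3 > t2"
  - "t2 > t1"
  - "t1 > td"
  - "t3 > tm"
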