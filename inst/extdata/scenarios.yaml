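# Five pathway scenarios over the core methylotroph network.
# The unconstrained reference setup (methanol uptake 10 mmol/gDW/h, product
# objective) is shared; the remaining scenarios add bound edits on
# literature reaction aliases. "calibrate:max"/"calibrate:min" resolve to
# the extreme feasible flux of the aliased reaction at application time.
- name: Ref
  edits: []
- name: TCA-
  edits:
    - {alias: PDHa1,    bound: upper, value: 0}
    - {alias: PDHcm,    bound: upper, value: 0}
    - {alias: ACLSm,    bound: upper, value: 0}
    - {alias: AKGDH1+2, bound: upper, value: 0}
    - {alias: CITtam,   bound: upper, value: 0}
    - {alias: CITtap,   bound: upper, value: 0}
    - {alias: CSp+m,    bound: upper, value: 0}
- name: TCA+
  edits:
    - {alias: AKGDam, bound: lower, value: "calibrate:max"}
- name: GlxStd
  edits:
    - {alias: ICL, bound: lower, value: "calibrate:max"}
- name: GlxVar
  edits:
    - {alias: ICL,  bound: lower, value: "calibrate:max"}
    - {alias: MDHm, bound: lower, value: -10}
    - {alias: MDHm, bound: upper, value: "calibrate:min"}
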