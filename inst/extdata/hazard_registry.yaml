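# Points of departure, health-based guidance values and TTC rules for the
# six benzophenone-type photoinitiators covered by the package.
# Units: pod_value in mg/kg bw/day; TTC thresholds in ug/person/day.
meta:
  description: >
    Hazard registry for benzophenone-type photoinitiators used in
    ultraviolet-cured printing inks on food packaging.
  group_tdi:
    value_mg_kg_bw_day: 0.01
    members: [BP, 4-OHBP]
    used: false
    note: >
      EFSA group tolerable daily intake for benzophenone and
      4-hydroxybenzophenone. Retained as metadata only: EFSA itself noted
      that in the absence of supporting data 4-OHBP should not be grouped
      with BP, so the group TDI is never applied in risk characterization.
ttc:
  default_bw_kg: 60
  thresholds_ug_person_day:
    I: 1800
    II: 540
    III: 90
analytes:
  BP:
    profiles:
      - pod_type: TDI
        pod_value: 0.03
        endpoint: nonneoplastic kidney effects (chronic rat study, UF 100)
        endpoint_class: noncarcinogen
        target_moe: 1
        use_for_moe: false
        source: EFSA 2009 tolerable daily intake
      - pod_type: BMDL10
        pod_value: 3.1
        endpoint: nonneoplastic kidney effects
        endpoint_class: noncarcinogen
        target_moe: 100
        use_for_moe: true
        source: EFSA benchmark-dose analysis (lower end of the 3.1-7.4 band)
      - pod_type: BMDL10
        pod_value: 18.5
        endpoint: neoplastic kidney effects (threshold carcinogen)
        endpoint_class: carcinogen
        target_moe: 100
        use_for_moe: true
        source: EFSA benchmark-dose analysis
  4-MBP:
    profiles:
      - pod_type: BMDL10
        pod_value: 3.1
        endpoint: kidney effects (read-across from benzophenone)
        endpoint_class: noncarcinogen
        target_moe: 200
        use_for_moe: true
        source: >
          EFSA read-across from benzophenone with two additional
          uncertainty factors (target margin of exposure 200)
  M2BB:
    profiles:
      - pod_type: NOAEL
        pod_value: 31.25
        endpoint: kidney degeneration and hyperplasia
        endpoint_class: noncarcinogen
        target_moe: 100
        use_for_moe: true
        source: ECHA 28-day repeated-dose toxicity study
  PBZ:
    profiles:
      - pod_type: NOAEL
        pod_value: 300
        endpoint: implantation-site effects
        endpoint_class: noncarcinogen
        target_moe: 100
        use_for_moe: true
        source: 28-day repeated-dose toxicity study in rats
  4-OHBP:
    profiles:
      - pod_type: NOAEL
        pod_value: 100
        endpoint: systemic toxicity
        endpoint_class: noncarcinogen
        target_moe: 100
        use_for_moe: true
        source: 28-day repeated-dose toxicity study
  2-OHBP:
    ttc_only: true
    cramer_class: III
    note: >
      No animal evidence available; screened with the threshold of
      toxicological concern (Cramer class III) instead of a margin of
      exposure.
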