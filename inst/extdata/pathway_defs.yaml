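# Packaged pathway/marker definitions for KO-based functional screening.
#
# Only four KO ids below are anchored in primary literature on soda-lake MAG
# screening: K14138 (acsB, bacterial-type CODH/ACS), K00193 (cdhC,
# archaeal-type CODH/ACS), K03385 (nrfA/TvNiR) and K00855 (PRK). All other KO
# memberships are best-effort configuration data assembled from KEGG module
# definitions (provenance noted per entry) and are meant to be edited, not
# treated as assertions.
pathways:
  - id: codh_acs_bacterial
    name: "CODH/ACS bacterial-type (acsB)"
    # single marker; KEGG K14138 acetyl-CoA synthase beta subunit
    required: [K14138]
    optional: []
    presence_threshold: 1.0
  - id: codh_acs_archaeal
    name: "CODH/ACS archaeal-type (cdhC)"
    # single marker; KEGG K00193 acetyl-CoA decarbonylase/synthase beta subunit
    required: [K00193]
    optional: []
    presence_threshold: 1.0
  - id: wl_eastern
    name: "Wood-Ljungdahl eastern (methyl) branch"
    # tetrahydrofolate branch; KEGG module M00377 (partial): fhs, folD, metF
    required: [K01938, K01491, K00297]
    optional: [K00122, K05299]
    presence_threshold: 1.0
  - id: emp_glycolysis
    name: "Glycolysis (Embden-Meyerhof-Parnas)"
    # core payoff + preparatory steps after hexokinase; KEGG module M00001
    required: [K00850, K01623, K00134, K00927, K01689, K00873]
    optional: [K01810, K01834]
    presence_threshold: 0.75
  - id: pfor
    name: "Pyruvate:ferredoxin oxidoreductase (PFOR)"
    # porABDG subunits; KEGG K00169-K00172
    required: [K00169, K00170, K00171, K00172]
    optional: []
    presence_threshold: 0.75
  - id: pta_ack
    name: "Acetate interconversion (pta + ack)"
    # phosphotransacetylase K00625, acetate kinase K00925
    required: [K00625, K00925]
    optional: []
    presence_threshold: 1.0
  - id: nrfA
    name: "Dissimilatory nitrite reduction to ammonia (nrfA/TvNiR)"
    required: [K03385]
    optional: []
    presence_threshold: 1.0
  - id: prk
    name: "Phosphoribulokinase (PRK)"
    required: [K00855]
    optional: []
    presence_threshold: 1.0
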