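# Default vegrisk configuration.
#
# references.background: geochemical background values (BV, mg/kg dry soil)
#   for agricultural soils of the study region.
# references.screening: soil risk-screening values (SV, mg/kg): GB 15618-2018
#   for Cd, Cr, Cu, Pb, Zn; Canadian soil quality guideline for V (flagged
#   under screening_source).
# references.veg_mpl: maximum permissible levels in vegetables (GB 2762-2017,
#   mg/kg fresh weight); defined only for Cd, Pb, Cr.
# scenarios: exposure parameters are handbook defaults, NOT study-specific
#   values: ingestion rates and body weights from Chinese exposure-factor
#   handbooks, oral reference doses from standard US EPA compilations.
#   at defaults to ed * 365 (non-carcinogenic averaging time).
references:
  background:
    Cd: 0.41
    Cr: 33.9
    Cu: 8.56
    Pb: 32.7
    V: 95.6
    Zn: 118
  screening:
    Cd: 0.30
    Cr: 150
    Cu: 50.0
    Pb: 90.0
    V: 130
    Zn: 200
  screening_source:
    V: "Canadian soil quality guideline"
  veg_mpl:
    Cd: 0.20
    Pb: 0.30
    Cr: 1.0
  igeo_classes:
    - upper: 0
      label: "unpolluted"
    - upper: 1
      label: "unpolluted to moderately contaminated"
    - upper: 2
      label: "moderately contaminated"
    - upper: 3
      label: "moderately to heavily contaminated"
    - upper: 4
      label: "heavily contaminated"
    - upper: 5
      label: "heavily to extremely contaminated"
    - upper: .inf
      label: "extremely contaminated"
scenarios:
  adult:
    ir_veg: 345      # g/day fresh weight
    ef: 365          # days/year
    ed: 30           # years
    bw: 61.8         # kg
    rfd:             # mg/kg/day, oral
      Cd: 0.001
      Cr: 0.003
      Cu: 0.04
      Pb: 0.0035
      V: 0.009
      Zn: 0.3
  child:
    ir_veg: 232
    ef: 365
    ed: 6
    bw: 23.6
    rfd:
      Cd: 0.001
      Cr: 0.003
      Cu: 0.04
      Pb: 0.0035
      V: 0.009
      Zn: 0.3
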