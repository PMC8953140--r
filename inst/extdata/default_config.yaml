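# Default analysis configuration. Any omitted entry keeps the package
# default; delivery-mode, abortion and stillbirth sets are fixed by the
# study design, the rest are dictionary-dependent.
code_sets:
  pregnancy: [Z32, Z33, Z34, Z35, Z36]
  delivery_vaginal: [O80, O81, O83, O84.0, O84.1]
  delivery_cesarean: [O82, O84.2]
  jaundice: [P58, P59]
  preterm: [O60]
  multiple_gestation: [O30, O31]
  abortion: [O00, O01, O02, O03, O04, O05, O06, O07, O08]
  stillbirth: [O36.4, Z37.1, Z37.4, Z37.7]
  pregnancy_related_exclusion: [O, Z32, Z33, Z34, Z35, Z36, Z37, Z38, Z39]
windows:
  flag_days: 28        # 4 weeks
  min_delivery_gap: 168 # 24 weeks
  max_gestation: 308   # 44 weeks
  preconception_days: 365
dialect:
  delim: "\t"
  date_format: "%Y-%m-%d"
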