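# Calibrated two-district pilot scenario. Category cost levels are the
# program's published annual totals (summary-table cells, US$/year);
# population denominators are not published and are back-solved at run
# time from the published per-user protocol totals (see
# calibrate_denominators()). Task times are degenerate (zero variance)
# with a balanced observation design, so the pipeline output has an
# exact closed form.
districts:
  Naqadeh:
    urban_pop: 81598
    rural_pop: 45720
  Shahreza:
    urban_pop: 134952
    rural_pop: 20988
supply_totals:
  MI_STROKE: 102859.24
  RESPIRATORY: 671.95
  CRC: 7413.57
  FEMALE_CANCER: 31270.27
  NCD_RISK: 129.39
personnel_totals:
  MI_STROKE: 186455.94
  RESPIRATORY: 37361.09
  CRC: 81284.81
  FEMALE_CANCER: 163802.66
  NCD_RISK: 207893.64
equipment_totals:
  MI_STROKE: 7389.52
  RESPIRATORY: 1513.00
  CRC: 0.00
  FEMALE_CANCER: 5.04
  NCD_RISK: 0.00
nonspecific:
  consultancy: 21455.02
  retraining: 1979.39
  supervision_recurrent: 16741.34
  introduction: 18771.88
  customization: 7414.07
  supervision_capital: 8273.52
published_totals_without:
  MI_STROKE: 7.45
  RESPIRATORY: 1.05
  CRC: 3.95
  FEMALE_CANCER: 7.13
  NCD_RISK: 5.32
published_total_without: 24.90
published_total_with: 25.32
usage_prob: 0.40
time_cv: 0.0
balanced_dom: true
pilot_duration_months: 13
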