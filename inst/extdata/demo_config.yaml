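# Demo study configuration: a synthetic anti-EGFR renal-safety study.
#
# The synth block plants the drug-event odds ratios and time-to-onset
# medians a real screen of this kind would be expected to recover; run
#   vigisignal generate --config demo_config.yaml
# first (or run_generate() in R) to materialise the reports file, then
# screen / describe / tto. The dictionary is the package's hand-written
# synthetic renal hierarchy, not licensed terminology.

reports: demo_reports.csv
reports_format: delimited
dictionary: renal_hierarchy_synthetic.csv
output_dir: demo_out

window_end: "2020-12-01"
drugs:
  - {name: erlotinib,   authorisation_date: "2005-09-19"}
  - {name: gefitinib,   authorisation_date: "2009-06-24"}
  - {name: afatinib,    authorisation_date: "2013-09-25"}
  - {name: osimertinib, authorisation_date: "2016-02-02"}
  - {name: cetuximab,   authorisation_date: "2004-06-29"}
  - {name: panitumumab, authorisation_date: "2007-12-03"}

hlts:
  - glomerulonephritis and nephrotic syndrome
  - nephritis NEC
  - nephropathies and tubular disorders NEC
  - renal disorders NEC
  - renal failure and impairment
  - renal hypertension and related conditions
  - renal vascular and ischaemic conditions

eligibility:
  require_health_professional: true
  require_known_age: true
  require_known_sex: true
  dedup: true
  dedup_window_days: 30

min_cases: 5
z: 1.96
era_cut: 2010
co_report_index_pts: [Acute kidney injury, Renal failure]
co_report_k: 5
seed: 1

synth:
  n_reports: 60000
  duplicate_rate: 0.02
  planted_or:
    - {drug: afatinib,  pt: Acute kidney injury,         theta: 2.70}
    - {drug: erlotinib, pt: Acute kidney injury,         theta: 1.73}
    - {drug: afatinib,  pt: Renal failure,               theta: 2.41}
    - {drug: cetuximab, pt: Renal failure,               theta: 1.42}
    - {drug: erlotinib, pt: Renal failure,               theta: 2.23}
    - {drug: erlotinib, pt: Haemolytic uraemic syndrome, theta: 4.01}
    - {drug: erlotinib, pt: Thrombotic microangiopathy,  theta: 4.94}
  tto_model:
    - {drug: afatinib,  pt: Acute kidney injury, median_days: 24.5, sigma: 0.9}
    - {drug: erlotinib, pt: Acute kidney injury, median_days: 34,   sigma: 0.9}
    - {drug: afatinib,  pt: Renal failure,       median_days: 15,   sigma: 0.9}
    - {drug: cetuximab, pt: Renal failure,       median_days: 23,   sigma: 0.9}
    - {drug: erlotinib, pt: Renal failure,       median_days: 41,   sigma: 0.9}
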