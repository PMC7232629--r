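# SNCT staffing multipliers for general adult inpatient units.
# Each acuity/dependency level maps to a whole-time-equivalent (WTE)
# staffing weight per patient.  Edit to use a different multiplier release
# or a locally agreed variant; the analysis code never hard-codes these.
levels: ["0", "1a", "1b", "2", "3"]
multipliers: [0.99, 1.39, 1.72, 1.97, 5.96]
uplift_fraction: 0.22
wte_weekly_hours: 37.5
specialing_hours_per_patient_day: 24
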