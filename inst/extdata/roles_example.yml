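patient_id: id
age: continuous
gender: categorical
disease: categorical
drug_name: categorical
dose_amount: dose_amount
dose_unit: dose_unit
dose_frequency: categorical
therapy_start: date_start
event_date: date_end
outcome_codes: outcome
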