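tables:
- name: demographic
  columns:
  - name: subject_id
    kind: numeric
    join_key: no
  - name: hadm_id
    kind: numeric
    join_key: yes
  - name: name
    kind: text
    join_key: no
  - name: marital_status
    kind: text
    join_key: no
  - name: age
    kind: numeric
    join_key: no
  - name: dob
    kind: text
    join_key: no
  - name: gender
    kind: text
    join_key: no
  - name: language
    kind: text
    join_key: no
  - name: religion
    kind: text
    join_key: no
  - name: admission_type
    kind: text
    join_key: no
  - name: days_stay
    kind: numeric
    join_key: no
  - name: insurance
    kind: text
    join_key: no
  - name: ethnicity
    kind: text
    join_key: no
  - name: expire_flag
    kind: numeric
    join_key: no
  - name: admission_location
    kind: text
    join_key: no
  - name: discharge_location
    kind: text
    join_key: no
  - name: diagnosis
    kind: text
    join_key: no
  - name: dod
    kind: text
    join_key: no
  - name: dob_year
    kind: numeric
    join_key: no
  - name: dod_year
    kind: numeric
    join_key: no
  - name: admittime
    kind: text
    join_key: no
  - name: dischtime
    kind: text
    join_key: no
  - name: admityear
    kind: numeric
    join_key: no
- name: diagnoses
  columns:
  - name: subject_id
    kind: numeric
    join_key: no
  - name: hadm_id
    kind: numeric
    join_key: yes
  - name: icd9_code
    kind: text
    join_key: no
  - name: short_title
    kind: text
    join_key: no
  - name: long_title
    kind: text
    join_key: no
- name: procedures
  columns:
  - name: subject_id
    kind: numeric
    join_key: no
  - name: hadm_id
    kind: numeric
    join_key: yes
  - name: icd9_code
    kind: text
    join_key: no
  - name: short_title
    kind: text
    join_key: no
  - name: long_title
    kind: text
    join_key: no
- name: prescriptions
  columns:
  - name: subject_id
    kind: numeric
    join_key: no
  - name: hadm_id
    kind: numeric
    join_key: yes
  - name: icustay_id
    kind: numeric
    join_key: no
  - name: drug_type
    kind: text
    join_key: no
  - name: drug
    kind: text
    join_key: no
  - name: formulary_drug_cd
    kind: text
    join_key: no
  - name: route
    kind: text
    join_key: no
- name: lab
  columns:
  - name: subject_id
    kind: numeric
    join_key: no
  - name: hadm_id
    kind: numeric
    join_key: yes
  - name: itemid
    kind: text
    join_key: no
  - name: charttime
    kind: text
    join_key: no
  - name: flag
    kind: text
    join_key: no
  - name: value_unit
    kind: text
    join_key: no
  - name: label
    kind: text
    join_key: no
  - name: fluid
    kind: text
    join_key: no
  - name: category
    kind: text
    join_key: no
joins:
- left: demographic
  right: diagnoses
  key: hadm_id
- left: demographic
  right: procedures
  key: hadm_id
- left: demographic
  right: prescriptions
  key: hadm_id
- left: demographic
  right: lab
  key: hadm_id
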