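# Shipped simulation configuration: stacked probability distributions for a
# stratified synthetic cancer registry (gender x 5-year age strata).
#
# The 60-64 diagnosis table and the colorectal therapy table carry the
# published calibration values; all other tables are plausible desk-scale
# defaults documented in the methods vignette.

namespace: "http://www.imib.es/ontologies/disease-times#"
index_date: "2010-01-01"
age_bin_width: 5
max_age_bin: 85          # last stratum is open-ended (85+)

multidx_fraction:
  default: 0.10

therapy_continue_prob: 0.5   # geometric stopping rule per therapy slot
max_therapies: 6
therapy_duration_months: [1, 3]
max_course_months: 60

gender_weights:
  M: 0.5
  F: 0.5

# Age pyramid of incident cases (shared by gender).
stratum_weights:
  "0-4": 0.002
  "5-9": 0.002
  "10-14": 0.003
  "15-19": 0.004
  "20-24": 0.006
  "25-29": 0.008
  "30-34": 0.012
  "35-39": 0.018
  "40-44": 0.028
  "45-49": 0.042
  "50-54": 0.062
  "55-59": 0.085
  "60-64": 0.105
  "65-69": 0.125
  "70-74": 0.135
  "75-79": 0.125
  "80-84": 0.110
  "85+": 0.128

# Ordered (category, weight) stacks; cumulative boundaries follow list order.
diagnosis_weights:
  default:
    - [Breast_cancer, 0.15]
    - [Lung_cancer, 0.12]
    - [Prostate_cancer, 0.10]
    - [Colorectal_cancer, 0.10]
    - [Melanoma, 0.08]
    - [Pharynx_cancer, 0.03]
    - [Other_cancer, 0.42]
  "60-64":
    - [Breast_cancer, 0.23]
    - [Lung_cancer, 0.17]
    - [Prostate_cancer, 0.17]
    - [Colorectal_cancer, 0.08]
    - [Other_cancer, 0.35]

therapy_weights:
  default:
    Colorectal_cancer:
      - [Teletherapy, 0.44]
      - [Chemotherapy, 0.44]
      - [SurgicalTreatment, 0.12]
    Breast_cancer:
      - [SurgicalTreatment, 0.40]
      - [Chemotherapy, 0.25]
      - [Anti-hormoneTherapy, 0.20]
      - [Teletherapy, 0.15]
    Lung_cancer:
      - [Chemotherapy, 0.45]
      - [Teletherapy, 0.30]
      - [SurgicalTreatment, 0.15]
      - [Immunotherapy, 0.10]
    Prostate_cancer:
      - [SurgicalTreatment, 0.35]
      - [Brachytherapy, 0.25]
      - [Anti-hormoneTherapy, 0.25]
      - [Wait_and_see, 0.15]
    Melanoma:
      - [SurgicalTreatment, 0.60]
      - [Immunotherapy, 0.25]
      - [Chemotherapy, 0.15]
    Pharynx_cancer:
      - [Teletherapy, 0.45]
      - [SurgicalTreatment, 0.35]
      - [Chemotherapy, 0.20]
    Other_cancer:
      - [SurgicalTreatment, 0.35]
      - [Chemotherapy, 0.35]
      - [Teletherapy, 0.20]
      - [Wait_and_see, 0.10]

# Diagnosis catalog: ICD-10 code stacks (optionally gender-specific),
# anatomical site and tumor type per pathological structure.
diagnosis_catalog:
  Colorectal_cancer:
    anatomical_structure: Colon
    tumor_type: adenocarcinoma
    icd10_codes:
      M:
        - [C18.0, 0.02]
        - [C18.2, 0.05]
        - [C18.4, 0.05]
        - [C18.7, 0.14]
        - [C18.9, 0.12]
        - [C19, 0.10]
        - [C20, 0.38]
        - [C21.0, 0.04]
        - [C17.0, 0.02]
        - [D01.0, 0.04]
        - [D01.2, 0.04]
      F:
        - [C18.0, 0.03]
        - [C18.2, 0.07]
        - [C18.4, 0.07]
        - [C18.7, 0.22]
        - [C18.9, 0.16]
        - [C19, 0.10]
        - [C20, 0.18]
        - [C21.0, 0.05]
        - [C17.0, 0.02]
        - [D01.0, 0.05]
        - [D01.2, 0.05]
  Lung_cancer:
    anatomical_structure: Lung
    tumor_type: carcinoma
    icd10_codes:
      default:
        - [C34.0, 0.08]
        - [C34.1, 0.30]
        - [C34.2, 0.07]
        - [C34.3, 0.25]
        - [C34.8, 0.10]
        - [C34.9, 0.20]
  Breast_cancer:
    anatomical_structure: Breast
    tumor_type: carcinoma
    icd10_codes:
      default:
        - [C50, 1.0]
  Prostate_cancer:
    anatomical_structure: Prostate
    tumor_type: adenocarcinoma
    icd10_codes:
      default:
        - [C61, 1.0]
  Melanoma:
    anatomical_structure: Skin
    tumor_type: melanoma
    icd10_codes:
      default:
        - [C43, 1.0]
  Pharynx_cancer:
    anatomical_structure: Pharynx
    tumor_type: squamous cell carcinoma
    icd10_codes:
      default:
        - [C10.9, 1.0]
  Other_cancer:
    anatomical_structure: ""
    tumor_type: other
    icd10_codes:
      default:
        - [C80.9, 1.0]

course_model:
  states: [Stable_disease, Partial_remission, Complete_remission,
           Progression, Recurrence, Death]
  absorbing: [Death, Complete_remission]
  initial:
    Stable_disease: 1.0
  transitions:
    default:
      Stable_disease:
        Stable_disease: 0.68
        Partial_remission: 0.10
        Complete_remission: 0.06
        Progression: 0.11
        Death: 0.05
      Partial_remission:
        Partial_remission: 0.58
        Complete_remission: 0.22
        Recurrence: 0.10
        Progression: 0.06
        Death: 0.04
      Progression:
        Progression: 0.58
        Partial_remission: 0.10
        Stable_disease: 0.08
        Death: 0.24
      Recurrence:
        Recurrence: 0.48
        Partial_remission: 0.20
        Progression: 0.22
        Death: 0.10
    Lung_cancer:
      Stable_disease:
        Stable_disease: 0.60
        Partial_remission: 0.08
        Complete_remission: 0.04
        Progression: 0.18
        Death: 0.10
      Partial_remission:
        Partial_remission: 0.55
        Complete_remission: 0.15
        Recurrence: 0.12
        Progression: 0.10
        Death: 0.08
      Progression:
        Progression: 0.55
        Partial_remission: 0.07
        Stable_disease: 0.05
        Death: 0.33
      Recurrence:
        Recurrence: 0.45
        Partial_remission: 0.15
        Progression: 0.25
        Death: 0.15

condition_model:
  weight_kg:
    M: [80, 12]
    F: [67, 11]
  height_cm:
    M: [175, 7]
    F: [162, 6]
  karnofsky_start: [90, 100]
  asa_weights: [0.15, 0.35, 0.30, 0.15, 0.04, 0.01]
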