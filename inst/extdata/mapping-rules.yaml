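# Mapping rules: registry CSV tables -> ontology classes and properties.
#
# Each table maps to a class (or a per-row subclass via class_column), each
# column to a datatype property, and each foreign-key column to an object
# property (optionally with its inverse). structure_columns create one
# auxiliary typed individual per row (e.g. the pathological structure of a
# diagnosis). derived_links follow a two-hop key path.

namespace: "http://www.imib.es/ontologies/disease-times#"

tables:
  patients:
    class: Patient
    key: patient_id
    datatype_columns:
      gender: {property: gender, kind: string}
      birth_date: {property: birth_date, kind: date}
  conditions:
    class: Patient_condition
    key: condition_id
    datatype_columns:
      ref_date: {property: ref_date, kind: date}
      age: {property: age, kind: integer}
      weight_kg: {property: weight, kind: decimal}
      height_cm: {property: height, kind: decimal}
      karnofsky: {property: karnofsky_index, kind: integer}
      asa: {property: asa_index, kind: integer}
      menopause_status: {property: menopause_status, kind: string}
    object_columns:
      patient_id: {property: hasPatient, table: patients, inverse: hasPatientCondition}
  diagnoses:
    class: Diagnosis
    key: diagnosis_id
    datatype_columns:
      icd10_code: {property: icd10_code, kind: string}
      grading: {property: grading, kind: string}
      tnm_t: {property: tnm_t, kind: string}
      tnm_n: {property: tnm_n, kind: string}
      tnm_m: {property: tnm_m, kind: string}
      date: {property: date, kind: date}
      tumor_type: {property: tumor_type, kind: string}
    object_columns:
      patient_id: {property: hasPatient, table: patients, inverse: hasDiagnosis}
    structure_columns:
      pathological_structure: {property: hasPathologicalStructure, individual_prefix: pathology}
      anatomical_structure: {property: hasAnatomicalStructure, individual_prefix: anatomy}
  therapies:
    class: Therapy
    class_column: therapy_class
    key: therapy_id
    datatype_columns:
      medication: {property: medication, kind: string}
      start_date: {property: start_date, kind: date}
      end_date: {property: end_date, kind: date}
    object_columns:
      diagnosis_id: {property: hasDiagnosis, table: diagnoses, inverse: hasTherapy}
  courses:
    class: Disease_course
    class_column: course_kind
    key: course_id
    datatype_columns:
      stage: {property: stage, kind: string}
      order: {property: order, kind: integer}
      date: {property: date, kind: date}
    object_columns:
      diagnosis_id: {property: hasDiagnosis, table: diagnoses, inverse: hasDiseaseCourse}

# Two-hop links: therapy -> diagnosis -> patient.
derived_links:
  - from: therapies
    via: [diagnosis_id, patient_id]
    property: hasPatient
    inverse: hasTherapy

# Materialised convenience property: patient age at first recorded condition
# (the printed query templates filter on it directly).
materialize:
  patient_age_from_conditions: true
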