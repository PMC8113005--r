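# MIABIS 2.0 core registry: the three main components (biobank, study,
# sample collection) plus the sub-entities attached to the sample
# collection. Every entity additionally receives a surrogate `id` primary
# key at DDL time; attribute lists are extensible without code changes.
model: miabis_core
hub: SampleCollection
entities:
  - name: Biobank
    stereotype: core
    attributes:
      - {name: biobank_ref, domain: text, nullable: false}
      - {name: acronym, domain: text, nullable: true}
      - {name: name, domain: text, nullable: false}
      - {name: url, domain: text, nullable: true}
      - {name: juristic_person, domain: text, nullable: true}
      - {name: country, domain: text, nullable: true}
      - {name: contact_information, domain: text, nullable: true}
  - name: Study
    stereotype: core
    attributes:
      - {name: study_ref, domain: text, nullable: false}
      - {name: name, domain: text, nullable: false}
      - {name: description, domain: text, nullable: true}
      - {name: principal_investigator, domain: text, nullable: true}
      - {name: study_design, domain: text, nullable: true}
  - name: SampleCollection
    stereotype: core
    attributes:
      - {name: collection_ref, domain: text, nullable: false}
      - {name: acronym, domain: text, nullable: true}
      - {name: name, domain: text, nullable: true}
      - {name: description, domain: text, nullable: true}
  - name: DonorAge
    stereotype: sub_entity
    attributes:
      - {name: age_low, domain: integer, nullable: true}
      - {name: age_high, domain: integer, nullable: true}
      - {name: age_unit, domain: text, nullable: true}
  - name: DonorSex
    stereotype: sub_entity
    attributes:
      - {name: sex, domain: text, nullable: false}
  - name: MaterialType
    stereotype: sub_entity
    attributes:
      - {name: material_type, domain: text, nullable: false}
  - name: StorageTemperature
    stereotype: sub_entity
    attributes:
      - {name: storage_temperature, domain: text, nullable: false}
relationships:
  - {source: Biobank, target: SampleCollection, cardinality: ONE_TO_MANY, label: hosts}
  - {source: Biobank, target: Study, cardinality: ONE_TO_MANY, label: conducts}
  - {source: Study, target: SampleCollection, cardinality: MANY_TO_MANY, label: uses}
  - {source: SampleCollection, target: DonorAge, cardinality: ONE_TO_MANY, label: donor_age}
  - {source: SampleCollection, target: DonorSex, cardinality: ONE_TO_MANY, label: donor_sex}
  - {source: SampleCollection, target: MaterialType, cardinality: ONE_TO_MANY, label: material}
  - {source: SampleCollection, target: StorageTemperature, cardinality: ONE_TO_MANY, label: storage}
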