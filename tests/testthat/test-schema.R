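# Schema engine: builders, graph queries, invariant validation.

test_that("MIABIS core has the three main components and their sub-entities", {
  core <- buildMiabisCore()
  core_names <- names(Filter(function(e) e@stereotype == "core",
                             schemaEntities(core)))
  expect_setequal(core_names, c("Biobank", "Study", "SampleCollection"))
  linked <- linkedEntities(core, "SampleCollection")
  expect_true(all(c("MaterialType", "StorageTemperature",
                    "DonorAge", "DonorSex") %in% linked))
  expect_true(isValid(validateSchema(core)))
})

test_that("integration model has the structure of the extended ERD", {
  ig <- buildIntegrationModel()
  expect_true(isValid(validateSchema(ig)))

  # Collection replaces SampleCollection as the hub, with exactly five
  # sub-collection types
  expect_true("Collection" %in% entityNames(ig))
  expect_false("SampleCollection" %in% entityNames(ig))
  subtypes <- names(Filter(function(e) e@stereotype == "collection_type",
                           schemaEntities(ig)))
  expect_setequal(subtypes, c("ImageCollection", "SampleTissueCollection",
                              "ClinicalVariableCollection",
                              "MolecularBiomarkerCollection",
                              "SoftwareSourceCode"))
  r <- schemaRelationships(ig)
  expect_setequal(r$target[r$source == "Collection" &
                             r$label == "sub_collection"], subtypes)

  # the five entities directly linked to the image collection
  expect_setequal(linkedEntities(ig, "ImageCollection"),
                  c("BodyPartExamined", "ModalityInformation", "DatasetType",
                    "ImageAnalysis", "RegistrationParameters"))

  # branch structure below the imaging entities
  expect_setequal(linkedEntities(ig, "ModalityInformation"),
                  c("Modality", "AcquisitionParameters",
                    "ReconstructionParameters", "ImageCollection"))
  expect_setequal(linkedEntities(ig, "ImageAnalysis"),
                  c("PreprocessingParameters", "Segmentation",
                    "ImagingBiomarkers", "ImageCollection"))
  expect_setequal(linkedEntities(ig, "Segmentation"),
                  c("Manual", "SemiAutomatic", "Automatic", "ImageAnalysis"))
  expect_setequal(linkedEntities(ig, "ImagingBiomarkers"),
                  c("TextureFeatures", "DeepFeatures",
                    "DynamicSignalFeatures", "ImageAnalysis"))
  expect_setequal(linkedEntities(ig, "RegistrationParameters"),
                  c("IntraSequence", "InterSequence", "InterModal",
                    "ImageCollection"))
})

test_that("tissue-specific sub-entities attach only to the tissue sub-collection", {
  ig <- buildIntegrationModel()
  r <- schemaRelationships(ig)
  for (ent in c("MaterialType", "StorageTemperature")) {
    parents <- r$source[r$target == ent]
    expect_identical(parents, "SampleTissueCollection")
  }
  # donor-level descriptors attach to the macro-category instead
  for (ent in c("DonorAge", "DonorSex"))
    expect_true("Collection" %in% r$source[r$target == ent])
  expect_false("BodyPartExamined" %in%
                 linkedEntities(ig, "SampleTissueCollection"))
})

test_that("every entity named in the model description is present", {
  ig <- buildIntegrationModel()
  named <- c("Biobank", "Study", "Collection",
             "ImageCollection", "SampleTissueCollection",
             "ClinicalVariableCollection", "MolecularBiomarkerCollection",
             "SoftwareSourceCode", "BodyPartExamined",
             "ModalityInformation", "DatasetType", "ImageAnalysis",
             "RegistrationParameters", "Modality", "AcquisitionParameters",
             "ReconstructionParameters", "PreprocessingParameters",
             "Segmentation", "ImagingBiomarkers", "Manual",
             "SemiAutomatic", "Automatic", "TextureFeatures",
             "DeepFeatures", "DynamicSignalFeatures", "IntraSequence",
             "InterSequence", "InterModal", "MaterialType",
             "StorageTemperature", "DonorAge", "DonorSex")
  expect_true(all(named %in% entityNames(ig)))
})

test_that("builders are deterministic (set equality on entities and edges)", {
  a <- buildIntegrationModel()
  b <- buildIntegrationModel()
  expect_identical(entityNames(a), entityNames(b))
  expect_identical(schemaRelationships(a), schemaRelationships(b))
  expect_identical(
    lapply(schemaEntities(a), function(e) e@attributes),
    lapply(schemaEntities(b), function(e) e@attributes))
})

test_that("cardinalities are restricted to the 1:1 / 1:N / N:M legend", {
  ig <- buildIntegrationModel()
  expect_true(all(schemaRelationships(ig)$cardinality %in% CARDINALITIES))
  r2 <- schemaRelationships(ig)
  r2$cardinality[1] <- "MANY_TO_ONE"
  bad <- ig
  expect_error({ bad@relationships <- r2; validObject(bad) },
               "cardinality")
})

test_that("linkedEntities rejects unknown names and handles isolated entities", {
  ig <- buildIntegrationModel()
  expect_error(linkedEntities(ig, "NoSuchEntity"),
               class = "unknown_entity_error")
  lone <- new("SchemaGraph", model = "lone", hub = NA_character_,
              entities = list(Only = new(
                "EntityDef", name = "Only", stereotype = "core",
                attributes = data.frame(name = "ref", domain = "text",
                                        nullable = FALSE))),
              relationships = schemaRelationships(ig)[0, ])
  expect_identical(linkedEntities(lone, "Only"), character(0))
})

test_that("validateSchema reports each kind of forced violation", {
  ig <- buildIntegrationModel()

  # dangling endpoint: drop an entity but keep its relationships
  broken <- ig
  broken@entities <- broken@entities[setdiff(entityNames(ig), "Modality")]
  rep <- validateSchema(broken)
  expect_false(isValid(rep))
  expect_true("dangling_endpoint" %in% violations(rep)$rule)

  # duplicate entity name
  dup <- ig
  extra <- dup@entities[["Collection"]]
  dup@entities <- c(dup@entities, list(extra))
  names(dup@entities)[length(dup@entities)] <- "Collection2"
  rep2 <- validateSchema(dup)
  expect_true("duplicate_name" %in% violations(rep2)$rule)

  # disconnected entity
  iso <- ig
  iso@entities$Orphan <- new(
    "EntityDef", name = "Orphan", stereotype = "sub_entity",
    attributes = data.frame(name = "x", domain = "text", nullable = TRUE))
  rep3 <- validateSchema(iso)
  expect_true("disconnected" %in% violations(rep3)$rule)

  # coded domain referencing an unregistered vocabulary
  voc <- ig
  voc@entities$Modality@attributes$domain[1] <- "coded(NOT_A_VOCAB)"
  rep4 <- validateSchema(voc)
  expect_true("unknown_vocabulary" %in% violations(rep4)$rule)
})

test_that("registry files round-trip through the reader", {
  path <- system.file("extdata", "registry", "integration_model.yaml",
                      package = "dicomiabis")
  direct <- readSchemaRegistry(path)
  expect_identical(entityNames(direct), entityNames(buildIntegrationModel()))
  expect_error(readSchemaRegistry(1), class = "usage_error")
})
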