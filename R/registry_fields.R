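# The complete 3D-MMS v1 field inventory, encoded as data.
#
# Scope of a field:
#   record   - one value per dataset record
#   entry    - one value per repeated entry of an entry-list category
#              (Contributors, Funders, Publication)
#   channel  - one value per imaging channel (Image category)
#   landmark - one value per anatomical landmark (Image category)
#
# provenance marks whether a field's name is printed in the standard's
# required-field table ("table-1") or synthesized from the standard's prose
# description of the optional fields ("synthesized-from-prose"), so the
# synthesized roster is auditable and replaceable.

mms_categories <- function() {
  c("Contributors", "Funders", "Dataset", "Image", "Instrument",
    "Publication", "Specimen")
}

# closed vocabularies
.vocab_axis <- c("Left to right", "Right to left", "Anterior to posterior",
                 "Posterior to anterior", "Inferior to superior",
                 "Superior to inferior", "Oblique")
.vocab_scheme <- c("GRID", "ISNI", "ORCID", "ROR", "RRID")
.vocab_contributor_type <- c("ContactPerson", "DataCollector", "DataCurator",
                             "ProjectLeader", "ProjectManager",
                             "ProjectMember", "RelatedPerson", "Researcher",
                             "ResearchGroup", "Other")
.vocab_name_type <- c("Organizational", "Personal")
.vocab_yes_no <- c("Yes", "No")
.vocab_ageunit <- c("Days", "Months", "Years")
.vocab_sex <- c("Male", "Female", "Unknown")
.vocab_related_id_type <- c("DOI", "ISBN", "ISSN", "PMID", "arXiv",
                            "Handle", "URL")
.vocab_relation_type <- c("IsCitedBy", "Cites", "IsSupplementTo",
                          "IsSupplementedBy", "IsDescribedBy", "Describes",
                          "IsDocumentedBy", "Documents", "IsDerivedFrom",
                          "IsSourceOf", "IsReferencedBy", "References")

# advisory ("suggested value") lists for free-text fields; membership
# failures are advice-level, never errors
.sugg_modality <- c("anatomy", "cell morphology", "connectivity",
                    "histology imaging", "population imaging",
                    "spatial transcriptomics", "multimodal")
.sugg_technique <- c("confocal microscopy", "two-photon microscopy",
                     "light sheet fluorescence microscopy",
                     "oblique light sheet microscopy",
                     "serial two-photon tomography", "fMOST", "smFISH",
                     "MERFISH", "anterograde tracing", "retrograde tracing",
                     "immunohistochemistry", "tissue clearing")
.sugg_microscope_type <- c("inverted", "upright", "light sheet", "confocal",
                           "two photon")
.sugg_immersion <- c("Oil", "Water", "WaterDipping", "Air", "Multi",
                     "Glycerol", "Other")
.sugg_illumination <- c("Transmitted", "Epifluorescence", "Oblique",
                        "NonLinear")
.sugg_detector <- c("CCD", "EMCCD", "CMOS", "sCMOS", "PMT", "Hybrid",
                    "Photodiode")
.sugg_spdx <- c("CC0-1.0", "CC-BY-4.0", "CC-BY-NC-4.0", "CC-BY-SA-4.0",
                "MIT", "GPL-3.0-only")

.condition_text <- c(
  none = "",
  personal_name_type = "Required when nameType is Personal.",
  government_funded =
    "Required only when the project is funded by government agencies.",
  common_license = "Required only when a common license is used."
)

# one field definition; compact constructor used by mms_field_table()
.fld <- function(name, category, definition, value_kind = "free_text",
                 vocabulary = character(), suggested = character(),
                 requirement = "optional", condition = "none",
                 scope = "record", doi = FALSE, datacite = NA_character_,
                 ome = NA_character_, units = NA_character_,
                 provenance = "table-1") {
  list(name = name, category = category, definition = definition,
       value_kind = value_kind, vocabulary = vocabulary,
       suggested_values = suggested, requirement_level = requirement,
       condition = condition,
       condition_text = unname(.condition_text[[condition]]),
       scope = scope,
       repeatable = scope != "record",
       max_occurrences = if (scope == "record") 1 else Inf,
       doi_support = doi, datacite_property = datacite, ome_term = ome,
       units = units, provenance = provenance)
}

# full inventory: 91 fields, seven categories in the standard's order
mms_field_list <- function() {
  syn <- "synthesized-from-prose"
  c(
    ## Contributors -- 9 fields, all DOI-supporting, entry-scoped ----------
    list(
      .fld("contributorName", "Contributors",
           "Person (last name, first name) or organization contributing to or responsible for the project; funders are listed separately. A contributor holding several roles is repeated, one entry per role.",
           requirement = "required", scope = "entry", doi = TRUE,
           datacite = "contributorName"),
      .fld("Creator", "Contributors",
           "Whether this contributor is one of the main researchers who produced the data; every dataset needs at least one creator.",
           value_kind = "vocabulary", vocabulary = .vocab_yes_no,
           requirement = "required", scope = "entry", doi = TRUE,
           datacite = "creators"),
      .fld("contributorType", "Contributors",
           "Role of the contributor on the project (ProjectLeader is recommended for the principal investigator, ResearchGroup for a laboratory or department).",
           value_kind = "vocabulary", vocabulary = .vocab_contributor_type,
           requirement = "required", scope = "entry", doi = TRUE,
           datacite = "contributorType"),
      .fld("nameType", "Contributors",
           "Whether contributorName denotes a person or an organization.",
           value_kind = "vocabulary", vocabulary = .vocab_name_type,
           requirement = "required", scope = "entry", doi = TRUE,
           datacite = "nameType"),
      .fld("nameIdentifier", "Contributors",
           "Unique identifier for the person or legal entity named in contributorName; ORCID is preferred for persons, ROR for organizations.",
           requirement = "conditional", condition = "personal_name_type",
           scope = "entry", doi = TRUE, datacite = "nameIdentifier"),
      .fld("nameIdentifierScheme", "Contributors",
           "Identifier scheme used in nameIdentifier.",
           value_kind = "vocabulary", vocabulary = .vocab_scheme,
           requirement = "conditional", condition = "personal_name_type",
           scope = "entry", doi = TRUE, datacite = "nameIdentifierScheme"),
      .fld("affiliation", "Contributors",
           "Organizational or institutional affiliation of the contributor.",
           requirement = "required", scope = "entry", doi = TRUE,
           datacite = "affiliation"),
      .fld("affiliationIdentifier", "Contributors",
           "Unique identifier (ROR preferred) for the contributor's affiliation.",
           requirement = "required", scope = "entry", doi = TRUE,
           datacite = "affiliationIdentifier"),
      .fld("affiliationIdentifierScheme", "Contributors",
           "Identifier scheme used in affiliationIdentifier.",
           value_kind = "vocabulary", vocabulary = .vocab_scheme,
           requirement = "required", scope = "entry", doi = TRUE,
           datacite = "affiliationIdentifierScheme")
    ),
    ## Funders -- 5 fields, all DOI-supporting, required when government
    ## funding applies ----------------------------------------------------
    list(
      .fld("funderName", "Funders", "Name of the funding organization.",
           requirement = "conditional", condition = "government_funded",
           scope = "entry", doi = TRUE, datacite = "funderName"),
      .fld("fundingReferenceIdentifier", "Funders",
           "Unique identifier (ROR preferred) or URL for the funding organization.",
           requirement = "conditional", condition = "government_funded",
           scope = "entry", doi = TRUE, datacite = "funderIdentifier"),
      .fld("fundingReferenceIdentifierType", "Funders",
           "Identifier scheme used in fundingReferenceIdentifier.",
           value_kind = "vocabulary", vocabulary = .vocab_scheme,
           requirement = "conditional", condition = "government_funded",
           scope = "entry", doi = TRUE, datacite = "funderIdentifierType"),
      .fld("awardNumber", "Funders",
           "Funding code or project number assigned to the grant.",
           requirement = "conditional", condition = "government_funded",
           scope = "entry", doi = TRUE, datacite = "awardNumber"),
      .fld("awardTitle", "Funders", "Title of the grant award.",
           requirement = "conditional", condition = "government_funded",
           scope = "entry", doi = TRUE, datacite = "awardTitle")
    ),
    ## Dataset -- 15 fields (5 in the required table) ----------------------
    list(
      .fld("Title", "Dataset",
           "Short phrase by which the dataset is known.",
           requirement = "required", doi = TRUE, datacite = "title"),
      .fld("Rights", "Dataset",
           "Rights information for the dataset: license name, embargo or other use restrictions.",
           requirement = "required", doi = TRUE, datacite = "rights"),
      .fld("rightsURI", "Dataset",
           "Link to the license text when a common online license is used.",
           requirement = "conditional", condition = "common_license",
           doi = TRUE, datacite = "rightsUri"),
      .fld("rightsIdentifier", "Dataset",
           "SPDX code of the license when a common license is used.",
           suggested = .sugg_spdx,
           requirement = "conditional", condition = "common_license",
           doi = TRUE, datacite = "rightsIdentifier"),
      .fld("Abstract", "Dataset",
           "Descriptive summary of the dataset and the context in which it was created; shown on the DOI landing page, ideally more than 100 words.",
           requirement = "required", doi = TRUE, datacite = "description"),
      .fld("generalModality", "Dataset",
           "Imaging modality the dataset addresses (e.g. cell morphology, connectivity).",
           suggested = .sugg_modality, provenance = syn),
      .fld("otherModality", "Dataset",
           "Modality description when none of the suggested modality values applies.",
           provenance = syn),
      .fld("technique", "Dataset",
           "Experimental technique used to generate the dataset (e.g. anterograde tracing, smFISH).",
           suggested = .sugg_technique, provenance = syn),
      .fld("otherTechnique", "Dataset",
           "Technique description when none of the suggested technique values applies.",
           provenance = syn),
      .fld("Methods", "Dataset",
           "Methods used to generate the biological materials in the dataset.",
           provenance = syn),
      .fld("technicalInfo", "Dataset",
           "Methods used to computationally process the data.",
           provenance = syn),
      .fld("Keywords", "Dataset",
           "Semicolon-separated keywords characterizing the dataset.",
           provenance = syn, datacite = "subjects"),
      .fld("Date", "Dataset",
           "Date relevant to the dataset (e.g. collection date), ISO 8601.",
           provenance = syn, datacite = "dates"),
      .fld("datasetVersion", "Dataset",
           "Version label of the dataset itself.",
           provenance = syn, datacite = "version"),
      .fld("Acknowledgement", "Dataset",
           "Acknowledgement of contributions not covered by Contributors or Funders.",
           provenance = syn)
    ),
    ## Image -- 33 fields (8 in the required table) ------------------------
    list(
      .fld("xAxis", "Image",
           "Predominant tissue direction moving from the left side of the image to the right side.",
           value_kind = "vocabulary", vocabulary = .vocab_axis,
           requirement = "required"),
      .fld("yAxis", "Image",
           "Predominant tissue direction moving from the top of the image to the bottom.",
           value_kind = "vocabulary", vocabulary = .vocab_axis,
           requirement = "required"),
      .fld("zAxis", "Image",
           "Predominant tissue direction following a pixel position through the stack from first image to last.",
           value_kind = "vocabulary", vocabulary = .vocab_axis,
           requirement = "required"),
      .fld("Number", "Image", "Label assigned to each channel.",
           requirement = "required", scope = "channel",
           ome = "Channel:ID"),
      .fld("displayColor", "Image",
           "Original display color for rendering each channel, as a (red, green, blue) triplet.",
           requirement = "required", scope = "channel",
           ome = "Channel:Color"),
      .fld("stepSizeX", "Image",
           "Physical size represented by one pixel in the X dimension.",
           value_kind = "number", requirement = "required",
           units = "microns per pixel", ome = "Pixels:PhysicalSizeX"),
      .fld("stepSizeY", "Image",
           "Physical size represented by one pixel in the Y dimension.",
           value_kind = "number", requirement = "required",
           units = "microns per pixel", ome = "Pixels:PhysicalSizeY"),
      .fld("stepSizeZ", "Image",
           "Distance between the centers of adjacent images in the Z dimension (spacing between slices).",
           value_kind = "number", requirement = "required",
           units = "microns", ome = "Pixels:PhysicalSizeZ"),
      .fld("stepSizeT", "Image",
           "Time increment between timepoints for time series.",
           value_kind = "number", units = "seconds",
           ome = "Pixels:TimeIncrement", provenance = syn),
      .fld("sizeX", "Image", "Number of pixels in the X dimension.",
           value_kind = "number", ome = "Pixels:SizeX", provenance = syn),
      .fld("sizeY", "Image", "Number of pixels in the Y dimension.",
           value_kind = "number", ome = "Pixels:SizeY", provenance = syn),
      .fld("sizeZ", "Image", "Number of pixels in the Z dimension.",
           value_kind = "number", ome = "Pixels:SizeZ", provenance = syn),
      .fld("numberOfFiles", "Image",
           "Number of files making up the dataset.",
           value_kind = "number", provenance = syn),
      .fld("numberOfTimepoints", "Image", "Number of timepoints.",
           value_kind = "number", ome = "Pixels:SizeT", provenance = syn),
      .fld("numberOfChannels", "Image", "Number of imaging channels.",
           value_kind = "number", ome = "Pixels:SizeC", provenance = syn),
      .fld("numberOfSlices", "Image", "Number of slices in the stack.",
           value_kind = "number", provenance = syn),
      .fld("bitDepth", "Image", "Significant bits per pixel sample.",
           value_kind = "number", ome = "Pixels:SignificantBits",
           provenance = syn),
      .fld("Fluorophore", "Image",
           "Fluorophore imaged in each channel.",
           scope = "channel", ome = "Channel:Fluor", provenance = syn),
      .fld("excitationWavelength", "Image",
           "Excitation wavelength of each channel.",
           value_kind = "number", scope = "channel", units = "nanometers",
           ome = "Channel:ExcitationWavelength", provenance = syn),
      .fld("emissionWavelength", "Image",
           "Emission wavelength of each channel.",
           value_kind = "number", scope = "channel", units = "nanometers",
           ome = "Channel:EmissionWavelength", provenance = syn),
      .fld("obliqueXDim1", "Image",
           "First anatomical direction component of an oblique X axis.",
           provenance = syn),
      .fld("obliqueXDim2", "Image",
           "Second anatomical direction component of an oblique X axis.",
           provenance = syn),
      .fld("obliqueXDim3", "Image",
           "Third anatomical direction component of an oblique X axis.",
           provenance = syn),
      .fld("obliqueYDim1", "Image",
           "First anatomical direction component of an oblique Y axis.",
           provenance = syn),
      .fld("obliqueYDim2", "Image",
           "Second anatomical direction component of an oblique Y axis.",
           provenance = syn),
      .fld("obliqueYDim3", "Image",
           "Third anatomical direction component of an oblique Y axis.",
           provenance = syn),
      .fld("obliqueZDim1", "Image",
           "First anatomical direction component of an oblique Z axis.",
           provenance = syn),
      .fld("obliqueZDim2", "Image",
           "Second anatomical direction component of an oblique Z axis.",
           provenance = syn),
      .fld("obliqueZDim3", "Image",
           "Third anatomical direction component of an oblique Z axis.",
           provenance = syn),
      .fld("landmarkName", "Image",
           "Name of an anatomical landmark visible in the image.",
           scope = "landmark", provenance = syn),
      .fld("landmarkX", "Image", "X pixel coordinate of the landmark.",
           value_kind = "number", scope = "landmark", provenance = syn),
      .fld("landmarkY", "Image", "Y pixel coordinate of the landmark.",
           value_kind = "number", scope = "landmark", provenance = syn),
      .fld("landmarkZ", "Image",
           "Z slice coordinate of the landmark.",
           value_kind = "number", scope = "landmark", provenance = syn)
    ),
    ## Instrument -- 12 fields (2 in the required table), all OME-mapped ---
    list(
      .fld("MicroscopeType", "Instrument",
           "Type of microscope used to capture the image (e.g. inverted, upright, light sheet, confocal, two photon).",
           suggested = .sugg_microscope_type, requirement = "required",
           ome = "Microscope:Type"),
      .fld("MicroscopeManufacturerAndModel", "Instrument",
           "Manufacturer and model of the microscope used.",
           requirement = "required", ome = "Microscope:Manufacturer/Model"),
      .fld("objectiveName", "Instrument",
           "Name or model of the objective used.",
           ome = "Objective:Model", provenance = syn),
      .fld("objectiveMagnification", "Instrument",
           "Nominal magnification of the objective.",
           value_kind = "number", ome = "Objective:NominalMagnification",
           provenance = syn),
      .fld("objectiveNA", "Instrument",
           "Numerical aperture of the objective.",
           value_kind = "number", ome = "Objective:LensNA",
           provenance = syn),
      .fld("objectiveImmersion", "Instrument",
           "Immersion medium of the objective.",
           suggested = .sugg_immersion, ome = "Objective:Immersion",
           provenance = syn),
      .fld("objectiveWorkingDistance", "Instrument",
           "Working distance of the objective.",
           value_kind = "number", units = "microns",
           ome = "Objective:WorkingDistance", provenance = syn),
      .fld("detectorType", "Instrument",
           "Type of detector used to capture the image.",
           suggested = .sugg_detector, ome = "Detector:Type",
           provenance = syn),
      .fld("detectorModel", "Instrument",
           "Manufacturer and model of the detector.",
           ome = "Detector:Model", provenance = syn),
      .fld("illuminationType", "Instrument",
           "Type of illumination used.",
           suggested = .sugg_illumination, ome = "Channel:IlluminationType",
           provenance = syn),
      .fld("illuminationWavelength", "Instrument",
           "Wavelength of the illumination source.",
           value_kind = "number", units = "nanometers",
           ome = "LightSource:Wavelength", provenance = syn),
      .fld("sampleTemperature", "Instrument",
           "Temperature of the sample during acquisition.",
           value_kind = "number", units = "degrees Celsius",
           ome = "ImagingEnvironment:Temperature", provenance = syn)
    ),
    ## Publication -- 5 fields, all optional, entry-scoped -----------------
    list(
      .fld("relatedIdentifier", "Publication",
           "Globally unique identifier of a publication, preprint or protocol related to the dataset.",
           scope = "entry", datacite = "relatedIdentifier",
           provenance = syn),
      .fld("relatedIdentifierType", "Publication",
           "Type of the related identifier.",
           value_kind = "vocabulary", vocabulary = .vocab_related_id_type,
           scope = "entry", datacite = "relatedIdentifierType",
           provenance = syn),
      .fld("relationType", "Publication",
           "Relationship of the publication, preprint or protocol to the dataset.",
           value_kind = "vocabulary", vocabulary = .vocab_relation_type,
           scope = "entry", datacite = "relationType", provenance = syn),
      .fld("PMCID", "Publication",
           "PubMed Central identifier of the related publication, if any.",
           scope = "entry", provenance = syn),
      .fld("Citation", "Publication",
           "Full citation of the related publication, preprint or protocol.",
           scope = "entry", provenance = syn)
    ),
    ## Specimen -- 12 fields (5 in the required table) ---------------------
    list(
      .fld("Species", "Specimen",
           "Common organism classification name of the donor organism (e.g. mouse, human).",
           requirement = "required"),
      .fld("NCBITaxonomy", "Specimen",
           "NCBI taxonomy code for the species of the donor organism.",
           requirement = "required"),
      .fld("Age", "Specimen",
           "Age of the donor, or the literal text \"unknown\".",
           value_kind = "number", requirement = "required"),
      .fld("Ageunit", "Specimen", "Unit for the age of the donor.",
           value_kind = "vocabulary", vocabulary = .vocab_ageunit,
           requirement = "required"),
      .fld("Sex", "Specimen", "Sex of the donor.",
           value_kind = "vocabulary", vocabulary = .vocab_sex,
           requirement = "required"),
      .fld("Genotype", "Specimen", "Genotype of the donor organism.",
           provenance = syn),
      .fld("Strain", "Specimen",
           "Strain of the donor organism (e.g. C57BL/6J).",
           provenance = syn),
      .fld("Organ", "Specimen", "Name of the organ sampled.",
           provenance = syn),
      .fld("OrganSubstructure", "Specimen",
           "Substructure of the organ sampled (e.g. hippocampus).",
           provenance = syn),
      .fld("Locations", "Specimen",
           "Location or region where the sample is found.",
           provenance = syn),
      .fld("Atlas", "Specimen",
           "Name of the atlas used to describe the location, if any.",
           provenance = syn),
      .fld("DonorID", "Specimen",
           "Local identifier of the donor organism.",
           provenance = syn)
    )
  )
}
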