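# Seed-reproducible synthetic records and ground-truth-labeled corrupted
# records, so the registry, validator, converters and crosswalks are all
# testable without any external data. One pseudo-random stream is derived
# per record from (master seed, record index), so corpus membership does
# not depend on generation order.

# word material for generated free text
.wl <- list(
  first = c("Ada", "Grace", "Santiago", "Mei", "Tomas", "Priya", "Lena",
            "Kwame", "Hana", "Diego", "Ingrid", "Yusuf"),
  last = c("Alvarez", "Chen", "Okafor", "Silva", "Novak", "Haddad",
           "Kim", "Fischer", "Tanaka", "Moreau", "Singh", "Larsen"),
  org = c("Institute for Brain Science", "Center for Neural Circuits",
          "Microscopy Core Facility", "Department of Neurobiology",
          "Laboratory of Systems Neuroscience"),
  agency = c("National Institutes of Health", "National Science Foundation",
             "European Research Council", "Wellcome Trust",
             "Japan Science and Technology Agency"),
  noun = c("cortex", "hippocampus", "cerebellum", "thalamus", "striatum",
           "amygdala", "retina", "olfactory bulb", "spinal cord",
           "brainstem"),
  adj = c("cleared", "labeled", "whole", "developing", "adult", "sparse",
          "dense", "bilateral", "serial", "registered"),
  lorem = c("the", "dataset", "comprises", "volumetric", "images",
            "acquired", "from", "fluorescently", "labeled", "tissue",
            "after", "clearing", "and", "staining", "to", "resolve",
            "cell", "types", "their", "morphology", "projection",
            "patterns", "across", "regions", "of", "interest", "using",
            "high", "resolution", "optical", "sectioning", "with",
            "isotropic", "sampling", "for", "quantitative", "analysis"),
  fluor = c("GFP", "tdTomato", "DAPI", "Alexa Fluor 488", "mCherry",
            "YFP", "Cy5"),
  scope_model = c("Zeiss Lightsheet Z.1", "Olympus FV3000",
                  "Leica SP8", "LifeCanvas SmartSPIM",
                  "Nikon AX R", "Bruker Ultima 2P"),
  detector_model = c("Hamamatsu ORCA-Flash4.0", "Andor Zyla 4.2",
                     "Photometrics Prime BSI", "Hamamatsu H7422"),
  landmark = c("bregma", "lambda", "anterior commissure",
               "corpus callosum midline", "fourth ventricle"),
  license = list(
    list(name = "Creative Commons Attribution 4.0 International",
         uri = "https://creativecommons.org/licenses/by/4.0/",
         spdx = "CC-BY-4.0"),
    list(name = "Creative Commons Zero v1.0 Universal",
         uri = "https://creativecommons.org/publicdomain/zero/1.0/",
         spdx = "CC0-1.0"),
    list(name = "Creative Commons Attribution Share Alike 4.0",
         uri = "https://creativecommons.org/licenses/by-sa/4.0/",
         spdx = "CC-BY-SA-4.0")
  ),
  species = list(
    list(species = "mouse", taxon = "10090"),
    list(species = "human", taxon = "9606"),
    list(species = "rat", taxon = "10116"),
    list(species = "zebrafish", taxon = "7955"),
    list(species = "fruit fly", taxon = "7227")
  )
)

# run code under a seed without disturbing the caller's RNG state
local_seed <- function(seed, code) {
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE))
    get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE))
        rm(".Random.seed", envir = genv)
    } else assign(".Random.seed", old, envir = genv)
  })
  set.seed(seed)
  force(code)
}

# per-record stream seed; kept below 2^31
derive_seed <- function(master, index, salt = 0L) {
  (as.numeric(master) * 1000003 + index * 7919 + salt * 104729) %%
    2147483647
}

pick <- function(x, n = 1L) {
  if (length(x) == 1L) return(rep(x, n)[seq_len(n)])
  x[sample.int(length(x), n, replace = n > length(x))]
}

maybe <- function(p) stats::runif(1) < p

words <- function(n, pool = .wl$lorem) {
  paste(pick(pool, n), collapse = " ")
}

gen_orcid <- function() {
  digits <- sample(0:9, 15, replace = TRUE)
  chk <- iso7064_mod11_2_check(digits)
  grp <- function(i) paste(digits[i], collapse = "")
  paste0(grp(1:4), "-", grp(5:8), "-", grp(9:12), "-", grp(13:15), chk)
}

gen_ror <- function() {
  paste0("0", paste(sample(c(letters, 0:9), 8, replace = TRUE),
                    collapse = ""))
}

#' Configuration for the synthetic record generator
#'
#' Ranges are inclusive `(min, max)` pairs; a record draws each count
#' uniformly from its range. Defaults emulate a typical light-microscopy
#' repository submission: a small lab author list, government funding
#' declared (so the Funders category applies), one to four imaging
#' channels, and an abstract of at least 100 words as the standard
#' recommends.
#'
#' @param seed Master seed for reproducibility.
#' @param n_contributors,n_funders,n_channels,n_publications Count
#'   ranges.
#' @param optional_fill_probability Probability that each optional field
#'   is populated.
#' @param funding_declared Whether generated records declare government
#'   funding.
#' @param abstract_words Length of the generated abstract, in words.
#' @return A `mms_generator_config` list.
#' @export
generator_config <- function(seed = 1L,
                             n_contributors = c(1L, 4L),
                             n_funders = c(1L, 3L),
                             n_channels = c(1L, 4L),
                             n_publications = c(0L, 3L),
                             optional_fill_probability = 0.5,
                             funding_declared = TRUE,
                             abstract_words = 105L) {
  norm_range <- function(r) {
    r <- as.integer(r)
    if (length(r) == 1L) r <- c(r, r)
    stopifnot(length(r) == 2L, r[1] <= r[2], r[1] >= 0L)
    r
  }
  stopifnot(is.numeric(optional_fill_probability),
            optional_fill_probability >= 0,
            optional_fill_probability <= 1)
  structure(list(seed = as.integer(seed),
                 n_contributors = norm_range(n_contributors),
                 n_funders = norm_range(n_funders),
                 n_channels = norm_range(n_channels),
                 n_publications = norm_range(n_publications),
                 optional_fill_probability = optional_fill_probability,
                 funding_declared = isTRUE(funding_declared),
                 abstract_words = as.integer(abstract_words)),
            class = "mms_generator_config")
}

range_draw <- function(r) {
  if (r[1] == r[2]) return(r[1])
  sample(seq.int(r[1], r[2]), 1L)
}

#' Generate one valid synthetic metadata record
#'
#' The generated record passes [validate_record()] under profile `bil`
#' with zero errors for every seed: vocabulary fields are drawn from the
#' registry vocabularies, ORCID/ROR identifiers are built with correct
#' syntax (ORCIDs carry a correct ISO 7064 mod 11-2 check digit), step
#' sizes are drawn log-uniformly from a positive range, and all required
#' fields are populated. The same seed yields an identical record.
#'
#' @param config A `mms_generator_config` (see [generator_config()]).
#' @param registry An `mms_registry`.
#' @return An `mms_record`.
#' @export
generate_valid_record <- function(config = generator_config(),
                                  registry = build_default_registry()) {
  stopifnot(inherits(config, "mms_generator_config"))
  local_seed(config$seed, generate_record_impl(config, registry))
}

generate_record_impl <- function(config, registry) {
  p <- config$optional_fill_probability
  vocab <- function(cat_, name) get_field(registry, name, cat_)$vocabulary[[1]]
  rec <- empty_record(config$funding_declared)

  ## contributors
  n <- range_draw(config$n_contributors)
  rec$Contributors <- lapply(seq_len(n), function(i) {
    personal <- i == 1L || maybe(0.7)
    e <- list()
    if (personal) {
      e$contributorName <- paste0(pick(.wl$last), ", ", pick(.wl$first))
      e$nameType <- "Personal"
      e$nameIdentifier <- gen_orcid()
      e$nameIdentifierScheme <- "ORCID"
    } else {
      e$contributorName <- pick(.wl$org)
      e$nameType <- "Organizational"
      if (maybe(p)) {
        e$nameIdentifier <- gen_ror()
        e$nameIdentifierScheme <- "ROR"
      }
    }
    e$Creator <- i == 1L || maybe(0.4)
    e$contributorType <- if (i == 1L) "ProjectLeader"
      else pick(vocab("Contributors", "contributorType"))
    e$affiliation <- pick(.wl$org)
    e$affiliationIdentifier <- gen_ror()
    e$affiliationIdentifierScheme <- "ROR"
    e
  })

  ## funders
  n <- range_draw(config$n_funders)
  if (config$funding_declared) n <- max(1L, n)
  rec$Funders <- lapply(seq_len(n), function(i) {
    list(funderName = pick(.wl$agency),
         fundingReferenceIdentifier = gen_ror(),
         fundingReferenceIdentifierType = "ROR",
         awardNumber = sprintf("R01%s%06d", paste(pick(LETTERS, 2),
                                                  collapse = ""),
                               sample.int(999999, 1)),
         awardTitle = paste("Mapping", words(3, .wl$noun), "circuits"))
  })

  ## dataset
  lic <- .wl$license[[sample.int(length(.wl$license), 1)]]
  ds <- list(
    Title = paste("A", pick(.wl$adj), "3D image volume of the",
                  pick(.wl$noun)),
    Rights = lic$name, rightsURI = lic$uri, rightsIdentifier = lic$spdx,
    Abstract = words(config$abstract_words)
  )
  if (maybe(p)) ds$generalModality <-
    pick(get_field(registry, "generalModality")$suggested_values[[1]])
  if (maybe(p)) ds$technique <-
    pick(get_field(registry, "technique")$suggested_values[[1]])
  if (maybe(p)) ds$Methods <- words(12)
  if (maybe(p)) ds$technicalInfo <- words(10)
  if (maybe(p)) ds$Keywords <- paste(pick(.wl$noun, 3), collapse = "; ")
  if (maybe(p)) ds$Date <- sprintf("20%02d-%02d-%02d", sample(18:24, 1),
                                   sample(1:12, 1), sample(1:28, 1))
  if (maybe(p)) ds$datasetVersion <- sprintf("%d.%d", sample(1:3, 1),
                                             sample(0:9, 1))
  if (maybe(p)) ds$Acknowledgement <- paste("We thank the",
                                            pick(.wl$org))
  rec$Dataset <- ds

  ## image
  axis_vocab <- vocab("Image", "xAxis")
  img <- list(
    xAxis = pick(axis_vocab), yAxis = pick(axis_vocab),
    zAxis = pick(axis_vocab),
    stepSizeX = signif(exp(stats::runif(1, log(0.1), log(10))), 4),
    stepSizeY = signif(exp(stats::runif(1, log(0.1), log(10))), 4),
    stepSizeZ = signif(exp(stats::runif(1, log(0.2), log(50))), 4)
  )
  n_ch <- range_draw(config$n_channels)
  if (maybe(p)) {
    img$sizeX <- sample(512:4096, 1)
    img$sizeY <- sample(512:4096, 1)
    img$sizeZ <- sample(100:3000, 1)
  }
  if (maybe(p)) img$numberOfFiles <- sample(1:5000, 1)
  if (maybe(p)) img$numberOfTimepoints <- 1
  if (maybe(p)) img$numberOfChannels <- n_ch
  if (maybe(p)) img$numberOfSlices <- sample(100:3000, 1)
  if (maybe(p)) img$bitDepth <- pick(c(8, 12, 16))
  if (maybe(p)) img$stepSizeT <- signif(stats::runif(1, 0.5, 60), 3)
  img$Channels <- lapply(seq_len(n_ch), function(i) {
    ch <- list(Number = as.character(i),
               displayColor = as.integer(sample(0:255, 3, replace = TRUE)))
    if (maybe(p)) ch$Fluorophore <- pick(.wl$fluor)
    if (maybe(p)) ch$excitationWavelength <- sample(380:650, 1)
    if (maybe(p)) ch$emissionWavelength <- sample(420:750, 1)
    ch
  })
  n_lm <- if (maybe(p)) sample(0:2, 1) else 0L
  img$Landmarks <- lapply(seq_len(n_lm), function(i)
    list(landmarkName = pick(.wl$landmark),
         landmarkX = sample(1:4096, 1), landmarkY = sample(1:4096, 1),
         landmarkZ = sample(1:3000, 1)))
  rec$Image <- img

  ## instrument
  ins <- list(
    MicroscopeType = pick(get_field(registry,
                                    "MicroscopeType")$suggested_values[[1]]),
    MicroscopeManufacturerAndModel = pick(.wl$scope_model)
  )
  if (maybe(p)) ins$objectiveName <- sprintf("Plan-Apochromat %dx",
                                             pick(c(4, 10, 20, 40)))
  if (maybe(p)) ins$objectiveMagnification <- pick(c(4, 10, 20, 40, 63))
  if (maybe(p)) ins$objectiveNA <- signif(stats::runif(1, 0.3, 1.4), 2)
  if (maybe(p)) ins$objectiveImmersion <-
    pick(get_field(registry, "objectiveImmersion")$suggested_values[[1]])
  if (maybe(p)) ins$objectiveWorkingDistance <-
    signif(stats::runif(1, 100, 6000), 3)
  if (maybe(p)) ins$detectorType <-
    pick(get_field(registry, "detectorType")$suggested_values[[1]])
  if (maybe(p)) ins$detectorModel <- pick(.wl$detector_model)
  if (maybe(p)) ins$illuminationType <-
    pick(get_field(registry, "illuminationType")$suggested_values[[1]])
  if (maybe(p)) ins$illuminationWavelength <- sample(380:650, 1)
  if (maybe(p)) ins$sampleTemperature <- signif(stats::runif(1, 18, 37), 3)
  rec$Instrument <- ins

  ## publications
  n_pub <- range_draw(config$n_publications)
  rec$Publication <- lapply(seq_len(n_pub), function(i) {
    e <- list(relatedIdentifier = sprintf("10.%04d/mms.%05d",
                                          sample.int(9999, 1),
                                          sample.int(99999, 1)),
              relatedIdentifierType = "DOI",
              relationType = pick(vocab("Publication", "relationType")))
    if (maybe(p)) e$PMCID <- sprintf("PMC%07d", sample.int(9999999, 1))
    if (maybe(p)) e$Citation <- paste0(pick(.wl$last), " et al. (20",
                                       sample(18:24, 1), ")")
    e
  })

  ## specimen
  sp <- .wl$species[[sample.int(length(.wl$species), 1)]]
  spec <- list(Species = sp$species, NCBITaxonomy = sp$taxon,
               Age = if (maybe(0.1)) "unknown"
                     else signif(stats::runif(1, 0.2, 30), 3),
               Ageunit = pick(vocab("Specimen", "Ageunit")),
               Sex = pick(vocab("Specimen", "Sex")))
  if (maybe(p)) spec$Genotype <- pick(c("wild type", "Thy1-GFP",
                                        "PV-Cre;Ai14", "5xFAD"))
  if (maybe(p)) spec$Strain <- pick(c("C57BL/6J", "CD-1", "BALB/c"))
  if (maybe(p)) spec$Organ <- "brain"
  if (maybe(p)) spec$OrganSubstructure <- pick(.wl$noun)
  if (maybe(p)) spec$Locations <- pick(.wl$noun)
  if (maybe(p)) spec$Atlas <- pick(c("Allen CCFv3", "Paxinos and Franklin",
                                     "Waxholm Space"))
  if (maybe(p)) spec$DonorID <- sprintf("donor-%04d", sample.int(9999, 1))
  rec$Specimen <- spec
  rec
}

# ---- fault injection --------------------------------------------------------

# break an ORCID's check character (any change away from the unique
# correct character invalidates it)
break_check_char <- function(orcid) {
  last <- substr(orcid, nchar(orcid), nchar(orcid))
  bad <- if (last == "X") "0"
         else as.character((as.integer(last) + 1L) %% 10L)
  paste0(substr(orcid, 1L, nchar(orcid) - 1L), bad)
}

# corruption recipes: each returns list(record=, path=, description=)
fault_recipes <- function() {
  list(
    REQUIRED_MISSING = function(rec) {
      candidates <- list(c("Dataset", "Title"), c("Dataset", "Rights"),
                         c("Dataset", "Abstract"),
                         c("Instrument", "MicroscopeType"),
                         c("Instrument", "MicroscopeManufacturerAndModel"),
                         c("Specimen", "Species"), c("Image", "xAxis"),
                         c("Image", "yAxis"), c("Image", "zAxis"))
      tgt <- candidates[[sample.int(length(candidates), 1)]]
      rec[[tgt[1]]][[tgt[2]]] <- NULL
      list(record = rec, path = paste(tgt, collapse = "."),
           description = sprintf("deleted required field %s", tgt[2]))
    },
    COND_FUNDERS = function(rec) {
      rec$funding_declared <- TRUE
      if (length(rec$Funders) == 0L)
        return(list(record = rec, path = "Funders",
                    description = "funding declared with no funder entries"))
      rec$Funders[[1]]$awardNumber <- NULL
      list(record = rec, path = "Funders[1].awardNumber",
           description = "removed awardNumber from a funder entry")
    },
    COND_PERSONAL_ID = function(rec) {
      if (length(rec$Contributors) == 0L)
        rec$Contributors <- list(list(contributorName = "Doe, Jo",
                                      Creator = TRUE,
                                      contributorType = "Researcher"))
      rec$Contributors[[1]]$nameType <- "Personal"
      rec$Contributors[[1]]$nameIdentifier <- NULL
      rec$Contributors[[1]]$nameIdentifierScheme <- NULL
      list(record = rec, path = "Contributors[1].nameIdentifier",
           description = "stripped identifiers from a Personal contributor")
    },
    NO_CREATOR = function(rec) {
      for (i in seq_along(rec$Contributors))
        rec$Contributors[[i]]$Creator <- FALSE
      list(record = rec, path = "Contributors",
           description = "cleared every creator flag")
    },
    VOCAB_VIOLATION = function(rec) {
      rec$Specimen$Sex <- "Hermaphrodite"
      list(record = rec, path = "Specimen.Sex",
           description = "out-of-vocabulary Sex value")
    },
    COLOR_FORMAT = function(rec) {
      bad <- if (maybe(0.5)) "999,0,0" else "crimson"
      if (length(rec$Image$Channels) == 0L)
        rec$Image$Channels <- list(list(Number = "1"))
      rec$Image$Channels[[1]]$displayColor <- bad
      list(record = rec, path = "Image.Channels[1].displayColor",
           description = "malformed display color triplet")
    },
    STEP_NONPOSITIVE = function(rec) {
      rec$Image$stepSizeX <- -abs(
        if (is.numeric(rec$Image$stepSizeX)) rec$Image$stepSizeX else 1)
      list(record = rec, path = "Image.stepSizeX",
           description = "non-positive step size")
    },
    AGE_NEGATIVE = function(rec) {
      rec$Specimen$Age <- -sample(1:20, 1)
      list(record = rec, path = "Specimen.Age",
           description = "negative donor age")
    },
    TAXON_SYNTAX = function(rec) {
      rec$Specimen$NCBITaxonomy <- "NCBI:10090"
      list(record = rec, path = "Specimen.NCBITaxonomy",
           description = "taxonomy code with non-digit characters")
    },
    ID_SYNTAX = function(rec) {
      if (length(rec$Contributors) == 0L)
        rec$Contributors <- list(list(contributorName = "Doe, Jo",
                                      Creator = TRUE))
      rec$Contributors[[1]]$affiliationIdentifierScheme <- "ORCID"
      rec$Contributors[[1]]$affiliationIdentifier <-
        break_check_char(gen_orcid())
      list(record = rec, path = "Contributors[1].affiliationIdentifier",
           description = "identifier with a broken ISO 7064 check digit")
    },
    SPDX_HINT = function(rec) {
      rec$Dataset$rightsIdentifier <- "our lab's own license!!"
      list(record = rec, path = "Dataset.rightsIdentifier",
           description = "rightsIdentifier not shaped like an SPDX token")
    },
    SUGGESTED_VALUE_MISS = function(rec) {
      rec$Dataset$generalModality <- "levitation imaging"
      list(record = rec, path = "Dataset.generalModality",
           description = "modality outside the suggested-value list")
    },
    CARDINALITY = function(rec) {
      rec$Dataset$Keywords <- c("cortex; atlas", "second keyword block")
      list(record = rec, path = "Dataset.Keywords",
           description = "two values in a single-occurrence field")
    },
    CHANNEL_MISMATCH = function(rec) {
      if (length(rec$Image$Channels) == 0L)
        rec$Image$Channels <- list(list(displayColor = c(255L, 0L, 0L)))
      rec$Image$Channels[[1]]$Number <- NULL
      list(record = rec, path = "Image.Channels[1]",
           description = "channel without a Number")
    }
  )
}

#' Inject labeled faults into a record
#'
#' Applies one corruption recipe per requested rule code and returns the
#' corrupted copy together with one ground-truth fault label per applied
#' recipe (path, code, description). The original record is untouched.
#' Recipes target disjoint fields so that multiple injected faults stay
#' independently detectable.
#'
#' @param record An `mms_record`.
#' @param codes Character vector of rule codes (see [fault_codes()]).
#' @param seed Seed controlling the recipes' random choices.
#' @return List with `record` (corrupted copy) and `labels` (tibble with
#'   columns path, code, description).
#' @export
inject_errors <- function(record, codes, seed = 1L) {
  stopifnot(inherits(record, "mms_record"), is.character(codes) ||
              length(codes) == 0L)
  recipes <- fault_recipes()
  unknown <- setdiff(codes, names(recipes))
  if (length(unknown) > 0L)
    stop("no corruption recipe for code(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  labels <- tibble::tibble(path = character(), code = character(),
                           description = character())
  local_seed(seed, {
    for (code in codes) {
      res <- recipes[[code]](record)
      record <- res$record
      labels <- tibble::add_row(labels, path = res$path, code = code,
                                description = res$description)
    }
  })
  list(record = record, labels = labels)
}

#' Generate a corpus of records with optional fault injection
#'
#' Generates `n` records; each is independently corrupted with
#' probability `fault_rate` using one to three randomly chosen recipes.
#' The corpus is fully reproducible from `(n, config$seed, fault_rate)`,
#' and each record has its own derived stream, so the i-th record does
#' not depend on how many records precede it.
#'
#' @param n Number of records.
#' @param config A `mms_generator_config`; its `seed` is the master seed.
#' @param fault_rate Probability in `[0, 1]` that a record is corrupted.
#' @param registry An `mms_registry`.
#' @return A list of `n` elements, each a list with `record` and
#'   `labels` (empty tibble for clean records).
#' @export
generate_corpus <- function(n, config = generator_config(),
                            fault_rate = 0,
                            registry = build_default_registry()) {
  stopifnot(n > 0, fault_rate >= 0, fault_rate <= 1)
  lapply(seq_len(n), function(i) {
    cfg_i <- config
    cfg_i$seed <- derive_seed(config$seed, i)
    rec <- generate_valid_record(cfg_i, registry)
    corrupt <- local_seed(derive_seed(config$seed, i, salt = 1L),
                          stats::runif(1) < fault_rate)
    if (!corrupt)
      return(list(record = rec,
                  labels = tibble::tibble(path = character(),
                                          code = character(),
                                          description = character())))
    local_seed(derive_seed(config$seed, i, salt = 2L), {
      k <- sample.int(3L, 1L)
      codes <- sample(names(fault_recipes()), k)
      inj_seed <- sample.int(2147483646L, 1L)
    })
    inject_errors(rec, codes, seed = inj_seed)
  })
}
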