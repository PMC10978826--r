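#' @import methods
NULL

#' Biogeographic region labels
#'
#' The seven biogeographic regions used to aggregate countries:
#' Afrotropical, Australian, Nearctic, Neotropical, Oceanian, Oriental and
#' Palearctic. Every country in a [TaxonCatalogue] region map must carry one
#' of these labels.
#'
#' @return A character vector of length 7.
#' @examples
#' biogeographicRegions()
#' @export
biogeographicRegions <- function() {
    c("Afrotropical", "Australian", "Nearctic", "Neotropical",
      "Oceanian", "Oriental", "Palearctic")
}

#' TaxonCatalogue: an authoritative species checklist
#'
#' Holds the universe of valid species names together with their per-species
#' country distributions, medical-importance flags, and a country-to-region
#' map. The catalogue defines which record species names are valid, which
#' countries exist, and which species are endemic (a species whose full
#' catalogue distribution is a single country).
#'
#' @slot species character vector of unique verbatim binomials.
#' @slot countriesOf named list; for each species, the character vector of
#'   countries where the catalogue reports it.
#' @slot medical named logical; medical-importance flag per species.
#' @slot regionMap named character; biogeographic region label per country.
#'
#' @seealso [readTaxonCatalogue()], [countrySummary()]
#' @export
setClass("TaxonCatalogue",
    representation(
        species = "character",
        countriesOf = "list",
        medical = "logical",
        regionMap = "character"
    )
)

setValidity("TaxonCatalogue", function(object) {
    msg <- character()
    sp <- object@species
    if (anyDuplicated(sp))
        msg <- c(msg, "species names must be unique")
    if (!identical(sort(names(object@countriesOf)), sort(sp)))
        msg <- c(msg, "countriesOf must be named by exactly the species set")
    if (!identical(sort(names(object@medical)), sort(sp)))
        msg <- c(msg, "medical must be named by exactly the species set")
    nc <- lengths(object@countriesOf)
    if (any(nc < 1L))
        msg <- c(msg, "every species must have at least one country")
    ctry <- unique(unlist(object@countriesOf, use.names = FALSE))
    if (!all(ctry %in% names(object@regionMap)))
        msg <- c(msg, "every country referenced by a species must appear in the region map")
    if (!all(object@regionMap %in% biogeographicRegions()))
        msg <- c(msg, sprintf(
            "unknown region label(s): %s",
            paste(setdiff(unique(object@regionMap), biogeographicRegions()),
                  collapse = ", ")))
    if (length(msg)) msg else TRUE
})

#' BarcodeRecordSet: specimen/sequence records
#'
#' A validated container for DNA barcode records from a BOLD-style
#' specimen+sequence dump or a GenBank-style FASTA. One row per record;
#' missing fields are `NA`. Sequences, when present, contain only IUPAC
#' nucleotide codes with alignment gaps/hyphens stripped at construction.
#'
#' @slot records data.frame with columns `record_id`, `source`, `accession`,
#'   `species_name`, `marker`, `sequence`, `country`, `latitude`,
#'   `longitude`, `definition`, `parsed`.
#' @seealso [readBoldRecords()], [readGenbankRecords()], [curateRecords()]
#' @export
setClass("BarcodeRecordSet", representation(records = "data.frame"))

.RECORD_COLS <- c(record_id = "character", source = "character",
                  accession = "character", species_name = "character",
                  marker = "character", sequence = "character",
                  country = "character", latitude = "numeric",
                  longitude = "numeric", definition = "character",
                  parsed = "logical")

setValidity("BarcodeRecordSet", function(object) {
    df <- object@records
    msg <- character()
    missing_cols <- setdiff(names(.RECORD_COLS), names(df))
    if (length(missing_cols))
        return(sprintf("missing record columns: %s",
                       paste(missing_cols, collapse = ", ")))
    if (anyNA(df$record_id))
        msg <- c(msg, "record_id must not be NA")
    seqs <- df$sequence[!is.na(df$sequence)]
    if (length(seqs)) {
        iupac <- paste0("^[", paste(names(Biostrings::IUPAC_CODE_MAP),
                                    collapse = ""), "]*$")
        bad <- !grepl(iupac, toupper(seqs))
        if (any(bad))
            msg <- c(msg, sprintf(
                "%d sequence(s) contain non-IUPAC characters", sum(bad)))
    }
    if (length(msg)) msg else TRUE
})

#' CurationReport: stage-by-stage accounting of a filter chain
#'
#' Records, for every curation stage, the rows entering, removed and
#' surviving, plus the distinct species surviving, and the list of species
#' excluded outright with the reason.
#'
#' @slot stages data.frame with columns `stage`, `rows_in`, `rows_removed`,
#'   `rows_out`, `species_out`.
#' @slot excluded data.frame with columns `species`, `reason`.
#' @seealso [curateRecords()]
#' @export
setClass("CurationReport",
    representation(stages = "data.frame", excluded = "data.frame"))

setValidity("CurationReport", function(object) {
    st <- object@stages
    msg <- character()
    need <- c("stage", "rows_in", "rows_removed", "rows_out", "species_out")
    if (!all(need %in% names(st)))
        return("stages must have columns stage, rows_in, rows_removed, rows_out, species_out")
    if (nrow(st)) {
        if (any(st$rows_in < 0 | st$rows_removed < 0 | st$rows_out < 0))
            msg <- c(msg, "stage counts must be non-negative")
        if (any(st$rows_in != st$rows_removed + st$rows_out))
            msg <- c(msg, "rows_in must equal rows_removed + rows_out at every stage")
        if (nrow(st) > 1 &&
            any(st$rows_out[-nrow(st)] != st$rows_in[-1]))
            msg <- c(msg, "rows_out of each stage must equal rows_in of the next")
    }
    if (length(msg)) msg else TRUE
})

#' BinomialGlmFit: a fitted binomial regression
#'
#' Wraps a logit-link binomial GLM fit with the derived quantities used in
#' reference-library audits: Wald standard errors, odds ratios `exp(beta)`
#' with 95% Wald intervals `exp(beta +/- 1.96 SE)`, the log-likelihood, the
#' parameter count `k` and `AIC = -2 logLik + 2k`.
#'
#' @slot coefficients named numeric vector of coefficients (log-odds scale).
#' @slot se named numeric vector of Wald standard errors.
#' @slot oddsRatios named numeric, `exp(coefficients)`.
#' @slot ciLower,ciUpper named numeric, 95% Wald CI bounds on the odds-ratio
#'   scale.
#' @slot pValues named numeric Wald p-values.
#' @slot logLik numeric scalar.
#' @slot k integer, number of estimated parameters.
#' @slot aic numeric scalar.
#' @slot converged logical.
#' @slot diagnostics character, convergence/separation notes (may be empty).
#' @slot transform list recording any predictor transform applied upstream.
#' @slot fit the underlying fit object (`glm` or `merMod`).
#' @seealso [fitBinomialGlm()], [fitBinomialGlmm()]
#' @export
setClass("BinomialGlmFit",
    representation(
        coefficients = "numeric", se = "numeric", oddsRatios = "numeric",
        ciLower = "numeric", ciUpper = "numeric", pValues = "numeric",
        logLik = "numeric", k = "integer", aic = "numeric",
        converged = "logical", diagnostics = "character",
        transform = "list", fit = "ANY"
    )
)

setValidity("BinomialGlmFit", function(object) {
    msg <- character()
    if (abs(object@aic - (-2 * object@logLik + 2 * object@k)) > 1e-6)
        msg <- c(msg, "aic must equal -2*logLik + 2*k")
    if (any(object@oddsRatios <= 0, na.rm = TRUE))
        msg <- c(msg, "odds ratios must be strictly positive")
    if (length(msg)) msg else TRUE
})

#' BinomialGlmmFit: a fitted random-intercept binomial GLMM
#'
#' Extends [BinomialGlmFit-class] with the random-intercept variance and the
#' grouping labels. The AIC counts the random-effect variance as one
#' estimated parameter.
#'
#' @slot sigmaGroup numeric, random-intercept variance (sigma^2, >= 0).
#' @slot groups character, levels of the grouping factor.
#' @slot boundary logical, TRUE when the variance estimate hit the zero
#'   boundary.
#' @seealso [fitBinomialGlmm()]
#' @export
setClass("BinomialGlmmFit", contains = "BinomialGlmFit",
    representation(sigmaGroup = "numeric", groups = "character",
                   boundary = "logical"))

setValidity("BinomialGlmmFit", function(object) {
    if (object@sigmaGroup < 0) "sigmaGroup must be >= 0" else TRUE
})

#' ModelSelectionTable: ranked all-subsets AIC table
#'
#' One row per additive predictor subset (the intercept-only model
#' included), ranked by AIC. `delta_aic` is the difference from the best
#' converged model and models with `delta_aic < 2` are flagged as equally
#' plausible.
#'
#' @slot table data.frame with columns `model`, `n_predictors`, `k`, `aic`,
#'   `delta_aic`, `plausible`, `converged`.
#' @slot best character, formula-like label of the best converged model.
#' @slot fits list of the underlying [BinomialGlmFit-class] objects, named
#'   as in `table$model`.
#' @seealso [selectModels()]
#' @export
setClass("ModelSelectionTable",
    representation(table = "data.frame", best = "character", fits = "list"))

setValidity("ModelSelectionTable", function(object) {
    tb <- object@table
    msg <- character()
    ok <- tb$converged
    if (any(ok) && abs(min(tb$delta_aic[ok])) > 1e-9)
        msg <- c(msg, "minimum delta_aic over converged models must be 0")
    if (any(ok) && !identical(tb$plausible[ok], tb$delta_aic[ok] < 2))
        msg <- c(msg, "plausible must mean delta_aic < 2")
    if (length(msg)) msg else TRUE
})

#' SimulationConfig: parameters of the synthetic-data generator
#'
#' Everything the generator needs to produce a catalogue, barcode sequences
#' and a record table with known ground truth. All outputs are a
#' deterministic function of the config (seed included).
#'
#' @slot seed integer seed; mandatory, all outputs reproducible from it.
#' @slot nSpecies,nCountries,nRegions integer dimensions of the synthetic
#'   world (nRegions at most 7, one per biogeographic region label).
#' @slot endemicFrac numeric in `[0,1]`; fraction of species whose full
#'   distribution is one country.
#' @slot medicalFrac numeric in `[0,1]`; fraction flagged medically
#'   important.
#' @slot sequenceLength integer, barcode length in bases (default 658, the
#'   standard COI-5P barcode).
#' @slot intraDivergence expected substitutions/site between a sequence and
#'   its species centroid; in `[0, 0.75)`.
#' @slot interDivergence expected substitutions/site between a species
#'   centroid and the shared root; in `[0, 0.75)`.
#' @slot seqsPerSpecies list with elements `dist` ("fixed" or "geometric")
#'   and `mean`, the per-species (or per species-country pair) sequence
#'   count distribution.
#' @slot coverageBetas numeric; true coefficients (intercept first) of the
#'   logistic record-inclusion model used by [simulateRecords()].
#' @slot groupSigma numeric >= 0; SD of the between-region random intercept.
#' @slot defectRate numeric in `[0,1]`; fraction of record rows receiving an
#'   injected curation defect.
#' @slot marker character, marker code stamped on clean records.
#' @seealso [simulationConfig()], [simulateCatalogue()],
#'   [simulateBarcodes()], [simulateRecords()]
#' @export
setClass("SimulationConfig",
    representation(
        seed = "integer", nSpecies = "integer", nCountries = "integer",
        nRegions = "integer", endemicFrac = "numeric",
        medicalFrac = "numeric", sequenceLength = "integer",
        intraDivergence = "numeric", interDivergence = "numeric",
        seqsPerSpecies = "list", coverageBetas = "numeric",
        groupSigma = "numeric", defectRate = "numeric", marker = "character"
    )
)

setValidity("SimulationConfig", function(object) {
    msg <- character()
    if (length(object@seed) != 1L || is.na(object@seed))
        msg <- c(msg, "seed is mandatory")
    frac_ok <- function(x) length(x) == 1L && !is.na(x) && x >= 0 && x <= 1
    if (!frac_ok(object@endemicFrac))
        msg <- c(msg, "endemicFrac must be in [0,1]")
    if (!frac_ok(object@medicalFrac))
        msg <- c(msg, "medicalFrac must be in [0,1]")
    if (!frac_ok(object@defectRate))
        msg <- c(msg, "defectRate must be in [0,1]")
    div_ok <- function(x) length(x) == 1L && !is.na(x) && x >= 0 && x < 0.75
    if (!div_ok(object@intraDivergence))
        msg <- c(msg, "intraDivergence must be in [0, 0.75)")
    if (!div_ok(object@interDivergence))
        msg <- c(msg, "interDivergence must be in [0, 0.75)")
    if (object@nCountries < 2L && object@endemicFrac < 1)
        msg <- c(msg, "need at least 2 countries unless endemicFrac == 1")
    if (object@nRegions < 1L || object@nRegions > 7L)
        msg <- c(msg, "nRegions must be between 1 and 7")
    if (!object@seqsPerSpecies$dist %in% c("fixed", "geometric"))
        msg <- c(msg, "seqsPerSpecies$dist must be 'fixed' or 'geometric'")
    if (object@seqsPerSpecies$mean < 1)
        msg <- c(msg, "seqsPerSpecies$mean must be >= 1")
    if (object@groupSigma < 0)
        msg <- c(msg, "groupSigma must be >= 0")
    if (length(object@coverageBetas) < 1L)
        msg <- c(msg, "coverageBetas needs at least an intercept")
    if (length(msg)) msg else TRUE
})
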