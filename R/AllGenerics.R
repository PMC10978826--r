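#' @include AllClasses.R
NULL

#' Accessors for TaxonCatalogue
#'
#' `speciesNames()` and `countryNames()` return the species and country
#' universes; `nSpecies()`/`nCountries()` their sizes. `countriesOf()`
#' returns the catalogue distribution of one or more species,
#' `regionOf()` maps countries to biogeographic regions, `isEndemic()`
#' flags species whose full distribution is a single country and
#' `isMedical()` returns the medical-importance flag.
#'
#' @param x A [TaxonCatalogue-class].
#' @param species Character vector of species names (default: all).
#' @param country Character vector of country names (default: all).
#' @return See the individual descriptions; vectors are named by species or
#'   country where applicable.
#' @name catalogue-accessors
NULL

#' @rdname catalogue-accessors
#' @export
setGeneric("speciesNames", function(x) standardGeneric("speciesNames"))

#' @rdname catalogue-accessors
#' @export
setGeneric("countryNames", function(x) standardGeneric("countryNames"))

#' @rdname catalogue-accessors
#' @export
setGeneric("nSpecies", function(x) standardGeneric("nSpecies"))

#' @rdname catalogue-accessors
#' @export
setGeneric("nCountries", function(x) standardGeneric("nCountries"))

#' @rdname catalogue-accessors
#' @export
setGeneric("countriesOf", function(x, species) standardGeneric("countriesOf"))

#' @rdname catalogue-accessors
#' @export
setGeneric("regionOf", function(x, country) standardGeneric("regionOf"))

#' @rdname catalogue-accessors
#' @export
setGeneric("isEndemic", function(x, species) standardGeneric("isEndemic"))

#' @rdname catalogue-accessors
#' @export
setGeneric("isMedical", function(x, species) standardGeneric("isMedical"))

#' Extract record sequences as a DNAStringSet
#'
#' Returns the sequences of the records that carry one, as a
#' [Biostrings::DNAStringSet] named by `record_id`. Records without a
#' sequence are omitted.
#'
#' @param x A [BarcodeRecordSet-class].
#' @return A `DNAStringSet`.
#' @export
setGeneric("recordSequences", function(x) standardGeneric("recordSequences"))

#' Stage table of a curation report
#'
#' @param x A [CurationReport-class].
#' @return `stageTable()`: the per-stage accounting data.frame;
#'   `excludedSpecies()`: the data.frame of species excluded outright with
#'   reasons.
#' @name report-accessors
NULL

#' @rdname report-accessors
#' @export
setGeneric("stageTable", function(x) standardGeneric("stageTable"))

#' @rdname report-accessors
#' @export
setGeneric("excludedSpecies", function(x) standardGeneric("excludedSpecies"))

#' Accessors for fitted binomial models
#'
#' `oddsRatios()` returns `exp(beta)` per term; `coefTable()` the full
#' coefficient table (coefficient, SE, odds ratio, 95% CI, p-value);
#' `modelAIC()` the Akaike information criterion `-2 logLik + 2k`.
#'
#' @param x A [BinomialGlmFit-class] (or [BinomialGlmmFit-class]).
#' @name fit-accessors
NULL

#' @rdname fit-accessors
#' @export
setGeneric("oddsRatios", function(x) standardGeneric("oddsRatios"))

#' @rdname fit-accessors
#' @export
setGeneric("coefTable", function(x) standardGeneric("coefTable"))

#' @rdname fit-accessors
#' @export
setGeneric("modelAIC", function(x) standardGeneric("modelAIC"))

#' Selection table of an all-subsets AIC run
#'
#' @param x A [ModelSelectionTable-class].
#' @return `selectionTable()`: the ranked data.frame; `bestModel()`: the
#'   [BinomialGlmFit-class] of the lowest-AIC converged subset.
#' @name selection-accessors
NULL

#' @rdname selection-accessors
#' @export
setGeneric("selectionTable", function(x) standardGeneric("selectionTable"))

#' @rdname selection-accessors
#' @export
setGeneric("bestModel", function(x) standardGeneric("bestModel"))
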