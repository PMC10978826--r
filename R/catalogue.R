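#' @include AllGenerics.R
NULL

# Collapse runs of whitespace and trim; used for species names and country
# labels before any matching.
.squeezeWs <- function(x) {
    x <- gsub("[[:space:]]+", " ", x)
    trimws(x)
}

#' Normalize country names against a gazetteer
#'
#' Case-insensitive, whitespace-normalized lookup of country names against a
#' gazetteer (a character vector of canonical spellings). Matched names are
#' returned in their canonical spelling; unmatched names become `NA` and are
#' reported via the `"unmatched"` attribute — never silently dropped.
#'
#' @param x Character vector of country names (may contain `NA`).
#' @param gazetteer Character vector of canonical country names.
#' @return Character vector like `x` with canonical spellings or `NA`;
#'   attribute `"unmatched"` lists the distinct unmatched inputs.
#' @examples
#' normalizeCountry(c(" brazil", "Atlantis"), gazetteer = c("Brazil", "Peru"))
#' @export
normalizeCountry <- function(x, gazetteer) {
    gaz <- .squeezeWs(gazetteer)
    key <- tolower(gaz)
    xn <- tolower(.squeezeWs(x))
    idx <- match(xn, key)
    out <- gaz[idx]
    unmatched <- unique(x[!is.na(x) & is.na(out)])
    attr(out, "unmatched") <- unmatched
    out
}

# Internal constructor from a long (species, country) table.
.newCatalogue <- function(species, country, medical, regionMap) {
    species <- .squeezeWs(species)
    country <- .squeezeWs(country)
    keep <- !duplicated(paste(species, country, sep = "\r"))
    species <- species[keep]; country <- country[keep]; medical <- medical[keep]
    sp <- unique(species)
    countriesOf <- split(country, factor(species, levels = sp))
    med <- vapply(split(medical, factor(species, levels = sp)), any, logical(1))
    names(regionMap) <- .squeezeWs(names(regionMap))
    regionMap <- regionMap[order(names(regionMap))] # canonical order
    new("TaxonCatalogue", species = sp, countriesOf = countriesOf,
        medical = med, regionMap = regionMap)
}

#' Read a taxonomic checklist into a TaxonCatalogue
#'
#' Parses a flat checklist table with one species-country row per line and
#' columns `species`, `country`, `medical` and (unless `regionMap` is
#' supplied) `region`. Duplicate (species, country) pairs are deduplicated;
#' a region label outside the seven biogeographic regions, a missing
#' required column, or a species without a country is an error.
#'
#' @param path Path to a TSV (default) or CSV checklist; comma separation is
#'   assumed when the file extension is `.csv`.
#' @param regionMap Optional named character vector (country -> region) or
#'   path to a two-column TSV `country<TAB>region`; overrides any `region`
#'   column in the checklist.
#' @return A [TaxonCatalogue-class].
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("species\tcountry\tregion\tmedical",
#'              "Aedes albopictus\tBrazil\tNeotropical\tTRUE",
#'              "Aedes albopictus\tPeru\tNeotropical\tTRUE",
#'              "Culex modestus\tFrance\tPalearctic\tFALSE"), tf)
#' cat <- readTaxonCatalogue(tf)
#' nSpecies(cat)
#' @export
readTaxonCatalogue <- function(path, regionMap = NULL) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    df <- utils::read.table(path, sep = sep, header = TRUE,
                            stringsAsFactors = FALSE, quote = "",
                            comment.char = "", na.strings = c("NA", ""))
    need <- c("species", "country", "medical")
    if (!all(need %in% names(df)))
        stop("checklist is missing required column(s): ",
             paste(setdiff(need, names(df)), collapse = ", "))
    if (is.null(regionMap)) {
        if (!"region" %in% names(df))
            stop("checklist has no 'region' column and no regionMap was given")
        rm_df <- unique(df[, c("country", "region")])
        if (anyDuplicated(rm_df$country))
            stop("conflicting region labels for some countries")
        regionMap <- stats::setNames(rm_df$region, rm_df$country)
    } else if (is.character(regionMap) && length(regionMap) == 1L &&
               is.null(names(regionMap)) && file.exists(regionMap)) {
        rm_df <- utils::read.table(regionMap, sep = "\t", header = TRUE,
                                   stringsAsFactors = FALSE)
        regionMap <- stats::setNames(rm_df[[2L]], rm_df[[1L]])
    }
    if (anyNA(df$species) || anyNA(df$country))
        stop("checklist rows must carry both species and country")
    med <- df$medical
    if (!is.logical(med)) med <- as.logical(med) | (med %in% c("1", "yes"))
    cat <- .newCatalogue(df$species, df$country, med, regionMap)
    validObject(cat)
    cat
}

#' Write a TaxonCatalogue back to a checklist file
#'
#' Serializes the catalogue to the same flat format [readTaxonCatalogue()]
#' reads (columns `species`, `country`, `region`, `medical`), so a
#' parse-serialize-parse round trip is the identity.
#'
#' @param cat A [TaxonCatalogue-class].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
writeTaxonCatalogue <- function(cat, path) {
    df <- data.frame(
        species = rep(cat@species, lengths(cat@countriesOf)),
        country = unlist(cat@countriesOf, use.names = FALSE),
        stringsAsFactors = FALSE)
    df$region <- unname(cat@regionMap[df$country])
    df$medical <- unname(cat@medical[df$species])
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname catalogue-accessors
setMethod("speciesNames", "TaxonCatalogue", function(x) x@species)

#' @rdname catalogue-accessors
setMethod("countryNames", "TaxonCatalogue",
          function(x) names(x@regionMap))

#' @rdname catalogue-accessors
setMethod("nSpecies", "TaxonCatalogue", function(x) length(x@species))

#' @rdname catalogue-accessors
setMethod("nCountries", "TaxonCatalogue",
          function(x) length(x@regionMap))

#' @rdname catalogue-accessors
setMethod("countriesOf", "TaxonCatalogue", function(x, species) {
    if (missing(species)) return(x@countriesOf)
    bad <- setdiff(species, x@species)
    if (length(bad))
        stop("unknown species: ", paste(bad, collapse = ", "))
    if (length(species) == 1L) x@countriesOf[[species]]
    else x@countriesOf[species]
})

#' @rdname catalogue-accessors
setMethod("regionOf", "TaxonCatalogue", function(x, country) {
    if (missing(country)) return(x@regionMap)
    x@regionMap[country]
})

#' @rdname catalogue-accessors
setMethod("isEndemic", "TaxonCatalogue", function(x, species) {
    if (missing(species)) species <- x@species
    stats::setNames(lengths(x@countriesOf[species]) == 1L, species)
})

#' @rdname catalogue-accessors
setMethod("isMedical", "TaxonCatalogue", function(x, species) {
    if (missing(species)) species <- x@species
    x@medical[species]
})

setMethod("show", "TaxonCatalogue", function(object) {
    cat("TaxonCatalogue with", length(object@species), "species over",
        length(object@regionMap), "countries\n")
    cat("  endemic species:", sum(lengths(object@countriesOf) == 1L), "\n")
    cat("  medically important species:", sum(object@medical), "\n")
    cat("  regions:",
        paste(sort(unique(object@regionMap)), collapse = ", "), "\n")
})

#' Per-country catalogue summary
#'
#' Tabulates, for every country in the catalogue's region map (countries
#' with no species included, with zeros), the number of catalogue species,
#' the number of endemics (species whose entire catalogue distribution is
#' exactly that country) and the number of medically important species
#' occurring there.
#'
#' @param cat A [TaxonCatalogue-class].
#' @return data.frame with columns `country`, `region`, `n_species`,
#'   `n_endemic`, `n_medical`.
#' @export
countrySummary <- function(cat) {
    stopifnot(is(cat, "TaxonCatalogue"))
    countries <- names(cat@regionMap)
    long <- data.frame(
        species = rep(cat@species, lengths(cat@countriesOf)),
        country = unlist(cat@countriesOf, use.names = FALSE),
        stringsAsFactors = FALSE)
    long$endemic <- unname(isEndemic(cat)[long$species])
    long$medical <- unname(cat@medical[long$species])
    cf <- factor(long$country, levels = countries)
    data.frame(
        country = countries,
        region = unname(cat@regionMap[countries]),
        n_species = as.integer(table(cf)),
        n_endemic = as.integer(tapply(long$endemic, cf, sum, default = 0L)),
        n_medical = as.integer(tapply(long$medical, cf, sum, default = 0L)),
        stringsAsFactors = FALSE)
}
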