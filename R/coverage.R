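#' @include AllClasses.R catalogue.R
NULL

# Round half away from zero (the convention behind the reported
# percentages), since base round() rounds half to even.
.roundHalfUp <- function(x, digits = 2L) {
    p <- 10^digits
    sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Taxonomic coverage percentage
#'
#' The percentage of catalogue species that have at least one record in the
#' database for a given unit: `100 * n_db_species / n_cat_species`, reported
#' to two decimals (half-up).
#'
#' @param n_db_species Number of catalogue-matched species in the database.
#' @param n_cat_species Number of catalogue species (> 0).
#' @return Numeric percentage, rounded to two decimals. Vectorized.
#' @examples
#' taxonomicCoverage(1054, 3570) # 29.52
#' @export
taxonomicCoverage <- function(n_db_species, n_cat_species) {
    if (any(n_cat_species == 0))
        stop("coverage is undefined when the catalogue has no species")
    .roundHalfUp(100 * n_db_species / n_cat_species, 2L)
}

#' Country- or region-level coverage table
#'
#' Builds one row per country (or biogeographic region) having catalogue
#' species: catalogue richness, database richness (distinct
#' catalogue-matched species with at least one curated record in the unit),
#' the taxonomic coverage percentage, the number of sequences, and the
#' catalogue-derived predictors (endemic and medically important species
#' counts). Region rows aggregate member countries by species-set union, not
#' by sum: a species recorded in two countries of one region counts once.
#'
#' @param records Curated [BarcodeRecordSet-class] (every record must carry
#'   a catalogue country).
#' @param cat A [TaxonCatalogue-class].
#' @param unit `"country"` or `"region"`.
#' @return data.frame with columns `unit`, `region` (for countries),
#'   `n_cat_species`, `n_db_species`, `coverage_pct`, `n_sequences`,
#'   `n_endemic`, `n_medical`.
#' @export
buildCoverageTable <- function(records, cat, unit = c("country", "region")) {
    unit <- match.arg(unit)
    stopifnot(is(records, "BarcodeRecordSet"), is(cat, "TaxonCatalogue"))
    df <- records@records
    bad <- setdiff(unique(stats::na.omit(df$country)), countryNames(cat))
    if (length(bad))
        stop("record countries missing from the catalogue region map: ",
             paste(bad, collapse = ", "))
    cs <- countrySummary(cat)
    long <- data.frame(
        species = rep(cat@species, lengths(cat@countriesOf)),
        country = unlist(cat@countriesOf, use.names = FALSE),
        stringsAsFactors = FALSE)
    if (unit == "country") {
        units <- cs$country[cs$n_species > 0L]
        cat_sets <- split(long$species, long$country)
        db_sets <- split(df$species_name, df$country)
        nseq <- table(factor(df$country, levels = units))
        out <- data.frame(
            unit = units,
            region = unname(cat@regionMap[units]),
            n_cat_species = cs$n_species[match(units, cs$country)],
            n_endemic = cs$n_endemic[match(units, cs$country)],
            n_medical = cs$n_medical[match(units, cs$country)],
            stringsAsFactors = FALSE)
    } else {
        long$region <- unname(cat@regionMap[long$country])
        df$region <- unname(cat@regionMap[df$country])
        cat_sets <- lapply(split(long$species, long$region), unique)
        units <- names(cat_sets)[lengths(cat_sets) > 0L]
        db_sets <- split(df$species_name, df$region)
        nseq <- table(factor(df$region, levels = units))
        med <- isMedical(cat); endem <- isEndemic(cat)
        out <- data.frame(
            unit = units,
            region = units,
            n_cat_species = lengths(cat_sets)[units],
            n_endemic = vapply(units, function(r) {
                sp <- unique(long$species[long$region == r])
                # endemic to the region: all catalogue countries inside it
                sum(vapply(cat@countriesOf[sp], function(cc)
                    all(cat@regionMap[cc] == r), logical(1)))
            }, integer(1)),
            n_medical = vapply(cat_sets[units],
                               function(sp) sum(med[unique(sp)]),
                               integer(1)),
            stringsAsFactors = FALSE)
    }
    out$n_db_species <- vapply(out$unit, function(u) {
        s <- db_sets[[u]]
        if (is.null(s)) 0L else length(unique(s))
    }, integer(1))
    out$n_sequences <- as.integer(nseq[out$unit])
    out$coverage_pct <- taxonomicCoverage(out$n_db_species,
                                          out$n_cat_species)
    rownames(out) <- NULL
    out[, c("unit", "region", "n_cat_species", "n_db_species",
            "coverage_pct", "n_sequences", "n_endemic", "n_medical")]
}

#' Per-species coverage and effort table
#'
#' One row per species present in the curated records: sequence count, mean
#' sequence length (arithmetic mean, in bases), distinct database countries,
#' catalogue countries, the geographic coverage (proportion of catalogue
#' countries where the database has at least one record; in `(0, 1]` for
#' curated data), and the medical flag.
#'
#' @param records Curated [BarcodeRecordSet-class].
#' @param cat A [TaxonCatalogue-class].
#' @return data.frame with columns `species`, `n_sequences`,
#'   `mean_seq_length`, `n_db_countries`, `n_cat_countries`,
#'   `geographic_coverage`, `medical`.
#' @export
buildSpeciesTable <- function(records, cat) {
    stopifnot(is(records, "BarcodeRecordSet"), is(cat, "TaxonCatalogue"))
    df <- records@records
    sp <- sort(unique(df$species_name))
    f <- factor(df$species_name, levels = sp)
    n_cat <- lengths(countriesOf(cat))[sp]
    out <- data.frame(
        species = sp,
        n_sequences = as.integer(table(f)),
        mean_seq_length = as.numeric(tapply(nchar(df$sequence), f, mean)),
        n_db_countries = as.integer(tapply(df$country, f,
                                    function(x) length(unique(x)))),
        n_cat_countries = as.integer(n_cat),
        stringsAsFactors = FALSE)
    out$geographic_coverage <- out$n_db_countries / out$n_cat_countries
    out$medical <- unname(isMedical(cat, sp))
    rownames(out) <- NULL
    out
}
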