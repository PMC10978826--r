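#' @include AllClasses.R catalogue.R records.R
NULL

#' Curate barcode records against a taxonomic catalogue
#'
#' Applies the fixed five-stage filter chain that turns a raw repository
#' dump into an analysis-ready record set:
#'
#' 1. `marker` — keep rows whose marker equals the requested code;
#' 2. `sequence` — drop rows without a sequence;
#' 3. `country` — drop rows whose country is absent or fails gazetteer
#'    validation (coordinates are never used to rescue a missing country);
#' 4. `name_match` — drop rows whose species name has no exact match
#'    (after whitespace normalization) in the catalogue;
#' 5. `country_count` — drop *all* rows of any species whose distinct
#'    surviving-record countries outnumber its catalogue countries
#'    (species-atomic removal; this is what guarantees geographic
#'    coverage <= 1 downstream).
#'
#' Every stage is accounted for in the returned [CurationReport-class];
#' species excluded at stages 4-5 are listed with the reason. Curation is
#' idempotent: re-running it on its own output removes nothing.
#'
#' @param records A [BarcodeRecordSet-class].
#' @param cat A [TaxonCatalogue-class].
#' @param marker Marker code to keep, e.g. `"COI-5P"`.
#' @param gazetteer Character vector of valid country names; defaults to the
#'   catalogue's countries. Matching is case-insensitive after whitespace
#'   normalization (see [normalizeCountry()]).
#' @return A list with `records` (curated [BarcodeRecordSet-class], country
#'   and species names in canonical spelling) and `report`
#'   ([CurationReport-class]).
#' @examples
#' cat <- simulateCatalogue(simulationConfig(seed = 1))$catalogue
#' sim <- simulateRecords(cat, simulationConfig(seed = 1, defectRate = 0.1))
#' cur <- curateRecords(sim$records, cat, marker = "COI-5P")
#' stageTable(cur$report)
#' @export
curateRecords <- function(records, cat, marker,
                          gazetteer = countryNames(cat)) {
    stopifnot(is(records, "BarcodeRecordSet"), is(cat, "TaxonCatalogue"),
              is.character(marker), length(marker) == 1L)
    df <- records@records
    stages <- data.frame(stage = character(), rows_in = integer(),
                         rows_removed = integer(), rows_out = integer(),
                         species_out = integer(), stringsAsFactors = FALSE)
    excluded <- data.frame(species = character(), reason = character(),
                           stringsAsFactors = FALSE)
    note <- function(stage, n_in, keep, d) {
        rbind(stages, data.frame(
            stage = stage, rows_in = n_in, rows_removed = n_in - sum(keep),
            rows_out = sum(keep),
            species_out = length(unique(stats::na.omit(
                d$species_name[keep]))),
            stringsAsFactors = FALSE))
    }

    # (1) marker
    keep <- !is.na(df$marker) & df$marker == marker
    stages <- note("marker", nrow(df), keep, df)
    df <- df[keep, , drop = FALSE]

    # (2) sequence present
    keep <- !is.na(df$sequence)
    stages <- note("sequence", nrow(df), keep, df)
    df <- df[keep, , drop = FALSE]

    # (3) country present and valid under the gazetteer
    norm <- normalizeCountry(df$country, gazetteer)
    keep <- !is.na(norm)
    df$country <- as.character(norm)
    stages <- note("country", nrow(df), keep, df)
    df <- df[keep, , drop = FALSE]

    # (4) exact species-name match in the catalogue
    df$species_name <- .squeezeWs(df$species_name)
    keep <- !is.na(df$species_name) & df$species_name %in% speciesNames(cat)
    unmatched <- unique(stats::na.omit(df$species_name[!keep]))
    if (length(unmatched))
        excluded <- rbind(excluded, data.frame(
            species = unmatched, reason = "no exact catalogue match",
            stringsAsFactors = FALSE))
    stages <- note("name_match", nrow(df), keep, df)
    df <- df[keep, , drop = FALSE]

    # (5) species-atomic country-count sanity check
    n_db <- tapply(df$country, df$species_name,
                   function(x) length(unique(x)))
    n_cat <- lengths(countriesOf(cat))[names(n_db)]
    bad_sp <- names(n_db)[n_db > n_cat]
    keep <- !(df$species_name %in% bad_sp)
    if (length(bad_sp))
        excluded <- rbind(excluded, data.frame(
            species = bad_sp,
            reason = "database countries exceed catalogue countries",
            stringsAsFactors = FALSE))
    stages <- note("country_count", nrow(df), keep, df)
    df <- df[keep, , drop = FALSE]

    rownames(df) <- NULL
    report <- new("CurationReport", stages = stages, excluded = excluded)
    validObject(report)
    list(records = new("BarcodeRecordSet", records = df), report = report)
}

#' @rdname report-accessors
setMethod("stageTable", "CurationReport", function(x) x@stages)

#' @rdname report-accessors
setMethod("excludedSpecies", "CurationReport", function(x) x@excluded)

setMethod("show", "CurationReport", function(object) {
    st <- object@stages
    cat("CurationReport:", if (nrow(st)) st$rows_in[1L] else 0L, "->",
        if (nrow(st)) st$rows_out[nrow(st)] else 0L, "records\n")
    for (i in seq_len(nrow(st)))
        cat(sprintf("  %-13s removed %6d, kept %6d (%d species)\n",
                    st$stage[i], st$rows_removed[i], st$rows_out[i],
                    st$species_out[i]))
    if (nrow(object@excluded))
        cat("  excluded species:", nrow(object@excluded), "\n")
})

# Strip GenBank accession version suffixes and case-fold for reconciliation.
.normAccession <- function(x) {
    out <- toupper(trimws(x))
    sub("\\.[0-9]+$", "", out)
}

#' Reconcile records shared between two repositories
#'
#' Partitions BOLD-style and GenBank-style record sets by accession.
#' Comparison is case-insensitive with version suffixes stripped
#' (`AB123456.1` matches `AB123456`). `shared` holds the records (from both
#' sets) whose accession occurs in both; `mined_from_genbank` flags the
#' BOLD-style records that carry a GenBank accession absent from the GenBank
#' set — sequences mined into one repository from the other. BOLD records
#' without any accession count as unique to BOLD.
#'
#' @param bold_records,genbank_records [BarcodeRecordSet-class] objects.
#' @return A list with record subsets `shared_bold`, `shared_genbank`,
#'   `unique_bold`, `unique_genbank`, `mined_from_genbank` and a `summary`
#'   data.frame of record and species counts per partition (species counted
#'   on the union for `shared`).
#' @export
crossReferenceSources <- function(bold_records, genbank_records) {
    stopifnot(is(bold_records, "BarcodeRecordSet"),
              is(genbank_records, "BarcodeRecordSet"))
    b <- bold_records@records
    g <- genbank_records@records
    bacc <- .normAccession(b$accession)
    gacc <- .normAccession(g$accession)
    shared_acc <- intersect(stats::na.omit(bacc), stats::na.omit(gacc))
    b_shared <- !is.na(bacc) & bacc %in% shared_acc
    g_shared <- !is.na(gacc) & gacc %in% shared_acc
    mined <- !is.na(bacc) & !b_shared
    out <- list(
        shared_bold = bold_records[b_shared],
        shared_genbank = genbank_records[g_shared],
        unique_bold = bold_records[!b_shared],
        unique_genbank = genbank_records[!g_shared],
        mined_from_genbank = bold_records[mined])
    nsp <- function(df) length(unique(stats::na.omit(df$species_name)))
    shared_species <- length(unique(stats::na.omit(
        c(b$species_name[b_shared], g$species_name[g_shared]))))
    out$summary <- data.frame(
        partition = c("shared", "unique_bold", "unique_genbank",
                      "mined_from_genbank"),
        n_records = c(length(shared_acc), sum(!b_shared), sum(!g_shared),
                      sum(mined)),
        n_species = c(shared_species, nsp(b[!b_shared, ]),
                      nsp(g[!g_shared, ]), nsp(b[mined, ])),
        stringsAsFactors = FALSE)
    out
}
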