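#' @include AllClasses.R
NULL

# Build the canonical record data.frame from whatever columns are supplied;
# everything missing becomes NA of the right type. Gaps/hyphens are stripped
# from sequences and empty strings become NA.
.recordFrame <- function(n, ...) {
    cols <- list(...)
    df <- data.frame(row.names = seq_len(n))
    for (nm in names(.RECORD_COLS)) {
        v <- cols[[nm]]
        if (is.null(v)) {
            v <- if (.RECORD_COLS[[nm]] == "numeric") NA_real_
                 else if (.RECORD_COLS[[nm]] == "logical") NA
                 else NA_character_
            v <- rep(v, n)
        }
        if (.RECORD_COLS[[nm]] == "character") {
            v <- as.character(v)
            v[!is.na(v) & !nzchar(trimws(v))] <- NA_character_
        } else if (.RECORD_COLS[[nm]] == "numeric") {
            v <- suppressWarnings(as.numeric(v))
        }
        df[[nm]] <- v
    }
    df$sequence <- ifelse(is.na(df$sequence), NA_character_,
                          toupper(gsub("[-. ]", "", df$sequence)))
    df$sequence[!is.na(df$sequence) & !nzchar(df$sequence)] <- NA_character_
    if (all(is.na(df$parsed))) df$parsed <- rep(TRUE, n)
    df
}

#' Construct a BarcodeRecordSet from vectors
#'
#' Low-level constructor used by the file readers and the simulator. All
#' arguments except `record_id` are optional and recycled to `NA` when
#' absent. Sequences are upper-cased with gaps/hyphens stripped.
#'
#' @param record_id Character vector of record identifiers (required).
#' @param source Record source, `"BOLD"` or `"GenBank"` style.
#' @param accession,species_name,marker,sequence,country,definition Optional
#'   character fields.
#' @param latitude,longitude Optional decimal degrees.
#' @param parsed Optional logical; FALSE flags records whose definition line
#'   could not be parsed.
#' @return A [BarcodeRecordSet-class].
#' @export
BarcodeRecordSet <- function(record_id, source = "BOLD", accession = NULL,
                             species_name = NULL, marker = NULL,
                             sequence = NULL, country = NULL,
                             latitude = NULL, longitude = NULL,
                             definition = NULL, parsed = NULL) {
    n <- length(record_id)
    df <- .recordFrame(n, record_id = record_id,
                       source = rep_len(source, n), accession = accession,
                       species_name = species_name, marker = marker,
                       sequence = sequence, country = country,
                       latitude = latitude, longitude = longitude,
                       definition = definition, parsed = parsed)
    obj <- new("BarcodeRecordSet", records = df)
    validObject(obj)
    obj
}

#' @describeIn BarcodeRecordSet Number of records.
#' @param x A `BarcodeRecordSet`.
#' @export
setMethod("length", "BarcodeRecordSet", function(x) nrow(x@records))

#' Coerce records to a data.frame
#'
#' @param x A [BarcodeRecordSet-class].
#' @param row.names,optional,... Passed for signature compatibility.
#' @return The underlying record data.frame.
#' @export
setMethod("as.data.frame", "BarcodeRecordSet",
          function(x, row.names = NULL, optional = FALSE, ...) {
    df <- x@records
    rownames(df) <- row.names
    df
})

#' Subset records
#'
#' @param x A [BarcodeRecordSet-class].
#' @param i Row index (logical, integer or record_id character).
#' @param j,...,drop Ignored.
#' @export
setMethod("[", "BarcodeRecordSet", function(x, i, j, ..., drop = FALSE) {
    if (is.character(i)) i <- match(i, x@records$record_id)
    df <- x@records[i, , drop = FALSE]
    rownames(df) <- NULL
    new("BarcodeRecordSet", records = df)
})

#' @rdname recordSequences
setMethod("recordSequences", "BarcodeRecordSet", function(x) {
    df <- x@records
    keep <- !is.na(df$sequence)
    Biostrings::DNAStringSet(stats::setNames(df$sequence[keep],
                                             df$record_id[keep]))
})

setMethod("show", "BarcodeRecordSet", function(object) {
    df <- object@records
    cat("BarcodeRecordSet with", nrow(df), "records\n")
    if (nrow(df)) {
        cat("  sources:", paste(names(table(df$source)),
                                table(df$source), collapse = ", "), "\n")
        cat("  with sequence:", sum(!is.na(df$sequence)),
            "| with country:", sum(!is.na(df$country)), "\n")
        cat("  distinct species names:",
            length(unique(stats::na.omit(df$species_name))), "\n")
    }
})

#' Read a BOLD-style specimen+sequence dump
#'
#' Reads a tab-separated specimen dump (one record per row) into a
#' [BarcodeRecordSet-class]. Empty cells become absent (`NA`) fields and row
#' order is preserved. Column names are configurable for dumps whose headers
#' differ from the defaults.
#'
#' @param path Path to the TSV dump.
#' @param columns Named character vector mapping the canonical fields
#'   (`record_id`, `accession`, `species_name`, `marker`, `country`,
#'   `latitude`, `longitude`, `sequence`) to column names in the file.
#' @return A [BarcodeRecordSet-class] with `source = "BOLD"`.
#' @export
readBoldRecords <- function(path,
                            columns = c(record_id = "processid",
                                        accession = "genbank_accession",
                                        species_name = "species_name",
                                        marker = "markercode",
                                        country = "country",
                                        latitude = "lat", longitude = "lon",
                                        sequence = "nucleotides")) {
    df <- tryCatch(
        suppressWarnings(
            utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                              comment.char = "", stringsAsFactors = FALSE,
                              na.strings = c("NA", ""))),
        error = function(e) stop("cannot read BOLD-style dump '", path,
                                 "': ", conditionMessage(e)))
    if (!columns[["record_id"]] %in% names(df))
        stop("mandatory id column '", columns[["record_id"]],
             "' not present in ", path)
    get <- function(field) {
        nm <- columns[[field]]
        if (!is.null(nm) && !is.na(nm) && nm %in% names(df)) df[[nm]] else NULL
    }
    BarcodeRecordSet(
        record_id = as.character(df[[columns[["record_id"]]]]),
        source = "BOLD",
        accession = get("accession"), species_name = get("species_name"),
        marker = get("marker"), sequence = get("sequence"),
        country = get("country"), latitude = get("latitude"),
        longitude = get("longitude"))
}

#' Read GenBank-style FASTA records
#'
#' Reads a FASTA file whose definition lines carry the accession and the
#' organism (binomial), e.g. `>AB123456 Aedes albopictus cytochrome ...`.
#' Records whose definition does not match the pattern are kept but flagged
#' `parsed = FALSE` (their accession and species stay `NA`); this is not
#' fatal. Country is always absent for this source.
#'
#' @param path FASTA path.
#' @param pattern Regular expression with two capture groups (accession,
#'   binomial) applied to each definition line.
#' @return A [BarcodeRecordSet-class] with `source = "GenBank"`.
#' @export
readGenbankRecords <- function(path,
    pattern = "^([A-Za-z]{1,4}_?[0-9]{4,10}(?:\\.[0-9]+)?)\\s+([A-Z][a-z]+ [a-z]+)") {
    seqs <- tryCatch(Biostrings::readDNAStringSet(path),
                     error = function(e) stop("malformed FASTA '", path,
                                              "': ", conditionMessage(e)))
    n <- length(seqs)
    defs <- names(seqs)
    if (n == 0L)
        return(BarcodeRecordSet(record_id = character(), source = "GenBank"))
    m <- regexec(pattern, defs)
    hit <- regmatches(defs, m)
    ok <- lengths(hit) == 3L
    acc <- ifelse(ok, vapply(hit, function(h) if (length(h) == 3L) h[2L]
                             else NA_character_, ""), NA_character_)
    org <- ifelse(ok, vapply(hit, function(h) if (length(h) == 3L) h[3L]
                             else NA_character_, ""), NA_character_)
    BarcodeRecordSet(
        record_id = ifelse(ok, acc, paste0("unparsed_", seq_len(n))),
        source = "GenBank", accession = acc, species_name = org,
        sequence = as.character(seqs), definition = defs, parsed = ok)
}

#' Filter records by ITS2-related definition names
#'
#' Name-based filter for ITS2 data sets: keeps records whose definition line
#' mentions the internal transcribed spacer 2 under any configured synonym
#' (case-insensitive). Records with no definition are removed.
#'
#' @param records A [BarcodeRecordSet-class].
#' @param synonyms Character vector of acceptable ITS2 spellings.
#' @return A list with elements `kept` and `removed`, both
#'   [BarcodeRecordSet-class].
#' @export
filterIts2Names <- function(records,
    synonyms = c("ITS2", "ITS-2", "ITS 2", "ITSII",
                 "internal transcribed spacer 2")) {
    stopifnot(is(records, "BarcodeRecordSet"))
    defs <- records@records$definition
    rx <- paste(vapply(synonyms, function(s)
        gsub("([][{}()*+?.\\^$|])", "\\\\\\1", s), ""), collapse = "|")
    keep <- !is.na(defs) & grepl(rx, defs, ignore.case = TRUE)
    list(kept = records[keep], removed = records[!keep])
}

#' Write records as a TSV + FASTA pair
#'
#' @param records A [BarcodeRecordSet-class].
#' @param tsv,fasta Output paths; either may be `NULL` to skip.
#' @return Invisibly, a character vector of the files written.
#' @export
writeRecords <- function(records, tsv = NULL, fasta = NULL) {
    stopifnot(is(records, "BarcodeRecordSet"))
    written <- character()
    if (!is.null(tsv)) {
        utils::write.table(records@records, tsv, sep = "\t", quote = FALSE,
                           row.names = FALSE, na = "")
        written <- c(written, tsv)
    }
    if (!is.null(fasta)) {
        Biostrings::writeXStringSet(recordSequences(records), fasta)
        written <- c(written, fasta)
    }
    invisible(written)
}
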