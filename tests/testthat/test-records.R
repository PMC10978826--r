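writeBoldDump <- function(df) {
    tf <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
    utils::write.table(df, tf, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "")
    tf
}

test_that("BOLD-style dumps parse with absent fields as NA", {
    dump <- data.frame(
        processid = c("BOLD1", "BOLD2", "BOLD3"),
        genbank_accession = c("AB000001", "", "AB000003.2"),
        species_name = c("Aedes alpha", "Culex beta", "Aedes alpha"),
        markercode = c("COI-5P", "COI-5P", "ITS2"),
        country = c("Brazil", "", "Peru"),
        lat = c(-3.1, NA, 4.2), lon = c(-60.0, NA, -70.1),
        nucleotides = c("ACGT-ACGT", "", "acgtacgt"),
        stringsAsFactors = FALSE)
    rec <- readBoldRecords(writeBoldDump(dump))
    df <- as.data.frame(rec)
    expect_equal(length(rec), 3L)
    expect_equal(df$record_id, c("BOLD1", "BOLD2", "BOLD3")) # order kept
    expect_equal(df$sequence[1L], "ACGTACGT") # gaps stripped, upper-cased
    expect_true(is.na(df$sequence[2L]))
    expect_true(is.na(df$country[2L]))
    expect_equal(df$accession[3L], "AB000003.2") # kept for reconciliation
    expect_equal(df$marker[2L], "COI-5P")
})

test_that("BOLD reader rejects unreadable files and missing id columns", {
    expect_error(readBoldRecords(file.path(tempdir(), "nope.tsv")),
                 "cannot read")
    dump <- data.frame(species_name = "x", markercode = "COI-5P")
    expect_error(readBoldRecords(writeBoldDump(dump)), "id column")
})

test_that("GenBank-style FASTA parses accession and organism", {
    tf <- withr::local_tempfile(fileext = ".fasta")
    writeLines(c(
        ">AB123456 Aedes albopictus cytochrome oxidase subunit I",
        "ACGTACGTACGT",
        ">not a parsable definition line",
        "TTTTCCCC"), tf)
    rec <- readGenbankRecords(tf)
    df <- as.data.frame(rec)
    expect_equal(length(rec), 2L)
    expect_equal(df$accession[1L], "AB123456")
    expect_equal(df$species_name[1L], "Aedes albopictus")
    expect_true(df$parsed[1L])
    expect_false(df$parsed[2L]) # flagged, not fatal
    expect_true(all(is.na(df$country)))

    empty <- withr::local_tempfile(fileext = ".fasta")
    writeLines(character(), empty)
    expect_equal(length(readGenbankRecords(empty)), 0L)
})

test_that("ITS2 name filter keeps synonym matches only", {
    rec <- BarcodeRecordSet(
        record_id = sprintf("G%02d", 1:6), source = "GenBank",
        sequence = rep("ACGT", 6L),
        definition = c(
            "AB1 Aedes x internal transcribed spacer 2, partial sequence",
            "AB2 Aedes x ITS2 region",
            "AB3 Aedes x 5.8S rRNA and ITS-2",
            "AB4 Aedes x cytochrome oxidase subunit I",
            "AB5 Aedes x 18S ribosomal RNA",
            NA))
    out <- filterIts2Names(rec)
    expect_equal(as.data.frame(out$kept)$record_id,
                 c("G01", "G02", "G03"))
    expect_equal(length(out$removed), 3L)
})

test_that("ITS2 filter arithmetic: removed non-matching names", {
    # scaled-down emulation of a mixed query result: matching plus
    # non-matching definition lines; kept = total - non-matching
    n_match <- 130L
    n_other <- 9L
    rec <- BarcodeRecordSet(
        record_id = sprintf("Q%03d", seq_len(n_match + n_other)),
        source = "GenBank", sequence = "ACGT",
        definition = c(rep("Culex x ITS2 ribosomal spacer", n_match),
                       rep("Culex x 28S ribosomal RNA gene", n_other)))
    out <- filterIts2Names(rec)
    expect_equal(length(out$kept), n_match)
    expect_equal(length(out$kept) + length(out$removed), n_match + n_other)
})

test_that("cross-repository reconciliation partitions by accession", {
    bold <- BarcodeRecordSet(
        record_id = c("B1", "B2", "B3", "B4"), source = "BOLD",
        accession = c("AB000001.1", "AB000002", NA, "AB000004"),
        species_name = c("s1", "s2", "s3", "s4"))
    gb <- BarcodeRecordSet(
        record_id = c("G1", "G2"), source = "GenBank",
        accession = c("ab000001", "AB000009"),
        species_name = c("s1", "s9"))
    xr <- crossReferenceSources(bold, gb)
    # AB000001 shared despite version suffix and case
    expect_equal(as.data.frame(xr$shared_bold)$record_id, "B1")
    expect_equal(as.data.frame(xr$shared_genbank)$record_id, "G1")
    # B2/B4 carry GenBank accessions absent from the GenBank set
    expect_setequal(as.data.frame(xr$mined_from_genbank)$record_id,
                    c("B2", "B4"))
    # B3 (no accession) is unique to BOLD but not "mined"
    expect_true("B3" %in% as.data.frame(xr$unique_bold)$record_id)
    s <- xr$summary
    expect_equal(s$n_records[s$partition == "shared"], 1L)

    # disjoint sets of sizes 3 and 4
    b2 <- BarcodeRecordSet(record_id = paste0("b", 1:3), source = "BOLD",
                           accession = paste0("AA00000", 1:3))
    g2 <- BarcodeRecordSet(record_id = paste0("g", 1:4), source = "GenBank",
                           accession = paste0("BB00000", 1:4))
    x2 <- crossReferenceSources(b2, g2)
    expect_equal(length(x2$unique_bold), 3L)
    expect_equal(length(x2$unique_genbank), 4L)
    expect_equal(length(x2$shared_bold), 0L)
})

test_that("record sets reject non-IUPAC sequences", {
    expect_error(BarcodeRecordSet(record_id = "x", sequence = "ACGTQ"),
                 "non-IUPAC")
})
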