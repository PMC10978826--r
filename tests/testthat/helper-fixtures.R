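# Fixture builders shared across the suite. Everything is generated in code;
# no data files.

# Write a checklist TSV and read it back as a TaxonCatalogue.
makeCatalogue <- function(species, country, region, medical = FALSE) {
    df <- data.frame(species = species, country = country, region = region,
                     medical = rep_len(medical, length(species)),
                     stringsAsFactors = FALSE)
    tf <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
    utils::write.table(df, tf, sep = "\t", quote = FALSE, row.names = FALSE)
    readTaxonCatalogue(tf)
}

# Three species over two countries.
tinyCatalogue <- function() {
    makeCatalogue(
        species = c("Aedes albopictus", "Aedes albopictus",
                    "Culex modestus", "Anopheles gambiae"),
        country = c("Brazil", "Peru", "Peru", "Brazil"),
        region = c("Neotropical", "Neotropical", "Neotropical",
                   "Neotropical"),
        medical = c(TRUE, TRUE, FALSE, TRUE))
}

randSeq <- function(L) paste(sample(c("A", "C", "G", "T"), L,
                                    replace = TRUE), collapse = "")

# Mutate exactly k interior positions of a sequence (never the first or
# last base, so a local alignment keeps the full span).
mutateAt <- function(seq, k) {
    bases <- c("A", "C", "G", "T")
    s <- strsplit(seq, "")[[1]]
    pos <- sample(seq(2L, length(s) - 1L), k)
    for (p in pos) s[p] <- sample(setdiff(bases, s[p]), 1L)
    paste(s, collapse = "")
}

# Exhaustive all-pairs identity-search oracle: a plain R loop over every
# ordered (query, subject) pair through the scalar aligner, then sort and
# truncate. Independent of the batch matrix path used by identitySearch().
bruteForceSearch <- function(seqs, top_k) {
    ids <- names(seqs)
    n <- length(seqs)
    rows <- list()
    for (i in seq_len(n)) {
        hit <- data.frame(query_id = ids[i], subject_id = ids,
                          pident = NA_real_, alignment_length = NA_integer_,
                          strand = NA_character_, stringsAsFactors = FALSE)
        for (j in seq_len(n)) {
            if (i == j) {
                hit$pident[j] <- 100
                hit$alignment_length[j] <- nchar(as.character(seqs[[j]]))
                hit$strand[j] <- "+"
            } else {
                r <- alignIdentity(as.character(seqs[[i]]),
                                   as.character(seqs[[j]]))
                hit$pident[j] <- r$pident
                hit$alignment_length[j] <- r$alignment_length
                hit$strand[j] <- r$strand
            }
        }
        o <- order(-hit$pident, -hit$alignment_length, hit$subject_id)
        rows[[i]] <- hit[o[seq_len(min(top_k, n))], ]
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

# The ten-row defect fixture: two survivors (species A twice is replaced by
# A and B once each), and one known removal per defect bucket -- 2 wrong
# marker, 1 missing sequence, 2 invalid/missing country, 1 unmatched name,
# 2 rows of a country-count-overflow species.
defectFixture <- function() {
    cat10 <- makeCatalogue(
        species = c("Aedes alpha", "Aedes alpha", "Culex beta",
                    "Culex gamma", "Anopheles delta"),
        country = c("Brazil", "Peru", "Brazil", "Brazil", "Brazil"),
        region = rep("Neotropical", 5L))
    seq100 <- strrep("ACGT", 25L)
    rec <- BarcodeRecordSet(
        record_id = sprintf("R%02d", 1:10),
        source = "BOLD",
        species_name = c("Aedes alpha", "Culex beta", "Aedes alpha",
                         "Culex beta", "Culex gamma", "Aedes alpha",
                         "Culex beta", "Fakeus inventus",
                         "Anopheles delta", "Anopheles delta"),
        marker = c("COI-5P", "COI-5P", "ITS2", "16S", "COI-5P", "COI-5P",
                   "COI-5P", "COI-5P", "COI-5P", "COI-5P"),
        sequence = c(seq100, seq100, seq100, seq100, NA, seq100, seq100,
                     seq100, seq100, seq100),
        country = c("Brazil", "Brazil", "Brazil", "Brazil", "Brazil",
                    NA, "Atlantis", "Brazil", "Brazil", "Peru"))
    list(catalogue = cat10, records = rec,
         survivors = c("R01", "R02"),
         removed_per_stage = c(marker = 2L, sequence = 1L, country = 2L,
                               name_match = 1L, country_count = 2L))
}
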