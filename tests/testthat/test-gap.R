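hitRow <- function(q, s, pid) {
    data.frame(query_id = q, subject_id = s, pident = pid,
               alignment_length = 100L, strand = "+",
               stringsAsFactors = FALSE)
}

test_that("gap decisions match hand-computed min/max identities", {
    sp <- c(a1 = "A", a2 = "A", b1 = "B", c1 = "C", d1 = "D")
    hits <- rbind(
        # species A: min intra 99, nearest heterospecific 95 -> present
        hitRow("a1", "a1", 100), hitRow("a1", "a2", 99),
        hitRow("a1", "b1", 95),
        hitRow("a2", "a2", 100), hitRow("a2", "a1", 99),
        hitRow("a2", "b1", 94),
        # species B: min intra 97 equals max inter 97 -> absent
        hitRow("b1", "b1", 100), hitRow("b1", "b2", 97),
        hitRow("b1", "a1", 97),
        hitRow("b2", "b2", 100), hitRow("b2", "b1", 97),
        hitRow("b2", "a1", 96),
        # singleton C: total heterospecific match -> absent
        hitRow("c1", "c1", 100), hitRow("c1", "a1", 100),
        # singleton D: best heterospecific 98 -> present (self-hit rule)
        hitRow("d1", "d1", 100), hitRow("d1", "a1", 98))
    sp <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B", c1 = "C", d1 = "D")
    res <- callSpeciesGap(hits, sp)
    res <- res[order(res$species), ]
    expect_equal(res$min_intra, c(99, 97, 100, 100))
    expect_equal(res$max_inter, c(95, 97, 100, 98))
    expect_equal(res$gap_present, c(TRUE, FALSE, FALSE, TRUE))
    expect_equal(res$singleton, c(FALSE, FALSE, TRUE, TRUE))
})

test_that("species without heterospecific hits are flagged gap-present", {
    sp <- c(x1 = "X", x2 = "X", y1 = "Y")
    hits <- rbind(hitRow("x1", "x1", 100), hitRow("x1", "x2", 99),
                  hitRow("x2", "x2", 100), hitRow("x2", "x1", 99),
                  hitRow("y1", "y1", 100), hitRow("y1", "x1", 90))
    res <- callSpeciesGap(hits, sp)
    x <- res[res$species == "X", ]
    expect_true(x$gap_present)
    expect_true(x$no_inter_hit)
    expect_true(is.na(x$max_inter))
})

test_that("unmapped records and truncated species are reported", {
    hits <- rbind(hitRow("u1", "u1", 100), hitRow("u1", "u2", 95),
                  hitRow("u2", "u2", 100), hitRow("u2", "u1", 95))
    expect_error(callSpeciesGap(hits, c(u1 = "U")), "without a species")
    sp <- c(u1 = "U", u2 = "U")
    expect_warning(callSpeciesGap(hits, sp, top_k = 1L), "truncation")
})

test_that("gap calls are invariant to record order and id relabeling", {
    set.seed(107)
    cfg <- simulationConfig(seed = 107, nSpecies = 8, nCountries = 3,
                            sequenceLength = 200L,
                            seqsPerSpecies = list(dist = "fixed", mean = 3))
    bc <- simulateBarcodes(simulateCatalogue(cfg)$catalogue, cfg)
    hits <- identitySearch(bc$sequences, top_k = 100L)
    res <- callSpeciesGap(hits, bc$speciesMap)

    perm <- sample(length(bc$sequences))
    hits_p <- identitySearch(bc$sequences[perm], top_k = 100L)
    res_p <- callSpeciesGap(hits_p, bc$speciesMap)
    expect_equal(res_p[order(res_p$species), ],
                 res[order(res$species), ], ignore_attr = TRUE)

    relabel <- stats::setNames(sprintf("Z%03d", seq_along(bc$sequences)),
                               names(bc$sequences))
    seqs2 <- bc$sequences
    names(seqs2) <- relabel[names(seqs2)]
    map2 <- stats::setNames(unname(bc$speciesMap), unname(relabel))
    res_r <- callSpeciesGap(identitySearch(seqs2, top_k = 100L), map2)
    expect_equal(res_r[order(res_r$species), c("min_intra", "max_inter",
                                               "gap_present")],
                 res[order(res$species), c("min_intra", "max_inter",
                                           "gap_present")],
                 ignore_attr = TRUE)
})

test_that("raising intraspecific identity never loses a gap", {
    set.seed(108)
    sp <- stats::setNames(rep(sprintf("S%02d", 1:6), each = 3),
                          sprintf("r%02d", 1:18))
    hits <- do.call(rbind, lapply(names(sp), function(q) {
        subj <- names(sp)
        hitRow(q, subj, ifelse(sp[subj] == sp[q],
                               round(stats::runif(18, 90, 100), 2),
                               round(stats::runif(18, 85, 99), 2)))
    }))
    hits$pident[hits$query_id == hits$subject_id] <- 100
    before <- callSpeciesGap(hits, sp)
    lifted <- hits
    intra <- sp[lifted$query_id] == sp[lifted$subject_id]
    lifted$pident[intra] <- pmin(100, lifted$pident[intra] + 3)
    after <- callSpeciesGap(lifted, sp)
    expect_true(all(!(before$gap_present & !after$gap_present)))
})

test_that("prevalence handles the all-identical degenerate case", {
    s <- strrep("ACGT", 50L)
    seqs <- Biostrings::DNAStringSet(stats::setNames(
        rep(s, 6L), sprintf("r%d", 1:6)))
    sp <- stats::setNames(rep(c("A", "B", "C"), each = 2L), names(seqs))
    res <- callSpeciesGap(identitySearch(seqs, top_k = 100L), sp)
    expect_equal(gapPrevalence(res), 0)
    expect_error(gapPrevalence(res[0, ]), "no species")
})

test_that("top-k equal to database size reproduces exhaustive results", {
    set.seed(109)
    seqs <- Biostrings::DNAStringSet(stats::setNames(
        replicate(8L, randSeq(150L)), sprintf("k%d", 1:8)))
    full <- identitySearch(seqs, top_k = 8L)
    huge <- identitySearch(seqs, top_k = 1000L)
    expect_identical(full, huge)
})
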