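test_that("simulated catalogues honour the config", {
    cfg <- simulationConfig(seed = 301, nSpecies = 100, nCountries = 12,
                            endemicFrac = 0.4, medicalFrac = 0.1)
    cs <- simulateCatalogue(cfg)
    expect_equal(nSpecies(cs$catalogue), 100L)
    expect_equal(nCountries(cs$catalogue), 12L)
    # realized endemic fraction within 1/nSpecies of the target
    expect_lte(abs(mean(isEndemic(cs$catalogue)) - 0.4), 1 / 100)
    expect_identical(unname(isEndemic(cs$catalogue)), cs$truth$endemic)

    all_end <- simulateCatalogue(simulationConfig(seed = 301, nSpecies = 50,
                                                  nCountries = 6,
                                                  endemicFrac = 1))
    expect_true(all(lengths(countriesOf(all_end$catalogue)) == 1L))

    expect_error(simulationConfig(seed = 1, nCountries = 1,
                                  endemicFrac = 0.5), "at least 2 countries")
    expect_error(simulationConfig(seed = 1, intraDivergence = 0.8),
                 "0.75")
    expect_error(simulationConfig(), "mandatory")
})

test_that("identical configs give byte-identical outputs", {
    cfg <- simulationConfig(seed = 302, nSpecies = 15, nCountries = 5,
                            sequenceLength = 120L, defectRate = 0.1)
    a <- simulateCatalogue(cfg)
    b <- simulateCatalogue(cfg)
    expect_identical(countriesOf(a$catalogue), countriesOf(b$catalogue))
    expect_identical(a$truth, b$truth)
    ba <- simulateBarcodes(a$catalogue, cfg)
    bb <- simulateBarcodes(b$catalogue, cfg)
    expect_identical(as.character(ba$sequences), as.character(bb$sequences))
    ra <- simulateRecords(a$catalogue, cfg)
    rb <- simulateRecords(b$catalogue, cfg)
    expect_identical(as.data.frame(ra$records), as.data.frame(rb$records))
})

test_that("zero intraspecific divergence gives identical conspecifics", {
    cfg <- simulationConfig(seed = 303, nSpecies = 6, nCountries = 3,
                            sequenceLength = 150L, intraDivergence = 0,
                            seqsPerSpecies = list(dist = "fixed", mean = 3))
    bc <- simulateBarcodes(simulateCatalogue(cfg)$catalogue, cfg)
    expect_true(all(bc$truth$intraPairs$divergence == 0))
    pr <- bc$truth$intraPairs[1L, ]
    r <- alignIdentity(as.character(bc$sequences[[pr$id1]]),
                       as.character(bc$sequences[[pr$id2]]))
    expect_equal(r$pident, 100)
})

test_that("realized conspecific divergence matches the JC expectation", {
    # 20 species x 5 sequences = 200 conspecific pairs
    cfg <- simulationConfig(seed = 304, nSpecies = 20, nCountries = 5,
                            sequenceLength = 658L, intraDivergence = 0.01,
                            seqsPerSpecies = list(dist = "fixed", mean = 5))
    bc <- simulateBarcodes(simulateCatalogue(cfg)$catalogue, cfg)
    d <- bc$truth$intraPairs$divergence
    expect_equal(length(d), 20L * choose(5L, 2L))
    p <- bc$truth$expectedIntraMismatch
    mc_se <- stats::sd(d) / sqrt(length(d))
    expect_lt(abs(mean(d) - p), 3 * mc_se)
})

test_that("ground-truth gap labels agree with pipeline calls when separated", {
    cfg <- simulationConfig(seed = 305, nSpecies = 12, nCountries = 4,
                            sequenceLength = 300L,
                            seqsPerSpecies = list(dist = "fixed", mean = 3))
    bc <- simulateBarcodes(simulateCatalogue(cfg)$catalogue, cfg)
    hits <- identitySearch(bc$sequences, top_k = 100L)
    res <- callSpeciesGap(hits, bc$speciesMap)
    m <- merge(res, bc$truth$gapLabels, by = "species",
               suffixes = c("_call", "_truth"))
    expect_equal(nrow(m), 12L)
    expect_gte(mean(m$gap_present_call == m$gap_present_truth), 0.99)
})

test_that("record inclusion follows the forced-probability limits", {
    cat_s <- simulateCatalogue(simulationConfig(seed = 306, nSpecies = 30,
                                                nCountries = 6))$catalogue
    all_in <- simulateRecords(cat_s, simulationConfig(
        seed = 306, nSpecies = 30, nCountries = 6,
        coverageBetas = c(Inf), sequenceLength = 60L))
    cur <- curateRecords(all_in$records, cat_s, marker = "COI-5P")
    tab <- buildCoverageTable(cur$records, cat_s, unit = "country")
    expect_true(all(tab$coverage_pct == 100))

    none <- simulateRecords(cat_s, simulationConfig(
        seed = 306, nSpecies = 30, nCountries = 6,
        coverageBetas = c(-Inf), sequenceLength = 60L))
    expect_equal(length(none$records), 0L)
})

test_that("defect-free output curates as a no-op", {
    cfg <- simulationConfig(seed = 307, nSpecies = 40, nCountries = 8,
                            sequenceLength = 80L, defectRate = 0)
    cs <- simulateCatalogue(cfg)
    sim <- simulateRecords(cs$catalogue, cfg)
    cur <- curateRecords(sim$records, cs$catalogue, marker = "COI-5P")
    expect_equal(sum(stageTable(cur$report)$rows_removed), 0L)
    expect_setequal(as.data.frame(cur$records)$record_id,
                    sim$truth$expectedSurvivorIds)
})

test_that("defect injection leaves the clean-row ground truth intact", {
    base <- simulationConfig(seed = 308, nSpecies = 40, nCountries = 8,
                             sequenceLength = 80L, defectRate = 0)
    hurt <- simulationConfig(seed = 308, nSpecies = 40, nCountries = 8,
                             sequenceLength = 80L, defectRate = 0.25)
    cs <- simulateCatalogue(base)
    clean <- simulateRecords(cs$catalogue, base)
    dirty <- simulateRecords(cs$catalogue, hurt)
    # same inclusion draw: the pair-level truth is identical
    expect_identical(clean$truth$pairs, dirty$truth$pairs)
    df <- as.data.frame(dirty$records)
    expect_true(all(dirty$truth$expectedSurvivorIds %in% df$record_id))
})
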