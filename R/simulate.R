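#' @include AllClasses.R catalogue.R records.R
NULL

#' Build a simulation configuration
#'
#' Constructs a validated [SimulationConfig-class]. The defaults emulate the
#' scale of the mosquito study system: a catalogue of 3570 species over 317
#' countries, roughly half of the species endemic, about 3.6% flagged
#' medically important, 658-base barcodes, 1% expected intraspecific and 15%
#' expected interspecific divergence, and a geometric sequence-count
#' distribution with mean 5.
#'
#' @param seed Integer seed (mandatory; every generator output is a
#'   deterministic function of the config).
#' @param nSpecies,nCountries,nRegions World dimensions.
#' @param endemicFrac Fraction of single-country species.
#' @param medicalFrac Fraction of medically important species.
#' @param sequenceLength Barcode length in bases.
#' @param intraDivergence,interDivergence Expected substitutions/site within
#'   species and between species centroids, in `[0, 0.75)`.
#' @param seqsPerSpecies list(dist = "fixed"|"geometric", mean = ...).
#' @param coverageBetas True inclusion-model coefficients, intercept first.
#' @param groupSigma SD of the between-region random intercept.
#' @param defectRate Fraction of record rows receiving injected defects.
#' @param marker Marker code stamped on clean records.
#' @return A [SimulationConfig-class].
#' @examples
#' cfg <- simulationConfig(seed = 1, nSpecies = 20, nCountries = 5)
#' @export
simulationConfig <- function(seed, nSpecies = 3570L, nCountries = 317L,
                             nRegions = 7L, endemicFrac = 0.5,
                             medicalFrac = 0.036, sequenceLength = 658L,
                             intraDivergence = 0.01, interDivergence = 0.15,
                             seqsPerSpecies = list(dist = "geometric",
                                                   mean = 5),
                             coverageBetas = c(-1.0, 0.8),
                             groupSigma = 1.0, defectRate = 0,
                             marker = "COI-5P") {
    if (missing(seed)) stop("seed is mandatory")
    obj <- new("SimulationConfig", seed = as.integer(seed),
               nSpecies = as.integer(nSpecies),
               nCountries = as.integer(nCountries),
               nRegions = as.integer(nRegions), endemicFrac = endemicFrac,
               medicalFrac = medicalFrac,
               sequenceLength = as.integer(sequenceLength),
               intraDivergence = intraDivergence,
               interDivergence = interDivergence,
               seqsPerSpecies = seqsPerSpecies,
               coverageBetas = coverageBetas, groupSigma = groupSigma,
               defectRate = defectRate, marker = marker)
    validObject(obj)
    obj
}

setMethod("show", "SimulationConfig", function(object) {
    cat("SimulationConfig: seed", object@seed, "|", object@nSpecies,
        "species x", object@nCountries, "countries x", object@nRegions,
        "regions\n")
    cat("  endemicFrac", object@endemicFrac, "| medicalFrac",
        object@medicalFrac, "| defectRate", object@defectRate, "\n")
    cat("  barcodes:", object@sequenceLength, "bp, intra",
        object@intraDivergence, "inter", object@interDivergence, "\n")
})

# Jukes-Cantor: probability that a site differs after expected divergence d.
.jcMismatch <- function(d) 0.75 * (1 - exp(-4 * d / 3))

.drawCounts <- function(n, spec) {
    if (spec$dist == "fixed") rep(as.integer(round(spec$mean)), n)
    else 1L + stats::rgeom(n, prob = 1 / spec$mean)
}

# Integer-coded sequences (0:3 = A,C,G,T); a substitution replaces the base
# by one of the other three uniformly, the JC transition kernel.
.randSeqInt <- function(L) sample.int(4L, L, replace = TRUE) - 1L

.mutateInt <- function(x, p) {
    idx <- which(stats::runif(length(x)) < p)
    if (length(idx))
        x[idx] <- (x[idx] + sample.int(3L, length(idx),
                                       replace = TRUE)) %% 4L
    x
}

.intToDna <- function(x) paste(c("A", "C", "G", "T")[x + 1L], collapse = "")

#' Simulate a taxonomic catalogue with known ground truth
#'
#' Generates a [TaxonCatalogue-class] whose realized endemic fraction equals
#' `round(endemicFrac * nSpecies) / nSpecies` (within 1/nSpecies of the
#' target), with countries partitioned round-robin into biogeographic
#' regions and medical flags drawn at `medicalFrac`. Identical configs give
#' byte-identical catalogues.
#'
#' @param cfg A [SimulationConfig-class].
#' @return list with `catalogue` ([TaxonCatalogue-class]) and `truth`, a
#'   data.frame (`species`, `n_countries`, `endemic`, `medical`).
#' @export
simulateCatalogue <- function(cfg) {
    stopifnot(is(cfg, "SimulationConfig"))
    set.seed(cfg@seed)
    n <- cfg@nSpecies
    countries <- sprintf("Country%03d", seq_len(cfg@nCountries))
    regions <- stats::setNames(
        rep_len(biogeographicRegions()[seq_len(cfg@nRegions)],
                cfg@nCountries), countries)
    genera <- c("Aedes", "Anopheles", "Culex", "Culiseta", "Mansonia",
                "Psorophora", "Uranotaenia", "Wyeomyia")
    species <- paste(sample(genera, n, replace = TRUE),
                     sprintf("sp%04d", seq_len(n)))
    n_end <- round(cfg@endemicFrac * n)
    endemic <- seq_len(n) %in% sample.int(n, n_end)
    kmax <- min(6L, cfg@nCountries)
    n_ctry <- ifelse(endemic, 1L,
                     sample(seq(2L, max(2L, kmax)), n, replace = TRUE))
    countriesOf <- lapply(n_ctry, function(k) sample(countries, k))
    medical <- stats::runif(n) < cfg@medicalFrac
    long_sp <- rep(species, n_ctry)
    long_ct <- unlist(countriesOf, use.names = FALSE)
    cat_obj <- .newCatalogue(long_sp, long_ct, rep(medical, n_ctry), regions)
    validObject(cat_obj)
    list(catalogue = cat_obj,
         truth = data.frame(species = species, n_countries = n_ctry,
                            endemic = endemic, medical = medical,
                            stringsAsFactors = FALSE))
}

#' Simulate barcode sequences with controlled divergence
#'
#' Star-topology centroid model: a shared root sequence is mutated once per
#' species at `interDivergence` (expected substitutions/site, Jukes-Cantor
#' kernel) to give the species centroid, and each individual sequence
#' mutates the centroid at `intraDivergence`. This gives direct control over
#' the intra- vs interspecific identity structure that the barcode-gap
#' statistic consumes. The generator records every realized conspecific
#' pairwise divergence and, when the total sequence count is at most
#' `maxTruthSeqs`, sequence-level gap ground-truth labels (from exact
#' Hamming divergences).
#'
#' @param cat A [TaxonCatalogue-class] (or character vector of species).
#' @param cfg A [SimulationConfig-class].
#' @param maxTruthSeqs Skip the quadratic gap-label bookkeeping above this
#'   many sequences.
#' @return list with `sequences` (named `DNAStringSet`), `speciesMap` (named
#'   character, record id -> species) and `truth` (list: `intraPairs`
#'   data.frame of realized conspecific divergences,
#'   `expectedIntraMismatch`, the Jukes-Cantor expectation for a conspecific
#'   pair, and `gapLabels` data.frame or NULL).
#' @export
simulateBarcodes <- function(cat, cfg, maxTruthSeqs = 3000L) {
    stopifnot(is(cfg, "SimulationConfig"))
    species <- if (is(cat, "TaxonCatalogue")) speciesNames(cat)
               else as.character(cat)
    set.seed(cfg@seed + 1L)
    L <- cfg@sequenceLength
    p_inter <- .jcMismatch(cfg@interDivergence)
    p_intra <- .jcMismatch(cfg@intraDivergence)
    root <- .randSeqInt(L)
    counts <- .drawCounts(length(species), cfg@seqsPerSpecies)
    N <- sum(counts)
    M <- matrix(0L, nrow = N, ncol = L)
    sp_of <- character(N)
    ids <- character(N)
    r <- 0L
    for (s in seq_along(species)) {
        centroid <- .mutateInt(root, p_inter)
        for (j in seq_len(counts[s])) {
            r <- r + 1L
            M[r, ] <- .mutateInt(centroid, p_intra)
            sp_of[r] <- species[s]
            ids[r] <- sprintf("SIM%06d", r)
        }
    }
    seqs <- Biostrings::DNAStringSet(stats::setNames(
        apply(M, 1L, .intToDna), ids))
    # realized conspecific divergences
    intra <- do.call(rbind, lapply(split(seq_len(N), sp_of), function(rows) {
        if (length(rows) < 2L) return(NULL)
        prs <- utils::combn(rows, 2L)
        data.frame(species = sp_of[prs[1L, ]],
                   id1 = ids[prs[1L, ]], id2 = ids[prs[2L, ]],
                   divergence = vapply(seq_len(ncol(prs)), function(k)
                       mean(M[prs[1L, k], ] != M[prs[2L, k], ]),
                       numeric(1)),
                   stringsAsFactors = FALSE)
    }))
    rownames(intra) <- NULL
    gapLabels <- NULL
    if (N <= maxTruthSeqs) {
        D <- matrix(0, N, N)
        for (i in seq_len(N))
            D[i, ] <- rowSums(M != matrix(M[i, ], N, L, byrow = TRUE)) / L
        spf <- factor(sp_of, levels = unique(sp_of))
        gapLabels <- do.call(rbind, lapply(levels(spf), function(s) {
            rows <- which(sp_of == s)
            if (length(rows) == N) return(NULL) # no heterospecifics
            d_intra <- if (length(rows) > 1L)
                max(D[rows, rows]) else 0
            d_inter <- min(D[rows, -rows, drop = FALSE])
            data.frame(species = s,
                       min_intra_identity = 100 * (1 - d_intra),
                       max_inter_identity = 100 * (1 - d_inter),
                       gap_present = (d_inter - d_intra) > 0,
                       stringsAsFactors = FALSE)
        }))
        rownames(gapLabels) <- NULL
    }
    list(sequences = seqs,
         speciesMap = stats::setNames(sp_of, ids),
         truth = list(
             intraPairs = intra,
             expectedIntraMismatch = .jcMismatch(2 * cfg@intraDivergence),
             gapLabels = gapLabels))
}

#' Simulate a BOLD-style record table with a recoverable inclusion model
#'
#' Every catalogue (species, country) pair is included in the database with
#' probability `plogis(b0 + Z beta + u_region)`, where `Z` are standard
#' normal pair-level covariates (one per non-intercept element of
#' `coverageBetas`) and `u_region ~ N(0, groupSigma^2)`. Included pairs
#' receive sequence counts from `seqsPerSpecies`; sequences come from the
#' same star-topology centroid model as [simulateBarcodes()]. A
#' `defectRate` fraction of rows get injected curation defects (missing
#' sequence, missing country or wrong marker), and a small set of species
#' get extra rows in countries outside their catalogue distribution
#' (inflated country lists) so the species-atomic curation stage is
#' exercised. Defects never touch the clean rows' bookkeeping: curating a
#' defect-free table is a no-op.
#'
#' @param cat A [TaxonCatalogue-class].
#' @param cfg A [SimulationConfig-class].
#' @return list with `records` ([BarcodeRecordSet-class]) and `truth`, a
#'   list: `pairs` (per species-country pair: covariates, `eta`,
#'   `include`), `u` (region intercepts), `defects` (per record id: type or
#'   "clean"), `inflatedSpecies`, `expectedSurvivorIds` (record ids a
#'   correct curation must keep).
#' @export
simulateRecords <- function(cat, cfg) {
    stopifnot(is(cat, "TaxonCatalogue"), is(cfg, "SimulationConfig"))
    set.seed(cfg@seed + 2L)
    long <- data.frame(
        species = rep(cat@species, lengths(cat@countriesOf)),
        country = unlist(cat@countriesOf, use.names = FALSE),
        stringsAsFactors = FALSE)
    long$region <- unname(regionOf(cat, long$country))
    npair <- nrow(long)
    betas <- cfg@coverageBetas
    ncov <- length(betas) - 1L
    Z <- if (ncov > 0L)
        matrix(stats::rnorm(npair * ncov), npair, ncov,
               dimnames = list(NULL, paste0("z", seq_len(ncov))))
    else matrix(0, npair, 0L)
    regions <- sort(unique(long$region))
    u <- stats::setNames(stats::rnorm(length(regions), 0, cfg@groupSigma),
                         regions)
    eta <- betas[1L] + if (ncov > 0L) drop(Z %*% betas[-1L]) else 0
    eta <- eta + u[long$region]
    p <- stats::plogis(eta)
    include <- stats::rbinom(npair, 1L, p) == 1L
    pairs <- cbind(long, as.data.frame(Z),
                   data.frame(eta = unname(eta), include = include))

    inc <- which(include)
    counts <- .drawCounts(length(inc), cfg@seqsPerSpecies)
    rec_sp <- rep(long$species[inc], counts)
    rec_ct <- rep(long$country[inc], counts)
    n <- length(rec_sp)

    # centroid-model sequences for the species that have records
    L <- cfg@sequenceLength
    root <- .randSeqInt(L)
    sp_with <- unique(rec_sp)
    centroids <- lapply(sp_with, function(s)
        .mutateInt(root, .jcMismatch(cfg@interDivergence)))
    names(centroids) <- sp_with
    p_intra <- .jcMismatch(cfg@intraDivergence)
    seqs <- vapply(seq_len(n), function(i)
        .intToDna(.mutateInt(centroids[[rec_sp[i]]], p_intra)), "")

    ids <- sprintf("REC%06d", seq_len(n))
    df <- data.frame(
        record_id = ids, species = rec_sp, country = rec_ct,
        marker = rep(cfg@marker, n), sequence = seqs,
        lat = round(stats::runif(n, -60, 60), 4L),
        lon = round(stats::runif(n, -180, 180), 4L),
        stringsAsFactors = FALSE)
    defects <- stats::setNames(rep("clean", n), ids)

    if (cfg@defectRate > 0 && n > 0L) {
        hit <- which(stats::runif(n) < cfg@defectRate)
        types <- sample(c("missing_sequence", "missing_country",
                          "wrong_marker"), length(hit), replace = TRUE)
        defects[hit] <- types
        df$sequence[hit[types == "missing_sequence"]] <- NA_character_
        df$country[hit[types == "missing_country"]] <- NA_character_
        df$marker[hit[types == "wrong_marker"]] <- "ITS2"
    }

    # inflated country lists: extra rows pushing a species' distinct
    # database countries above its catalogue count (species-atomic removal)
    inflated <- character()
    if (cfg@defectRate > 0 && length(sp_with)) {
        n_inflate <- max(1L, ceiling(cfg@defectRate * length(sp_with) / 4))
        cand <- sample(sp_with, min(n_inflate, length(sp_with)))
        extra <- list()
        for (s in cand) {
            own <- countriesOf(cat, s)
            # countries this species will still show after the row-level
            # defect stages have removed their rows
            ok_row <- df$species == s &
                defects[df$record_id] == "clean" & !is.na(df$country)
            obs <- unique(df$country[ok_row])
            spare <- setdiff(countryNames(cat), own)
            need <- length(own) - length(intersect(obs, own)) + 1L
            if (length(spare) < need) next
            inflated <- c(inflated, s)
            add <- sample(spare, need)
            extra[[s]] <- data.frame(
                record_id = NA_character_, species = s, country = add,
                marker = cfg@marker,
                sequence = vapply(seq_along(add), function(i)
                    .intToDna(.mutateInt(centroids[[s]], p_intra)), ""),
                lat = NA_real_, lon = NA_real_, stringsAsFactors = FALSE)
        }
        if (length(extra)) {
            extra <- do.call(rbind, extra)
            extra$record_id <- sprintf("INF%06d", seq_len(nrow(extra)))
            df <- rbind(df, extra)
            defects <- c(defects, stats::setNames(
                rep("inflated_country", nrow(extra)), extra$record_id))
        }
    }

    records <- BarcodeRecordSet(
        record_id = df$record_id, source = "BOLD",
        species_name = df$species, marker = df$marker,
        sequence = df$sequence, country = df$country,
        latitude = df$lat, longitude = df$lon)
    clean_ids <- names(defects)[defects == "clean"]
    surv <- clean_ids[!(df$species[match(clean_ids, df$record_id)] %in%
                        inflated)]
    list(records = records,
         truth = list(pairs = pairs, u = u, defects = defects,
                      inflatedSpecies = inflated,
                      expectedSurvivorIds = surv))
}
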