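#' @include AllClasses.R records.R
NULL

#' Alignment scoring scheme
#'
#' Default scoring of the internal local aligner: match +2, mismatch -3, gap
#' open -5, gap extend -2 (a gap of length k costs `open + k * extend`),
#' chosen to mimic megablast-like behaviour. Only exact A/C/G/T equality
#' scores a match or counts as an identity; ambiguity codes (N, R, Y, ...)
#' never match.
#'
#' @param match,mismatch Per-column scores (match positive).
#' @param gapOpen,gapExtend Positive gap costs.
#' @return A named list used by [alignIdentity()] and [identitySearch()].
#' @export
alignmentScoring <- function(match = 2L, mismatch = -3L, gapOpen = 5L,
                             gapExtend = 2L) {
    stopifnot(match > 0, mismatch < 0, gapOpen >= 0, gapExtend > 0)
    list(match = as.integer(match), mismatch = as.integer(mismatch),
         gapOpen = as.integer(gapOpen), gapExtend = as.integer(gapExtend))
}

.checkDna <- function(x, what) {
    if (length(x) != 1L || is.na(x) || !nzchar(x))
        stop(what, " must be a non-empty DNA string")
    if (!grepl(paste0("^[", paste(names(Biostrings::IUPAC_CODE_MAP),
                                  collapse = ""), "]+$"), toupper(x)))
        stop(what, " contains non-IUPAC characters")
    toupper(x)
}

.revComp <- function(x) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Pairwise percent identity of two sequences
#'
#' Best local alignment of `seq_a` against both strands of `seq_b` under the
#' affine scoring scheme. The percent identity is
#' `100 * identical columns / alignment length`, where the alignment length
#' counts gap columns (the BLAST pident convention) and only exact-base
#' equality counts as an identity.
#'
#' @param seq_a,seq_b Non-empty IUPAC DNA strings (or length-1
#'   `DNAStringSet`/`DNAString`).
#' @param scoring See [alignmentScoring()].
#' @return Named list: `pident`, `alignment_length`, `strand` (`"+"`/`"-"`,
#'   ties resolved to `"+"`), `score`.
#' @examples
#' alignIdentity(strrep("ACGT", 25), strrep("ACGT", 25))$pident # 100
#' @export
alignIdentity <- function(seq_a, seq_b, scoring = alignmentScoring()) {
    a <- .checkDna(as.character(seq_a), "seq_a")
    b <- .checkDna(as.character(seq_b), "seq_b")
    # canonical argument order => exact symmetry even under alignment ties
    if (a > b) { tmp <- a; a <- b; b <- tmp }
    fwd <- .sw_align_one(a, b, scoring$match, scoring$mismatch,
                         scoring$gapOpen, scoring$gapExtend)
    rev <- .sw_align_one(a, .revComp(b), scoring$match, scoring$mismatch,
                         scoring$gapOpen, scoring$gapExtend)
    use_rev <- rev[["score"]] > fwd[["score"]]
    best <- if (use_rev) rev else fwd
    len <- best[["length"]]
    list(pident = if (len > 0) 100 * best[["identities"]] / len else 0,
         alignment_length = len,
         strand = if (use_rev) "-" else "+",
         score = best[["score"]])
}

#' All-vs-all identity search with top-k hit retention
#'
#' Aligns every sequence against every other (both strands) and, per query,
#' keeps at most `top_k` hits including the self-hit, sorted by percent
#' identity descending — the contract of a BLAST all-vs-all search with
#' `-max_target_seqs`. Identity ties are broken by alignment length
#' (descending, so a full-length total match outranks a short perfect local
#' segment and the self-hit leads its query) and then by subject id, making
#' the output fully deterministic. With `top_k` at least the database size
#' the result is exactly the exhaustive all-pairs table.
#'
#' @param records A curated [BarcodeRecordSet-class] with sequences, or a
#'   named `DNAStringSet` / named character vector of sequences.
#' @param top_k Maximum hits retained per query (default 100).
#' @param scoring See [alignmentScoring()].
#' @return data.frame with columns `query_id`, `subject_id`, `pident`,
#'   `alignment_length`, `strand`.
#' @export
identitySearch <- function(records, top_k = 100L,
                           scoring = alignmentScoring()) {
    if (is(records, "BarcodeRecordSet")) {
        seqs <- recordSequences(records)
    } else if (is(records, "DNAStringSet")) {
        seqs <- records
    } else {
        seqs <- Biostrings::DNAStringSet(records)
    }
    n <- length(seqs)
    if (n < 2L) stop("identitySearch needs at least 2 sequences")
    ids <- names(seqs)
    if (is.null(ids) || anyDuplicated(ids) || anyNA(ids))
        stop("sequences must carry unique names (record ids)")
    mats <- .sw_identity_matrix(
        as.character(seqs), as.character(Biostrings::reverseComplement(seqs)),
        scoring$match, scoring$mismatch, scoring$gapOpen, scoring$gapExtend)
    hits <- vector("list", n)
    for (i in seq_len(n)) {
        pid <- mats$pident[i, ]
        o <- order(-pid, -mats$length[i, ], ids)
        o <- o[seq_len(min(top_k, n))]
        hits[[i]] <- data.frame(
            query_id = ids[i], subject_id = ids[o],
            pident = pid[o],
            alignment_length = mats$length[i, o],
            strand = ifelse(mats$minus[i, o], "-", "+"),
            stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, hits)
    rownames(out) <- NULL
    out
}

#' Per-species DNA barcode gap calls
#'
#' From a hit table (see [identitySearch()]) and a record-to-species map,
#' computes per species the minimum intraspecific identity (over hits whose
#' query and subject are conspecific; self-hits are retained, so a singleton
#' species gets `min_intra = 100`) and the maximum interspecific identity
#' (over heterospecific hits). The barcode gap is present when
#' `min_intra - max_inter > 0` and absent when the difference is zero or
#' negative — so a singleton whose best heterospecific hit is a total match
#' (100%) is called gap-absent. Species with no heterospecific hit in the
#' retained table are called gap-present and flagged `no_inter_hit`
#' (not confusable within the searched neighbourhood).
#'
#' Species represented by more sequences than `top_k` used in the search can
#' have their conspecific tail truncated, which can only raise `min_intra`;
#' a truncation warning names them.
#'
#' @param hits data.frame from [identitySearch()].
#' @param species_of Named character vector mapping record id -> species.
#' @param top_k The `top_k` used in the search (for the truncation warning).
#' @return data.frame with columns `species`, `n_sequences`, `min_intra`,
#'   `max_inter`, `gap_present`, `singleton`, `no_inter_hit`.
#' @export
callSpeciesGap <- function(hits, species_of, top_k = 100L) {
    stopifnot(is.data.frame(hits),
              all(c("query_id", "subject_id", "pident") %in% names(hits)))
    ids <- unique(c(hits$query_id, hits$subject_id))
    unmapped <- setdiff(ids, names(species_of))
    if (length(unmapped))
        stop("records without a species mapping: ",
             paste(utils::head(unmapped, 5L), collapse = ", "))
    qs <- unname(species_of[hits$query_id])
    ss <- unname(species_of[hits$subject_id])
    qids <- unique(hits$query_id)
    n_seq <- table(factor(unname(species_of[qids]),
                          levels = sort(unique(unname(species_of[qids])))))
    sp <- names(n_seq)
    intra <- hits$pident[qs == ss]
    intra_sp <- qs[qs == ss]
    inter <- hits$pident[qs != ss]
    inter_sp <- qs[qs != ss]
    min_intra <- tapply(intra, factor(intra_sp, levels = sp), min)
    max_inter <- tapply(inter, factor(inter_sp, levels = sp), max)
    no_inter <- is.na(max_inter)
    gap <- ifelse(no_inter, TRUE, (min_intra - max_inter) > 0)
    out <- data.frame(
        species = sp,
        n_sequences = as.integer(n_seq),
        min_intra = as.numeric(min_intra),
        max_inter = as.numeric(max_inter),
        gap_present = as.logical(gap),
        singleton = as.integer(n_seq) == 1L,
        no_inter_hit = as.logical(no_inter),
        stringsAsFactors = FALSE)
    trunc_sp <- out$species[out$n_sequences > top_k]
    if (length(trunc_sp))
        warning("top-k truncation may raise min_intra for: ",
                paste(trunc_sp, collapse = ", "))
    rownames(out) <- NULL
    out
}

#' Prevalence of the barcode gap
#'
#' Percentage of species with the gap present, to one decimal (half-up).
#'
#' @param results data.frame from [callSpeciesGap()].
#' @return Numeric percentage.
#' @export
gapPrevalence <- function(results) {
    stopifnot(is.data.frame(results), "gap_present" %in% names(results))
    if (nrow(results) == 0L) stop("no species in gap results")
    .roundHalfUp(100 * sum(results$gap_present) / nrow(results), 1L)
}
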