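---
title: "Auditing DNA barcode reference libraries with BarcodeAudit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing DNA barcode reference libraries with BarcodeAudit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(BarcodeAudit)
```

## The problem

DNA barcoding identifies specimens by comparing a short standard marker
(COI-5P for animals, 658 bp; ITS2 as a nuclear alternative) against a
reference library of sequences from taxonomically identified vouchers. The
usefulness of such a library depends on two things that are rarely
quantified together:

* **coverage** — which fraction of the valid species of a group, per country
  and per biogeographic region, have at least one reference sequence; and
* **diagnosability** — whether each species shows a *barcode gap*, i.e.
  whether its least similar conspecific sequence is still more similar than
  its most similar heterospecific sequence.

`BarcodeAudit` implements a complete, reproducible audit of this kind for a
mosquito-style study system: a taxonomic catalogue defines the universe of
valid names and their country distributions; repository dumps (a BOLD-style
specimen table and a GenBank-style FASTA) are curated against it; coverage
statistics and a country-level modelling table are derived; an internal
aligner performs the all-vs-all identity search behind per-species gap
calls; and binomial GLM/GLMM fits with all-subsets AIC selection relate
coverage and gap presence to country- and species-level predictors. A
deterministic simulator generates catalogues, record tables and barcode
sequences with known ground truth, so each stage is testable without any
download.

## Curation

`curateRecords()` applies a fixed, ordered filter chain and accounts for
every row:

1. keep rows of the requested marker code (e.g. `COI-5P`);
2. drop rows without a sequence;
3. drop rows whose country is missing or fails gazetteer validation —
   coordinates are never used to rescue a missing country, because
   coordinates on records without a country are typically unreliable;
4. drop rows whose species name has no exact match in the catalogue
   (exact binomial equality after whitespace normalization — no fuzzy
   matching, no synonym resolution);
5. drop **all** rows of any species whose distinct surviving-record
   countries outnumber its catalogue countries.

Stage 5 is species-atomic on purpose: a species whose database distribution
exceeds its accepted distribution is suspect as a whole (misidentifications
cannot be localized to single rows), and removing it entirely is also what
guarantees that per-species geographic coverage is at most 1 downstream.
The `CurationReport` records rows in/removed/out and surviving species per
stage; conservation (`rows_in == rows_removed + rows_out`, stages chained)
is enforced by the class validity. Curation is idempotent, and its counts
are invariant under row permutation.

The gazetteer defaults to the catalogue's own country list: the catalogue
is the audit's single authority for what counts as a valid occurrence unit.
Any other canonical list can be passed via `gazetteer=`. Matching is
case-insensitive after whitespace normalization, and unmatched names are
reported, never silently dropped.

Cross-repository reconciliation (`crossReferenceSources()`) partitions
records by accession, case-insensitively and with version suffixes stripped
(`AB123456.1` is `AB123456`) — versioned duplicates would otherwise break
the shared/unique partition. BOLD-style records carrying a GenBank
accession that the GenBank set lacks are flagged `mined_from_genbank`.

## Coverage statistics

Taxonomic coverage of a unit (country or region) is
`100 * n_db_species / n_cat_species`, reported to two decimals. Reported
percentages round half away from zero, matching how such tables are usually
printed; base R's `round()` rounds half to even, so the package uses its
own rounding helper. Units with records but no catalogue species raise an
error rather than producing an infinite coverage. Region rows aggregate
member countries by species-set union, not by sum, so a species recorded in
two countries of one region counts once.

Per-species rows (`buildSpeciesTable()`) carry the predictors of the gap
model: sequence count, mean sequence length in bases, distinct database
countries, catalogue countries, geographic coverage
(`n_db_countries / n_cat_countries`, in (0, 1] after curation), and the
medical-importance flag.

Endemism is *defined* as "catalogue distribution is exactly one country".
The catalogue compiles endemic counts without stating an operational rule;
single-country occurrence is the only rule computable from a
species-country table, and it is applied uniformly.

## The identity engine and the barcode gap

The all-vs-all search (`identitySearch()`) uses an internal Smith-Waterman
local aligner (affine gaps, both strands) written in C++:

* scoring defaults: match +2, mismatch −3, gap open −5, gap extend −2 (a
  gap of length *k* costs `open + k·extend`) — megablast-like behaviour;
  configurable via `alignmentScoring()`;
* `pident = 100 × identical columns / alignment length`, with gap columns
  counted in the denominator (the BLAST pident convention);
* only exact A/C/G/T equality counts as an identity — `N` never matches;
* per query, the top `top_k` hits (default 100, self-hit included) are
  retained, sorted by pident with ties broken by subject id, so output is
  deterministic. With `top_k` at least the database size the table equals
  the exhaustive all-pairs search.

Two numerical choices make results exactly reproducible: each unordered
pair is aligned once (the hit matrix is symmetric by construction), and the
pair is always aligned in a canonical argument order, so co-optimal
alignment ties cannot make `pident(a, b)` differ from `pident(b, a)` or
depend on input order. Strand ties resolve to `+`.

`callSpeciesGap()` computes, per species, the minimum conspecific identity
(`min_intra`) and maximum heterospecific identity (`max_inter`) over the
retained hits; the gap is **present** iff `min_intra − max_inter > 0`, and
absent when the difference is zero or negative. Self-hits are retained
deliberately: a singleton species then gets `min_intra = 100` with no
special case, which reproduces the natural rule for singletons — gap absent
exactly when some heterospecific hit is a total match (100%), present
otherwise. A species with no heterospecific hit in the retained table is
called gap-present and flagged `no_inter_hit` ("not confusable within the
searched neighbourhood"); with the default `top_k = 100` this happens only
in very small databases. Species with more sequences than `top_k` can have
their conspecific tail truncated, which can only raise `min_intra`; the
caller warns per affected species — a fidelity caveat of top-k retention,
not a bug.

## Statistical layer

Coverage is modelled as binomial counts per country — `(covered,
uncovered)` out of `n_cat_species` trials — with a country-level logit
model and a biogeographic-region random intercept
(`fitBinomialGlmm()`, Laplace-approximated ML via `lme4`); gap presence is
a Bernoulli GLM over species (`fitBinomialGlm()`). Count predictors should
be passed through `transformPredictors()` (log(x+1), then z-scored): raw
counts spanning four orders of magnitude make logistic coefficients
unreadable, and the transform is recorded in the fit object. Each fit
exposes coefficients, Wald SEs, odds ratios `exp(β)` with 95% Wald
intervals `exp(β ± 1.96·SE)`, the log-likelihood, the parameter count `k`
(the GLMM counts the random-intercept variance as one parameter), and
`AIC = −2ℓ + 2k` — an identity enforced by the class validity.

`selectModels()` fits all `2^p` additive predictor subsets (intercept-only
included, capped at p = 12), ranks by AIC, and flags subsets with
`ΔAIC < 2` as equally plausible. AIC ties break toward the smaller model.
Subsets that fail to converge keep their row, flagged, but are excluded
from the best-model choice and the ΔAIC baseline. `computeVif()` screens
predictors beforehand (`VIF_j = 1/(1 − R²_j)`); the conventional rule
excludes predictors with VIF ≥ 5, and exact collinearity reports `Inf`
with a warning rather than failing.

Quasi-separation in a GLM (runaway coefficients with fitted probabilities
at 0/1) and non-convergence are flagged on the fit object — the fit is
still returned so a selection table stays complete. A GLMM variance
estimate at the zero boundary is returned with `boundary = TRUE`; in that
limit the fixed effects match the plain GLM.

## The simulator: what it emulates, and what it does not

`simulationConfig()` defaults describe the study system's scale: 3570
species over 317 countries in 7 biogeographic regions, half the species
endemic, 3.6% medically flagged, 658-bp barcodes, and a geometric
sequence-count distribution with mean 5 (most species have few sequences; the
real count distribution has a heavier tail — a handful of widespread
vector species carry thousands of sequences — which the geometric default
deliberately does not reproduce).

`simulateBarcodes()` uses a star topology: one root sequence, one centroid
per species mutated from the root at `interDivergence` expected
substitutions/site under a Jukes-Cantor kernel (each substituted site moves
to one of the other three bases uniformly), and individual sequences
mutated from the centroid at `intraDivergence`. A star topology was chosen
over a coalescent because it gives direct, independent control of the
intra- vs interspecific identity structure, which is exactly what the gap
statistic consumes. Two consequences matter for interpreting tests:

* a conspecific pair diverges along a path of `2·intra`, a heterospecific
  pair along `2·inter + 2·intra`; so equal *parameters* still separate the
  two distributions. The fully overlapping regime — realized conspecific
  and heterospecific divergence identically distributed — is
  `interDivergence = 0` with `intraDivergence > 0`, and that is the regime
  used for the "no gap detectable" checks;
* evolution is substitution-only with equal base frequencies: no indels, no
  rate heterogeneity, no NUMTs, no sequencing error. Passing gap tests
  therefore validate the *decision logic and the search contract*, not
  robustness to alignment-confounding features of real data.

`simulateRecords()` gives the statistical layer a recoverable truth: each
catalogue (species, country) pair enters the database with probability
`plogis(β0 + Zβ + u_region)`, `u_region ~ N(0, σ²)`, with standard normal
pair-level covariates. Defect injection (missing sequence/country, wrong
marker, inflated country lists) exercises every curation stage; the
generator records which rows a correct curation must keep, and curating a
defect-free table is a no-op.

All generator outputs are deterministic functions of the config, seed
included.

## Problem sizes used in the tests

The shipped tests and the acceptance script run the identity engine at 50
sequences × 300 bp (oracle equivalence against an exhaustive all-pairs
search) and 20 species × 5 sequences × 658 bp (both gap regimes); the
statistical recovery uses n = 2000 for the GLM, 20 groups × 100
observations for the GLMM, and 100 replicates of n = 1000 for the
all-subsets selection experiment. These sizes were chosen to estimate each
quantity stably while keeping a full run of the suite in the minutes range.

## A worked example

```{r example, eval = FALSE}
cfg <- simulationConfig(seed = 1, nSpecies = 60, nCountries = 10,
                        defectRate = 0.1)
world <- simulateCatalogue(cfg)
sim <- simulateRecords(world$catalogue, cfg)

cur <- curateRecords(sim$records, world$catalogue, marker = "COI-5P")
stageTable(cur$report)

head(buildCoverageTable(cur$records, world$catalogue, unit = "country"))
buildCoverageTable(cur$records, world$catalogue, unit = "region")

gap_cfg <- simulationConfig(seed = 1, nSpecies = 20, nCountries = 5,
                            seqsPerSpecies = list(dist = "fixed", mean = 5))
bc <- simulateBarcodes(simulateCatalogue(gap_cfg)$catalogue, gap_cfg)
hits <- identitySearch(bc$sequences, top_k = 100)
gapPrevalence(callSpeciesGap(hits, bc$speciesMap))
```

## Known limitations

* The identity engine is an exact Smith-Waterman, not a heuristic
  seed-and-extend search: results are deterministic and complete, but
  quadratic — databases beyond a few thousand sequences become slow.
  Prevalence estimates from heuristic tools on real data can differ by a
  small margin, as they may miss co-optimal or low-identity hits.
* Name-based ITS2 filtering keeps whole records; it does not excise the
  5.8S/28S flanking regions, which inflates identities among ITS2 records
  that include conserved flanks.
* No synonym resolution: records under outdated names are dropped at the
  exact-match stage, which undercounts coverage where nomenclature has
  moved.
* The binomial-counts coverage response treats species within a country as
  independent Bernoulli trials; overdispersion beyond the region random
  intercept is not modelled.
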