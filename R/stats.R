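#' @include AllClasses.R
NULL

#' Variance inflation factors
#'
#' Computes, for each predictor, `VIF_j = 1 / (1 - R^2_j)` where `R^2_j`
#' comes from the least-squares regression of predictor j on all other
#' predictors plus an intercept. Exact collinearity yields `Inf` with a
#' warning. The conventional screening rule excludes predictors with
#' VIF >= 5 before model selection.
#'
#' @param X Numeric matrix or data.frame with at least two predictor columns
#'   and at least `p + 2` rows.
#' @return Named numeric vector of VIFs.
#' @examples
#' set.seed(1)
#' computeVif(matrix(rnorm(200), ncol = 2, dimnames = list(NULL, c("a", "b"))))
#' @export
computeVif <- function(X) {
    X <- as.matrix(X)
    p <- ncol(X)
    if (p < 2L) stop("VIF needs at least 2 predictors")
    if (nrow(X) < p + 2L) stop("VIF needs at least p + 2 observations")
    if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p))
    out <- vapply(seq_len(p), function(j) {
        fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
        tss <- sum((X[, j] - mean(X[, j]))^2)
        rss <- sum(fit$residuals^2)
        r2 <- 1 - rss / tss
        if (r2 > 1 - 1e-10) Inf else 1 / (1 - r2)
    }, numeric(1))
    names(out) <- colnames(X)
    if (any(is.infinite(out)))
        warning("exact collinearity: ",
                paste(names(out)[is.infinite(out)], collapse = ", "))
    out
}

#' Log + z-score predictor transform
#'
#' The transform applied to count predictors before model fitting:
#' `log(x + 1)` followed by z-scoring (centering and scaling to unit SD).
#' Columns with zero variance after the log are centered only.
#'
#' @param X Numeric matrix or data.frame of non-negative predictors.
#' @return Numeric matrix with attributes `center` and `scale` recording the
#'   transform.
#' @export
transformPredictors <- function(X) {
    X <- as.matrix(X)
    if (any(X < 0, na.rm = TRUE)) stop("count predictors must be >= 0")
    L <- log(X + 1)
    ctr <- colMeans(L)
    scl <- apply(L, 2L, stats::sd)
    scl[scl == 0] <- 1
    out <- sweep(sweep(L, 2L, ctr), 2L, scl, "/")
    attr(out, "center") <- ctr
    attr(out, "scale") <- scl
    out
}

# Shared post-processing: derive the audit quantities from a fitted glm or
# merMod object.
.wrapFit <- function(fit, coefs, se, ll, k, converged, diagnostics,
                     transform) {
    or <- exp(coefs)
    z <- coefs / se
    new("BinomialGlmFit",
        coefficients = coefs, se = se, oddsRatios = or,
        ciLower = exp(coefs - 1.96 * se), ciUpper = exp(coefs + 1.96 * se),
        pValues = 2 * stats::pnorm(-abs(z)),
        logLik = ll, k = as.integer(k), aic = -2 * ll + 2 * k,
        converged = converged, diagnostics = diagnostics,
        transform = transform, fit = fit)
}

.asModelFrame <- function(X, n) {
    if (is.null(X)) return(data.frame(row.names = seq_len(n)))
    df <- as.data.frame(X)
    if (is.null(colnames(X)) && ncol(df))
        names(df) <- paste0("x", seq_len(ncol(df)))
    df
}

#' Fit a binomial GLM (logit link)
#'
#' Fits `cbind(successes, trials - successes) ~ X` by iteratively reweighted
#' least squares, with Wald standard errors from the inverse Fisher
#' information. Bernoulli responses are the `trials = 1` special case.
#' Non-convergence or quasi-separation (fitted probabilities numerically at
#' 0/1 with runaway coefficients) is flagged in `converged`/`diagnostics`;
#' the fit is still returned.
#'
#' @param successes Integer successes (or 0/1 outcomes).
#' @param trials Integer trials; `NULL` (default) means Bernoulli.
#' @param X Predictor matrix/data.frame, or `NULL` for intercept-only.
#' @param transform Optional list recording any predictor transform applied
#'   by the caller (stored in the fit object).
#' @return A [BinomialGlmFit-class].
#' @examples
#' f <- fitBinomialGlm(30, 100)
#' coefTable(f) # intercept = logit(0.3)
#' @export
fitBinomialGlm <- function(successes, trials = NULL, X = NULL,
                           transform = list()) {
    if (is.null(trials)) trials <- rep(1L, length(successes))
    stopifnot(length(trials) == length(successes),
              all(trials >= successes), all(successes >= 0))
    df <- .asModelFrame(X, length(successes))
    preds <- names(df)
    df$.succ <- successes
    df$.fail <- trials - successes
    form <- stats::as.formula(paste(
        "cbind(.succ, .fail) ~",
        if (length(preds)) paste(preds, collapse = " + ") else "1"))
    diagnostics <- character()
    fit <- withCallingHandlers(
        stats::glm(form, family = stats::binomial(),
                   data = df, control = stats::glm.control(epsilon = 1e-8,
                                                           maxit = 100L)),
        warning = function(w) {
            diagnostics <<- c(diagnostics, conditionMessage(w))
            invokeRestart("muffleWarning")
        })
    coefs <- stats::coef(fit)
    sm <- summary(fit)$coefficients
    se <- stats::setNames(rep(NA_real_, length(coefs)), names(coefs))
    se[rownames(sm)] <- sm[, 2L] # aliased (all-zero) terms stay NA
    sep <- any(abs(coefs) > 15, na.rm = TRUE) || any(se > 100, na.rm = TRUE)
    if (sep) diagnostics <- c(diagnostics, "possible quasi-separation")
    ll <- as.numeric(stats::logLik(fit))
    k <- attr(stats::logLik(fit), "df")
    .wrapFit(fit, coefs, se, ll, k, fit$converged && !sep, diagnostics,
             transform)
}

#' Fit a random-intercept binomial GLMM
#'
#' Fits `cbind(successes, failures) ~ X + (1 | group)` by Laplace-
#' approximated maximum likelihood. The AIC counts the random-intercept
#' variance as one estimated parameter. A variance estimate at the zero
#' boundary is returned with `boundary = TRUE`, not an error; a single group
#' is a degenerate design and errors.
#'
#' @inheritParams fitBinomialGlm
#' @param group Factor (or coercible) of group labels, at least 2 levels.
#' @return A [BinomialGlmmFit-class] with `sigmaGroup` the random-intercept
#'   variance (sigma^2).
#' @export
fitBinomialGlmm <- function(successes, trials = NULL, X = NULL, group,
                            transform = list()) {
    if (is.null(trials)) trials <- rep(1L, length(successes))
    group <- factor(group)
    if (nlevels(group) < 2L)
        stop("degenerate design: random intercept needs >= 2 groups")
    df <- .asModelFrame(X, length(successes))
    preds <- names(df)
    df$.succ <- successes
    df$.fail <- trials - successes
    df$.grp <- group
    form <- stats::as.formula(paste(
        "cbind(.succ, .fail) ~",
        if (length(preds)) paste(preds, collapse = " + ") else "1",
        "+ (1 | .grp)"))
    diagnostics <- character()
    fit <- withCallingHandlers(
        lme4::glmer(form, family = stats::binomial(), data = df),
        warning = function(w) {
            diagnostics <<- c(diagnostics, conditionMessage(w))
            invokeRestart("muffleWarning")
        },
        message = function(m) {
            diagnostics <<- c(diagnostics, conditionMessage(m))
            invokeRestart("muffleMessage")
        })
    coefs <- lme4::fixef(fit)
    se <- sqrt(diag(as.matrix(stats::vcov(fit))))
    names(se) <- names(coefs)
    ll <- as.numeric(stats::logLik(fit))
    k <- attr(stats::logLik(fit), "df")
    sig2 <- unname(lme4::VarCorr(fit)$.grp[1L, 1L])
    boundary <- lme4::isSingular(fit, tol = 1e-5)
    conv <- !any(grepl("failed to converge", diagnostics))
    base <- .wrapFit(fit, coefs, se, ll, k, conv, diagnostics, transform)
    new("BinomialGlmmFit", base, sigmaGroup = sig2,
        groups = levels(group), boundary = boundary)
}

#' @rdname fit-accessors
setMethod("oddsRatios", "BinomialGlmFit", function(x) x@oddsRatios)

#' @rdname fit-accessors
setMethod("modelAIC", "BinomialGlmFit", function(x) x@aic)

#' @rdname fit-accessors
setMethod("coefTable", "BinomialGlmFit", function(x) {
    data.frame(term = names(x@coefficients),
               coefficient = unname(x@coefficients), se = unname(x@se),
               odds_ratio = unname(x@oddsRatios),
               ci_lower = unname(x@ciLower), ci_upper = unname(x@ciUpper),
               p_value = unname(x@pValues), stringsAsFactors = FALSE)
})

setMethod("show", "BinomialGlmFit", function(object) {
    cat(class(object), "| AIC", format(object@aic, digits = 6),
        "| logLik", format(object@logLik, digits = 6), "| k", object@k,
        if (!object@converged) "| NOT CONVERGED" else "", "\n")
    tb <- coefTable(object)
    tb[, -1L] <- lapply(tb[, -1L], function(v) signif(v, 3L))
    print(tb, row.names = FALSE)
    if (is(object, "BinomialGlmmFit"))
        cat("random-intercept variance:", signif(object@sigmaGroup, 4L),
            if (object@boundary) "(boundary)" else "", "\n")
})

#' All-subsets AIC model selection
#'
#' Fits additive binomial models for every subset of the candidate
#' predictors (the intercept-only model included; `2^p` fits, p <= 12),
#' ranks them by AIC and flags the equally plausible ones (`delta_aic < 2`).
#' With a `group` argument every subset is fitted as a random-intercept GLMM
#' instead of a GLM. Non-converging subsets keep their row, flagged, but are
#' excluded from the best-model choice and the delta-AIC baseline. Ties in
#' AIC are broken toward the smaller model.
#'
#' @inheritParams fitBinomialGlm
#' @param X data.frame/matrix of candidate predictors (max 12 columns).
#' @param group Optional grouping factor: fit GLMMs.
#' @return A [ModelSelectionTable-class].
#' @export
selectModels <- function(successes, trials = NULL, X, group = NULL,
                         transform = list()) {
    X <- as.data.frame(X)
    p <- ncol(X)
    if (p > 12L) stop("all-subsets enumeration capped at 12 predictors")
    subsets <- lapply(0:(2^p - 1L), function(m)
        which(bitwAnd(m, 2^(seq_len(p) - 1L)) > 0L))
    labels <- vapply(subsets, function(s)
        if (!length(s)) "~ 1"
        else paste("~", paste(names(X)[s], collapse = " + ")), "")
    fits <- lapply(subsets, function(s) {
        Xi <- if (length(s)) X[, s, drop = FALSE] else NULL
        tryCatch({
            if (is.null(group)) fitBinomialGlm(successes, trials, Xi,
                                               transform)
            else fitBinomialGlmm(successes, trials, Xi, group, transform)
        }, error = function(e) e)
    })
    names(fits) <- labels
    ok_fit <- !vapply(fits, inherits, logical(1), "error")
    aic <- ifelse(ok_fit, vapply(fits, function(f)
        if (is(f, "BinomialGlmFit")) f@aic else NA_real_, numeric(1)),
        NA_real_)
    conv <- ok_fit & vapply(fits, function(f)
        is(f, "BinomialGlmFit") && f@converged, logical(1))
    k <- ifelse(ok_fit, vapply(fits, function(f)
        if (is(f, "BinomialGlmFit")) as.numeric(f@k) else NA_real_,
        numeric(1)), NA_real_)
    base_aic <- min(aic[conv])
    tb <- data.frame(model = labels, n_predictors = lengths(subsets),
                     k = as.integer(k), aic = aic,
                     delta_aic = aic - base_aic,
                     converged = conv, stringsAsFactors = FALSE)
    tb$plausible <- tb$converged & tb$delta_aic < 2
    ord <- order(tb$aic, tb$n_predictors, !tb$converged)
    tb <- tb[ord, ]
    rownames(tb) <- NULL
    best_candidates <- tb$model[tb$converged]
    obj <- new("ModelSelectionTable", table = tb,
               best = best_candidates[1L], fits = fits[ord])
    validObject(obj)
    obj
}

#' @rdname selection-accessors
setMethod("selectionTable", "ModelSelectionTable", function(x) x@table)

#' @rdname selection-accessors
setMethod("bestModel", "ModelSelectionTable", function(x) x@fits[[x@best]])

setMethod("show", "ModelSelectionTable", function(object) {
    cat("ModelSelectionTable:", nrow(object@table), "candidate models\n")
    cat("best:", object@best, "\n")
    tb <- utils::head(object@table, 10L)
    tb$aic <- round(tb$aic, 2L)
    tb$delta_aic <- round(tb$delta_aic, 2L)
    print(tb, row.names = FALSE)
})
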