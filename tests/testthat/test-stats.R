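test_that("VIF matches the closed form and the car reference", {
    set.seed(201)
    n <- 300L
    x <- stats::rnorm(n)
    v <- as.numeric(scale(stats::resid(stats::lm(stats::rnorm(n) ~ x))))
    u <- as.numeric(scale(x))
    b <- 0.8 * u + 0.6 * v # sample correlation with u exactly 0.8
    X <- cbind(p1 = u, p2 = b)
    vif <- computeVif(X)
    expect_equal(unname(vif), rep(1 / (1 - 0.64), 2L), tolerance = 1e-8)

    # independent reference implementation
    y <- stats::rnorm(n)
    ref <- car::vif(stats::lm(y ~ p1 + p2, data = as.data.frame(X)))
    expect_equal(unname(vif), unname(ref), tolerance = 1e-8)

    # orthogonal predictors
    expect_equal(unname(computeVif(cbind(u, v))), c(1, 1),
                 tolerance = 1e-8)
    # duplicated column
    expect_warning(v2 <- computeVif(cbind(a = u, b = u)), "collinearity")
    expect_true(all(is.infinite(v2)))
})

test_that("intercept-only binomial fit hits the closed form", {
    f <- fitBinomialGlm(30, 100)
    expect_equal(unname(f@coefficients), stats::qlogis(0.3),
                 tolerance = 1e-8)
    expect_equal(unname(oddsRatios(f)), 0.3 / 0.7, tolerance = 1e-8)
    expect_equal(modelAIC(f), -2 * f@logLik + 2 * f@k)
})

test_that("GLM recovers simulated coefficients within Wald error", {
    set.seed(202)
    n <- 2000L
    x <- stats::rnorm(n)
    y <- stats::rbinom(n, 1L, stats::plogis(-1 + 0.8 * x))
    f <- fitBinomialGlm(y, X = data.frame(x = x))
    expect_true(all(abs(f@coefficients - c(-1, 0.8)) < 3 * f@se))
    expect_true(f@converged)
    # Bernoulli fit equals the aggregated binomial fit
    key <- round(x, 1L)
    agg <- stats::aggregate(y, list(key = key), sum)
    tri <- stats::aggregate(rep(1L, n), list(key = key), sum)
    fb <- fitBinomialGlm(agg$x, tri$x, X = data.frame(x = agg$key))
    fe <- fitBinomialGlm(y[order(key)],
                         X = data.frame(x = sort(key)))
    expect_equal(fb@coefficients, fe@coefficients, tolerance = 1e-8)
})

test_that("quasi-separation is flagged, not fatal", {
    x <- c(rep(0, 20L), rep(1, 20L))
    y <- x
    f <- fitBinomialGlm(y, X = data.frame(x = x))
    expect_false(f@converged)
    expect_true(length(f@diagnostics) > 0L)
})

test_that("GLMM recovers variance and fixed effects", {
    set.seed(203)
    g <- rep(seq_len(20L), each = 100L)
    u <- stats::rnorm(20L, 0, 1)
    x <- stats::rnorm(2000L)
    y <- stats::rbinom(2000L, 1L, stats::plogis(-1 + 0.8 * x + u[g]))
    f <- fitBinomialGlmm(y, X = data.frame(x = x), group = g)
    # interval frozen from an independent Laplace reference fit (glmmTMB)
    expect_true(sqrt(f@sigmaGroup) > 0.6 && sqrt(f@sigmaGroup) < 1.4)
    expect_true(all(abs(f@coefficients - c(-1, 0.8)) < 3 * f@se))
    ref <- glmmTMB::glmmTMB(y ~ x + (1 | grp), family = stats::binomial(),
                            data = data.frame(y = y, x = x,
                                              grp = factor(g)))
    expect_equal(unname(f@coefficients), unname(glmmTMB::fixef(ref)$cond),
                 tolerance = 1e-3)
    ref_sig2 <- glmmTMB::VarCorr(ref)$cond$grp[1L, 1L]
    expect_equal(f@sigmaGroup, unname(ref_sig2), tolerance = 0.02)
    expect_equal(modelAIC(f), -2 * f@logLik + 2 * f@k)
})

test_that("GLMM degenerates gracefully", {
    # under a true zero between-group variance the ML estimate sits at the
    # boundary in about half of realizations; this seed realizes the limit
    set.seed(210)
    x <- stats::rnorm(400L)
    y <- stats::rbinom(400L, 1L, stats::plogis(0.3 + 0.5 * x))
    g <- rep(1:8, each = 50L) # no true between-group variance
    fm <- fitBinomialGlmm(y, X = data.frame(x = x), group = g)
    fg <- fitBinomialGlm(y, X = data.frame(x = x))
    expect_lt(fm@sigmaGroup, 1e-3)
    expect_true(fm@boundary)
    expect_equal(fm@coefficients, fg@coefficients, tolerance = 1e-3)
    # GLMM likelihood never below the GLM's when sigma^2 is free
    expect_gte(fm@logLik, fg@logLik - 1e-6)
    expect_error(fitBinomialGlmm(y, X = data.frame(x = x),
                                 group = rep(1L, 400L)), "degenerate")
})

test_that("an all-zero predictor does not change the likelihood", {
    set.seed(205)
    x <- stats::rnorm(500L)
    y <- stats::rbinom(500L, 1L, stats::plogis(0.2 + x))
    f1 <- fitBinomialGlm(y, X = data.frame(x = x))
    f2 <- fitBinomialGlm(y, X = data.frame(x = x, z = rep(0, 500L)))
    expect_equal(f1@logLik, f2@logLik, tolerance = 1e-6)
})

test_that("all-subsets selection enumerates, ranks and flags", {
    set.seed(206)
    z1 <- stats::rnorm(500L)
    z2 <- stats::rnorm(500L)
    y <- stats::rbinom(500L, 1L, stats::plogis(0.8 * z1))
    ms <- selectModels(y, X = data.frame(z1 = z1, z2 = z2))
    tb <- selectionTable(ms)
    expect_equal(nrow(tb), 4L) # 2 predictors -> 4 subsets
    expect_equal(min(tb$delta_aic[tb$converged]), 0)
    expect_identical(tb$plausible, tb$converged & tb$delta_aic < 2)
    # AIC identity holds for every row
    for (f in ms@fits)
        expect_equal(f@aic, -2 * f@logLik + 2 * f@k, tolerance = 1e-9)
    # the true model's predictor is in the best subset
    expect_match(selectionTable(ms)$model[1L], "z1")
})

test_that("predictor transform is log then z-score", {
    X <- cbind(n1 = c(0, 9, 99), n2 = c(1, 1, 1))
    tr <- transformPredictors(X)
    expect_equal(unname(tr[, "n1"]),
                 as.numeric(scale(log(c(0, 9, 99) + 1))))
    expect_true(all(tr[, "n2"] == 0)) # zero variance: centered only
    expect_error(transformPredictors(cbind(a = c(-1, 2, 3), b = 1:3)),
                 ">= 0")
})
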