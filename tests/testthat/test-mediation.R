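test_that("path coefficients match the lm oracle on random data", {
    set.seed(61)
    for (i in 1:5) {
        coh <- mediationCohort(n = 30, a = runif(1, -1, 1),
                               b = runif(1, -1, 1),
                               c_prime = runif(1, -1, 1), seed = 600 + i)
        spec <- mediationSpec("BA46", "BA39")
        fit <- fitPaths(coh, "G", spec)
        ln <- lnAO(coh)
        X <- ln["BA46_GM", ]; Y <- ln["BA39_GM", ]
        M <- colMeans(ln[c("BA46_WM", "BA39_WM"), ])
        m_x <- lm(M ~ X); y_x <- lm(Y ~ X); y_xm <- lm(Y ~ X + M)
        expect_equal(fit$a, unname(coef(m_x)["X"]), tolerance = 1e-10)
        expect_equal(fit$c, unname(coef(y_x)["X"]), tolerance = 1e-10)
        expect_equal(fit$c_prime, unname(coef(y_xm)["X"]), tolerance = 1e-10)
        expect_equal(fit$b, unname(coef(y_xm)["M"]), tolerance = 1e-10)
        expect_equal(fit$p_c, summary(y_x)$coefficients["X", 4],
                     tolerance = 1e-10)
        expect_equal(fit$p_c_prime, summary(y_xm)$coefficients["X", 4],
                     tolerance = 1e-10)
        expect_equal(fit$c, fit$c_prime + fit$a * fit$b, tolerance = 1e-8)
    }
})

test_that("a noiseless chain recovers its construction", {
    # M ~= 2X, Y ~= 3M: a ~ 2, b ~ 3, c ~ 6, c' ~ 0
    set.seed(5)
    n <- 200
    X <- rnorm(n)
    M <- 2 * X + rnorm(n, sd = 0.01)
    Y <- 3 * M + rnorm(n, sd = 0.01)
    coh <- cohortFromValues(list(BA46_GM = X, BA46_WM = M, BA39_WM = M,
                                 BA39_GM = Y))
    fit <- fitPaths(coh, "A", mediationSpec("BA46", "BA39"))
    expect_equal(fit$a, 2, tolerance = 0.01)
    # X and M are near-collinear by construction, so b and c_prime are
    # individually noisier than a and c
    expect_equal(fit$b, 3, tolerance = 0.1)
    expect_equal(fit$c, 6, tolerance = 0.01)
    expect_equal(fit$c_prime, 0, tolerance = 0.3)
})

test_that("independent X and M give a near-zero indirect effect", {
    coh <- mediationCohort(n = 2000, a = 0, b = 0.5, c_prime = 0.3,
                           seed = 77)
    fit <- fitPaths(coh, "G", mediationSpec("BA46", "BA39"))
    expect_lt(abs(fit$indirect), 0.05)
})

test_that("fitPaths guards its preconditions", {
    coh <- mediationCohort(n = 8, seed = 2)
    expect_error(fitPaths(coh, "G", mediationSpec("BA46", "BA39")),
                 "complete cases")
    const <- cohortFromValues(list(BA46_GM = rep(1, 12) + 0 * rnorm(12),
                                   BA46_WM = rnorm(12), BA39_WM = rnorm(12),
                                   BA39_GM = rnorm(12)))
    expect_error(fitPaths(const, "A", mediationSpec("BA46", "BA39")),
                 "degenerate variance")
    expect_error(fitPaths(mediationCohort(n = 20, seed = 3), "G",
                          mediationSpec("BA46", "BA13")),
                 "not in cohort")
})

test_that("bootstrap CI is deterministic given the seed", {
    coh <- mediationCohort(n = 60, seed = 8)
    spec <- mediationSpec("BA46", "BA39")
    b1 <- bootstrapIndirect(coh, "G", spec, n_boot = 300, seed = 99)
    b2 <- bootstrapIndirect(coh, "G", spec, n_boot = 300, seed = 99)
    expect_identical(b1, b2)
    b3 <- bootstrapIndirect(coh, "G", spec, n_boot = 300, seed = 100)
    expect_false(identical(b1$ci_low, b3$ci_low))
    expect_lte(b1$ci_low, b1$ci_high)
})

test_that("classification implements the full/partial/none rules", {
    base <- list(ci_low = 0.1, ci_high = 0.5, p_c_prime = 0.4, p_c = 0.01)
    expect_identical(classifyMediation(base), "full")
    expect_identical(classifyMediation(modifyList(base,
        list(p_c_prime = 0.01))), "partial")
    expect_identical(classifyMediation(modifyList(base,
        list(ci_low = -0.1, ci_high = 0.2))), "none")
    # a significant total effect can be required
    weak_c <- modifyList(base, list(p_c = 0.3))
    expect_identical(classifyMediation(weak_c), "full")
    expect_identical(classifyMediation(weak_c, require_total = TRUE), "none")
})

test_that("panel runs one cell per group and spec and survives bad cells", {
    presets <- tauTdpPresets(seed = 12, mediation = TRUE)
    coh <- simulateCohort(presets)
    med <- runMediationPanel(coh, n_boot = 200, seed = 17)
    expect_identical(nrow(med), 6L)
    expect_setequal(unique(med$group), c("tau_like", "tdp_like"))
    # an unresolvable spec flags its cell and leaves the rest computed
    specs <- c(defaultMediationPanel(), list(mediationSpec("BA99", "BA39")))
    med2 <- runMediationPanel(coh, specs = specs, n_boot = 100, seed = 17)
    expect_identical(nrow(med2), 8L)
    bad <- med2[med2$x_region == "BA99", ]
    expect_true(all(is.na(bad$indirect)))
    expect_match(bad$note[1], "not in cohort")
    expect_true(all(med2$note[med2$x_region != "BA99"] == ""))
})

test_that("panel recovers planted mediation in the coupled group only", {
    presets <- tauTdpPresets(seed = 23, mediation = TRUE)
    coh <- simulateCohort(presets)
    med <- runMediationPanel(coh, n_boot = 500, seed = 29)
    tau <- med$classification[med$group == "tau_like"]
    tdp <- med$classification[med$group == "tdp_like"]
    expect_gte(sum(tau %in% c("full", "partial")), 2)
    expect_true(all(tdp == "none"))
})

test_that("panel results are byte-identical across reruns with one seed", {
    coh <- mediationCohort(n = 50, seed = 41)
    m1 <- runMediationPanel(coh, specs = list(mediationSpec("BA46", "BA39")),
                            n_boot = 200, seed = 7)
    m2 <- runMediationPanel(coh, specs = list(mediationSpec("BA46", "BA39")),
                            n_boot = 200, seed = 7)
    expect_identical(m1, m2)
})
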