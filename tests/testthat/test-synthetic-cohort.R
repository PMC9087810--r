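test_that("generation is deterministic given the seed", {
    cfg <- syntheticGroupConfig(regions = c("BA46", "BA39"), n_subjects = 20,
                                missingness = 0.2, seed = 55)
    c1 <- simulateCohort(cfg)
    c2 <- simulateCohort(cfg)
    expect_identical(cohortToLong(c1), cohortToLong(c2))
})

test_that("missingness removes GM and WM of a region together", {
    cfg <- syntheticGroupConfig(regions = c("BA46", "BA39"), n_subjects = 200,
                                missingness = c(BA46 = 0.5), seed = 66)
    ln <- lnAO(simulateCohort(cfg))
    gm <- is.na(ln["BA46_GM", ]); wm <- is.na(ln["BA46_WM", ])
    expect_identical(gm, wm)                       # co-missing by slide
    expect_true(any(gm))
    expect_false(any(is.na(ln["BA39_GM", ])))      # untouched region complete
})

test_that("missingness rate matches its binomial expectation", {
    cfg <- syntheticGroupConfig(regions = c("BA46", "BA39"),
                                n_subjects = 1000,
                                missingness = c(BA46 = 0.4), seed = 91)
    s <- summarizeNodes(simulateCohort(cfg), "groupA")
    n46 <- s$n[s$region == "BA46" & s$compartment == "GM"]
    # 3.5 binomial SDs around 600
    expect_lt(abs(n46 - 600), 3.5 * sqrt(1000 * 0.4 * 0.6))
})

test_that("configured location and scale are recovered at large n", {
    cfg <- syntheticGroupConfig(regions = "BA11", n_subjects = 10000,
                                node_means = c(BA11_GM = -2.54),
                                node_sds = c(BA11_GM = 1.66), seed = 72)
    s <- summarizeNodes(simulateCohort(cfg), "groupA")
    gm <- s[s$compartment == "GM", ]
    expect_lt(abs(gm$mean_ln_ao - (-2.54)), 0.05)
    expect_lt(abs(gm$sd_ln_ao - 1.66), 0.05)
})

test_that("empirical correlations converge to the configured blocks", {
    regions <- sprintf("R%d", 1:4)
    cfg <- syntheticGroupConfig(regions = regions, n_subjects = 10000,
                                rho_gm = 0.5, rho_wm = 0.4, rho_cross = 0.2,
                                seed = 81)
    g <- buildGraph(simulateCohort(cfg), "groupA", min_pairs = 5)
    e <- graphEdges(g)
    expected <- c(`GM-GM` = 0.5, `WM-WM` = 0.4, `GM-WM` = 0.2)
    for (cl in names(expected))
        expect_lt(max(abs(e$r[e$class == cl] - expected[[cl]])), 0.05)
})

test_that("uncorrelated configuration yields near-zero correlations", {
    cfg <- syntheticGroupConfig(regions = sprintf("R%d", 1:3),
                                n_subjects = 10000, rho_gm = 0, rho_wm = 0,
                                rho_cross = 0, seed = 83)
    e <- graphEdges(buildGraph(simulateCohort(cfg), "groupA"))
    expect_lt(max(abs(e$r)), 0.05)
})

test_that("non-PSD correlation specifications are refused, not repaired", {
    expect_error(
        syntheticGroupConfig(regions = sprintf("R%02d", 1:13),
                             rho_gm = 0.5, rho_wm = 0.5, rho_cross = 0.6),
        "not positive semi-definite")
    expect_error(
        syntheticGroupConfig(regions = c("A", "B"), missingness = 1),
        "missingness")
})

test_that("presets pass validation and encode the group contrast", {
    p <- tauTdpPresets(seed = 3)
    expect_identical(p$tau_like$n_subjects, 53L)
    expect_identical(p$tdp_like$n_subjects, 66L)
    k <- length(p$tau_like$regions)
    cross_tau <- p$tau_like$corr[seq_len(k), k + seq_len(k)]
    cross_tdp <- p$tdp_like$corr[seq_len(k), k + seq_len(k)]
    expect_true(all(cross_tau == 0.45))
    expect_true(all(cross_tdp == 0))
    # per-region missingness mirrors the bundled per-region N
    tab <- ftldRegionParams()
    tau46 <- max(tab$n[tab$region == "BA46" & tab$group == "FTLD-Tau"])
    expect_equal(p$tau_like$missingness[["BA46"]], 1 - tau46 / 53)
})

test_that("preset node parameters come from the bundled summary table", {
    p <- tauTdpPresets(seed = 3)
    tab <- ftldRegionParams()
    tdp <- tab[tab$group == "FTLD-TDP", ]
    expect_equal(p$tdp_like$node_means[["BA11_GM"]],
                 tdp$mean_ln_ao[tdp$region == "BA11" & tdp$compartment == "GM"])
    expect_equal(p$tdp_like$node_sds[["BA39_WM"]],
                 tdp$sd_ln_ao[tdp$region == "BA39" & tdp$compartment == "WM"])
})

test_that("raising the uncoupled preset's cross-rho removes the asymmetry", {
    # same cross-coupling in both groups: no directional excess of GM-WM
    # edge differences beyond chance
    regions <- sprintf("R%02d", 1:13)
    mk <- function(label, seed)
        syntheticGroupConfig(group = label, regions = regions,
                             n_subjects = 60, rho_gm = 0.5, rho_wm = 0.5,
                             rho_cross = 0.45, seed = seed)
    coh <- simulateCohort(list(mk("A", 401), mk("B", 402)))
    cmp <- compareGraphs(buildGraph(coh, "A"), buildGraph(coh, "B"),
                         tail = "one_tailed")
    s <- attr(cmp, "summary")
    gw <- s[s$class == "GM-WM", ]
    expect_lt(abs(diff(gw$n_significant)), 15)
})

test_that("planted mediation chains override the block structure", {
    coh <- mediationCohort(n = 5000, a = 0.7, b = 0.4, c_prime = 0.2,
                           seed = 19)
    fit <- fitPaths(coh, "G", mediationSpec("BA46", "BA39"))
    expect_lt(abs(fit$a - 0.7), 0.06)
    expect_lt(abs(fit$b - 0.4), 0.06)
    expect_lt(abs(fit$c_prime - 0.2), 0.06)
})
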