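test_that("edge weights reproduce closed-form Pearson correlations", {
    vals <- list(BA46_GM = c(0, 1, 2, 3, 4), BA39_GM = c(1, 1, 3, 3, 5),
                 BA22_GM = c(4, 3, 2, 1, 0))
    g <- buildGraph(cohortFromValues(vals), "A", min_pairs = 3)
    e <- graphEdges(g)
    pick <- function(a, b) e$r[(e$node1 == a & e$node2 == b) |
                               (e$node1 == b & e$node2 == a)]
    expect_equal(pick("BA46_GM", "BA39_GM"),
                 pearsonOracle(c(0, 1, 2, 3, 4), c(1, 1, 3, 3, 5)),
                 tolerance = 1e-12)
    expect_equal(pick("BA46_GM", "BA22_GM"), -1)  # exact anti-collinearity
    # identical subject vectors give r = 1
    g2 <- buildGraph(cohortFromValues(list(BA46_GM = 1:4, BA46_WM = 1:4)),
                     "A", min_pairs = 3)
    expect_equal(graphEdges(g2)$r, 1)
})

test_that("edge p-values match the t-distribution correlation test", {
    set.seed(21)
    vals <- list(BA46_GM = rnorm(15), BA39_GM = rnorm(15), BA22_WM = rnorm(15))
    g <- buildGraph(cohortFromValues(vals), "A", min_pairs = 3)
    e <- graphEdges(g)
    for (k in seq_len(nrow(e))) {
        x <- lnAO(cohortFromValues(vals))[e$node1[k], ]
        y <- lnAO(cohortFromValues(vals))[e$node2[k], ]
        ct <- cor.test(x, y)
        expect_equal(e$r[k], unname(ct$estimate), tolerance = 1e-12)
        expect_equal(e$p[k], ct$p.value, tolerance = 1e-12)
    }
})

test_that("pairs below min_pairs are excluded and carry no correlation", {
    vals <- list(BA46_GM = c(1, 2, NA, NA, 3),
                 BA39_GM = c(4, 1, 2, 5, NA))   # only 2 shared subjects
    expect_warning(g <- buildGraph(cohortFromValues(vals), "A",
                                   min_pairs = 3),
                   "all edges excluded")
    e <- graphEdges(g)
    expect_identical(e$n_pairs, 2L)
    expect_false(e$included)
    expect_true(is.na(e$r))
    expect_error(buildGraph(cohortFromValues(vals), "A", min_pairs = 2),
                 "min_pairs")
})

test_that("pairwise-complete correlations equal brute-force recomputation", {
    set.seed(33)
    regions <- sprintf("R%02d", 1:6)
    cfg <- syntheticGroupConfig(regions = regions, n_subjects = 40,
                                missingness = 0.3, seed = 33)
    coh <- simulateCohort(cfg)
    g <- buildGraph(coh, "groupA", min_pairs = 5)
    ln <- lnAO(coh)
    e <- graphEdges(g)
    for (k in seq_len(nrow(e))) {
        x <- ln[e$node1[k], ]; y <- ln[e$node2[k], ]
        ok <- !is.na(x) & !is.na(y)
        expect_identical(e$n_pairs[k], sum(ok))
        expect_identical(e$included[k], sum(ok) >= 5L)
        if (e$included[k])
            expect_equal(e$r[k], pearsonOracle(x[ok], y[ok]),
                         tolerance = 1e-12)
    }
})

test_that("graph construction is invariant to input row order", {
    set.seed(5)
    long <- longFromValues(list(BA46_GM = rnorm(10), BA39_GM = rnorm(10),
                                BA22_WM = rnorm(10)))
    g1 <- buildGraph(cohortAssemble(long), "A", min_pairs = 3)
    g2 <- buildGraph(cohortAssemble(long[sample(nrow(long)), ]), "A",
                     min_pairs = 3)
    e1 <- graphEdges(g1)
    e2 <- graphEdges(g2)
    key <- function(e) paste(pmin(e$node1, e$node2), pmax(e$node1, e$node2))
    expect_equal(e2$r[match(key(e1), key(e2))], e1$r, tolerance = 1e-12)
})

test_that("on complete data, pairwise-complete equals listwise-complete", {
    set.seed(8)
    vals <- list(BA46_GM = rnorm(20), BA39_GM = rnorm(20), BA22_GM = rnorm(20))
    coh <- cohortFromValues(vals)
    g <- buildGraph(coh, "A", min_pairs = 3)
    M <- correlationMatrix(g)
    listwise <- cor(t(lnAO(coh)), use = "complete.obs")
    expect_equal(M[rownames(listwise), colnames(listwise)], listwise,
                 tolerance = 1e-12)
})

test_that("node strength sums incident included weights", {
    # triangle with all r = 0.5: strengths 1.0 (via collinear construction)
    x <- c(1, 2, 3, 4, 5, 6)
    set.seed(2)
    # construct exact weights instead: two edges 0.6 and -0.4 at one node
    vals <- list(A_GM = c(0, 1, 2, 3), B_GM = c(0, 1, 2, 3),
                 C_WM = c(3, 2, 1, 0))
    g <- buildGraph(cohortFromValues(vals), "A", min_pairs = 3)
    st_signed <- nodeStrength(g, "signed")
    st_abs <- nodeStrength(g, "absolute")
    a <- which(st_signed$node == "A_GM")
    expect_equal(st_signed$strength[a], 1 - 1)   # +1 (B) - 1 (C)
    expect_equal(st_abs$strength[a], 2)
})

test_that("strength conservation: sum of strengths is twice the edge total", {
    set.seed(13)
    cfg <- syntheticGroupConfig(regions = sprintf("R%d", 1:5),
                                n_subjects = 25, missingness = 0.2, seed = 13)
    g <- buildGraph(simulateCohort(cfg), "groupA", min_pairs = 5)
    st <- nodeStrength(g)
    e <- graphEdges(g)
    expect_equal(sum(st$strength), 2 * sum(e$r[e$included]),
                 tolerance = 1e-10)
    # isolated nodes have strength zero
    iso <- st$node[st$n_edges == 0]
    expect_true(all(st$strength[st$node %in% iso] == 0))
})

test_that("strength-burden correlation matches a closed-form oracle", {
    set.seed(44)
    coh <- simulateCohort(wmCouplingGradientConfig(n_subjects = 40, seed = 44))
    st <- nodeStrength(buildGraph(coh, "coupled"))
    res <- strengthBurdenCorrelation(st, "WM")
    wm <- st[st$compartment == "WM", ]
    expect_equal(res$r, pearsonOracle(wm$strength, wm$burden),
                 tolerance = 1e-12)
    expect_identical(res$n_nodes, nrow(wm))
    # burden exactly proportional to strength -> r = 1
    fake <- data.frame(node = letters[1:4], region = letters[1:4],
                       compartment = "GM", strength = 1:4, n_edges = 1L,
                       burden = 2 * (1:4))
    expect_equal(strengthBurdenCorrelation(fake, "GM")$r, 1)
    # constant burden -> undefined
    fake$burden <- 1
    expect_error(strengthBurdenCorrelation(fake, "GM"), "zero variance")
})

test_that("edge-list export round-trips at full precision and thresholds", {
    set.seed(3)
    vals <- list(A_GM = rnorm(8), B_GM = rnorm(8), C_WM = rnorm(8))
    g <- buildGraph(cohortFromValues(vals), "A", min_pairs = 3)
    tf <- withr::local_tempfile(fileext = ".tsv")
    exportGraph(g, tf, "edge_tsv")
    back <- readEdgeTable(tf)
    e <- graphEdges(g)
    expect_identical(back$r, e$r[e$included])
    expect_identical(back$n_pairs, e$n_pairs[e$included])
    # |r| threshold keeps only strong edges
    exportGraph(g, tf, "edge_tsv", abs_r_min = max(abs(e$r)) - 1e-9)
    expect_identical(nrow(readEdgeTable(tf)), 1L)
    # graphml parses and carries attributes
    tg <- withr::local_tempfile(fileext = ".graphml")
    exportGraph(g, tg, "graphml")
    ig <- igraph::read_graph(tg, format = "graphml")
    expect_equal(igraph::vcount(ig), 3)
    expect_true("r" %in% igraph::edge_attr_names(ig))
})

test_that("degenerate graphs are rejected or flagged", {
    one <- cohortFromValues(list(A_GM = rnorm(5)))
    expect_error(buildGraph(one, "A"), "fewer than 2 nodes")
    sparse <- cohortFromValues(list(A_GM = c(1, 2, NA, NA),
                                    B_GM = c(NA, NA, 1, 2)))
    expect_warning(g <- buildGraph(sparse, "A", min_pairs = 3),
                   "all edges excluded")
    expect_identical(sum(graphEdges(g)$included), 0L)
})
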