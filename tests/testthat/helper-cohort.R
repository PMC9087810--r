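# Builders for small in-code fixtures.

# long table with one group; `values` is a named list node -> numeric vector
# over subjects (NA = missing measurement)
longFromValues <- function(values, group = "A", subjects = NULL) {
    n <- max(lengths(values))
    if (is.null(subjects)) subjects <- sprintf("s%02d", seq_len(n))
    rows <- lapply(names(values), function(nd) {
        reg <- sub("_(GM|WM)$", "", nd)
        comp <- sub("^.*_(GM|WM)$", "\\1", nd)
        v <- rep(NA_real_, n)                  # shorter nodes pad with NA
        v[seq_along(values[[nd]])] <- values[[nd]]
        data.frame(subject = subjects, group = group, region = reg,
                   compartment = comp, pct_ao = exp(v),
                   stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
    df[!is.na(df$pct_ao), , drop = FALSE]
}

cohortFromValues <- function(values, group = "A", subjects = NULL)
    cohortAssemble(longFromValues(values, group, subjects))

# two-node-pair mediation cohort: regions X ("BA46") and Y ("BA39"), with a
# planted chain; no missingness
mediationCohort <- function(n = 100, a = 0.5, b = 0.5, c_prime = 0,
                            noise_sd = 1, seed = 1) {
    cfg <- syntheticGroupConfig(
        group = "G", regions = c("BA46", "BA39"), n_subjects = n,
        rho_gm = 0, rho_wm = 0, rho_cross = 0,
        mediation_triples = list(list(x_region = "BA46", y_region = "BA39",
                                      a = a, b = b, c_prime = c_prime,
                                      noise_sd = noise_sd)),
        seed = seed)
    simulateCohort(cfg)
}

# independently coded two-sample Fisher r-to-z oracle (kept free of the
# package's compareEdge implementation)
fisherOracle <- function(r1, n1, r2, n2, tail = "two_tailed") {
    z1 <- 0.5 * log((1 + r1) / (1 - r1))
    z2 <- 0.5 * log((1 + r2) / (1 - r2))
    se <- sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
    z <- (z1 - z2) / se
    p <- 2 * pnorm(-abs(z))         # upper-tail form keeps tiny p accurate
    if (tail == "one_tailed") p <- p / 2
    list(z = z, p = p)
}

# closed-form Pearson correlation, written out from the definition
pearsonOracle <- function(x, y) {
    dx <- x - sum(x) / length(x)
    dy <- y - sum(y) / length(y)
    sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}
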