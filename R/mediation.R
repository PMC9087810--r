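#' Define a mediation triple (X, M, Y)
#'
#' X and Y are gray-matter nodes; the mediator M is the per-subject mean of
#' ln(\%AO) over a set of white-matter nodes, by default the WM adjacent to
#' the X and Y regions — a proxy for the long-range tracts connecting the
#' two cortical regions.
#'
#' @param x_region region code of the predictor GM node (e.g. \code{"BA11"})
#' @param y_region region code of the outcome GM node (e.g. \code{"BA39"})
#' @param m_regions region codes whose WM measurements are averaged into the
#'   mediator; default \code{c(x_region, y_region)}
#' @return a \code{MediationSpec} (list with x_node, y_node, m_nodes)
#' @examples
#' mediationSpec("BA11", "BA39")
#' @export
mediationSpec <- function(x_region, y_region,
                          m_regions = c(x_region, y_region)) {
    stopifnot(is.character(x_region), is.character(y_region),
              length(m_regions) >= 1)
    if (x_region == y_region) stop("x_region and y_region must differ")
    structure(list(x_node = .nodeName(x_region, "GM"),
                   y_node = .nodeName(y_region, "GM"),
                   m_nodes = .nodeName(unique(m_regions), "WM"),
                   x_region = x_region, y_region = y_region),
              class = "MediationSpec")
}

# complete-case X, mediator (mean of m-node ln values) and Y for one group
.extractXMY <- function(cohort, group, spec) {
    if (!group %in% cohortGroups(cohort))
        stop("unknown group: ", group)
    ln <- lnAO(cohort)[, colData(cohort)$group == group, drop = FALSE]
    need <- c(spec$x_node, spec$y_node, spec$m_nodes)
    absent <- setdiff(need, rownames(ln))
    if (length(absent))
        stop("node(s) not in cohort: ", paste(absent, collapse = ", "))
    X <- ln[spec$x_node, ]
    Y <- ln[spec$y_node, ]
    Mmat <- ln[spec$m_nodes, , drop = FALSE]
    M <- colMeans(Mmat)                     # NA unless every m node observed
    ok <- !is.na(X) & !is.na(M) & !is.na(Y)
    data.frame(X = X[ok], M = M[ok], Y = Y[ok], row.names = NULL)
}

# closed-form OLS paths on complete cases; normal-equation solve, t tests
.pathsFromXMY <- function(X, M, Y) {
    n <- length(X)
    x <- X - mean(X); m <- M - mean(M); y <- Y - mean(Y)
    Sxx <- sum(x^2); Smm <- sum(m^2); Syy <- sum(y^2)
    Sxm <- sum(x * m); Sxy <- sum(x * y); Smy <- sum(m * y)
    det2 <- Sxx * Smm - Sxm^2
    if (Sxx <= 1e-12 || Smm <= 1e-12 || Syy <= 1e-12 || det2 <= 1e-12 * Sxx * Smm)
        stop("degenerate variance in X, M or Y")
    a <- Sxm / Sxx
    cc <- Sxy / Sxx
    c_prime <- (Smm * Sxy - Sxm * Smy) / det2
    b <- (Sxx * Smy - Sxm * Sxy) / det2
    # standard errors
    rss_a <- Smm - a * Sxm
    rss_c <- Syy - cc * Sxy
    rss_cb <- Syy - c_prime * Sxy - b * Smy
    se_a <- sqrt(max(rss_a, 0) / (n - 2) / Sxx)
    se_c <- sqrt(max(rss_c, 0) / (n - 2) / Sxx)
    sig2 <- max(rss_cb, 0) / (n - 3)
    se_cp <- sqrt(sig2 * Smm / det2)
    se_b <- sqrt(sig2 * Sxx / det2)
    p_t <- function(est, se, df)
        if (se == 0) as.numeric(est == 0) else
            2 * stats::pt(abs(est / se), df = df, lower.tail = FALSE)
    list(a = a, b = b, c = cc, c_prime = c_prime, indirect = a * b,
         n_complete = n,
         p_a = p_t(a, se_a, n - 2), p_c = p_t(cc, se_c, n - 2),
         p_b = p_t(b, se_b, n - 3), p_c_prime = p_t(c_prime, se_cp, n - 3))
}

#' Fit the mediation path models for one group
#'
#' Three ordinary-least-squares fits on the identical complete-case subject
#' set: \code{M ~ X} (slope a), \code{Y ~ X} (total effect c), and
#' \code{Y ~ X + M} (direct effect c' and mediator slope b). Without an
#' X-by-M interaction the decomposition \code{c = c' + a*b} is an exact
#' algebraic identity of the fits.
#'
#' @param cohort a [PathologyCohort]
#' @param group group label
#' @param spec a [mediationSpec()]
#' @param min_n minimum complete-case subjects (default 10)
#' @return list with \code{a, b, c, c_prime, indirect, n_complete} and
#'   two-tailed slope p-values \code{p_a, p_b, p_c, p_c_prime}
#' @export
fitPaths <- function(cohort, group, spec, min_n = 10) {
    stopifnot(inherits(spec, "MediationSpec"))
    d <- .extractXMY(cohort, group, spec)
    if (nrow(d) < min_n)
        stop(sprintf("only %d complete cases (< %d) for %s -> %s",
                     nrow(d), min_n, spec$x_node, spec$y_node))
    .pathsFromXMY(d$X, d$M, d$Y)
}

# vectorised a*b over B resamples given an n x B index matrix
.bootAB <- function(X, M, Y, idx) {
    n <- nrow(idx)
    Xb <- matrix(X[idx], n); Mb <- matrix(M[idx], n); Yb <- matrix(Y[idx], n)
    mx <- colMeans(Xb); mm <- colMeans(Mb); my <- colMeans(Yb)
    Sxx <- colSums(Xb^2) - n * mx^2
    Smm <- colSums(Mb^2) - n * mm^2
    Sxm <- colSums(Xb * Mb) - n * mx * mm
    Sxy <- colSums(Xb * Yb) - n * mx * my
    Smy <- colSums(Mb * Yb) - n * mm * my
    det2 <- Sxx * Smm - Sxm^2
    ok <- Sxx > 1e-12 & Smm > 1e-12 & det2 > 1e-12 * pmax(Sxx * Smm, 1e-300)
    a <- Sxm / Sxx
    b <- (Sxx * Smy - Sxm * Sxy) / det2
    list(ab = a * b, ok = ok)
}

#' Percentile-bootstrap confidence interval for the indirect effect
#'
#' Resamples subjects with replacement (X, M, Y drawn jointly), recomputes
#' the indirect effect \code{a*b} in each resample, and reports the
#' percentile interval. Bootstrapping the product avoids the normality
#' assumption that fails for products of coefficients at modest n.
#' Degenerate resamples (zero variance) are redrawn, counted, and capped at
#' ten times \code{n_boot} total draws.
#'
#' @inheritParams fitPaths
#' @param n_boot bootstrap resamples (default 1000)
#' @param ci_level confidence level (default 0.95)
#' @param seed integer seed; identical inputs and seed give identical
#'   intervals
#' @return list with \code{indirect} (full-sample point estimate),
#'   \code{ci_low}, \code{ci_high}, \code{n_boot}, \code{n_redrawn},
#'   \code{seed}
#' @export
bootstrapIndirect <- function(cohort, group, spec, n_boot = 1000,
                              ci_level = 0.95, seed = NULL, min_n = 10) {
    stopifnot(inherits(spec, "MediationSpec"))
    d <- .extractXMY(cohort, group, spec)
    if (nrow(d) < min_n)
        stop(sprintf("only %d complete cases (< %d)", nrow(d), min_n))
    fit <- .pathsFromXMY(d$X, d$M, d$Y)
    if (!is.null(seed)) set.seed(seed)
    n <- nrow(d)
    ab <- numeric(0)
    drawn <- 0L; redrawn <- 0L
    need <- n_boot
    while (need > 0 && drawn < 10L * n_boot) {
        take <- min(need, n_boot)
        idx <- matrix(sample.int(n, n * take, replace = TRUE), n, take)
        res <- .bootAB(d$X, d$M, d$Y, idx)
        ab <- c(ab, res$ab[res$ok])
        redrawn <- redrawn + sum(!res$ok)
        drawn <- drawn + take
        need <- n_boot - length(ab)
    }
    if (length(ab) < n_boot)
        stop("could not obtain ", n_boot, " non-degenerate resamples")
    alpha <- 1 - ci_level
    qs <- unname(stats::quantile(ab, c(alpha / 2, 1 - alpha / 2)))
    list(indirect = fit$indirect, ci_low = qs[1], ci_high = qs[2],
         n_boot = n_boot, n_redrawn = redrawn, seed = seed)
}

#' Classify a mediation result as full, partial, or none
#'
#' The indirect effect is called significant when its bootstrap CI excludes
#' zero. If it is not, there is no mediation. If it is, the mediation is
#' full when the direct effect c' is no longer significant at \code{alpha},
#' and partial when a significant residual X-Y relationship remains. With
#' \code{require_total = TRUE}, full/partial additionally require a
#' significant total effect c (the classical premediated-relationship
#' requirement); the modern default does not.
#'
#' @param result list with \code{ci_low}, \code{ci_high}, \code{p_c_prime},
#'   \code{p_c} (as produced by [runMediation()])
#' @param alpha significance threshold (default 0.05)
#' @param require_total require a significant total effect for full/partial
#' @return \code{"full"}, \code{"partial"} or \code{"none"}
#' @export
classifyMediation <- function(result, alpha = 0.05, require_total = FALSE) {
    if (result$ci_low <= 0 && result$ci_high >= 0)
        return("none")
    if (require_total && result$p_c >= alpha)
        return("none")
    if (result$p_c_prime >= alpha) "full" else "partial"
}

#' Run one complete mediation analysis
#'
#' Path fits, percentile bootstrap of the indirect effect, and
#' classification, for one (group, triple) cell.
#'
#' @inheritParams bootstrapIndirect
#' @param alpha significance threshold for classification
#' @param require_total see [classifyMediation()]
#' @return one-row \code{data.frame}: group, x_region, y_region,
#'   n_complete, a, b, c, c_prime, indirect, ci_low, ci_high, p_c,
#'   p_c_prime, classification, n_boot, seed
#' @export
runMediation <- function(cohort, group, spec, n_boot = 1000,
                         ci_level = 0.95, seed = NULL, alpha = 0.05,
                         require_total = FALSE, min_n = 10) {
    fit <- fitPaths(cohort, group, spec, min_n = min_n)
    bt <- bootstrapIndirect(cohort, group, spec, n_boot = n_boot,
                            ci_level = ci_level, seed = seed, min_n = min_n)
    res <- c(fit, bt[c("ci_low", "ci_high")])
    data.frame(group = group, x_region = spec$x_region,
               y_region = spec$y_region, n_complete = fit$n_complete,
               a = fit$a, b = fit$b, c = fit$c, c_prime = fit$c_prime,
               indirect = fit$indirect, ci_low = bt$ci_low,
               ci_high = bt$ci_high, p_c = fit$p_c,
               p_c_prime = fit$p_c_prime,
               classification = classifyMediation(res, alpha = alpha,
                                                  require_total = require_total),
               n_boot = n_boot, seed = if (is.null(seed)) NA_integer_ else seed,
               note = "", stringsAsFactors = FALSE)
}

#' Default anterior-to-posterior mediation panel
#'
#' Predictors are the three anterior frontotemporal core regions
#' (orbitofrontal BA11, midfrontal BA46, superior temporal BA22), the
#' outcome is the posterior parietal angular gyrus (BA39), and the mediator
#' averages the WM of each X region with BA39 WM.
#'
#' @return list of [mediationSpec()]s
#' @export
defaultMediationPanel <- function() {
    lapply(c("BA11", "BA46", "BA22"), mediationSpec, y_region = "BA39")
}

#' Run a mediation panel over groups and triples
#'
#' One [runMediation()] per (group, spec). A cell that cannot be computed
#' (unresolvable nodes, too few complete cases, degenerate variance) is
#' flagged in its \code{note} column with \code{NA} estimates; the rest of
#' the panel still runs. Per-cell seeds are derived deterministically from
#' \code{seed}.
#'
#' @inheritParams runMediation
#' @param groups group labels (default: all groups in the cohort)
#' @param specs list of [mediationSpec()]s (default
#'   [defaultMediationPanel()])
#' @return \code{data.frame}, one row per (group, spec)
#' @export
runMediationPanel <- function(cohort, groups = NULL,
                              specs = defaultMediationPanel(),
                              n_boot = 1000, ci_level = 0.95, seed = NULL,
                              alpha = 0.05, require_total = FALSE,
                              min_n = 10) {
    if (is.null(groups)) groups <- cohortGroups(cohort)
    cells <- expand.grid(si = seq_along(specs), gi = seq_along(groups))
    rows <- lapply(seq_len(nrow(cells)), function(k) {
        g <- groups[cells$gi[k]]; sp <- specs[[cells$si[k]]]
        cell_seed <- if (is.null(seed)) NULL else (seed + k) %% .Machine$integer.max
        tryCatch(
            runMediation(cohort, g, sp, n_boot = n_boot,
                         ci_level = ci_level, seed = cell_seed,
                         alpha = alpha, require_total = require_total,
                         min_n = min_n),
            error = function(e) data.frame(
                group = g, x_region = sp$x_region, y_region = sp$y_region,
                n_complete = NA_integer_, a = NA_real_, b = NA_real_,
                c = NA_real_, c_prime = NA_real_, indirect = NA_real_,
                ci_low = NA_real_, ci_high = NA_real_, p_c = NA_real_,
                p_c_prime = NA_real_, classification = NA_character_,
                n_boot = n_boot,
                seed = if (is.null(cell_seed)) NA_integer_ else cell_seed,
                note = conditionMessage(e), stringsAsFactors = FALSE))
    })
    do.call(rbind, rows)
}
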