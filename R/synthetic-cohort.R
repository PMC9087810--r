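#' Published regional summary parameters for the two proteinopathy groups
#'
#' Group-level summary statistics of regional digital pathology (per-node N,
#' mean and SD of ln \%AO) for an FTLD-Tau group (N = 53) and an FTLD-TDP
#' group (N = 66) across the 13 core cortical regions. These are the default
#' location/scale/missingness parameters of the synthetic-cohort generator;
#' they parameterise group summary tables, not individual subjects, so any
#' cohort drawn from them is synthetic.
#'
#' @return \code{data.frame} with \code{region}, \code{compartment},
#'   \code{group} (\code{"FTLD-Tau"}/\code{"FTLD-TDP"}), \code{n_group}
#'   (group size), \code{n} (available measurements), \code{mean_ln_ao},
#'   \code{sd_ln_ao}
#' @export
ftldRegionParams <- function() {
    # region, compartment, tau n/mean/sd, tdp n/mean/sd
    raw <- list(
        list("BA13", "GM", 11,  0.96, 1.75, 17, -2.15, 1.18),
        list("BA13", "WM", 11,  1.04, 1.84, 18, -3.71, 1.25),
        list("BA11", "GM", 34,  0.01, 1.28, 60, -2.54, 1.66),
        list("BA11", "WM", 34, -0.37, 1.13, 62, -4.74, 1.69),
        list("BA9",  "GM", 10,  1.96, 2.51, 12, -3.29, 1.50),
        list("BA9",  "WM", 11,  1.19, 2.36, 13, -4.42, 1.69),
        list("BA44", "GM", 10,  2.26, 2.37,  7, -2.56, 1.23),
        list("BA44", "WM", 10,  1.83, 2.48,  8, -3.50, 1.15),
        list("BA45", "GM",  6,  0.92, 2.13, 13, -2.76, 1.28),
        list("BA45", "WM",  9,  0.37, 2.33, 14, -4.40, 1.70),
        list("BA46", "GM", 42,  0.94, 2.07, 52, -2.94, 1.38),
        list("BA46", "WM", 42,  0.41, 2.94, 56, -4.58, 1.96),
        list("BA24", "GM", 29,  0.79, 3.03, 54, -2.41, 1.50),
        list("BA24", "WM", 31, -0.11, 3.75, 59, -4.74, 1.83),
        list("BA32", "GM",  7,  1.48, 3.67, 12, -2.55, 0.97),
        list("BA32", "WM",  9,  0.81, 3.73, 13, -4.43, 2.06),
        list("BA20", "GM",  7,  1.44, 4.83, 17, -2.98, 1.92),
        list("BA20", "WM", 11,  0.49, 4.66, 17, -5.09, 2.05),
        list("BA22", "GM", 36, -0.14, 4.55, 54, -2.90, 1.48),
        list("BA22", "WM", 36, -0.55, 4.37, 54, -4.83, 1.98),
        list("BA39", "GM", 33,  0.67, 5.01, 53, -3.05, 1.76),
        list("BA39", "WM", 36, -0.15, 5.01, 57, -5.14, 1.79),
        list("BA23", "GM",  5,  0.82, 5.71,  8, -2.49, 1.72),
        list("BA23", "WM",  3, -0.50, 5.44,  8, -4.96, 1.91),
        list("BA5",  "GM", 16,  0.68, 5.83, 23, -3.28, 1.64),
        list("BA5",  "WM", 15, -0.53, 5.44, 22, -4.69, 1.70))
    m <- do.call(rbind, lapply(raw, function(x)
        data.frame(region = x[[1]], compartment = x[[2]],
                   tau_n = x[[3]], tau_mean = x[[4]], tau_sd = x[[5]],
                   tdp_n = x[[6]], tdp_mean = x[[7]], tdp_sd = x[[8]],
                   stringsAsFactors = FALSE)))
    rbind(
        data.frame(region = m$region, compartment = m$compartment,
                   group = "FTLD-Tau", n_group = 53L, n = m$tau_n,
                   mean_ln_ao = m$tau_mean, sd_ln_ao = m$tau_sd,
                   stringsAsFactors = FALSE),
        data.frame(region = m$region, compartment = m$compartment,
                   group = "FTLD-TDP", n_group = 66L, n = m$tdp_n,
                   mean_ln_ao = m$tdp_mean, sd_ln_ao = m$tdp_sd,
                   stringsAsFactors = FALSE))
}

.coreRegions <- function() unique(ftldRegionParams()$region)

# node order used by the generator: all GM nodes, then all WM nodes
.configNodes <- function(regions)
    c(.nodeName(regions, "GM"), .nodeName(regions, "WM"))

#' Block-exchangeable node correlation matrix
#'
#' Correlation matrix over the generator's node order (all GM nodes then all
#' WM nodes) with a common within-GM correlation, within-WM correlation, and
#' GM-to-WM cross-correlation. This three-parameter family is the minimal
#' structure expressing "coupled vs uncoupled compartments".
#'
#' @param regions region codes
#' @param rho_gm,rho_wm,rho_cross block correlations
#' @return correlation matrix with dimnames in generator node order
#' @export
blockCorrelationMatrix <- function(regions, rho_gm, rho_wm, rho_cross) {
    k <- length(regions)
    R <- matrix(rho_cross, 2 * k, 2 * k)
    R[seq_len(k), seq_len(k)] <- rho_gm
    R[k + seq_len(k), k + seq_len(k)] <- rho_wm
    diag(R) <- 1
    dimnames(R) <- list(.configNodes(regions), .configNodes(regions))
    R
}

#' Configure one synthetic group
#'
#' Specifies a multivariate log-normal group: subjects are drawn from a
#' multivariate normal on the ln(\%AO) scale (so \%AO itself is log-normal
#' and strictly positive) with per-node means/SDs and a block-structured
#' node correlation matrix; region-level missingness then removes both the
#' GM and WM rows of a region for a subject, emulating slide-level tissue
#' availability; optional mediation triples overwrite selected nodes with an
#' explicit linear causal chain.
#'
#' @param group group label
#' @param regions region codes (default: the 13-region core panel)
#' @param n_subjects subjects to draw
#' @param node_means,node_sds named numeric vectors over nodes
#'   (\code{<region>_GM}/\code{<region>_WM}); unnamed scalars recycle;
#'   defaults 0 and 1
#' @param rho_gm,rho_wm,rho_cross block correlations (defaults 0.5, 0.5, 0.3)
#' @param corr_matrix optional full correlation matrix in generator node
#'   order, overriding the blocks
#' @param missingness named per-region probability that a subject lacks that
#'   region's slide (scalar recycles; default 0)
#' @param mediation_triples list of planted chains, each
#'   \code{list(x_region=, y_region=, a=, b=, c_prime=, noise_sd=1)}: after
#'   the correlated draw, each WM node of the X and Y regions is replaced
#'   by \code{a*X + e} (independent noise per node) and the Y GM node by
#'   \code{b*M + c_prime*X + e'} where M is the per-subject average of
#'   those WM nodes — the same aggregate the mediation analysis uses.
#'   Triples apply in list order; a later triple overwrites any node it
#'   shares with an earlier one.
#' @param seed integer seed for [simulateCohort()]
#' @return a \code{SyntheticGroupConfig} (validated list); the implied
#'   correlation matrix must be positive semi-definite, otherwise an error
#'   names the offending blocks rather than silently repairing them
#' @export
syntheticGroupConfig <- function(group = "groupA",
                                 regions = .coreRegions(),
                                 n_subjects = 50,
                                 node_means = 0, node_sds = 1,
                                 rho_gm = 0.5, rho_wm = 0.5, rho_cross = 0.3,
                                 corr_matrix = NULL,
                                 missingness = 0,
                                 mediation_triples = list(),
                                 seed = NULL) {
    stopifnot(n_subjects >= 1, length(regions) >= 1)
    nodes <- .configNodes(regions)
    expand <- function(x, default) {
        out <- stats::setNames(rep(default, length(nodes)), nodes)
        if (length(x) == 1 && is.null(names(x))) {
            out[] <- x
        } else {
            bad <- setdiff(names(x), nodes)
            if (length(bad)) stop("unknown node(s): ", paste(bad, collapse = ", "))
            out[names(x)] <- x
        }
        out
    }
    mu <- expand(node_means, 0)
    sds <- expand(node_sds, 1)
    if (any(sds <= 0)) stop("node_sds must be positive")
    if (is.null(corr_matrix)) {
        R <- blockCorrelationMatrix(regions, rho_gm, rho_wm, rho_cross)
    } else {
        R <- corr_matrix
        stopifnot(nrow(R) == length(nodes), ncol(R) == length(nodes))
        dimnames(R) <- list(nodes, nodes)
    }
    ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8)
        stop(sprintf(paste0("correlation specification is not positive ",
                            "semi-definite (min eigenvalue %.3g); check the ",
                            "rho_gm/rho_wm/rho_cross blocks"), min(ev)))
    pm <- stats::setNames(rep(0, length(regions)), regions)
    if (length(missingness) == 1 && is.null(names(missingness))) {
        pm[] <- missingness
    } else {
        bad <- setdiff(names(missingness), regions)
        if (length(bad)) stop("missingness for unknown region(s): ",
                              paste(bad, collapse = ", "))
        pm[names(missingness)] <- missingness
    }
    if (any(pm < 0 | pm >= 1)) stop("missingness must be in [0, 1)")
    for (tr in mediation_triples) {
        need <- c("x_region", "y_region", "a", "b", "c_prime")
        if (!all(need %in% names(tr)))
            stop("mediation triple needs: ", paste(need, collapse = ", "))
        if (!all(c(tr$x_region, tr$y_region) %in% regions))
            stop("mediation triple regions must be simulated regions")
    }
    structure(list(group = group, regions = regions,
                   n_subjects = as.integer(n_subjects), node_means = mu,
                   node_sds = sds, corr = R, missingness = pm,
                   mediation_triples = mediation_triples, seed = seed),
              class = "SyntheticGroupConfig")
}

.simulateGroup <- function(cfg) {
    if (!is.null(cfg$seed)) set.seed(cfg$seed)
    nodes <- names(cfg$node_means)
    D <- diag(cfg$node_sds)
    Sigma <- D %*% cfg$corr %*% D
    ln <- MASS::mvrnorm(cfg$n_subjects, mu = cfg$node_means, Sigma = Sigma)
    ln <- matrix(ln, nrow = cfg$n_subjects,
                 dimnames = list(NULL, nodes))       # guard n_subjects = 1
    for (tr in cfg$mediation_triples) {
        nsd <- if (is.null(tr$noise_sd)) 1 else tr$noise_sd
        X <- ln[, .nodeName(tr$x_region, "GM")]
        # each mediator node gets its own noise; the causal mediator is
        # their per-subject average, matching the analysis-side definition
        m_nodes <- .nodeName(unique(c(tr$x_region, tr$y_region)), "WM")
        for (mn in m_nodes)
            ln[, mn] <- tr$a * X + stats::rnorm(cfg$n_subjects, sd = nsd)
        Mbar <- rowMeans(ln[, m_nodes, drop = FALSE])
        ln[, .nodeName(tr$y_region, "GM")] <-
            tr$b * Mbar + tr$c_prime * X + stats::rnorm(cfg$n_subjects, sd = nsd)
    }
    # region-level missingness: GM and WM of a region are lost together
    for (rg in cfg$regions) {
        drop <- stats::runif(cfg$n_subjects) < cfg$missingness[[rg]]
        ln[drop, .nodeName(rg, "GM")] <- NA
        ln[drop, .nodeName(rg, "WM")] <- NA
    }
    subj <- sprintf("%s_S%03d", gsub("[^A-Za-z0-9]", "", cfg$group),
                    seq_len(cfg$n_subjects))
    long <- do.call(rbind, lapply(seq_along(nodes), function(j) {
        comp <- sub("^.*_(GM|WM)$", "\\1", nodes[j])
        data.frame(subject = subj, group = cfg$group,
                   region = sub("_(GM|WM)$", "", nodes[j]),
                   compartment = comp, pct_ao = exp(ln[, j]),
                   stringsAsFactors = FALSE)
    }))
    long[!is.na(long$pct_ao), , drop = FALSE]
}

#' Draw a synthetic cohort
#'
#' Simulates one or more groups from their [syntheticGroupConfig()]s and
#' assembles them into a [PathologyCohort]. Deterministic given each
#' config's seed.
#'
#' @param configs a single config or a list of configs (one per group)
#' @return a [PathologyCohort]
#' @examples
#' presets <- tauTdpPresets(seed = 7)
#' coh <- simulateCohort(presets)
#' coh
#' @export
simulateCohort <- function(configs) {
    if (inherits(configs, "SyntheticGroupConfig")) configs <- list(configs)
    stopifnot(length(configs) >= 1,
              all(vapply(configs, inherits, TRUE, "SyntheticGroupConfig")))
    long <- do.call(rbind, lapply(configs, .simulateGroup))
    cohortAssemble(long)
}

#' Stylised two-group presets: coupled vs uncoupled compartments
#'
#' Two configurations reproducing the qualitative contrast between the
#' proteinopathy groups: both have moderate within-GM and within-WM
#' correlation (0.5), but the tau-like group couples GM and WM
#' (\code{rho_cross = 0.45}, n = 53) while the tdp-like group does not
#' (\code{rho_cross = 0}, n = 66). Node means/SDs come from
#' [ftldRegionParams()] and per-region missingness from that table's
#' per-region N (\code{1 - max(N_GM, N_WM)/N_group}). The cross-block rho
#' is stylised (the source correlations exist only as heat maps) and sits
#' inside the positive-semi-definite boundary of the 13-region
#' block-exchangeable family, \code{rho_cross <= (1 + 12*rho)/13 = 0.538}:
#' a cross block as strong as the within blocks times 1.2 is not a valid
#' correlation structure at this dimension.
#'
#' @param seed base seed; the two groups use \code{seed} and \code{seed + 1}
#' @param mediation if \code{TRUE}, the tau-like group additionally plants
#'   the default anterior-to-posterior mediation chains
#'   (X in BA11/BA46/BA22, Y = BA39, a = 0.7, b = 0.7, c' = 0.2)
#' @return named list of two [syntheticGroupConfig()]s
#'   (\code{tau_like}, \code{tdp_like})
#' @export
tauTdpPresets <- function(seed = 1L, mediation = FALSE) {
    tab <- ftldRegionParams()
    mkcfg <- function(grp_src, label, n, rho_cross, seed, triples) {
        t2 <- tab[tab$group == grp_src, , drop = FALSE]
        nodes <- .nodeName(t2$region, t2$compartment)
        byreg <- split(t2$n, t2$region)
        miss <- vapply(byreg, function(x) 1 - max(x) / n, numeric(1))
        syntheticGroupConfig(
            group = label, regions = unique(t2$region), n_subjects = n,
            node_means = stats::setNames(t2$mean_ln_ao, nodes),
            node_sds = stats::setNames(t2$sd_ln_ao, nodes),
            rho_gm = 0.5, rho_wm = 0.5, rho_cross = rho_cross,
            missingness = miss, mediation_triples = triples, seed = seed)
    }
    triples <- if (mediation)
        lapply(c("BA11", "BA46", "BA22"), function(x)
            list(x_region = x, y_region = "BA39", a = 0.7, b = 0.7,
                 c_prime = 0.2, noise_sd = 1))
    else list()
    list(tau_like = mkcfg("FTLD-Tau", "tau_like", 53L, 0.45, seed, triples),
         tdp_like = mkcfg("FTLD-TDP", "tdp_like", 66L, 0.0, seed + 1L,
                          list()))
}

#' Configuration with region-varying GM-WM coupling tied to WM burden
#'
#' A single-group configuration built from an explicit latent-factor model,
#' so the joint correlation matrix is valid by construction: node
#' \code{GM_r = sqrt(0.45) g + 0.6 lambda_r h + noise} and
#' \code{WM_r = sqrt(0.45) w + 0.6 lambda_r h + noise}, where g (GM
#' factor), w (WM factor) and h (the GM-WM coupling factor) are independent
#' standard normals and each region carries a coupling loading
#' \code{lambda_r} on a grid over [0.3, 0.95]. The implied cross-correlation
#' \code{0.36 lambda_r lambda_s} therefore varies by region, and the WM
#' node mean increases linearly with the region's own coupling
#' (\code{-4 + 3 lambda_r}), so WM node strength and WM burden co-vary by
#' design, giving a positive strength-burden correlation for WM nodes.
#'
#' @param n_subjects subjects (default 53)
#' @param seed integer seed
#' @return a [syntheticGroupConfig()]
#' @export
wmCouplingGradientConfig <- function(n_subjects = 53, seed = NULL) {
    regions <- .coreRegions()
    k <- length(regions)
    lambda <- seq(0.3, 0.95, length.out = k)
    base <- 0.45                 # shared within-compartment factor variance
    load <- 0.6 * lambda         # coupling-factor loadings
    within <- base + outer(load, load)
    cross <- outer(load, load)
    R <- rbind(cbind(within, cross), cbind(t(cross), within))
    diag(R) <- 1
    dimnames(R) <- list(.configNodes(regions), .configNodes(regions))
    wm_means <- stats::setNames(-4 + 3 * lambda, .nodeName(regions, "WM"))
    syntheticGroupConfig(group = "coupled", regions = regions,
                         n_subjects = n_subjects,
                         node_means = wm_means, corr_matrix = R, seed = seed)
}
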