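#' Configuration for a full end-to-end analysis run
#'
#' Bundles every analysis choice so that a run is reproducible from its
#' configuration alone. Either an input table or the built-in two-group
#' presets can supply the cohort.
#'
#' @param input path to a cohort table for [loadCohort()], or \code{NULL}
#' @param preset \code{"tau_tdp"} to simulate [tauTdpPresets()] instead of
#'   reading a file, or \code{"none"}
#' @param schema,zero_offset passed to [loadCohort()]
#' @param groups the two group labels to compare (\code{NULL}: first two in
#'   the cohort)
#' @param min_pairs per-edge inclusion threshold (default 5)
#' @param tail edge-comparison tail; graph-difference maps conventionally
#'   use \code{"one_tailed"} (the default here), while scalar statistics are
#'   reported two-tailed
#' @param alpha significance threshold (default 0.05, uncorrected)
#' @param correction \code{"none"} or \code{"bh"}
#' @param n_boot,ci_level mediation bootstrap settings
#' @param mediation plant mediation chains in the tau-like preset group
#' @param subtype_sensitivity rerun the GM+WM comparison leaving each
#'   pathologic subtype out in turn (needs a \code{subtype} column)
#' @param seed integer seed controlling simulation and bootstrap
#' @param out_dir output directory (created if absent)
#' @return a \code{RunConfig} list
#' @export
runConfig <- function(input = NULL, preset = c("none", "tau_tdp"),
                      schema = NULL, zero_offset = 0.001, groups = NULL,
                      min_pairs = 5L, tail = c("one_tailed", "two_tailed"),
                      alpha = 0.05, correction = c("none", "bh"),
                      n_boot = 1000, ci_level = 0.95, mediation = TRUE,
                      subtype_sensitivity = FALSE, seed = 1L,
                      out_dir = "neuropathnet-run") {
    preset <- match.arg(preset)
    if (is.null(input) && preset == "none")
        stop("either 'input' or preset = 'tau_tdp' is required")
    structure(list(input = input, preset = preset, schema = schema,
                   zero_offset = zero_offset, groups = groups,
                   min_pairs = as.integer(min_pairs),
                   tail = match.arg(tail), alpha = alpha,
                   correction = match.arg(correction),
                   n_boot = n_boot, ci_level = ci_level,
                   mediation = mediation,
                   subtype_sensitivity = subtype_sensitivity,
                   seed = as.integer(seed), out_dir = out_dir),
              class = "RunConfig")
}

.writeTsv <- function(df, path)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)

.comparisonTable <- function(cmp) {
    out <- cmp
    out$significant <- as.logical(out$significant)
    out
}

#' Run the full analysis pipeline
#'
#' Executes every stage on one cohort and writes the output bundle to
#' \code{config$out_dir}: per-group node summaries and correlation-matrix
#' CSVs; GM, WM and GM+WM graphs (edge TSV + GraphML); cross-group edge
#' comparisons per graph; node-strength tables with strength-vs-burden
#' statistics; the mediation panel; a \code{summary.json} with
#' significant-edge counts by class and direction; and a
#' \code{provenance.json} (package/R versions, seed, config hash) from
#' which the identical bundle can be regenerated. A stage that fails is
#' recorded in the summary under \code{errors} and downstream stages that
#' depend on it are skipped.
#'
#' @param config a [runConfig()]
#' @param cohort optionally, a ready [PathologyCohort] (overrides
#'   \code{config$input}/\code{preset})
#' @return invisibly, a list with the in-memory results (\code{cohort},
#'   \code{graphs}, \code{comparisons}, \code{strengths},
#'   \code{strength_burden}, \code{mediation}, \code{summary})
#' @export
runFullAnalysis <- function(config, cohort = NULL) {
    stopifnot(inherits(config, "RunConfig"))
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    errors <- list()
    if (is.null(cohort)) {
        cohort <- if (config$preset == "tau_tdp")
            simulateCohort(tauTdpPresets(seed = config$seed,
                                         mediation = config$mediation))
        else loadCohort(config$input, schema = config$schema,
                        zero_offset = config$zero_offset)
    }
    groups <- config$groups
    if (is.null(groups)) groups <- utils::head(cohortGroups(cohort), 2)
    if (length(groups) != 2) stop("exactly two groups are required")
    writeCohort(cohort, file.path(config$out_dir, "cohort.tsv"))

    filters <- list(GM = "GM", WM = "WM", `GM+WM` = c("GM", "WM"))
    graphs <- list(); comparisons <- list()
    strengths <- list(); sb <- list()
    for (g in groups) {
        .writeTsv(summarizeNodes(cohort, g),
                  file.path(config$out_dir,
                            sprintf("node_summary_%s.tsv", g)))
    }
    for (fn in names(filters)) {
        tag <- gsub("\\+", "", fn)
        gs <- lapply(groups, function(g) tryCatch(
            buildGraph(cohort, g, node_filter = filters[[fn]],
                       min_pairs = config$min_pairs),
            error = function(e) e))
        names(gs) <- groups
        bad <- vapply(gs, inherits, TRUE, "error")
        if (any(bad)) {
            errors[[paste0("graph_", tag)]] <-
                paste(groups[bad], vapply(gs[bad], conditionMessage, ""),
                      collapse = "; ")
            next
        }
        graphs[[fn]] <- gs
        for (g in groups) {
            base <- file.path(config$out_dir,
                              sprintf("graph_%s_%s", tag, g))
            exportGraph(gs[[g]], paste0(base, ".tsv"), "edge_tsv")
            exportGraph(gs[[g]], paste0(base, ".graphml"), "graphml")
            utils::write.csv(correlationMatrix(gs[[g]]),
                             paste0(base, "_matrix.csv"), na = "")
        }
        cmp <- tryCatch(
            compareGraphs(gs[[1]], gs[[2]], tail = config$tail,
                          alpha = config$alpha,
                          correction = config$correction),
            error = function(e) e)
        if (inherits(cmp, "error")) {
            errors[[paste0("comparison_", tag)]] <- conditionMessage(cmp)
        } else {
            comparisons[[fn]] <- cmp
            .writeTsv(.comparisonTable(cmp),
                      file.path(config$out_dir,
                                sprintf("comparison_%s.tsv", tag)))
        }
    }
    if (!is.null(graphs[["GM+WM"]])) {
        for (g in groups) {
            st <- nodeStrength(graphs[["GM+WM"]][[g]])
            strengths[[g]] <- st
            .writeTsv(st, file.path(config$out_dir,
                                    sprintf("node_strength_%s.tsv", g)))
            for (comp in c("GM", "WM")) {
                key <- paste(g, comp, sep = "_")
                sb[[key]] <- tryCatch(
                    strengthBurdenCorrelation(st, comp),
                    error = function(e) list(error = conditionMessage(e)))
            }
        }
    } else {
        errors[["node_strength"]] <- "GM+WM graph unavailable"
    }
    med <- tryCatch(
        runMediationPanel(cohort, groups = groups, n_boot = config$n_boot,
                          ci_level = config$ci_level,
                          seed = config$seed, alpha = config$alpha),
        error = function(e) { errors[["mediation"]] <<- conditionMessage(e); NULL })
    if (!is.null(med))
        .writeTsv(med, file.path(config$out_dir, "mediation_panel.tsv"))

    sensitivity <- list()
    if (isTRUE(config$subtype_sensitivity) &&
        "subtype" %in% colnames(colData(cohort))) {
        cd <- colData(cohort)
        for (g in groups) {
            subs <- unique(stats::na.omit(cd$subtype[cd$group == g]))
            for (s in subs) {
                sub_coh <- excludeSubtype(cohort, s)
                gs <- tryCatch(lapply(groups, function(gg)
                    buildGraph(sub_coh, gg, min_pairs = config$min_pairs)),
                    error = function(e) e)
                if (inherits(gs, "error")) next
                cmp <- tryCatch(compareGraphs(gs[[1]], gs[[2]],
                                              tail = config$tail,
                                              alpha = config$alpha),
                                error = function(e) NULL)
                if (is.null(cmp)) next
                tag <- sprintf("excl_%s_%s", g, s)
                sensitivity[[tag]] <- attr(cmp, "summary")
                .writeTsv(.comparisonTable(cmp),
                          file.path(config$out_dir,
                                    sprintf("comparison_GMWM_%s.tsv", tag)))
            }
        }
    }

    summary <- list(
        groups = groups,
        n_subjects = as.integer(table(colData(cohort)$group)[groups]),
        significant_edges = lapply(comparisons, function(x)
            attr(x, "summary")),
        tail = config$tail, alpha = config$alpha,
        min_pairs = config$min_pairs,
        strength_burden = sb,
        mediation_classification = if (!is.null(med))
            stats::setNames(as.list(med$classification),
                            paste(med$group, med$x_region, sep = ":")),
        subtype_sensitivity = sensitivity,
        errors = errors)
    jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)

    cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                                 digits = NA, null = "null")
    cfg_path <- file.path(config$out_dir, "config.json")
    writeLines(cfg_json, cfg_path)
    # the hash covers the analysis choices, not the output location
    hashed <- unclass(config)
    hashed$out_dir <- NULL
    hash_path <- tempfile()
    writeLines(jsonlite::toJSON(hashed, auto_unbox = TRUE, digits = NA,
                                null = "null"), hash_path)
    prov <- list(package = "neuropathNet",
                 version = as.character(utils::packageVersion("neuropathNet")),
                 r_version = paste(R.version$major, R.version$minor, sep = "."),
                 seed = config$seed,
                 config_md5 = unname(tools::md5sum(hash_path)))
    unlink(hash_path)
    jsonlite::write_json(prov, file.path(config$out_dir, "provenance.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    invisible(list(cohort = cohort, graphs = graphs,
                   comparisons = comparisons, strengths = strengths,
                   strength_burden = sb, mediation = med,
                   summary = summary))
}
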