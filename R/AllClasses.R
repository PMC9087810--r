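#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   rowData colData assayNames
NULL

#' PathologyCohort: regional pathology measurements for an autopsy cohort
#'
#' A \linkS4class{SummarizedExperiment} subclass holding percent-area-occupied
#' (\%AO) pathology measurements. Rows are network nodes, i.e. (region,
#' compartment) pairs where compartment is gray matter (\code{"GM"}) or
#' adjacent white matter (\code{"WM"}); columns are subjects. Two assays are
#' carried: \code{pctAO} (raw \%AO, non-negative) and \code{lnAO} (natural-log
#' transformed \%AO, the scale on which all analyses run). Missing tissue
#' samples are \code{NA} in both assays. \code{colData} holds the group label
#' (and optionally a pathologic subtype); \code{rowData} holds \code{region}
#' and \code{compartment}.
#'
#' @seealso [loadCohort()], [simulateCohort()], [buildGraph()]
#' @export
setClass("PathologyCohort", contains = "SummarizedExperiment")

.validPathologyCohort <- function(object) {
    msg <- character()
    an <- assayNames(object)
    if (!all(c("pctAO", "lnAO") %in% an))
        msg <- c(msg, "assays 'pctAO' and 'lnAO' are required")
    rd <- rowData(object)
    if (!all(c("region", "compartment") %in% colnames(rd))) {
        msg <- c(msg, "rowData must contain 'region' and 'compartment'")
    } else {
        if (!all(rd$compartment %in% c("GM", "WM")))
            msg <- c(msg, "compartment must be 'GM' or 'WM'")
        key <- paste(rd$region, rd$compartment)
        if (anyDuplicated(key))
            msg <- c(msg, "duplicated (region, compartment) nodes")
    }
    if (!"group" %in% colnames(colData(object)))
        msg <- c(msg, "colData must contain 'group'")
    if ("pctAO" %in% an) {
        p <- assay(object, "pctAO")
        if (any(p < 0, na.rm = TRUE))
            msg <- c(msg, "pctAO must be non-negative")
    }
    if (length(msg)) msg else TRUE
}
setValidity("PathologyCohort", .validPathologyCohort)

#' CorrelationGraph: a group-level weighted non-directed pathology network
#'
#' Nodes are (region, compartment) pairs; each edge of the complete node-pair
#' set carries the group-level pairwise-complete Pearson correlation of
#' ln(\%AO) across subjects, the number of subjects observed at both nodes
#' (\code{n_pairs}), a two-tailed correlation p-value, and an inclusion flag
#' (\code{n_pairs >= min_pairs}). Excluded edges carry \code{NA} weights and
#' correspond to the blacked-out cells of a correlation heat map with
#' insufficient sampling.
#'
#' @slot group group label the graph was built for.
#' @slot nodes \code{data.frame} with columns \code{node}, \code{region},
#'   \code{compartment}, \code{n} (subjects measured), \code{burden}
#'   (group-mean ln \%AO).
#' @slot edges \code{data.frame} with columns \code{node1}, \code{node2},
#'   \code{class} (\code{"GM-GM"}, \code{"WM-WM"}, \code{"GM-WM"}), \code{r},
#'   \code{n_pairs}, \code{p}, \code{included}.
#' @slot min_pairs minimum per-edge sample size used at build time.
#'
#' @seealso [buildGraph()], [nodeStrength()], [compareGraphs()]
#' @export
setClass("CorrelationGraph",
    representation(group = "character", nodes = "data.frame",
                   edges = "data.frame", min_pairs = "integer"))

.validCorrelationGraph <- function(object) {
    msg <- character()
    need_n <- c("node", "region", "compartment", "n", "burden")
    if (!all(need_n %in% colnames(object@nodes)))
        msg <- c(msg, "nodes must have columns node, region, compartment, n, burden")
    need_e <- c("node1", "node2", "class", "r", "n_pairs", "p", "included")
    if (!all(need_e %in% colnames(object@edges)))
        msg <- c(msg, "edges must have columns node1..included")
    e <- object@edges
    if (nrow(e)) {
        if (any(e$node1 == e$node2))
            msg <- c(msg, "self-edges are not allowed")
        if (any(abs(e$r) > 1 + 1e-12, na.rm = TRUE))
            msg <- c(msg, "|r| must be <= 1")
        if (any(!is.na(e$r) & !e$included))
            msg <- c(msg, "excluded edges must not carry a correlation")
    }
    if (length(msg)) msg else TRUE
}
setValidity("CorrelationGraph", .validCorrelationGraph)

#' @describeIn PathologyCohort compact display
#' @param object a \code{PathologyCohort}
#' @export
setMethod("show", "PathologyCohort", function(object) {
    cat("PathologyCohort:", ncol(object), "subjects,",
        nrow(object), "nodes\n")
    gr <- table(colData(object)$group)
    cat("groups:", paste(sprintf("%s (n=%d)", names(gr), as.integer(gr)),
                         collapse = ", "), "\n")
    nmiss <- sum(is.na(assay(object, "lnAO")))
    cat(sprintf("missing measurements: %d of %d (%.1f%%)\n",
                nmiss, length(assay(object, "lnAO")),
                100 * nmiss / max(1L, length(assay(object, "lnAO")))))
    invisible(NULL)
})

#' @describeIn CorrelationGraph compact display
#' @param object a \code{CorrelationGraph}
#' @export
setMethod("show", "CorrelationGraph", function(object) {
    e <- object@edges
    cat(sprintf("CorrelationGraph [%s]: %d nodes, %d/%d edges included (min_pairs=%d)\n",
                object@group, nrow(object@nodes), sum(e$included),
                nrow(e), object@min_pairs))
    if (any(e$included))
        cat(sprintf("edge weight range: [%.3f, %.3f]\n",
                    min(e$r[e$included]), max(e$r[e$included])))
    invisible(NULL)
})
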