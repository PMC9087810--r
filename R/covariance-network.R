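.corPvalue <- function(r, n) {
    # two-tailed p for a Pearson correlation via the t distribution, n-2 df
    p <- rep(NA_real_, length(r))
    ok <- !is.na(r) & n > 2
    rr <- pmin(pmax(r[ok], -1), 1)
    tt <- ifelse(abs(rr) >= 1, Inf, rr * sqrt((n[ok] - 2) / (1 - rr^2)))
    p[ok] <- 2 * stats::pt(abs(tt), df = n[ok] - 2, lower.tail = FALSE)
    p
}

#' Build a group-level correlation graph
#'
#' Computes the weighted non-directed pathology network for one group: every
#' unordered pair of (region, compartment) nodes becomes an edge weighted by
#' the pairwise-complete Pearson correlation of ln(\%AO) across subjects.
#' Because tissue availability differs by region, each edge uses exactly the
#' subjects measured at both of its nodes and records that count as
#' \code{n_pairs}; pairs with \code{n_pairs < min_pairs} are marked excluded
#' and carry no correlation, matching the blacked-out cells of a correlation
#' heat map with insufficient sampling.
#'
#' @param cohort a [PathologyCohort]
#' @param group group label to build the graph for
#' @param node_filter compartments to keep: \code{"GM"}, \code{"WM"} or
#'   both (default)
#' @param min_pairs minimum subjects per edge (default 5; hard floor 3,
#'   below which a correlation p-value is undefined)
#' @return a [CorrelationGraph]
#' @examples
#' coh <- simulateCohort(syntheticGroupConfig(n_subjects = 40, seed = 1))
#' g <- buildGraph(coh, "groupA")
#' head(graphEdges(g))
#' @export
buildGraph <- function(cohort, group, node_filter = c("GM", "WM"),
                       min_pairs = 5L) {
    stopifnot(is(cohort, "PathologyCohort"))
    node_filter <- match.arg(node_filter, c("GM", "WM"), several.ok = TRUE)
    min_pairs <- as.integer(min_pairs)
    if (min_pairs < 3L)
        stop("min_pairs must be >= 3")
    if (!group %in% cohortGroups(cohort))
        stop("unknown group: ", group)

    keep_col <- colData(cohort)$group == group
    keep_row <- rowData(cohort)$compartment %in% node_filter
    ln <- lnAO(cohort)[keep_row, keep_col, drop = FALSE]
    nobs <- rowSums(!is.na(ln))
    ln <- ln[nobs > 0, , drop = FALSE]
    if (nrow(ln) < 2)
        stop("fewer than 2 nodes with data after filtering")

    rd <- rowData(cohort)[rownames(ln), , drop = FALSE]
    nodes <- data.frame(node = rownames(ln),
                        region = as.character(rd$region),
                        compartment = as.character(rd$compartment),
                        n = as.integer(rowSums(!is.na(ln))),
                        burden = rowMeans(ln, na.rm = TRUE),
                        row.names = NULL, stringsAsFactors = FALSE)

    x <- t(ln)                               # subjects x nodes
    suppressWarnings(R <- stats::cor(x, use = "pairwise.complete.obs"))
    N <- crossprod(!is.na(x))                # per-pair shared-subject counts

    ut <- which(upper.tri(R), arr.ind = TRUE)
    i <- ut[, 1]; j <- ut[, 2]
    r <- R[ut]; np <- as.integer(N[ut])
    included <- np >= min_pairs & !is.na(r)
    r[!included] <- NA_real_
    cls <- ifelse(nodes$compartment[i] == nodes$compartment[j],
                  paste(nodes$compartment[i], nodes$compartment[j], sep = "-"),
                  "GM-WM")
    edges <- data.frame(node1 = nodes$node[i], node2 = nodes$node[j],
                        class = cls, r = r, n_pairs = np,
                        p = .corPvalue(r, np), included = included,
                        row.names = NULL, stringsAsFactors = FALSE)
    if (nrow(edges) && !any(edges$included))
        warning("all edges excluded at min_pairs = ", min_pairs)
    new("CorrelationGraph", group = group, nodes = nodes, edges = edges,
        min_pairs = min_pairs)
}

#' Weighted node strength
#'
#' Strength of a node is the sum of its incident included edge weights, i.e.
#' the sum of that node's group-level correlations with every other node.
#' High strength marks a node as tightly integrated in the covariance
#' network, the graph metric interpreted here as participation in pathologic
#' spread. Signed summation is the literal definition; \code{"absolute"}
#' sums \code{|r|} for users who prefer magnitude-only integration.
#'
#' @param graph a [CorrelationGraph]
#' @param edge_weight_mode \code{"signed"} (default) or \code{"absolute"}
#' @return \code{data.frame} with \code{node}, \code{region},
#'   \code{compartment}, \code{strength}, \code{n_edges} (included incident
#'   edges), \code{burden} (group-mean ln \%AO)
#' @export
nodeStrength <- function(graph, edge_weight_mode = c("signed", "absolute")) {
    stopifnot(is(graph, "CorrelationGraph"))
    edge_weight_mode <- match.arg(edge_weight_mode)
    nd <- graph@nodes
    e <- graph@edges[graph@edges$included, , drop = FALSE]
    w <- if (edge_weight_mode == "absolute") abs(e$r) else e$r
    strength <- stats::setNames(numeric(nrow(nd)), nd$node)
    degree <- stats::setNames(integer(nrow(nd)), nd$node)
    for (k in seq_len(nrow(e))) {
        strength[e$node1[k]] <- strength[e$node1[k]] + w[k]
        strength[e$node2[k]] <- strength[e$node2[k]] + w[k]
        degree[e$node1[k]] <- degree[e$node1[k]] + 1L
        degree[e$node2[k]] <- degree[e$node2[k]] + 1L
    }
    data.frame(node = nd$node, region = nd$region,
               compartment = nd$compartment,
               strength = unname(strength), n_edges = unname(degree),
               burden = nd$burden, row.names = NULL,
               stringsAsFactors = FALSE)
}

#' Correlate node strength with regional pathology burden
#'
#' Across the nodes of one compartment, tests whether network integration
#' (node strength) tracks the group-mean ln(\%AO) burden. A correlation
#' network alone cannot distinguish tightly correlated low-pathology nodes
#' from genuine high-burden hubs; this statistic asks whether the heavy
#' nodes are also the integrated ones.
#'
#' @param strengths output of [nodeStrength()]
#' @param compartment \code{"GM"} or \code{"WM"}
#' @return list with \code{r}, \code{p} (two-tailed, t distribution on
#'   \code{n_nodes - 2} df), \code{n_nodes}
#' @export
strengthBurdenCorrelation <- function(strengths, compartment = c("GM", "WM")) {
    compartment <- match.arg(compartment)
    s <- strengths[strengths$compartment == compartment, , drop = FALSE]
    if (nrow(s) < 3)
        stop("need >= 3 ", compartment, " nodes, have ", nrow(s))
    if (stats::sd(s$burden) == 0 || stats::sd(s$strength) == 0)
        stop("zero variance in burden or strength: correlation undefined")
    ct <- stats::cor.test(s$strength, s$burden, method = "pearson")
    list(r = unname(ct$estimate), p = ct$p.value, n_nodes = nrow(s))
}

#' Full correlation matrix of a graph
#'
#' Symmetric node-by-node matrix of included edge weights; excluded pairs
#' are \code{NA} and the diagonal is 1.
#'
#' @param graph a [CorrelationGraph]
#' @return numeric matrix
#' @export
correlationMatrix <- function(graph) {
    nd <- graph@nodes$node
    M <- matrix(NA_real_, length(nd), length(nd), dimnames = list(nd, nd))
    diag(M) <- 1
    e <- graph@edges
    M[cbind(e$node1, e$node2)] <- e$r
    M[cbind(e$node2, e$node1)] <- e$r
    M
}

.fmtNum <- function(x) ifelse(is.na(x), "NA", sprintf("%.17g", x))

#' Export a graph to GraphML or an edge-list TSV
#'
#' GraphML carries typed node attributes (region, compartment, burden, n)
#' and edge attributes (r, n_pairs, p) for included edges. The TSV format
#' writes the edge table (fixed columns node1, node2, class, r, n_pairs, p,
#' included; numeric values at full precision) plus a companion
#' \code{*_nodes.tsv}, and round-trips through [readEdgeTable()].
#' Optional thresholds restrict the exported edges.
#'
#' @param graph a [CorrelationGraph]
#' @param path output file path
#' @param format \code{"edge_tsv"} or \code{"graphml"}
#' @param p_max optional: keep only edges with \code{p <= p_max}
#' @param abs_r_min optional: keep only edges with \code{|r| >= abs_r_min}
#' @return \code{path}, invisibly
#' @export
exportGraph <- function(graph, path, format = c("edge_tsv", "graphml"),
                        p_max = NULL, abs_r_min = NULL) {
    stopifnot(is(graph, "CorrelationGraph"))
    format <- match.arg(format)
    e <- graph@edges[graph@edges$included, , drop = FALSE]
    if (!is.null(p_max)) e <- e[e$p <= p_max, , drop = FALSE]
    if (!is.null(abs_r_min)) e <- e[abs(e$r) >= abs_r_min, , drop = FALSE]
    nd <- graph@nodes
    if (format == "graphml") {
        g <- igraph::graph_from_data_frame(
            e[, c("node1", "node2", "class", "r", "n_pairs", "p")],
            directed = FALSE,
            vertices = nd[, c("node", "region", "compartment", "n", "burden")])
        igraph::write_graph(g, path, format = "graphml")
    } else {
        out <- e
        for (cn in c("r", "p")) out[[cn]] <- .fmtNum(out[[cn]])
        write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
        npath <- sub("(\\.[^.]+)?$", "_nodes.tsv", path)
        nout <- nd
        nout$burden <- .fmtNum(nout$burden)
        write.table(nout, npath, sep = "\t", quote = FALSE, row.names = FALSE)
    }
    invisible(path)
}

#' @rdname exportGraph
#' @details \code{readEdgeTable} reads back an edge-list TSV written by
#'   \code{exportGraph}, restoring numeric types exactly.
#' @export
readEdgeTable <- function(path) {
    df <- read.table(path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
    for (cn in c("r", "p")) df[[cn]] <- as.numeric(df[[cn]])
    df$n_pairs <- as.integer(df$n_pairs)
    df$included <- as.logical(df$included)
    df
}
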