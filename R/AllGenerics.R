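#' Accessors for PathologyCohort and CorrelationGraph
#'
#' \code{cohortGroups} returns the group labels present; \code{nodeIndex}
#' the ordered (region, compartment) node table; \code{lnAO} the nodes x
#' subjects matrix of ln-transformed \%AO; \code{graphNodes} /
#' \code{graphEdges} the node and edge tables of a graph.
#'
#' @param x a \code{PathologyCohort} or \code{CorrelationGraph}
#' @return see per-method descriptions
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("cohortGroups", function(x) standardGeneric("cohortGroups"))

#' @rdname accessors
#' @export
setGeneric("nodeIndex", function(x) standardGeneric("nodeIndex"))

#' @rdname accessors
#' @export
setGeneric("lnAO", function(x) standardGeneric("lnAO"))

#' @rdname accessors
#' @export
setGeneric("graphNodes", function(x) standardGeneric("graphNodes"))

#' @rdname accessors
#' @export
setGeneric("graphEdges", function(x) standardGeneric("graphEdges"))

#' @rdname accessors
#' @export
setMethod("cohortGroups", "PathologyCohort", function(x)
    sort(unique(as.character(colData(x)$group))))

#' @rdname accessors
#' @export
setMethod("nodeIndex", "PathologyCohort", function(x) {
    rd <- rowData(x)
    data.frame(node = rownames(x), region = as.character(rd$region),
               compartment = as.character(rd$compartment),
               row.names = NULL, stringsAsFactors = FALSE)
})

#' @rdname accessors
#' @export
setMethod("lnAO", "PathologyCohort", function(x) assay(x, "lnAO"))

#' @rdname accessors
#' @export
setMethod("graphNodes", "CorrelationGraph", function(x) x@nodes)

#' @rdname accessors
#' @export
setMethod("graphEdges", "CorrelationGraph", function(x) x@edges)
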