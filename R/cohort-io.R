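#' @importFrom utils read.table write.table
NULL

.nodeName <- function(region, compartment) paste(region, compartment, sep = "_")

.canonicalCols <- c("subject", "group", "region", "compartment", "pct_ao")

#' Bundled cortical region metadata
#'
#' The sampled cortical regions with anatomical names and lobar roles. The
#' core panel covers 13 regions spanning anterior ventral frontal, anterior
#' dorsolateral/medial frontal, anterior-mid temporal and posterior parietal
#' territory, plus the entorhinal cortex (BA28) used in exploratory
#' hippocampal analyses. The \code{role} column drives the default mediation
#' panel (anterior frontotemporal predictors vs the posterior parietal
#' angular gyrus outcome).
#'
#' @return \code{data.frame} with columns \code{region} (Brodmann-area code),
#'   \code{name}, \code{lobe}, \code{role}, \code{core} (logical, in the
#'   13-region core panel).
#' @examples
#' subset(regionMetadata(), role != "other")
#' @export
regionMetadata <- function() {
    data.frame(
        region = c("BA13", "BA11", "BA9", "BA44", "BA45", "BA46", "BA24",
                   "BA32", "BA20", "BA22", "BA39", "BA23", "BA5", "BA28"),
        name = c("anterior insula", "orbitofrontal cortex",
                 "dorsolateral prefrontal cortex", "inferior frontal cortex",
                 "inferior prefrontal cortex", "midfrontal cortex",
                 "anterior cingulate cortex", "medial prefrontal cortex",
                 "anterior inferior temporal cortex", "superior temporal cortex",
                 "angular gyrus", "posterior cingulate cortex",
                 "superior parietal cortex", "entorhinal cortex"),
        lobe = c("anterior ventral frontal", "anterior ventral frontal",
                 "anterior dorsolateral/medial frontal",
                 "anterior dorsolateral/medial frontal",
                 "anterior dorsolateral/medial frontal",
                 "anterior dorsolateral/medial frontal",
                 "anterior dorsolateral/medial frontal",
                 "anterior dorsolateral/medial frontal",
                 "anterior-mid temporal", "anterior-mid temporal",
                 "posterior parietal", "posterior parietal",
                 "posterior parietal", "medial temporal"),
        role = c("other", "anterior frontal", "other", "other", "other",
                 "anterior frontal", "other", "other", "other",
                 "anterior temporal", "posterior parietal", "other", "other",
                 "other"),
        core = c(rep(TRUE, 13), FALSE),
        stringsAsFactors = FALSE)
}

.resolveSchema <- function(schema) {
    if (is.null(schema))
        return(stats::setNames(.canonicalCols, .canonicalCols))
    if (is.character(schema) && length(schema) == 1 && file.exists(schema)) {
        schema <- if (grepl("\\.ya?ml$", schema))
            yaml::read_yaml(schema)
        else jsonlite::read_json(schema, simplifyVector = TRUE)
    }
    schema <- unlist(schema)
    out <- stats::setNames(.canonicalCols, .canonicalCols)
    extra <- setdiff(names(schema), c(.canonicalCols, "subtype"))
    if (length(extra))
        stop("unknown schema entries: ", paste(extra, collapse = ", "))
    out[names(schema)] <- schema
    out
}

#' Assemble a PathologyCohort from a long measurement table
#'
#' Takes one row per (subject, region, compartment) measurement and returns
#' the matrix-shaped cohort object. The \%AO values are natural-log
#' transformed; exact zeros (which have no finite log) are floored at
#' \code{zero_offset} before the transform, and the number of floored rows is
#' recorded. Rows whose \%AO is \code{NA} are dropped and counted: a missing
#' row and an absent row mean the same thing, an unsampled node.
#'
#' @param df \code{data.frame} with columns \code{subject}, \code{group},
#'   \code{region}, \code{compartment} ("GM"/"WM"), \code{pct_ao}, and
#'   optionally \code{subtype}.
#' @param zero_offset positive \%AO floor substituted for exact zeros before
#'   the log transform (default 0.001\%).
#' @return a [PathologyCohort]; \code{metadata(x)$load_report} records rows
#'   dropped as missing and rows floored at zero.
#' @export
cohortAssemble <- function(df, zero_offset = 0.001) {
    stopifnot(is.data.frame(df), zero_offset > 0)
    miss <- setdiff(.canonicalCols, colnames(df))
    if (length(miss))
        stop("missing required columns: ", paste(miss, collapse = ", "))
    df$compartment <- as.character(df$compartment)
    if (!all(df$compartment %in% c("GM", "WM")))
        stop("compartment must be 'GM' or 'WM'")
    bad <- which(!is.na(df$pct_ao) & df$pct_ao < 0)
    if (length(bad))
        stop("negative %AO in row(s): ", paste(utils::head(bad, 5), collapse = ", "))
    n_missing <- sum(is.na(df$pct_ao))
    df <- df[!is.na(df$pct_ao), , drop = FALSE]
    key <- paste(df$subject, df$region, df$compartment, sep = "\r")
    if (anyDuplicated(key)) {
        d <- df[duplicated(key), , drop = FALSE][1, ]
        stop(sprintf("duplicate measurement for subject '%s' at %s %s",
                     d$subject, d$region, d$compartment))
    }
    gmap <- unique(df[, c("subject", "group")])
    if (anyDuplicated(gmap$subject))
        stop("subjects assigned to more than one group")

    # the floor applies only to exact zeros; small positive values keep
    # their own logarithm
    n_floored <- sum(df$pct_ao == 0)
    ln <- ifelse(df$pct_ao > 0, log(df$pct_ao), log(zero_offset))

    nodes <- unique(df[, c("region", "compartment")])
    nodes <- nodes[order(match(nodes$region, unique(df$region)),
                         nodes$compartment), , drop = FALSE]
    node_id <- .nodeName(nodes$region, nodes$compartment)
    subjects <- unique(df$subject)

    ri <- match(.nodeName(df$region, df$compartment), node_id)
    ci <- match(df$subject, subjects)
    pct <- ln_m <- matrix(NA_real_, nrow(nodes), length(subjects),
                          dimnames = list(node_id, subjects))
    pct[cbind(ri, ci)] <- df$pct_ao
    ln_m[cbind(ri, ci)] <- ln

    cd <- DataFrame(group = gmap$group[match(subjects, gmap$subject)],
                    row.names = subjects)
    if ("subtype" %in% colnames(df)) {
        smap <- unique(df[, c("subject", "subtype")])
        cd$subtype <- smap$subtype[match(subjects, smap$subject)]
    }
    se <- SummarizedExperiment(
        assays = list(pctAO = pct, lnAO = ln_m),
        rowData = DataFrame(region = nodes$region,
                            compartment = nodes$compartment,
                            row.names = node_id),
        colData = cd)
    obj <- new("PathologyCohort", se)
    metadata(obj)$load_report <- list(n_dropped_missing = n_missing,
                                      n_floored_zero = n_floored,
                                      zero_offset = zero_offset)
    validObject(obj)
    obj
}

#' Read a cohort measurement table from disk
#'
#' Reads a UTF-8 CSV/TSV with a header row, one row per (subject, region,
#' compartment) measurement, and builds a [PathologyCohort]. Column names are
#' mapped through \code{schema}; a wide table (one row per subject, one
#' column per \code{region_compartment} node) is accepted with
#' \code{format = "wide"}.
#'
#' @param path file path; \code{.csv} is read comma-separated, anything else
#'   tab-separated.
#' @param schema \code{NULL} for canonical column names, a named character
#'   vector \code{c(subject = "ID", ...)}, or a path to a YAML/JSON file with
#'   the same mapping. An optional \code{subtype} entry is carried through.
#' @param zero_offset passed to [cohortAssemble()].
#' @param format \code{"long"} (default) or \code{"wide"}.
#' @return a [PathologyCohort]
#' @export
loadCohort <- function(path, schema = NULL, zero_offset = 0.001,
                       format = c("long", "wide")) {
    format <- match.arg(format)
    if (!file.exists(path)) stop("file not found: ", path)
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    df <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                     check.names = FALSE, quote = "\"", comment.char = "")
    if (format == "wide") {
        idc <- intersect(c("subject", "group", "subtype"), colnames(df))
        meas <- setdiff(colnames(df), idc)
        if (!all(c("subject", "group") %in% idc))
            stop("wide input needs 'subject' and 'group' columns")
        parts <- strsplit(meas, "_")
        if (any(lengths(parts) != 2))
            stop("wide measurement columns must be named <region>_<GM|WM>")
        long <- do.call(rbind, lapply(seq_along(meas), function(i) {
            data.frame(subject = df$subject, group = df$group,
                       region = parts[[i]][1], compartment = parts[[i]][2],
                       pct_ao = df[[meas[i]]], stringsAsFactors = FALSE)
        }))
        if ("subtype" %in% idc)
            long$subtype <- df$subtype[match(long$subject, df$subject)]
        return(cohortAssemble(long, zero_offset = zero_offset))
    }
    sch <- .resolveSchema(schema)
    missing_cols <- sch[!sch %in% colnames(df)]
    if (length(missing_cols))
        stop("schema error: column(s) not found: ",
             paste(missing_cols, collapse = ", "))
    out <- data.frame(lapply(sch, function(cn) df[[cn]]),
                      stringsAsFactors = FALSE)
    names(out) <- names(sch)
    if (!is.null(schema)) {
        sv <- unlist(schema)
        if ("subtype" %in% names(sv) && sv[["subtype"]] %in% colnames(df))
            out$subtype <- df[[sv[["subtype"]]]]
    } else if ("subtype" %in% colnames(df)) {
        out$subtype <- df$subtype
    }
    cohortAssemble(out, zero_offset = zero_offset)
}

#' Write a cohort back to the canonical long TSV
#'
#' One row per observed measurement with columns \code{subject},
#' \code{group}, \code{region}, \code{compartment}, \code{pct_ao},
#' \code{ln_ao} (and \code{subtype} when present). \code{loadCohort} on the
#' result reproduces the cohort.
#'
#' @param cohort a [PathologyCohort]
#' @param path output file path (TSV)
#' @return \code{path}, invisibly
#' @export
writeCohort <- function(cohort, path) {
    stopifnot(is(cohort, "PathologyCohort"))
    df <- cohortToLong(cohort)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeCohort
#' @details \code{cohortToLong} returns the same long table as a
#'   \code{data.frame} without touching disk.
#' @export
cohortToLong <- function(cohort) {
    stopifnot(is(cohort, "PathologyCohort"))
    pct <- assay(cohort, "pctAO")
    ln <- assay(cohort, "lnAO")
    rd <- rowData(cohort)
    cd <- colData(cohort)
    idx <- which(!is.na(pct), arr.ind = TRUE)
    df <- data.frame(
        subject = colnames(pct)[idx[, 2]],
        group = as.character(cd$group)[idx[, 2]],
        region = as.character(rd$region)[idx[, 1]],
        compartment = as.character(rd$compartment)[idx[, 1]],
        pct_ao = pct[idx],
        ln_ao = ln[idx],
        stringsAsFactors = FALSE)
    if ("subtype" %in% colnames(cd))
        df$subtype <- as.character(cd$subtype)[idx[, 2]]
    df[order(df$subject, df$region, df$compartment), , drop = FALSE]
}

#' Per-node summary for one group
#'
#' Counts and moments of ln(\%AO) per (region, compartment) node over the
#' subjects of one group, mirroring a published-style regional measurement
#' table. Nodes with no observed subjects in the group are omitted; a node
#' with a single subject reports \code{sd = NA}.
#'
#' @param cohort a [PathologyCohort]
#' @param group group label
#' @return \code{data.frame} with \code{region}, \code{compartment},
#'   \code{n}, \code{mean_ln_ao}, \code{sd_ln_ao}
#' @export
summarizeNodes <- function(cohort, group) {
    stopifnot(is(cohort, "PathologyCohort"))
    if (!group %in% cohortGroups(cohort))
        stop("unknown group: ", group)
    ln <- lnAO(cohort)[, colData(cohort)$group == group, drop = FALSE]
    n <- rowSums(!is.na(ln))
    out <- data.frame(
        region = as.character(rowData(cohort)$region),
        compartment = as.character(rowData(cohort)$compartment),
        n = as.integer(n),
        mean_ln_ao = rowMeans(ln, na.rm = TRUE),
        sd_ln_ao = apply(ln, 1, stats::sd, na.rm = TRUE),
        row.names = NULL, stringsAsFactors = FALSE)
    out$mean_ln_ao[out$n == 0] <- NA_real_
    out[out$n > 0, , drop = FALSE]
}

#' Subset a cohort by subjects or by excluding a pathologic subtype
#'
#' \code{excludeSubtype} drops all subjects of one subtype (requires a
#' \code{subtype} column in \code{colData}), supporting leave-one-subtype-out
#' sensitivity reruns of the full graph comparison.
#'
#' @param cohort a [PathologyCohort]
#' @param subtype subtype label to drop
#' @return a [PathologyCohort]
#' @export
excludeSubtype <- function(cohort, subtype) {
    stopifnot(is(cohort, "PathologyCohort"))
    cd <- colData(cohort)
    if (!"subtype" %in% colnames(cd))
        stop("cohort has no 'subtype' column")
    keep <- is.na(cd$subtype) | cd$subtype != subtype
    if (all(keep)) warning("subtype not present: ", subtype)
    cohort[, keep]
}
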