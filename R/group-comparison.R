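#' Fisher's variance-stabilizing z-transform of a correlation
#'
#' \code{arctanh(r) = 0.5 * ln((1 + r) / (1 - r))}. On this scale a sample
#' Pearson correlation is approximately normal with variance
#' \code{1 / (n - 3)}, which is what makes the two-sample edge comparison a
#' plain z-test.
#'
#' @param r correlation coefficient(s), strictly inside (-1, 1)
#' @return transformed value(s)
#' @examples
#' fisherZ(0.5)   # 0.5 * log(3)
#' @export
fisherZ <- function(r) {
    if (any(!is.finite(r)) || any(abs(r) >= 1))
        stop("fisherZ is defined for |r| < 1")
    atanh(r)
}

#' Compare one correlation between two groups (Fisher r-to-z test)
#'
#' Tests whether a node-pair correlation differs between two groups, using
#' the group-specific per-edge sample sizes: the test statistic is
#' \deqn{z = (\mathrm{arctanh}\, r_1 - \mathrm{arctanh}\, r_2) /
#'       \sqrt{1/(n_1-3) + 1/(n_2-3)}}
#' referred to the standard normal. Because each edge carries its own
#' pairwise-complete n, the test naturally absorbs discrepancies in tissue
#' availability between groups.
#'
#' @param r1,r2 Pearson correlations of the two groups, \code{|r| < 1}
#' @param n1,n2 per-edge pair counts, both \code{>= 4}
#' @param tail \code{"two_tailed"} (default) or \code{"one_tailed"}; the
#'   one-tailed p is for the observed direction
#' @param alpha significance threshold for the \code{significant} flag
#' @return \code{data.frame} row: \code{r1, n1, r2, n2, z_stat, p,
#'   direction} (\code{"1>2"}, \code{"2>1"} or \code{"equal"}),
#'   \code{significant}
#' @export
compareEdge <- function(r1, n1, r2, n2,
                        tail = c("two_tailed", "one_tailed"),
                        alpha = 0.05) {
    tail <- match.arg(tail)
    if (any(c(n1, n2) <= 3))
        stop("Fisher comparison needs n >= 4 in both groups")
    z <- (fisherZ(r1) - fisherZ(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
    p2 <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
    p <- if (tail == "one_tailed") p2 / 2 else p2
    data.frame(r1 = r1, n1 = n1, r2 = r2, n2 = n2, z_stat = z, p = p,
               direction = ifelse(z > 0, "1>2", ifelse(z < 0, "2>1", "equal")),
               significant = p < alpha, stringsAsFactors = FALSE)
}

#' Compare all shared edges of two group graphs
#'
#' Runs [compareEdge()] for every node pair included in both graphs. Edges
#' included in only one graph cannot be compared and are returned separately
#' as skipped. Edge classes (GM-GM, WM-WM, GM-WM) are carried through so
#' that direction-wise significant-edge counts can be summarised per class.
#'
#' @param g1,g2 [CorrelationGraph]s over a shared node universe
#' @param tail as in [compareEdge()]; graph-difference maps conventionally
#'   use one-tailed edge tests while omnibus reporting is two-tailed, so the
#'   tail actually used is recorded in the result attributes
#' @param alpha significance threshold (default 0.05, uncorrected)
#' @param correction \code{"none"} (default) or \code{"bh"}
#'   (Benjamini-Hochberg on the comparison p-values)
#' @return \code{data.frame} with one row per shared included edge
#'   (\code{node1, node2, class, r1, n1, r2, n2, z_stat, p, direction,
#'   significant}); attributes \code{skipped} (edges included in exactly one
#'   graph), \code{summary} (per class and direction significant counts),
#'   \code{tail}, \code{alpha}
#' @export
compareGraphs <- function(g1, g2, tail = c("two_tailed", "one_tailed"),
                          alpha = 0.05, correction = c("none", "bh")) {
    stopifnot(is(g1, "CorrelationGraph"), is(g2, "CorrelationGraph"))
    tail <- match.arg(tail)
    correction <- match.arg(correction)
    e1 <- g1@edges; e2 <- g2@edges
    key1 <- paste(e1$node1, e1$node2); key2 <- paste(e2$node1, e2$node2)
    m <- match(key1, key2)
    shared <- !is.na(m) & e1$included & e2$included[m]
    skipped <- rbind(
        data.frame(node1 = e1$node1, node2 = e1$node2,
                   only_in = g1@group,
                   stringsAsFactors = FALSE)[e1$included &
                       !(key1 %in% key2[e2$included]), , drop = FALSE],
        data.frame(node1 = e2$node1, node2 = e2$node2,
                   only_in = g2@group,
                   stringsAsFactors = FALSE)[e2$included &
                       !(key2 %in% key1[e1$included]), , drop = FALSE])
    if (!any(shared)) {
        warning("no shared included edges between graphs")
        res <- data.frame(node1 = character(), node2 = character(),
                          class = character(), r1 = numeric(),
                          n1 = integer(), r2 = numeric(), n2 = integer(),
                          z_stat = numeric(), p = numeric(),
                          direction = character(), significant = logical(),
                          stringsAsFactors = FALSE)
    } else {
        a <- e1[shared, , drop = FALSE]
        b <- e2[m[shared], , drop = FALSE]
        # edges with n <= 3 or a degenerate |r| = 1 in either group have no
        # finite z-transform variance/value; treat as skipped
        testable <- a$n_pairs > 3 & b$n_pairs > 3 &
            abs(a$r) < 1 & abs(b$r) < 1
        if (any(!testable))
            skipped <- rbind(skipped,
                data.frame(node1 = a$node1[!testable],
                           node2 = a$node2[!testable],
                           only_in = "untestable (n_pairs <= 3 or |r| = 1)",
                           stringsAsFactors = FALSE))
        a <- a[testable, , drop = FALSE]; b <- b[testable, , drop = FALSE]
        cmp <- compareEdge(a$r, a$n_pairs, b$r, b$n_pairs, tail = tail,
                           alpha = alpha)
        if (correction == "bh") {
            cmp$p <- stats::p.adjust(cmp$p, method = "BH")
            cmp$significant <- cmp$p < alpha
        }
        res <- cbind(data.frame(node1 = a$node1, node2 = a$node2,
                                class = a$class, stringsAsFactors = FALSE),
                     cmp)
    }
    sig <- res[res$significant, , drop = FALSE]
    summ <- as.data.frame(table(class = factor(sig$class,
                                    levels = c("GM-GM", "WM-WM", "GM-WM")),
                                direction = factor(sig$direction,
                                    levels = c("1>2", "2>1"))),
                          stringsAsFactors = FALSE)
    names(summ)[3] <- "n_significant"
    attr(res, "skipped") <- skipped
    attr(res, "summary") <- summ
    attr(res, "tail") <- tail
    attr(res, "alpha") <- alpha
    attr(res, "groups") <- c(g1@group, g2@group)
    res
}
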