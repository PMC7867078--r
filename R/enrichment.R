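#' Build a gene-set collection
#'
#' Members outside the universe are dropped with a logged count; empty sets
#' (before or after the drop) are rejected.
#'
#' @param sets named list of character vectors (gene identifiers).
#' @param universe character vector of gene identifiers considered testable.
#' @return list with elements `sets` (trimmed) and `universe`, of class
#'   `GeneSetCollection`-like plain list.
#' @export
geneSetCollection <- function(sets, universe) {
    if (!length(universe)) stop("universe must be nonempty")
    universe <- unique(.stripIds(universe))
    if (is.null(names(sets)) || any(!nzchar(names(sets))))
        stop("every gene set must be named")
    if (any(!vapply(sets, length, integer(1))))
        stop("empty gene set(s): ",
             paste(names(sets)[!vapply(sets, length, integer(1))],
                   collapse = ", "))
    dropped <- 0L
    sets <- lapply(sets, function(s) {
        s <- unique(.stripIds(s))
        keep <- s %in% universe
        dropped <<- dropped + sum(!keep)
        s[keep]
    })
    if (dropped) message(dropped, " off-universe gene(s) dropped from sets")
    list(sets = sets, universe = universe)
}

#' Hypergeometric over-representation analysis
#'
#' For each gene set, the p-value is the hypergeometric upper tail
#' \eqn{P(X \ge k)} of drawing `k` or more set members in a query of size
#' `n` from a universe of `N` genes of which `K` belong to the set
#' (classical ORA; the discrete analogue of term-level enrichment of a
#' fixed gene list). Benjamini-Hochberg adjusted q-values are appended and
#' results sorted by p ascending (stable tie-break by set name).
#'
#' @param query character vector of gene identifiers; intersected with the
#'   universe before testing.
#' @param collection result of [geneSetCollection()].
#' @return `data.frame` with columns `set_name`, `k`, `K`, `n`, `N`,
#'   `p_value`, `q_value`.
#' @examples
#' col <- geneSetCollection(list(s = letters[1:5]), letters[1:10])
#' oraTest(letters[1:5], col)  # p = 1/choose(10, 5)
#' @export
oraTest <- function(query, collection) {
    universe <- collection$universe
    query <- intersect(unique(.stripIds(query)), universe)
    if (!length(query)) {
        warning("query is empty after intersection with the universe")
        return(data.frame(set_name = character(), k = integer(),
                          K = integer(), n = integer(), N = integer(),
                          p_value = numeric(), q_value = numeric(),
                          stringsAsFactors = FALSE))
    }
    N <- length(universe)
    n <- length(query)
    res <- lapply(names(collection$sets), function(nm) {
        s <- collection$sets[[nm]]
        K <- length(s)
        k <- length(intersect(query, s))
        data.frame(set_name = nm, k = k, K = K, n = n, N = N,
                   p_value = phyper(k - 1, K, N - K, n, lower.tail = FALSE),
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, c(res, make.row.names = FALSE))
    out$q_value <- bhAdjust(out$p_value)
    out <- out[order(out$p_value, out$set_name), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement,
#' stable under ties; a thin validated front over [stats::p.adjust()].
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return q-values in input order.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03))  # all 0.03
#' @export
bhAdjust <- function(p) {
    if (any(is.na(p)) || any(p < 0) || any(p > 1))
        stop("p-values must lie in [0, 1] and be non-missing")
    p.adjust(p, method = "BH")
}
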