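.stripIds <- function(x) trimws(as.character(x))

# rbind a list of data.frames, ignoring NULLs; NULL when nothing remains
.rbindRows <- function(rows) {
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (!length(rows)) return(NULL)
    do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Aggregate per-tool predictions into HIT counts
#'
#' HIT for a (miRNA, gene) pair is the number of distinct prediction tools
#' reporting the pair, plus one if the pair carries validated-interaction
#' evidence. Duplicate records within one tool count once; validated
#' evidence contributes exactly one hit regardless of database multiplicity.
#' Identifier matching is case-sensitive exact string match after
#' whitespace stripping.
#'
#' @param predictions `data.frame` with columns `tool`, `mirna_id`,
#'   `gene_id`.
#' @param validated optional `data.frame` with columns `mirna_id`,
#'   `gene_id` of experimentally validated pairs.
#' @return `data.frame` with columns `mirna_id`, `gene_id`, `hit`, sorted
#'   by miRNA then gene.
#' @examples
#' preds <- data.frame(tool = c("A", "B", "B"), mirna_id = "miR-1",
#'                     gene_id = "TP53")
#' aggregateHits(preds)  # hit = 2 (tool B deduplicated)
#' @export
aggregateHits <- function(predictions, validated = NULL) {
    p <- data.frame(tool = .stripIds(predictions$tool),
                    mirna_id = .stripIds(predictions$mirna_id),
                    gene_id = .stripIds(predictions$gene_id),
                    stringsAsFactors = FALSE)
    p <- unique(p)
    key <- paste(p$mirna_id, p$gene_id, sep = "\r")
    tab <- table(key)
    pairs <- unique(p[, c("mirna_id", "gene_id")])
    pkey <- paste(pairs$mirna_id, pairs$gene_id, sep = "\r")
    hit <- as.integer(tab[pkey])
    if (!is.null(validated) && nrow(validated)) {
        vkey <- unique(paste(.stripIds(validated$mirna_id),
                             .stripIds(validated$gene_id), sep = "\r"))
        hit <- hit + as.integer(pkey %in% vkey)
        # validated pairs never predicted by any tool still carry one hit
        novel <- setdiff(vkey, pkey)
        if (length(novel)) {
            parts <- strsplit(novel, "\r", fixed = TRUE)
            pairs <- rbind(pairs, data.frame(
                mirna_id = vapply(parts, `[`, "", 1L),
                gene_id = vapply(parts, `[`, "", 2L),
                stringsAsFactors = FALSE))
            hit <- c(hit, rep(1L, length(novel)))
        }
    }
    out <- data.frame(pairs, hit = hit, stringsAsFactors = FALSE)
    out <- out[order(out$mirna_id, out$gene_id), , drop = FALSE]
    rownames(out) <- NULL
    out
}

.expectedHits <- function(predictions, config, eps = 1e-9) {
    p <- unique(data.frame(tool = .stripIds(predictions$tool),
                           mirna_id = .stripIds(predictions$mirna_id),
                           gene_id = .stripIds(predictions$gene_id),
                           stringsAsFactors = FALSE))
    # n_t(miRNA): genes tool t predicts for that miRNA
    nt <- stats::aggregate(gene_id ~ tool + mirna_id, data = p, FUN = length)
    exp_per_mirna <- tapply(nt$gene_id, nt$mirna_id, sum) / config@universeSize
    floorIdx <- exp_per_mirna < eps
    if (any(floorIdx)) {
        message("expected hit count floored at ", eps, " for ",
                sum(floorIdx), " miRNA(s)")
        exp_per_mirna[floorIdx] <- eps
    }
    exp_per_mirna
}

#' Observed/expected ratios for miRNA-target pairs
#'
#' The expected support for a pair under tool independence is
#' \eqn{E(\mathrm{miRNA}) = \sum_t n_t(\mathrm{miRNA}) / N_{universe}}, where
#' \eqn{n_t} is the number of genes tool *t* predicts for that miRNA and
#' \eqn{N_{universe}} the size of the gene universe the tools consider. The
#' observed/expected (O/E) ratio of a pair is its HIT count divided by this
#' expectation; expectations are floored at a small epsilon (with a logged
#' message) to avoid division by zero.
#'
#' @param hits HIT table from [aggregateHits()].
#' @param predictions the per-tool prediction records.
#' @param config a [consensusConfig()] (supplies `universeSize`).
#' @return the `hits` table with an added `oe_ratio` column.
#' @export
oeRatios <- function(hits, predictions, config) {
    stopifnot(methods::is(config, "ConsensusConfig"))
    expd <- .expectedHits(predictions, config)
    e <- expd[hits$mirna_id]
    # miRNA absent from every tool (validated-only pair): expected ~ 0
    e[is.na(e)] <- 1e-9
    hits$oe_ratio <- ifelse(hits$hit == 0, 0, hits$hit / as.numeric(e))
    hits
}

#' O/E ratio of a single pair
#'
#' Scalar form of [oeRatios()]; querying a pair absent from the HIT table
#' is an error (distinct from a ratio of zero).
#'
#' @inheritParams oeRatios
#' @param mirna,gene identifiers of the pair.
#' @return a single numeric O/E ratio.
#' @export
pairOeRatio <- function(hits, predictions, config, mirna, gene) {
    idx <- which(hits$mirna_id == .stripIds(mirna) &
                 hits$gene_id == .stripIds(gene))
    if (length(idx) != 1L)
        stop("pair (", mirna, ", ", gene, ") not present in the HIT table")
    oeRatios(hits[idx, , drop = FALSE], predictions, config)$oe_ratio
}

#' Filter consensus targets by the inclusive HIT / O-E rule
#'
#' A pair is retained iff `hit >= hitMin` AND `oe_ratio >= oeMin`, both
#' thresholds inclusive and the rule conjunctive. Output is deterministic
#' (sorted by miRNA then gene).
#'
#' @param oeTable table from [oeRatios()] (columns `mirna_id`, `gene_id`,
#'   `hit`, `oe_ratio`).
#' @param config a [consensusConfig()].
#' @return the input table with a logical `retained` column.
#' @export
filterConsensus <- function(oeTable, config) {
    stopifnot(methods::is(config, "ConsensusConfig"))
    oeTable$retained <- oeTable$hit >= config@hitMin &
        oeTable$oe_ratio >= config@oeMin
    oeTable <- oeTable[order(oeTable$mirna_id, oeTable$gene_id), ,
                       drop = FALSE]
    rownames(oeTable) <- NULL
    oeTable
}

#' Consensus miRNA targets in one call
#'
#' Convenience wrapper: [aggregateHits()] then [oeRatios()] then
#' [filterConsensus()].
#'
#' @inheritParams aggregateHits
#' @inheritParams oeRatios
#' @return consensus table with columns `mirna_id`, `gene_id`, `hit`,
#'   `oe_ratio`, `retained`.
#' @export
consensusTargets <- function(predictions, validated = NULL, config) {
    filterConsensus(oeRatios(aggregateHits(predictions, validated),
                             predictions, config), config)
}
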