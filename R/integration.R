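.joinIds <- function(x) paste(sort(unique(x)), collapse = ";")

#' Split a semicolon-joined id column
#'
#' Inverse of the semicolon-joined annotation columns produced by
#' [matchAnticorrelated()] and [overlayInteractome()].
#'
#' @param x character vector of semicolon-joined identifiers.
#' @return list of character vectors.
#' @export
splitIds <- function(x) strsplit(as.character(x), ";", fixed = TRUE)

#' Match consensus targets against anti-correlated gene fold changes
#'
#' Implements the anti-correlation integration step: a gene down-regulated
#' in the transcriptome is "confirmed" when it is a retained consensus
#' target of at least one up-regulated miRNA, and vice versa. Concordant
#' annotations (down gene / down miRNA) never contribute.
#'
#' @param geneDe `data.frame` with columns `gene_id`, `log2fc`
#'   (treated vs control); direction is `down` iff `log2fc < 0`. Genes with
#'   `log2fc == 0` are dropped with a message; a gene appearing more than
#'   once is a validation error.
#' @param consensus consensus table from [consensusTargets()]; only rows
#'   with `retained == TRUE` are used.
#' @param mirnaDe miRNA DE table from [differentialExpression()] (columns
#'   `mirna_id`, `direction`); `unchanged` miRNAs never support a match.
#' @return list with elements `down` and `up`, each a `data.frame` with
#'   columns `gene_id`, `log2fc`, `mirnas` (semicolon-joined sorted
#'   supporting miRNA ids).
#' @export
matchAnticorrelated <- function(geneDe, consensus, mirnaDe) {
    if (anyDuplicated(geneDe$gene_id))
        stop("gene(s) appear more than once in the gene DE table: ",
             paste(unique(geneDe$gene_id[duplicated(geneDe$gene_id)]),
                   collapse = ", "))
    zero <- geneDe$log2fc == 0
    if (any(zero)) {
        message("dropping ", sum(zero), " gene(s) with log2fc == 0")
        geneDe <- geneDe[!zero, , drop = FALSE]
    }
    geneDir <- ifelse(geneDe$log2fc < 0, "down", "up")
    ret <- consensus[consensus$retained %in% TRUE, , drop = FALSE]
    mdir <- setNames(mirnaDe$direction, mirnaDe$mirna_id)
    ret$mirna_dir <- mdir[ret$mirna_id]
    ret <- ret[ret$mirna_dir %in% c("up", "down"), , drop = FALSE]

    confirm <- function(gdir, wantMirnaDir) {
        genes <- geneDe$gene_id[geneDir == gdir]
        sup <- ret[ret$mirna_dir == wantMirnaDir &
                   ret$gene_id %in% genes, , drop = FALSE]
        if (!nrow(sup))
            return(data.frame(gene_id = character(), log2fc = numeric(),
                              mirnas = character(), stringsAsFactors = FALSE))
        ann <- tapply(sup$mirna_id, sup$gene_id, .joinIds)
        g <- sort(names(ann))
        data.frame(gene_id = g,
                   log2fc = geneDe$log2fc[match(g, geneDe$gene_id)],
                   mirnas = as.character(ann[g]),
                   stringsAsFactors = FALSE)
    }
    list(down = confirm("down", "up"), up = confirm("up", "down"))
}

.resolveRepresentation <- function(interactors,
                                   timepointRule = c("concordant", "use24")) {
    timepointRule <- match.arg(timepointRule)
    key <- paste(interactors$bait, interactors$gene_id, sep = "\r")
    out <- lapply(split(interactors, key), function(d) {
        reps <- unique(d$representation)
        if (timepointRule == "concordant") {
            if (length(reps) > 1L) return(NULL)  # discordant -> dropped
            data.frame(bait = d$bait[1L], gene_id = d$gene_id[1L],
                       representation = reps, stringsAsFactors = FALSE)
        } else {
            d24 <- d[d$timepoint_h == 24, , drop = FALSE]
            if (!nrow(d24)) return(NULL)
            data.frame(bait = d$bait[1L], gene_id = d$gene_id[1L],
                       representation = d24$representation[1L],
                       stringsAsFactors = FALSE)
        }
    })
    dropped <- sum(vapply(out, is.null, logical(1)))
    if (dropped)
        message(dropped, " (bait, gene) record(s) dropped by timepoint ",
                "rule '", timepointRule, "'")
    .rbindRows(out)
}

#' Overlay bait interactome calls on confirmed target sets
#'
#' For each immunoprecipitation bait, interactors under-represented after
#' treatment are intersected with the confirmed down-regulated target genes
#' (and over-represented interactors with the confirmed up-regulated ones).
#' Each surviving gene is annotated with the anti-correlated differentially
#' expressed miRNAs that target it, yielding the "bona fide" interactor
#' table. A gene surviving for several baits carries all of them.
#'
#' Per-gene representation calls are reconciled across the 6 h and 24 h
#' timepoints by `timepointRule`: `"concordant"` (default) excludes genes
#' whose two timepoints disagree (with a logged count) and otherwise uses
#' the consistent call; `"use24"` always takes the 24 h call and requires a
#' 24 h record.
#'
#' @param confirmed list from [matchAnticorrelated()].
#' @param interactors `data.frame` with columns `bait`, `gene_id`,
#'   `timepoint_h` (6 or 24), `representation` (`under`/`over`) and
#'   optionally `log10_intensity`.
#' @param timepointRule `"concordant"` or `"use24"`.
#' @return `data.frame` with columns `gene_id`, `direction` (`down` for
#'   under-represented/confirmed-down genes, `up` otherwise), `baits` and
#'   `mirnas` (both semicolon-joined, sorted), sorted by direction then
#'   gene.
#' @export
overlayInteractome <- function(confirmed, interactors,
                               timepointRule = c("concordant", "use24")) {
    if (!nrow(interactors)) stop("empty interactome table")
    calls <- .resolveRepresentation(interactors, timepointRule)
    if (is.null(calls) || !nrow(calls))
        return(data.frame(gene_id = character(), direction = character(),
                          baits = character(), mirnas = character(),
                          stringsAsFactors = FALSE))
    blocks <- list(
        down = calls[calls$representation == "under" &
                     calls$gene_id %in% confirmed$down$gene_id, , drop = FALSE],
        up = calls[calls$representation == "over" &
                   calls$gene_id %in% confirmed$up$gene_id, , drop = FALSE])
    rows <- lapply(names(blocks), function(dir) {
        b <- blocks[[dir]]
        if (!nrow(b)) return(NULL)
        conf <- confirmed[[dir]]
        baits <- tapply(b$bait, b$gene_id, .joinIds)
        g <- sort(names(baits))
        data.frame(gene_id = g, direction = dir,
                   baits = as.character(baits[g]),
                   mirnas = conf$mirnas[match(g, conf$gene_id)],
                   stringsAsFactors = FALSE)
    })
    out <- .rbindRows(rows)
    if (is.null(out))
        return(data.frame(gene_id = character(), direction = character(),
                          baits = character(), mirnas = character(),
                          stringsAsFactors = FALSE))
    out <- out[order(out$direction, out$gene_id), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Interactors shared between baits
#'
#' Returns the down-regulated bona fide interactors associated with every
#' bait in `baits` (by default both the ER-alpha and LSD1 pulldowns).
#'
#' @param bonaFide table from [overlayInteractome()].
#' @param baits bait identifiers that must all be present.
#' @return sorted character vector of gene identifiers.
#' @export
sharedInteractors <- function(bonaFide, baits = c("ERalpha", "LSD1")) {
    down <- bonaFide[bonaFide$direction == "down", , drop = FALSE]
    if (!nrow(down)) return(character())
    has <- vapply(splitIds(down$baits),
                  function(b) all(baits %in% b), logical(1))
    sort(down$gene_id[has])
}

#' Rank convergent candidate miRNAs
#'
#' Scores every miRNA annotated in the bona fide interactor table by the
#' number of shared (both-bait, down-regulated) interactors it targets,
#' then breaks ties by membership in a curated ER-alpha-signaling miRNA
#' set, then by membership in a predicted ESR1-targeting miRNA set, then
#' lexicographically. Ranks are assigned after ordering and form a
#' permutation of 1..n.
#'
#' @param bonaFide table from [overlayInteractome()].
#' @param shared gene vector from [sharedInteractors()].
#' @param erSignalingMirnas curated miRNA ids associated with ER-alpha
#'   signaling (an input list, not inferred).
#' @param esr1TargetMirnas curated miRNA ids predicted to target ESR1.
#' @return `data.frame` with columns `mirna_id`, `n_shared_targets`,
#'   `in_er_signaling`, `targets_esr1`, `rank`.
#' @export
rankCandidates <- function(bonaFide, shared,
                           erSignalingMirnas = character(),
                           esr1TargetMirnas = character()) {
    if (!nrow(bonaFide))
        return(data.frame(mirna_id = character(),
                          n_shared_targets = integer(),
                          in_er_signaling = logical(),
                          targets_esr1 = logical(), rank = integer(),
                          stringsAsFactors = FALSE))
    mirnaSets <- splitIds(bonaFide$mirnas)
    mirnas <- sort(unique(unlist(mirnaSets)))
    downTab <- bonaFide[bonaFide$direction == "down", , drop = FALSE]
    sharedSets <- splitIds(downTab$mirnas[match(shared, downTab$gene_id)])
    nShared <- vapply(mirnas, function(m)
        sum(vapply(sharedSets, function(s) m %in% s, logical(1))),
        integer(1))
    inEr <- mirnas %in% erSignalingMirnas
    esr1 <- mirnas %in% esr1TargetMirnas
    ord <- order(-nShared, -inEr, -esr1, mirnas)
    out <- data.frame(mirna_id = mirnas[ord],
                      n_shared_targets = nShared[ord],
                      in_er_signaling = inEr[ord],
                      targets_esr1 = esr1[ord],
                      rank = seq_along(mirnas),
                      stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
}
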