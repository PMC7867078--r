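#' Run the full inference cascade
#'
#' Orchestrates the stages in order: quantify (normalization, detection,
#' differential expression, Venn decomposition) -> consensus targets ->
#' anti-correlated integration -> interactome overlay -> candidate ranking
#' -> optional over-representation analysis -> optional cohort analysis.
#' Identical inputs and configuration yield identical outputs. A stage
#' failure aborts with the failing stage named; stages already computed
#' are returned via the error's `partial` attribute.
#'
#' @param inputs list with elements `ct` (a [CtExperiment-class]),
#'   `predictions`, `validated` (may be `NULL`), `geneDe`, `interactome`,
#'   `erSignalingMirnas`, `esr1TargetMirnas`, and optionally `collection`
#'   (from [geneSetCollection()]) and `cohort` (list with `measurements`
#'   and `groups`). [simulateStudy()] produces a compatible list.
#' @param quant a [quantConfig()].
#' @param consensus a [consensusConfig()]; when `NULL`, defaults to
#'   `hitMin = 4`, `oeMin = 2` with the universe taken as all genes in
#'   `geneDe`.
#' @param timepointRule passed to [overlayInteractome()].
#' @param outDir optional directory; when given, every stage output is
#'   written there as TSV.
#' @return list with per-stage outputs (`dct`, `calls`, `venn`, `mirnaDe`,
#'   `consensus`, `confirmed`, `bonaFide`, `shared`, `candidates`,
#'   `enrichment`, `cohort`) and a `summary` list.
#' @examples
#' \donttest{
#' study <- simulateStudy(seed = 7)
#' res <- runPipeline(study)
#' res$summary$topCandidate
#' }
#' @export
runPipeline <- function(inputs, quant = quantConfig(), consensus = NULL,
                        timepointRule = "concordant", outDir = NULL) {
    out <- list()
    stage <- function(name, expr) {
        tryCatch(expr, error = function(e) {
            err <- simpleError(paste0("stage '", name, "' failed: ",
                                      conditionMessage(e)))
            attr(err, "partial") <- out
            stop(err)
        })
    }
    out$dct <- stage("quantify", normalizeCt(inputs$ct, quant))
    out$calls <- stage("quantify", callDetection(inputs$ct, quant))
    out$venn <- stage("quantify", vennDecompose(out$calls))
    out$mirnaDe <- stage("quantify",
                         differentialExpression(out$dct, out$calls, quant))
    if (is.null(consensus))
        consensus <- consensusConfig(
            universeSize = length(unique(inputs$geneDe$gene_id)))
    out$consensus <- stage("consensus",
        consensusTargets(inputs$predictions, inputs$validated, consensus))
    out$confirmed <- stage("integrate",
        matchAnticorrelated(inputs$geneDe, out$consensus, out$mirnaDe))
    if (!is.null(inputs$interactome)) {
        out$bonaFide <- stage("overlay",
            overlayInteractome(out$confirmed, inputs$interactome,
                               timepointRule = timepointRule))
        out$shared <- stage("overlay", sharedInteractors(out$bonaFide))
        out$candidates <- stage("rank",
            rankCandidates(out$bonaFide, out$shared,
                           inputs$erSignalingMirnas,
                           inputs$esr1TargetMirnas))
    }
    if (!is.null(inputs$collection)) {
        out$enrichment <- stage("enrich",
            oraTest(out$confirmed$down$gene_id, inputs$collection))
    }
    if (!is.null(inputs$cohort)) {
        out$cohort <- stage("cohort", {
            folds <- treatmentResponse(inputs$cohort$measurements, quant)
            list(tumorVsNormal = tumorVsNormal(inputs$cohort$measurements,
                                               quant),
                 folds = folds,
                 contrast = rbind(
                     groupResponseContrast(folds, inputs$cohort$groups,
                                           "tumor"),
                     groupResponseContrast(folds, inputs$cohort$groups,
                                           "normal")))
        })
    }
    out$summary <- list(
        venn = out$venn,
        nDeUp = sum(out$mirnaDe$direction == "up"),
        nDeDown = sum(out$mirnaDe$direction == "down"),
        nRetainedPairs = sum(out$consensus$retained),
        nConfirmedDown = nrow(out$confirmed$down),
        nConfirmedUp = nrow(out$confirmed$up),
        nBonaFide = if (is.null(out$bonaFide)) NA_integer_
                    else nrow(out$bonaFide),
        sharedInteractors = out$shared,
        topCandidate = if (is.null(out$candidates) || !nrow(out$candidates))
            NA_character_ else out$candidates$mirna_id[1L])
    if (!is.null(outDir)) {
        if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
        writeTsvTable(out$dct, file.path(outDir, "dct.tsv"))
        writeTsvTable(out$calls, file.path(outDir, "detection_calls.tsv"))
        writeTsvTable(out$mirnaDe, file.path(outDir, "mirna_de.tsv"))
        writeTsvTable(out$consensus, file.path(outDir, "consensus.tsv"))
        if (!is.null(out$bonaFide)) {
            writeTsvTable(out$bonaFide, file.path(outDir, "bona_fide.tsv"))
            writeInteractorBlocks(out$bonaFide,
                                  file.path(outDir,
                                            "interactor_blocks.tsv"))
            writeTsvTable(out$candidates,
                          file.path(outDir, "candidates.tsv"))
        }
        if (!is.null(out$enrichment))
            writeTsvTable(out$enrichment,
                          file.path(outDir, "enrichment.tsv"))
        if (!is.null(out$cohort)) {
            writeTsvTable(out$cohort$tumorVsNormal,
                          file.path(outDir, "tumor_vs_normal.tsv"))
            writeTsvTable(out$cohort$folds,
                          file.path(outDir, "treatment_response.tsv"))
            writeTsvTable(out$cohort$contrast,
                          file.path(outDir, "group_contrast.tsv"))
        }
    }
    out
}
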