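#' Simulate a qPCR CT matrix with planted effects
#'
#' Emulates a miRNome profiling panel: each miRNA receives a baseline CT
#' drawn uniformly within `baselineCtRange`; treated-condition wells are
#' shifted by the planted \eqn{\Delta\Delta Ct} effect (negative effect =
#' up-regulation after treatment); Gaussian noise with standard deviation
#' `ctNoiseSd` cycles is added to every well. Condition-specific miRNAs are
#' emitted above the upper detection bound in the opposite condition, and
#' reference assays carry no planted effect.
#'
#' @param nMirnas number of (non-reference) miRNA assays.
#' @param nReplicates replicates per condition.
#' @param ctNoiseSd Gaussian CT noise, cycles.
#' @param baselineCtRange baseline CT interval (within the detection
#'   bounds).
#' @param plantedDe named numeric vector of \eqn{\Delta\Delta Ct} effects
#'   (names are assay ids, values in cycles; negative = up).
#' @param plantedControlOnly,plantedTreatedOnly assay ids emitted only in
#'   one condition (CT above `undetectedCt` elsewhere).
#' @param nReference number of reference assays appended (ids
#'   `sim-ref-*`), emitted at CT 20 with no planted effect.
#' @param undetectedCt CT value used for non-expressed wells (above the
#'   upper detection bound).
#' @param seed optional integer seed (full determinism).
#' @return list with elements `ct` (a [CtExperiment-class]) and `truth`
#'   (the planted assignments).
#' @examples
#' sim <- simulateCtMatrix(nMirnas = 20, ctNoiseSd = 0,
#'                         plantedDe = c("sim-miR-001" = -3), seed = 1)
#' sim$truth$plantedDe
#' @export
simulateCtMatrix <- function(nMirnas = 300, nReplicates = 3,
                             ctNoiseSd = 0.2, baselineCtRange = c(20, 30),
                             plantedDe = numeric(),
                             plantedControlOnly = character(),
                             plantedTreatedOnly = character(),
                             nReference = 2, undetectedCt = 42,
                             seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    ids <- sprintf("sim-miR-%03d", seq_len(nMirnas))
    bad <- setdiff(c(names(plantedDe), plantedControlOnly,
                     plantedTreatedOnly), ids)
    if (length(bad))
        stop("planted id(s) outside the generated assay space: ",
             paste(bad, collapse = ", "))
    refs <- if (nReference > 0) sprintf("sim-ref-%d", seq_len(nReference))
            else character()
    allIds <- c(ids, refs)
    baseline <- c(runif(nMirnas, baselineCtRange[1], baselineCtRange[2]),
                  rep(20, nReference))
    names(baseline) <- allIds
    effect <- setNames(rep(0, length(allIds)), allIds)
    effect[names(plantedDe)] <- plantedDe

    samples <- c(sprintf("ctrl_r%d", seq_len(nReplicates)),
                 sprintf("trt_r%d", seq_len(nReplicates)))
    condition <- rep(c("control", "treated"), each = nReplicates)
    ct <- matrix(NA_real_, nrow = length(allIds), ncol = length(samples),
                 dimnames = list(allIds, samples))
    for (j in seq_along(samples)) {
        mu <- baseline + if (condition[j] == "treated") effect else 0
        ct[, j] <- mu + rnorm(length(allIds), sd = ctNoiseSd)
    }
    ct[plantedControlOnly, condition == "treated"] <- undetectedCt
    ct[plantedTreatedOnly, condition == "control"] <- undetectedCt

    list(ct = CtExperiment(ct, condition,
                           replicate = rep(seq_len(nReplicates), 2),
                           referenceAssays = refs),
         truth = list(plantedDe = plantedDe,
                      plantedControlOnly = plantedControlOnly,
                      plantedTreatedOnly = plantedTreatedOnly,
                      baseline = baseline))
}

#' Simulate multi-tool target-prediction tables
#'
#' Each tool reports each true (miRNA, gene) pair with probability
#' `toolSensitivity` and each false pair (every other gene in the
#' universe) with probability `toolFpr`. A validated-interaction set is
#' sampled from the true pairs.
#'
#' @param trueTargetMap named list: miRNA id -> character vector of true
#'   target genes.
#' @param geneUniverse character vector of all gene ids the tools consider.
#' @param nTools number of prediction tools.
#' @param toolSensitivity per-tool probability of reporting a true pair.
#' @param toolFpr per-tool probability of reporting any given false pair.
#' @param nValidated number of true pairs flagged as validated.
#' @param seed optional integer seed.
#' @return list with `predictions` (`tool`, `mirna_id`, `gene_id`),
#'   `validated` (`mirna_id`, `gene_id`) and `truth` (the true pair table).
#' @export
simulatePredictions <- function(trueTargetMap, geneUniverse, nTools = 7,
                                toolSensitivity = 0.8, toolFpr = 0.001,
                                nValidated = 20, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    tools <- sprintf("tool-%d", seq_len(nTools))
    truePairs <- data.frame(
        mirna_id = rep(names(trueTargetMap),
                       vapply(trueTargetMap, length, integer(1))),
        gene_id = unlist(trueTargetMap, use.names = FALSE),
        stringsAsFactors = FALSE)
    rows <- vector("list", nTools * (length(trueTargetMap) + 1L))
    k <- 0L
    for (t in tools) {
        keep <- runif(nrow(truePairs)) < toolSensitivity
        if (any(keep)) {
            k <- k + 1L
            rows[[k]] <- data.frame(tool = t,
                                    truePairs[keep, , drop = FALSE],
                                    stringsAsFactors = FALSE)
        }
        for (m in names(trueTargetMap)) {
            falseGenes <- setdiff(geneUniverse, trueTargetMap[[m]])
            nf <- rbinom(1, length(falseGenes), toolFpr)
            if (nf > 0) {
                k <- k + 1L
                rows[[k]] <- data.frame(
                    tool = t, mirna_id = m,
                    gene_id = sample(falseGenes, nf),
                    stringsAsFactors = FALSE)
            }
        }
    }
    predictions <- .rbindRows(rows[seq_len(k)])
    if (is.null(predictions))
        predictions <- data.frame(tool = character(),
                                  mirna_id = character(),
                                  gene_id = character(),
                                  stringsAsFactors = FALSE)
    vIdx <- sample(nrow(truePairs), min(nValidated, nrow(truePairs)))
    list(predictions = predictions,
         validated = truePairs[sort(vIdx), , drop = FALSE],
         truth = list(truePairs = truePairs))
}

#' Simulate a transcriptome DE table with planted anti-correlation
#'
#' True targets of planted up-regulated miRNAs receive a negative log2
#' fold change with probability `anticorrelationStrength` (and targets of
#' down-regulated miRNAs a positive one); all other genes draw
#' `log2fc ~ N(0, log2fcSd)`.
#'
#' @param trueTargetMap named list: miRNA id -> target genes.
#' @param mirnaDirections named character vector (`up`/`down`) for the
#'   planted miRNAs.
#' @param geneUniverse all gene ids.
#' @param log2fcSd background fold-change spread.
#' @param anticorrelationStrength probability a true target receives the
#'   direction opposite to its miRNA.
#' @param effectMean,effectSd magnitude distribution of planted gene
#'   effects (absolute log2 fold change).
#' @param seed optional integer seed.
#' @return list with `geneDe` (`gene_id`, `log2fc`) and `truth`
#'   (`plantedDown`, `plantedUp` gene vectors).
#' @export
simulateGeneDe <- function(trueTargetMap, mirnaDirections, geneUniverse,
                           log2fcSd = 1, anticorrelationStrength = 0.9,
                           effectMean = 1.5, effectSd = 0.4, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    log2fc <- rnorm(length(geneUniverse), 0, log2fcSd)
    names(log2fc) <- geneUniverse
    plantedDown <- character(); plantedUp <- character()
    for (m in names(trueTargetMap)) {
        dir <- mirnaDirections[[m]]
        if (is.null(dir) || !dir %in% c("up", "down")) next
        for (g in trueTargetMap[[m]]) {
            if (runif(1) < anticorrelationStrength) {
                mag <- abs(rnorm(1, effectMean, effectSd)) + 0.2
                if (dir == "up") {
                    log2fc[g] <- -mag; plantedDown <- c(plantedDown, g)
                } else {
                    log2fc[g] <- mag; plantedUp <- c(plantedUp, g)
                }
            }
        }
    }
    list(geneDe = data.frame(gene_id = geneUniverse,
                             log2fc = unname(log2fc),
                             stringsAsFactors = FALSE),
         truth = list(plantedDown = unique(plantedDown),
                      plantedUp = unique(plantedUp)))
}

#' Simulate a bait interactome table from an under/over plan
#'
#' The plan is emitted verbatim as concordant 6 h and 24 h records with
#' Gaussian noise on the log10 intensity.
#'
#' @param plan `data.frame` with columns `bait`, `gene_id`,
#'   `representation` (`under`/`over`).
#' @param intensityMean,intensityNoiseSd log10 intensity location and
#'   noise.
#' @param timepoints timepoints (hours) at which each record is emitted.
#' @param seed optional integer seed.
#' @return `data.frame` with columns `bait`, `gene_id`, `timepoint_h`,
#'   `representation`, `log10_intensity`.
#' @export
simulateInteractome <- function(plan, intensityMean = 5,
                                intensityNoiseSd = 0.1,
                                timepoints = c(6, 24), seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    key <- paste(plan$bait, plan$gene_id)
    conflict <- tapply(plan$representation, key,
                       function(r) length(unique(r)) > 1L)
    if (any(conflict))
        stop("inconsistent plan: gene(s) both under- and over-represented ",
             "for one bait: ",
             paste(names(conflict)[conflict], collapse = ", "))
    plan <- unique(plan[, c("bait", "gene_id", "representation")])
    if (!nrow(plan))
        return(data.frame(bait = character(), gene_id = character(),
                          timepoint_h = numeric(),
                          representation = character(),
                          log10_intensity = numeric(),
                          stringsAsFactors = FALSE))
    out <- do.call(rbind, lapply(timepoints, function(tp) {
        data.frame(bait = plan$bait, gene_id = plan$gene_id,
                   timepoint_h = tp, representation = plan$representation,
                   log10_intensity = rnorm(nrow(plan), intensityMean,
                                           intensityNoiseSd),
                   stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out
}

#' Simulate a paired tumor/normal treatment cohort
#'
#' Emulates the ex vivo cohort design: each patient contributes paired
#' tumor and adjacent-normal tissue, each measured under a control arm and
#' a treated (MC3324) arm. Baseline tumor/normal expression ratios and
#' group-mean treatment-response folds are planted; multiplicative
#' log-normal noise (`noiseSdLog` on the log scale) preserves positivity.
#' Fold draws use `meanlog = log(m) - noiseSdLog^2/2` so the planted group
#' means are unbiased.
#'
#' Defaults mirror the study conditions: 18 patients of which 5
#' (#4, 7, 8, 13, 14) are ER-alpha-negative; baseline tumor/normal
#' down-regulation in 15 patients (ratio 0.25) and up-regulation in 3
#' (ratio 4); group-mean response folds 1.73 vs 1.00 in tumor tissue and
#' 1.38 vs 1.00 in normal tissue.
#'
#' @param nPatients cohort size.
#' @param erNegative indices of ER-alpha-negative patients.
#' @param upPatients indices of patients with tumor > normal baseline.
#' @param downRatio,upRatio planted baseline tumor/normal ratios.
#' @param groupMeanFold named numeric vector with elements `tumor_pos`,
#'   `tumor_neg`, `normal_pos`, `normal_neg` (planted group-mean
#'   treatment-response folds).
#' @param noiseSdLog log-scale noise standard deviation (0 = noiseless).
#' @param mirna measured miRNA identifier.
#' @param seed optional integer seed.
#' @return list with `measurements` (`patient_id`, `tissue`, `treatment`,
#'   `mirna_id`, `value`), `groups` (`patient_id`, `group`) and `truth`.
#' @export
simulateCohort <- function(nPatients = 18,
                           erNegative = c(4, 7, 8, 13, 14),
                           upPatients = c(16, 17, 18),
                           downRatio = 0.25, upRatio = 4,
                           groupMeanFold = c(tumor_pos = 1.73,
                                             tumor_neg = 1,
                                             normal_pos = 1.38,
                                             normal_neg = 1),
                           noiseSdLog = 0.2, mirna = "miR-181a-5p",
                           seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    pid <- sprintf("PT%d", seq_len(nPatients))
    group <- ifelse(seq_len(nPatients) %in% erNegative,
                    "ER_negative", "ER_positive")
    ratio <- ifelse(seq_len(nPatients) %in% upPatients, upRatio, downRatio)
    drawFold <- function(m, n) {
        exp(rnorm(n, log(m) - noiseSdLog^2 / 2, noiseSdLog))
    }
    rows <- lapply(seq_len(nPatients), function(i) {
        normalCtrl <- exp(rnorm(1, 0, noiseSdLog))
        tumorCtrl <- normalCtrl * ratio[i] *
            exp(rnorm(1, -noiseSdLog^2 / 2, noiseSdLog))
        g <- if (group[i] == "ER_positive") "pos" else "neg"
        tumorFold <- drawFold(groupMeanFold[[paste0("tumor_", g)]], 1)
        normalFold <- drawFold(groupMeanFold[[paste0("normal_", g)]], 1)
        data.frame(patient_id = pid[i],
                   tissue = rep(c("tumor", "normal"), each = 2),
                   treatment = rep(c("ctrl", "MC3324"), 2),
                   mirna_id = mirna,
                   value = c(tumorCtrl, tumorCtrl * tumorFold,
                             normalCtrl, normalCtrl * normalFold),
                   stringsAsFactors = FALSE)
    })
    list(measurements = .rbindRows(rows),
         groups = data.frame(patient_id = pid, group = group,
                             stringsAsFactors = FALSE),
         truth = list(erNegative = pid[erNegative],
                      upPatients = pid[upPatients],
                      tumorNormalRatio = setNames(ratio, pid),
                      groupMeanFold = groupMeanFold))
}

#' Simulate a complete multi-omics study with one planted convergent miRNA
#'
#' Generates every pipeline input under one seed: a profiling CT matrix
#' with 40 up- and 40 down-regulated miRNAs (|ddCt| drawn in [1.5, 3]),
#' condition-specific miRNAs, a seven-tool prediction table over a
#' 2000-gene universe, an anti-correlated transcriptome DE table, a
#' two-bait interactome in which the targets of one designated convergent
#' up-regulated miRNA are under-represented for both baits (single-bait
#' decoys included), curated miRNA sets containing the convergent miRNA,
#' and a paired treatment cohort.
#'
#' @param seed integer seed (fully determines the output).
#' @param nMirnas,nGenes,nTools problem sizes.
#' @param nUp,nDown numbers of planted up-/down-regulated miRNAs.
#' @param nControlOnly,nTreatedOnly condition-specific miRNA counts.
#' @param targetsPerMirna true targets per planted miRNA (disjoint sets).
#' @param nConvergentTargets how many of the convergent miRNA's targets
#'   are planted as both-bait under-represented interactors.
#' @param ctNoiseSd,toolSensitivity,toolFpr,anticorrelationStrength noise
#'   and error rates.
#' @return list with `ct`, `predictions`, `validated`, `geneDe`,
#'   `interactome`, `erSignalingMirnas`, `esr1TargetMirnas`, `cohort` and
#'   `truth` (including `convergentMirna`).
#' @export
simulateStudy <- function(seed = 1, nMirnas = 300, nGenes = 2000,
                          nTools = 7, nUp = 40, nDown = 40,
                          nControlOnly = 6, nTreatedOnly = 3,
                          targetsPerMirna = 10, nConvergentTargets = 4,
                          ctNoiseSd = 0.2, toolSensitivity = 0.8,
                          toolFpr = 0.001,
                          anticorrelationStrength = 0.9) {
    set.seed(seed)
    ids <- sprintf("sim-miR-%03d", seq_len(nMirnas))
    pool <- sample(ids)
    upM <- pool[seq_len(nUp)]
    downM <- pool[nUp + seq_len(nDown)]
    ctrlOnly <- pool[nUp + nDown + seq_len(nControlOnly)]
    trtOnly <- pool[nUp + nDown + nControlOnly + seq_len(nTreatedOnly)]
    convergent <- upM[1L]
    eff <- c(setNames(-runif(nUp, 1.5, 3), upM),
             setNames(runif(nDown, 1.5, 3), downM))
    eff[convergent] <- -3

    genes <- sprintf("GENE%04d", seq_len(nGenes))
    planted <- c(upM, downM)
    targetGenes <- sample(genes, length(planted) * targetsPerMirna)
    trueTargetMap <- split(targetGenes,
                           rep(planted, each = targetsPerMirna))
    mirnaDirections <- c(setNames(rep("up", nUp), upM),
                         setNames(rep("down", nDown), downM))

    sim <- simulateCtMatrix(nMirnas = nMirnas, ctNoiseSd = ctNoiseSd,
                            plantedDe = eff,
                            plantedControlOnly = ctrlOnly,
                            plantedTreatedOnly = trtOnly)
    preds <- simulatePredictions(trueTargetMap, genes, nTools = nTools,
                                 toolSensitivity = toolSensitivity,
                                 toolFpr = toolFpr)
    gde <- simulateGeneDe(trueTargetMap, mirnaDirections, genes,
                          anticorrelationStrength = anticorrelationStrength)

    convTargets <- trueTargetMap[[convergent]][seq_len(nConvergentTargets)]
    decoyUp <- utils::head(setdiff(upM, convergent), 6)
    decoyDown <- utils::head(downM, 3)
    plan <- rbind(
        data.frame(bait = rep(c("ERalpha", "LSD1"),
                              each = length(convTargets)),
                   gene_id = rep(convTargets, 2), representation = "under",
                   stringsAsFactors = FALSE),
        data.frame(bait = "ERalpha",
                   gene_id = vapply(trueTargetMap[decoyUp], `[`, "", 1L),
                   representation = "under", stringsAsFactors = FALSE),
        data.frame(bait = "LSD1",
                   gene_id = vapply(trueTargetMap[decoyDown], `[`, "", 1L),
                   representation = "over", stringsAsFactors = FALSE),
        local({
            unrelated <- setdiff(genes, targetGenes)
            if (!length(unrelated)) return(NULL)
            data.frame(bait = "ERalpha",
                       gene_id = sample(unrelated,
                                        min(5, length(unrelated))),
                       representation = "under", stringsAsFactors = FALSE)
        }))
    interactome <- simulateInteractome(plan)
    cohort <- simulateCohort()

    list(ct = sim$ct, predictions = preds$predictions,
         validated = preds$validated, geneDe = gde$geneDe,
         interactome = interactome,
         erSignalingMirnas = c(convergent, decoyUp[1:2]),
         esr1TargetMirnas = convergent,
         cohort = cohort,
         truth = list(upMirnas = upM, downMirnas = downM,
                      controlOnly = ctrlOnly, treatedOnly = trtOnly,
                      effects = eff, convergentMirna = convergent,
                      convergentTargets = convTargets,
                      trueTargetMap = trueTargetMap,
                      geneTruth = gde$truth,
                      truePairs = preds$truth$truePairs))
}
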