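#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData rowData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats phyper p.adjust rbinom rnorm runif setNames
#' @importFrom utils read.delim write.table
NULL

#' CtExperiment: qPCR cycle-threshold matrices with sample annotations
#'
#' `CtExperiment` extends
#' [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#' to hold a miRNA-by-sample matrix of qPCR cycle-threshold (CT) values
#' together with the per-sample condition (`control` / `treated`) and
#' replicate labels required for \eqn{-\Delta\Delta Ct} quantification.
#' Lower CT means higher abundance; `NA` encodes a non-amplifying
#' (undetected) well. Rows flagged in `rowData(x)$is_reference` are
#' normalization reference assays (for example the RNU6B small nuclear RNA).
#'
#' @slot . inherits all slots from `SummarizedExperiment`; the single assay
#'   is named `"ct"`.
#'
#' @seealso [normalizeCt()], [callDetection()], [simulateCtMatrix()]
#' @export
setClass("CtExperiment", contains = "SummarizedExperiment")

.validCtExperiment <- function(object) {
    msg <- character()
    if (!("ct" %in% SummarizedExperiment::assayNames(object)))
        msg <- c(msg, "assay 'ct' is required")
    cd <- SummarizedExperiment::colData(object)
    if (!("condition" %in% colnames(cd))) {
        msg <- c(msg, "colData must contain a 'condition' column")
    } else {
        cond <- as.character(cd$condition)
        bad <- setdiff(unique(cond), c("control", "treated"))
        if (length(bad))
            msg <- c(msg, paste0("unknown condition label(s): ",
                                 paste(bad, collapse = ", ")))
        if (!all(c("control", "treated") %in% cond))
            msg <- c(msg, "at least one sample per condition is required")
    }
    if ("replicate" %in% colnames(cd)) {
        rep <- cd$replicate
        if (any(is.na(rep)) || any(rep < 1) || any(rep != round(rep)))
            msg <- c(msg, "'replicate' must be positive integers")
    }
    if ("ct" %in% SummarizedExperiment::assayNames(object)) {
        ct <- SummarizedExperiment::assay(object, "ct")
        if (!is.numeric(ct))
            msg <- c(msg, "CT values must be numeric")
        if (any(is.infinite(ct)))
            msg <- c(msg, "CT values must be finite or missing (NA)")
    }
    rd <- SummarizedExperiment::rowData(object)
    if ("is_reference" %in% colnames(rd) && !is.logical(rd$is_reference))
        msg <- c(msg, "rowData 'is_reference' must be logical")
    if (length(msg)) msg else TRUE
}

setValidity("CtExperiment", .validCtExperiment)

#' Construct a CtExperiment
#'
#' @param ct numeric matrix of CT values, rows = miRNA assays (rownames
#'   required), columns = samples (colnames required). `NA` marks an
#'   undetected well.
#' @param condition character vector (one per sample) with values
#'   `"control"` or `"treated"`.
#' @param replicate integer replicate index per sample; defaults to
#'   1..k within each condition.
#' @param referenceAssays character vector of assay (row) identifiers to be
#'   used as normalization references; must be a subset of `rownames(ct)`.
#'
#' @return A [CtExperiment-class] object.
#' @examples
#' ct <- matrix(c(25, 25.2, 24.1, 24.3, 20, 20, 20, 20), nrow = 2,
#'              byrow = TRUE,
#'              dimnames = list(c("miR-1", "RNU6B"),
#'                              c("c1", "c2", "t1", "t2")))
#' cte <- CtExperiment(ct, condition = c("control", "control",
#'                                       "treated", "treated"),
#'                     referenceAssays = "RNU6B")
#' referenceAssays(cte)
#' @export
CtExperiment <- function(ct, condition, replicate = NULL,
                         referenceAssays = character()) {
    if (is.null(rownames(ct)) || is.null(colnames(ct)))
        stop("'ct' must have row (assay) and column (sample) names")
    condition <- as.character(condition)
    if (length(condition) != ncol(ct))
        stop("'condition' must have one entry per sample")
    if (is.null(replicate)) {
        replicate <- stats::ave(seq_along(condition), condition,
                                FUN = seq_along)
    }
    extra <- setdiff(referenceAssays, rownames(ct))
    if (length(extra))
        stop("reference assay(s) not in matrix: ",
             paste(extra, collapse = ", "))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(ct = ct),
        colData = S4Vectors::DataFrame(
            condition = condition,
            replicate = as.integer(replicate),
            row.names = colnames(ct)),
        rowData = S4Vectors::DataFrame(
            is_reference = rownames(ct) %in% referenceAssays,
            row.names = rownames(ct)))
    methods::new("CtExperiment", se)
}

#' @describeIn CtExperiment CT value matrix accessor.
#' @param x a `CtExperiment`
#' @export
ctValues <- function(x) SummarizedExperiment::assay(x, "ct")

#' @describeIn CtExperiment identifiers of the normalization reference
#'   assays (possibly empty).
#' @export
referenceAssays <- function(x) {
    rd <- SummarizedExperiment::rowData(x)
    if (!("is_reference" %in% colnames(rd))) return(character())
    rownames(x)[rd$is_reference]
}

#' @describeIn CtExperiment per-sample condition labels, named by sample.
#' @export
sampleConditions <- function(x) {
    setNames(as.character(SummarizedExperiment::colData(x)$condition),
             colnames(x))
}

setMethod("show", "CtExperiment", function(object) {
    cond <- table(sampleConditions(object))
    cat("CtExperiment with", nrow(object), "assays,",
        ncol(object), "samples\n")
    cat("  conditions:",
        paste(sprintf("%s=%d", names(cond), cond), collapse = ", "), "\n")
    nref <- length(referenceAssays(object))
    cat("  reference assays:", nref, "\n")
    nmiss <- sum(is.na(ctValues(object)))
    cat("  missing CT wells:", nmiss, "\n")
    invisible(NULL)
})

#' Quantification configuration
#'
#' Holds the detection bounds and fold-change thresholds used by the
#' \eqn{-\Delta\Delta Ct} quantification operations. An assay is considered
#' detected in a well when `ctMin <= CT <= ctMax` (bounds inclusive); a
#' miRNA is called up-regulated when its relative quantity
#' \eqn{2^{-\Delta\Delta Ct}} is `>= foldUp` and down-regulated when it is
#' `<= foldDown = 1/foldUp`, both inclusive.
#'
#' @slot ctMin,ctMax detection bounds on the CT (cycle) scale.
#' @slot foldUp,foldDown inclusive fold-change thresholds;
#'   `foldDown == 1/foldUp` is enforced.
#' @slot normalization `"reference"` (subtract the mean CT of the reference
#'   assay set) or `"global_mean"` (subtract the per-sample mean CT over all
#'   in-bounds assays, the usual choice for profiling panels without a
#'   designated reference).
#' @slot detectionRule `"all_replicates"` (every replicate in-bounds) or
#'   `"majority"` (more than half).
#' @export
setClass("QuantConfig", representation(
    ctMin = "numeric", ctMax = "numeric",
    foldUp = "numeric", foldDown = "numeric",
    normalization = "character", detectionRule = "character"))

setValidity("QuantConfig", function(object) {
    msg <- character()
    if (object@ctMin >= object@ctMax) msg <- c(msg, "ctMin must be < ctMax")
    if (object@foldUp <= 1) msg <- c(msg, "foldUp must be > 1")
    if (abs(object@foldDown - 1 / object@foldUp) > 1e-12)
        msg <- c(msg, "foldDown must equal 1/foldUp")
    if (!object@normalization %in% c("reference", "global_mean"))
        msg <- c(msg, "normalization must be 'reference' or 'global_mean'")
    if (!object@detectionRule %in% c("all_replicates", "majority"))
        msg <- c(msg, "detectionRule must be 'all_replicates' or 'majority'")
    if (length(msg)) msg else TRUE
})

#' @rdname QuantConfig-class
#' @param ctMin,ctMax inclusive CT detection bounds (default 16 and 37).
#' @param foldUp inclusive up-regulation threshold on the
#'   \eqn{2^{-\Delta\Delta Ct}} scale (default 2; down threshold is its
#'   reciprocal).
#' @param normalization `"global_mean"` (default, profiling panels) or
#'   `"reference"` (validation qPCR against e.g. RNU6B).
#' @param detectionRule `"all_replicates"` (default) or `"majority"`.
#' @return A `QuantConfig` object.
#' @examples
#' quantConfig()
#' quantConfig(normalization = "reference")
#' @export
quantConfig <- function(ctMin = 16, ctMax = 37, foldUp = 2,
                        normalization = c("global_mean", "reference"),
                        detectionRule = c("all_replicates", "majority")) {
    methods::new("QuantConfig", ctMin = ctMin, ctMax = ctMax,
                 foldUp = foldUp, foldDown = 1 / foldUp,
                 normalization = match.arg(normalization),
                 detectionRule = match.arg(detectionRule))
}

setMethod("show", "QuantConfig", function(object) {
    cat(sprintf(paste0("QuantConfig: detection %g <= CT <= %g; fold ",
                       "thresholds >= %g (up) / <= %g (down), inclusive\n"),
                object@ctMin, object@ctMax, object@foldUp, object@foldDown))
    cat("  normalization:", object@normalization,
        "| detection rule:", object@detectionRule, "\n")
    invisible(NULL)
})

#' Consensus-target configuration
#'
#' Inclusion thresholds for consensus miRNA-target filtering: a
#' (miRNA, gene) pair is retained when it is supported by at least `hitMin`
#' distinct sources (prediction tools, plus one for validated evidence) AND
#' its observed/expected ratio is at least `oeMin`, both inclusive.
#'
#' @slot hitMin minimum HIT count (default 4).
#' @slot oeMin minimum observed/expected ratio (default 2).
#' @slot universeSize number of genes in the prediction universe.
#' @export
setClass("ConsensusConfig", representation(
    hitMin = "numeric", oeMin = "numeric", universeSize = "numeric"))

setValidity("ConsensusConfig", function(object) {
    msg <- character()
    if (object@hitMin < 1) msg <- c(msg, "hitMin must be >= 1")
    if (object@universeSize < 1) msg <- c(msg, "universeSize must be >= 1")
    if (object@oeMin < 0) msg <- c(msg, "oeMin must be >= 0")
    if (length(msg)) msg else TRUE
})

#' @rdname ConsensusConfig-class
#' @param hitMin minimum number of distinct supporting sources (default 4).
#' @param oeMin minimum observed/expected ratio (default 2).
#' @param universeSize number of genes the tools consider.
#' @return A `ConsensusConfig` object.
#' @examples
#' consensusConfig(universeSize = 2000)
#' @export
consensusConfig <- function(hitMin = 4, oeMin = 2, universeSize) {
    methods::new("ConsensusConfig", hitMin = hitMin, oeMin = oeMin,
                 universeSize = universeSize)
}

setMethod("show", "ConsensusConfig", function(object) {
    cat(sprintf(paste0("ConsensusConfig: retain HIT >= %g AND O/E >= %g ",
                       "(universe %g genes)\n"),
                object@hitMin, object@oeMin, object@universeSize))
    invisible(NULL)
})
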