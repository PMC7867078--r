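#' Normalize CT values to per-condition delta-Ct
#'
#' Computes \eqn{\Delta Ct(\mathrm{assay}, \mathrm{condition}) =
#' \overline{CT}(\mathrm{assay}) - \overline{CT}(\mathrm{reference\ term})}
#' within each condition. Replicate CT values are averaged on the CT scale
#' before subtraction. With `normalization = "reference"` the reference term
#' is the mean CT of the reference assay set within the condition; with
#' `"global_mean"` it is the mean over samples of each sample's mean CT over
#' all in-bounds assays (the standard global-mean normalization for
#' profiling panels with no designated reference).
#'
#' Missing CT wells are dropped from the averages; an assay with no finite
#' CT in a condition gets a missing (`NA`) delta-Ct, never zero.
#'
#' @param x a [CtExperiment-class].
#' @param config a [quantConfig()] object.
#' @return `data.frame` with columns `mirna_id`, `dct_control`,
#'   `dct_treated` (cycles), one row per assay, in matrix row order.
#' @examples
#' ct <- matrix(c(25, 24, 20, 20), nrow = 2, byrow = TRUE,
#'              dimnames = list(c("miR-1", "RNU6B"), c("c1", "t1")))
#' cte <- CtExperiment(ct, c("control", "treated"), referenceAssays = "RNU6B")
#' normalizeCt(cte, quantConfig(normalization = "reference"))
#' @export
normalizeCt <- function(x, config = quantConfig()) {
    stopifnot(methods::is(x, "CtExperiment"), methods::is(config, "QuantConfig"))
    ct <- ctValues(x)
    cond <- sampleConditions(x)
    refs <- referenceAssays(x)
    if (config@normalization == "reference" && length(refs) == 0)
        stop("normalization = 'reference' requires at least one reference ",
             "assay; none flagged")

    condMean <- function(cols) {
        m <- ct[, cols, drop = FALSE]
        mm <- rowMeans(m, na.rm = TRUE)
        mm[!is.finite(mm)] <- NA_real_
        mm
    }
    refTerm <- function(cols) {
        if (config@normalization == "reference") {
            for (s in cols) {
                if (all(is.na(ct[refs, s])))
                    stop("reference assay CT missing in sample '", s,
                         "' under reference normalization")
            }
            mean(ct[refs, cols], na.rm = TRUE)
        } else {
            inb <- ct[, cols, drop = FALSE]
            inb[inb < config@ctMin | inb > config@ctMax] <- NA
            perSample <- colMeans(inb, na.rm = TRUE)
            if (any(!is.finite(perSample)))
                stop("no in-bounds CT values in sample(s): ",
                     paste(cols[!is.finite(perSample)], collapse = ", "))
            mean(perSample)
        }
    }
    out <- data.frame(mirna_id = rownames(ct), stringsAsFactors = FALSE)
    for (cc in c("control", "treated")) {
        cols <- names(cond)[cond == cc]
        out[[paste0("dct_", cc)]] <- condMean(cols) - refTerm(cols)
    }
    rownames(out) <- NULL
    out
}

#' Call per-condition detection status
#'
#' An assay is "expressed" in a condition when its replicate CT values lie
#' within the inclusive detection bounds `[ctMin, ctMax]` under the
#' configured detection rule (`all_replicates`: every replicate in-bounds;
#' `majority`: more than half). A missing CT counts as out-of-bounds, never
#' imputed. The two per-condition flags map to one of four expression
#' classes: `common`, `control_only`, `treated_only`, `undetected`.
#'
#' @inheritParams normalizeCt
#' @return `data.frame` with columns `mirna_id`, `expressed_control`,
#'   `expressed_treated` (logical) and `status`.
#' @export
callDetection <- function(x, config = quantConfig()) {
    stopifnot(methods::is(x, "CtExperiment"), methods::is(config, "QuantConfig"))
    ct <- ctValues(x)
    cond <- sampleConditions(x)
    inBounds <- !is.na(ct) & ct >= config@ctMin & ct <= config@ctMax
    expressedIn <- function(cc) {
        m <- inBounds[, names(cond)[cond == cc], drop = FALSE]
        if (config@detectionRule == "all_replicates")
            rowSums(m) == ncol(m)
        else
            rowSums(m) > ncol(m) / 2
    }
    ec <- expressedIn("control")
    et <- expressedIn("treated")
    status <- ifelse(ec & et, "common",
              ifelse(ec, "control_only",
              ifelse(et, "treated_only", "undetected")))
    data.frame(mirna_id = rownames(ct), expressed_control = unname(ec),
               expressed_treated = unname(et), status = unname(status),
               stringsAsFactors = FALSE)
}

#' Differential miRNA expression by the -ddCt method
#'
#' Scores every commonly expressed assay:
#' \eqn{\Delta\Delta Ct = \Delta Ct_{treated} - \Delta Ct_{control}},
#' relative quantity \eqn{RQ = 2^{-\Delta\Delta Ct}}, and a direction call
#' by the inclusive thresholds (`up` iff `RQ >= foldUp`, `down` iff
#' `RQ <= foldDown`, otherwise `unchanged`). Output is sorted by
#' `|log2(RQ)|` descending with a lexicographic miRNA-id tie-break.
#'
#' @param dct delta-Ct table from [normalizeCt()].
#' @param calls detection table from [callDetection()].
#' @param config a [quantConfig()].
#' @return `data.frame` with columns `mirna_id`, `dct_control`,
#'   `dct_treated`, `ddct`, `rel_quantity`, `direction`, `status`
#'   (restricted to `status == "common"`).
#' @examples
#' dct <- data.frame(mirna_id = c("a", "b"), dct_control = c(5, 2),
#'                   dct_treated = c(2, 2))
#' calls <- data.frame(mirna_id = c("a", "b"),
#'                     status = c("common", "common"))
#' differentialExpression(dct, calls, quantConfig())
#' @export
differentialExpression <- function(dct, calls, config = quantConfig()) {
    stopifnot(methods::is(config, "QuantConfig"))
    common <- calls$mirna_id[calls$status == "common"]
    missing <- setdiff(common, dct$mirna_id)
    if (length(missing)) {
        warning("skipping ", length(missing),
                " common assay(s) absent from the delta-Ct table: ",
                paste(utils::head(missing, 5), collapse = ", "))
        common <- setdiff(common, missing)
    }
    d <- dct[match(common, dct$mirna_id), , drop = FALSE]
    ddct <- d$dct_treated - d$dct_control
    rq <- 2^(-ddct)
    direction <- ifelse(rq >= config@foldUp, "up",
                 ifelse(rq <= config@foldDown, "down", "unchanged"))
    out <- data.frame(mirna_id = d$mirna_id,
                      dct_control = d$dct_control,
                      dct_treated = d$dct_treated,
                      ddct = ddct, rel_quantity = rq,
                      direction = direction, status = "common",
                      stringsAsFactors = FALSE)
    ord <- order(-abs(log2(out$rel_quantity)), out$mirna_id)
    out <- out[ord, , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Venn decomposition of detection classes
#'
#' Counts the commonly expressed, control-only and treated-only assays;
#' undetected assays are excluded from the diagram (the four classes always
#' partition the assay list).
#'
#' @param calls detection table from [callDetection()].
#' @return named integer vector with elements `n_common`, `n_control_only`,
#'   `n_treated_only`.
#' @export
vennDecompose <- function(calls) {
    if (anyDuplicated(calls$mirna_id))
        stop("duplicate assay id(s) in detection calls: ",
             paste(unique(calls$mirna_id[duplicated(calls$mirna_id)]),
                   collapse = ", "))
    c(n_common = sum(calls$status == "common"),
      n_control_only = sum(calls$status == "control_only"),
      n_treated_only = sum(calls$status == "treated_only"))
}
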